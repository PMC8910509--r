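#' Land-use grid and zone map containers
#'
#' A `lu_grid` is a single-band categorical raster for one calendar year:
#' an integer matrix of land class codes (row-major, origin top-left) plus
#' the per-cell area in hm² and a nodata code. A `zone_map` is an integer
#' raster of zone (county) labels aligned cell-for-cell to the grids it
#' partitions, with a lookup of zone names.
#'
#' @param codes integer matrix of class codes (values in 1..7 or `nodata`).
#' @param year calendar year the grid describes.
#' @param cell_area area of one cell in hm² (default 100, i.e. 1 km²).
#' @param nodata integer code marking unclassified cells (default 0).
#' @return `lu_grid()` an object of class `lu_grid`; `zone_map()` an object
#'   of class `zone_map`.
#' @examples
#' g <- lu_grid(matrix(c(1L, 1L, 2L, 4L), 2, 2), year = 2000)
#' g
#' @export
lu_grid <- function(codes, year, cell_area = 100, nodata = 0L) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (any(dim(codes) < 2)) stop("degenerate grid: both dimensions must be >= 2")
  if (!is.numeric(cell_area) || cell_area <= 0) stop("cell_area must be > 0")
  vals <- codes[codes != nodata & !is.na(codes)]
  bad <- setdiff(unique(vals), unname(land_classes()))
  if (length(bad)) {
    stop("codes outside 1..7 present: ", paste(sort(bad), collapse = ", "),
         " (reclassify first)")
  }
  structure(
    list(codes = codes, year = as.integer(year),
         cell_area = as.numeric(cell_area), nodata = as.integer(nodata)),
    class = "lu_grid"
  )
}

#' @param labels integer matrix of zone labels (>= 1; `nodata` allowed).
#' @param names optional character vector naming zones, indexed by label.
#' @rdname lu_grid
#' @export
zone_map <- function(labels, names = NULL, nodata = 0L) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  ids <- sort(unique(labels[labels != nodata & !is.na(labels)]))
  if (is.null(names)) names <- paste0("zone_", ids)
  structure(
    list(labels = labels, ids = ids,
         names = stats::setNames(names, ids), nodata = as.integer(nodata)),
    class = "zone_map"
  )
}

#' @export
print.lu_grid <- function(x, ...) {
  cat(sprintf("<lu_grid %d> %d x %d cells, %.0f hm2/cell\n",
              x$year, nrow(x$codes), ncol(x$codes), x$cell_area))
  tab <- table(factor(x$codes[x$codes != x$nodata],
                      levels = unname(land_classes()),
                      labels = names(land_classes())))
  print(tab)
  invisible(x)
}

#' @export
print.zone_map <- function(x, ...) {
  cat(sprintf("<zone_map> %d x %d cells, %d zones\n",
              nrow(x$labels), ncol(x$labels), length(x$ids)))
  invisible(x)
}

check_aligned <- function(a, b) {
  da <- dim(if (inherits(a, "lu_grid")) a$codes else a$labels)
  db <- dim(if (inherits(b, "lu_grid")) b$codes else b$labels)
  if (!identical(da, db)) {
    stop("shape mismatch: ", paste(da, collapse = "x"), " vs ",
         paste(db, collapse = "x"))
  }
  invisible(TRUE)
}

#' Read and write single-band integer rasters as ESRI ASCII grid
#'
#' Plain-text raster exchange format (`ncols`/`nrows`/`xllcorner`/`yllcorner`/
#' `cellsize`/`NODATA_value` header followed by rows of cell values, top row
#' first). Used for land-use and zone rasters so that runs are fully
#' text-based and diffable.
#'
#' @param path file path.
#' @param m integer matrix to write (top raster row = first matrix row).
#' @param cellsize cell edge length written to the header (map units).
#' @param nodata nodata code.
#' @return `read_ascii_grid()` returns a list with `matrix`, `cellsize` and
#'   `nodata`; `write_ascii_grid()` returns `path` invisibly.
#' @export
write_ascii_grid <- function(m, path, cellsize = 1000, nodata = 0L) {
  m <- as.matrix(m)
  hdr <- c(
    paste("ncols", ncol(m)), paste("nrows", nrow(m)),
    paste("xllcorner", 0), paste("yllcorner", 0),
    paste("cellsize", cellsize), paste("NODATA_value", nodata)
  )
  body <- apply(m, 1L, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, "", 1L))
  vals <- as.numeric(vapply(hdr, `[`, "", 2L))
  names(vals) <- keys
  need <- c("ncols", "nrows", "cellsize", "nodata_value")
  if (!all(need %in% keys)) stop("not an ESRI ASCII grid: ", path)
  body <- lines[-(1:6)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != vals[["nrows"]]) stop("row count mismatch in ", path)
  m <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.integer))
  if (ncol(m) != vals[["ncols"]]) stop("column count mismatch in ", path)
  list(matrix = m, cellsize = vals[["cellsize"]],
       nodata = as.integer(vals[["nodata_value"]]))
}
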