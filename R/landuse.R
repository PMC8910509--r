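#' Reclassify raw land-use codes to the seven-class scheme
#'
#' Collapses a raw categorical raster (e.g. the 19+ CNLUCC level-2 codes) to
#' the seven analysis classes via an explicit lookup. The default lookup
#' shipped with the package (`system.file("extdata/cnlucc_reclass.csv")`)
#' follows the CNLUCC first-digit convention with swamp/marsh and
#' flat/shoal codes mapped to wetland; it is an editable CSV.
#'
#' @param raw integer matrix of raw codes.
#' @param mapping data frame with columns `raw_code`, `class_code`, or a
#'   named integer vector (names = raw codes). Must cover every observed
#'   non-nodata code.
#' @param year,cell_area,nodata passed to [lu_grid()].
#' @return a [lu_grid()].
#' @export
reclassify <- function(raw, mapping, year, cell_area = 100, nodata = 0L) {
  raw <- as.matrix(raw)
  storage.mode(raw) <- "integer"
  if (is.data.frame(mapping)) {
    map <- stats::setNames(as.integer(mapping$class_code),
                           as.character(mapping$raw_code))
  } else {
    map <- stats::setNames(as.integer(mapping), names(mapping))
  }
  obs <- unique(raw[raw != nodata & !is.na(raw)])
  missing <- setdiff(as.character(obs), names(map))
  if (length(missing)) {
    stop("unmapped raw code(s): ", paste(sort(as.integer(missing)), collapse = ", "))
  }
  out <- raw
  idx <- raw != nodata & !is.na(raw)
  out[idx] <- map[as.character(raw[idx])]
  lu_grid(out, year = year, cell_area = cell_area, nodata = nodata)
}

#' @rdname reclassify
#' @export
default_reclass_mapping <- function() {
  read.csv(system.file("extdata", "cnlucc_reclass.csv", package = "esvland"))
}

new_area_table <- function(df) {
  df <- tibble::as_tibble(df)
  class(df) <- c("area_table", class(df))
  df
}

#' Tabulate land-class areas per zone
#'
#' Cross-tabulates a classified grid against a zone map and converts cell
#' counts to areas (count × cell area). Every (zone, class) pair is present
#' in the output, zero-filled where a class does not occur in a zone.
#'
#' @param grid a [lu_grid()].
#' @param zones a [zone_map()] aligned to `grid`. Omit for a single
#'   whole-grid zone.
#' @return a tibble of class `area_table` with columns `year`, `zone`,
#'   `class` (abbreviation) and `area_hm2`.
#' @export
tabulate_areas <- function(grid, zones = NULL) {
  stopifnot(inherits(grid, "lu_grid"))
  if (is.null(zones)) {
    zones <- zone_map(matrix(1L, nrow(grid$codes), ncol(grid$codes)),
                      names = "all")
  }
  check_aligned(grid, zones)
  keep <- grid$codes != grid$nodata & zones$labels != zones$nodata
  cls <- factor(grid$codes[keep], levels = unname(land_classes()),
                labels = names(land_classes()))
  zn <- factor(zones$labels[keep], levels = zones$ids)
  counts <- table(zone = zn, class = cls)
  df <- as.data.frame(counts, responseName = "n")
  new_area_table(tibble::tibble(
    year = grid$year,
    zone = as.integer(as.character(df$zone)),
    class = as.character(df$class),
    area_hm2 = df$n * grid$cell_area
  ))
}

#' Land-use transition matrix between two years
#'
#' Cell-wise cross-tabulation of two aligned grids, scaled to area. The
#' diagonal holds unchanged area; row marginals reproduce the from-year
#' class areas and column marginals the to-year areas.
#'
#' @param a,b two aligned [lu_grid()]s with `a$year < b$year`.
#' @param zones optional [zone_map()]; when given, a matrix is returned per
#'   zone (a named list).
#' @return a `transition_matrix`: 7×7 numeric matrix (hm²) with attributes
#'   `from_year`/`to_year`, or a list of them per zone.
#' @export
transition_matrix <- function(a, b, zones = NULL) {
  stopifnot(inherits(a, "lu_grid"), inherits(b, "lu_grid"))
  check_aligned(a, b)
  if (a$year >= b$year) stop("a$year must precede b$year")
  if (a$cell_area != b$cell_area) stop("cell_area differs between grids")
  lv <- land_classes()
  xtab_area <- function(keep) {
    fa <- factor(a$codes[keep], levels = unname(lv), labels = names(lv))
    fb <- factor(b$codes[keep], levels = unname(lv), labels = names(lv))
    m <- table(from = fa, to = fb) * a$cell_area
    m <- unclass(m)
    structure(m, from_year = a$year, to_year = b$year,
              class = c("transition_matrix", "matrix"))
  }
  keep <- a$codes != a$nodata & b$codes != b$nodata
  if (is.null(zones)) return(xtab_area(keep))
  check_aligned(a, zones)
  out <- lapply(zones$ids, function(z) xtab_area(keep & zones$labels == z))
  stats::setNames(out, zones$names[as.character(zones$ids)])
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix %d -> %d> (hm2)\n",
              attr(x, "from_year"), attr(x, "to_year")))
  print(unclass(x))
  invisible(x)
}

#' Single land-use dynamic degree
#'
#' Annualized relative change of one land class over a study period:
#' `K = (Lb - La) / max(La, zero_floor) / H * 100` (percent per year), where
#' `La` and `Lb` are the class areas at the start and end of the period and
#' `H` the period length in years. A class absent at the start would make
#' the ratio undefined, so the start area is floored at `zero_floor`
#' (default 100 hm² = 1 km², the conventional assumption for a class
#' emerging from zero).
#'
#' @param la,lb start and end areas (same units), vectorized.
#' @param horizon period length H in years.
#' @param zero_floor minimum start area used as denominator.
#' @return dynamic degree K in percent per year.
#' @examples
#' dynamic_degree(100, 100, 18)        # 0
#' dynamic_degree(0, 600, 18)          # emerging class, floored denominator
#' @export
dynamic_degree <- function(la, lb, horizon, zero_floor = 100) {
  if (!is.numeric(horizon) || any(horizon <= 0)) stop("horizon must be > 0")
  if (any(la < 0) || any(lb < 0)) stop("areas must be non-negative")
  (lb - la) / pmax(la, zero_floor) / horizon * 100
}

#' Dynamic degree for every class (and optionally zone) of an area table
#'
#' @param areas an `area_table` (see [tabulate_areas()]).
#' @param from_year,to_year the two years compared.
#' @param horizon period length; default `to_year - from_year`.
#' @param by_zone compute per zone rather than over summed zones.
#' @inheritParams dynamic_degree
#' @return tibble with `class` (and `zone` if `by_zone`), `la`, `lb`, `K`.
#' @export
dynamic_degree_table <- function(areas, from_year, to_year,
                                 horizon = to_year - from_year,
                                 zero_floor = 100, by_zone = FALSE) {
  stopifnot(all(c(from_year, to_year) %in% areas$year))
  grp <- if (by_zone) c("zone", "class") else "class"
  wide <- areas |>
    dplyr::filter(.data$year %in% c(from_year, to_year)) |>
    dplyr::summarise(area_hm2 = sum(.data$area_hm2),
                     .by = dplyr::all_of(c("year", grp))) |>
    tidyr::pivot_wider(names_from = "year", values_from = "area_hm2",
                       values_fill = 0)
  wide |>
    dplyr::mutate(la = .data[[as.character(from_year)]],
                  lb = .data[[as.character(to_year)]],
                  K = dynamic_degree(.data$la, .data$lb, horizon, zero_floor)) |>
    dplyr::select(dplyr::all_of(grp), "la", "lb", "K")
}
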