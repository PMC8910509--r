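#' Load the vendored valuation fixtures
#'
#' Reads the machine-readable copies of the published constants shipped under
#' `inst/extdata/`: the per-hectare ESV coefficient matrix (7 land classes ×
#' 9 service functions, yuan/hm²), the ESV-by-function-by-class table for the
#' four study years (billion yuan, as printed), the anthropogenic disturbance
#' coefficients Pi, and the back-derived per-year land areas (see
#' `scripts/derive_implied_areas.R`). File integrity is checked against the
#' vendored MD5 checksums at load time.
#'
#' @return a list of class `paper_fixtures` with elements
#' \describe{
#'   \item{coefficients}{[esv_coefficients()] matrix, yuan/hm².}
#'   \item{esv_table}{tibble `(class, year, function, billion_yuan)` —
#'     bit-identical to the vendored CSV.}
#'   \item{implied_areas}{`area_table` of back-derived areas (hm²), one row
#'     per (year, class) for the five valued classes, `zone = 1`.}
#'   \item{pi}{named numeric vector of disturbance coefficients per class.}
#'   \item{standard_equivalent}{value of one standard equivalence unit,
#'     1793.88 yuan/hm².}
#'   \item{total_area_km2}{study area, 60500 km².}
#'   \item{study_years}{2000, 2005, 2010, 2018.}
#'   \item{horizon}{study period H = 18 years.}
#' }
#' @examples
#' fx <- load_fixtures()
#' fx$coefficients["WO", "RM"]
#' @export
load_fixtures <- function() {
  dir <- system.file("extdata", package = "esvland")
  files <- c("table1_coefficients.csv", "table2_esv.csv",
             "pi_coefficients.csv", "implied_areas.csv")
  verify_checksums(dir, files)

  coef_df <- read.csv(file.path(dir, "table1_coefficients.csv"),
                      check.names = FALSE)
  coef <- as.matrix(coef_df[, service_functions()])
  rownames(coef) <- coef_df$class
  coef <- esv_coefficients(coef[names(land_classes()), ])

  t2 <- tibble::as_tibble(read.csv(file.path(dir, "table2_esv.csv"),
                                   check.names = FALSE))
  esv_long <- tidyr::pivot_longer(t2, dplyr::all_of(service_functions()),
                                  names_to = "function",
                                  values_to = "billion_yuan")

  pi_df <- read.csv(file.path(dir, "pi_coefficients.csv"))
  pi <- stats::setNames(pi_df$pi, pi_df$class)[names(land_classes())]

  ia <- read.csv(file.path(dir, "implied_areas.csv"), check.names = FALSE)
  implied <- new_area_table(tibble::tibble(
    year = ia$year, zone = 1L, class = ia$class, area_hm2 = ia$area_hm2
  ))

  structure(list(
    coefficients = coef,
    esv_table = esv_long,
    implied_areas = implied,
    pi = pi,
    standard_equivalent = 1793.88,
    total_area_km2 = 60500,
    study_years = c(2000L, 2005L, 2010L, 2018L),
    horizon = 18L
  ), class = "paper_fixtures")
}

verify_checksums <- function(dir, files) {
  sumfile <- file.path(dir, "checksums.md5")
  if (!file.exists(sumfile)) stop("fixture checksum file missing: ", sumfile)
  expected <- read.table(sumfile, col.names = c("md5", "file"),
                         stringsAsFactors = FALSE)
  for (f in files) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("fixture file missing: ", f)
    want <- expected$md5[expected$file == f]
    if (length(want) != 1L) stop("no checksum recorded for fixture: ", f)
    got <- unname(tools::md5sum(path))
    if (!identical(got, want)) stop("fixture corrupted (md5 mismatch): ", f)
  }
  invisible(TRUE)
}

#' Convert the printed valuation fixture to the internal ESV table
#'
#' The fixture stores billions of yuan as printed; internally all money is in
#' yuan. The whole study area is treated as a single zone (`zone = 1`).
#'
#' @param fixtures result of [load_fixtures()] (or any tibble shaped like its
#'   `esv_table` element).
#' @return an [esv_table] (columns `year`, `zone`, `class`, `function`,
#'   `yuan`) with provenance `"fixture"`.
#' @export
fixture_esv_table <- function(fixtures = load_fixtures()) {
  tab <- if (inherits(fixtures, "paper_fixtures")) fixtures$esv_table else fixtures
  stopifnot(all(c("class", "year", "function", "billion_yuan") %in% names(tab)))
  new_esv_table(tibble::tibble(
    year = as.integer(tab$year),
    zone = 1L,
    class = tab$class,
    "function" = tab[["function"]],
    yuan = tab$billion_yuan * 1e9
  ), provenance = "fixture")
}

#' @export
print.paper_fixtures <- function(x, ...) {
  cat("<paper_fixtures>\n",
      " coefficients: 7 classes x 9 functions (yuan/hm2)\n",
      sprintf("  esv_table: %d cells over years %s (billion yuan)\n",
              nrow(x$esv_table), paste(x$study_years, collapse = ", ")),
      sprintf("  standard equivalent: %.2f yuan/hm2; study area %d km2; H = %d\n",
              x$standard_equivalent, x$total_area_km2, x$horizon))
  invisible(x)
}
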