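#' Human impact index per zone and year
#'
#' Area-weighted mean of per-class anthropogenic disturbance coefficients:
#' `HAI = sum_i(Bi * Pi) / TA`, where `Bi` is the area of class i in the
#' zone, `Pi` its disturbance coefficient and `TA` the zone's total
#' classified area. By construction HAI lies between the smallest and
#' largest Pi (here 0.05 and 0.96) and is invariant to uniform rescaling of
#' a zone's areas. Zones with no classified area are skipped with a warning.
#'
#' @param areas an `area_table` (see [tabulate_areas()]).
#' @param pi named numeric vector of disturbance coefficients per class
#'   abbreviation; defaults to the study coefficients shipped with the
#'   package fixtures.
#' @return tibble with `zone`, `year`, `hai`, `band` (see [classify_hai()]).
#' @examples
#' fx <- load_fixtures()
#' compute_hai(fx$implied_areas, fx$pi)
#' @export
compute_hai <- function(areas, pi = load_fixtures()$pi) {
  bad <- setdiff(unique(areas$class), names(pi))
  if (length(bad)) stop("no Pi coefficient for class(es): ",
                        paste(bad, collapse = ", "))
  out <- areas |>
    dplyr::summarise(
      ta = sum(.data$area_hm2),
      weighted = sum(.data$area_hm2 * pi[.data$class]),
      .by = c("zone", "year")
    )
  empty <- out$ta <= 0
  if (any(empty)) {
    warning(sum(empty), " zone-year(s) with zero classified area skipped")
    out <- out[!empty, ]
  }
  out |>
    dplyr::mutate(hai = .data$weighted / .data$ta,
                  band = classify_hai(.data$hai)) |>
    dplyr::select("zone", "year", "hai", "band") |>
    dplyr::arrange(.data$year, .data$zone)
}

#' Disturbance intensity bands
#'
#' Classifies HAI values into the three conventional bands: `high` for
#' HAI > 0.5, `medium` for 0.35 <= HAI <= 0.5 (both boundaries inclusive),
#' `low` for HAI < 0.35.
#'
#' @param hai numeric vector in \[0, 1\].
#' @return character vector (`"high"`, `"medium"`, `"low"`).
#' @examples
#' classify_hai(c(0.349, 0.35, 0.5, 0.501))
#' @export
classify_hai <- function(hai) {
  if (any(hai < 0 | hai > 1, na.rm = TRUE)) {
    stop("hai values must lie in [0, 1]")
  }
  dplyr::case_when(
    hai > 0.5 ~ "high",
    hai >= 0.35 ~ "medium",
    .default = "low"
  )
}
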