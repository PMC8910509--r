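#' ESV coefficient matrix
#'
#' Per-hectare monetary value of each service function delivered by each land
#' class (yuan/hm²), the product of dimensionless equivalence factors and the
#' standard equivalent value. Construction land delivers no services and
#' must carry an all-zero row.
#'
#' @param values 7×9 numeric matrix, rows named by land class abbreviation,
#'   columns by service function abbreviation.
#' @param eb value of one standard equivalence unit (yuan/hm²), stored as an
#'   attribute for reference.
#' @return numeric matrix of class `esv_coefficients`.
#' @export
esv_coefficients <- function(values, eb = NA_real_) {
  values <- as.matrix(values)
  if (!setequal(rownames(values), names(land_classes())) ||
      !setequal(colnames(values), service_functions())) {
    stop("coefficients must be a 7 class x 9 function matrix with named dims")
  }
  values <- values[names(land_classes()), service_functions()]
  if (any(values < 0)) stop("coefficients must be non-negative")
  if (any(values["CO", ] != 0)) stop("construction land (CO) row must be all zero")
  structure(values, eb = eb, class = c("esv_coefficients", "matrix"))
}

#' Standard equivalence unit from crop statistics
#'
#' The value of one ESV equivalence unit is the area-weighted mean net profit
#' of the three staple crops: `V = R1*V1 + R2*V2 + R3*V3`, with `Ri` the
#' share of crop i in the combined sown area and `Vi` its net profit per
#' hm². Provided for users with their own crop statistics; the study-period
#' default used elsewhere in the package is 1793.88 yuan/hm².
#'
#' @param shares length-3 non-negative crop area shares (wheat, corn, rice),
#'   summing to 1 within ±0.01.
#' @param profits length-3 net profits (yuan/hm²).
#' @return V in yuan/hm².
#' @export
standard_equivalent <- function(shares, profits) {
  stopifnot(length(shares) == 3, length(profits) == 3)
  if (any(shares < 0)) stop("shares must be non-negative")
  s <- sum(shares)
  if (s < 0.99 || s > 1.01) stop("crop shares must sum to 1 (got ", signif(s, 4), ")")
  sum(shares * profits)
}

#' Build the coefficient matrix from equivalence factors
#'
#' @param factors 7×9 matrix of dimensionless equivalence factors (class ×
#'   function).
#' @param eb standard equivalent value in yuan/hm² (default the study value).
#' @return an [esv_coefficients()] matrix `factors * eb`.
#' @export
build_coefficients <- function(factors, eb = 1793.88) {
  factors <- as.matrix(factors)
  if (any(factors < 0)) stop("equivalence factors must be non-negative")
  esv_coefficients(factors * eb, eb = eb)
}

new_esv_table <- function(df, provenance = "computed") {
  df <- tibble::as_tibble(df)
  attr(df, "provenance") <- provenance
  class(df) <- c("esv_table", class(df))
  df
}

#' Compute ecosystem service values from areas
#'
#' The core valuation: every (year, zone, class, function) cell is
#' `area (hm²) × coefficient (yuan/hm²)`; totals are sums of cells.
#'
#' @param areas an `area_table` (see [tabulate_areas()]).
#' @param coef an [esv_coefficients()] matrix.
#' @return an [esv_table]: tibble with `year`, `zone`, `class`, `function`,
#'   `yuan`, provenance `"computed"`.
#' @export
compute_esv <- function(areas, coef) {
  stopifnot(inherits(coef, "esv_coefficients"))
  bad <- setdiff(unique(areas$class), rownames(coef))
  if (length(bad)) stop("class present in areas but absent from coefficients: ",
                        paste(bad, collapse = ", "))
  cf <- as.data.frame(as.table(unclass(coef)), stringsAsFactors = FALSE)
  names(cf) <- c("class", "function", "coef")
  out <- areas |>
    dplyr::inner_join(cf, by = "class", relationship = "many-to-many") |>
    dplyr::mutate(yuan = .data$area_hm2 * .data$coef) |>
    dplyr::select("year", "zone", "class", "function", "yuan") |>
    dplyr::arrange(.data$year, .data$zone, .data$class, .data$`function`)
  new_esv_table(out)
}

#' Recover areas from an ESV table
#'
#' Inverse of [compute_esv()]: for each (year, zone, class) the function with
#' the largest monetary value is divided by its coefficient. On computed
#' tables this recovers areas exactly; on printed (rounded) tables the
#' largest cell minimizes relative rounding error. Classes whose coefficient
#' row is all zero (construction land) are skipped with a warning.
#'
#' @param esv an [esv_table] (yuan).
#' @param coef an [esv_coefficients()] matrix.
#' @return an `area_table` (`year`, `zone`, `class`, `area_hm2`).
#' @export
infer_areas <- function(esv, coef) {
  stopifnot(inherits(coef, "esv_coefficients"))
  zero_rows <- rownames(coef)[rowSums(unclass(coef)) == 0]
  skipped <- intersect(unique(esv$class), zero_rows)
  if (length(skipped)) {
    warning("class(es) with all-zero coefficients skipped: ",
            paste(skipped, collapse = ", "))
  }
  cf <- as.data.frame(as.table(unclass(coef)), stringsAsFactors = FALSE)
  names(cf) <- c("class", "function", "coef")
  out <- esv |>
    dplyr::filter(!.data$class %in% zero_rows) |>
    dplyr::inner_join(cf, by = c("class", "function")) |>
    dplyr::filter(.data$coef > 0) |>
    dplyr::slice_max(.data$yuan, n = 1, with_ties = FALSE,
                     by = c("year", "zone", "class")) |>
    dplyr::mutate(area_hm2 = .data$yuan / .data$coef) |>
    dplyr::select("year", "zone", "class", "area_hm2") |>
    dplyr::arrange(.data$year, .data$zone, .data$class)
  new_area_table(out)
}

#' Summarize an ESV table
#'
#' Produces the standard reporting set: per-year totals; per-class and
#' per-function totals with within-year shares; multi-year mean shares;
#' and absolute deltas plus relative growth rates between two years
#' (`delta / value_in_from_year`).
#'
#' @param esv an [esv_table] (yuan).
#' @param from_year,to_year years compared for deltas/growth (defaults: first
#'   and last year present).
#' @return list of class `esv_summary` with tibbles `year_totals`,
#'   `class_totals`, `function_totals`, `class_share_mean`,
#'   `function_share_mean`, `class_change`, `function_change`, and scalars
#'   `total_delta_yuan`, `from_year`, `to_year`. Shares are percentages.
#' @export
summarize_esv <- function(esv, from_year = NULL, to_year = NULL) {
  years <- sort(unique(esv$year))
  if (is.null(from_year)) from_year <- years[1]
  if (is.null(to_year)) to_year <- years[length(years)]
  if (!all(c(from_year, to_year) %in% years)) {
    stop("requested year(s) absent from table: ",
         paste(setdiff(c(from_year, to_year), years), collapse = ", "))
  }

  year_totals <- esv |>
    dplyr::summarise(yuan = sum(.data$yuan), .by = "year") |>
    dplyr::arrange(.data$year)

  by_dim <- function(dim) {
    esv |>
      dplyr::summarise(yuan = sum(.data$yuan), .by = dplyr::all_of(c("year", dim))) |>
      dplyr::mutate(share_pct = .data$yuan / sum(.data$yuan) * 100,
                    .by = "year") |>
      dplyr::arrange(.data$year, dplyr::desc(.data$yuan))
  }
  class_totals <- by_dim("class")
  function_totals <- by_dim("function")

  mean_share <- function(tot, dim) {
    tot |>
      dplyr::summarise(mean_share_pct = mean(.data$share_pct),
                       .by = dplyr::all_of(dim)) |>
      dplyr::arrange(dplyr::desc(.data$mean_share_pct))
  }

  change <- function(tot, dim) {
    tot |>
      dplyr::filter(.data$year %in% c(from_year, to_year)) |>
      dplyr::select(dplyr::all_of(c("year", dim)), "yuan") |>
      tidyr::pivot_wider(names_from = "year", values_from = "yuan",
                         values_fill = 0) |>
      dplyr::mutate(
        delta_yuan = .data[[as.character(to_year)]] -
          .data[[as.character(from_year)]],
        growth_pct = ifelse(.data[[as.character(from_year)]] > 0,
                            .data$delta_yuan /
                              .data[[as.character(from_year)]] * 100, NA_real_)
      ) |>
      dplyr::arrange(dplyr::desc(.data$delta_yuan))
  }

  structure(list(
    year_totals = year_totals,
    class_totals = class_totals,
    function_totals = function_totals,
    class_share_mean = mean_share(class_totals, "class"),
    function_share_mean = mean_share(function_totals, "function"),
    class_change = change(class_totals, "class"),
    function_change = change(function_totals, "function"),
    total_delta_yuan = year_totals$yuan[year_totals$year == to_year] -
      year_totals$yuan[year_totals$year == from_year],
    from_year = from_year, to_year = to_year
  ), class = "esv_summary")
}

#' @export
print.esv_summary <- function(x, ...) {
  bn <- function(v) sprintf("%.2f", v / 1e9)
  cat("== ESV summary ==\n\nTotals (billion yuan):\n")
  for (i in seq_len(nrow(x$year_totals))) {
    cat(sprintf("  %d  %s\n", x$year_totals$year[i], bn(x$year_totals$yuan[i])))
  }
  cat(sprintf("\nChange %d -> %d: %s billion yuan\n", x$from_year, x$to_year,
              bn(x$total_delta_yuan)))
  cat("\nMean class shares (%):\n")
  s <- x$class_share_mean
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-3s %6.2f\n", s$class[i], s$mean_share_pct[i]))
  }
  cat("\nMean function shares (%):\n")
  s <- x$function_share_mean
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-4s %6.2f\n", s[["function"]][i], s$mean_share_pct[i]))
  }
  invisible(x)
}
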