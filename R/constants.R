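#' Land class and service function vocabularies
#'
#' Seven land classes follow a fixed integer coding used everywhere in the
#' package (rasters, tables, matrices): CL cultivated land = 1, WO forestland
#' = 2, GL grassland = 3, WA water area = 4, CO construction land = 5,
#' UL unused land = 6, WL wetland = 7. The nine ecosystem service functions
#' are FP food production, RM raw material, GR gas regulation, CR climate
#' regulation, WS water supply (water conservation), WD waste treatment,
#' SFR soil formation and retention, BD biodiversity protection, EC
#' recreation and culture.
#'
#' @return `land_classes()` returns a named integer vector (names are class
#'   abbreviations, values the raster codes); `service_functions()` a
#'   character vector of the nine function abbreviations.
#' @examples
#' land_classes()
#' service_functions()
#' @export
land_classes <- function() {
  c(CL = 1L, WO = 2L, GL = 3L, WA = 4L, CO = 5L, UL = 6L, WL = 7L)
}

#' @rdname land_classes
#' @export
service_functions <- function() {
  c("FP", "RM", "GR", "CR", "WS", "WD", "SFR", "BD", "EC")
}

#' @rdname land_classes
#' @export
driver_features <- function() {
  c("HAI", "GPP", "Slope", "DEM", "POP", "Temp", "GDP", "Pre", "PM")
}

class_name_from_code <- function(code) {
  lc <- land_classes()
  out <- names(lc)[match(code, lc)]
  if (anyNA(out) && !anyNA(code)) {
    stop("unknown land class code(s): ",
         paste(unique(code[is.na(out)]), collapse = ", "))
  }
  out
}

class_code_from_name <- function(name) {
  lc <- land_classes()
  out <- unname(lc[match(name, names(lc))])
  if (anyNA(out)) {
    stop("unknown land class abbreviation(s): ",
         paste(unique(name[is.na(match(name, names(lc)))]), collapse = ", "))
  }
  out
}

# 1 km^2 = 100 hm^2; all internal areas are hm^2, money in yuan
KM2_TO_HM2 <- 100
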