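# small scenario used across tests: fast to generate, all 7 classes present
small_scenario <- function(seed = 1, n_zones = 6, grid = c(40, 40), ...) {
  landscape_scenario(seed = seed, grid_shape = grid, n_zones = n_zones, ...)
}

# hand-built tree ensembles in the package's flat node layout, bypassing
# xgboost entirely; usable with predict(use_trees = TRUE), shapley_values()
# and brute_force_shapley()
manual_model <- function(trees, features, base_score = 0) {
  flat <- list(feature = integer(0), threshold = numeric(0),
               yes = integer(0), no = integer(0), value = numeric(0),
               roots = integer(0))
  for (tr in trees) {
    off <- length(flat$feature)
    flat$roots <- c(flat$roots, off)
    flat$feature <- c(flat$feature, tr$feature)
    flat$threshold <- c(flat$threshold, tr$threshold)
    flat$yes <- c(flat$yes, ifelse(tr$yes < 0, -1L, tr$yes + off))
    flat$no <- c(flat$no, ifelse(tr$no < 0, -1L, tr$no + off))
    flat$value <- c(flat$value, tr$value)
  }
  structure(list(trees = flat, features = features, base_score = base_score,
                 params = list(max_depth = NA), nrounds = length(trees)),
            class = "esv_ensemble")
}

# stump: f(x) = left if x[feature] < threshold else right
stump <- function(feature0, threshold, left, right) {
  list(feature = c(feature0, -1L, -1L), threshold = c(threshold, 0, 0),
       yes = c(1L, -1L, -1L), no = c(2L, -1L, -1L),
       value = c(0, left, right))
}

leaf_tree <- function(value) {
  list(feature = -1L, threshold = 0, yes = -1L, no = -1L, value = value)
}

# area table built directly (hm2), single year/zone unless given
toy_areas <- function(areas, year = 2000, zone = 1) {
  tibble::tibble(year = year, zone = zone, class = names(areas),
                 area_hm2 = unname(areas))
}
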