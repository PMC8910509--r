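#' Assemble the county-level driver table
#'
#' Joins zone ESV totals (the response), the human impact index and the
#' remaining driver covariates into one modeling table with a fixed,
#' recorded column order. Rows missing any driver are dropped with a
#' warning.
#'
#' @param esv an [esv_table] (yuan); the response is the per-(zone, year)
#'   total.
#' @param hai output of [compute_hai()].
#' @param drivers tibble `(zone, year, GPP, DEM, Slope, POP, GDP, Temp,
#'   Pre, PM)`, e.g. from [generate_drivers()].
#' @return tibble `(zone, year, HAI, GPP, Slope, DEM, POP, Temp, GDP, Pre,
#'   PM, ESV)`.
#' @export
assemble_driver_table <- function(esv, hai, drivers) {
  resp <- esv |>
    dplyr::summarise(ESV = sum(.data$yuan), .by = c("zone", "year"))
  tab <- resp |>
    dplyr::inner_join(hai[, c("zone", "year", "hai")], by = c("zone", "year")) |>
    dplyr::left_join(drivers, by = c("zone", "year"))
  names(tab)[names(tab) == "hai"] <- "HAI"
  feat <- driver_features()
  miss <- setdiff(feat, names(tab))
  if (length(miss)) stop("driver(s) absent from inputs: ",
                         paste(miss, collapse = ", "))
  ok <- stats::complete.cases(tab[, feat])
  if (!all(ok)) {
    warning(sum(!ok), " row(s) dropped: missing driver values")
    tab <- tab[ok, ]
  }
  tab[, c("zone", "year", feat, "ESV")]
}

#' Fit the gradient-boosted regression-tree ensemble
#'
#' Wraps `xgboost::xgb.train` (squared-error objective, exact greedy splits,
#' single thread) and parses the fitted trees into a flat table used by the
#' exact Shapley routines. The fit is deterministic given the seed; with
#' `subsample = 1` it is deterministic regardless. Defaults: 200 trees of
#' depth 3, learning rate 0.1, L2 penalty 1 — a conservative setting for
#' small county-level tables. The base score is fixed to the response mean.
#'
#' @param table driver table from [assemble_driver_table()] (or any data
#'   frame holding the feature columns and the response).
#' @param features feature column names, in the order recorded on the model.
#' @param response response column name.
#' @param nrounds,max_depth,eta,lambda,subsample boosting hyperparameters.
#' @param seed integer seed passed to xgboost.
#' @return object of class `esv_ensemble`: list with the fitted `booster`,
#'   parsed `trees`, `features`, `base_score`, training `r2`, `params`.
#' @export
fit_esv_model <- function(table, features = driver_features(),
                          response = "ESV", nrounds = 200, max_depth = 3,
                          eta = 0.1, lambda = 1, subsample = 1, seed = 1L) {
  miss <- setdiff(c(features, response), names(table))
  if (length(miss)) stop("column(s) absent from table: ",
                         paste(miss, collapse = ", "))
  X <- as.matrix(table[, features])
  if (!is.numeric(X)) stop("all feature columns must be numeric")
  if (anyNA(X)) stop("feature columns must not contain missing values")
  y <- table[[response]]
  if (anyNA(y)) stop("response must not contain missing values")

  params <- list(objective = "reg:squarederror", max_depth = max_depth,
                 eta = eta, lambda = lambda, subsample = subsample,
                 base_score = mean(y), tree_method = "exact", nthread = 1,
                 seed = as.integer(seed))
  dm <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  booster <- xgboost::xgb.train(params = params, data = dm,
                                nrounds = nrounds, verbose = 0)
  pred <- predict(booster, X)
  r2 <- if (stats::var(y) > 0) 1 - sum((y - pred)^2) / sum((y - mean(y))^2) else NA_real_

  structure(list(
    booster = booster,
    trees = parse_xgb_trees(booster, features),
    features = features, response = response,
    base_score = mean(y), r2 = r2, n = nrow(X),
    params = params, nrounds = nrounds, seed = as.integer(seed)
  ), class = "esv_ensemble")
}

# flatten the booster's JSON dump into parallel node arrays (0-based indices)
parse_xgb_trees <- function(booster, features) {
  txt <- xgboost::xgb.dump(booster, dump_format = "json")
  trees <- jsonlite::fromJSON(paste(txt, collapse = "\n"),
                              simplifyVector = FALSE)
  feature <- integer(0); threshold <- numeric(0)
  yes <- integer(0); no <- integer(0); value <- numeric(0)
  roots <- integer(length(trees))
  offset <- 0L
  for (t in seq_along(trees)) {
    nodes <- list(); collect <- function(nd) {
      nodes[[length(nodes) + 1L]] <<- nd
      for (ch in nd$children) collect(ch)
    }
    collect(trees[[t]])
    ids <- vapply(nodes, function(nd) nd$nodeid, 0)
    idx <- stats::setNames(seq_along(ids) - 1L + offset, ids)
    for (nd in nodes) {
      if (!is.null(nd$leaf)) {
        feature <- c(feature, -1L); threshold <- c(threshold, 0)
        yes <- c(yes, -1L); no <- c(no, -1L)
        value <- c(value, nd$leaf)
      } else {
        fi <- match(nd$split, features) - 1L
        if (is.na(fi)) stop("tree split on unknown feature: ", nd$split)
        feature <- c(feature, fi); threshold <- c(threshold, nd$split_condition)
        yes <- c(yes, idx[[as.character(nd$yes)]])
        no <- c(no, idx[[as.character(nd$no)]])
        value <- c(value, 0)
      }
    }
    roots[t] <- offset
    offset <- offset + length(nodes)
  }
  list(feature = feature, threshold = threshold, yes = yes, no = no,
       value = value, roots = roots)
}

#' @export
print.esv_ensemble <- function(x, ...) {
  cat(sprintf(
    "<esv_ensemble> %d trees (depth <= %d, eta %.2f, lambda %.1f), %d rows\n",
    x$nrounds, x$params$max_depth, x$params$eta, x$params$lambda, x$n))
  cat(sprintf("  features: %s\n  training R2 = %.4f\n",
              paste(x$features, collapse = ", "), x$r2))
  invisible(x)
}

#' Predict from a fitted ensemble
#'
#' @param object an `esv_ensemble`.
#' @param newdata data frame or matrix with the model's feature columns.
#' @param use_trees predict by traversing the parsed trees (the
#'   representation the Shapley routines attribute) instead of the xgboost
#'   booster; the two agree to float precision.
#' @param ... unused.
#' @export
predict.esv_ensemble <- function(object, newdata, use_trees = FALSE, ...) {
  X <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  storage.mode(X) <- "double"
  if (use_trees) {
    tr <- object$trees
    predict_trees_cpp(X, tr$feature, tr$threshold, tr$yes, tr$no, tr$value,
                      tr$roots, object$base_score)
  } else {
    predict(object$booster, X)
  }
}
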