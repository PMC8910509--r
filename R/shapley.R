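#' Exact interventional Shapley attributions for a tree ensemble
#'
#' Computes, for every row of `table`, the exact Shapley value of each
#' feature under the interventional value function
#' `v(S) = E_b[ f(x_S, b_{-S}) ]`, the expectation taken over the rows of a
#' background table (default: the table itself, i.e. the training
#' distribution). The computation enumerates, per tree and per
#' foreground/background pair, the hybrid root-to-leaf paths and applies the
#' closed-form Shapley weights of the induced unanimity games — exact, not
#' sampled, and equal to the classical subset-sum definition (see
#' [brute_force_shapley()], the independent oracle used in the tests).
#'
#' Local accuracy holds by construction: `base + sum(phi[i, ]) = f(x_i)` for
#' every instance, with `base = mean_b f(b)`.
#'
#' @param model an [fit_esv_model()] ensemble.
#' @param table data frame holding the model's feature columns (instances to
#'   explain).
#' @param background data frame of background rows defining the expectation
#'   (default `table`).
#' @return object of class `esv_attribution`: list with `phi` (instance ×
#'   feature matrix, response units), `base` (scalar expected prediction),
#'   `prediction` (per-instance model output), `features`, and the
#'   explained `table`.
#' @export
shapley_values <- function(model, table, background = table) {
  stopifnot(inherits(model, "esv_ensemble"))
  X <- feature_matrix(model, table)
  B <- feature_matrix(model, background)
  tr <- model$trees
  phi <- shap_interventional_cpp(X, B, tr$feature, tr$threshold, tr$yes,
                                 tr$no, tr$value, tr$roots)
  colnames(phi) <- model$features
  base <- mean(predict_trees_cpp(B, tr$feature, tr$threshold, tr$yes, tr$no,
                                 tr$value, tr$roots, model$base_score))
  pred <- predict_trees_cpp(X, tr$feature, tr$threshold, tr$yes, tr$no,
                            tr$value, tr$roots, model$base_score)
  structure(list(phi = phi, base = base, prediction = pred,
                 features = model$features,
                 table = tibble::as_tibble(table)),
            class = "esv_attribution")
}

feature_matrix <- function(model, table) {
  miss <- setdiff(model$features, colnames(table))
  if (length(miss)) stop("feature-set mismatch; table lacks: ",
                         paste(miss, collapse = ", "))
  X <- as.matrix(as.data.frame(table)[, model$features, drop = FALSE])
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("feature columns must not contain missing values")
  X
}

#' @export
print.esv_attribution <- function(x, ...) {
  cat(sprintf("<esv_attribution> %d instances x %d features, base = %.4g\n",
              nrow(x$phi), ncol(x$phi), x$base))
  print(importance_ranking(x))
  invisible(x)
}

# v(S) for every subset of model features at one instance:
# mean over background rows of the prediction on hybrid rows.
subset_values <- function(model, instance, background) {
  B <- feature_matrix(model, background)
  x <- as.numeric(feature_matrix(model, instance)[1L, ])
  p <- length(model$features)
  nb <- nrow(B)
  nsub <- bitwShiftL(1L, p)
  big <- B[rep(seq_len(nb), nsub), , drop = FALSE]
  for (s in 0:(nsub - 1L)) {
    rows <- s * nb + seq_len(nb)
    for (j in seq_len(p)) {
      if (bitwAnd(bitwShiftL(1L, j - 1L), s)) big[rows, j] <- x[j]
    }
  }
  pred <- predict(model, big, use_trees = TRUE)
  v <- colMeans(matrix(pred, nrow = nb))
  names(v) <- as.character(0:(nsub - 1L))
  v
}

#' Brute-force Shapley values by subset enumeration
#'
#' The classical Shapley definition evaluated literally:
#' `phi_j = sum_{S not containing j} |S|! (N-|S|-1)! / N! (v(S+j) - v(S))`,
#' with `v(S)` the expected model prediction when the features in `S` are
#' fixed to the instance and the rest are averaged over the background
#' rows. Cost grows as `2^N`; feature counts above 15 are refused. The
#' subset enumeration shares nothing with the path-enumeration algebra of
#' [shapley_values()] beyond the tree predictor itself, so the two routes
#' serve as mutual cross-checks.
#'
#' @param model an [fit_esv_model()] ensemble.
#' @param instance single-row data frame (the instance to explain).
#' @param background data frame of background rows.
#' @return named numeric vector of Shapley values with attribute `base`
#'   (`v(empty set)`).
#' @export
brute_force_shapley <- function(model, instance, background) {
  p <- length(model$features)
  if (p > 15) stop("brute force limited to 15 features (cost 2^N)")
  v <- subset_values(model, instance, background)
  phi <- stats::setNames(numeric(p), model$features)
  for (j in seq_len(p)) {
    bit <- bitwShiftL(1L, j - 1L)
    for (s in 0:(length(v) - 1L)) {
      if (bitwAnd(s, bit) == 0L) {
        size <- popcount(s)
        w <- factorial(size) * factorial(p - size - 1L) / factorial(p)
        phi[j] <- phi[j] + w * (v[[s + bit + 1L]] - v[[s + 1L]])
      }
    }
  }
  attr(phi, "base") <- unname(v[[1L]])
  phi
}

popcount <- function(x) {
  n <- 0L
  while (x > 0L) { n <- n + bitwAnd(x, 1L); x <- bitwShiftR(x, 1L) }
  n
}

#' Shapley interaction values by subset enumeration
#'
#' Off-diagonal entries follow the pairwise interaction decomposition
#' `phi_mn = sum_{R excluding m,n} |R|! (N-|R|-2)! / (2 (N-1)!) eps_mn(R)`
#' with `eps_mn(R) = v(R+m+n) - v(R+m) - v(R+n) + v(R)`; the diagonal is the
#' main effect `phi_m - sum_{n != m} phi_mn`. The matrix is symmetric, its
#' rows sum to the per-feature Shapley values, and its grand total plus the
#' base value reconstructs the prediction.
#'
#' @inheritParams brute_force_shapley
#' @return symmetric feature × feature matrix with attribute `base`.
#' @export
shapley_interactions <- function(model, instance, background) {
  p <- length(model$features)
  if (p > 15) stop("interaction enumeration limited to 15 features")
  v <- subset_values(model, instance, background)
  phi <- brute_force_shapley(model, instance, background)
  M <- matrix(0, p, p, dimnames = list(model$features, model$features))
  for (m in seq_len(p - 1L)) {
    for (n in (m + 1L):p) {
      bm <- bitwShiftL(1L, m - 1L); bn <- bitwShiftL(1L, n - 1L)
      acc <- 0
      for (s in 0:(length(v) - 1L)) {
        if (bitwAnd(s, bm) == 0L && bitwAnd(s, bn) == 0L) {
          size <- popcount(s)
          w <- factorial(size) * factorial(p - size - 2L) /
            (2 * factorial(p - 1L))
          acc <- acc + w * (v[[s + bm + bn + 1L]] - v[[s + bm + 1L]] -
                              v[[s + bn + 1L]] + v[[s + 1L]])
        }
      }
      M[m, n] <- M[n, m] <- acc
    }
  }
  diag(M) <- phi - rowSums(M)
  attr(M, "base") <- attr(phi, "base")
  M
}

#' Rank features by mean absolute Shapley value
#'
#' The standard attribution summary: features ordered by the mean of
#' `|phi|` across instances, descending; ties broken by the model's fixed
#' feature order. Invariant to permuting instances.
#'
#' @param attr an `esv_attribution` from [shapley_values()].
#' @return tibble `(rank, feature, mean_abs_phi)`.
#' @export
importance_ranking <- function(attr) {
  stopifnot(inherits(attr, "esv_attribution"))
  if (nrow(attr$phi) == 0) stop("empty attribution")
  imp <- colMeans(abs(attr$phi))
  ord <- order(-imp, seq_along(imp))
  tibble::tibble(rank = seq_along(imp), feature = attr$features[ord],
                 mean_abs_phi = unname(imp[ord]))
}

#' Per-instance dependence table for one feature
#'
#' One row per explained instance: the feature's value, its Shapley value,
#' and the value of a coloring feature (default HAI) used to read off
#' interactions — the tabular equivalent of a SHAP dependence plot.
#'
#' @param attr an `esv_attribution` from [shapley_values()].
#' @param feature feature whose attribution is tabulated.
#' @param color_feature secondary feature carried along for coloring.
#' @return tibble `(instance, value, phi, color)` sorted by `value`.
#' @export
dependence_table <- function(attr, feature, color_feature = "HAI") {
  stopifnot(inherits(attr, "esv_attribution"))
  for (f in c(feature, color_feature)) {
    if (!f %in% attr$features) stop("unknown feature: ", f)
  }
  out <- tibble::tibble(
    instance = seq_len(nrow(attr$phi)),
    value = attr$table[[feature]],
    phi = attr$phi[, feature],
    color = attr$table[[color_feature]]
  )
  out[order(out$value), ]
}
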