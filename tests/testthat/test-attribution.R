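feat <- driver_features()

random_table <- function(n, seed = 1) {
  set.seed(seed)
  tab <- as.data.frame(matrix(rnorm(n * 9), n, 9, dimnames = list(NULL, feat)))
  tab$zone <- seq_len(n); tab$year <- 2000L
  tab
}

test_that("driver table assembly joins zones, years and the impact index", {
  fx <- load_fixtures()
  areas <- dplyr::bind_rows(lapply(c(2000, 2005, 2010, 2018), function(y) {
    dplyr::bind_rows(lapply(1:3, function(z) {
      toy_areas(c(CL = 100 + z, WO = 200, CO = 10 * z), year = y, zone = z)
    }))
  }))
  esv <- compute_esv(areas, fx$coefficients)
  hai <- compute_hai(areas, fx$pi)
  drv <- expand.grid(zone = 1:3, year = c(2000, 2005, 2010, 2018))
  for (f in setdiff(feat, "HAI")) drv[[f]] <- rnorm(nrow(drv))
  tab <- assemble_driver_table(esv, hai, drv)
  expect_identical(nrow(tab), 12L)
  expect_identical(names(tab), c("zone", "year", feat, "ESV"))
  # pipeline identity: the HAI column is exactly the hai module output
  joined <- dplyr::inner_join(tab, hai, by = c("zone", "year"))
  expect_identical(joined$HAI, joined$hai)

  drv2 <- drv; drv2$GPP[drv2$zone == 2 & drv2$year == 2000] <- NA
  expect_warning(tab2 <- assemble_driver_table(esv, hai, drv2), "dropped")
  expect_identical(nrow(tab2), 11L)
})

test_that("ensemble fitting is deterministic and fits planted signal", {
  tab <- random_table(80, seed = 5)
  tab$ESV <- 4 * tab$HAI - 2 * tab$GPP          # noiseless planted response
  m1 <- fit_esv_model(tab, nrounds = 300, seed = 9)
  m2 <- fit_esv_model(tab, nrounds = 300, seed = 9)
  expect_identical(predict(m1, tab), predict(m2, tab))
  expect_gt(m1$r2, 0.99)

  const <- tab; const$ESV <- 7.5
  mc <- fit_esv_model(const, seed = 1)
  expect_equal(predict(mc, const), rep(7.5, nrow(const)), tolerance = 1e-7)

  bad <- tab; bad$GPP <- as.character(bad$GPP)
  expect_error(fit_esv_model(bad), "numeric")
})

test_that("parsed trees reproduce booster predictions", {
  tab <- random_table(60, seed = 2)
  tab$ESV <- tab$HAI^2 + tab$Pre * tab$Temp + rnorm(60, 0, 0.1)
  m <- fit_esv_model(tab, seed = 4)
  a <- predict(m, tab)
  b <- predict(m, tab, use_trees = TRUE)
  expect_equal(a, b, tolerance = 1e-6)  # booster works in float32
})

test_that("a stump attributes everything to its split feature", {
  m <- manual_model(list(stump(0L, 0.5, left = 10, right = 30)), feat)
  bg <- random_table(2, seed = 3)
  bg$HAI <- c(0.2, 0.8)                # one background point on each side
  x <- bg[1, ]; x$HAI <- 0.9           # above threshold
  at <- shapley_values(m, x, background = bg)
  fx_pred <- 30
  base <- mean(c(10, 30))
  expect_equal(at$base, base)
  expect_equal(unname(at$phi[1, "HAI"]), fx_pred - base)
  expect_true(all(at$phi[1, setdiff(feat, "HAI")] == 0))
})

test_that("a constant model attributes nothing", {
  m <- manual_model(list(leaf_tree(3), leaf_tree(-1)), feat, base_score = 2)
  tab <- random_table(5, seed = 6)
  at <- shapley_values(m, tab)
  expect_true(all(at$phi == 0))
  expect_equal(at$prediction, rep(4, 5))
})

test_that("features unused by every tree get exactly zero attribution", {
  tab <- random_table(100, seed = 7)
  for (f in setdiff(feat, "HAI")) tab[[f]] <- 1  # constants: never split on
  tab$ESV <- sin(3 * tab$HAI)
  m <- fit_esv_model(tab, seed = 2)
  used <- unique(m$trees$feature[m$trees$feature >= 0])
  expect_identical(used, 0L)  # only HAI
  at <- shapley_values(m, tab)
  expect_true(all(at$phi[, setdiff(feat, "HAI")] == 0))
  expect_true(any(at$phi[, "HAI"] != 0))
})

test_that("identically used duplicate features share credit equally", {
  # two identical stumps, one on POP, one on GDP; columns duplicated
  i_pop <- match("POP", feat) - 1L; i_gdp <- match("GDP", feat) - 1L
  m <- manual_model(list(stump(i_pop, 0, -5, 5), stump(i_gdp, 0, -5, 5)), feat)
  bg <- random_table(6, seed = 8)
  bg$GDP <- bg$POP
  x <- bg[3, ]
  phi <- brute_force_shapley(m, x, bg)
  expect_equal(phi[["POP"]], phi[["GDP"]], tolerance = 1e-12)
})

test_that("brute force matches closed forms for tiny models", {
  # single feature: phi = f(x) - mean background prediction
  m1 <- manual_model(list(stump(0L, 0, -2, 6)), "HAI")
  bg <- data.frame(HAI = c(-1, -0.5, 2))
  x <- data.frame(HAI = 1)
  phi <- brute_force_shapley(m1, x, bg)
  expect_equal(as.numeric(phi), 6 - mean(c(-2, -2, 6)))
  expect_equal(attr(phi, "base"), mean(c(-2, -2, 6)))

  # additive two-feature model: phi_i = g_i(x_i) - mean g_i(background)
  m2 <- manual_model(list(stump(0L, 0, -1, 1), stump(1L, 0.5, 0, 10)),
                     c("HAI", "GPP"))
  bg2 <- data.frame(HAI = c(-1, 1), GPP = c(0, 1))
  x2 <- data.frame(HAI = 0.3, GPP = 0.9)
  phi2 <- brute_force_shapley(m2, x2, bg2)
  expect_equal(phi2[["HAI"]], 1 - mean(c(-1, 1)))
  expect_equal(phi2[["GPP"]], 10 - mean(c(0, 10)))
})

test_that("path-enumeration and subset-enumeration Shapley values agree", {
  sim <- simulate_attribution_data(small_scenario(seed = 14, n_zones = 15,
                                                  grid = c(50, 50)))
  m <- fit_esv_model(sim$table, nrounds = 60, seed = 14)
  bg <- sim$table
  at <- shapley_values(m, sim$table, background = bg)
  set.seed(14)
  for (i in sample(nrow(sim$table), 5)) {
    bf <- brute_force_shapley(m, sim$table[i, ], bg)
    expect_equal(unname(at$phi[i, ]), unname(bf),
                 tolerance = 1e-9, ignore_attr = TRUE)
    # local accuracy of the oracle itself
    expect_equal(sum(bf) + attr(bf, "base"),
                 predict(m, sim$table[i, ], use_trees = TRUE),
                 tolerance = 1e-10)
  }
})

test_that("interaction values are symmetric and reconstruct the prediction", {
  tab <- random_table(150, seed = 15)
  tab$ESV <- 2 * tab$HAI * tab$GPP + 0.5 * tab$DEM + rnorm(150, 0, 0.05)
  m <- fit_esv_model(tab, nrounds = 120, seed = 15)
  acc <- matrix(0, 9, 9)
  for (i in c(5, 30, 55, 80, 105, 130)) {
    x <- tab[i, ]
    M <- shapley_interactions(m, x, tab)
    expect_equal(M, t(M), ignore_attr = TRUE)
    phi <- brute_force_shapley(m, x, tab)
    expect_equal(rowSums(M), phi, tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(sum(M) + attr(M, "base"),
                 predict(m, x, use_trees = TRUE), tolerance = 1e-9)
    acc <- acc + abs(M)
  }
  # the planted HAI x GPP interaction dominates the off-diagonal mass
  diag(acc) <- 0
  top <- which(acc == max(acc), arr.ind = TRUE)[1, ]
  expect_setequal(feat[top], c("HAI", "GPP"))
})

test_that("importance ranking is stable and order-invariant", {
  tab <- random_table(60, seed = 16)
  tab$ESV <- 5 * tab$HAI + rnorm(60, 0, 0.1)
  m <- fit_esv_model(tab, seed = 16)
  at <- shapley_values(m, tab)
  rk <- importance_ranking(at)
  expect_identical(rk$feature[1], "HAI")
  # permuting instances leaves the ranking unchanged
  at2 <- at; perm <- sample(nrow(at$phi))
  at2$phi <- at$phi[perm, ]; at2$table <- at$table[perm, ]
  expect_identical(importance_ranking(at2)$feature, rk$feature)

  mc <- manual_model(list(leaf_tree(1)), feat)
  atc <- shapley_values(mc, tab)
  rc <- importance_ranking(atc)
  expect_true(all(rc$mean_abs_phi == 0))
  expect_identical(rc$feature, feat)   # ties broken by column order
})

test_that("dependence tables expose planted interactions", {
  tab <- random_table(30, seed = 17)
  tab$ESV <- tab$GPP
  m <- fit_esv_model(tab, nrounds = 50, seed = 17)
  at <- shapley_values(m, tab)
  dep <- dependence_table(at, "GPP")
  expect_identical(nrow(dep), 30L)
  expect_false(is.unsorted(dep$value))
  same <- dependence_table(at, "GPP", color_feature = "GPP")
  expect_identical(same$color, same$value)
  expect_error(dependence_table(at, "NOPE"), "unknown feature")

  # GPP effect scaled by HAI: attribution spread widens in the high tercile
  ratios <- vapply(1:5, function(s) {
    t2 <- random_table(200, seed = 100 + s)
    t2$HAI <- runif(200, 0.25, 0.55)
    t2$ESV <- 3 * t2$HAI * t2$GPP + 0.5 * t2$HAI + rnorm(200, 0, 0.2)
    m2 <- fit_esv_model(t2, nrounds = 100, seed = s)
    a2 <- shapley_values(m2, t2)
    d <- dependence_table(a2, "GPP")
    ter <- cut(d$color, quantile(d$color, c(0, 1/3, 2/3, 1)),
               include.lowest = TRUE, labels = c("lo", "mid", "hi"))
    var(d$phi[ter == "hi"]) / var(d$phi[ter == "lo"])
  }, 0)
  expect_gt(mean(ratios > 1), 0.5)
  expect_gt(mean(ratios), 1)
})
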