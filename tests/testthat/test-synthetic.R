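test_that("scenario validation rejects degenerate inputs", {
  expect_error(landscape_scenario(grid_shape = c(1, 20)), "degenerate")
  expect_error(landscape_scenario(years = c(2005, 2000)), "increasing")
  bad_prop <- default_class_proportions(); bad_prop["CL"] <- 0.9
  expect_error(landscape_scenario(class_proportions = bad_prop), "sum to 1")
  bad_k <- default_transition_kernel(); bad_k[1, 1] <- 0.5
  expect_error(landscape_scenario(transition_kernel = bad_k), "sum to 1")
})

test_that("default scenario invariants hold", {
  scen <- landscape_scenario()
  expect_equal(sum(scen$class_proportions), 1, tolerance = 1e-12)
  expect_equal(unname(rowSums(scen$transition_kernel)), rep(1, 7),
               tolerance = 1e-12)
  # cropland-forest exchange dominates off-diagonal mass
  k <- scen$transition_kernel; diag(k) <- 0
  expect_identical(names(which.max(k["CL", ])), "WO")
  expect_identical(names(which.max(k["WO", ])), "CL")
})

test_that("identity kernel freezes the landscape", {
  ident <- diag(7); dimnames(ident) <- dimnames(default_transition_kernel())
  scen <- small_scenario(seed = 11, transition_kernel = ident)
  land <- generate_landscape(scen)
  for (g in land$grids[-1]) expect_identical(g$codes, land$grids[[1]]$codes)
})

test_that("generation is a pure function of the seed", {
  a <- generate_landscape(small_scenario(seed = 42))
  b <- generate_landscape(small_scenario(seed = 42))
  expect_identical(lapply(a$grids, `[[`, "codes"),
                   lapply(b$grids, `[[`, "codes"))
  expect_identical(a$zones$labels, b$zones$labels)
  da <- generate_drivers(small_scenario(seed = 42), a$grids, a$zones)
  db <- generate_drivers(small_scenario(seed = 42), b$grids, b$zones)
  expect_identical(da, db)
  c <- generate_landscape(small_scenario(seed = 43))
  expect_false(identical(a$grids[[1]]$codes, c$grids[[1]]$codes))
})

test_that("zone map partitions the grid with consecutive labels", {
  land <- generate_landscape(small_scenario(seed = 5, n_zones = 4,
                                            grid = c(20, 20)))
  expect_identical(dim(land$zones$labels), c(20L, 20L))
  expect_setequal(unique(as.vector(land$zones$labels)), 1:4)
})

test_that("year-1 class histogram follows the scenario proportions", {
  scen <- small_scenario(seed = 9, grid = c(60, 60))
  land <- generate_landscape(scen)
  n <- length(land$grids[[1]]$codes)
  counts <- tabulate(land$grids[[1]]$codes, nbins = 7)
  p <- scen$class_proportions
  sd3 <- 3 * sqrt(n * p * (1 - p))
  expect_true(all(abs(counts - n * p) <= pmax(sd3, 3)))
})

test_that("empirical transition frequencies match the kernel", {
  k <- diag(7) * 0.9
  k[1, 2] <- 0.1                       # CL -> WO mass 0.1 per step
  for (i in 2:7) k[i, 1] <- 0.1
  dimnames(k) <- dimnames(default_transition_kernel())
  scen <- small_scenario(seed = 21, grid = c(60, 60), transition_kernel = k,
                         years = c(2000, 2001, 2002))
  land <- generate_landscape(scen)
  for (t in 2:3) {
    prev <- land$grids[[t - 1]]$codes; cur <- land$grids[[t]]$codes
    n_cl <- sum(prev == 1)
    frac <- sum(prev == 1 & cur == 2) / n_cl
    expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / n_cl))
  }
})

test_that("noise-free linked drivers are exact functions of composition", {
  spec <- default_driver_spec()
  spec$GPP$noise_sd <- 0
  scen <- small_scenario(seed = 2, driver_spec = spec)
  land <- generate_landscape(scen)
  drv <- generate_drivers(scen, land$grids, land$zones)
  areas <- dplyr::bind_rows(lapply(land$grids, tabulate_areas,
                                   zones = land$zones))
  ff <- areas |>
    dplyr::summarise(frac = sum(area_hm2[class == "WO"]) / sum(area_hm2),
                     .by = c(zone, year))
  joined <- dplyr::inner_join(drv, ff, by = c("zone", "year"))
  expect_equal(joined$GPP,
               spec$GPP$intercept + spec$GPP$slope * joined$frac,
               tolerance = 1e-12)
})

test_that("planted GPP-forest link yields a strong positive correlation", {
  scen <- small_scenario(seed = 31, n_zones = 30, grid = c(60, 60))
  land <- generate_landscape(scen)
  drv <- generate_drivers(scen, land$grids, land$zones)
  g1 <- land$grids[[1]]
  ff <- vapply(land$zones$ids, function(z) {
    mean(g1$codes[land$zones$labels == z] == 2)
  }, 0)
  r <- cor(drv$GPP[drv$year == g1$year], ff)
  expect_gt(r, 0.5)
})

test_that("unknown driver names in the spec are rejected", {
  spec <- default_driver_spec()
  spec$Ozone <- list(link = "none", mean = 1, sd = 1)
  scen <- small_scenario(driver_spec = spec)
  land <- generate_landscape(scen)
  expect_error(generate_drivers(scen, land$grids, land$zones),
               "unknown driver name")
})

test_that("the independent PM driver stays uncorrelated with the response", {
  # across 100 seeds, |r(PM, ESV)| over the pooled zone-year rows must stay
  # below 0.2 in at least 95% of replicates
  hits <- vapply(1:100, function(s) {
    sim <- simulate_attribution_data(
      landscape_scenario(seed = s, grid_shape = c(60, 60), n_zones = 60))
    abs(cor(sim$table$PM, sim$table$ESV)) < 0.2
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("simulated attribution tables carry the planted structure", {
  sim <- simulate_attribution_data(small_scenario(seed = 8, n_zones = 25,
                                                  grid = c(60, 60)))
  expect_identical(names(sim$table),
                   c("zone", "year", driver_features(), "ESV"))
  expect_identical(nrow(sim$table), 25L * 4L)
  # dominant planted effect: response strongly rank-associated with HAI
  expect_lt(cor(sim$table$HAI, sim$table$ESV, method = "spearman"), -0.5)
})
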