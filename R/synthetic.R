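#' Synthetic landscape scenario
#'
#' Bundles every knob of the synthetic data generator: grid geometry, zone
#' count, study years, initial class proportions, the per-step Markov
#' transition kernel, per-driver generation rules and the planted zone-level
#' response used for attribution ground truth. The defaults emulate the
#' study region: a 246×246 grid of 1-km cells (≈ 60,500 km²), 33 county
#' zones, years 2000/2005/2010/2018, a landscape dominated by cropland and
#' forest (together > 79% of area) with a tiny but nonzero unused-land
#' share, and year-to-year change dominated by cropland↔forest exchange.
#'
#' @param seed integer seed; generation is a pure function of the scenario
#'   (same seed, same output, bit for bit).
#' @param grid_shape integer `c(rows, cols)`, both >= 2.
#' @param n_zones number of contiguous zones (counties).
#' @param years increasing calendar years, one grid each.
#' @param class_proportions named length-7 vector summing to 1 (1e-9).
#' @param transition_kernel 7×7 row-stochastic matrix (rows sum to 1 within
#'   1e-9): probability a cell of class i becomes class j over one step
#'   between consecutive listed years.
#' @param driver_spec named list of per-driver generation rules, see
#'   [default_driver_spec()].
#' @param planted_effect true zone-level response coefficients, see
#'   [default_planted_effect()].
#' @param cell_area hm² per cell.
#' @return list of class `landscape_scenario`.
#' @export
landscape_scenario <- function(seed = 1L,
                               grid_shape = c(246L, 246L),
                               n_zones = 33L,
                               years = c(2000L, 2005L, 2010L, 2018L),
                               class_proportions = default_class_proportions(),
                               transition_kernel = default_transition_kernel(),
                               driver_spec = default_driver_spec(),
                               planted_effect = default_planted_effect(),
                               cell_area = 100) {
  if (any(grid_shape < 2)) stop("degenerate grid: both dimensions must be >= 2")
  if (is.unsorted(years, strictly = TRUE)) stop("years must be strictly increasing")
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    stop("class_proportions must sum to 1")
  }
  if (!setequal(names(class_proportions), names(land_classes()))) {
    stop("class_proportions must be named by the 7 class abbreviations")
  }
  k <- as.matrix(transition_kernel)
  if (!all(dim(k) == c(7, 7))) stop("transition_kernel must be 7x7")
  if (any(abs(rowSums(k) - 1) > 1e-9)) {
    stop("transition_kernel rows must sum to 1")
  }
  if (any(k < 0)) stop("transition_kernel entries must be non-negative")
  if (n_zones < 1 || n_zones > prod(grid_shape)) stop("invalid n_zones")
  structure(list(
    seed = as.integer(seed), grid_shape = as.integer(grid_shape),
    n_zones = as.integer(n_zones), years = as.integer(years),
    class_proportions = class_proportions[names(land_classes())],
    transition_kernel = k, driver_spec = driver_spec,
    planted_effect = planted_effect, cell_area = cell_area
  ), class = "landscape_scenario")
}

#' @rdname landscape_scenario
#' @export
default_class_proportions <- function() {
  c(CL = 0.45, WO = 0.35, GL = 0.02, WA = 0.10, CO = 0.035, UL = 0.005,
    WL = 0.04)
}

#' @rdname landscape_scenario
#' @export
default_transition_kernel <- function() {
  lv <- names(land_classes())
  k <- matrix(0, 7, 7, dimnames = list(lv, lv))
  k["CL", c("WO", "CO", "WA", "WL", "UL")] <- c(0.020, 0.008, 0.004, 0.002, 0.0005)
  k["WO", c("CL", "GL")] <- c(0.010, 0.002)
  k["GL", c("WO", "CL")] <- c(0.015, 0.005)
  k["WA", c("WL", "CL")] <- c(0.010, 0.002)
  k["CO", "CL"] <- 0.002
  k["UL", c("CL", "WO")] <- c(0.005, 0.003)
  k["WL", c("WA", "CL")] <- c(0.008, 0.002)
  diag(k) <- 1 - rowSums(k)
  k
}

#' Driver generation rules
#'
#' Each entry describes how one county-level covariate is produced. Three
#' mechanisms exist: `link = "forest"` / `"construction"` draw the driver as
#' `intercept + slope * zone class fraction + N(0, noise_sd)` per (zone,
#' year); `link = "field"` / `"gradient"` build a smooth cell-level surface
#' (white noise box-smoothed with `smooth` half-width, plus for `"gradient"`
#' a linear north-south trend of amplitude `range`) that is zonally
#' averaged; `link = "none"` is pure zone-year noise (`N(mean, sd)`),
#' independent of everything — the planted "irrelevant" driver. `Slope` is
#' always derived from the DEM surface by finite differences before zonal
#' averaging. Units are conventional for the drivers they emulate (GPP in
#' gC·m⁻²·yr⁻¹, DEM in m, Slope in m per cell step, POP in persons/km²,
#' GDP in 10⁴ yuan per capita, Temp in °C, Pre in mm, PM in µg/m³).
#'
#' @return named list understood by [generate_drivers()].
#' @export
default_driver_spec <- function() {
  list(
    GPP = list(link = "forest", intercept = 800, slope = 900, noise_sd = 60),
    DEM = list(link = "field", base = 50, relief = 900, smooth = 12, noise_sd = 5),
    Slope = list(link = "dem"),
    POP = list(link = "construction", intercept = 150, slope = 8000, noise_sd = 60),
    GDP = list(link = "construction", intercept = 2, slope = 250, noise_sd = 2),
    Temp = list(link = "gradient", base = 16.7, range = 0.6, smooth = 20,
                noise_sd = 0.05),
    Pre = list(link = "gradient", base = 1375, range = 350, smooth = 20,
               noise_sd = 15),
    PM = list(link = "none", mean = 45, sd = 8)
  )
}

#' Planted zone-level response
#'
#' The true data-generating function for the attribution stage: the response
#' is a linear combination of z-scored drivers plus Gaussian noise, mapped
#' to a yuan scale. The human impact index dominates (|beta| largest), GPP
#' is second, PM2.5 carries exactly zero effect; the remaining drivers
#' contribute weakly. `beta` is in response standard-deviation units per
#' driver standard deviation.
#'
#' @return list with `beta` (named, one per driver feature), `beta0`,
#'   `noise_sd` (z-units), `center_yuan` and `scale_yuan`.
#' @export
default_planted_effect <- function() {
  list(
    beta = c(HAI = -3, GPP = 1.5, Slope = 0.5, DEM = 0.5, POP = -0.35,
             Temp = 0.3, GDP = -0.3, Pre = 0.25, PM = 0),
    beta0 = 0, noise_sd = 0.4, center_yuan = 1.5e10, scale_yuan = 1e9
  )
}

with_scenario_seed <- function(seed, offset, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed((seed + offset) %% .Machine$integer.max)
  force(code)
}

#' Generate a multi-year synthetic land-use raster series with zones
#'
#' Year-1 cells are drawn independently from the scenario's class
#' proportions; each later grid is drawn cell-wise from the Markov
#' transition kernel conditioned on the previous grid (one kernel step per
#' consecutive pair of listed years). Zones are a nearest-seed-point
#' (Voronoi-on-grid) partition: contiguous, deterministic, gap-free.
#'
#' @param scenario a [landscape_scenario()].
#' @return list with `grids` (list of [lu_grid()], one per year) and
#'   `zones` (a [zone_map()]).
#' @export
generate_landscape <- function(scenario) {
  stopifnot(inherits(scenario, "landscape_scenario"))
  nr <- scenario$grid_shape[1]; nc <- scenario$grid_shape[2]
  ncell <- nr * nc
  with_scenario_seed(scenario$seed, 0L, {
    codes <- matrix(sample.int(7L, ncell, replace = TRUE,
                               prob = scenario$class_proportions), nr, nc)
    grids <- vector("list", length(scenario$years))
    grids[[1]] <- lu_grid(codes, scenario$years[1],
                          cell_area = scenario$cell_area)
    for (t in seq_along(scenario$years)[-1]) {
      prev <- grids[[t - 1]]$codes
      nxt <- prev
      for (cls in 1:7) {
        idx <- which(prev == cls)
        if (length(idx)) {
          nxt[idx] <- sample.int(7L, length(idx), replace = TRUE,
                                 prob = scenario$transition_kernel[cls, ])
        }
      }
      grids[[t]] <- lu_grid(nxt, scenario$years[t],
                            cell_area = scenario$cell_area)
    }
    seeds <- sample.int(ncell, scenario$n_zones)
    sr <- (seeds - 1L) %% nr + 1L
    sc <- (seeds - 1L) %/% nr + 1L
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    best <- matrix(Inf, nr, nc)
    lab <- matrix(0L, nr, nc)
    for (z in seq_len(scenario$n_zones)) {
      d <- (rows - sr[z])^2 + (cols - sc[z])^2
      upd <- d < best
      best[upd] <- d[upd]
      lab[upd] <- z
    }
    list(grids = grids, zones = zone_map(lab))
  })
}

# separable box-mean smoother with edge renormalization
box_smooth <- function(m, w) {
  if (w < 1) return(m)
  smooth1 <- function(x) {
    n <- length(x)
    cs <- cumsum(c(0, x))
    lo <- pmax(seq_len(n) - w, 1); hi <- pmin(seq_len(n) + w, n)
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  m <- apply(m, 2, smooth1)
  t(apply(m, 1, smooth1))
}

zonal_mean <- function(field, zones) {
  keep <- zones$labels != zones$nodata
  tapply(field[keep], zones$labels[keep], mean)[as.character(zones$ids)]
}

class_fraction <- function(grid, zones, cls_code) {
  keep <- grid$codes != grid$nodata & zones$labels != zones$nodata
  lab <- zones$labels[keep]
  hit <- tapply(grid$codes[keep] == cls_code, lab, mean)
  as.numeric(hit[as.character(zones$ids)])
}

#' Generate county-level driver covariates
#'
#' Produces one row per (zone, year) with the eight environmental and
#' socio-economic drivers, honoring the links declared in the scenario's
#' driver spec (see [default_driver_spec()]): GPP rises with a zone's forest
#' fraction, POP and GDP with its construction fraction, DEM/Temp/Pre are
#' zonal means of smooth surfaces, Slope is derived from the DEM surface by
#' finite differences before zonal averaging, and PM is independent noise.
#'
#' @param scenario a [landscape_scenario()].
#' @param grids,zones output of [generate_landscape()] for the scenario.
#' @return tibble `(zone, year, GPP, DEM, Slope, POP, GDP, Temp, Pre, PM)`.
#' @export
generate_drivers <- function(scenario, grids, zones) {
  stopifnot(inherits(scenario, "landscape_scenario"))
  spec <- scenario$driver_spec
  known <- c("GPP", "DEM", "Slope", "POP", "GDP", "Temp", "Pre", "PM")
  bad <- setdiff(names(spec), known)
  if (length(bad)) stop("unknown driver name(s) in spec: ",
                        paste(bad, collapse = ", "))
  miss <- setdiff(known, names(spec))
  if (length(miss)) stop("driver spec missing: ", paste(miss, collapse = ", "))
  nr <- scenario$grid_shape[1]; nc <- scenario$grid_shape[2]
  nz <- length(zones$ids); ny <- length(grids)

  with_scenario_seed(scenario$seed, 1L, {
    # static smooth surfaces
    s <- spec$DEM
    dem_field <- s$base + s$relief *
      rescale01(box_smooth(matrix(rnorm(nr * nc), nr, nc), s$smooth)) +
      rnorm(nr * nc, 0, s$noise_sd)
    dx <- dem_field[, c(2:nc, nc)] - dem_field[, c(1, 1:(nc - 1))]
    dy <- dem_field[c(2:nr, nr), ] - dem_field[c(1, 1:(nr - 1)), ]
    slope_field <- sqrt((dx / 2)^2 + (dy / 2)^2)

    grad <- matrix(seq(-0.5, 0.5, length.out = nr), nr, nc)
    surf <- function(sp) {
      sp$base + sp$range * (grad + 0.25 *
        rescale01(box_smooth(matrix(rnorm(nr * nc), nr, nc), sp$smooth)) - 0.125)
    }
    temp_field <- surf(spec$Temp)
    pre_field <- surf(spec$Pre)

    dem_z <- as.numeric(zonal_mean(dem_field, zones))
    slope_z <- as.numeric(zonal_mean(slope_field, zones))
    temp_z <- as.numeric(zonal_mean(temp_field, zones))
    pre_z <- as.numeric(zonal_mean(pre_field, zones))

    rows <- lapply(seq_len(ny), function(t) {
      g <- grids[[t]]
      ff <- class_fraction(g, zones, land_classes()[["WO"]])
      cf <- class_fraction(g, zones, land_classes()[["CO"]])
      lin <- function(sp, frac) sp$intercept + sp$slope * frac +
        rnorm(nz, 0, sp$noise_sd)
      tibble::tibble(
        zone = zones$ids, year = g$year,
        GPP = lin(spec$GPP, ff),
        DEM = dem_z,
        Slope = slope_z,
        POP = lin(spec$POP, cf),
        GDP = lin(spec$GDP, cf),
        Temp = temp_z + rnorm(nz, 0, spec$Temp$noise_sd),
        Pre = pre_z + rnorm(nz, 0, spec$Pre$noise_sd),
        PM = rnorm(nz, spec$PM$mean, spec$PM$sd)
      )
    })
    dplyr::bind_rows(rows)
  })
}

rescale01 <- function(m) {
  r <- range(m)
  if (r[1] == r[2]) return(m * 0)
  (m - r[1]) / (r[2] - r[1])
}

#' Simulate a complete attribution problem with known ground truth
#'
#' Runs the synthetic pipeline end to end — landscape, zones, areas, human
#' impact index, drivers — then draws the response from the scenario's
#' planted effect: a linear function of the z-scored feature columns plus
#' Gaussian noise, mapped to a yuan scale (see [default_planted_effect()]).
#' Because the true coefficients are known, recovery of the dominant driver
#' and of the null driver by the attribution stage can be tested.
#'
#' @param scenario a [landscape_scenario()].
#' @return list with `table` (a driver table ready for [fit_esv_model()]:
#'   `zone`, `year`, the nine features, `ESV`), `truth` (the planted
#'   effect), plus the intermediate `grids`, `zones`, `areas`, `hai`,
#'   `drivers`.
#' @export
simulate_attribution_data <- function(scenario) {
  land <- generate_landscape(scenario)
  areas <- dplyr::bind_rows(lapply(land$grids, tabulate_areas,
                                   zones = land$zones))
  hai <- compute_hai(areas)
  drivers <- generate_drivers(scenario, land$grids, land$zones)
  tab <- dplyr::inner_join(hai[, c("zone", "year", "hai")], drivers,
                           by = c("zone", "year"))
  names(tab)[names(tab) == "hai"] <- "HAI"
  tab <- tab[, c("zone", "year", driver_features())]

  pe <- scenario$planted_effect
  z <- scale(as.matrix(tab[, driver_features()]))
  z[is.nan(z)] <- 0  # constant column safeguard
  eta <- with_scenario_seed(scenario$seed, 2L, {
    drop(z %*% pe$beta[driver_features()]) + pe$beta0 +
      rnorm(nrow(tab), 0, pe$noise_sd)
  })
  tab$ESV <- pe$center_yuan + pe$scale_yuan * eta
  list(table = tab, truth = pe, grids = land$grids, zones = land$zones,
       areas = new_area_table(areas), hai = hai, drivers = drivers)
}
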