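#' Validate a pipeline run configuration
#'
#' Reads a YAML configuration (or takes an equivalent named list) and checks
#' it as a whole, reporting every problem at once rather than failing on the
#' first. Recognized top-level fields: `mode` (`"synthetic"`, `"fixture"` or
#' `"files"`), `seed`, `output_dir`, `constants`
#' (`standard_equivalent`, `horizon`, `zero_floor`, `pi` overrides), `model`
#' (hyperparameters for [fit_esv_model()]), `attribution` (logical), and the
#' mode-specific blocks `synthetic` (arguments of [landscape_scenario()]),
#' `fixture` (`esv_csv`), `files` (`rasters` year→path map of ASCII grids,
#' `zones` path, `drivers` CSV path).
#'
#' @param config path to a YAML file, or a named list.
#' @return the validated config (class `run_config`), or an error listing
#'   every violation.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  errs <- character(0)
  note <- function(msg) errs <<- c(errs, msg)

  mode <- config$mode
  if (is.null(mode) || !mode %in% c("synthetic", "fixture", "files")) {
    note("mode: must be one of synthetic, fixture, files")
  }
  if (is.null(config$output_dir)) note("output_dir: required")
  if (!is.null(config$seed) &&
      (!is.numeric(config$seed) || config$seed != round(config$seed))) {
    note("seed: must be an integer")
  }
  years <- config$synthetic$years
  if (!is.null(years) && is.unsorted(years, strictly = TRUE)) {
    note("synthetic$years: must be strictly increasing")
  }
  if (identical(mode, "files")) {
    r <- config$files$rasters
    if (is.null(r) || !length(r)) {
      note("files$rasters: required in files mode (year: path map)")
    } else {
      ry <- suppressWarnings(as.integer(names(r)))
      if (anyNA(ry)) note("files$rasters: names must be years")
      else if (is.unsorted(ry, strictly = TRUE)) {
        note("files$rasters: years must be strictly increasing")
      }
      for (p in unlist(r)) if (!file.exists(p)) note(paste0("files$rasters: missing file ", p))
    }
    if (is.null(config$files$zones)) note("files$zones: required in files mode")
    else if (!file.exists(config$files$zones)) {
      note(paste0("files$zones: missing file ", config$files$zones))
    }
    if (!is.null(config$files$drivers) && !file.exists(config$files$drivers)) {
      note(paste0("files$drivers: missing file ", config$files$drivers))
    }
  }
  if (identical(mode, "fixture") && !is.null(config$fixture$esv_csv) &&
      !file.exists(config$fixture$esv_csv)) {
    note(paste0("fixture$esv_csv: missing file ", config$fixture$esv_csv))
  }
  pi <- config$constants$pi
  if (!is.null(pi)) {
    bad <- setdiff(names(pi), names(land_classes()))
    if (length(bad)) note(paste0("constants$pi: unknown class(es) ",
                                 paste(bad, collapse = ", ")))
  }
  if (length(errs)) {
    stop("invalid configuration:\n", paste0("  - ", errs, collapse = "\n"))
  }
  defaults <- list(seed = 1L, attribution = TRUE, constants = list(),
                   model = list(), synthetic = list())
  config <- utils::modifyList(defaults, config)
  class(config) <- c("run_config", class(config))
  config
}

#' Run the full valuation pipeline
#'
#' Wires the stages end to end — rasters → zonal areas → transition
#' matrices → ESV → human impact index → driver attribution → report — and
#' writes every intermediate table as tidy CSV into the run directory,
#' together with a plain-text summary and a machine-readable
#' `manifest.json` (seed, configuration echo, package version, MD5 of each
#' output). Reruns with the same configuration and seed produce
#' byte-identical outputs.
#'
#' In `fixture` mode the published valuation table (or a CSV shaped like
#' it) is summarized directly, with areas back-derived from the table; no
#' rasters or attribution are involved.
#'
#' @param config a [validate_config()] result, a YAML path, or a list.
#' @return (invisibly) list with the output directory and the written
#'   files; stages are also returned for programmatic use.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  fx <- load_fixtures()
  consts <- config$constants
  pi <- fx$pi
  if (!is.null(consts$pi)) pi[names(consts$pi)] <- unlist(consts$pi)
  zero_floor <- consts$zero_floor %||% 100
  horizon <- consts$horizon %||% NULL

  written <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    write.csv(df, p, row.names = FALSE, quote = FALSE)
    written <<- c(written, p)
    p
  }

  stages <- list()
  if (config$mode == "fixture") {
    esv <- if (!is.null(config$fixture$esv_csv)) {
      raw <- tibble::as_tibble(read.csv(config$fixture$esv_csv,
                                        check.names = FALSE))
      fixture_esv_table(tidyr::pivot_longer(
        raw, dplyr::all_of(intersect(service_functions(), names(raw))),
        names_to = "function", values_to = "billion_yuan"))
    } else {
      fixture_esv_table(fx)
    }
    areas <- suppressWarnings(infer_areas(esv, fx$coefficients))
  } else {
    if (config$mode == "synthetic") {
      scen <- do.call(landscape_scenario,
                      c(list(seed = seed), config$synthetic))
      land <- generate_landscape(scen)
      drivers <- generate_drivers(scen, land$grids, land$zones)
    } else {
      rasters <- config$files$rasters
      grids <- lapply(names(rasters), function(y) {
        g <- read_ascii_grid(rasters[[y]])
        # header cellsize is in metres; 1 hm2 = (100 m)^2
        lu_grid(g$matrix, year = as.integer(y),
                cell_area = (g$cellsize / 100)^2,
                nodata = g$nodata)
      })
      z <- read_ascii_grid(config$files$zones)
      land <- list(grids = grids,
                   zones = zone_map(z$matrix, nodata = z$nodata))
      drivers <- if (!is.null(config$files$drivers)) {
        tibble::as_tibble(read.csv(config$files$drivers))
      }
    }
    areas <- dplyr::bind_rows(lapply(land$grids, tabulate_areas,
                                     zones = land$zones))
    areas <- new_area_table(areas)
    for (i in seq_along(land$grids)[-1]) {
      tm <- transition_matrix(land$grids[[i - 1]], land$grids[[i]])
      df <- as.data.frame(as.table(unclass(tm)), stringsAsFactors = FALSE)
      names(df) <- c("from", "to", "area_hm2")
      emit(df, sprintf("transitions_%d_%d.csv",
                       attr(tm, "from_year"), attr(tm, "to_year")))
    }
    esv <- compute_esv(areas, fx$coefficients)
    stages$landscape <- land
    stages$drivers <- drivers
  }

  emit(areas, "areas.csv")
  esv_out <- esv
  esv_out$yuan <- round(esv_out$yuan, 2)
  emit(esv_out, "esv.csv")

  hai <- compute_hai(areas, pi)
  hai_out <- hai; hai_out$hai <- round(hai_out$hai, 4)
  emit(hai_out, "hai.csv")

  yrs <- sort(unique(areas$year))
  smry <- summarize_esv(esv)
  kdeg <- dynamic_degree_table(areas, yrs[1], yrs[length(yrs)],
                               horizon = horizon %||% (yrs[length(yrs)] - yrs[1]),
                               zero_floor = zero_floor)
  emit(kdeg, "dynamic_degree.csv")
  emit(smry$class_totals, "summary_class_totals.csv")
  emit(smry$function_totals, "summary_function_totals.csv")
  emit(smry$class_change, "summary_class_change.csv")
  emit(smry$function_change, "summary_function_change.csv")

  stages <- c(stages, list(areas = areas, esv = esv, hai = hai,
                           summary = smry, dynamic_degree = kdeg))

  if (config$mode != "fixture" && isTRUE(config$attribution) &&
      !is.null(stages$drivers)) {
    tab <- assemble_driver_table(esv, hai, stages$drivers)
    model <- do.call(fit_esv_model,
                     c(list(table = tab, seed = seed), config$model))
    attr_ <- shapley_values(model, tab)
    emit(tab, "driver_table.csv")
    phi <- as.data.frame(attr_$phi)
    phi <- cbind(tab[, c("zone", "year")], phi,
                 base = attr_$base, prediction = attr_$prediction)
    emit(phi, "attribution_phi.csv")
    emit(importance_ranking(attr_), "importance.csv")
    stages$model <- model
    stages$attribution <- attr_
  }

  report <- file.path(out_dir, "report.txt")
  withCallingHandlers({
    sink(report)
    on.exit(sink(), add = TRUE)
    print(smry)
    cat("\nDynamic degree (", yrs[1], "->", yrs[length(yrs)], ", % per yr):\n")
    print(as.data.frame(kdeg), row.names = FALSE)
    cat("\nDisturbance bands (zone-years):\n")
    print(table(hai$band))
    if (!is.null(stages$model)) {
      cat("\n"); print(stages$model); cat("\n")
      print(as.data.frame(importance_ranking(stages$attribution)),
            row.names = FALSE)
    }
  }, error = function(e) { sink(); stop(e) })
  written <- c(written, report)

  manifest <- list(
    package = "esvland",
    version = as.character(utils::packageVersion("esvland")),
    seed = seed,
    mode = config$mode,
    config = unclass(config)[setdiff(names(config), "output_dir")],
    outputs = lapply(stats::setNames(nm = basename(written)), function(b) {
      unname(tools::md5sum(file.path(out_dir, b)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(c(list(output_dir = out_dir, files = written), stages))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
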