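## End-to-end pipeline: one YAML config drives generate -> prepare -> plant
## -> simulate -> analyze, with a JSON manifest for provenance.

#' Validate a pipeline configuration file
#'
#' Parses the YAML config and reports every violation found (threshold
#' ordering, year range, positive stems, known scenario and rule ids,
#' resolvable species sets); it never throws on content problems.
#'
#' @param config Path to a YAML config file, or an already-parsed list.
#' @return Character vector of violations (empty when valid).
#' @export
validateConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) return(paste("config file not found:", config))
    config <- yaml::read_yaml(config)
  }
  v <- character()
  ls <- config$landscape %||% list()
  if (!is.null(ls$size) && (!is.numeric(ls$size) || ls$size < 8))
    v <- c(v, "landscape.size: must be >= 8")
  sc <- config$scenarios %||% list()
  dry <- sc$dry_threshold %||% 0.33
  wet <- sc$wet_threshold %||% 0.67
  if (!(dry > 0 && dry < wet && wet < 1))
    v <- c(v, "scenarios.dry_threshold/wet_threshold: require 0 < dry < wet < 1")
  sy <- sc$start_year %||% 2025; ey <- sc$end_year %||% 2080
  if (sy > ey) v <- c(v, "scenarios.start_year: must be <= end_year")
  if (sy < 2025 || ey > 2080)
    v <- c(v, "scenarios.start_year/end_year: must lie within [2025, 2080]")
  if ((sc$initial_stems %||% 1650) <= 0)
    v <- c(v, "scenarios.initial_stems: must be > 0")
  for (cs in sc$climate_scenarios %||% CLIMATE_SCENARIOS)
    if (!cs %in% CLIMATE_SCENARIOS)
      v <- c(v, paste0("scenarios.climate_scenarios: unknown id '", cs, "'"))
  for (r in sc$planting_rules %||% PLANTING_RULES)
    if (!r %in% PLANTING_RULES)
      v <- c(v, paste0("scenarios.planting_rules: unknown id '", r, "'"))
  for (key in c("conifer_species", "deciduous_species")) {
    spec <- sc[[key]]
    if (is.null(spec)) next
    ok <- spec %in% c("black_spruce", "lodgepole_pine", "generic_deciduous") ||
      file.exists(spec)
    if (!ok) v <- c(v, paste0("scenarios.", key,
                              ": not a shipped species or existing file ('",
                              spec, "')"))
  }
  soil <- (config$site %||% list())$soil_class %||% "sandy_loam"
  if (!soil %in% names(soilClassTable()))
    v <- c(v, paste0("site.soil_class: unknown class '", soil, "'"))
  v
}

resolveSpecies <- function(spec, fallback) {
  if (is.null(spec)) return(defaultSpecies(fallback))
  if (spec %in% c("black_spruce", "lodgepole_pine", "generic_deciduous"))
    return(defaultSpecies(spec))
  readSpeciesParams(spec)
}

#' Run the full pipeline from a configuration file
#'
#' Executes generate, prepare, plant, simulate and analyze in order,
#' short-circuiting with a structured error when validation fails. All
#' stages are deterministic given the config (landscape and planting seeds
#' are recorded in the manifest).
#'
#' @param config Path to a YAML config file, or a parsed list.
#' @param outdir Output directory (overrides the config's \code{outdir}).
#' @param verbose Emit per-stage progress messages.
#' @return The run manifest (also written to \code{manifest.json}):
#'   config hash, seeds, per-stage outputs with row/cell counts and file
#'   hashes, and timestamps.
#' @export
runPipeline <- function(config, outdir = NULL, verbose = FALSE) {
  config_path <- if (is.character(config)) config else NULL
  viol <- validateConfig(config)
  if (length(viol))
    stop("invalid configuration:\n  ", paste(viol, collapse = "\n  "),
         call. = FALSE)
  if (is.character(config)) config <- yaml::read_yaml(config)
  outdir <- outdir %||% config$outdir %||% "afforest3PG_run"
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ls <- config$landscape %||% list()
  sc <- config$scenarios %||% list()
  an <- config$analysis %||% list()
  seed <- as.integer(ls$seed %||% 1L)
  stage <- function(msg) if (verbose) message("[afforest3PG] ", msg)

  stage("generate: synthetic landscape")
  bundle <- generateLandscape(size = ls$size %||% 32,
                              latitude = ls$latitude %||% 55,
                              seed = seed, relief = ls$relief %||% 200,
                              cellsize = ls$cellsize %||% 100,
                              missing_frac = ls$missing_frac %||% 0.05)
  lsdir <- file.path(outdir, "landscape")
  files_ls <- writeLandscape(bundle, lsdir)

  stage("prepare: site grid")
  site <- prepareSite(bundle,
                      soil_class = (config$site %||% list())$soil_class %||%
                        "sandy_loam",
                      smooth_window = (config$site %||% list())$smooth_window %||% 3)
  sitedir <- file.path(outdir, "site")
  files_site <- writeSiteGrid(site, sitedir)

  stage("simulate: scenario grid")
  results <- runAll(site, climateNormals(bundle),
                    rules = sc$planting_rules %||% PLANTING_RULES,
                    scenarios = sc$climate_scenarios %||% CLIMATE_SCENARIOS,
                    verbose = verbose,
                    start_year = sc$start_year %||% 2025,
                    end_year = sc$end_year %||% 2080,
                    initial_stems = sc$initial_stems %||% 1650,
                    dry_threshold = sc$dry_threshold %||% 0.33,
                    wet_threshold = sc$wet_threshold %||% 0.67,
                    planting_seed = as.integer(sc$planting_seed %||% 1L),
                    trace_year = sc$trace_year %||%
                      ((sc$end_year %||% 2080) - 1),
                    conifer = resolveSpecies(sc$conifer_species,
                                             "black_spruce"),
                    deciduous = resolveSpecies(sc$deciduous_species,
                                               "generic_deciduous"))
  resdir <- file.path(outdir, "results")
  files_res <- unlist(lapply(results, writeScenarioResult, outdir = resdir))

  stage("analyze: summaries and tests")
  tabdir <- file.path(outdir, "tables")
  dir.create(tabdir, showWarnings = FALSE, recursive = TRUE)
  summ <- biomassSummary(results)
  f_sum <- file.path(tabdir, "biomass_summary.csv")
  write.csv(summ, f_sum, row.names = FALSE)
  cmp <- compareScenarios(results,
                          adjust_method = an$adjust_method %||% "holm")
  f_kw <- file.path(tabdir, "kruskal_tests.csv")
  write.csv(cmp$kruskal, f_kw, row.names = FALSE)
  f_dunn <- file.path(tabdir, "dunn_posthoc.csv")
  write.csv(cmp$dunn, f_dunn, row.names = FALSE)
  files_tab <- c(f_sum, f_kw, f_dunn)
  ## paired stress analysis where both pure arms ran
  scns <- unique(vapply(results, function(r) r@scenario, character(1)))
  stress_rows <- list()
  for (scn in scns) {
    k1 <- paste0("SM1x", scn); k2 <- paste0("SM2x", scn)
    if (all(c(k1, k2) %in% names(results))) {
      st <- stressAnalysis(modifierTrace(results[[k1]]),
                           modifierTrace(results[[k2]]),
                           flag_threshold = an$flag_threshold %||% 0.05)
      stress_rows[[scn]] <- cbind(scenario = scn, st)
    }
  }
  if (length(stress_rows)) {
    f_st <- file.path(tabdir, "monthly_stress.csv")
    write.csv(do.call(rbind, stress_rows), f_st, row.names = FALSE)
    files_tab <- c(files_tab, f_st)
  }

  outputs <- c(files_ls, files_site, files_res, files_tab)
  manifest <- list(
    package = "afforest3PG",
    version = as.character(utils::packageVersion("afforest3PG")),
    config_hash = if (!is.null(config_path))
      unname(tools::md5sum(config_path)) else NA,
    seeds = list(landscape = seed,
                 planting = as.integer(sc$planting_seed %||% 1L)),
    cells = list(total = length(site@fr), eligible = sum(site@eligible)),
    scenarios = names(results),
    outputs = lapply(setNames(outputs, basename(outputs)), function(f)
      list(path = f, md5 = unname(tools::md5sum(f)),
           rows = if (grepl("\\.csv$", f)) nrow(read.csv(f)) else NA)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
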