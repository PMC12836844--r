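## Planting rules SM1-SM3 and the scenario grid: drive the growth engine
## over every planted cell for 2025-2080 under each climate scenario.

#' Scenario configuration
#'
#' Validated configuration for a single planting-rule x climate-scenario run.
#'
#' @param planting_rule \code{"SM1"} (all conifer), \code{"SM2"} (all
#'   deciduous) or \code{"SM3"} (wetness-stratified mixture).
#' @param climate_scenario \code{"CS1"}, \code{"CS2"} or \code{"CS3"}.
#' @param start_year,end_year Simulation span (calendar years).
#' @param initial_stems Planting density (trees ha-1).
#' @param dry_threshold,wet_threshold Normalized-wetness cut points of the
#'   SM3 stratification, \code{0 < dry < wet < 1}.
#' @param planting_seed Seed for the SM3 random middle band.
#' @param trace_year Calendar year whose monthly modifiers are recorded.
#' @param co2_table Scenario x period CO2 table (ppm); default
#'   \code{\link{defaultCO2Table}}.
#' @param conifer,deciduous \linkS4class{SpeciesParams} for the two planting
#'   roles; defaults to the shipped black spruce and generic deciduous sets.
#' @return A named list of validated settings.
#' @export
scenarioConfig <- function(planting_rule = "SM1", climate_scenario = "CS1",
                           start_year = 2025, end_year = 2080,
                           initial_stems = 1650, dry_threshold = 0.33,
                           wet_threshold = 0.67, planting_seed = 1L,
                           trace_year = 2079, co2_table = defaultCO2Table(),
                           conifer = NULL, deciduous = NULL) {
  if (!planting_rule %in% PLANTING_RULES)
    stop("unknown planting rule: ", planting_rule, call. = FALSE)
  if (!climate_scenario %in% CLIMATE_SCENARIOS)
    stop("unknown climate scenario: ", climate_scenario, call. = FALSE)
  if (!(dry_threshold > 0 && dry_threshold < wet_threshold &&
        wet_threshold < 1))
    stop("require 0 < dry_threshold < wet_threshold < 1", call. = FALSE)
  if (initial_stems <= 0) stop("'initial_stems' must be > 0", call. = FALSE)
  if (start_year > end_year) stop("'start_year' must be <= 'end_year'",
                                  call. = FALSE)
  list(planting_rule = planting_rule, climate_scenario = climate_scenario,
       start_year = start_year, end_year = end_year,
       initial_stems = initial_stems, dry_threshold = dry_threshold,
       wet_threshold = wet_threshold, planting_seed = as.integer(planting_seed),
       trace_year = trace_year, co2_table = co2_table,
       conifer = conifer %||% defaultSpecies("black_spruce"),
       deciduous = deciduous %||% defaultSpecies("generic_deciduous"))
}

#' Assign a species to every eligible cell under a planting rule
#'
#' SM1 plants conifer everywhere; SM2 deciduous everywhere; SM3 plants
#' deciduous below the dry threshold, conifer above the wet threshold, and
#' draws a fair independent Bernoulli per cell in the closed middle band
#' from the seeded generator.
#'
#' @param nw Normalized wetness matrix.
#' @param eligible Logical eligibility matrix.
#' @param rule Planting rule id.
#' @param seed Integer seed (only used by SM3).
#' @param dry_threshold,wet_threshold Wetness cut points.
#' @return A \linkS4class{PlantingMap}.
#' @export
assignPlanting <- function(nw, eligible, rule, seed = 1L,
                           dry_threshold = 0.33, wet_threshold = 0.67) {
  if (!rule %in% PLANTING_RULES)
    stop("unknown planting rule: ", rule, call. = FALSE)
  stopifnot(identical(dim(nw), dim(eligible)))
  a <- matrix(NA_character_, nrow(nw), ncol(nw))
  idx <- which(eligible)
  if (rule == "SM1") {
    a[idx] <- "conifer"
  } else if (rule == "SM2") {
    a[idx] <- "deciduous"
  } else {
    w <- nw[idx]
    a[idx[w < dry_threshold]] <- "deciduous"
    a[idx[w > wet_threshold]] <- "conifer"
    mid <- idx[w >= dry_threshold & w <= wet_threshold]
    if (length(mid)) {
      draw <- withSeed(childSeed(seed, 71L), runif(length(mid)) < 0.5)
      a[mid] <- ifelse(draw, "deciduous", "conifer")
    }
  }
  new("PlantingMap", assignment = a, rule = rule, seed = as.integer(seed))
}

#' Monthly climate records for one simulated year
#'
#' Selects the 20-year normal period containing the year (2025-2040 uses the
#' 2021-2040 normals; 2041-2060 and 2061-2080 their own) and attaches the
#' CO2 value for the scenario and period.
#'
#' @param year Calendar year in [2025, 2080].
#' @param scenario Climate scenario id.
#' @param normals Named list of \linkS4class{ClimateNormals} keyed
#'   \code{"<scenario>|<period>"} (e.g. \code{climateNormals(bundle)}).
#' @param co2_table Scenario x period CO2 table (ppm).
#' @return data.frame with 12 monthly rows (columns as consumed by
#'   \code{\link{runStand}}).
#' @export
climateForYear <- function(year, scenario, normals,
                           co2_table = defaultCO2Table()) {
  if (year < 2025 || year > 2080)
    stop("'year' must lie in [2025, 2080]", call. = FALSE)
  period <- if (year <= 2040) "2021-2040"
            else if (year <= 2060) "2041-2060" else "2061-2080"
  key <- paste(scenario, period, sep = "|")
  if (!key %in% names(normals))
    stop("no climate normals available for ", key, call. = FALSE)
  cn <- normals[[key]]
  df <- cn@normals
  data.frame(year = year, month = df$month, tmin = df$tmin, tmax = df$tmax,
             tmean = df$tmean, precip = df$precip, solar_rad = df$solar_rad,
             frost_days = df$frost_days, days = df$days,
             co2 = co2_table[scenario, period])
}

## Full monthly climate series for a span of years.
climateSeries <- function(start_year, end_year, scenario, normals,
                          co2_table = defaultCO2Table()) {
  do.call(rbind, lapply(start_year:end_year, climateForYear,
                        scenario = scenario, normals = normals,
                        co2_table = co2_table))
}

#' Run one planting-rule x climate-scenario combination
#'
#' Runs the growth engine independently on every planted cell with the
#' cell's fertility, soil-water capacity and assigned species, and collects
#' annual August aboveground biomass plus the analysis-year monthly
#' fSW/fVPD trace.
#'
#' @param config A \code{\link{scenarioConfig}}.
#' @param site A \linkS4class{SiteGrid}.
#' @param planting A \linkS4class{PlantingMap} (built from \code{config} if
#'   \code{NULL}).
#' @param normals Named list of \linkS4class{ClimateNormals}.
#' @param verbose Emit per-scenario progress.
#' @return A \linkS4class{ScenarioResult}.
#' @export
runScenario <- function(config, site, normals, planting = NULL,
                        verbose = FALSE) {
  stopifnot(is(site, "SiteGrid"))
  if (is.null(planting))
    planting <- assignPlanting(site@nw, site@eligible, config$planting_rule,
                               seed = config$planting_seed,
                               dry_threshold = config$dry_threshold,
                               wet_threshold = config$wet_threshold)
  cells <- which(!is.na(planting@assignment))
  spNames <- planting@assignment[cells]
  years <- config$start_year:config$end_year
  soil <- soilClassTable()[[site@soil_class]]
  scn <- config$climate_scenario
  series <- climateSeries(config$start_year, config$end_year, scn, normals,
                          config$co2_table)
  np <- length(cells)
  agb <- matrix(NA_real_, np, length(years))
  stems <- dbh <- lai <- numeric(np)
  traces <- vector("list", np)
  params <- list(conifer = config$conifer, deciduous = config$deciduous)
  t0 <- Sys.time()
  for (i in seq_len(np)) {
    cell <- cells[i]
    res <- runStand(series, params[[spNames[i]]],
                    site = list(fr = site@fr[cell], masw = site@masw[cell],
                                SWconst = soil[["SWconst"]],
                                SWpower = soil[["SWpower"]]),
                    stems = config$initial_stems,
                    trace_year = config$trace_year)
    agb[i, ] <- res$agb
    stems[i] <- res$stems; dbh[i] <- res$dbh; lai[i] <- res$lai
    traces[[i]] <- cbind(cell = cell, species = spNames[i], res$trace)
  }
  if (verbose)
    message(sprintf("[%s x %s] %d cells in %.1f s", config$planting_rule,
                    scn, np, as.numeric(Sys.time() - t0, units = "secs")))
  trace <- if (np) do.call(rbind, traces) else
    data.frame(cell = integer(), species = character(), month = integer(),
               fSW = numeric(), fVPD = numeric())
  new("ScenarioResult", rule = config$planting_rule, scenario = scn,
      cells = as.integer(cells), species = unname(spNames), agb = agb,
      years = as.integer(years), stems = stems, dbh = dbh, lai = lai,
      trace = trace, trace_year = as.integer(config$trace_year),
      dim = dim(site@fr))
}

#' Run the full planting-rule by climate-scenario grid
#'
#' Executes all nine SM x CS combinations. The planting map for a given rule
#' is drawn once from the planting seed and shared across climate scenarios,
#' so contrasts between climates are paired cell by cell.
#'
#' @param site A \linkS4class{SiteGrid}.
#' @param normals Named list of \linkS4class{ClimateNormals}.
#' @param rules,scenarios Subsets of the planting rules / climate scenarios.
#' @param verbose Emit per-scenario progress.
#' @param ... Passed to \code{\link{scenarioConfig}}.
#' @return Named list of \linkS4class{ScenarioResult} (\code{"SM1xCS1"},
#'   ...).
#' @export
runAll <- function(site, normals, rules = PLANTING_RULES,
                   scenarios = CLIMATE_SCENARIOS, verbose = FALSE, ...) {
  results <- list()
  for (rule in rules) {
    cfg0 <- scenarioConfig(planting_rule = rule, ...)
    planting <- assignPlanting(site@nw, site@eligible, rule,
                               seed = cfg0$planting_seed,
                               dry_threshold = cfg0$dry_threshold,
                               wet_threshold = cfg0$wet_threshold)
    for (scn in scenarios) {
      cfg <- scenarioConfig(planting_rule = rule, climate_scenario = scn, ...)
      results[[paste0(rule, "x", scn)]] <-
        runScenario(cfg, site, normals, planting = planting,
                    verbose = verbose)
    }
  }
  results
}

#' Write a scenario result to tidy CSV files
#'
#' One biomass table (cell, species, year, agb) and one modifier-trace table
#' (cell, species, month, fSW, fVPD).
#'
#' @param result A \linkS4class{ScenarioResult}.
#' @param outdir Output directory.
#' @return Invisibly, the files written.
#' @export
writeScenarioResult <- function(result, outdir) {
  stopifnot(is(result, "ScenarioResult"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tag <- paste0(result@rule, "_", result@scenario)
  long <- data.frame(
    cell = rep(result@cells, times = length(result@years)),
    species = rep(result@species, times = length(result@years)),
    year = rep(result@years, each = length(result@cells)),
    agb = as.vector(result@agb))
  f1 <- file.path(outdir, paste0("agb_", tag, ".csv"))
  write.csv(long, f1, row.names = FALSE)
  f2 <- file.path(outdir, paste0("trace_", tag, ".csv"))
  write.csv(result@trace, f2, row.names = FALSE)
  invisible(c(f1, f2))
}
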