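## Synthetic study-site generator: stands in for downscaled climate normals,
## satellite landcover mosaics, soil-carbon surveys and a DEM, with the
## statistical structure the pipeline assumes (warming ordered across
## emissions pathways, valley SOC accumulation, hilly terrain).

## End-of-century warming midpoints (degC) per scenario, fully expressed in
## the 2061-2080 period and phased in linearly over earlier periods.
WARMING_MIDPOINT <- c(CS1 = 1.85, CS2 = 2.8, CS3 = 3.7)

## Mean global CO2 (ppm) per scenario and 20-year period, approximating the
## published SSP concentration trajectories.
DEFAULT_CO2_TABLE <- matrix(
  c(425, 450, 455,    # CS1 (SSP1-2.6)
    435, 490, 550,    # CS2 (SSP2-4.5)
    445, 525, 645),   # CS3 (SSP3-7.0)
  nrow = 3, byrow = TRUE,
  dimnames = list(CLIMATE_SCENARIOS, CLIMATE_PERIODS))

#' Default CO2 concentration table
#'
#' Mean atmospheric CO2 (ppm) for each climate scenario and 20-year normal
#' period, used to drive the CO2 response of canopy quantum efficiency.
#' Values approximate the published SSP trajectories; override by passing
#' \code{co2_table} to \code{\link{runScenario}}.
#'
#' @return A 3 x 3 numeric matrix (scenarios x periods).
#' @export
defaultCO2Table <- function() DEFAULT_CO2_TABLE

#' Generate a synthetic digital elevation model
#'
#' Smooth correlated random surface (Gaussian-filtered white noise) rescaled
#' to span \code{relief} metres, containing both ridges and hollows so the
#' topographic wetness index varies.
#'
#' @param size Cells per side (>= 8).
#' @param relief Total elevation range (m, > 0).
#' @param seed Integer seed; the surface is deterministic per seed.
#' @param smoothness Gaussian kernel standard deviation as a fraction of the
#'   grid side; larger is smoother.
#' @return A \code{size x size} numeric elevation matrix (m).
#' @export
generateDEM <- function(size, relief, seed = 1L, smoothness = 0.08) {
  if (!is.numeric(size) || size < 8) stop("'size' must be >= 8", call. = FALSE)
  if (!is.numeric(relief) || relief <= 0)
    stop("'relief' must be > 0", call. = FALSE)
  size <- as.integer(size)
  withSeed(childSeed(seed, 11L), {
    f <- gaussianSmoothField(size, sigma = max(1, smoothness * size))
    rescaleRange(f, 0, relief)
  })
}

#' Generate a synthetic soil organic carbon grid
#'
#' SOC (t C ha-1) negatively correlated with elevation (valley accumulation),
#' with added spatial noise, clamped to [0, 400], and an exact fraction of
#' cells flagged missing (\code{NA}) to emulate survey gaps. Default settings
#' straddle both fertility-scaling endpoints (below 40 and above 200 t/ha).
#'
#' @param dem Elevation matrix from \code{\link{generateDEM}}.
#' @param missing_frac Fraction of cells flagged missing, in [0, 1).
#' @param seed Integer seed.
#' @return Numeric matrix of SOC with \code{NA} for missing cells.
#' @export
generateSOC <- function(dem, missing_frac = 0.05, seed = 1L) {
  stopifnot(is.matrix(dem))
  if (!is.numeric(missing_frac) || missing_frac < 0 || missing_frac >= 1)
    stop("'missing_frac' must lie in [0, 1)", call. = FALSE)
  n <- length(dem)
  withSeed(childSeed(seed, 23L), {
    dn <- (dem - min(dem)) / max(max(dem) - min(dem), 1e-12)
    noise <- gaussianSmoothField(nrow(dem), sigma = max(1, 0.04 * nrow(dem)))
    noise <- noise / max(sd(noise), 1e-12) * 35
    soc <- 250 - 240 * dn + noise
    soc <- pmin(pmax(soc, 0), 400)
    nmiss <- floor(missing_frac * n)
    if (nmiss > 0) soc[sample.int(n, nmiss)] <- NA_real_
    matrix(soc, nrow(dem), ncol(dem))
  })
}

#' Generate a synthetic landcover mosaic and forest-extent history
#'
#' Produces a categorical mosaic containing (at minimum) shrubland, herbs,
#' existing coniferous/deciduous forest and water. The forest-history mask is
#' true on existing-forest cells plus an extra fraction of shrub/herb cells
#' (burned or harvested former forest); non-vegetated classes are never
#' marked as historical forest.
#'
#' @param dem Elevation matrix.
#' @param seed Integer seed.
#' @param former_forest_frac Fraction of non-forest vegetated cells also
#'   marked as historical forest.
#' @return List with integer matrix \code{landcover} (codes into
#'   \code{\link{landcoverLevels}}) and logical matrix \code{forest_history}.
#' @export
generateLandcover <- function(dem, seed = 1L, former_forest_frac = 0.15) {
  stopifnot(is.matrix(dem), nrow(dem) >= 8)
  if (former_forest_frac < 0 || former_forest_frac > 1)
    stop("'former_forest_frac' must lie in [0, 1]", call. = FALSE)
  n <- nrow(dem)
  withSeed(childSeed(seed, 37L), {
    dn <- (dem - min(dem)) / max(max(dem) - min(dem), 1e-12)
    u <- gaussianSmoothField(n, sigma = max(1, 0.06 * n))
    u <- rank(u) / length(u)                 # uniform spatial field
    lc <- matrix(NA_integer_, n, n)
    code <- function(name) match(name, LANDCOVER_LEVELS)
    water <- dn <= stats::quantile(dn, 0.04)
    rock <- dn >= stats::quantile(dn, 0.98)
    lc[water] <- code("water")
    lc[rock] <- code("rock_rubble")
    open <- is.na(lc)
    ## carve the vegetated area by the correlated uniform field
    lc[open & u < 0.28] <- code("coniferous_forest")
    lc[open & u >= 0.28 & u < 0.38] <- code("deciduous_forest")
    lc[open & u >= 0.38 & u < 0.72] <- code("shrubland")
    lc[is.na(lc)] <- code("herbs")
    forest <- lc %in% c(code("coniferous_forest"), code("deciduous_forest"))
    hist <- matrix(forest, n, n)
    openveg <- which(lc %in% c(code("shrubland"), code("herbs")))
    extra <- sample(openveg, size = floor(former_forest_frac * length(openveg)))
    hist[extra] <- TRUE
    list(landcover = lc, forest_history = hist)
  })
}

## Daily extraterrestrial solar radiation (MJ m-2 d-1) at mid-month, standard
## astronomical formula.
extraterrestrialRadiation <- function(latitude, month) {
  J <- cumsum(c(0, DAYS_IN_MONTH))[month] + DAYS_IN_MONTH[month] / 2
  phi <- latitude * pi / 180
  delta <- 0.409 * sin(2 * pi * J / 365 - 1.39)
  dr <- 1 + 0.033 * cos(2 * pi * J / 365)
  x <- pmin(pmax(-tan(phi) * tan(delta), -1), 1)
  ws <- acos(x)
  (24 * 60 / pi) * 0.0820 * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
}

#' Generate monthly climate normals for one scenario and period
#'
#' Sinusoidal annual temperature cycle with latitude-dependent mean and
#' amplitude; precipitation with a summer maximum; solar radiation from the
#' top-of-atmosphere seasonal curve attenuated by a fixed cloudiness factor;
#' frost days as a normal dose-response on tmin. Scenario warming is additive:
#' the 2061-2080 increment defaults to the midpoints of the published
#' end-of-century ranges (CS1 1.85, CS2 2.8, CS3 3.7 degC) and is phased in
#' linearly across the three periods. The seed perturbs the monthly curves;
#' the perturbation is shared across scenarios and periods so warming
#' contrasts are exact.
#'
#' @param latitude Degrees north, in [45, 70].
#' @param scenario \code{"CS1"}, \code{"CS2"} or \code{"CS3"}.
#' @param period \code{"2021-2040"}, \code{"2041-2060"} or \code{"2061-2080"}.
#' @param seed Integer seed.
#' @param warming_2080 Named end-of-period warming (degC) per scenario.
#' @param cloud_attenuation Fraction of clear-sky radiation reaching the
#'   ground.
#' @param frost_sigma Width (degC) of the frost-day dose-response on tmin.
#' @return A \linkS4class{ClimateNormals}.
#' @export
generateClimate <- function(latitude, scenario, period, seed = 1L,
                            warming_2080 = WARMING_MIDPOINT,
                            cloud_attenuation = 0.55, frost_sigma = 4) {
  if (!is.numeric(latitude) || latitude < 45 || latitude > 70)
    stop("'latitude' must lie in [45, 70]", call. = FALSE)
  if (!scenario %in% CLIMATE_SCENARIOS)
    stop("unknown scenario: ", scenario, call. = FALSE)
  if (!period %in% CLIMATE_PERIODS)
    stop("unknown period: ", period, call. = FALSE)
  m <- 1:12
  days <- DAYS_IN_MONTH
  ## seed-driven perturbation independent of scenario/period, so that the
  ## additive warming schedule orders periods and scenarios exactly
  jit <- withSeed(childSeed(seed, 53L), list(
    t = rnorm(12, 0, 0.4), p = rnorm(12, 0, 4), mat = rnorm(1, 0, 0.8)))
  mat <- 22 - 0.4 * latitude + jit$mat
  amp <- 8 + 0.15 * latitude
  pidx <- match(period, CLIMATE_PERIODS)
  warm <- warming_2080[[scenario]] * pidx / 3
  tmean <- mat + amp * cos(2 * pi * (m - 7) / 12) + jit$t + warm
  dtr <- 9
  tmin <- tmean - dtr / 2
  tmax <- tmean + dtr / 2
  precip <- pmax(40 * (1 + 0.6 * cos(2 * pi * (m - 7) / 12)) + jit$p, 0)
  solar <- pmax(cloud_attenuation * extraterrestrialRadiation(latitude, m),
                0.1)
  frost <- days * pnorm(-tmin / frost_sigma)
  new("ClimateNormals",
      normals = data.frame(month = m, tmin = tmin, tmax = tmax,
                           tmean = tmean, precip = precip, solar_rad = solar,
                           frost_days = frost, days = days),
      scenario = scenario, period = period, latitude = latitude)
}

#' Generate a complete synthetic landscape bundle
#'
#' Convenience wrapper: DEM, SOC, landcover/forest history, and climate
#' normals for every scenario x period combination, co-registered on one
#' square grid.
#'
#' @param size Cells per side.
#' @param latitude Degrees north.
#' @param seed Integer master seed (layer-specific streams are derived).
#' @param relief DEM relief (m).
#' @param cellsize Cell edge length (m); default 100 m (1 ha cells).
#' @param missing_frac Missing-SOC fraction.
#' @param ... Passed to \code{\link{generateClimate}}.
#' @return A \linkS4class{LandscapeBundle}.
#' @export
generateLandscape <- function(size = 32, latitude = 55, seed = 1L,
                              relief = 200, cellsize = 100,
                              missing_frac = 0.05, ...) {
  dem <- generateDEM(size, relief, seed = seed)
  soc <- generateSOC(dem, missing_frac = missing_frac, seed = seed)
  lc <- generateLandcover(dem, seed = seed)
  clim <- list()
  for (cs in CLIMATE_SCENARIOS)
    for (pd in CLIMATE_PERIODS)
      clim[[paste(cs, pd, sep = "|")]] <-
        generateClimate(latitude, cs, pd, seed = seed, ...)
  new("LandscapeBundle", dem = dem, soc = soc, landcover = lc$landcover,
      forest_history = lc$forest_history, cellsize = cellsize,
      climate = clim, seed = as.integer(seed))
}

#' Write a landscape bundle to disk
#'
#' Each static layer is written as an ESRI ASCII grid plus a JSON sidecar of
#' generation parameters; climate normals go to one tidy CSV (scenario,
#' period, month, variable columns).
#'
#' @param bundle A \linkS4class{LandscapeBundle}.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
writeLandscape <- function(bundle, outdir) {
  stopifnot(is(bundle, "LandscapeBundle"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cs <- bundle@cellsize
  files <- c(
    writeAsciiGrid(bundle@dem, file.path(outdir, "dem.asc"), cellsize = cs),
    writeAsciiGrid(bundle@soc, file.path(outdir, "soc.asc"), cellsize = cs),
    writeAsciiGrid(bundle@landcover + 0,
                   file.path(outdir, "landcover.asc"), cellsize = cs),
    writeAsciiGrid(bundle@forest_history + 0,
                   file.path(outdir, "forest_history.asc"), cellsize = cs))
  clim <- do.call(rbind, lapply(bundle@climate, function(cn)
    cbind(scenario = cn@scenario, period = cn@period, cn@normals)))
  cf <- file.path(outdir, "climate_normals.csv")
  write.csv(clim, cf, row.names = FALSE)
  sidecar <- file.path(outdir, "landscape.json")
  jsonlite::write_json(list(seed = bundle@seed, cellsize = cs,
                            size = nrow(bundle@dem),
                            landcover_levels = LANDCOVER_LEVELS),
                       sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(files, cf, sidecar))
}
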