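#' @import methods
NULL

#' ClimateNormals: monthly climate normals for one scenario and period
#'
#' Holds the twelve monthly normals (tmin, tmax, precipitation, solar
#' radiation, frost days) that drive the growth engine, tagged with the
#' emissions scenario (CS1 = SSP1-2.6, CS2 = SSP2-4.5, CS3 = SSP3-7.0) and the
#' 20-year normal period. Normals are site-level: every cell of a landscape
#' shares them, mirroring downscaled point normals at a site centroid.
#'
#' @slot normals data.frame with columns \code{month}, \code{tmin},
#'   \code{tmax}, \code{tmean}, \code{precip}, \code{solar_rad},
#'   \code{frost_days}, \code{days} (units: degC, degC, degC, mm/month,
#'   MJ m-2 d-1, days, days).
#' @slot scenario Character, one of \code{"CS1"}, \code{"CS2"}, \code{"CS3"}.
#' @slot period Character, one of \code{"2021-2040"}, \code{"2041-2060"},
#'   \code{"2061-2080"}.
#' @slot latitude Numeric, degrees north.
#' @exportClass ClimateNormals
setClass("ClimateNormals",
  representation(normals = "data.frame", scenario = "character",
                 period = "character", latitude = "numeric"),
  validity = function(object) {
    n <- object@normals
    need <- c("month", "tmin", "tmax", "tmean", "precip", "solar_rad",
              "frost_days", "days")
    if (!all(need %in% names(n)))
      return(paste("normals must contain columns:", paste(need, collapse = ", ")))
    if (nrow(n) != 12L || !identical(as.integer(n$month), 1:12))
      return("normals must have one row per calendar month, in order")
    if (any(n$tmax < n$tmin)) return("tmax must be >= tmin")
    if (any(n$precip < 0)) return("precip must be >= 0")
    if (any(n$solar_rad <= 0)) return("solar_rad must be > 0")
    if (any(n$frost_days < 0 | n$frost_days > n$days))
      return("frost_days must lie in [0, days-in-month]")
    if (!object@scenario %in% CLIMATE_SCENARIOS) return("unknown scenario")
    if (!object@period %in% CLIMATE_PERIODS) return("unknown period")
    TRUE
  })

#' LandscapeBundle: co-registered synthetic landscape layers
#'
#' All static layers of a synthetic study site on one square grid: elevation,
#' soil organic carbon (with explicit missing cells), landcover class, the
#' "ever classified as forest" history mask, plus the climate normals for
#' every scenario x period combination.
#'
#' @slot dem Numeric matrix, elevation (m).
#' @slot soc Numeric matrix, soil organic carbon (t C ha-1); \code{NA} where
#'   missing.
#' @slot landcover Integer matrix of codes into \code{landcoverLevels()}.
#' @slot forest_history Logical matrix.
#' @slot cellsize Numeric, cell edge length (m).
#' @slot climate List of \linkS4class{ClimateNormals}, named
#'   \code{"<scenario>|<period>"}.
#' @slot seed Integer seed the bundle was generated from.
#' @exportClass LandscapeBundle
setClass("LandscapeBundle",
  representation(dem = "matrix", soc = "matrix", landcover = "matrix",
                 forest_history = "matrix", cellsize = "numeric",
                 climate = "list", seed = "integer"),
  validity = function(object) {
    dm <- dim(object@dem)
    for (ly in c("soc", "landcover", "forest_history"))
      if (!identical(dim(slot(object, ly)), dm))
        return(sprintf("layer '%s' does not share the DEM grid geometry", ly))
    lc <- object@landcover
    if (any(!lc %in% seq_along(LANDCOVER_LEVELS)))
      return("landcover codes outside the class vocabulary")
    bad <- LANDCOVER_LEVELS[lc] %in% NONVEGETATED_CLASSES & object@forest_history
    if (any(bad))
      return("water/rock/snow/bryoid cells must never be marked forest_history")
    if (length(object@cellsize) != 1L || object@cellsize <= 0)
      return("cellsize must be a single positive number")
    TRUE
  })

#' SiteGrid: static per-cell model inputs derived from a landscape
#'
#' @slot fr Numeric matrix, fertility rating in [0, 1].
#' @slot masw Numeric matrix, maximum available soil water (mm), in
#'   [100, 300].
#' @slot eligible Logical matrix, planting eligibility.
#' @slot nw Numeric matrix, normalized wetness in [0, 1].
#' @slot soil_class Character scalar soil texture class (one of
#'   \code{names(soilClassTable())}).
#' @slot cellsize Numeric, cell edge length (m).
#' @exportClass SiteGrid
setClass("SiteGrid",
  representation(fr = "matrix", masw = "matrix", eligible = "matrix",
                 nw = "matrix", soil_class = "character",
                 cellsize = "numeric"),
  validity = function(object) {
    dm <- dim(object@fr)
    for (ly in c("masw", "eligible", "nw"))
      if (!identical(dim(slot(object, ly)), dm))
        return(sprintf("layer '%s' does not share the grid geometry", ly))
    if (any(object@fr < 0 | object@fr > 1, na.rm = TRUE))
      return("fertility rating must lie in [0, 1]")
    if (any(object@masw < 100 - 1e-9 | object@masw > 300 + 1e-9, na.rm = TRUE))
      return("MASW must lie in [100, 300] mm")
    ok <- is.finite(object@nw)
    if (any(object@nw[ok] < -1e-12 | object@nw[ok] > 1 + 1e-12))
      return("normalized wetness must lie in [0, 1]")
    TRUE
  })

#' PlantingMap: per-cell species assignment under a planting rule
#'
#' @slot assignment Character matrix: \code{"conifer"}, \code{"deciduous"} on
#'   eligible cells, \code{NA} elsewhere.
#' @slot rule Character, one of \code{"SM1"}, \code{"SM2"}, \code{"SM3"}.
#' @slot seed Integer seed used for the random middle wetness band.
#' @exportClass PlantingMap
setClass("PlantingMap",
  representation(assignment = "matrix", rule = "character", seed = "integer"),
  validity = function(object) {
    a <- object@assignment
    if (!all(a[!is.na(a)] %in% c("conifer", "deciduous")))
      return("assignments must be 'conifer' or 'deciduous'")
    if (!object@rule %in% PLANTING_RULES) return("unknown planting rule")
    TRUE
  })

#' ScenarioResult: outputs of one planting-rule x climate-scenario run
#'
#' @slot rule Planting rule id (SM1-SM3).
#' @slot scenario Climate scenario id (CS1-CS3).
#' @slot cells Integer vector of planted cell indices (column-major into the
#'   site grid).
#' @slot species Character vector, species role per planted cell.
#' @slot agb Numeric matrix (planted cells x years): aboveground biomass,
#'   tDM ha-1, recorded at the August state of each year.
#' @slot years Integer vector of simulation years.
#' @slot stems Numeric vector, final stem density (trees ha-1) per cell.
#' @slot dbh Numeric vector, final mean diameter at breast height (cm).
#' @slot lai Numeric vector, final-August leaf area index.
#' @slot trace data.frame of the analysis-year monthly modifier trace:
#'   \code{cell}, \code{species}, \code{month}, \code{fSW}, \code{fVPD}.
#' @slot trace_year Integer, calendar year of the trace.
#' @slot dim Integer grid dimensions of the parent site.
#' @exportClass ScenarioResult
setClass("ScenarioResult",
  representation(rule = "character", scenario = "character",
                 cells = "integer", species = "character", agb = "matrix",
                 years = "integer", stems = "numeric", dbh = "numeric",
                 lai = "numeric", trace = "data.frame", trace_year = "integer",
                 dim = "integer"),
  validity = function(object) {
    np <- length(object@cells)
    if (length(object@species) != np) return("species length != cells length")
    if (np > 0 && nrow(object@agb) != np) return("agb rows != cells length")
    if (np > 0 && ncol(object@agb) != length(object@years))
      return("agb columns != years length")
    if (any(object@agb < 0, na.rm = TRUE)) return("AGB must be >= 0")
    TRUE
  })

#' @describeIn ClimateNormals-class compact display
#' @param object A \code{ClimateNormals}.
#' @export
setMethod("show", "ClimateNormals", function(object) {
  n <- object@normals
  cat(sprintf("ClimateNormals %s / %s (lat %.1f)\n", object@scenario,
              object@period, object@latitude))
  cat(sprintf("  MAT %.2f degC | annual precip %.0f mm | solar %.1f-%.1f MJ m-2 d-1\n",
              mean(n$tmean), sum(n$precip), min(n$solar_rad), max(n$solar_rad)))
})

#' @describeIn LandscapeBundle-class compact display
#' @param object A \code{LandscapeBundle}.
#' @export
setMethod("show", "LandscapeBundle", function(object) {
  dm <- dim(object@dem)
  lc <- table(factor(LANDCOVER_LEVELS[object@landcover],
                     levels = LANDCOVER_LEVELS))
  cat(sprintf("LandscapeBundle %dx%d cells (%.0f m), seed %d\n",
              dm[1], dm[2], object@cellsize, object@seed))
  cat(sprintf("  elevation %.0f-%.0f m | SOC %.0f-%.0f t/ha (%d missing)\n",
              min(object@dem), max(object@dem), min(object@soc, na.rm = TRUE),
              max(object@soc, na.rm = TRUE), sum(is.na(object@soc))))
  cat("  landcover:", paste(sprintf("%s=%d", names(lc)[lc > 0], lc[lc > 0]),
                            collapse = ", "), "\n")
  cat(sprintf("  climate sets: %d\n", length(object@climate)))
})

#' @describeIn SiteGrid-class compact display
#' @param object A \code{SiteGrid}.
#' @export
setMethod("show", "SiteGrid", function(object) {
  cat(sprintf("SiteGrid %dx%d cells: %d eligible (%.1f%%)\n",
              nrow(object@fr), ncol(object@fr), sum(object@eligible),
              100 * mean(object@eligible)))
  cat(sprintf("  FR %.2f-%.2f | MASW %.0f-%.0f mm | soil '%s'\n",
              min(object@fr), max(object@fr), min(object@masw),
              max(object@masw), object@soil_class))
})

#' @describeIn ScenarioResult-class compact display
#' @param object A \code{ScenarioResult}.
#' @export
setMethod("show", "ScenarioResult", function(object) {
  cat(sprintf("ScenarioResult %s x %s: %d planted cells, %d-%d\n",
              object@rule, object@scenario, length(object@cells),
              min(object@years), max(object@years)))
  if (length(object@cells)) {
    fin <- object@agb[, ncol(object@agb)]
    cat(sprintf("  final AGB mean %.1f (median %.1f, sd %.1f) tDM ha-1\n",
                mean(fin), median(fin), sd(fin)))
  }
})

#' Landcover class vocabulary
#'
#' @return Character vector of the landcover class names, in code order.
#' @export
landcoverLevels <- function() LANDCOVER_LEVELS
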