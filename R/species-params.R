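## Species physiological parameter sets. Values are configuration, shipped as
## editable YAML files under inst/extdata/species/; the constructor validates
## ordering/range constraints that the engine relies on.

SPECIES_PARAM_NAMES <- c(
  "Tmin_g", "Topt_g", "Tmax_g", "kF", "CoeffCond", "MaxCond", "LAIgcx",
  "SWconst", "SWpower", "fN0", "fNn", "MaxAge", "rAge", "nAge", "alphaCx",
  "Y", "k", "pFS2", "pFS20", "aS", "nS", "pRx", "pRn", "m0", "gammaF0",
  "gammaFx", "tgammaF", "gammaR", "gammaN", "wSx1000", "thinPower", "SLA0",
  "SLA1", "tSLA", "fCalpha700", "MaxIntcptn", "LAImaxIntcptn", "deciduous",
  "leaf_on_Tthresh")

#' SpeciesParams: the 3-PG physiological parameter set for one species
#'
#' @slot name Species identifier.
#' @slot params Named list of parameter values (see
#'   \code{\link{speciesParams}} for the vocabulary and units).
#' @exportClass SpeciesParams
setClass("SpeciesParams",
  representation(name = "character", params = "list"),
  validity = function(object) {
    p <- object@params
    miss <- setdiff(SPECIES_PARAM_NAMES, names(p))
    if (length(miss))
      return(paste("missing parameters:", paste(miss, collapse = ", ")))
    if (!(p$Tmin_g < p$Topt_g && p$Topt_g < p$Tmax_g))
      return("require Tmin_g < Topt_g < Tmax_g")
    if (!(p$Y > 0 && p$Y <= 1)) return("Y must lie in (0, 1]")
    if (p$pRn > p$pRx) return("require pRn <= pRx")
    if (p$gammaF0 > p$gammaFx) return("require gammaF0 <= gammaFx")
    rates <- c(p$gammaF0, p$gammaFx, p$gammaR, p$gammaN, p$kF)
    if (any(rates < 0)) return("rates must be >= 0")
    if (p$MaxAge <= 0) return("MaxAge must be > 0")
    TRUE
  })

#' @describeIn SpeciesParams-class compact display
#' @param object A \code{SpeciesParams}.
#' @export
setMethod("show", "SpeciesParams", function(object) {
  p <- object@params
  cat(sprintf("SpeciesParams '%s' (%s)\n", object@name,
              if (isTRUE(p$deciduous)) "deciduous" else "evergreen"))
  cat(sprintf("  T range %g/%g/%g degC | alphaCx %g | Y %g | wSx1000 %g kg\n",
              p$Tmin_g, p$Topt_g, p$Tmax_g, p$alphaCx, p$Y, p$wSx1000))
})

#' Extract a parameter value
#' @param x A \code{SpeciesParams}.
#' @param i Parameter name.
#' @param exact Ignored (standard generic argument).
#' @export
setMethod("[[", "SpeciesParams", function(x, i, exact = TRUE) x@params[[i]])

#' Construct a species parameter set
#'
#' Units follow 3-PG convention: growth temperatures (\code{Tmin_g},
#' \code{Topt_g}, \code{Tmax_g}, degC); frost sensitivity \code{kF}
#' (dimensionless); stomatal VPD response \code{CoeffCond} (mbar-1); maximum
#' canopy conductance \code{MaxCond} (m s-1) saturating at LAI
#' \code{LAIgcx}; soil-water response \code{SWconst}/\code{SWpower}; fertility
#' response \code{fN0}/\code{fNn}; age response \code{MaxAge} (yr),
#' \code{rAge}, \code{nAge}; maximum canopy quantum efficiency \code{alphaCx}
#' (mol C mol PAR-1); NPP:GPP ratio \code{Y}; light extinction \code{k};
#' foliage:stem partitioning \code{pFS2}/\code{pFS20} at 2 and 20 cm DBH;
#' stem allometry \code{aS}/\code{nS} (kg tree-1 = aS DBH^nS); root
#' allocation bounds \code{pRx}/\code{pRn} and fertility effect \code{m0};
#' litterfall \code{gammaF0}/\code{gammaFx} (month-1) with midpoint
#' \code{tgammaF} (months); root turnover \code{gammaR} (month-1); background
#' mortality \code{gammaN} (yr-1); self-thinning \code{wSx1000} (kg tree-1 at
#' 1000 trees ha-1) and \code{thinPower}; specific leaf area
#' \code{SLA0}/\code{SLA1} (m2 kg-1) with age midpoint \code{tSLA} (yr); CO2
#' response \code{fCalpha700}; rainfall interception \code{MaxIntcptn}
#' saturating at LAI \code{LAImaxIntcptn}; phenology flags \code{deciduous}
#' and \code{leaf_on_Tthresh} (degC).
#'
#' @param name Species identifier.
#' @param ... Parameter values overriding nothing: all parameters in the
#'   vocabulary must be supplied (use \code{\link{readSpeciesParams}} or
#'   \code{\link{defaultSpecies}} for shipped sets).
#' @return A \linkS4class{SpeciesParams}.
#' @export
speciesParams <- function(name, ...) {
  p <- list(...)
  if (length(p) == 1L && is.list(p[[1]]) && is.null(names(p)[1]))
    p <- p[[1]]
  new("SpeciesParams", name = name, params = p[SPECIES_PARAM_NAMES])
}

#' Read a species parameter file
#'
#' Flat key-value YAML, one file per species; the \code{name} key is optional
#' (defaults to the file stem).
#'
#' @param path Path to a YAML parameter file.
#' @return A \linkS4class{SpeciesParams}.
#' @export
readSpeciesParams <- function(path) {
  if (!file.exists(path)) stop("species file not found: ", path, call. = FALSE)
  p <- yaml::read_yaml(path)
  ## a bare `Y` key is YAML-1.1 boolean TRUE; accept files written that way
  names(p)[names(p) == "TRUE"] <- "Y"
  nm <- p$name %||% sub("\\.[^.]*$", "", basename(path))
  p$name <- NULL
  speciesParams(nm, p)
}

#' Write a species parameter file
#'
#' @param params A \linkS4class{SpeciesParams}.
#' @param path Output YAML path.
#' @return Invisibly, \code{path}.
#' @export
writeSpeciesParams <- function(params, path) {
  stopifnot(is(params, "SpeciesParams"))
  yaml::write_yaml(c(list(name = params@name), params@params), path)
  invisible(path)
}

#' Load a shipped species parameter set
#'
#' Three editable sets ship with the package: \code{"black_spruce"} and
#' \code{"lodgepole_pine"} (evergreen conifers) and \code{"generic_deciduous"}
#' (a hybrid-poplar-like fast-growing broadleaf).
#'
#' @param species One of the shipped species identifiers.
#' @return A \linkS4class{SpeciesParams}.
#' @export
defaultSpecies <- function(species = c("black_spruce", "lodgepole_pine",
                                       "generic_deciduous")) {
  species <- match.arg(species)
  path <- system.file("extdata", "species", paste0(species, ".yaml"),
                      package = "afforest3PG", mustWork = TRUE)
  readSpeciesParams(path)
}

#' Soil texture class table
#'
#' Canonical 3-PG soil-water response constants by texture class; the site
#' grid's \code{soil_class} selects the row used for every cell.
#'
#' @return Named list of \code{c(SWconst, SWpower)} pairs.
#' @export
soilClassTable <- function() {
  list(sand = c(SWconst = 0.7, SWpower = 9),
       sandy_loam = c(SWconst = 0.6, SWpower = 7),
       clay_loam = c(SWconst = 0.5, SWpower = 5),
       clay = c(SWconst = 0.4, SWpower = 3))
}
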