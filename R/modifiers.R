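## Dimensionless environmental growth modifiers. Each takes a value between
## 0 (system shut-down) and 1 (no constraint); the CO2 modifier exceeds 1
## above the 350 ppm baseline. All functions are vectorised over their first
## argument.

#' Vapour pressure deficit from the diurnal temperature range
#'
#' Day-time VPD approximated as half the difference between saturation vapour
#' pressure at the daily maximum and minimum temperature (Tetens form,
#' mbar).
#'
#' @param tmin,tmax Daily minimum and maximum temperature (degC),
#'   \code{tmax >= tmin}.
#' @return VPD in mbar.
#' @export
computeVPD <- function(tmin, tmax) {
  if (any(tmax < tmin)) stop("'tmax' must be >= 'tmin'", call. = FALSE)
  esat <- function(T) 6.1078 * exp(17.269 * T / (237.3 + T))
  0.5 * (esat(tmax) - esat(tmin))
}

#' Temperature growth modifier
#'
#' Skewed parabolic response between the growth minimum and maximum
#' temperatures, equal to 1 at the optimum and 0 outside the range.
#'
#' @param tmean Mean monthly temperature (degC).
#' @param params A \linkS4class{SpeciesParams} (uses \code{Tmin_g},
#'   \code{Topt_g}, \code{Tmax_g}).
#' @return fT in [0, 1].
#' @export
temperatureModifier <- function(tmean, params) {
  Tn <- params[["Tmin_g"]]; To <- params[["Topt_g"]]; Tx <- params[["Tmax_g"]]
  ft <- ((tmean - Tn) / (To - Tn)) *
    ((Tx - tmean) / (Tx - To))^((Tx - To) / (To - Tn))
  ft[tmean <= Tn | tmean >= Tx] <- 0
  pmin(pmax(ft, 0), 1)
}

#' Frost-day growth modifier
#'
#' Linear penalty on the fraction of frost days in the month, scaled by the
#' species frost sensitivity and clamped to [0, 1].
#'
#' @param frost_days Number of frost days in the month.
#' @param days_in_month Days in the month.
#' @param kF Frost sensitivity (dimensionless, >= 0).
#' @return fFrost in [0, 1].
#' @export
frostModifier <- function(frost_days, days_in_month, kF) {
  if (any(frost_days < 0) || any(frost_days > days_in_month))
    stop("'frost_days' must lie in [0, days_in_month]", call. = FALSE)
  pmin(pmax(1 - kF * (frost_days / days_in_month), 0), 1)
}

#' Vapour-pressure-deficit growth modifier
#'
#' Exponential stomatal closure with increasing day-time VPD.
#'
#' @param vpd Vapour pressure deficit (mbar, >= 0).
#' @param CoeffCond Stomatal response coefficient (mbar-1).
#' @return fVPD in (0, 1].
#' @export
vpdModifier <- function(vpd, CoeffCond) {
  if (any(vpd < 0)) stop("'vpd' must be >= 0", call. = FALSE)
  exp(-CoeffCond * vpd)
}

#' Soil-water growth modifier
#'
#' Sigmoidal response to the relative soil-water deficit, shaped by the soil
#' texture constants.
#'
#' @param asw Available soil water (mm), in [0, masw].
#' @param masw Maximum available soil water (mm, > 0).
#' @param SWconst,SWpower Soil texture response constants.
#' @return fSW in (0, 1].
#' @export
soilWaterModifier <- function(asw, masw, SWconst, SWpower) {
  if (any(masw <= 0)) stop("'masw' must be > 0", call. = FALSE)
  moistRatio <- asw / masw
  1 / (1 + ((1 - moistRatio) / SWconst)^SWpower)
}

#' Fertility growth modifier
#'
#' @param fr Fertility rating in [0, 1].
#' @param fN0 Modifier value at fertility 0.
#' @param fNn Response power.
#' @return fNutr in [fN0, 1].
#' @export
fertilityModifier <- function(fr, fN0, fNn) {
  if (any(fr < 0 | fr > 1)) stop("'fr' must lie in [0, 1]", call. = FALSE)
  1 - (1 - fN0) * (1 - fr)^fNn
}

#' Age growth modifier
#'
#' Declining hydraulic/age-related efficiency, 1 at age 0 and 0.5 at relative
#' age \code{rAge}.
#'
#' @param age_years Stand age (yr, >= 0).
#' @param MaxAge Maximum stand age (yr).
#' @param rAge Relative age at which the modifier halves.
#' @param nAge Response power.
#' @return fAge in (0, 1].
#' @export
ageModifier <- function(age_years, MaxAge, rAge, nAge) {
  stopifnot(MaxAge > 0, all(age_years >= 0))
  1 / (1 + ((age_years / MaxAge) / rAge)^nAge)
}

#' Atmospheric CO2 modifier of canopy quantum efficiency
#'
#' Saturating response anchored at 1 for the 350 ppm baseline and at
#' \code{fCalpha700} for 700 ppm.
#'
#' @param co2_ppm Atmospheric CO2 concentration (ppm, > 0).
#' @param fCalpha700 Quantum-efficiency ratio at 700 ppm.
#' @return fCalpha (>= 1 for CO2 >= 350 ppm when \code{fCalpha700 >= 1}).
#' @export
co2Modifier <- function(co2_ppm, fCalpha700) {
  if (any(co2_ppm <= 0)) stop("'co2_ppm' must be > 0", call. = FALSE)
  fcax <- fCalpha700 / (2 - fCalpha700)
  fcax * co2_ppm / (350 * (fcax - 1) + co2_ppm)
}

#' Full modifier set for one month
#'
#' Convenience constructor evaluating every modifier and the physiological
#' product \code{PhysMod = fAge * min(fVPD, fSW)} (the most limiting of the
#' water-related constraints, scaled by age).
#'
#' @param climate Named list with \code{tmin}, \code{tmax}, \code{tmean},
#'   \code{frost_days}, \code{days}, \code{co2}.
#' @param asw Available soil water (mm).
#' @param masw Maximum available soil water (mm).
#' @param fr Fertility rating.
#' @param age_years Stand age (yr).
#' @param params A \linkS4class{SpeciesParams}.
#' @param SWconst,SWpower Optional soil texture overrides (default from
#'   \code{params}).
#' @return Named list with fT, fFrost, fVPD, fSW, fNutr, fAge, fCalpha, VPD
#'   and PhysMod.
#' @export
modifierSet <- function(climate, asw, masw, fr, age_years, params,
                        SWconst = NULL, SWpower = NULL) {
  vpd <- computeVPD(climate$tmin, climate$tmax)
  fT <- temperatureModifier(climate$tmean, params)
  fFrost <- frostModifier(climate$frost_days, climate$days, params[["kF"]])
  fVPD <- vpdModifier(vpd, params[["CoeffCond"]])
  fSW <- soilWaterModifier(asw, masw, SWconst %||% params[["SWconst"]],
                           SWpower %||% params[["SWpower"]])
  fNutr <- fertilityModifier(fr, params[["fN0"]], params[["fNn"]])
  fAge <- ageModifier(age_years, params[["MaxAge"]], params[["rAge"]],
                      params[["nAge"]])
  fCalpha <- co2Modifier(climate$co2 %||% 350, params[["fCalpha700"]])
  list(fT = fT, fFrost = fFrost, fVPD = fVPD, fSW = fSW, fNutr = fNutr,
       fAge = fAge, fCalpha = fCalpha, VPD = vpd,
       PhysMod = fAge * pmin(fVPD, fSW))
}
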