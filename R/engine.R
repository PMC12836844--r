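## Monthly 3-PG stand simulator for one species on one cell: light-use-
## efficiency production constrained by environmental modifiers, allometric
## allocation, litterfall and deciduous phenology, density-dependent
## mortality, and a monthly soil-water bucket with Penman-Monteith
## transpiration.

## physical constants of the production and transpiration chains
MOL_PAR_PER_MJ_PAR <- 4.6   # mol PAR per MJ of PAR (PAR = half of solar)
GDM_PER_MOL_C <- 24         # g dry matter per mol C fixed
RHO_AIR <- 1.2              # kg m-3
LAMBDA_VAP <- 2460000       # J kg-1, latent heat of vaporisation
VPD_CONV <- 0.000622        # specific-humidity deficit per mbar VPD
E20 <- 2.2                  # dimensionless slope term of the combination eq.
BL_COND <- 0.2              # m s-1, fixed boundary-layer conductance
NETRAD_FRAC <- 0.8          # net radiation as a fraction of solar radiation
DYING_TREE_MASS_FRAC <- 0.2 # mass fraction of the mean tree lost per death

#' Initial stand state at planting
#'
#' @param params A \linkS4class{SpeciesParams}.
#' @param stems Initial stem density (trees ha-1).
#' @param Wf,Ws,Wr Initial foliage/stem/root dry mass pools (tDM ha-1).
#' @param masw Site maximum available soil water (mm); the bucket starts
#'   full.
#' @param first_tmean Mean temperature of the first simulated month, used to
#'   set the initial leaf state of deciduous stands (foliage held as reserve
#'   when planting happens before the growing season).
#' @return A stand-state list with elements \code{Wf}, \code{Ws}, \code{Wr}
#'   (tDM ha-1), \code{N} (trees ha-1), \code{ASW} (mm), \code{age} (months),
#'   \code{foliage_reserve} (tDM ha-1) and \code{leaf_on}.
#' @export
newStandState <- function(params, stems = 1650, Wf = 0.2, Ws = 0.6, Wr = 0.2,
                          masw = 200, first_tmean = -10) {
  st <- list(Wf = Wf, Ws = Ws, Wr = Wr, N = stems, ASW = masw, age = 0L,
             foliage_reserve = 0, leaf_on = TRUE)
  if (isTRUE(params[["deciduous"]]) &&
      first_tmean < params[["leaf_on_Tthresh"]]) {
    st$foliage_reserve <- st$Wf
    st$Wf <- 0
    st$leaf_on <- FALSE
  }
  st
}

#' Age-dependent specific leaf area
#'
#' Interpolates between the young and mature specific leaf area with a
#' Gaussian-in-age transition centred on \code{tSLA}; recomputed every month
#' so deciduous canopies re-expressed from reserve carry the current-age SLA.
#'
#' @param age_months Stand age in months.
#' @param params A \linkS4class{SpeciesParams}.
#' @return SLA (m2 kg-1).
#' @export
specificLeafArea <- function(age_months, params) {
  age_yr <- age_months / 12
  params[["SLA1"]] + (params[["SLA0"]] - params[["SLA1"]]) *
    exp(-log(2) * (age_yr / params[["tSLA"]])^2)
}

#' Canopy light interception and production for one month
#'
#' LAI from foliage mass and age-dependent SLA; absorbed PAR from Beer's law;
#' GPP as maximum quantum efficiency down-regulated by the modifier product;
#' NPP as a fixed fraction Y of GPP. Deciduous stands in the leaf-off state
#' produce nothing.
#'
#' @param state Stand state (see \code{\link{newStandState}}).
#' @param climate Month climate list (\code{tmin}, \code{tmax}, \code{tmean},
#'   \code{precip}, \code{solar_rad}, \code{frost_days}, \code{days},
#'   \code{co2}).
#' @param fr Site fertility rating.
#' @param params A \linkS4class{SpeciesParams}.
#' @param modifiers Optional precomputed \code{\link{modifierSet}}.
#' @param SWconst,SWpower Optional soil texture overrides.
#' @return List with \code{GPP}, \code{NPP} (tDM ha-1 month-1), \code{LAI},
#'   \code{SLA} and the \code{modifiers} used.
#' @export
canopyProduction <- function(state, climate, fr, params, modifiers = NULL,
                             SWconst = NULL, SWpower = NULL) {
  if (is.null(modifiers))
    modifiers <- modifierSet(climate, state$ASW, climate$masw %||% state$ASW,
                             fr, state$age / 12, params, SWconst, SWpower)
  sla <- specificLeafArea(state$age, params)
  lai <- state$Wf * sla * 0.1
  if (isTRUE(params[["deciduous"]]) && !isTRUE(state$leaf_on)) {
    return(list(GPP = 0, NPP = 0, LAI = lai, SLA = sla,
                modifiers = modifiers))
  }
  apar_mj <- climate$solar_rad * climate$days * 0.5 *
    (1 - exp(-params[["k"]] * lai))
  apar_mol <- MOL_PAR_PER_MJ_PAR * apar_mj
  alpha_eff <- params[["alphaCx"]] * modifiers$fCalpha * modifiers$fNutr *
    modifiers$fT * modifiers$fFrost * modifiers$PhysMod
  gpp <- alpha_eff * apar_mol * GDM_PER_MOL_C / 100  # gDM m-2 -> tDM ha-1
  list(GPP = gpp, NPP = params[["Y"]] * gpp, LAI = lai, SLA = sla,
       modifiers = modifiers)
}

#' Allocate net production to foliage, stem and roots
#'
#' Root fraction increases with drought (low \code{PhysMod}) and decreases
#' with fertility; the remainder splits between stem and foliage by the
#' diameter-dependent partitioning ratio.
#'
#' @param npp Net primary production for the month (tDM ha-1, >= 0).
#' @param state Stand state.
#' @param phys_mod Physiological modifier product for the month.
#' @param fr Site fertility rating.
#' @param params A \linkS4class{SpeciesParams}.
#' @return List with increments \code{dWf}, \code{dWs}, \code{dWr} and
#'   fractions \code{pF}, \code{pS}, \code{pR}.
#' @export
allocateNPP <- function(npp, state, phys_mod, fr, params) {
  if (npp < 0) stop("'npp' must be >= 0", call. = FALSE)
  if (state$N <= 0) {
    if (npp > 0) stop("cannot allocate production with no live stems",
                      call. = FALSE)
    return(list(dWf = 0, dWs = 0, dWr = 0, pF = 0, pS = 0, pR = 0))
  }
  m <- params[["m0"]] + (1 - params[["m0"]]) * fr
  pRx <- params[["pRx"]]; pRn <- params[["pRn"]]
  pR <- pRx * pRn / (pRn + (pRx - pRn) * m * phys_mod)
  avWs <- max(1000 * state$Ws / state$N, 1e-9)   # kg tree-1
  dbh <- (avWs / params[["aS"]])^(1 / params[["nS"]])
  pfsPower <- log(params[["pFS20"]] / params[["pFS2"]]) / log(10)
  pfsConst <- params[["pFS2"]] / 2^pfsPower
  pFS <- pfsConst * dbh^pfsPower
  pS <- (1 - pR) / (1 + pFS)
  pF <- 1 - pR - pS
  list(dWf = npp * pF, dWs = npp * pS, dWr = npp * pR,
       pF = pF, pS = pS, pR = pR)
}

#' Continuous litterfall rate
#'
#' Sigmoid increase from the juvenile rate to the mature rate with midpoint
#' at \code{tgammaF} months. Applies to the expressed canopy of both leaf
#' habits; deciduous stands additionally drop their whole remaining canopy
#' at the leaf-off event (see \code{\link{applyPhenology}}).
#'
#' @param age_months Stand age (months, >= 0).
#' @param gammaF0,gammaFx Initial and mature monthly litterfall rates.
#' @param tgammaF Months to the midpoint.
#' @return Litterfall rate (month-1).
#' @export
litterfallRate <- function(age_months, gammaF0, gammaFx, tgammaF) {
  stopifnot(all(age_months >= 0))
  if (gammaFx <= 0) return(rep(0, length(age_months)))
  if (gammaF0 <= 0)
    stop("'gammaF0' must be > 0 when 'gammaFx' > 0", call. = FALSE)
  kg <- log(1 + gammaFx / gammaF0) / tgammaF
  gammaFx * gammaF0 / (gammaF0 + (gammaFx - gammaF0) * exp(-kg * age_months))
}

#' Deciduous phenology transition
#'
#' Evergreen species pass through unchanged. For deciduous species the leaf
#' state follows the mean monthly temperature: on the leaf-off transition the
#' whole canopy drops as litter and its mass is banked as the foliage
#' reserve; on the leaf-on transition the canopy is re-expressed from the
#' reserve (no production is double counted: the reserve only moves mass
#' between the canopy and the bank).
#'
#' @param state Stand state.
#' @param climate Month climate list (uses \code{tmean}).
#' @param params A \linkS4class{SpeciesParams}.
#' @return List with the updated \code{state} and the phenological
#'   \code{litter} (tDM ha-1) dropped this month.
#' @export
applyPhenology <- function(state, climate, params) {
  if (!isTRUE(params[["deciduous"]])) return(list(state = state, litter = 0))
  leaf_on_new <- climate$tmean >= params[["leaf_on_Tthresh"]]
  litter <- 0
  if (isTRUE(state$leaf_on) && !leaf_on_new) {       # leaf-off
    litter <- state$Wf
    state$foliage_reserve <- state$Wf
    state$Wf <- 0
  } else if (!isTRUE(state$leaf_on) && leaf_on_new) { # leaf-on
    state$Wf <- state$foliage_reserve
    state$foliage_reserve <- 0
  }
  state$leaf_on <- leaf_on_new
  list(state = state, litter = litter)
}

## Trees to remove so the mean stem mass drops back to the self-thinning
## limit; root of the thinning identity found by uniroot.
selfThinningDeaths <- function(N, Ws, wSx1000, thinPower,
                               mS = DYING_TREE_MASS_FRAC) {
  wSmax <- wSx1000 * (1000 / N)^thinPower
  if (1000 * Ws / N <= wSmax) return(0)
  g <- function(n) {
    Nn <- N - n
    1000 * Ws * (1 - mS * n / N) / Nn - wSx1000 * (1000 / Nn)^thinPower
  }
  upper <- N * (1 - 1e-9)
  if (g(upper) > 0) return(upper)
  stats::uniroot(g, c(0, upper), tol = 1e-10)$root
}

#' Density-dependent and background mortality
#'
#' Background mortality removes a constant annual fraction of stems;
#' self-thinning then enforces the maximum mean stem mass allowed at the
#' current density (a power law anchored at 1000 trees ha-1). Dying trees
#' are assumed smaller than average: each removes only a fraction (0.2) of
#' the mean mass from every pool, including the deciduous foliage reserve.
#'
#' @param state Stand state.
#' @param params A \linkS4class{SpeciesParams}.
#' @return List with the updated \code{state} and \code{deaths} (trees ha-1).
#' @export
mortalityUpdate <- function(state, params) {
  if (state$N <= 0) return(list(state = state, deaths = 0))
  removeTrees <- function(state, n) {
    lossFrac <- DYING_TREE_MASS_FRAC * n / state$N
    state$Wf <- state$Wf * (1 - lossFrac)
    state$Ws <- state$Ws * (1 - lossFrac)
    state$Wr <- state$Wr * (1 - lossFrac)
    state$foliage_reserve <- state$foliage_reserve * (1 - lossFrac)
    state$N <- state$N - n
    state
  }
  d_bg <- state$N * params[["gammaN"]] / 12
  state <- removeTrees(state, d_bg)
  d_st <- selfThinningDeaths(state$N, state$Ws, params[["wSx1000"]],
                             params[["thinPower"]])
  if (d_st > 0) state <- removeTrees(state, d_st)
  list(state = state, deaths = d_bg + d_st)
}

#' Monthly soil-water balance
#'
#' Canopy conductance saturates with LAI and is down-regulated by the
#' physiological modifier; transpiration follows the Penman-Monteith
#' combination equation with net radiation taken as a fixed fraction of
#' solar radiation and a fixed boundary-layer conductance; rainfall
#' interception saturates with LAI. The bucket is clamped to [0, MASW]:
#' overflow leaves as runoff and transpiration is capped at availability.
#' The balance \code{precip - interception - transpiration - runoff} equals
#' the storage change exactly.
#'
#' @param state Stand state.
#' @param climate Month climate list.
#' @param modifiers A \code{\link{modifierSet}} for the month (uses
#'   \code{VPD} and \code{PhysMod}).
#' @param params A \linkS4class{SpeciesParams}.
#' @param masw Maximum available soil water (mm).
#' @param lai Optional LAI override (default from state and age).
#' @return List with updated \code{state}, \code{transpiration},
#'   \code{interception}, \code{runoff} and \code{delta_asw} (all mm).
#' @export
soilWaterUpdate <- function(state, climate, modifiers, params, masw,
                            lai = NULL) {
  if (is.null(lai))
    lai <- state$Wf * specificLeafArea(state$age, params) * 0.1
  gC <- params[["MaxCond"]] * modifiers$PhysMod *
    min(1, lai / params[["LAIgcx"]])
  netRad <- NETRAD_FRAC * climate$solar_rad * 1e6 / 86400      # W m-2
  defTerm <- RHO_AIR * LAMBDA_VAP * VPD_CONV * modifiers$VPD * BL_COND
  transp <- if (gC > 0) {
    e <- gC * (E20 * netRad + defTerm) / (gC * (1 + E20) + BL_COND) # W m-2
    max(e / LAMBDA_VAP * 86400 * climate$days, 0)                  # mm month-1
  } else 0
  interception <- params[["MaxIntcptn"]] *
    min(1, lai / params[["LAImaxIntcptn"]]) * climate$precip
  supply <- state$ASW + climate$precip - interception
  if (transp > supply) transp <- max(supply, 0)
  asw_new <- state$ASW + climate$precip - interception - transp
  runoff <- max(asw_new - masw, 0)
  asw_new <- min(max(asw_new, 0), masw)
  delta <- asw_new - state$ASW
  state$ASW <- asw_new
  list(state = state, transpiration = transp, interception = interception,
       runoff = runoff, delta_asw = delta)
}

#' Stand structural metrics
#'
#' @param state Stand state.
#' @param params A \linkS4class{SpeciesParams}.
#' @return List with \code{dbh} (cm, \code{NA} when no stems),
#'   \code{basal_area} (m2 ha-1), \code{agb} (tDM ha-1, stem plus foliage)
#'   and \code{lai}.
#' @export
standMetrics <- function(state, params) {
  agb <- state$Ws + state$Wf
  lai <- state$Wf * specificLeafArea(state$age, params) * 0.1
  if (state$N <= 0)
    return(list(dbh = NA_real_, basal_area = 0, agb = agb, lai = lai))
  avWs <- 1000 * state$Ws / state$N
  dbh <- (avWs / params[["aS"]])^(1 / params[["nS"]])
  list(dbh = dbh, basal_area = state$N * pi * (dbh / 200)^2, agb = agb,
       lai = lai)
}

#' Advance the stand by one month
#'
#' Order of operations: phenology, environmental modifiers, canopy
#' production, allocation, litterfall and root turnover, mortality, soil
#' water; age then advances one month.
#'
#' @param state Stand state.
#' @param climate Month climate list.
#' @param site List with \code{fr}, \code{masw} and optional \code{SWconst},
#'   \code{SWpower} texture overrides.
#' @param params A \linkS4class{SpeciesParams}.
#' @return List with the new \code{state}, the month's \code{modifiers} and
#'   a \code{fluxes} list (production, litter, water-balance terms and the
#'   exact water-balance residual).
#' @export
stepMonth <- function(state, climate, site, params) {
  ph <- applyPhenology(state, climate, params)
  state <- ph$state
  mods <- modifierSet(climate, state$ASW, site$masw, site$fr,
                      state$age / 12, params,
                      SWconst = site$SWconst, SWpower = site$SWpower)
  prod <- canopyProduction(state, climate, site$fr, params, modifiers = mods)
  al <- allocateNPP(prod$NPP, state, mods$PhysMod, site$fr, params)
  if (isTRUE(params[["deciduous"]]) && !isTRUE(state$leaf_on)) {
    ## out of leaf: foliage share banks into the reserve
    state$foliage_reserve <- state$foliage_reserve + al$dWf
  } else {
    state$Wf <- state$Wf + al$dWf
  }
  state$Ws <- state$Ws + al$dWs
  state$Wr <- state$Wr + al$dWr
  ## continuous litterfall applies to the expressed canopy only (deciduous
  ## stands out of leaf hold no canopy, so this is a no-op then)
  litter <- ph$litter
  gF <- litterfallRate(state$age, params[["gammaF0"]], params[["gammaFx"]],
                       params[["tgammaF"]])
  litter <- litter + gF * state$Wf
  state$Wf <- state$Wf * (1 - gF)
  root_turnover <- params[["gammaR"]] * state$Wr
  state$Wr <- state$Wr - root_turnover
  mo <- mortalityUpdate(state, params)
  state <- mo$state
  sw <- soilWaterUpdate(state, climate, mods, params, site$masw,
                        lai = prod$LAI)
  state <- sw$state
  state$age <- state$age + 1L
  residual <- climate$precip - sw$interception - sw$transpiration -
    sw$runoff - sw$delta_asw
  list(state = state, modifiers = mods,
       fluxes = list(GPP = prod$GPP, NPP = prod$NPP, LAI = prod$LAI,
                     litter = litter, root_turnover = root_turnover,
                     alloc = al, deaths = mo$deaths,
                     transpiration = sw$transpiration,
                     interception = sw$interception, runoff = sw$runoff,
                     delta_asw = sw$delta_asw, water_residual = residual))
}

#' Run one stand from planting to the simulation horizon
#'
#' Initialises the stand (default 1650 stems ha-1 with small seedling pools)
#' and iterates \code{\link{stepMonth}} over the supplied monthly climate
#' series, recording the August aboveground biomass of each year and the
#' full monthly fSW/fVPD trace of the analysis year.
#'
#' @param climate_series data.frame with one row per simulated month and
#'   columns \code{year}, \code{month}, \code{tmin}, \code{tmax},
#'   \code{tmean}, \code{precip}, \code{solar_rad}, \code{frost_days},
#'   \code{days}, \code{co2} (see \code{\link{climateForYear}}).
#' @param params A \linkS4class{SpeciesParams}.
#' @param site List with \code{fr}, \code{masw} and optional texture
#'   overrides.
#' @param stems Initial stem density (trees ha-1).
#' @param trace_year Calendar year whose monthly modifiers are recorded.
#' @param init Optional named list overriding the seedling pools
#'   (\code{Wf}, \code{Ws}, \code{Wr}).
#' @param diagnostics Record running conservation diagnostics.
#' @return List with \code{years}, \code{agb}, \code{trace} (data.frame
#'   \code{month}, \code{fSW}, \code{fVPD}), final \code{stems}, \code{dbh},
#'   \code{lai}, the final \code{state}, and \code{diagnostics}.
#' @export
runStand <- function(climate_series, params, site, stems = 1650,
                     trace_year = NULL, init = list(), diagnostics = FALSE) {
  need <- c("year", "month", "tmin", "tmax", "tmean", "precip", "solar_rad",
            "frost_days", "days", "co2")
  if (!all(need %in% names(climate_series)))
    stop("climate series is missing columns: ",
         paste(setdiff(need, names(climate_series)), collapse = ", "),
         call. = FALSE)
  years <- sort(unique(climate_series$year))
  if (!all(table(climate_series$year) == 12L))
    stop("climate series must cover all 12 months of every year",
         call. = FALSE)
  if (is.null(trace_year)) trace_year <- max(years) - 1L
  state <- newStandState(params, stems = stems,
                         Wf = init$Wf %||% 0.2, Ws = init$Ws %||% 0.6,
                         Wr = init$Wr %||% 0.2, masw = site$masw,
                         first_tmean = climate_series$tmean[1])
  agb <- setNames(numeric(length(years)), years)
  trace <- data.frame(month = 1:12, fSW = NA_real_, fVPD = NA_real_)
  maxres <- 0; maxalloc <- 0
  cs <- climate_series
  n <- nrow(cs)

  ## hot loop: climate- and age-driven quantities are precomputed as
  ## vectors; the monthly recursion below is arithmetically identical to
  ## iterating stepMonth() (asserted by the test suite) but avoids its
  ## per-call overhead
  deciduous <- isTRUE(params[["deciduous"]])
  leafT <- params[["leaf_on_Tthresh"]]
  kext <- params[["k"]]; alphaCx <- params[["alphaCx"]]; Y <- params[["Y"]]
  aS <- params[["aS"]]; nS <- params[["nS"]]
  pRx <- params[["pRx"]]; pRn <- params[["pRn"]]
  pfsPower <- log(params[["pFS20"]] / params[["pFS2"]]) / log(10)
  pfsConst <- params[["pFS2"]] / 2^pfsPower
  mfert <- params[["m0"]] + (1 - params[["m0"]]) * site$fr
  gammaR <- params[["gammaR"]]; gammaN12 <- params[["gammaN"]] / 12
  wSx1000 <- params[["wSx1000"]]; thinPower <- params[["thinPower"]]
  MaxCond <- params[["MaxCond"]]; LAIgcx <- params[["LAIgcx"]]
  MaxIntcptn <- params[["MaxIntcptn"]]
  LAImaxIntcptn <- params[["LAImaxIntcptn"]]
  SWconst <- site$SWconst %||% params[["SWconst"]]
  SWpower <- site$SWpower %||% params[["SWpower"]]
  masw <- site$masw
  mS <- DYING_TREE_MASS_FRAC
  fNutr <- fertilityModifier(site$fr, params[["fN0"]], params[["fNn"]])
  agev <- (seq_len(n) - 1)                          # age at month start
  vpdV <- computeVPD(cs$tmin, cs$tmax)
  fTV <- temperatureModifier(cs$tmean, params)
  fFrostV <- frostModifier(cs$frost_days, cs$days, params[["kF"]])
  fVPDV <- vpdModifier(vpdV, params[["CoeffCond"]])
  fCaV <- co2Modifier(cs$co2, params[["fCalpha700"]])
  fAgeV <- ageModifier(agev / 12, params[["MaxAge"]], params[["rAge"]],
                       params[["nAge"]])
  slaV <- specificLeafArea(agev, params)
  gFV <- litterfallRate(agev, params[["gammaF0"]], params[["gammaFx"]],
                        params[["tgammaF"]])
  netRadV <- NETRAD_FRAC * cs$solar_rad * 1e6 / 86400
  defTermV <- RHO_AIR * LAMBDA_VAP * VPD_CONV * vpdV * BL_COND
  Wf <- state$Wf; Ws <- state$Ws; Wr <- state$Wr; N <- state$N
  ASW <- state$ASW; reserve <- state$foliage_reserve
  leaf_on <- isTRUE(state$leaf_on)

  for (i in seq_len(n)) {
    if (deciduous) {
      leaf_new <- cs$tmean[i] >= leafT
      if (leaf_on && !leaf_new) { reserve <- Wf; Wf <- 0 }
      else if (!leaf_on && leaf_new) { Wf <- reserve; reserve <- 0 }
      leaf_on <- leaf_new
    }
    fsw <- 1 / (1 + ((1 - ASW / masw) / SWconst)^SWpower)
    phys <- fAgeV[i] * min(fVPDV[i], fsw)
    lai <- Wf * slaV[i] * 0.1
    producing <- !deciduous || leaf_on
    if (producing && N > 0) {
      apar_mol <- MOL_PAR_PER_MJ_PAR * cs$solar_rad[i] * cs$days[i] * 0.5 *
        (1 - exp(-kext * lai))
      npp <- Y * alphaCx * fCaV[i] * fNutr * fTV[i] * fFrostV[i] * phys *
        apar_mol * GDM_PER_MOL_C / 100
      if (npp > 0) {
        pR <- pRx * pRn / (pRn + (pRx - pRn) * mfert * phys)
        dbh <- (max(1000 * Ws / N, 1e-9) / aS)^(1 / nS)
        pFS <- pfsConst * dbh^pfsPower
        pS <- (1 - pR) / (1 + pFS)
        pF <- 1 - pR - pS
        if (deciduous && !leaf_on) reserve <- reserve + npp * pF
        else Wf <- Wf + npp * pF
        Ws <- Ws + npp * pS
        Wr <- Wr + npp * pR
        if (diagnostics) maxalloc <- max(maxalloc, abs(pF + pS + pR - 1))
      }
    }
    Wf <- Wf * (1 - gFV[i])
    Wr <- Wr * (1 - gammaR)
    if (N > 0) {
      d_bg <- N * gammaN12
      lf <- mS * d_bg / N
      Wf <- Wf * (1 - lf); Ws <- Ws * (1 - lf); Wr <- Wr * (1 - lf)
      reserve <- reserve * (1 - lf)
      N <- N - d_bg
      if (1000 * Ws / N > wSx1000 * (1000 / N)^thinPower) {
        d_st <- selfThinningDeaths(N, Ws, wSx1000, thinPower)
        lf <- mS * d_st / N
        Wf <- Wf * (1 - lf); Ws <- Ws * (1 - lf); Wr <- Wr * (1 - lf)
        reserve <- reserve * (1 - lf)
        N <- N - d_st
      }
    }
    gC <- MaxCond * phys * min(1, lai / LAIgcx)
    transp <- if (gC > 0) {
      e <- gC * (E20 * netRadV[i] + defTermV[i]) / (gC * (1 + E20) + BL_COND)
      max(e / LAMBDA_VAP * 86400 * cs$days[i], 0)
    } else 0
    interception <- MaxIntcptn * min(1, lai / LAImaxIntcptn) * cs$precip[i]
    supply <- ASW + cs$precip[i] - interception
    if (transp > supply) transp <- max(supply, 0)
    asw_new <- ASW + cs$precip[i] - interception - transp
    runoff <- max(asw_new - masw, 0)
    asw_new <- min(max(asw_new, 0), masw)
    if (diagnostics)
      maxres <- max(maxres, abs(cs$precip[i] - interception - transp -
                                  runoff - (asw_new - ASW)))
    ASW <- asw_new
    if (cs$month[i] == 8L) {
      agb[as.character(cs$year[i])] <- Ws + Wf
      if (cs$year[i] == max(years)) lai_aug <- Wf * slaV[i] * 0.1
    }
    if (cs$year[i] == trace_year) {
      trace$fSW[cs$month[i]] <- fsw
      trace$fVPD[cs$month[i]] <- fVPDV[i]
    }
  }
  state <- list(Wf = Wf, Ws = Ws, Wr = Wr, N = N, ASW = ASW,
                age = state$age + n, foliage_reserve = reserve,
                leaf_on = leaf_on)
  met <- standMetrics(state, params)
  list(years = years, agb = agb, trace = trace, stems = state$N,
       dbh = met$dbh, lai = if (exists("lai_aug")) lai_aug else met$lai,
       state = state,
       diagnostics = if (diagnostics)
         list(max_water_residual = maxres,
              max_allocation_deviation = maxalloc) else NULL)
}
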