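test_that("canopy production reproduces the hand-computed light-use chain", {
  p <- fixtureConifer()
  cl <- fixtureMonth()
  state <- newStandState(p, masw = 200)
  state$Wf <- 3; state$age <- 60
  ms <- modifierSet(cl, asw = 150, masw = 200, fr = 0.8, age_years = 5,
                    params = p)
  out <- canopyProduction(state, cl, fr = 0.8, params = p, modifiers = ms)
  ## independent evaluation of the stated chain
  sla <- 4 + (6 - 4) * exp(-log(2) * (5 / 5)^2)
  lai <- 3 * sla * 0.1
  apar_mol <- 4.6 * (15 * 30 * 0.5 * (1 - exp(-0.5 * lai)))
  gpp <- 0.05 * ms$fCalpha * ms$fNutr * ms$fT * ms$fFrost * ms$PhysMod *
    apar_mol * 24 / 100
  expect_equal(out$LAI, lai)
  expect_equal(out$GPP, gpp, tolerance = 1e-12)
  expect_equal(out$NPP, 0.5 * gpp, tolerance = 1e-12)
})

test_that("production is zero without foliage, under a zero modifier, and out of leaf", {
  p <- fixtureConifer()
  cl <- fixtureMonth()
  st <- newStandState(p, masw = 200); st$Wf <- 0
  ms <- modifierSet(cl, 150, 200, 0.8, 1, p)
  expect_equal(canopyProduction(st, cl, 0.8, p, ms)$GPP, 0)
  st$Wf <- 3
  cl0 <- fixtureMonth(tmin = -40, tmax = -30)  # fT = 0
  ms0 <- modifierSet(cl0, 150, 200, 0.8, 1, p)
  expect_equal(canopyProduction(st, cl0, 0.8, p, ms0)$NPP, 0)
  pd <- fixtureDeciduous()
  std <- newStandState(pd, masw = 200, first_tmean = -10)
  expect_false(std$leaf_on)
  expect_equal(canopyProduction(std, cl, 0.8, pd, ms)$GPP, 0)
})

test_that("allocation fractions sum to one and hit their algebraic limits", {
  p <- fixtureConifer()
  st <- newStandState(p, masw = 200)
  for (phys in c(0, 0.3, 1)) for (fr in c(0, 0.5, 1)) {
    al <- allocateNPP(1.7, st, phys, fr, p)
    expect_equal(al$pF + al$pS + al$pR, 1, tolerance = 1e-12)
  }
  expect_equal(allocateNPP(1, st, 1, 1, p)$pR, p[["pRn"]])
  expect_equal(allocateNPP(1, st, 0, 1, p)$pR, p[["pRx"]])
  st0 <- st; st0$N <- 0
  expect_error(allocateNPP(1, st0, 1, 1, p), "stems")
})

test_that("litterfall rises from the juvenile rate through the midpoint to the mature rate", {
  expect_equal(litterfallRate(0, 0.001, 0.02, 24), 0.001)
  expect_equal(litterfallRate(24, 0.001, 0.02, 24), (0.001 + 0.02) / 2)
  expect_equal(litterfallRate(1e5, 0.001, 0.02, 24), 0.02, tolerance = 1e-8)
  expect_true(all(diff(litterfallRate(0:200, 0.001, 0.02, 24)) > 0))
})

test_that("deciduous phenology transfers the canopy through the reserve", {
  pd <- fixtureDeciduous()
  st <- newStandState(pd, masw = 200, first_tmean = 15)
  st$Wf <- 2.5
  ## evergreen identity
  pe <- fixtureConifer()
  expect_identical(applyPhenology(st, fixtureMonth(tmin = -20, tmax = -10),
                                  pe)$state, st)
  ## leaf-off: canopy drops and is banked
  off <- applyPhenology(st, fixtureMonth(tmin = -5, tmax = 5), pd)
  expect_equal(off$litter, 2.5)
  expect_equal(off$state$Wf, 0)
  expect_equal(off$state$foliage_reserve, 2.5)
  ## leaf-on: reserve re-expressed, nothing dropped
  on <- applyPhenology(off$state, fixtureMonth(tmin = 5, tmax = 15), pd)
  expect_equal(on$litter, 0)
  expect_equal(on$state$Wf, 2.5)
  expect_equal(on$state$foliage_reserve, 0)
})

test_that("leaf-off litter equals the foliage expressed the following spring", {
  pd <- fixtureDeciduous(gammaN = 0)      # no mortality, clean conservation
  site <- fixtureSite()
  ser <- fixtureSeries(2025:2028)
  st <- newStandState(pd, masw = site$masw, first_tmean = ser$tmean[1])
  litter_by_year <- numeric(0)
  expressed <- numeric(0)
  prev_leaf <- st$leaf_on
  for (i in seq_len(nrow(ser))) {
    cl <- as.list(ser[i, c("tmin", "tmax", "tmean", "precip", "solar_rad",
                           "frost_days", "days", "co2")])
    ph <- applyPhenology(st, cl, pd)
    if (!prev_leaf && ph$state$leaf_on)
      expressed <- c(expressed, ph$state$Wf)
    if (prev_leaf && !ph$state$leaf_on)
      litter_by_year <- c(litter_by_year, ph$litter)
    prev_leaf <- ph$state$leaf_on
    st <- stepMonth(st, cl, site, pd)$state
  }
  ## each autumn's drop is exactly what unfolds the following spring
  expect_gte(length(litter_by_year), 3)
  expect_equal(expressed[-1], litter_by_year[seq_along(expressed[-1])],
               tolerance = 1e-12)
})

test_that("mortality enforces the self-thinning frontier", {
  p <- fixtureConifer()
  ## at 1000 trees/ha the cap is wSx1000 itself: just below it, no deaths
  st <- newStandState(p, stems = 1000, masw = 200)
  st$Ws <- 299.9  # avWs 299.9 kg < 300
  out <- mortalityUpdate(st, fixtureConifer(gammaN = 0))
  expect_equal(out$deaths, 0)
  ## over-stocked: solver lands on the frontier
  st$Ws <- 400    # avWs 400 kg > cap
  out <- mortalityUpdate(st, fixtureConifer(gammaN = 0))
  expect_gt(out$deaths, 0)
  avWs <- 1000 * out$state$Ws / out$state$N
  cap <- 300 * (1000 / out$state$N)^1.5
  expect_lt(avWs, cap + 1e-6)
  expect_equal(avWs, cap, tolerance = 1e-6)
})

test_that("stand metrics invert the stem allometry", {
  p <- fixtureConifer()
  st <- newStandState(p, stems = 500, masw = 200)
  st$Ws <- 500 * 0.095 * 10^2.4 / 1000   # avWs = aS * 10^nS -> DBH 10
  m <- standMetrics(st, p)
  expect_equal(m$dbh, 10, tolerance = 1e-12)
  st$Wf <- 0
  expect_equal(standMetrics(st, p)$agb, st$Ws)
  st2 <- st; st2$N <- 100
  st2$Ws <- 100 * 0.095 * 20^2.4 / 1000  # DBH 20 at 100 trees
  expect_equal(standMetrics(st2, p)$basal_area, 100 * pi * 0.01,
               tolerance = 1e-12)
})

test_that("soil-water balance closes exactly and matches the combination-equation oracle", {
  p <- fixtureConifer()
  cl <- fixtureMonth(precip = 0)
  st <- newStandState(p, masw = 200); st$Wf <- 0; st$ASW <- 120
  ms <- modifierSet(cl, 120, 200, 0.8, 1, p)
  out <- soilWaterUpdate(st, cl, ms, p, masw = 200)
  expect_equal(out$interception, 0)
  expect_equal(out$transpiration, 0)
  expect_equal(out$state$ASW, 120)
  ## Penman-Monteith oracle: LAI 3, VPD 10 mbar, solar 15 MJ m-2 d-1,
  ## PhysMod 0.5 -> gC = 0.01; independent arithmetic
  ms2 <- ms; ms2$VPD <- 10; ms2$PhysMod <- 0.5
  st$ASW <- 200
  out2 <- soilWaterUpdate(st, cl, ms2, p, masw = 200, lai = 3)
  gC <- 0.02 * 0.5 * 1
  netRad <- 0.8 * 15 * 1e6 / 86400
  defTerm <- 1.2 * 2.46e6 * 0.000622 * 10 * 0.2
  e <- gC * (2.2 * netRad + defTerm) / (gC * (1 + 2.2) + 0.2)
  expect_equal(out2$transpiration, e / 2.46e6 * 86400 * 30,
               tolerance = 1e-12)
  ## conservation under random states
  set.seed(7)
  for (r in 1:50) {
    st$ASW <- runif(1, 0, 200); st$Wf <- runif(1, 0, 12)
    clr <- fixtureMonth(precip = runif(1, 0, 250),
                        tmin = runif(1, -5, 15), tmax = runif(1, 15, 35))
    msr <- modifierSet(clr, st$ASW, 200, 0.8, 1, p)
    o <- soilWaterUpdate(st, clr, msr, p, masw = 200)
    expect_equal(clr$precip - o$interception - o$transpiration - o$runoff,
                 o$delta_asw, tolerance = 1e-9)
    expect_true(o$state$ASW >= 0 && o$state$ASW <= 200)
  }
})

test_that("a zero-production year only loses biomass to turnover and mortality", {
  p <- fixtureConifer()
  site <- fixtureSite()
  st <- newStandState(p, masw = site$masw)
  cl <- fixtureMonth(tmin = -45, tmax = -35, precip = 30)  # fT = 0
  for (i in 1:12) {
    prev <- st
    out <- stepMonth(st, cl, site, p)
    expect_equal(out$fluxes$NPP, 0)
    st <- out$state
    expect_lte(st$Wf, prev$Wf)
    expect_lte(st$Ws, prev$Ws)
    expect_lte(st$Wr, prev$Wr)
    expect_lt(st$N, prev$N)  # background mortality continues
  }
})

test_that("state invariants survive hundreds of random months", {
  set.seed(11)
  p <- fixtureConifer()
  pd <- fixtureDeciduous()
  site <- fixtureSite()
  for (params in list(p, pd)) {
    st <- newStandState(params, masw = site$masw, first_tmean = -10)
    for (i in 1:660) {
      tmin <- runif(1, -35, 15)
      cl <- fixtureMonth(tmin = tmin, tmax = tmin + runif(1, 2, 15),
                         precip = runif(1, 0, 200),
                         solar_rad = runif(1, 1, 25),
                         frost_days = round(runif(1, 0, 28)), days = 30,
                         co2 = runif(1, 350, 700))
      st <- stepMonth(st, cl, site, params)$state
      expect_true(st$Wf >= 0 && st$Ws >= 0 && st$Wr >= 0 &&
                    st$foliage_reserve >= 0)
      expect_true(st$ASW >= 0 && st$ASW <= site$masw)
      expect_true(st$N >= 0)
    }
  }
})

test_that("with modifiers pinned to one, cumulative NPP is exactly Y times cumulative GPP", {
  p <- fixtureConifer(gammaN = 0, kF = 0)
  site <- fixtureSite(fr = 1, masw = 200)
  cl <- fixtureMonth(tmin = 15, tmax = 15, precip = 300, co2 = 350,
                     frost_days = 0)
  ## tmin = tmax -> VPD 0 -> fVPD 1; full bucket -> fSW 1; Topt -> fT 1
  st <- newStandState(p, masw = 200)
  cumG <- cumN <- 0
  for (i in 1:60) {
    out <- stepMonth(st, cl, site, p)
    ms <- out$modifiers
    expect_equal(ms$fT, 1); expect_equal(ms$fVPD, 1)
    expect_equal(ms$fNutr, 1); expect_equal(ms$fCalpha, 1)
    expect_equal(ms$fSW, 1)
    cumG <- cumG + out$fluxes$GPP
    cumN <- cumN + out$fluxes$NPP
    st <- out$state
  }
  expect_equal(cumN, 0.5 * cumG, tolerance = 1e-12)
})

test_that("a never-shedding deciduous run is identical to the evergreen twin", {
  pd <- fixtureDeciduous(leaf_on_Tthresh = -1e9, gammaF0 = 0.001,
                         gammaFx = 0.02)
  pe <- fixtureConifer()
  ser <- fixtureSeries(2025:2034)
  site <- fixtureSite()
  rd <- runStand(ser, pd, site)
  re <- runStand(ser, pe, site)
  expect_identical(rd$agb, re$agb)
  expect_identical(rd$state$Ws, re$state$Ws)
  expect_identical(rd$state$N, re$state$N)
})

test_that("the runStand fast loop reproduces stepMonth composition to machine precision", {
  ser <- fixtureSeries(2025:2027)
  site <- fixtureSite()
  for (params in list(fixtureConifer(), fixtureDeciduous())) {
    st <- newStandState(params, masw = site$masw,
                        first_tmean = ser$tmean[1])
    for (i in seq_len(nrow(ser))) {
      cl <- as.list(ser[i, c("tmin", "tmax", "tmean", "precip", "solar_rad",
                             "frost_days", "days", "co2")])
      st <- stepMonth(st, cl, site, params)$state
    }
    r <- runStand(ser, params, site)
    for (fld in c("Wf", "Ws", "Wr", "N", "ASW", "foliage_reserve"))
      expect_equal(r$state[[fld]], st[[fld]], tolerance = 1e-12)
  }
})

test_that("runStand validates its climate series and starts at the configured density", {
  ser <- fixtureSeries(2025:2026)
  expect_error(runStand(ser[, -3], fixtureConifer(), fixtureSite()),
               "missing columns")
  expect_error(runStand(ser[-1, ], fixtureConifer(), fixtureSite()),
               "12 months")
  r <- runStand(ser, fixtureConifer(), fixtureSite(), stems = 1650)
  expect_equal(length(r$agb), 2L)
  expect_lt(r$stems, 1650)   # background mortality only
  expect_gt(r$stems, 1600)
})
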