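## Shared fixtures: a small analytic species parameter set (round numbers so
## closed-form oracles are easy), a constant benign climate month, and a
## tiny climate series builder.

fixtureConifer <- function(...) {
  p <- list(
    Tmin_g = -2, Topt_g = 15, Tmax_g = 30, kF = 0.3, CoeffCond = 0.05,
    MaxCond = 0.02, LAIgcx = 3, SWconst = 0.7, SWpower = 9, fN0 = 0.6,
    fNn = 1, MaxAge = 200, rAge = 0.95, nAge = 4, alphaCx = 0.05, Y = 0.5,
    k = 0.5, pFS2 = 1, pFS20 = 0.3, aS = 0.095, nS = 2.4, pRx = 0.8,
    pRn = 0.25, m0 = 0, gammaF0 = 0.001, gammaFx = 0.02, tgammaF = 24,
    gammaR = 0.015, gammaN = 0.01, wSx1000 = 300, thinPower = 1.5,
    SLA0 = 6, SLA1 = 4, tSLA = 5, fCalpha700 = 1.4, MaxIntcptn = 0.15,
    LAImaxIntcptn = 3, deciduous = FALSE, leaf_on_Tthresh = -99)
  over <- list(...)
  p[names(over)] <- over
  speciesParams("fixture_conifer", p)
}

fixtureDeciduous <- function(...) {
  fixtureConifer(deciduous = TRUE, leaf_on_Tthresh = 5, gammaF0 = 0.05,
                 gammaFx = 0.05, ...)
}

## a benign summer month
fixtureMonth <- function(tmin = 10, tmax = 20, precip = 60, solar_rad = 15,
                         frost_days = 0, days = 30, co2 = 400) {
  list(tmin = tmin, tmax = tmax, tmean = (tmin + tmax) / 2, precip = precip,
       solar_rad = solar_rad, frost_days = frost_days, days = days,
       co2 = co2)
}

## constant repeating annual climate as a runStand-ready series; tmean
## follows a cosine with July peak so deciduous phenology cycles
fixtureSeries <- function(years, mat = 2, amp = 16, precip_base = 50,
                          co2 = 400) {
  m <- 1:12
  days <- daysInMonth(m)
  tmean <- mat + amp * cos(2 * pi * (m - 7) / 12)
  do.call(rbind, lapply(years, function(y)
    data.frame(year = y, month = m, tmin = tmean - 5, tmax = tmean + 5,
               tmean = tmean, precip = precip_base, solar_rad = 10 +
                 8 * cos(2 * pi * (m - 6.5) / 12), frost_days =
                 days * stats::pnorm(-(tmean - 5) / 4), days = days,
               co2 = co2)))
}

fixtureSite <- function(fr = 0.8, masw = 200, SWconst = 0.7, SWpower = 9) {
  list(fr = fr, masw = masw, SWconst = SWconst, SWpower = SWpower)
}
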