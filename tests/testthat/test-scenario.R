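test_that("planting rules assign species exactly as stratified", {
  nw <- matrix(c(0.1, 0.5, 0.9, 0.2), 2, 2)
  el <- matrix(TRUE, 2, 2)
  a1 <- assignmentLayer(assignPlanting(nw, el, "SM1"))
  expect_true(all(a1 == "conifer"))
  a2 <- assignmentLayer(assignPlanting(nw, el, "SM2"))
  expect_true(all(a2 == "deciduous"))
  a3 <- assignmentLayer(assignPlanting(nw, el, "SM3", seed = 5))
  expect_equal(a3[1, 1], "deciduous")  # nW 0.1 < 0.33
  expect_equal(a3[2, 2], "deciduous")  # nW 0.2 < 0.33
  expect_equal(a3[1, 2], "conifer")    # nW 0.9 > 0.67
  expect_true(a3[2, 1] %in% c("conifer", "deciduous"))  # nW 0.5: random band
  expect_identical(a3, assignmentLayer(assignPlanting(nw, el, "SM3",
                                                      seed = 5)))
  ## ineligible cells stay unassigned
  el2 <- el; el2[1, 1] <- FALSE
  expect_true(is.na(assignmentLayer(assignPlanting(nw, el2, "SM1"))[1, 1]))
  expect_error(assignPlanting(nw, el, "SM9"), "rule")
})

test_that("the SM3 middle band is a fair Bernoulli draw", {
  n <- 100
  nw <- matrix(runif(n * n, 0.34, 0.66), n, n)   # all cells in the band
  el <- matrix(TRUE, n, n)
  a <- assignmentLayer(assignPlanting(nw, el, "SM3", seed = 2))
  frac <- mean(a == "deciduous")
  sigma <- sqrt(0.25 / (n * n))
  expect_lt(abs(frac - 0.5), 3 * sigma + 1e-12)
})

test_that("climate lookup selects the normal period containing the year", {
  b <- generateLandscape(size = 8, seed = 1)
  nm <- climateNormals(b)
  y2040 <- climateForYear(2040, "CS2", nm)
  y2041 <- climateForYear(2041, "CS2", nm)
  y2061 <- climateForYear(2061, "CS2", nm)
  expect_equal(y2040$tmean,
               climateNormals(b, "CS2", "2021-2040")@normals$tmean)
  expect_equal(y2041$tmean,
               climateNormals(b, "CS2", "2041-2060")@normals$tmean)
  expect_equal(y2061$tmean,
               climateNormals(b, "CS2", "2061-2080")@normals$tmean)
  ## CO2 constant within a period
  expect_equal(length(unique(y2041$co2)), 1L)
  expect_equal(y2040$co2[1], defaultCO2Table()["CS2", "2021-2040"])
  expect_error(climateForYear(2024, "CS2", nm), "year")
  expect_error(climateForYear(2081, "CS2", nm), "year")
})

test_that("scenario runs are deterministic, paired, and empty on an empty mask", {
  b <- generateLandscape(size = 10, seed = 3)
  s <- prepareSite(b)
  cfg <- scenarioConfig(planting_rule = "SM3", climate_scenario = "CS1",
                        end_year = 2030, trace_year = 2029,
                        conifer = fixtureConifer(),
                        deciduous = fixtureDeciduous())
  r1 <- runScenario(cfg, s, climateNormals(b))
  r2 <- runScenario(cfg, s, climateNormals(b))
  expect_identical(agbByYear(r1), agbByYear(r2))
  expect_identical(modifierTrace(r1), modifierTrace(r2))
  ## empty mask
  s_empty <- s
  s_empty@eligible[] <- FALSE
  r0 <- runScenario(cfg, s_empty, climateNormals(b))
  expect_equal(length(plantedCells(r0)), 0L)
  expect_equal(length(finalAGB(r0)), 0L)
})

test_that("the scenario grid is paired across climates and complete", {
  b <- generateLandscape(size = 10, seed = 2)
  s <- prepareSite(b)
  res <- runAll(s, climateNormals(b), end_year = 2028, trace_year = 2027,
                conifer = fixtureConifer(), deciduous = fixtureDeciduous(),
                planting_seed = 4)
  expect_equal(length(res), 9L)
  expect_setequal(names(res),
                  as.vector(outer(c("SM1", "SM2", "SM3"),
                                  c("CS1", "CS2", "CS3"),
                                  function(a, b) paste0(a, "x", b))))
  ## planting map independent of climate for a fixed rule and seed
  for (rule in c("SM1", "SM2", "SM3")) {
    sp <- lapply(paste0(rule, "x", c("CS1", "CS2", "CS3")),
                 function(k) res[[k]]@species)
    expect_identical(sp[[1]], sp[[2]])
    expect_identical(sp[[1]], sp[[3]])
  }
  ## SM1 has no randomness: identical under a different planting seed
  res_b <- runAll(s, climateNormals(b), rules = "SM1", scenarios = "CS1",
                  end_year = 2028, trace_year = 2027,
                  conifer = fixtureConifer(), deciduous = fixtureDeciduous(),
                  planting_seed = 99)
  expect_identical(agbByYear(res[["SM1xCS1"]]), agbByYear(res_b[["SM1xCS1"]]))
})

test_that("SM3 is the paired mixture of the pure runs outside the random band", {
  b <- generateLandscape(size = 12, seed = 5)
  s <- prepareSite(b)
  res <- runAll(s, climateNormals(b), scenarios = "CS2", end_year = 2030,
                trace_year = 2029, conifer = fixtureConifer(),
                deciduous = fixtureDeciduous(), planting_seed = 7)
  r1 <- res[["SM1xCS2"]]; r2 <- res[["SM2xCS2"]]; r3 <- res[["SM3xCS2"]]
  expect_identical(plantedCells(r1), plantedCells(r3))
  nw <- normalizedWetnessLayer(s)[plantedCells(r3)]
  agb1 <- finalAGB(r1); agb2 <- finalAGB(r2); agb3 <- finalAGB(r3)
  dry <- nw < 0.33; wet <- nw > 0.67
  expect_equal(unname(agb3[dry]), unname(agb2[dry]))   # deciduous band
  expect_equal(unname(agb3[wet]), unname(agb1[wet]))   # conifer band
  ## and cell-wise the mixture equals whichever arm was drawn
  mid <- !dry & !wet
  expect_true(all(agb3[mid] == agb1[mid] | agb3[mid] == agb2[mid]))
})

test_that("scenario results serialise to tidy CSV", {
  b <- generateLandscape(size = 8, seed = 9)
  s <- prepareSite(b)
  cfg <- scenarioConfig(end_year = 2026, trace_year = 2026,
                        conifer = fixtureConifer(),
                        deciduous = fixtureDeciduous())
  r <- runScenario(cfg, s, climateNormals(b))
  out <- tempfile("res")
  files <- writeScenarioResult(r, out)
  expect_true(all(file.exists(files)))
  long <- read.csv(files[1])
  expect_setequal(names(long), c("cell", "species", "year", "agb"))
  expect_equal(nrow(long), length(plantedCells(r)) * 2)
  unlink(out, recursive = TRUE)
})
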