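## independent brute-force oracles for the rank statistics
bruteKW <- function(groups) {
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  rk <- rank(pooled)
  sizes <- lengths(groups)
  ends <- cumsum(sizes); starts <- ends - sizes + 1
  h <- 12 / (N * (N + 1)) * sum(vapply(seq_along(groups), function(i)
    sizes[i] * (mean(rk[starts[i]:ends[i]]) - (N + 1) / 2)^2, numeric(1)))
  tt <- table(pooled)
  h / (1 - sum(tt^3 - tt) / (N^3 - N))
}

bruteDunnZ <- function(groups, i, j) {
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  rk <- rank(pooled)
  sizes <- lengths(groups)
  ends <- cumsum(sizes); starts <- ends - sizes + 1
  rbar <- vapply(seq_along(groups), function(g)
    mean(rk[starts[g]:ends[g]]), numeric(1))
  tt <- table(pooled)
  s2 <- N * (N + 1) / 12 - sum(tt^3 - tt) / (12 * (N - 1))
  unname((rbar[i] - rbar[j]) / sqrt(s2 * (1 / sizes[i] + 1 / sizes[j])))
}

test_that("Kruskal-Wallis reproduces the hand-ranked fixture and degenerates gracefully", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6))
  kw <- kruskalWallis(g)
  expect_equal(round(kw$H, 3), 3.857)
  expect_equal(kw$H, bruteKW(g), tolerance = 1e-12)
  expect_equal(kw$df, 1)
  expect_equal(kw$p, pchisq(kw$H, 1, lower.tail = FALSE))
  same <- list(a = c(2, 2, 2), b = c(2, 2, 2))
  expect_equal(kruskalWallis(same)$H, 0)
  expect_equal(kruskalWallis(same)$p, 1)
  expect_error(kruskalWallis(list(a = 1:3)), "groups")
  expect_error(kruskalWallis(list(a = 1:3, b = 2)), "groups")
})

test_that("Kruskal-Wallis H agrees with the brute-force rank formula under ties", {
  set.seed(21)
  for (r in 1:20) {
    g <- list(a = sample(1:8, 5, replace = TRUE),
              b = sample(1:8, 7, replace = TRUE),
              c = sample(1:8, 6, replace = TRUE))
    if (length(unique(unlist(g))) == 1) next
    expect_equal(kruskalWallis(g)$H, bruteKW(g), tolerance = 1e-12)
  }
})

test_that("the chi-square p matches a permutation null within Monte-Carlo error", {
  set.seed(8)
  g <- list(a = c(3.1, 4.2, 2.7, 5.0, 3.3), b = c(4.8, 5.6, 4.1, 6.2, 5.3),
            c = c(2.9, 3.8, 4.4, 3.0, 2.5))
  kw <- kruskalWallis(g)
  pooled <- unlist(g, use.names = FALSE)
  sizes <- lengths(g)
  nperm <- 10000
  hs <- replicate(nperm, {
    sh <- sample(pooled)
    bruteKW(split(sh, rep(seq_along(sizes), sizes)))
  })
  p_perm <- (1 + sum(hs >= kw$H - 1e-12)) / (nperm + 1)
  mc_err <- 3 * sqrt(p_perm * (1 - p_perm) / nperm)
  expect_lt(abs(kw$p - p_perm), mc_err + 0.01)
})

test_that("Dunn z matches brute-force rank arithmetic and is antisymmetric", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(2, 3, 5))
  dn <- dunnPosthoc(g, adjust_method = "holm")
  expect_equal(nrow(dn), 3L)
  for (k in seq_len(nrow(dn))) {
    i <- match(dn$group1[k], names(g)); j <- match(dn$group2[k], names(g))
    expect_equal(dn$z[k], bruteDunnZ(g, i, j), tolerance = 1e-12)
    expect_equal(dn$z[k], -bruteDunnZ(g, j, i), tolerance = 1e-12)
  }
  expect_true(all(dn$p.adj >= dn$p - 1e-15))
  ## two equal-rank groups
  eq <- dunnPosthoc(list(a = c(1, 4, 2, 9), b = c(4, 1, 9, 2)))
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  expect_error(dunnPosthoc(g, adjust_method = "magic"), "adjustment")
  ## every supported adjustment only increases p
  for (m in c("holm", "bonferroni", "BH")) {
    dm <- dunnPosthoc(g, adjust_method = m)
    expect_true(all(dm$p.adj >= dm$p - 1e-15))
  }
})

test_that("rank tests are invariant under strictly monotone transforms", {
  set.seed(13)
  g <- list(a = rnorm(8, 1), b = rnorm(8, 2), c = rnorm(8, 1.5))
  tr <- function(x) exp(3 * x) + 7
  expect_equal(kruskalWallis(g)$H,
               kruskalWallis(lapply(g, tr))$H, tolerance = 1e-12)
  expect_equal(dunnPosthoc(g)$z, dunnPosthoc(lapply(g, tr))$z,
               tolerance = 1e-12)
})

test_that("biomass summaries report mean, median and sd per group", {
  mk <- function(vals, rule, scn) new("ScenarioResult", rule = rule,
    scenario = scn, cells = seq_along(vals), species =
      rep("conifer", length(vals)), agb = matrix(vals, ncol = 1),
    years = 2080L, stems = rep(1, length(vals)),
    dbh = rep(1, length(vals)), lai = rep(1, length(vals)),
    trace = data.frame(), trace_year = 2079L, dim = c(1L, length(vals)))
  s <- biomassSummary(list(mk(c(1, 2, 3), "SM1", "CS1")))
  expect_equal(s$mean, 2); expect_equal(s$median, 2); expect_equal(s$sd, 1)
  s1 <- biomassSummary(list(mk(5, "SM1", "CS1")))
  expect_equal(s1$sd, 0)
  expect_false(s1$sd_defined)
  expect_warning(biomassSummary(list(mk(numeric(0), "SM1", "CS1"))),
                 "empty group")
})

test_that("stress analysis differences paired traces month by month", {
  mkTrace <- function(f) do.call(rbind, lapply(1:4, function(cell)
    data.frame(cell = cell, species = "x", month = 1:12,
               fSW = f(cell), fVPD = 1)))
  t_dec <- mkTrace(function(cell) rep(0.8, 12))
  ## conifer arm 0.1 lower on half the cells
  t_con <- mkTrace(function(cell) rep(0.8 - 0.1 * (cell <= 2), 12))
  st <- stressAnalysis(t_con, t_dec)
  fsw <- st[st$variable == "fSW", ]
  expect_equal(fsw$flagged_frac, rep(0.5, 12))
  expect_equal(fsw$stress_deciduous, rep(0.2, 12))
  expect_equal(fsw$stress_conifer, rep(0.25, 12))
  expect_equal(fsw$pct_diff, rep(25, 12))
  ## identical traces: no difference, nothing flagged
  st0 <- stressAnalysis(t_dec, t_dec)
  expect_true(all(st0$pct_diff == 0, na.rm = TRUE))
  expect_true(all(st0$flagged_frac == 0))
  ## zero-stress denominator is reported as a sentinel, still flagged
  t_one <- mkTrace(function(cell) rep(1.0, 12))
  t_08 <- mkTrace(function(cell) rep(0.8, 12))
  stz <- stressAnalysis(t_08, t_one)
  fz <- stz[stz$variable == "fSW", ]
  expect_true(all(is.na(fz$pct_diff)))
  expect_true(all(fz$denom_zero))
  expect_equal(fz$flagged_frac, rep(1, 12))
  ## misaligned traces are rejected
  expect_error(stressAnalysis(t_con[-1, ], t_dec), "aligned")
})

test_that("stress percent differences ignore cell order and unplanted cells", {
  set.seed(4)
  tr <- do.call(rbind, lapply(1:6, function(cell)
    data.frame(cell = cell, month = 1:12,
               fSW = runif(12, 0.2, 1), fVPD = runif(12, 0.5, 1))))
  tr2 <- tr; tr2$fSW <- pmax(tr2$fSW - 0.07, 0)
  st_a <- stressAnalysis(tr2, tr)
  shuffle <- sample(nrow(tr))
  st_b <- stressAnalysis(tr2[shuffle, ], tr[shuffle, ])
  expect_equal(st_a, st_b)
})
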