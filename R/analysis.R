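## Post-processing of scenario results: biomass distribution summaries,
## Kruskal-Wallis tests, Dunn's post-hoc pairwise comparisons, and the
## monthly water-stress differencing between the conifer and deciduous arms.

#' Biomass distribution summary per group
#'
#' Sample mean, median and standard deviation (n - 1 denominator) of the
#' per-cell final-year aboveground biomass for every planting-rule x
#' climate-scenario group. Single-cell groups report SD 0 and are flagged;
#' empty groups are omitted with a warning.
#'
#' @param results A list of \linkS4class{ScenarioResult} (e.g. from
#'   \code{\link{runAll}}), or a single result.
#' @return data.frame with columns \code{rule}, \code{scenario}, \code{n},
#'   \code{mean}, \code{median}, \code{sd}, \code{sd_defined}.
#' @export
biomassSummary <- function(results) {
  if (is(results, "ScenarioResult")) results <- list(results)
  rows <- lapply(results, function(r) {
    v <- finalAGB(r)
    if (!length(v)) {
      warning("empty group omitted: ", r@rule, " x ", r@scenario,
              call. = FALSE)
      return(NULL)
    }
    data.frame(rule = r@rule, scenario = r@scenario, n = length(v),
               mean = mean(v), median = median(v),
               sd = if (length(v) > 1) sd(v) else 0,
               sd_defined = length(v) > 1)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Coerce the two supported group formats (named list of numeric vectors, or
## value/group vectors) into a named list.
asGroupList <- function(groups, values = NULL) {
  if (is.list(groups)) return(groups)
  split(values, groups)
}

#' Kruskal-Wallis rank sum test
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square tail p-value on k - 1
#' degrees of freedom (delegates to \code{stats::kruskal.test}). A pooled
#' sample with all values identical returns H = 0, p = 1.
#'
#' @param groups Named list of numeric vectors, each of length >= 2.
#' @return List with \code{H}, \code{df} and \code{p}.
#' @export
kruskalWallis <- function(groups) {
  groups <- asGroupList(groups)
  if (length(groups) < 2 || any(lengths(groups) < 2))
    stop("need >= 2 groups with >= 2 values each", call. = FALSE)
  pooled <- unlist(groups, use.names = FALSE)
  if (length(unique(pooled)) == 1L)
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  g <- factor(rep(names(groups) %||% seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(pooled, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = unname(kt$p.value))
}

#' Dunn's post-hoc pairwise comparisons
#'
#' Pairwise z statistics on the pooled mid-ranks with the tie correction
#' \code{sum(t^3 - t)}, two-sided normal p-values and the configured
#' multiplicity adjustment.
#'
#' @param groups Named list of numeric vectors.
#' @param adjust_method One of \code{"holm"} (default), \code{"bonferroni"},
#'   \code{"BH"}, or any method of \code{stats::p.adjust}.
#' @return data.frame with columns \code{group1}, \code{group2}, \code{z},
#'   \code{p}, \code{p.adj}.
#' @export
dunnPosthoc <- function(groups, adjust_method = "holm") {
  groups <- asGroupList(groups)
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (!adjust_method %in% stats::p.adjust.methods)
    stop("unknown adjustment method: ", adjust_method, call. = FALSE)
  nm <- names(groups) %||% as.character(seq_along(groups))
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  rk <- rank(pooled)                       # mid-ranks
  sizes <- lengths(groups)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  rbar <- vapply(seq_along(groups),
                 function(i) mean(rk[starts[i]:ends[i]]), numeric(1))
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab)
  sigma_base <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
  pairs <- utils::combn(seq_along(groups), 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt(sigma_base * (1 / sizes[i] + 1 / sizes[j]))
    z[k] <- if (se > 0) (rbar[i] - rbar[j]) / se else 0
    p[k] <- 2 * pnorm(-abs(z[k]))
  }
  data.frame(group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]], z = z, p = p,
             p.adj = stats::p.adjust(p, method = adjust_method))
}

#' Monthly water-stress comparison between planting arms
#'
#' For each month of the analysis year, compares the mean stress (defined as
#' 1 - modifier) between the conifer and deciduous arms of a paired run:
#' the relative percent difference of mean stress, and the fraction of cells
#' whose absolute modifier difference exceeds the flag threshold (default
#' 0.05 on the [0, 1] modifier scale). Applied to fSW and fVPD alike.
#'
#' @param trace_con,trace_dec Modifier-trace data.frames (\code{cell},
#'   \code{month}, \code{fSW}, \code{fVPD}) from paired runs sharing the
#'   same cells, e.g. \code{modifierTrace()} of an SM1 and an SM2 result.
#' @param variables Modifier columns to analyse.
#' @param flag_threshold Absolute modifier difference that flags a cell.
#' @param relative Use relative instead of absolute differences for
#'   flagging.
#' @return data.frame with one row per month x variable: mean stress per
#'   arm, \code{pct_diff} (100 x (con - dec) / dec of mean stress, \code{NA}
#'   when the deciduous-arm stress is zero), \code{denom_zero}, and
#'   \code{flagged_frac}.
#' @export
stressAnalysis <- function(trace_con, trace_dec,
                           variables = c("fSW", "fVPD"),
                           flag_threshold = 0.05, relative = FALSE) {
  for (v in c("cell", "month", variables)) {
    if (!v %in% names(trace_con) || !v %in% names(trace_dec))
      stop("traces are missing column: ", v, call. = FALSE)
  }
  con <- trace_con[order(trace_con$cell, trace_con$month), ]
  dec <- trace_dec[order(trace_dec$cell, trace_dec$month), ]
  if (!identical(con$cell, dec$cell) || !identical(con$month, dec$month))
    stop("traces are not aligned on cells and months", call. = FALSE)
  out <- list()
  for (v in variables) {
    for (m in sort(unique(con$month))) {
      ic <- con$month == m
      fc <- con[[v]][ic]; fd <- dec[[v]][ic]
      stress_con <- mean(1 - fc)
      stress_dec <- mean(1 - fd)
      dz <- stress_dec <= 0
      dif <- abs(fc - fd)
      if (relative) dif <- dif / pmax(pmin(fc, fd), .Machine$double.eps)
      out[[length(out) + 1]] <- data.frame(
        variable = v, month = m, stress_conifer = stress_con,
        stress_deciduous = stress_dec,
        pct_diff = if (dz) NA_real_ else
          100 * (stress_con - stress_dec) / stress_dec,
        denom_zero = dz,
        flagged_frac = mean(dif > flag_threshold))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare planting rules within and across climate scenarios
#'
#' Convenience wrapper reproducing the standard comparison battery on a
#' result grid: a Kruskal-Wallis test across planting rules within each
#' climate scenario (and across climates within each rule), with Dunn's
#' post-hoc pairwise comparisons.
#'
#' @param results Named list of \linkS4class{ScenarioResult} from
#'   \code{\link{runAll}}.
#' @param adjust_method Dunn p-adjustment method.
#' @return List with data.frames \code{kruskal} and \code{dunn}.
#' @export
compareScenarios <- function(results, adjust_method = "holm") {
  rules <- unique(vapply(results, function(r) r@rule, character(1)))
  scns <- unique(vapply(results, function(r) r@scenario, character(1)))
  kw_rows <- list(); dunn_rows <- list()
  addBattery <- function(groups, comparison, stratum) {
    groups <- groups[lengths(groups) >= 2]
    if (length(groups) < 2) return()
    kw <- kruskalWallis(groups)
    kw_rows[[length(kw_rows) + 1]] <<- data.frame(
      comparison = comparison, stratum = stratum, H = kw$H, df = kw$df,
      p = kw$p)
    dn <- dunnPosthoc(groups, adjust_method)
    dunn_rows[[length(dunn_rows) + 1]] <<- cbind(
      comparison = comparison, stratum = stratum, dn)
  }
  for (scn in scns) {
    groups <- lapply(results[vapply(results, function(r)
      r@scenario == scn, logical(1))], finalAGB)
    names(groups) <- sub("x.*$", "", names(groups))
    addBattery(groups, "rules_within_climate", scn)
  }
  for (rule in rules) {
    groups <- lapply(results[vapply(results, function(r)
      r@rule == rule, logical(1))], finalAGB)
    names(groups) <- sub("^.*x", "", names(groups))
    addBattery(groups, "climates_within_rule", rule)
  }
  list(kruskal = do.call(rbind, kw_rows), dunn = do.call(rbind, dunn_rows))
}
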