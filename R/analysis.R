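# Cohort-level statistics: summaries, capability rates, group comparisons,
# stratified cost tables, cost per successfully treated year, curve
# crossings.

#' Share of values violating a specification limit
#'
#' Capability-style rate: the share of per-run values beyond a spec limit.
#' With `side = "upper"` (e.g. model-error years with upper limit 0) the
#' rate is the share strictly above the limit; with `side = "lower"` (e.g.
#' first-failure year with lower limit 10) the share strictly below it.
#'
#' @param values Non-empty numeric vector of per-run values.
#' @param limit Specification limit.
#' @param side `"upper"` or `"lower"`.
#' @return Proportion in \[0, 1\].
#' @examples
#' spec_limit_rate(c(1, -1, 0), 0, "upper")  # 1/3
#' @export
spec_limit_rate <- function(values, limit, side = c("upper", "lower")) {
  side <- match.arg(side)
  if (length(values) == 0L) stop("'values' must be non-empty")
  if (side == "upper") mean(values > limit) else mean(values < limit)
}

#' Summarise a cost vector
#'
#' Mean, sample standard deviation (n - 1 denominator), median and the
#' cost-homogeneity coefficient `mean / (mean + sd)` — the casemix-style
#' homogeneity measure: 1 for perfectly predictable costs, smaller the
#' more the costs scatter relative to their level.
#'
#' @param costs Non-empty numeric vector (EUR).
#' @return A one-row data.frame with columns `n`, `mean`, `sd`, `median`,
#'   `homogeneity` (`sd` and `homogeneity` are `NA` for a single value).
#' @examples
#' summarize_costs(c(1, 3))
#' @export
summarize_costs <- function(costs) {
  if (length(costs) == 0L) stop("'costs' must be non-empty")
  m <- mean(costs)
  s <- if (length(costs) >= 2L) stats::sd(costs) else NA_real_
  data.frame(n = length(costs), mean = m, sd = s, median = stats::median(costs),
             homogeneity = m / (m + s))
}

#' Bonett's test for equality of two standard deviations
#'
#' Two-sample test of `H0: sd(x) = sd(y)` that stays close to its nominal
#' level for non-normal data (Bonett 2006): the log variance ratio, with a
#' small-sample correction factor, is studentised by a standard error
#' built from a pooled kurtosis estimate computed about trimmed means
#' (trim proportion `1/(2*sqrt(n - 4))`).
#'
#' @param x,y Numeric samples, each of length >= 5 and with positive
#'   variance.
#' @return A list of class `htest` with `statistic` (z), `p.value`
#'   (two-sided) and `estimate` (the two sds).
#' @references Bonett, D. G. (2006). Robust confidence interval for a
#'   ratio of standard deviations. Applied Psychological Measurement 30,
#'   432-439.
#' @export
bonett_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 5 || n2 < 5) stop("bonett_test needs at least 5 observations per sample")
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (v1 == 0 || v2 == 0) stop("bonett_test is undefined for zero-variance samples")
  trim1 <- 1 / (2 * sqrt(n1 - 4))
  trim2 <- 1 / (2 * sqrt(n2 - 4))
  m1 <- mean(x, trim = trim1)
  m2 <- mean(y, trim = trim2)
  # pooled kurtosis about the trimmed means
  gamma4 <- (n1 + n2) * (sum((x - m1)^4) + sum((y - m2)^4)) /
    (sum((x - mean(x))^2) + sum((y - mean(y))^2))^2
  se2 <- function(n) (gamma4 - (n - 3) / n) / (n - 1)
  cc <- (n1 / (n1 - 4)) / (n2 / (n2 - 4))  # small-sample correction
  z <- log(cc * v1 / v2) / sqrt(se2(n1) + se2(n2))
  structure(list(
    statistic = c(z = z),
    p.value = 2 * stats::pnorm(-abs(z)),
    estimate = c(sd.x = sqrt(v1), sd.y = sqrt(v2)),
    method = "Bonett test for equality of standard deviations",
    data.name = paste(deparse(substitute(x)), "and", deparse(substitute(y)))
  ), class = "htest")
}

#' Compare two cost cohorts
#'
#' Location comparison by Welch's unequal-variance two-sample t-test and
#' spread comparison by Bonett's test for equality of standard deviations.
#'
#' @param a,b Numeric cost vectors (each n >= 5).
#' @return A list with `location_p`, `sd_p` and the two underlying `htest`
#'   objects (`location_test`, `sd_test`).
#' @examples
#' set.seed(1)
#' compare_groups(rnorm(50), rnorm(50, sd = 2))
#' @export
compare_groups <- function(a, b) {
  tt <- stats::t.test(a, b, var.equal = FALSE)
  bt <- bonett_test(a, b)
  list(location_p = tt$p.value, sd_p = bt$p.value,
       location_test = tt, sd_test = bt)
}

#' Cost per successfully treated life-year
#'
#' Ratio of sums: total cohort cost divided by total cohort years of
#' successful treatment (not the mean of per-run ratios). For the implant
#' pathways the successful years are the full observation period; for the
#' surgeries-only pathway they exclude the care gap.
#'
#' @param costs Numeric vector of lifetime costs (EUR).
#' @param successful_years Numeric vector of the same length (years).
#' @return EUR per year.
#' @examples
#' cost_per_successful_year(19939.61, 10)
#' @export
cost_per_successful_year <- function(costs, successful_years) {
  if (length(costs) != length(successful_years)) {
    stop("'costs' and 'successful_years' must have equal length")
  }
  total_years <- sum(successful_years)
  if (total_years <= 0) stop("total successful years must be > 0")
  sum(costs) / total_years
}

#' Cost summaries stratified by an outcome variable
#'
#' Summarises lifetime costs within strata defined by exact equality of an
#' integer outcome column (e.g. observation period `top` = 10/20/30 years,
#' or pre-implant surgery count `nhi` = 1..5). Strata with no runs are
#' reported as missing (`NA`), not as zero.
#'
#' @param outcomes A cohort outcome data.frame (from [run_cohort()]).
#' @param stratifier Column name to stratify on (e.g. `"top"`, `"nhi"`).
#' @param levels Values defining the strata.
#' @param value Column summarised (default `"ltc"`).
#' @return A data.frame with one row per level: `level`, `n`, `mean`,
#'   `sd`, `median`, `homogeneity`.
#' @examples
#' g1 <- run_cohort(model_parameters(), "g1", 2000, seed = 1)
#' conditional_cost_table(g1, "top", c(10, 20, 30))
#' @export
conditional_cost_table <- function(outcomes, stratifier, levels, value = "ltc") {
  if (!stratifier %in% names(outcomes)) {
    stop("stratifier '", stratifier, "' is not a column of 'outcomes'")
  }
  rows <- lapply(levels, function(lv) {
    x <- outcomes[[value]][outcomes[[stratifier]] == lv]
    if (length(x) == 0L) {
      data.frame(level = lv, n = 0L, mean = NA_real_, sd = NA_real_,
                 median = NA_real_, homogeneity = NA_real_)
    } else {
      cbind(level = lv, summarize_costs(x))
    }
  })
  do.call(rbind, rows)
}

#' Cost curves over the treatment duration
#'
#' Helper for the crossing analyses. With `per_successful_year = FALSE`,
#' the mean of `value` at each integer observation period. With
#' `per_successful_year = TRUE`, the stratum-wise ratio of summed costs to
#' summed successfully treated years, with strata formed on the *rounded
#' successfully treated years*: for the implant pathways these coincide
#' with the observation period, while for the surgeries-only pathway runs
#' are placed at the duration they actually achieved, so that strata with
#' long nominal horizons but early care gaps contribute where their
#' successful years put them.
#'
#' @param outcomes A cohort outcome data.frame.
#' @param value Column to average (default `"ltc"`).
#' @param per_successful_year If `TRUE`, return the stratum-wise cost per
#'   successfully treated year instead of the mean.
#' @param grid Integer durations to evaluate (default: all observation
#'   periods present in the cohort).
#' @return Named numeric vector on `grid` (NA where a stratum is empty).
#' @export
mean_cost_by_top <- function(outcomes, value = "ltc",
                             per_successful_year = FALSE,
                             grid = sort(unique(outcomes$top))) {
  strat <- if (per_successful_year) {
    round_half_out(outcomes$successful_years)
  } else {
    outcomes$top
  }
  out <- vapply(grid, function(t) {
    idx <- strat == t
    if (!any(idx)) return(NA_real_)
    if (per_successful_year) {
      sy <- sum(outcomes$successful_years[idx])
      if (sy <= 0) return(NA_real_)
      sum(outcomes[[value]][idx]) / sy
    } else {
      mean(outcomes[[value]][idx])
    }
  }, numeric(1))
  names(out) <- grid
  out
}

#' First sign change between two curves on a common integer grid
#'
#' Finds the smallest grid point at which the sign of `curve_a - curve_b`
#' differs from its sign at the previous (non-missing) grid point, i.e.
#' the right edge of the one-year interval bracketing the crossing. No
#' sub-year interpolation is attempted.
#'
#' @param curve_a,curve_b Named numeric vectors (names = integer grid,
#'   e.g. observation period), as from [mean_cost_by_top()]. Missing
#'   values are skipped.
#' @param grid Optional integer grid to restrict the comparison to.
#' @return The grid value at which the sign change is first observed, with
#'   attribute `interval = c(before, at)`, or `NULL` if the curves never
#'   cross.
#' @examples
#' a <- c("1" = 1, "2" = 0.5, "3" = -0.5)
#' crossing_year(a, c("1" = 0, "2" = 0, "3" = 0))  # 3, interval 2..3
#' @export
crossing_year <- function(curve_a, curve_b, grid = NULL) {
  common <- intersect(names(curve_a), names(curve_b))
  if (!is.null(grid)) common <- intersect(common, as.character(grid))
  common <- common[order(as.numeric(common))]
  d <- curve_a[common] - curve_b[common]
  keep <- !is.na(d)
  d <- d[keep]
  g <- as.numeric(common[keep])
  if (length(d) < 2L) return(NULL)
  s <- sign(d)
  for (i in 2:length(d)) {
    if (s[i] != 0 && s[i - 1] != 0 && s[i] != s[i - 1]) {
      out <- g[i]
      attr(out, "interval") <- c(g[i - 1], g[i])
      return(out)
    }
  }
  NULL
}
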