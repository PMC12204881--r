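# Age-threshold treatment strategy: route each simulated patient to the
# pathway the remaining lifetime favours.

#' Age-threshold treatment policy
#'
#' The decision rule derived from the cohort comparisons: patients with a
#' short remaining lifetime (`top < g3_threshold`) stay with
#' hearing-improvement surgery only; patients with a long remaining
#' lifetime (`top > g1_threshold`) receive the implant directly; everyone
#' in between starts with one hearing-improvement surgery and switches to
#' the implant at the time of the second intervention if the remaining
#' years at that point exceed `switch_remaining_min`, otherwise stays with
#' surgery.
#'
#' @param g3_threshold Years; below this the surgeries-only pathway is
#'   chosen (default 14).
#' @param g1_threshold Years; above this the direct implant is chosen
#'   (default 35).
#' @param switch_remaining_min Years; minimum remaining lifetime at the
#'   second intervention for the mid-band switch to the implant
#'   (default 13).
#' @return An object of class `strategy_policy`.
#' @export
strategy_policy <- function(g3_threshold = 14, g1_threshold = 35,
                            switch_remaining_min = 13) {
  if (!(g3_threshold <= g1_threshold)) {
    stop("invalid policy: need g3_threshold <= g1_threshold")
  }
  if (g3_threshold <= 0 || g1_threshold <= 0 || switch_remaining_min <= 0) {
    stop("invalid policy: thresholds must be positive")
  }
  structure(list(g3_threshold = g3_threshold, g1_threshold = g1_threshold,
                 switch_remaining_min = switch_remaining_min),
            class = "strategy_policy")
}

#' Simulate the age-threshold treatment strategy
#'
#' Draws `n` runs, routes each into one of four arms per the policy and
#' evaluates the corresponding pathway on that run's draws:
#' * `g3_age_first`: `top` below the lower threshold — surgeries only.
#' * `g1_direct`: `top` above the upper threshold — direct implant.
#' * mid-band runs have one hearing-improvement surgery; at the scheduled
#'   second intervention (the integer event year of the first surgery's
#'   success duration) the remaining years decide:
#'   `surgery_then_implant` if they exceed the switch minimum (evaluated
#'   as the surgery-then-implant pathway with the pre-implant time fixed
#'   to that event year), else `g3_age_second` (surgeries only).
#'
#' @param params A [model_parameters] object.
#' @param n Number of runs.
#' @param seed Integer root seed (same substream scheme as
#'   [run_cohort()], so arm evaluations reuse identical draws).
#' @param policy A [strategy_policy].
#' @return A list of class `strategy_result`: `mean`, `sd`, `median`,
#'   `cost_per_successful_year`, `arm_shares` (named, sums to 1), `n`,
#'   and the per-run data.frame `runs` (arm, top, ltc,
#'   successful_years).
#' @examples
#' simulate_strategy(model_parameters(), 1000, seed = 1)
#' @export
simulate_strategy <- function(params, n, seed, policy = strategy_policy()) {
  if (!inherits(policy, "strategy_policy")) stop("'policy' must be a strategy_policy")
  draws <- draw_runs(params, n, seed)
  top <- compute_top(draws$AFIa, draws$AFIb, draws$AFIc,
                     params$lex, params$mia)$top
  # The second intervention is scheduled at the model's event year of the
  # first surgery's success duration; the switch decision compares the
  # remaining lifetime at that point against the policy minimum. When the
  # switch is taken, the pre-implant phase length follows the same
  # convention the surgery-then-implant equations use for converting a
  # continuous care duration to integer years (plain rounding).
  second_year <- event_year(draws$DSH1)
  remaining <- top - second_year
  thi_switch <- round_half_out(draws$DSH1)

  arm <- ifelse(top < policy$g3_threshold, "g3_age_first",
         ifelse(top > policy$g1_threshold, "g1_direct",
         ifelse(remaining > policy$switch_remaining_min,
                "surgery_then_implant", "g3_age_second")))

  ltc <- numeric(n)
  successful <- numeric(n)
  g3_idx <- arm %in% c("g3_age_first", "g3_age_second")
  if (any(g3_idx)) {
    o <- simulate_group3(draws[g3_idx, , drop = FALSE], params)
    ltc[g3_idx] <- o$ltc
    successful[g3_idx] <- o$successful_years
  }
  g1_idx <- arm == "g1_direct"
  if (any(g1_idx)) {
    o <- simulate_group1(draws[g1_idx, , drop = FALSE], params)
    ltc[g1_idx] <- o$ltc
    successful[g1_idx] <- o$successful_years
  }
  g2_idx <- arm == "surgery_then_implant"
  if (any(g2_idx)) {
    o <- simulate_group2(draws[g2_idx, , drop = FALSE], params,
                         thi = thi_switch[g2_idx])
    ltc[g2_idx] <- o$ltc
    successful[g2_idx] <- o$successful_years
  }

  shares <- vapply(c("g3_age_first", "g3_age_second", "g1_direct",
                     "surgery_then_implant"),
                   function(a) mean(arm == a), numeric(1))
  structure(list(
    mean = mean(ltc), sd = stats::sd(ltc), median = stats::median(ltc),
    cost_per_successful_year = cost_per_successful_year(ltc, successful),
    arm_shares = shares, n = n,
    runs = data.frame(run = draws$run, arm = arm, top = top,
                      ltc = ltc, successful_years = successful)
  ), class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, ...) {
  cat("<strategy_result>  n =", x$n, "\n")
  cat(sprintf("  lifetime cost: mean %.2f EUR (sd %.2f), median %.2f\n",
              x$mean, x$sd, x$median))
  cat(sprintf("  cost per successfully treated year: %.2f EUR\n",
              x$cost_per_successful_year))
  cat("  arm shares:\n")
  for (a in names(x$arm_shares)) {
    cat(sprintf("    %-22s %6.2f%%\n", a, 100 * x$arm_shares[[a]]))
  }
  invisible(x)
}
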