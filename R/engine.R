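# Deterministic per-run trajectory arithmetic: observation-period cascade,
# event scheduling, discounting, and the three pathway cost equations.

# Spreadsheet-style rounding: half away from zero (round(0.5) = 1,
# round(-0.5) = -1). Base R's round() is half-to-even and must not be used
# in the trajectory equations.
round_half_out <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Integer event year of a cumulative event time
#'
#' Maps a cumulative time since the start of observation to the integer
#' year used both as discount exponent and as scheduling index:
#' `round(t - 0.5)` with half rounded away from zero, clamped at 0 so an
#' event at time exactly 0 is charged undiscounted rather than at year -1.
#'
#' @param cumulative_time Non-negative cumulative time(s) in years.
#' @return Integer-valued numeric vector of event years (>= 0).
#' @examples
#' event_year(c(0, 2.4, 10.5))  # 0 2 10
#' @export
event_year <- function(cumulative_time) {
  pmax(0, round_half_out(cumulative_time - 0.5))
}

#' Present value of a future cost
#'
#' Discounts a cost arising in integer year `year` back to the start of
#' observation at annual rate `dir`.
#'
#' @param amount Cost in EUR.
#' @param year Integer year (>= 0) the cost arises in.
#' @param dir Annual discount rate (>= 0).
#' @return `amount / (1 + dir)^year`.
#' @examples
#' present_value(5719.9, 7, 0.05)
#' @export
present_value <- function(amount, year, dir) {
  if (any(year < 0)) stop("'year' must be >= 0: events before the first intervention are impossible")
  if (any(dir < 0)) stop("'dir' must be >= 0")
  amount / (1 + dir)^year
}

#' Present value of the annual check-up appointments
#'
#' Total discounted cost of one flat-rate outpatient check-up per year over
#' an observation period of `top` years. The first year's check-up is part
#' of the intervention's own follow-up package, so `top - 1` payments are
#' discounted as an immediate annuity:
#' `foa * ((1+dir)^(top-1) - 1) / ((1+dir)^(top-1) * dir)`,
#' with the analytic limit `foa * (top - 1)` at `dir = 0`.
#'
#' @param foa Flat-rate outpatient appointment cost (EUR).
#' @param top Integer observation period in years (>= 1).
#' @param dir Annual discount rate (>= 0).
#' @return Present value in EUR (0 when `top = 1`).
#' @examples
#' annual_checkup_cost(145, 10, 0.05)
#' @export
annual_checkup_cost <- function(foa, top, dir) {
  if (any(top < 1)) stop("'top' must be >= 1")
  if (any(dir < 0)) stop("'dir' must be >= 0")
  len <- max(length(foa), length(top), length(dir))
  foa <- rep_len(foa, len); top <- rep_len(top, len); dir <- rep_len(dir, len)
  g <- (1 + dir)^(top - 1)
  ifelse(dir == 0, foa * (top - 1), foa * (g - 1) / (g * dir))
}

#' Audio-processor upgrade schedule
#'
#' Years at which processor upgrades fall due: every `tap` years (the
#' rounded 6-year minimum plus the fitted extra time), as long as the
#' remaining device-use horizon covers the k-th upgrade, up to `cap`
#' upgrades. `offset` shifts the schedule by a pre-implant phase.
#'
#' @param tap Upgrade interval in integer years (>= 1).
#' @param horizon Device-use horizon in years; upgrade k happens iff
#'   `horizon >= k * tap`.
#' @param offset Years before the device phase starts (default 0).
#' @param cap Maximum number of upgrades (default 12).
#' @return Integer vector of upgrade years (possibly empty).
#' @examples
#' upgrade_schedule(7, 26)        # 7 14 21
#' @export
upgrade_schedule <- function(tap, horizon, offset = 0, cap = 12) {
  if (tap < 1) stop("'tap' must be >= 1")
  k <- seq_len(cap)
  offset + k[horizon >= k * tap] * tap
}

#' Total observation period from the age draws
#'
#' Derives the integer observation period TOP (years from first
#' intervention to the fixed life expectancy) from three independent
#' age-at-first-intervention draws via the model's bound-correction
#' cascade: the rounded `lex - afia` is used unless it exceeds the upper
#' check (falling back to `afib`, then `afic`) or falls below 1 year
#' (again falling back), is floored at 1 and finally clamped at
#' `lex - mia`. The literal upper check of the cascade is the constant 77
#' even though the final clamp is `lex - mia` (= 76 at the defaults); the
#' published equations are reproduced verbatim.
#'
#' @param afia,afib,afic Age-at-first-intervention draws (years).
#' @param lex Fixed life expectancy (years).
#' @param mia Minimum implantation age (years).
#' @return A list with integer-valued `top` (in `[1, lex - mia]`) and
#'   `afi = lex - top`.
#' @examples
#' compute_top(54.0, 60, 60, 81, 5)  # top 27
#' @export
compute_top <- function(afia, afib, afic, lex = 81, mia = 5) {
  if (!(lex > mia)) stop("need lex > mia")
  t_ub1 <- ifelse(round_half_out(lex - afia) > (lex - mia),
                  round_half_out(lex - afib), round_half_out(lex - afia))
  t_ub2 <- ifelse(t_ub1 > 77, round_half_out(lex - afic), t_ub1)
  t_lb1 <- ifelse(t_ub2 < 1, round_half_out(lex - afib), t_ub2)
  t_lb2 <- ifelse(t_lb1 < 1, round_half_out(lex - afic), t_lb1)
  t_lb3 <- ifelse(t_lb2 < 1, 1, t_lb2)
  top <- ifelse(t_lb3 > (lex - mia), lex - mia, t_lb3)
  list(top = top, afi = lex - top)
}

# Floored (non-negative) implant lifetimes and revision times as matrices,
# one column per event slot.
floored_matrix <- function(draws, prefix, k) {
  m <- as.matrix(draws[paste0(prefix, seq_len(k))])
  m[m < 0] <- 0
  unname(m)
}

# Discounted implant-phase costs shared by the direct-implant and
# surgery-then-implant pathways: re-implantations, revisions, upgrades.
# `horizon` is the device-use horizon (TOP or TSB), `offset` the years of
# pre-implant care added to every discount exponent.
implant_phase <- function(draws, params, horizon, offset = 0) {
  dir <- params$dir
  lts <- floored_matrix(draws, "LTS", 3)
  ttr <- floored_matrix(draws, "TTR", 4)
  cum_lts <- t(apply(lts, 1, cumsum))
  cum_ttr <- t(apply(ttr, 1, cumsum))

  reimpl_cost <- draws$ISB + 2 * params$foa
  cri <- numeric(nrow(lts))
  for (k in seq_len(params$caps$max_reimplantations)) {
    happens <- cum_lts[, k] < horizon
    yr <- round_half_out(offset + cum_lts[, k] - 0.5)
    cri <- cri + ifelse(happens, reimpl_cost / (1 + dir)^pmax(0, yr), 0)
  }
  noi <- 1 + rowSums(cum_lts[, seq_len(params$caps$max_reimplantations), drop = FALSE] < horizon)

  rev_cost <- draws$REV + params$foa
  cre <- numeric(nrow(ttr))
  for (k in seq_len(params$caps$max_revisions)) {
    happens <- cum_ttr[, k] < horizon
    yr <- round_half_out(offset + cum_ttr[, k] - 0.5)
    cre <- cre + ifelse(happens, rev_cost / (1 + dir)^pmax(0, yr), 0)
  }
  nor <- rowSums(cum_ttr[, seq_len(params$caps$max_revisions), drop = FALSE] < horizon)

  tap <- round_half_out(params$ttua + draws$TTUb)
  ks <- seq_len(params$caps$max_upgrades)
  due <- sapply(ks, function(k) horizon >= k * tap)
  if (is.null(dim(due))) due <- matrix(due, nrow = 1)
  disc <- sapply(ks, function(k) params$apu / (1 + dir)^(k * tap + offset))
  if (is.null(dim(disc))) disc <- matrix(disc, nrow = 1)
  apu <- rowSums(due * disc)
  nop <- rowSums(due)

  list(
    cri = cri, cre = cre, apu = apu,
    noi = noi, nor = nor, nop = nop, tap = tap,
    ep_lts = horizon - rowSums(lts),
    ep_ttr = horizon - rowSums(ttr),
    first_fail_year = event_year(lts[, 1]),
    first_rev_year = event_year(ttr[, 1])
  )
}

#' Simulate the direct-implant pathway (group 1)
#'
#' Evaluates the direct-implant trajectory for each row of `draws`: the
#' observation period from the age cascade, up to two re-implantations at
#' the drawn implant lifetimes, up to three revisions, processor upgrades
#' every `TAP` years (capped at 12), the annual check-up annuity, and the
#' resulting discounted lifetime cost
#' `ltc = cfi + cri + cre + apu + tsc`.
#'
#' @param draws A data.frame of per-run draws from [draw_runs()].
#' @param params A [model_parameters] object.
#' @return A data.frame, one row per run, with columns `top`, `afi`, `tap`,
#'   event counts `noi`/`nor`/`nop`, signed model-error years
#'   `ep_lts`/`ep_ttr`, rounded first-failure/first-revision years, cost
#'   components `cfi`/`cri`/`cre`/`apu`/`tsc`, lifetime cost `ltc`, and
#'   `successful_years` (the full observation period for this pathway).
#' @examples
#' p <- model_parameters()
#' head(simulate_group1(draw_runs(p, 100, seed = 1), p))
#' @export
simulate_group1 <- function(draws, params) {
  validate_parameters(params)
  tp <- compute_top(draws$AFIa, draws$AFIb, draws$AFIc, params$lex, params$mia)
  ph <- implant_phase(draws, params, horizon = tp$top, offset = 0)
  cfi <- draws$ISB + 3 * params$foa
  tsc <- annual_checkup_cost(params$foa, tp$top, params$dir)
  data.frame(
    run = draws$run, top = tp$top, afi = tp$afi, tap = ph$tap,
    noi = ph$noi, nor = ph$nor, nop = ph$nop,
    ep_lts = ph$ep_lts, ep_ttr = ph$ep_ttr,
    first_fail_year = ph$first_fail_year, first_rev_year = ph$first_rev_year,
    cfi = cfi, cri = ph$cri, cre = ph$cre, apu = ph$apu, tsc = tsc,
    ltc = cfi + ph$cri + ph$cre + ph$apu + tsc,
    successful_years = tp$top
  )
}

# Discounted further-surgery costs and surgery count for a horizon
# (pre-implant time THI for group 2, the whole period TOP for group 3).
# The published equations compare the *unrounded* first duration but the
# *rounded* later cumulative sums against the horizon; reproduced verbatim.
surgery_phase <- function(draws, params, horizon, max_nhi) {
  n <- nrow(draws)
  dsh <- as.matrix(draws[paste0("DSH", seq_len(15))])
  his <- as.matrix(draws[paste0("HIS", seq_len(15))])
  cum <- t(apply(dsh, 1, cumsum))
  cfs <- numeric(n)
  for (k in 2:max_nhi) {
    cum_prev <- cum[, k - 1]
    cond_val <- if (k == 2) cum_prev else round_half_out(cum_prev)
    happens <- cond_val < horizon
    yr <- pmax(0, round_half_out(cum_prev - 0.5))
    cfs <- cfs + ifelse(happens, (his[, k] + params$foa) / (1 + params$dir)^yr, 0)
  }
  # surgery count: unrounded cumulative sums throughout
  nhi <- 1 + rowSums(cum[, seq_len(max_nhi - 1), drop = FALSE] < horizon)
  ep_nhi <- horizon - rowSums(dsh[, seq_len(max_nhi), drop = FALSE])
  list(cfs = cfs, nhi = nhi, ep_nhi = ep_nhi)
}

#' Simulate the surgeries-then-implant pathway (group 2)
#'
#' Splits the observation period into a pre-implant phase `thi` of
#' hearing-improvement surgeries (the rounded drawn total, bounded by the
#' observation period and capped at 25 years) and the implant phase
#' `tsb = top - thi`. Up to six surgeries (including the initial one) are
#' scheduled by the drawn success durations; the implant is charged at year
#' `thi` and the implant-phase events (re-implantations, revisions,
#' upgrades) run against the shortened horizon `tsb` with all discount
#' exponents offset by `thi`. Lifetime cost is
#' `ltc = cfi + cfs + vsb + cri + cre + apu + tsc`. The implant cost `vsb`
#' is charged unconditionally, at year `top`, even in runs where `tsb = 0`,
#' exactly as the published equations define it.
#'
#' @inheritParams simulate_group1
#' @param thi Optional integer vector overriding the pre-implant time per
#'   run (used by the treatment strategy, where the switch time is set by
#'   the first surgery's outcome rather than by the fitted distribution).
#' @return A data.frame, one row per run, with the phase split
#'   (`thi`, `tsb`), surgery count `nhi` and error years `ep_nhi`, implant
#'   phase counts/errors as in group 1, the seven cost components, `ltc`,
#'   and `successful_years = top - max(0, ep_nhi)`.
#' @export
simulate_group2 <- function(draws, params, thi = NULL) {
  validate_parameters(params)
  tp <- compute_top(draws$AFIa, draws$AFIb, draws$AFIc, params$lex, params$mia)
  if (is.null(thi)) {
    thi_lb <- ifelse(round_half_out(draws$THIt) < tp$top,
                     round_half_out(draws$THIt), tp$top)
    thi <- ifelse(thi_lb < params$caps$thi_cap, thi_lb, params$caps$thi_cap)
  } else {
    thi <- pmin(thi, tp$top, params$caps$thi_cap)
  }
  tsb <- tp$top - thi
  sp <- surgery_phase(draws, params, horizon = thi,
                      max_nhi = params$caps$max_nhi_g2)
  ph <- implant_phase(draws, params, horizon = tsb, offset = thi)
  cfi <- draws$HIS1 + 2 * params$foa
  vsb <- (draws$ISB + 2 * params$foa) / (1 + params$dir)^thi
  tsc <- annual_checkup_cost(params$foa, tp$top, params$dir)
  data.frame(
    run = draws$run, top = tp$top, afi = tp$afi, thi = thi, tsb = tsb,
    nhi = sp$nhi, ep_nhi = sp$ep_nhi,
    noi = ph$noi, nor = ph$nor, nop = ph$nop, tap = ph$tap,
    ep_lts = ph$ep_lts, ep_ttr = ph$ep_ttr,
    cfi = cfi, cfs = sp$cfs, vsb = vsb,
    cri = ph$cri, cre = ph$cre, apu = ph$apu, tsc = tsc,
    ltc = cfi + sp$cfs + vsb + ph$cri + ph$cre + ph$apu + tsc,
    successful_years = tp$top - pmax(0, sp$ep_nhi)
  )
}

#' Simulate the surgeries-only pathway (group 3)
#'
#' Hearing-improvement surgeries over the whole observation period, up to
#' 15 interventions including the initial one. Runs whose 15 surgery
#' durations do not cover the period carry a positive model error
#' `ep_nhi`; its positive part is the care gap, and
#' `successful_years = top - care_gap`. Lifetime cost is
#' `ltc = cfi + cfs + tsc`.
#'
#' @inheritParams simulate_group1
#' @return A data.frame, one row per run, with `top`, `nhi`, `ep_nhi`,
#'   `care_gap`, `successful_years`, the cost components `cfi`/`cfs`/`tsc`
#'   and `ltc`.
#' @export
simulate_group3 <- function(draws, params) {
  validate_parameters(params)
  tp <- compute_top(draws$AFIa, draws$AFIb, draws$AFIc, params$lex, params$mia)
  sp <- surgery_phase(draws, params, horizon = tp$top,
                      max_nhi = params$caps$max_nhi_g3)
  cfi <- draws$HIS1 + 2 * params$foa
  tsc <- annual_checkup_cost(params$foa, tp$top, params$dir)
  care_gap <- pmax(0, sp$ep_nhi)
  data.frame(
    run = draws$run, top = tp$top, afi = tp$afi,
    nhi = sp$nhi, ep_nhi = sp$ep_nhi, care_gap = care_gap,
    successful_years = tp$top - care_gap,
    cfi = cfi, cfs = sp$cfs, tsc = tsc,
    ltc = cfi + sp$cfs + tsc
  )
}

#' Run a Monte-Carlo cohort through one treatment pathway
#'
#' Draws `n` independent runs with [draw_runs()] and evaluates the chosen
#' pathway. Identical `(params, group, n, seed)` reproduce identical
#' outcomes; run `i` is reproducible independently of `n`.
#'
#' @param params A [model_parameters] object.
#' @param group `"g1"` (direct implant), `"g2"` (surgeries then implant) or
#'   `"g3"` (surgeries only).
#' @param n Number of simulation runs (>= 1).
#' @param seed Integer root seed.
#' @return The pathway's outcome data.frame (see [simulate_group1()],
#'   [simulate_group2()], [simulate_group3()]) with an added `group`
#'   column; attributes `seed` and `parameter_hash` record provenance.
#' @examples
#' g1 <- run_cohort(model_parameters(), "g1", 500, seed = 7)
#' mean(g1$ltc)
#' @export
run_cohort <- function(params, group = c("g1", "g2", "g3"), n, seed) {
  group <- match.arg(group)
  draws <- draw_runs(params, n, seed)
  out <- switch(group,
    g1 = simulate_group1(draws, params),
    g2 = simulate_group2(draws, params),
    g3 = simulate_group3(draws, params)
  )
  out <- cbind(group = group, out)
  attr(out, "seed") <- seed
  attr(out, "parameter_hash") <- parameter_hash(params)
  out
}
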