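# Literal scalar transcription of the published trajectory equations,
# nested if()s and all, for a single run. This is deliberately naive and
# independent of the vectorised engine: validate_model() and the test
# suite require the two routes to agree to 1e-9 on random runs.
#
# Rounding is half away from zero throughout; discount exponents
# round(t - 0.5) are clamped at 0 (an event at time < 0.5 is charged
# undiscounted, never at year -1).

ref_round <- function(x) sign(x) * floor(abs(x) + 0.5)
ref_year <- function(t) max(0, ref_round(t - 0.5))

ref_top <- function(d, p) {
  LEX <- p$lex; MIA <- p$mia
  TOPuB1 <- if (ref_round(LEX - d$AFIa) > (LEX - MIA)) ref_round(LEX - d$AFIb) else ref_round(LEX - d$AFIa)
  TOPuB2 <- if (TOPuB1 > 77) ref_round(LEX - d$AFIc) else TOPuB1
  TOPlB1 <- if (TOPuB2 < 1) ref_round(LEX - d$AFIb) else TOPuB2
  TOPlB2 <- if (TOPlB1 < 1) ref_round(LEX - d$AFIc) else TOPlB1
  TOPlB3 <- if (TOPlB2 < 1) 1 else TOPlB2
  if (TOPlB3 > (LEX - MIA)) (LEX - MIA) else TOPlB3
}

# Implant-phase terms for one run; offset = THI (0 for the direct pathway),
# horizon = TOP or TSB.
ref_implant_terms <- function(d, p, horizon, offset) {
  DIR <- p$dir; FOA <- p$foa; ISB <- d$ISB; REV <- d$REV
  LTS1lB <- if (d$LTS1 < 0) 0 else d$LTS1
  LTS2lB <- if (d$LTS2 < 0) 0 else d$LTS2
  LTS3lB <- if (d$LTS3 < 0) 0 else d$LTS3
  TTR1lB <- if (d$TTR1 < 0) 0 else d$TTR1
  TTR2lB <- if (d$TTR2 < 0) 0 else d$TTR2
  TTR3lB <- if (d$TTR3 < 0) 0 else d$TTR3
  TTR4lB <- if (d$TTR4 < 0) 0 else d$TTR4
  # the published upper-bound revision columns are identity passes
  # (TTRxuB = TTRxlB) and are collapsed here
  TTR1uB <- TTR1lB; TTR2uB <- TTR2lB; TTR3uB <- TTR3lB

  CRI <- (if (LTS1lB < horizon) (ISB + 2 * FOA) / (1 + DIR)^ref_year(offset + LTS1lB) else 0) +
    (if ((LTS1lB + LTS2lB) < horizon) (ISB + 2 * FOA) / (1 + DIR)^ref_year(offset + LTS1lB + LTS2lB) else 0)
  NOI <- 1 + (if (LTS1lB >= horizon) 0 else 1) + (if ((LTS1lB + LTS2lB) >= horizon) 0 else 1)
  CRE <- (if (TTR1uB < horizon) (REV + FOA) / (1 + DIR)^ref_year(offset + TTR1uB) else 0) +
    (if ((TTR1uB + TTR2uB) < horizon) (REV + FOA) / (1 + DIR)^ref_year(offset + TTR1uB + TTR2uB) else 0) +
    (if ((TTR1uB + TTR2uB + TTR3uB) < horizon) (REV + FOA) / (1 + DIR)^ref_year(offset + TTR1uB + TTR2uB + TTR3uB) else 0)
  NOR <- (if (TTR1uB >= horizon) 0 else 1) + (if ((TTR1uB + TTR2uB) >= horizon) 0 else 1) +
    (if ((TTR1uB + TTR2uB + TTR3uB) >= horizon) 0 else 1)

  TAP <- ref_round(p$ttua + d$TTUb)
  APUc <- 0; NOP <- 0
  for (k in 1:12) {
    if (horizon >= k * TAP) {
      APUc <- APUc + p$apu / (1 + DIR)^(k * TAP + offset)
      NOP <- NOP + 1
    }
  }
  list(CRI = CRI, CRE = CRE, APU = APUc, NOI = NOI, NOR = NOR, NOP = NOP,
       TAP = TAP,
       EP_LTS = horizon - LTS1lB - LTS2lB - LTS3lB,
       EP_TTR = horizon - TTR1uB - TTR2uB - TTR3uB - TTR4lB,
       DR_LTS = ref_year(LTS1lB), DR_TTR = ref_year(TTR1uB))
}

ref_tsc <- function(p, TOP) {
  if (p$dir == 0) p$foa * (TOP - 1)
  else p$foa * (((1 + p$dir)^(TOP - 1)) - 1) / (((1 + p$dir)^(TOP - 1)) * p$dir)
}

# Further-surgery cost for one run over `horizon`; terms 2..max_nhi. The
# first term's condition compares the unrounded DSH1, later terms compare
# the rounded cumulative sums, exactly as published.
ref_cfs <- function(d, p, horizon, max_nhi) {
  DIR <- p$dir; FOA <- p$foa
  dsh <- unlist(d[paste0("DSH", 1:15)])
  his <- unlist(d[paste0("HIS", 1:15)])
  total <- 0
  for (k in 2:max_nhi) {
    s <- sum(dsh[seq_len(k - 1)])
    cond <- if (k == 2) s < horizon else ref_round(s) < horizon
    if (cond) total <- total + (his[k] + FOA) / (1 + DIR)^ref_year(s)
  }
  total
}

ref_nhi <- function(d, horizon, max_nhi) {
  dsh <- unlist(d[paste0("DSH", 1:15)])
  1 + sum(vapply(seq_len(max_nhi - 1),
                 function(k) sum(dsh[seq_len(k)]) < horizon, logical(1)))
}

#' Literal one-run reference evaluation
#'
#' Evaluates a single run's trajectory with a naive scalar transcription
#' of the published equations (nested conditionals, no vectorisation).
#' It is kept independent of the production engine and used by
#' [validate_model()] and the test suite as an equivalence oracle.
#'
#' @param draws A one-row data.frame (or named list) of draws as produced
#'   by [draw_run()].
#' @param params A [model_parameters] object.
#' @param group `"g1"`, `"g2"` or `"g3"`.
#' @return Named list of the run's outputs (counts, error years, cost
#'   components, lifetime cost `LTC`).
#' @export
reference_run <- function(draws, params, group = c("g1", "g2", "g3")) {
  group <- match.arg(group)
  d <- as.list(draws)
  p <- params
  TOP <- ref_top(d, p)
  TSC <- ref_tsc(p, TOP)
  if (group == "g1") {
    t <- ref_implant_terms(d, p, horizon = TOP, offset = 0)
    CFI <- (d$ISB + 3 * p$foa) / (1 + p$dir)^0
    return(list(TOP = TOP, CFI = CFI, CRI = t$CRI, CRE = t$CRE, APU = t$APU,
                TSC = TSC, NOI = t$NOI, NOR = t$NOR, NOP = t$NOP, TAP = t$TAP,
                EP_LTS = t$EP_LTS, EP_TTR = t$EP_TTR,
                DR_LTS = t$DR_LTS, DR_TTR = t$DR_TTR,
                LTC = CFI + t$CRI + t$CRE + t$APU + TSC))
  }
  if (group == "g2") {
    THIlB <- if (ref_round(d$THIt) < TOP) ref_round(d$THIt) else TOP
    THI <- if (THIlB < p$caps$thi_cap) THIlB else p$caps$thi_cap
    TSB <- TOP - THI
    NHI <- ref_nhi(d, THI, p$caps$max_nhi_g2)
    EP_NHI <- THI - sum(unlist(d[paste0("DSH", seq_len(p$caps$max_nhi_g2))]))
    CFI <- (d$HIS1 + 2 * p$foa) / (1 + p$dir)^0
    CFS <- ref_cfs(d, p, THI, p$caps$max_nhi_g2)
    VSB <- (d$ISB + 2 * p$foa) / (1 + p$dir)^THI
    t <- ref_implant_terms(d, p, horizon = TSB, offset = THI)
    return(list(TOP = TOP, THI = THI, TSB = TSB, NHI = NHI, EP_NHI = EP_NHI,
                CFI = CFI, CFS = CFS, VSB = VSB, CRI = t$CRI, CRE = t$CRE,
                APU = t$APU, TSC = TSC, NOI = t$NOI, NOR = t$NOR, NOP = t$NOP,
                EP_LTS = t$EP_LTS, EP_TTR = t$EP_TTR,
                LTC = CFI + CFS + VSB + t$CRI + t$CRE + t$APU + TSC))
  }
  NHI <- ref_nhi(d, TOP, p$caps$max_nhi_g3)
  EP_NHI <- TOP - sum(unlist(d[paste0("DSH", seq_len(p$caps$max_nhi_g3))]))
  CFI <- (d$HIS1 + 2 * p$foa) / (1 + p$dir)^0
  CFS <- ref_cfs(d, p, TOP, p$caps$max_nhi_g3)
  list(TOP = TOP, NHI = NHI, EP_NHI = EP_NHI, CFI = CFI, CFS = CFS, TSC = TSC,
       care_gap = max(0, EP_NHI), LTC = CFI + CFS + TSC)
}
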