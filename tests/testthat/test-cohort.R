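p <- model_parameters()

test_that("run_cohort is deterministic in (params, group, n, seed)", {
  for (g in c("g1", "g2", "g3")) {
    a <- run_cohort(p, g, 200, seed = 11)
    b <- run_cohort(p, g, 200, seed = 11)
    expect_identical(a, b)
  }
  expect_error(run_cohort(p, "g1", 0, seed = 1), "positive integer")
})

test_that("lifetime cost is monotone non-decreasing in the horizon", {
  # hold one run's event draws fixed and stretch the observation period;
  # for the surgery-then-implant pathway start above the drawn pre-implant
  # time: while the pre-implant phase itself is still growing, the
  # unconditionally charged implant is discounted further with every extra
  # year, so the published equations are not monotone in that regime
  for (g in c("g1", "g2", "g3")) {
    tops <- if (g == "g2") 7:40 else 2:40
    d <- make_draws(n = length(tops), ISB = 14000,
                    LTS = c(9.4, 14, 400), TTR = c(3.6, 30, 200, 200),
                    THIt = 6, DSH = c(2.4, 1.8, 3, rep(2.2, 12)),
                    TTUb = 0.7)
    d$AFIa <- d$AFIb <- d$AFIc <- p$lex - tops
    o <- switch(g, g1 = simulate_group1(d, p), g2 = simulate_group2(d, p),
                g3 = simulate_group3(d, p))
    expect_equal(o$top, tops)
    expect_true(all(diff(o$ltc) >= -1e-9), label = paste("monotone", g))
  }
})

test_that("vectorised engine agrees with the literal one-run evaluator", {
  d <- draw_runs(p, 1000, seed = 23)
  eng <- list(g1 = simulate_group1(d, p), g2 = simulate_group2(d, p),
              g3 = simulate_group3(d, p))
  fields <- list(
    g1 = c(TOP = "top", NOI = "noi", NOR = "nor", NOP = "nop",
           EP_LTS = "ep_lts", EP_TTR = "ep_ttr", CFI = "cfi", CRI = "cri",
           CRE = "cre", APU = "apu", TSC = "tsc", LTC = "ltc"),
    g2 = c(TOP = "top", THI = "thi", TSB = "tsb", NHI = "nhi",
           EP_NHI = "ep_nhi", CFI = "cfi", CFS = "cfs", VSB = "vsb",
           CRI = "cri", CRE = "cre", APU = "apu", TSC = "tsc", LTC = "ltc"),
    g3 = c(TOP = "top", NHI = "nhi", EP_NHI = "ep_nhi", CFI = "cfi",
           CFS = "cfs", TSC = "tsc", LTC = "ltc")
  )
  for (g in c("g1", "g2", "g3")) {
    worst <- 0
    for (i in seq_len(nrow(d))) {
      r <- reference_run(d[i, ], p, g)
      for (f in names(fields[[g]])) {
        worst <- max(worst, abs(r[[f]] - eng[[g]][[fields[[g]][[f]]]][i]))
      }
    }
    expect_lt(worst, 1e-9, label = paste("oracle equivalence", g))
  }
})

test_that("with no discounting every component is a plain sum of event costs", {
  p0 <- model_parameters(dir = 0)
  d <- draw_runs(p0, 500, seed = 29)
  o1 <- simulate_group1(d, p0)
  expect_equal(o1$cri, (o1$noi - 1) * (d$ISB + 2 * p0$foa), tolerance = 1e-12)
  expect_equal(o1$cre, o1$nor * (d$REV + p0$foa), tolerance = 1e-12)
  expect_equal(o1$apu, o1$nop * p0$apu, tolerance = 1e-12)
  expect_equal(o1$tsc, p0$foa * (o1$top - 1), tolerance = 1e-12)
  # surgeries-only: recompute the costed surgery terms independently
  o3 <- simulate_group3(d, p0)
  rnd <- function(x) sign(x) * floor(abs(x) + 0.5)
  cfs0 <- vapply(seq_len(nrow(d)), function(i) {
    dsh <- as.numeric(d[i, paste0("DSH", 1:15)])
    his <- as.numeric(d[i, paste0("HIS", 1:15)])
    total <- 0
    for (k in 2:15) {
      s <- sum(dsh[1:(k - 1)])
      cond <- if (k == 2) s < o3$top[i] else rnd(s) < o3$top[i]
      if (cond) total <- total + his[k] + p0$foa
    }
    total
  }, numeric(1))
  expect_equal(o3$cfs, cfs0, tolerance = 1e-12)
})

test_that("implant failure rate before year 10 matches the triangular CDF", {
  o <- simulate_group1(draw_runs(p, 10000, seed = 31), p)
  analytic <- 1 - 390^2 / (403 * 400)  # P(LTS1 < 10) = 5.645%
  rate <- spec_limit_rate(o$first_fail_year, 10, "lower")
  se <- sqrt(analytic * (1 - analytic) / 10000)
  expect_lt(abs(rate - analytic), 4 * se)
})
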