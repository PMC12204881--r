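p <- model_parameters()

test_that("surgery-then-implant run matches hand computation", {
  # TOP 20, three years of surgical care (two surgeries at years 0 and 2),
  # then the implant at year 3; no failures/revisions; upgrades at
  # 7+3 and 14+3 years
  d <- make_draws(AFIa = 61, AFIb = 61, AFIc = 61, ISB = 14000, THIt = 3,
                  DSH = c(2.4, 10, rep(50, 13)), HIS = rep(4000, 15),
                  TTUb = 0.7)
  o <- simulate_group2(d, p)
  expect_equal(o$top, 20)
  expect_equal(o$thi, 3)
  expect_equal(o$tsb, 17)
  expect_equal(o$nhi, 2)
  expect_equal(o$cfi, 4000 + 2 * 145)                  # 4,290
  expect_equal(o$cfs, (4000 + 145) / 1.05^2)           # 3,759.64
  expect_equal(o$vsb, (14000 + 2 * 145) / 1.05^3)      # 12,344.26
  expect_equal(o$cri, 0)
  expect_equal(o$cre, 0)
  expect_equal(o$apu, 5719.9 / 1.05^10 + 5719.9 / 1.05^17)  # 6,007.10
  expect_equal(o$tsc, 145 * (1.05^19 - 1) / (1.05^19 * 0.05))
  expect_equal(o$ltc, o$cfi + o$cfs + o$vsb + o$apu + o$tsc)
  expect_equal(round(o$ltc, 2), 28153.34)
})

test_that("pre-implant phase is capped at 25 years and flags under-modelling", {
  # drawn surgical-care time 30y with TOP 40: cap at 25; six 2-year
  # surgeries cover only 12 years -> positive model error
  d <- make_draws(AFIa = 41, AFIb = 41, AFIc = 41, THIt = 30,
                  DSH = rep(2, 15))
  o <- simulate_group2(d, p)
  expect_equal(o$thi, 25)
  expect_equal(o$nhi, 6)
  expect_equal(o$ep_nhi, 25 - 6 * 2)  # 13 years not covered
  expect_gt(o$ep_nhi, 0)
  expect_equal(o$successful_years, o$top - 13)
})

test_that("implant cost is charged even when the implant phase is empty", {
  # drawn care time exceeds TOP: thi = top, tsb = 0; the implant is still
  # charged, discounted at year top, and no implant-phase events occur
  d <- make_draws(AFIa = 61, AFIb = 61, AFIc = 61, ISB = 14000, THIt = 30,
                  LTS = c(1, 1, 1), TTR = c(1, 1, 1, 1))
  o <- simulate_group2(d, p)
  expect_equal(o$thi, 20)
  expect_equal(o$tsb, 0)
  expect_equal(o$vsb, (14000 + 290) / 1.05^20)
  expect_equal(o$noi, 1)
  expect_equal(o$nor, 0)
  expect_equal(o$nop, 0)
  expect_equal(o$cri + o$cre + o$apu, 0)
})

test_that("further-surgery conditions follow the published rounding scheme", {
  # second surgery: unrounded DSH1 < thi; third: rounded cumulative sum.
  # DSH1 = 2.6 < 3 fires; DSH1+DSH2 = 2.6+0.3 = 2.9, rounded to 3,
  # does NOT fire against thi = 3 even though the raw sum is below it
  d <- make_draws(AFIa = 61, AFIb = 61, AFIc = 61, THIt = 3,
                  DSH = c(2.6, 0.3, rep(50, 13)), HIS = rep(4000, 15))
  o <- simulate_group2(d, p)
  expect_equal(o$cfs, 4145 / 1.05^2)
  # the surgery count itself uses the unrounded sums: three surgeries
  expect_equal(o$nhi, 3)
})

test_that("group-2 cohort outcomes respect their structural invariants", {
  o <- simulate_group2(draw_runs(p, 2000, seed = 6), p)
  expect_true(all(o$thi <= 25))
  expect_true(all(o$thi + o$tsb == o$top))
  expect_true(all(o$tsb >= 0))
  expect_true(all(o$nhi %in% 1:6))
  expect_equal(o$ltc, o$cfi + o$cfs + o$vsb + o$cri + o$cre + o$apu + o$tsc,
               tolerance = 1e-12)
})
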