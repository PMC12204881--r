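test_that("spec-limit rates count strict violations on the correct side", {
  expect_equal(spec_limit_rate(c(1, -1, 0), 0, "upper"), 1 / 3)
  expect_equal(spec_limit_rate(c(0, 12, 30), 1, "lower"), 1 / 3)
  expect_error(spec_limit_rate(numeric(0), 0, "upper"), "non-empty")
  # complementary partition: below-limit share + at-or-above share = 1
  set.seed(4)
  x <- rnorm(500)
  expect_equal(spec_limit_rate(x, 0.3, "lower") + mean(x >= 0.3), 1)
})

test_that("cost summaries include the homogeneity coefficient", {
  s <- summarize_costs(c(1, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, sqrt(2))
  expect_equal(s$homogeneity, 2 / (2 + sqrt(2)))
  expect_equal(summarize_costs(rep(7, 10))$homogeneity, 1)
  expect_equal(summarize_costs(rep(7, 10))$sd, 0)
  # reference check: mean 28,325 and sd 6,121 give homogeneity 0.822,
  # via a two-point sample with exactly those moments
  x <- c(28325 - 6121 / sqrt(2), 28325 + 6121 / sqrt(2))
  expect_equal(summarize_costs(x)$mean, 28325)
  expect_equal(summarize_costs(x)$sd, 6121)
  expect_equal(round(summarize_costs(x)$homogeneity, 3), 0.822)
  expect_error(summarize_costs(numeric(0)), "non-empty")
})

test_that("homogeneity decreases as costs scatter more at fixed mean", {
  m <- 100
  h <- vapply(c(0, 5, 20, 50, 90), function(s) m / (m + s), numeric(1))
  expect_true(all(diff(h) < 0))
  # and through the summary itself
  base <- c(-1, 1)
  hs <- vapply(c(1, 10, 40), function(s) summarize_costs(m + s * base)$homogeneity,
               numeric(1))
  expect_true(all(diff(hs) < 0))
})

test_that("group comparison combines Welch and Bonett tests", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  cg <- compare_groups(x, x)
  expect_equal(cg$location_p, 1)
  expect_equal(unname(cg$location_test$statistic), 0)
  expect_equal(cg$sd_p, 1)  # equal n, identical variances -> z = 0
  set.seed(12)
  a <- rnorm(400, sd = 1)
  b <- rnorm(400, sd = 2)
  cg2 <- compare_groups(a, b)
  expect_lt(cg2$sd_p, 0.001)
  expect_error(bonett_test(rep(1, 10), rnorm(10)), "zero-variance")
  expect_error(bonett_test(rnorm(4), rnorm(10)), "at least 5")
})

test_that("Bonett test holds its nominal level under the null", {
  set.seed(631)
  rej <- 0
  reps <- 1000
  for (i in seq_len(reps)) {
    if (bonett_test(rnorm(50), rnorm(50))$p.value < 0.05) rej <- rej + 1
  }
  expect_gt(rej / reps, 0.025)
  expect_lt(rej / reps, 0.080)
})

test_that("cost per successful year is a ratio of sums", {
  expect_equal(cost_per_successful_year(19939.61, 10), 1993.961)
  expect_equal(cost_per_successful_year(c(0, 0), c(1, 2)), 0)
  costs <- c(100, 300, 50)
  years <- c(10, 20, 5)
  cps <- cost_per_successful_year(costs, years)
  expect_equal(cps * sum(years), sum(costs))  # exact identity
  # ratio of sums, not mean of per-run ratios
  expect_false(isTRUE(all.equal(cps, mean(costs / years))))
  expect_error(cost_per_successful_year(1:3, 1:2), "equal length")
  expect_error(cost_per_successful_year(c(1, 2), c(0, 0)), "> 0")
})

test_that("stratified cost tables use exact levels and report empty strata", {
  o <- data.frame(top = c(10, 10, 20, 20, 20, 31),
                  ltc = c(1, 3, 10, 20, 30, 99))
  tab <- conditional_cost_table(o, "top", c(10, 20, 30))
  expect_equal(tab$n, c(2L, 3L, 0L))
  expect_equal(tab$mean, c(2, 20, NA))
  expect_true(is.na(tab$homogeneity[3]))
  # strata are disjoint and cover exactly the runs at the listed levels
  expect_equal(sum(tab$n), sum(o$top %in% c(10, 20, 30)))
  expect_error(conditional_cost_table(o, "nhi", 1), "not a column")
})

test_that("crossing detection finds the first sign change only", {
  grid <- as.character(1:6)
  a <- c(5, 3, 1, -1, -2, -3); names(a) <- grid
  b <- rep(0, 6); names(b) <- grid
  cx <- crossing_year(a, b)
  expect_equal(as.numeric(cx), 4)
  expect_equal(attr(cx, "interval"), c(3, 4))
  # identical curves never cross
  expect_null(crossing_year(a, a))
  # curves that stay on one side never cross
  expect_null(crossing_year(a + 10, b))
  # missing strata are skipped, not treated as crossings
  a2 <- a; a2[3] <- NA
  cx2 <- crossing_year(a2, b)
  expect_equal(as.numeric(cx2), 4)
  expect_equal(attr(cx2, "interval"), c(2, 4))
})
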