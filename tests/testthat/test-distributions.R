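test_that("quantile functions match closed forms", {
  # degenerate spec is constant at every quantile
  expect_equal(dist_quantile(dist_fixed(145), c(0, 0.5, 1)), rep(145, 3))
  # lognormal median is exp(meanlog)
  expect_equal(dist_quantile(dist_lognormal(9.57283, 0.07429), 0.5),
               exp(9.57283))
  # triangular apex: the mode sits at cumulative mass (mode-lower)/(upper-lower)
  expect_equal(dist_quantile(dist_triangular(-3, 0, 400), 3 / 403), 0)
  expect_equal(dist_quantile(dist_triangular(-3, 0, 400), c(0, 1)), c(-3, 400))
  # shifted Weibull at quantile p: threshold + scale * (-log(1-p))^(1/shape)
  expect_equal(dist_quantile(dist_weibull3(0.68361, 1.74601, 0.28273), 0.7),
               0.28273 + 1.74601 * (-log(0.3))^(1 / 0.68361))
  # shifted exponential median: shift + log(2)/rate
  expect_equal(dist_quantile(dist_exponential_shifted(1.41988, 2), 0.5),
               2 + log(2) / 1.41988)
  expect_error(dist_quantile(dist_fixed(1), 1.5), "0, 1")
})

test_that("invalid distribution parameters are rejected", {
  expect_error(dist_triangular(5, 0, 400), "lower <= mode")
  expect_error(dist_triangular(0, 0, 0), "lower < upper")
  expect_error(dist_weibull3(-1, 1), "shape")
  expect_error(dist_weibull3(1, 0), "scale")
  expect_error(dist_lognormal(0, 0), "sdlog")
  expect_error(dist_exponential_shifted(0), "rate")
})

test_that("theoretical moments match closed forms", {
  expect_equal(theoretical_moments(dist_fixed(5719.9)),
               c(mean = 5719.9, sd = 0))
  expect_equal(theoretical_moments(dist_exponential_shifted(1.41988, 0)),
               c(mean = 1 / 1.41988, sd = 1 / 1.41988))
  expect_equal(theoretical_moments(dist_triangular(-3, 0, 140))[["mean"]],
               (-3 + 0 + 140) / 3)
  # triangular variance from the closed form (a^2+m^2+b^2-am-ab-mb)/18
  expect_equal(theoretical_moments(dist_triangular(-3, 0, 140))[["sd"]],
               sqrt((9 + 0 + 19600 - 0 + 420 - 0) / 18))
  mom <- theoretical_moments(dist_lognormal(2, 0.5))
  expect_equal(mom[["mean"]], exp(2 + 0.125))
  expect_equal(mom[["sd"]], exp(2 + 0.125) * sqrt(exp(0.25) - 1))
  mom <- theoretical_moments(dist_weibull3(2, 3, 1))
  expect_equal(mom[["mean"]], 1 + 3 * gamma(1.5))
  expect_equal(mom[["sd"]], 3 * sqrt(gamma(2) - gamma(1.5)^2))
})

test_that("empirical moments of every model input agree with closed forms", {
  p <- model_parameters()
  n <- 100000
  specs <- list(afi = p$afi, isb = p$isb, lts = p$lts, ttr = p$ttr,
                rev = p$rev, ttub = p$ttub, thit = p$thit, dsh = p$dsh,
                his = p$his)
  set.seed(20851)
  for (nm in names(specs)) {
    mom <- theoretical_moments(specs[[nm]])
    x <- sample_value(specs[[nm]], n)
    se_mean <- mom[["sd"]] / sqrt(n)
    expect_lt(abs(mean(x) - mom[["mean"]]), 4 * se_mean, label = nm)
    kurt <- mean((x - mean(x))^4) / var(x)^2
    se_sd <- mom[["sd"]] * sqrt((kurt - 1) / (4 * n))
    expect_lt(abs(sd(x) - mom[["sd"]]), 4 * se_sd, label = nm)
  }
})

test_that("triangular sampler matches the analytic CDF (KS distance)", {
  set.seed(1251)
  x <- sample_value(dist_triangular(-3, 0, 400), 10000)
  xs <- sort(x)
  fa <- meicost:::ptriangular(xs, -3, 0, 400)
  fe_hi <- seq_along(xs) / length(xs)
  fe_lo <- (seq_along(xs) - 1) / length(xs)
  ks <- max(pmax(abs(fe_hi - fa), abs(fe_lo - fa)))
  expect_lt(ks, 0.02)
})

test_that("sample_value is deterministic given uniforms", {
  spec <- dist_lognormal(8, 0.3)
  u <- c(0.1, 0.5, 0.9)
  expect_identical(sample_value(spec, u = u), sample_value(spec, u = u))
  expect_identical(sample_value(spec, u = u), qlnorm(u, 8, 0.3))
})
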