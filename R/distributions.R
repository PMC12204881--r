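#' Input distribution specifications
#'
#' The model's stochastic inputs (ages, device lifetimes, inter-event times,
#' inpatient costs) each follow one of five parametric families identified
#' from hospital treatment data: a degenerate (fixed) value, a
#' three-parameter (shifted) Weibull, a lognormal, a triangular, or a
#' shifted exponential. A `dist_spec` bundles the family name with its
#' parameters and is the unit the sampler, the quantile function and the
#' closed-form moments operate on.
#'
#' Parameterisations:
#' * `weibull3`: `threshold + scale * W` with `W ~ Weibull(shape)` (scale 1).
#' * `lognormal`: `meanlog`/`sdlog` on the log scale (location/scale).
#' * `triangular`: `lower <= mode <= upper`, `lower < upper`; note the model
#'   deliberately uses triangular event-time distributions with a negative
#'   lower bound (-3) and corrects negative draws downstream, so draws from
#'   a `dist_spec` are *not* truncated here.
#' * `exponential_shifted`: `shift + E` with `E ~ Exp(rate)`.
#'
#' @param value Fixed value.
#' @param shape,scale,threshold Shifted-Weibull parameters (`shape`, `scale`
#'   positive).
#' @param meanlog,sdlog Lognormal location and scale (`sdlog` positive).
#' @param lower,mode,upper Triangular bounds and mode.
#' @param rate,shift Shifted-exponential rate (positive) and shift.
#' @return An object of class `dist_spec`: a list with elements `family` and
#'   the family's parameters.
#' @examples
#' dist_quantile(dist_lognormal(9.57283, 0.07429), 0.5)  # lognormal median
#' theoretical_moments(dist_triangular(-3, 0, 140))
#' @name dist_spec
NULL

new_dist_spec <- function(family, params) {
  structure(c(list(family = family), params), class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_fixed <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  new_dist_spec("fixed", list(value = value))
}

#' @rdname dist_spec
#' @export
dist_weibull3 <- function(shape, scale, threshold = 0) {
  if (!is.numeric(shape) || shape <= 0) stop("weibull3: 'shape' must be > 0")
  if (!is.numeric(scale) || scale <= 0) stop("weibull3: 'scale' must be > 0")
  new_dist_spec("weibull3",
                list(shape = shape, scale = scale, threshold = threshold))
}

#' @rdname dist_spec
#' @export
dist_lognormal <- function(meanlog, sdlog) {
  if (!is.numeric(sdlog) || sdlog <= 0) stop("lognormal: 'sdlog' must be > 0")
  new_dist_spec("lognormal", list(meanlog = meanlog, sdlog = sdlog))
}

#' @rdname dist_spec
#' @export
dist_triangular <- function(lower, mode, upper) {
  if (!(lower <= mode && mode <= upper)) {
    stop("triangular: need lower <= mode <= upper")
  }
  if (!(lower < upper)) stop("triangular: need lower < upper")
  new_dist_spec("triangular", list(lower = lower, mode = mode, upper = upper))
}

#' @rdname dist_spec
#' @export
dist_exponential_shifted <- function(rate, shift = 0) {
  if (!is.numeric(rate) || rate <= 0) stop("exponential_shifted: 'rate' must be > 0")
  new_dist_spec("exponential_shifted", list(rate = rate, shift = shift))
}

dist_families <- c("fixed", "weibull3", "lognormal", "triangular",
                   "exponential_shifted")

#' @export
print.dist_spec <- function(x, ...) {
  pars <- unlist(x[setdiff(names(x), "family")])
  cat("<dist_spec> ", x$family, "(",
      paste(names(pars), "=", format(pars), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Quantile function of an input distribution
#'
#' Inverse CDF of a [dist_spec]. All sampling in the package is
#' inverse-transform, so this function *is* the sampler once fed uniform
#' variates; it is exposed for closed-form checks and plotting.
#'
#' @param spec A [dist_spec].
#' @param p Vector of probabilities in \[0, 1\].
#' @return Numeric vector of quantiles, same length as `p`.
#' @export
dist_quantile <- function(spec, p) {
  stopifnot(inherits(spec, "dist_spec"))
  if (any(p < 0 | p > 1)) stop("probabilities must be in [0, 1]")
  switch(spec$family,
    fixed = rep(spec$value, length(p)),
    weibull3 = spec$threshold + spec$scale * stats::qweibull(p, spec$shape),
    lognormal = stats::qlnorm(p, spec$meanlog, spec$sdlog),
    triangular = qtriangular(p, spec$lower, spec$mode, spec$upper),
    exponential_shifted = spec$shift + stats::qexp(p, spec$rate),
    stop("unknown distribution family: ", spec$family)
  )
}

# Triangular inverse CDF. At p equal to the mode's cumulative mass both
# branches return the mode.
qtriangular <- function(p, lower, mode, upper) {
  fm <- (mode - lower) / (upper - lower)
  left <- lower + sqrt(p * (upper - lower) * (mode - lower))
  right <- upper - sqrt((1 - p) * (upper - lower) * (upper - mode))
  ifelse(p <= fm, left, right)
}

# Triangular CDF (validation oracle for capability rates and KS checks).
ptriangular <- function(q, lower, mode, upper) {
  out <- numeric(length(q))
  below <- q <= mode
  out[below] <- (pmax(q[below], lower) - lower)^2 /
    ((upper - lower) * (mode - lower))
  out[!below] <- 1 - (upper - pmin(q[!below], upper))^2 /
    ((upper - lower) * (upper - mode))
  out
}

#' Draw random variates from an input distribution
#'
#' Inverse-transform sampling from a [dist_spec]. If `u` is supplied the
#' draws are the quantiles at those uniforms (deterministic); otherwise `n`
#' uniforms are taken from R's current random stream. A `fixed` spec
#' consumes no randomness.
#'
#' @param spec A [dist_spec].
#' @param n Number of draws.
#' @param u Optional uniform variates (overrides `n`).
#' @return Numeric vector of draws.
#' @examples
#' set.seed(1)
#' mean(sample_value(dist_triangular(-3, 0, 400), 1e4))  # ~ (a+m+b)/3
#' @export
sample_value <- function(spec, n = 1, u = NULL) {
  stopifnot(inherits(spec, "dist_spec"))
  if (is.null(u)) {
    if (spec$family == "fixed") return(rep(spec$value, n))
    u <- stats::runif(n)
  }
  dist_quantile(spec, u)
}

#' Closed-form mean and standard deviation of an input distribution
#'
#' Analytic first two moments for each family; used as the oracle that the
#' empirical sampler is validated against.
#'
#' @param spec A [dist_spec].
#' @return Named numeric vector `c(mean, sd)`.
#' @examples
#' theoretical_moments(dist_exponential_shifted(1.41988))
#' @export
theoretical_moments <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  mom <- switch(spec$family,
    fixed = c(spec$value, 0),
    weibull3 = {
      g1 <- gamma(1 + 1 / spec$shape)
      g2 <- gamma(1 + 2 / spec$shape)
      c(spec$threshold + spec$scale * g1, spec$scale * sqrt(g2 - g1^2))
    },
    lognormal = {
      m <- exp(spec$meanlog + spec$sdlog^2 / 2)
      c(m, m * sqrt(exp(spec$sdlog^2) - 1))
    },
    triangular = {
      a <- spec$lower; m <- spec$mode; b <- spec$upper
      c((a + m + b) / 3,
        sqrt((a^2 + m^2 + b^2 - a * m - a * b - m * b) / 18))
    },
    exponential_shifted = c(spec$shift + 1 / spec$rate, 1 / spec$rate),
    stop("unknown distribution family: ", spec$family)
  )
  names(mom) <- c("mean", "sd")
  mom
}
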