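#' Model parameters
#'
#' The complete input set of the lifetime-cost model: fixed scalars (life
#' expectancy, minimum implantation age, discount rate, flat-rate outpatient
#' appointment cost, audio processor price, minimum upgrade interval),
#' fitted input distributions ([dist_spec] objects) and the structural caps
#' on event counts. Defaults are the published input set the model was
#' fitted and validated with; any field can be overridden.
#'
#' Fixed scalars (defaults): life expectancy `lex` = 81 years, minimum
#' implantation age `mia` = 5 years, annual discount rate `dir` = 0.05,
#' outpatient flat rate `foa` = 145 EUR, audio processor `apu` = 5719.9 EUR,
#' minimum time to processor upgrade `ttua` = 6 years.
#'
#' Distributions (defaults):
#' * `afi` age at first intervention: shifted Weibull(244.32323, 2866.73542,
#'   -2806.08613); three independent draws per run feed the bound-correction
#'   cascade of [compute_top()].
#' * `isb` implantation cost: lognormal(9.57283, 0.07429) EUR.
#' * `lts` implant lifetime: triangular(-3, 0, 400) years.
#' * `ttr` time to revision: triangular(-3, 0, 140) years.
#' * `rev` revision cost: lognormal(8.29047, 0.20121) EUR.
#' * `ttub` extra time to processor upgrade beyond the 6-year minimum:
#'   shifted exponential(rate 1.41988, shift 0) years.
#' * `thit` total time under hearing-improvement surgery before an implant:
#'   lognormal(0.70939, 1.3453) years.
#' * `dsh` duration of success of one hearing-improvement surgery: shifted
#'   Weibull(0.68361, 1.74601, 0.28273) years.
#' * `his` hearing-improvement surgery cost: lognormal(8.2339, 0.25662) EUR.
#'
#' Caps: at most 2 re-implantations, 3 revisions and 12 processor upgrades
#' per run; at most 6 hearing-improvement surgeries (including the initial
#' one) before an implant and 15 in the surgeries-only pathway; the
#' pre-implant phase is capped at 25 years.
#'
#' @param lex,mia,dir,foa,apu,ttua Fixed scalars (see above).
#' @param afi,isb,lts,ttr,rev,ttub,thit,dsh,his [dist_spec] inputs.
#' @param caps Named list of positive integer caps (see above).
#' @param independent_event_costs Reserved switch for drawing a fresh
#'   implant/revision cost per event instead of reusing one draw per run;
#'   only `FALSE` is implemented.
#' @return An object of class `model_parameters`.
#' @examples
#' p <- model_parameters(dir = 0)      # undiscounted variant
#' p$caps$max_nhi_g3
#' @export
model_parameters <- function(
  lex = 81, mia = 5, dir = 0.05, foa = 145, apu = 5719.9, ttua = 6,
  afi = dist_weibull3(244.32323, 2866.73542, -2806.08613),
  isb = dist_lognormal(9.57283, 0.07429),
  lts = dist_triangular(-3, 0, 400),
  ttr = dist_triangular(-3, 0, 140),
  rev = dist_lognormal(8.29047, 0.20121),
  ttub = dist_exponential_shifted(1.41988, 0),
  thit = dist_lognormal(0.70939, 1.3453),
  dsh = dist_weibull3(0.68361, 1.74601, 0.28273),
  his = dist_lognormal(8.2339, 0.25662),
  caps = list(max_reimplantations = 2, max_revisions = 3, max_upgrades = 12,
              max_nhi_g2 = 6, max_nhi_g3 = 15, thi_cap = 25),
  independent_event_costs = FALSE
) {
  p <- structure(list(
    lex = lex, mia = mia, dir = dir, foa = foa, apu = apu, ttua = ttua,
    afi = afi, isb = isb, lts = lts, ttr = ttr, rev = rev, ttub = ttub,
    thit = thit, dsh = dsh, his = his, caps = caps,
    independent_event_costs = isTRUE(independent_event_costs)
  ), class = "model_parameters")
  validate_parameters(p)
  p
}

#' Validate a model-parameter set
#'
#' Checks the structural invariants: `lex > mia`, non-negative rate and
#' costs, positive integer caps, and per-family distribution invariants
#' (delegated to the [dist_spec] constructors on load).
#'
#' @param params A `model_parameters` object.
#' @return `params`, invisibly; stops with a message on the first violation.
#' @export
validate_parameters <- function(params) {
  if (!inherits(params, "model_parameters")) stop("not a model_parameters object")
  with(params, {
    if (!(lex > mia)) stop("invalid parameters: need lex > mia")
    if (dir < 0) stop("invalid parameters: discount rate must be >= 0")
    if (foa < 0 || apu < 0) stop("invalid parameters: costs must be >= 0")
    if (ttua < 0) stop("invalid parameters: ttua must be >= 0")
  })
  needed <- c("max_reimplantations", "max_revisions", "max_upgrades",
              "max_nhi_g2", "max_nhi_g3", "thi_cap")
  if (!all(needed %in% names(params$caps))) {
    stop("invalid parameters: caps must contain ",
         paste(setdiff(needed, names(params$caps)), collapse = ", "))
  }
  for (nm in needed) {
    v <- params$caps[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v != round(v)) {
      stop("invalid parameters: cap '", nm, "' must be a positive integer")
    }
  }
  for (nm in c("afi", "isb", "lts", "ttr", "rev", "ttub", "thit", "dsh", "his")) {
    if (!inherits(params[[nm]], "dist_spec")) {
      stop("invalid parameters: '", nm, "' must be a dist_spec")
    }
  }
  if (params$independent_event_costs) {
    stop("independent_event_costs is a reserved switch; only FALSE is implemented")
  }
  invisible(params)
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("<model_parameters>\n")
  cat(sprintf("  lex %g y | mia %g y | dir %g | foa %g EUR | apu %g EUR | ttua %g y\n",
              x$lex, x$mia, x$dir, x$foa, x$apu, x$ttua))
  for (nm in c("afi", "isb", "lts", "ttr", "rev", "ttub", "thit", "dsh", "his")) {
    cat("  ", nm, ": ", sep = ""); print(x[[nm]])
  }
  cat("  caps:", paste(names(x$caps), unlist(x$caps), sep = "=", collapse = " "), "\n")
  invisible(x)
}

spec_from_entry <- function(name, e) {
  fam <- e$family
  if (is.null(fam) || !fam %in% dist_families) {
    stop("parameter file: entry '", name, "' has unknown family '", fam, "'")
  }
  get_num <- function(k) {
    v <- e[[k]]
    if (is.null(v) || !is.numeric(v)) {
      stop("parameter file: entry '", name, "' is missing numeric field '", k, "'")
    }
    v
  }
  switch(fam,
    fixed = dist_fixed(get_num("value")),
    weibull3 = dist_weibull3(get_num("shape"), get_num("scale"), get_num("threshold")),
    lognormal = dist_lognormal(get_num("meanlog"), get_num("sdlog")),
    triangular = dist_triangular(get_num("lower"), get_num("mode"), get_num("upper")),
    exponential_shifted = dist_exponential_shifted(get_num("rate"), get_num("shift"))
  )
}

#' Read a model-parameter file
#'
#' Loads a JSON parameter file (one entry per model input, each a
#' distribution family plus its parameters, and a `caps` block) into a
#' validated [model_parameters] object. The packaged default file is
#' `system.file("extdata", "default_parameters.json", package = "meicost")`.
#'
#' @param path Path to a JSON parameter file; defaults to the packaged file.
#' @return A `model_parameters` object.
#' @export
read_parameters <- function(path = default_parameter_file()) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("LEX", "MIA", "DIR", "FOA", "APU", "TTUa", "AFI", "ISB", "LTS",
            "TTR", "REV", "TTUb", "THIt", "DSH", "HIS", "caps")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("parameter file: missing entries ", paste(missing, collapse = ", "))
  }
  fixed_value <- function(nm) {
    e <- raw[[nm]]
    if (!identical(e$family, "fixed")) stop("parameter file: '", nm, "' must be fixed")
    e$value
  }
  model_parameters(
    lex = fixed_value("LEX"), mia = fixed_value("MIA"), dir = fixed_value("DIR"),
    foa = fixed_value("FOA"), apu = fixed_value("APU"), ttua = fixed_value("TTUa"),
    afi = spec_from_entry("AFI", raw$AFI), isb = spec_from_entry("ISB", raw$ISB),
    lts = spec_from_entry("LTS", raw$LTS), ttr = spec_from_entry("TTR", raw$TTR),
    rev = spec_from_entry("REV", raw$REV), ttub = spec_from_entry("TTUb", raw$TTUb),
    thit = spec_from_entry("THIt", raw$THIt), dsh = spec_from_entry("DSH", raw$DSH),
    his = spec_from_entry("HIS", raw$HIS),
    caps = as.list(raw$caps)
  )
}

#' @rdname read_parameters
#' @export
default_parameter_file <- function() {
  system.file("extdata", "default_parameters.json", package = "meicost",
              mustWork = TRUE)
}

# Stable fingerprint of a parameter set, logged with every output so any
# reported number can be traced to its exact inputs.
parameter_hash <- function(params) {
  flat <- unlist(params[order(names(params))])
  txt <- paste(names(flat), vapply(flat, format, "", digits = 15),
               sep = "=", collapse = ";")
  # FNV-1a, 32-bit, in doubles (split multiply keeps exact 32-bit arithmetic);
  # avoids a digest dependency for a log fingerprint
  h <- 2166136261
  for (b in utf8ToInt(txt)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483648) + 0L)
}
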