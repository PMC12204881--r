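# Per-run random inputs.
#
# One simulation run consumes one draw per stochastic symbol: three
# independent age draws for the bound-correction cascade, one implantation
# cost and one revision cost (reused across all re-implantations/revisions
# of that run), three implant lifetimes, four times-to-revision, the extra
# upgrade time, the total pre-implant time, and fifteen surgery
# durations/costs each. 44 uniforms per run, in a fixed documented order.

run_draw_columns <- function() {
  c("AFIa", "AFIb", "AFIc", "ISB", "REV",
    paste0("LTS", 1:3), paste0("TTR", 1:4), "TTUb", "THIt",
    paste0("DSH", 1:15), paste0("HIS", 1:15))
}

# Which dist_spec feeds each draw column.
run_draw_specs <- function(params) {
  cols <- run_draw_columns()
  specs <- vector("list", length(cols))
  names(specs) <- cols
  for (nm in cols) {
    specs[[nm]] <- switch(sub("[0-9abc]+$", "", nm),
      AFI = params$afi, ISB = params$isb, REV = params$rev,
      LTS = params$lts, TTR = params$ttr, TTU = params$ttub,
      THIt = params$thit, DSH = params$dsh, HIS = params$his)
  }
  specs
}

# n x k matrix of uniforms where row i comes from the i-th L'Ecuyer-CMRG
# substream of the root seed, so run i's inputs depend only on (seed, i) and
# never on n or on evaluation order. The caller's RNG state is untouched.
substream_uniforms <- function(seed, n, k) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  suppressWarnings(RNGkind("L'Ecuyer-CMRG"))
  set.seed(as.integer(seed))
  s <- get(".Random.seed", globalenv())
  u <- matrix(NA_real_, n, k)
  for (i in seq_len(n)) {
    s <- parallel::nextRNGStream(s)
    assign(".Random.seed", s, envir = globalenv())
    u[i, ] <- stats::runif(k)
  }
  u
}

#' Draw per-run random model inputs
#'
#' Draws the raw stochastic inputs for `n` independent simulation runs: the
#' three age-at-first-intervention candidates `AFIa`/`AFIb`/`AFIc` (i.i.d.
#' from the single age distribution), the implantation cost `ISB` and
#' revision cost `REV` (one draw each per run, reused for every
#' re-implantation/revision of that run), implant lifetimes `LTS1..LTS3`,
#' times to revision `TTR1..TTR4`, the extra processor-upgrade time `TTUb`,
#' the total pre-implant time `THIt`, and the surgery durations `DSH1..15`
#' and costs `HIS1..15`.
#'
#' Triangular event times are *not* truncated here: negative draws (the
#' fitted lower bound is -3 years) are floored at zero downstream by the
#' trajectory equations, exactly as the model defines them.
#'
#' Run `i` is generated from the `i`-th L'Ecuyer-CMRG substream of `seed`,
#' so its draws are reproducible independently of `n`. The caller's RNG
#' state is left untouched.
#'
#' @param params A [model_parameters] object.
#' @param n Number of runs (rows).
#' @param seed Integer root seed.
#' @return A data.frame with `n` rows, one column per draw symbol plus a
#'   leading `run` index.
#' @examples
#' d <- draw_runs(model_parameters(), 5, seed = 1)
#' names(d)
#' @export
draw_runs <- function(params, n, seed) {
  validate_parameters(params)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("'n' must be a positive integer")
  }
  specs <- run_draw_specs(params)
  u <- substream_uniforms(seed, n, length(specs))
  out <- data.frame(run = seq_len(n))
  for (j in seq_along(specs)) {
    out[[names(specs)[j]]] <- dist_quantile(specs[[j]], u[, j])
  }
  out
}

#' @rdname draw_runs
#' @export
draw_run <- function(params, seed) {
  draw_runs(params, 1L, seed)
}
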