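p <- model_parameters()

test_that("packaged parameter file reproduces the in-code defaults", {
  expect_equal(read_parameters(), p)
})

test_that("parameter files are schema-validated on load", {
  raw <- jsonlite::read_json(default_parameter_file(), simplifyVector = TRUE)
  bad <- raw
  bad$LTS$lower <- 500  # triangular lower above upper
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(bad, f, auto_unbox = TRUE)
  expect_error(read_parameters(f), "lower")
  bad2 <- raw
  bad2$ISB <- NULL
  jsonlite::write_json(bad2, f, auto_unbox = TRUE)
  expect_error(read_parameters(f), "missing entries")
  bad3 <- raw
  bad3$REV$family <- "gamma"
  jsonlite::write_json(bad3, f, auto_unbox = TRUE)
  expect_error(read_parameters(f), "unknown family")
})

test_that("parameter invariants are enforced", {
  expect_error(model_parameters(lex = 5, mia = 5), "lex > mia")
  expect_error(model_parameters(dir = -0.1), "discount")
  expect_error(model_parameters(foa = -1), "costs")
  expect_error(model_parameters(caps = list(max_reimplantations = 2)),
               "caps")
  expect_error(model_parameters(independent_event_costs = TRUE), "reserved")
  # fingerprint changes with any parameter
  expect_false(meicost:::parameter_hash(p) ==
                 meicost:::parameter_hash(model_parameters(foa = 146)))
})

test_that("run_simulation writes reproducible per-run and summary files", {
  out1 <- file.path(tempdir(), "runA")
  out2 <- file.path(tempdir(), "runB")
  r1 <- run_simulation("g1", n = 50, seed = 9, outdir = out1)
  r2 <- run_simulation("g1", n = 50, seed = 9, outdir = out2)
  expect_true(file.exists(r1$runs_csv))
  expect_true(file.exists(r1$summary_json))
  expect_identical(readLines(r1$runs_csv), readLines(r2$runs_csv))
  expect_identical(readLines(r1$summary_json), readLines(r2$summary_json))
  runs <- read.csv(r1$runs_csv)
  expect_equal(nrow(runs), 50)
  expect_true(all(c("group", "run", "ltc", "seed") %in% names(runs)))
  expect_error(run_simulation("g1", n = 0, outdir = out1), "positive integer")
  # strategy selector writes arm shares
  rs <- run_simulation("strategy", n = 50, seed = 9, outdir = out1)
  expect_equal(sum(unlist(rs$summary$arm_shares)), 1, tolerance = 1e-12)
})

test_that("analysis outputs cover duration strata, surgery counts and ranks", {
  out <- file.path(tempdir(), "an")
  g1 <- run_cohort(p, "g1", 800, seed = 61)
  g2 <- run_cohort(p, "g2", 800, seed = 62)
  g3 <- run_cohort(p, "g3", 800, seed = 63)
  res <- analyze_cohorts(g1, g2, g3, outdir = out)
  expect_true(all(file.exists(file.path(out,
    c("analysis_by_duration.csv", "analysis_by_nhi.csv",
      "analysis_rank.csv", "capability_rates.json")))))
  expect_equal(nrow(res$by_nhi), 6)  # direct-implant baseline + nhi 1..5
  expect_equal(res$rank$group[1], "g1")  # direct implant ranks cheapest
  expect_true(all(diff(res$rank$cost_per_successful_year) >= 0))
})

test_that("model self-validation passes on the default inputs", {
  v <- validate_model(p, n_moment = 20000, n_runs = 60, seed = 77)
  expect_true(attr(v, "ok"))
  expect_true(all(v$pass))
  expect_gte(nrow(v), 14)
})

test_that("p-values are reported with the <0.001 floor", {
  expect_equal(format_p(c(0.5, 0.0321, 0.0004)),
               c("0.5", "0.0321", "<0.001"))
})
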