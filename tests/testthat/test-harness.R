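test_that("a single-point cumulative curve reproduces the full-data fit", {
  tr <- make_hybrid_cohort(15, w = runif(15), n_trials = 100, seed = 3)
  cv <- trial_number_curve(tr, step = 100L, max_trials = 100L,
                           mode = "cumulative", estimator = "pointwise")
  expect_equal(nrow(cv), 1L)
  full <- extract_mbi(fit_pointwise_all(build_stay_design(tr)))
  expect_equal(cv$mean_mbi, mean(full), tolerance = 1e-12)
  sh <- split_half_oddeven(tr)
  expect_equal(cv$split_half_r, sh$r, tolerance = 1e-12)
})

test_that("the cumulative endpoint equals the full-data fit", {
  set.seed(7)
  tr <- make_hybrid_cohort(15, w = runif(15), n_trials = 100, seed = 7)
  cv <- trial_number_curve(tr, step = 25L, max_trials = 100L,
                           mode = "cumulative", estimator = "pointwise")
  expect_equal(cv$grid, c(25, 50, 75, 100))
  full <- extract_mbi(fit_pointwise_all(build_stay_design(tr)))
  expect_equal(cv$mean_mbi[4], mean(full), tolerance = 1e-12)
})

test_that("binned mean MBI is flat for stationary agents", {
  # stationary agents have no order effects, so bin means share one
  # expectation; tested jointly (repeated-measures ANOVA on per-subject,
  # per-bin pointwise MBIs) rather than as 12 simultaneous 2-SE checks
  set.seed(11)
  tr <- make_hybrid_cohort(60, w = runif(60), n_trials = 200, seed = 11)
  per_bin <- list()
  for (g in seq(50, 200, by = 50)) {
    dt <- data.table::as.data.table(tr)
    data.table::setorder(dt, subject, session, block, trial)
    dt[, idx := seq_len(.N), by = subject]
    sub <- data.table::setDF(dt[idx > g - 50 & idx <= g])
    m <- extract_mbi(fit_pointwise_all(build_stay_design(sub)))
    per_bin[[length(per_bin) + 1]] <-
      data.frame(subject = names(m), mbi = m, bin = g)
  }
  d <- do.call(rbind, per_bin)
  fit <- stats::aov(mbi ~ factor(bin) + Error(factor(subject)), data = d)
  p <- summary(fit)[["Error: Within"]][[1]]["factor(bin)", "Pr(>F)"]
  expect_gt(p, 0.01)
})

test_that("dropped short subjects are counted", {
  tr <- make_hybrid_cohort(10, w = 0.5, n_trials = 100, seed = 13)
  short <- make_hybrid_cohort(2, w = 0.5, n_trials = 50, seed = 14,
                              prefix = "short")
  cv <- trial_number_curve(rbind(tr, short), step = 50L, max_trials = 100L,
                           estimator = "pointwise")
  expect_equal(attr(cv, "n_dropped"), 2L)
})

test_that("compare_design reports a generative contrast and a null", {
  ta <- make_hybrid_cohort(25, w = 0.8, n_trials = 150, seed = 21, prefix = "a")
  tb <- make_hybrid_cohort(25, w = 0.2, n_trials = 150, seed = 22, prefix = "b")
  cmp <- compare_design("transition_ratio", ta, tb, estimator = "pointwise",
                        comparison_fit = FALSE)
  expect_gt(cmp$mean_a, cmp$mean_b)
  expect_lt(cmp$p, 0.01)
  expect_false(cmp$paired)

  t0a <- make_hybrid_cohort(20, w = 0.5, n_trials = 120, seed = 23, prefix = "x")
  t0b <- make_hybrid_cohort(20, w = 0.5, n_trials = 120, seed = 24, prefix = "y")
  null_cmp <- compare_design("drift_set", t0a, t0b, estimator = "pointwise",
                             comparison_fit = TRUE)
  three <- null_cmp$fit$fixed[
    null_cmp$fit$fixed$term == "prev_reward:prev_transition:group", ]
  expect_lt(abs(three$z), 3)
  expect_s3_class(null_cmp$fit, "hier_fit")
})

test_that("paired arms are detected and disambiguated in the pooled fit", {
  ta <- make_hybrid_cohort(12, w = 0.6, n_trials = 100, seed = 31)
  tb <- make_hybrid_cohort(12, w = 0.6, n_trials = 100, seed = 32)
  cmp <- compare_design("difficulty_order", ta, tb, estimator = "pointwise",
                        comparison_fit = FALSE)
  expect_true(cmp$paired)
})

test_that("run_scenario writes a deterministic artifact set", {
  scen <- list(
    name = "tiny",
    population = list(n_subjects = 15, w_dist = "uniform"),
    estimation = list(estimator = "pointwise"),
    experiments = list(reliability = TRUE, recovery = TRUE)
  )
  d1 <- file.path(tempdir(), "scen1"); d2 <- file.path(tempdir(), "scen2")
  rep1 <- run_scenario(scen, d1, seed = 5)
  rep2 <- run_scenario(scen, d2, seed = 5)
  for (f in c("trials.csv", "covariates.csv", "coefficients.csv",
              "exclusions.json", "reliability.json", "report.json")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_equal(rep1$mean_mbi, rep2$mean_mbi)
  expect_true(is.numeric(rep1$recovery_r))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("the bundled null-cohort scenario brackets zero MBI", {
  path <- system.file("scenarios", "null_cohort.json", package = "twostepr")
  expect_true(nzchar(path))
  out <- file.path(tempdir(), "nullscen")
  rep <- run_scenario(path, out, seed = 9)
  expect_lte(rep$mean_mbi_ci$low, 0)
  expect_gte(rep$mean_mbi_ci$high, 0)
  unlink(out, recursive = TRUE)
})

test_that("the CLI round-trips simulate -> exclude -> fit -> reliability", {
  out <- file.path(tempdir(), "cli")
  run_cli(c("simulate", "--n-subjects", "12", "--seed", "3", "--out", out))
  expect_true(file.exists(file.path(out, "trials.csv")))
  run_cli(c("exclude", "--input", file.path(out, "trials.csv"), "--out", out))
  expect_true(file.exists(file.path(out, "exclusions.json")))
  run_cli(c("fit", "--input", file.path(out, "trials.csv"),
            "--estimator", "pointwise", "--out", out))
  co <- read.csv(file.path(out, "coefficients.csv"))
  expect_equal(nrow(co), 12L)
  run_cli(c("reliability", "--input", file.path(out, "trials.csv"),
            "--estimator", "pointwise", "--out", out))
  rel <- jsonlite::read_json(file.path(out, "reliability.json"))
  expect_identical(rel$method, "split_half")
  expect_error(run_cli(c("fit", "--out", out)), "--input")
  expect_error(run_cli(c("bogus")), "unknown subcommand")
  unlink(out, recursive = TRUE)
})
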