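toy_trials <- function(choices, transitions, rewards, missed = NULL,
                       block = NULL, subject = "s1") {
  n <- length(choices)
  if (is.null(missed)) missed <- rep(FALSE, n)
  if (is.null(block)) block <- rep(1L, n)
  data.frame(
    subject = subject, session = 1L, block = block, trial = 0:(n - 1L),
    choice = choices, transition = transitions,
    outcome_colour = ifelse(missed, NA, "purple"),
    reward = rewards, hit = ifelse(missed, NA_integer_, 0L),
    difficulty = "easy", missed = missed, stringsAsFactors = FALSE
  )
}

test_that("the lagged design follows the stay/switch coding exactly", {
  tr <- toy_trials(c("left", "left", "right"),
                   c("common", "rare", "common"),
                   c(1L, 0L, 1L))
  rows <- build_stay_design(tr)
  expect_equal(nrow(rows), 2L)
  expect_equal(rows$stay, c(1L, 0L))
  expect_equal(rows$prev_reward, c(1L, -1L))
  expect_equal(rows$prev_transition, c(1L, -1L))
  expect_equal(rows$trial, c(1L, 2L))
})

test_that("single-trial sessions yield no rows and blocks are never spanned", {
  expect_equal(nrow(build_stay_design(toy_trials("left", "common", 1L))), 0L)
  tr <- simulate_session(hybrid_agent(), task_config(), seed = 2)
  rows <- build_stay_design(tr)
  expect_equal(nrow(rows), 198L)            # n_trials - n_blocks
  expect_false(any(rows$trial %in% c(0L, 100L)))  # first trial of each block
})

test_that("a missed trial breaks the lag chain on both sides", {
  tr <- toy_trials(c("left", NA, "left", "left"),
                   c("common", NA, "common", "rare"),
                   c(1L, NA, 1L, 0L),
                   missed = c(FALSE, TRUE, FALSE, FALSE))
  rows <- build_stay_design(tr)
  expect_equal(nrow(rows), 1L)   # only the (t3, t4) pair survives
  expect_equal(rows$trial, 3L)
})

test_that("unsorted input is rejected", {
  tr <- simulate_session(hybrid_agent(), task_config(), seed = 2)
  expect_error(build_stay_design(tr[rev(seq_len(nrow(tr))), ]), "sorted")
})

test_that("prev_hit is coded +1/-1 and unrewarded trials keep -1", {
  tr <- toy_trials(c("left", "left", "left"),
                   c("common", "common", "common"),
                   c(1L, 0L, 1L))
  tr$hit <- c(1L, 0L, 0L)
  rows <- build_stay_design(tr, include_hit = TRUE)
  expect_equal(rows$prev_hit, c(1L, -1L))
})

test_that("a balanced symmetric design gives exactly zero coefficients", {
  cells <- expand.grid(r = c(-1L, 1L), t = c(-1L, 1L), y = c(0L, 1L))
  rows <- data.frame(subject = "s1", stay = cells$y, prev_reward = cells$r,
                     prev_transition = cells$t, session = 1L, block = 1L,
                     trial = seq_len(nrow(cells)))
  fit <- fit_pointwise(rows, ridge = 1e-3)
  expect_equal(unname(fit$coefficients), rep(0, 4), tolerance = 1e-10)
})

test_that("pointwise fits match the brute-force ML oracle to 1e-4", {
  set.seed(31)
  for (i in 1:12) {
    rows <- random_stay_rows(sample(30:100, 1))
    ours <- fit_pointwise(rows, ridge = 0)
    oracle <- oracle_logit(rows, ridge = 0)
    expect_equal(unname(ours$coefficients), oracle, tolerance = 1e-4)
  }
})

test_that("perfect separation is flagged and kept finite under ridge", {
  rows <- data.frame(subject = "s1", stay = rep(1L, 20),
                     prev_reward = rep(c(-1L, 1L), 10),
                     prev_transition = rep(c(-1L, -1L, 1L, 1L), 5),
                     session = 1L, block = 1L, trial = 1:20)
  fit <- fit_pointwise(rows, ridge = 1e-3)
  expect_true(all(is.finite(fit$coefficients)))
  expect_true(fit$separation_flag)
  expect_error(fit_pointwise(rows[0, ]))
})

test_that("coding symmetry: sign-flipping both regressors preserves the MBI", {
  set.seed(77)
  rows <- random_stay_rows(80)
  flipped <- rows
  flipped$prev_reward <- -rows$prev_reward
  flipped$prev_transition <- -rows$prev_transition
  f1 <- fit_pointwise(rows, ridge = 1e-3)$coefficients
  f2 <- fit_pointwise(flipped, ridge = 1e-3)$coefficients
  expect_equal(f2[["mbi"]], f1[["mbi"]], tolerance = 1e-6)
  expect_equal(f2[["stay_tendency"]], f1[["stay_tendency"]], tolerance = 1e-6)
  expect_equal(f2[["mfi"]], -f1[["mfi"]], tolerance = 1e-6)
  expect_equal(f2[["transition"]], -f1[["transition"]], tolerance = 1e-6)
})

# generate rows straight from a mixed logistic model with known parameters
simulate_mixed_rows <- function(n_subj, n_rows, fixed, re_sd) {
  out <- vector("list", n_subj)
  for (i in seq_len(n_subj)) {
    b <- fixed + stats::rnorm(4, 0, re_sd)
    r <- sample(c(-1L, 1L), n_rows, replace = TRUE)
    t <- sample(c(-1L, 1L), n_rows, replace = TRUE)
    eta <- b[1] + b[2] * r + b[3] * t + b[4] * r * t
    out[[i]] <- data.frame(
      subject = sprintf("s%03d", i), stay = stats::rbinom(n_rows, 1, plogis(eta)),
      prev_reward = r, prev_transition = t, session = 1L, block = 1L,
      trial = seq_len(n_rows), stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

test_that("the hierarchical fit recovers known generative fixed effects", {
  # scaled-down generative check: 80 subjects x 100 rows
  set.seed(41)
  fixed <- c(1.3, 0.4, 0.0, 0.3)
  rows <- simulate_mixed_rows(80, 100, fixed, re_sd = 0.5)
  fit <- fit_hierarchical(rows)
  expect_true(fit$converged)
  for (j in 1:4) {
    expect_lt(abs(fit$fixed$estimate[j] - fixed[j]), 2 * fit$fixed$se[j] + 0.05)
  }
  # empirical-Bayes per-subject effects centre on the fixed effects
  mbi <- extract_mbi(fit)
  expect_equal(mean(mbi), fit$fixed$estimate[4], tolerance = 0.03)
  # shrinkage: hierarchical per-subject MBIs vary less than pointwise ones
  pw <- extract_mbi(fit_pointwise_all(rows))
  expect_lte(var(mbi), var(pw))
  expect_gt(cor(mbi, pw[names(mbi)]), 0.5)
  # random-effect covariance is symmetric PSD
  ev <- eigen(fit$ranef_cov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-8))
})

test_that("with identical per-subject data the fit collapses to the pooled fit", {
  set.seed(53)
  one <- random_stay_rows(120)
  rows <- do.call(rbind, lapply(1:8, function(i) {
    r <- one; r$subject <- sprintf("s%02d", i); r
  }))
  rows <- rows[order(rows$subject), ]
  fit <- fit_hierarchical(rows)
  pooled <- fit_pointwise(one, ridge = 0)
  expect_equal(fit$fixed$estimate, unname(pooled$coefficients),
               tolerance = 0.05)
  expect_lt(max(diag(fit$ranef_cov)), 0.05)
})

test_that("the comparison model isolates a generative group contrast", {
  ta <- make_hybrid_cohort(25, w = 0.8, n_trials = 150, seed = 61, prefix = "a")
  tb <- make_hybrid_cohort(25, w = 0.3, n_trials = 150, seed = 62, prefix = "b")
  rows <- build_stay_design(rbind(ta, tb))
  grp <- c(setNames(rep(1, 25), unique(ta$subject)),
           setNames(rep(-1, 25), unique(tb$subject)))
  fit <- fit_comparison(rows, grp)
  three <- fit$fixed[fit$fixed$term == "prev_reward:prev_transition:group", ]
  expect_gt(three$estimate, 0)       # +1-coded arm is the high-w arm
  expect_lt(three$p, 0.01)
  expect_error(fit_comparison(rows, setNames(rep(1, 50), names(grp))),
               "both groups")
})

test_that("hit-model input validation rejects a constant hit column", {
  tr <- make_hybrid_cohort(5, w = 0.5, n_trials = 60, seed = 71)
  rows <- build_stay_design(tr, include_hit = TRUE)
  rows$prev_hit <- -1L
  expect_error(fit_hit_model(rows), "constant")
  expect_error(fit_hit_model(build_stay_design(tr)), "include_hit")
})

test_that("hit distraction surfaces as a negative lagged-hit effect", {
  # the reward x hit interaction is structurally aliased (hit => reward), so
  # the identified prev_hit main effect carries the contrast: hit vs no-hit
  # among previously rewarded trials
  cfg <- task_config()
  agents_off <- lapply(1:40, function(i) hybrid_agent(w = 0.5, beta_temp = 5,
                                                      stickiness = 0.2))
  names(agents_off) <- sprintf("o%03d", 1:40)
  rows_off <- build_stay_design(simulate_cohort(agents_off, cfg, seed = 81),
                                include_hit = TRUE)
  fit_off <- fit_hit_model(rows_off)
  h_off <- fit_off$fixed[fit_off$fixed$term == "prev_hit", ]
  expect_equal(nrow(h_off), 1L)
  expect_lt(abs(h_off$estimate), 2 * h_off$se + 0.02)  # hits causally inert

  agents_on <- lapply(1:40, function(i) hybrid_agent(w = 0.5, beta_temp = 5,
                                                     stickiness = 0.2,
                                                     hit_distraction = 0.1))
  names(agents_on) <- sprintf("d%03d", 1:40)
  rows_on <- build_stay_design(simulate_cohort(agents_on, cfg, seed = 82),
                               include_hit = TRUE)
  fit_on <- fit_hit_model(rows_on)
  h_on <- fit_on$fixed[fit_on$fixed$term == "prev_hit", ]
  expect_lt(h_on$estimate, 0)
  expect_lt(h_on$estimate, h_off$estimate)
})

test_that("extract_* accept pointwise tables and order subjects stably", {
  tr <- make_hybrid_cohort(6, w = 0.5, n_trials = 80, seed = 91)
  pw <- fit_pointwise_all(build_stay_design(tr))
  mbi <- extract_mbi(pw)
  expect_identical(names(mbi), sort(unique(tr$subject)))
  co <- extract_coefficients(pw)
  expect_named(co, c("subject", "stay_tendency", "mfi", "transition", "mbi"))
})
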