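#' Reliability and validity as a function of trial number
#'
#' Re-estimates the per-subject MBI from truncated (`cumulative`) or windowed
#' (`binned`) portions of each subject's log, on a grid of trial counts, and
#' reports per grid point the mean MBI, split-half reliability with CI, and
#' (when covariates are supplied) the covariate-association coefficients.
#' Subjects with fewer than `max_trials` non-missed trials are dropped with a
#' reported count. Trials are ordered chronologically within subject
#' (session, then block, then trial).
#'
#' @param trials Trial-record `data.frame`.
#' @param covariates Optional covariate `data.frame` (see [associate()]).
#' @param step Grid step in trials (default 25; must divide `max_trials`).
#' @param max_trials Largest trial count on the grid (default 300).
#' @param mode `"cumulative"` (first `g` trials) or `"binned"` (trials
#'   `g - step + 1 ... g`).
#' @param estimator `"hierarchical"` or `"pointwise"` (per-subject MBIs; the
#'   pointwise route is much faster on short windows).
#' @return A `curve_result`: `data.frame` with one row per grid point
#'   (`grid`, `mode`, `n_subjects`, `mean_mbi`, `split_half_r`, `sh_ci_low`,
#'   `sh_ci_high`) plus, as attribute `associations`, a long `data.frame` of
#'   association coefficients per grid point, and attribute `n_dropped`.
#' @export
trial_number_curve <- function(trials, covariates = NULL, step = 25L,
                               max_trials = 300L,
                               mode = c("cumulative", "binned"),
                               estimator = c("hierarchical", "pointwise")) {
  mode <- match.arg(mode)
  estimator <- match.arg(estimator)
  if (max_trials %% step != 0L) stop("step must divide max_trials")

  dt <- data.table::as.data.table(trials)
  data.table::setorder(dt, subject, session, block, trial)
  dt <- dt[missed == FALSE]
  dt[, idx := seq_len(.N), by = subject]
  n_per <- dt[, .N, by = subject]
  keep <- n_per$subject[n_per$N >= max_trials]
  n_dropped <- nrow(n_per) - length(keep)
  if (length(keep) < 3L) stop("need >= 3 subjects with max_trials trials")
  dt <- dt[subject %in% keep]

  grid <- seq(step, max_trials, by = step)
  res <- vector("list", length(grid))
  assoc <- list()
  for (gi in seq_along(grid)) {
    g <- grid[gi]
    sub <- if (mode == "cumulative") dt[idx <= g] else dt[idx > g - step & idx <= g]
    sub_df <- data.table::setDF(data.table::copy(sub))
    rows <- build_stay_design(sub_df)
    mbi <- if (estimator == "hierarchical") {
      extract_mbi(fit_hierarchical(rows))
    } else {
      extract_mbi(fit_pointwise_all(rows))
    }
    sh <- tryCatch(
      split_half_oddeven(rows = rows,
                         estimator = if (estimator == "hierarchical")
                           "hierarchical" else "pointwise"),
      error = function(e) NULL
    )
    res[[gi]] <- data.frame(
      grid = g, mode = mode, n_subjects = length(mbi),
      mean_mbi = mean(mbi),
      split_half_r = if (is.null(sh)) NA_real_ else sh$r,
      sh_ci_low = if (is.null(sh)) NA_real_ else sh$ci_low,
      sh_ci_high = if (is.null(sh)) NA_real_ else sh$ci_high,
      stringsAsFactors = FALSE
    )
    if (!is.null(covariates)) {
      a <- associate(mbi, covariates)
      a$grid <- g
      assoc[[length(assoc) + 1L]] <- a
    }
  }
  out <- do.call(rbind, res)
  attr(out, "associations") <- if (length(assoc)) do.call(rbind, assoc) else NULL
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("curve_result", class(out))
  out
}

#' Compare two task-design arms
#'
#' Estimates per-subject MBIs in each arm with the same estimator, reports
#' group means/SDs and a t statistic (paired when both arms contain the same
#' subjects, Welch two-sample otherwise), and fits the group-comparison
#' hierarchical model on the pooled rows (arm A coded +1, arm B -1). Subject
#' ids are disambiguated across arms for the pooled fit when they overlap.
#'
#' @param factor Label for the manipulated factor: `"transition_ratio"`,
#'   `"drift_set"` or `"difficulty_order"`.
#' @param trials_a,trials_b Trial logs of the two arms.
#' @param estimator `"hierarchical"` or `"pointwise"`.
#' @param comparison_fit Also fit the pooled [fit_comparison()] model
#'   (default `TRUE`; the slowest part).
#' @return A `design_comparison` list: `factor`, `mean_a`, `sd_a`, `mean_b`,
#'   `sd_b`, `t`, `df`, `p`, `paired`, and `fit` (a `hier_fit` or `NULL`).
#' @export
compare_design <- function(factor = c("transition_ratio", "drift_set",
                                      "difficulty_order"),
                           trials_a, trials_b,
                           estimator = c("hierarchical", "pointwise"),
                           comparison_fit = TRUE) {
  factor <- match.arg(factor)
  estimator <- match.arg(estimator)
  est <- function(tr) {
    rows <- build_stay_design(tr)
    if (estimator == "hierarchical") extract_mbi(fit_hierarchical(rows))
    else extract_mbi(fit_pointwise_all(rows))
  }
  m_a <- est(trials_a)
  m_b <- est(trials_b)
  paired <- setequal(names(m_a), names(m_b))
  tt <- if (paired) {
    stats::t.test(m_a[sort(names(m_a))], m_b[sort(names(m_b))], paired = TRUE)
  } else {
    stats::t.test(m_a, m_b)
  }
  fit <- NULL
  if (comparison_fit) {
    ta <- trials_a; tb <- trials_b
    if (paired || length(intersect(unique(ta$subject), unique(tb$subject)))) {
      ta$subject <- paste0(ta$subject, "_A")
      tb$subject <- paste0(tb$subject, "_B")
    }
    rows <- build_stay_design(rbind(ta, tb)[order(c(ta$subject, tb$subject)), ])
    grp <- c(stats::setNames(rep(1, length(unique(ta$subject))), unique(ta$subject)),
             stats::setNames(rep(-1, length(unique(tb$subject))), unique(tb$subject)))
    fit <- fit_comparison(rows, grp)
  }
  structure(
    list(factor = factor, mean_a = mean(m_a), sd_a = stats::sd(m_a),
         mean_b = mean(m_b), sd_b = stats::sd(m_b),
         t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, paired = paired, mbi_a = m_a, mbi_b = m_b,
         fit = fit),
    class = "design_comparison"
  )
}

#' @export
print.design_comparison <- function(x, ...) {
  cat(sprintf(
    "<design_comparison> %s: A %.3f (%.3f) vs B %.3f (%.3f), t(%.1f) = %.2f, p = %.3g%s\n",
    x$factor, x$mean_a, x$sd_a, x$mean_b, x$sd_b, x$df, x$t, x$p,
    if (x$paired) " [paired]" else ""))
  invisible(x)
}

# ---- scenario runner ------------------------------------------------------

config_from_list <- function(task) {
  if (is.null(task)) return(task_config())
  blocks <- lapply(task$blocks %||% list(list(), list(n_trials = 100, difficulty = "medium")),
                   function(b) block_spec(
                     n_trials = b$n_trials %||% 100L,
                     difficulty = b$difficulty %||% "easy",
                     drift = b$drift %||% list(kind = "random_walk")
                   ))
  hr <- task$hit_rates
  hr <- if (is.null(hr)) c(easy = 0.52, medium = 0.45, hard = 0.30) else unlist(hr)
  task_config(p_common = task$p_common %||% 0.8, blocks = blocks,
              hit_rates = hr, miss_rate = task$miss_rate %||% 0)
}

spec_from_list <- function(pop) {
  defaults <- formals(population_spec)
  args <- list()
  for (nm in names(defaults)) {
    if (!is.null(pop[[nm]])) args[[nm]] <- pop[[nm]]
  }
  do.call(population_spec, args)
}

#' Run a scenario end to end
#'
#' Executes simulate -> exclude -> fit -> psychometrics (-> recovery), and
#' writes all artifacts (trial CSV, covariate CSV, coefficient CSV, JSON
#' model/reliability/report summaries, run log) to `out_dir`. Deterministic
#' given (config, seed).
#'
#' The scenario is a JSON file (or an equivalent list) with optional
#' sections: `name`; `task` (`p_common`, `blocks`, `hit_rates`, `miss_rate`);
#' `population` (any [population_spec()] argument, plus `w_dist` and
#' `agent_kind`); `estimation` (`estimator`: `"pointwise"`/`"hierarchical"`,
#' `ridge`); `experiments` (`reliability`, `recovery` flags). Two bundled
#' scenarios live under `system.file("scenarios", package = "twostepr")`:
#' `null_cohort.json` and `recovery.json`.
#'
#' @param scenario Path to a JSON scenario file, or a list.
#' @param out_dir Output directory (created; cleared of partial outputs on
#'   failure).
#' @param seed Master integer seed.
#' @return Invisibly, the report list (also written as `report.json`).
#' @export
run_scenario <- function(scenario, out_dir, seed = 1L) {
  cfg <- if (is.character(scenario)) jsonlite::read_json(scenario) else scenario
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit(if (!ok) unlink(file.path(out_dir, c(
    "trials.csv", "covariates.csv", "coefficients.csv", "model.json",
    "reliability.json", "exclusions.json", "report.json", "run_log.txt"))))

  config <- config_from_list(cfg$task)
  spec <- spec_from_list(cfg$population)
  pop <- synth_population(
    spec, config, seed = seed,
    w_dist = cfg$population$w_dist %||% "trait",
    agent_kind = cfg$population$agent_kind %||% "hybrid"
  )
  write_trials(pop$trials, file.path(out_dir, "trials.csv"))
  data.table::fwrite(pop$covariates, file.path(out_dir, "covariates.csv"))

  excl <- apply_exclusions(pop$trials)
  jsonlite::write_json(
    list(kept = excl$kept, excluded = excl$excluded,
         counts = as.list(excl$counts)),
    file.path(out_dir, "exclusions.json"), auto_unbox = TRUE, digits = NA)

  trials <- pop$trials[pop$trials$subject %in% excl$kept, , drop = FALSE]
  rows <- build_stay_design(trials)
  estimator <- cfg$estimation$estimator %||% "hierarchical"
  if (estimator == "hierarchical") {
    fit <- fit_hierarchical(rows)
    write_hier_fit(fit, file.path(out_dir, "model.json"))
    coefs <- extract_coefficients(fit)
  } else {
    coefs <- extract_coefficients(
      fit_pointwise_all(rows, ridge = cfg$estimation$ridge %||% 1e-3))
  }
  data.table::fwrite(coefs, file.path(out_dir, "coefficients.csv"))
  mbi <- stats::setNames(coefs$mbi, coefs$subject)

  report <- list(
    name = cfg$name %||% "scenario", seed = seed,
    n_subjects = spec$n_subjects, n_kept = length(excl$kept),
    estimator = estimator,
    mean_mbi = mean(mbi), sd_mbi = stats::sd(mbi),
    mean_mbi_ci = as.list(stats::setNames(
      mean(mbi) + c(-1, 1) * stats::qt(0.975, length(mbi) - 1) *
        stats::sd(mbi) / sqrt(length(mbi)), c("low", "high")))
  )
  if (isTRUE(cfg$experiments$reliability %||% TRUE)) {
    sh <- split_half_oddeven(
      rows = rows,
      estimator = if (estimator == "hierarchical") "hierarchical" else "pointwise")
    write_reliability(sh, file.path(out_dir, "reliability.json"))
    report$split_half_r <- sh$r
    report$split_half_corrected <- sh$corrected
  }
  if (isTRUE(cfg$experiments$recovery)) {
    cov_kept <- pop$covariates[pop$covariates$subject %in% names(mbi), ]
    report$recovery_r <- stats::cor(
      cov_kept$w_true[match(names(mbi), cov_kept$subject)], mbi)
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(c(
    sprintf("scenario: %s", report$name),
    sprintf("seed: %d", seed),
    sprintf("twostepr version: %s",
            as.character(utils::packageVersion("twostepr"))),
    sprintf("R version: %s", R.version.string),
    sprintf("finished: kept %d of %d subjects", report$n_kept, report$n_subjects)
  ), file.path(out_dir, "run_log.txt"))
  ok <- TRUE
  invisible(report)
}
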