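# Calibration constant: empirical correlation between the agents' latent
# decision-weight scale (logit of w) and the estimated (pointwise) MBI under
# the default 200-trial task, measured once by simulation at n = 3000 with
# all other population parameters at their defaults (see the methods
# vignette, "Calibrating the latent trait") and then frozen. It converts a
# target trait-MBI correlation into a slope on the logit-w scale.
.mbi_eta_corr <- 0.36

#' Synthetic population specification
#'
#' Describes a cohort of hybrid agents whose model-based weight `w` is driven
#' by a standard-normal latent trait (a stand-in for a compulsivity-like
#' symptom dimension), demographic covariates, and independent noise, on the
#' logit scale: `w = plogis(intercept + b_c * trait + effects + noise)`. The
#' trait slope `b_c` is derived from `trait_target_r`, the intended
#' correlation between the trait and the *estimated* MBI, via a frozen
#' simulation-calibrated attenuation constant. Degenerate perseverative
#' agents and per-trial missingness can be mixed in for exclusion testing.
#'
#' Default covariate distributions mirror a large general-population
#' smartphone cohort: age ~ Normal(45.4, 14.5) truncated to 18-84, 64% women,
#' 64% with post-secondary education. Effect sizes on the logit-w scale are
#' the package's own modest choices (age -0.10 per SD, woman -0.08, educated
#' +0.10), signed to reproduce the canonical directions (older, female,
#' less-educated individuals show lower model-based planning).
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param trait_target_r Intended trait-MBI correlation (default -0.12).
#' @param w_logit_mean Intercept on the logit-w scale.
#' @param w_noise_sd Independent noise sd on the logit-w scale.
#' @param age_effect,gender_effect,edu_effect Signed effects on logit-w
#'   (age per SD; gender for woman = 1; education for post-secondary = 1).
#' @param alpha_shape1,alpha_shape2 Beta parameters for learning rates.
#' @param beta_shape,beta_rate Gamma parameters for inverse temperatures
#'   (defaults give mean 5).
#' @param stickiness_mean,stickiness_sd Normal parameters for stickiness.
#' @param contamination Fraction of subjects replaced by perseverative
#'   `fixed_side` agents.
#' @param miss_rate Per-trial probability of a missed trial.
#' @return A `population_spec` object.
#' @export
population_spec <- function(n_subjects = 200L,
                            trait_target_r = -0.12,
                            w_logit_mean = 0,
                            w_noise_sd = 0.9,
                            age_effect = -0.10,
                            gender_effect = -0.08,
                            edu_effect = 0.10,
                            alpha_shape1 = 3, alpha_shape2 = 3,
                            beta_shape = 10, beta_rate = 2,
                            stickiness_mean = 0.2, stickiness_sd = 0.3,
                            contamination = 0, miss_rate = 0) {
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  if (abs(trait_target_r) >= .mbi_eta_corr) {
    stop(sprintf(
      "trait_target_r beyond the attainable range (+/-%.2f) given estimation noise",
      .mbi_eta_corr))
  }
  if (contamination < 0 || contamination > 1) stop("contamination must be in [0, 1]")
  if (miss_rate < 0 || miss_rate > 1) stop("miss_rate must be in [0, 1]")
  if (w_noise_sd < 0) stop("w_noise_sd must be >= 0")
  structure(
    list(n_subjects = as.integer(n_subjects), trait_target_r = trait_target_r,
         w_logit_mean = w_logit_mean, w_noise_sd = w_noise_sd,
         age_effect = age_effect, gender_effect = gender_effect,
         edu_effect = edu_effect,
         alpha_shape1 = alpha_shape1, alpha_shape2 = alpha_shape2,
         beta_shape = beta_shape, beta_rate = beta_rate,
         stickiness_mean = stickiness_mean, stickiness_sd = stickiness_sd,
         contamination = contamination, miss_rate = miss_rate),
    class = "population_spec"
  )
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf(
    "<population_spec> n = %d, trait_target_r = %.3f, contamination = %.2f, miss_rate = %.2f\n",
    x$n_subjects, x$trait_target_r, x$contamination, x$miss_rate))
  invisible(x)
}

# Slope on logit-w per unit trait so that corr(trait, estimated MBI) hits the
# target: corr(trait, eta) must be q = target / K (K = .mbi_eta_corr), and
# with eta = b * c + Z, sd(Z) = s0, that requires b = s0 * q / sqrt(1 - q^2).
trait_slope <- function(spec) {
  q <- spec$trait_target_r / .mbi_eta_corr
  s0 <- sqrt(spec$age_effect^2 +
               spec$gender_effect^2 * 0.64 * 0.36 +
               spec$edu_effect^2 * 0.64 * 0.36 +
               spec$w_noise_sd^2)
  s0 * q / sqrt(1 - q^2)
}

#' Simulate a synthetic cohort with covariates
#'
#' Draws per-subject latent traits, covariates, agent parameters and
#' model-based weights per the [population_spec()], instantiates hybrid (or
#' contaminating perseverative) agents, and simulates one session each.
#'
#' @param spec A [population_spec()].
#' @param config A [task_config()]; its `miss_rate` is overridden by the
#'   spec's when the spec's is non-zero.
#' @param seed Master integer seed.
#' @param w_dist `"trait"` (default; the latent-trait model above) or
#'   `"uniform"` (w ~ Uniform(0, 1), for parameter-recovery studies).
#' @param agent_kind `"hybrid"` (default) or a degenerate kind; degenerate
#'   cohorts ignore the w model (used for null calibration).
#' @return A list: `trials` (trial-record `data.frame`) and `covariates`
#'   (`data.frame` with `subject`, `trait`, `age`, `gender_woman`,
#'   `education`, `w_true`, `alpha`, `beta_temp`, `stickiness`,
#'   `contaminant`).
#' @export
synth_population <- function(spec = population_spec(), config = task_config(),
                             seed = 1L, w_dist = c("trait", "uniform"),
                             agent_kind = "hybrid") {
  w_dist <- match.arg(w_dist)
  set.seed(seed)
  n <- spec$n_subjects
  ids <- sprintf("s%04d", seq_len(n))

  trait <- stats::rnorm(n)
  age <- pmin(pmax(stats::rnorm(n, 45.4, 14.5), 18), 84)
  woman <- stats::rbinom(n, 1, 0.64)
  edu <- stats::rbinom(n, 1, 0.64)
  alpha <- stats::rbeta(n, spec$alpha_shape1, spec$alpha_shape2)
  alpha <- pmin(pmax(alpha, 0.01), 1)
  beta_temp <- stats::rgamma(n, spec$beta_shape, spec$beta_rate)
  stickiness <- stats::rnorm(n, spec$stickiness_mean, spec$stickiness_sd)

  if (w_dist == "uniform") {
    # parameter-recovery mode: vary only the parameter of interest and hold
    # the nuisance parameters at their population means
    w <- stats::runif(n)
    alpha <- rep(0.5, n)
    beta_temp <- rep(5, n)
    stickiness <- rep(0.2, n)
  } else {
    b_c <- trait_slope(spec)
    z_age <- (age - 45.4) / 14.5
    eta <- spec$w_logit_mean + b_c * trait +
      spec$age_effect * z_age + spec$gender_effect * woman +
      spec$edu_effect * edu + stats::rnorm(n, 0, spec$w_noise_sd)
    w <- stats::plogis(eta)
  }

  contaminant <- stats::runif(n) < spec$contamination
  agents <- vector("list", n)
  for (i in seq_len(n)) {
    agents[[i]] <- if (contaminant[i]) {
      degenerate_agent("fixed_side", side = sample(c("left", "right"), 1))
    } else if (agent_kind == "hybrid") {
      hybrid_agent(w = w[i], alpha = alpha[i], beta_temp = beta_temp[i],
                   stickiness = stickiness[i])
    } else {
      degenerate_agent(agent_kind)
    }
  }
  names(agents) <- ids

  if (spec$miss_rate > 0) {
    config <- task_config(p_common = config$p_common, blocks = config$blocks,
                          hit_rates = config$hit_rates,
                          miss_rate = spec$miss_rate)
  }
  trials <- simulate_cohort(agents, config, seed = sample.int(.Machine$integer.max, 1))
  covariates <- data.frame(
    subject = ids, trait = trait, age = age, gender_woman = woman,
    education = edu, w_true = w, alpha = alpha, beta_temp = beta_temp,
    stickiness = stickiness, contaminant = contaminant,
    stringsAsFactors = FALSE
  )
  list(trials = trials, covariates = covariates)
}

#' Apply the cohort exclusion filters
#'
#' Excludes a subject when (a) the fraction of missed trials over scheduled
#' trials is strictly above `missed_threshold`, (b) the most frequent single
#' container accounts for strictly more than `same_choice_threshold` of
#' non-missed choices, or (c) required covariates are incomplete. Strict
#' inequalities match the "more than 20% / more than 95%" rules. A subject
#' with no usable (non-missed) trials is excluded under the missed rule.
#'
#' @param trials Trial-record `data.frame`.
#' @param missed_threshold,same_choice_threshold Thresholds in `[0, 1]`.
#' @param require_covariates If `TRUE`, subjects absent from `covariates` or
#'   with `NA` entries are excluded.
#' @param covariates Covariate `data.frame` with a `subject` column.
#' @return An `exclusion_report`: `kept` (subject ids), `excluded`
#'   (`data.frame` subject/reason, one row per reason), `counts`.
#' @export
apply_exclusions <- function(trials, missed_threshold = 0.20,
                             same_choice_threshold = 0.95,
                             require_covariates = FALSE, covariates = NULL) {
  stopifnot(missed_threshold >= 0, missed_threshold <= 1,
            same_choice_threshold >= 0, same_choice_threshold <= 1)
  dt <- data.table::as.data.table(trials)
  per <- dt[, .(
    n_sched = .N,
    miss_frac = mean(missed),
    same_frac = {
      ch <- choice[!missed]
      if (!length(ch)) 1 else max(table(ch)) / length(ch)
    }
  ), by = subject]

  reasons <- list()
  bad_miss <- per$subject[per$miss_frac > missed_threshold | per$n_sched == 0]
  if (length(bad_miss)) {
    reasons$missed <- data.frame(subject = bad_miss,
                                 reason = "missed_gt_20pct",
                                 stringsAsFactors = FALSE)
  }
  usable <- per$subject[per$miss_frac < 1]
  bad_same <- intersect(
    per$subject[per$same_frac > same_choice_threshold], usable)
  if (length(bad_same)) {
    reasons$same <- data.frame(subject = bad_same,
                               reason = "same_choice_gt_95pct",
                               stringsAsFactors = FALSE)
  }
  if (require_covariates) {
    if (is.null(covariates)) stop("require_covariates = TRUE needs covariates")
    incomplete <- stats::complete.cases(covariates)
    have <- covariates$subject[incomplete]
    bad_cov <- setdiff(per$subject, have)
    if (length(bad_cov)) {
      reasons$cov <- data.frame(subject = bad_cov,
                                reason = "incomplete_covariates",
                                stringsAsFactors = FALSE)
    }
  }
  excluded <- if (length(reasons)) do.call(rbind, unname(reasons)) else
    data.frame(subject = character(), reason = character(),
               stringsAsFactors = FALSE)
  kept <- sort(setdiff(per$subject, excluded$subject))
  structure(
    list(kept = kept, excluded = excluded,
         counts = c(kept = length(kept),
                    excluded = length(unique(excluded$subject)),
                    table(excluded$reason))),
    class = "exclusion_report"
  )
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("<exclusion_report> kept %d, excluded %d\n",
              length(x$kept), length(unique(x$excluded$subject))))
  if (nrow(x$excluded)) print(table(x$excluded$reason))
  invisible(x)
}

#' Covariate-association model on per-subject MBI
#'
#' Ordinary linear model of the per-subject model-based index on a covariate
#' set. With `standardize = TRUE` the outcome and all continuous covariates
#' are z-scored, so a continuous covariate's coefficient is comparable to a
#' (partial) correlation. Incomplete cases are dropped with a reported count.
#'
#' @param mbi Named numeric vector (names = subjects) or `data.frame` with
#'   `subject` and `mbi`.
#' @param covariates `data.frame` with a `subject` column; every other column
#'   enters the model.
#' @param standardize Z-score the outcome and continuous covariates.
#' @return `data.frame` with `term`, `estimate`, `se`, `t`, `p`; attribute
#'   `n_dropped` counts incomplete cases.
#' @export
associate <- function(mbi, covariates, standardize = TRUE) {
  if (is.numeric(mbi)) {
    mbi <- data.frame(subject = names(mbi), mbi = as.numeric(mbi),
                      stringsAsFactors = FALSE)
  }
  stopifnot("subject" %in% names(covariates))
  d <- merge(mbi, covariates, by = "subject")
  cc <- stats::complete.cases(d)
  n_dropped <- sum(!cc)
  d <- d[cc, , drop = FALSE]
  preds <- setdiff(names(d), c("subject", "mbi"))
  if (!length(preds)) stop("no covariates supplied")
  for (p in preds) {
    v <- d[[p]]
    if (!is.numeric(v)) {
      d[[p]] <- as.numeric(factor(v)) - 1
      v <- d[[p]]
    }
    if (stats::sd(v) < 1e-12) stop(sprintf("zero-variance covariate '%s'", p))
    if (standardize && length(unique(v)) > 2L) {
      d[[p]] <- (v - mean(v)) / stats::sd(v)
    }
  }
  y <- d$mbi
  if (standardize) y <- (y - mean(y)) / stats::sd(y)
  fit <- stats::lm(stats::reformulate(preds, response = "y"),
                   data = cbind(d[preds], y = y))
  sm <- summary(fit)$coefficients
  out <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                    t = sm[, 3], p = sm[, 4], row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- n_dropped
  attr(out, "n_used") <- nrow(d)
  out
}
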