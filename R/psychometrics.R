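#' Spearman-Brown prophecy correction
#'
#' `corrected = 2 * r / (1 + r)`, projecting half-length reliability to full
#' length.
#'
#' @param r Reliability coefficient in `(-1, 1]`.
#' @return The corrected coefficient.
#' @export
spearman_brown <- function(r) {
  if (any(!is.finite(r)) || any(r <= -1) || any(r > 1)) {
    stop("r must lie in (-1, 1]")
  }
  2 * r / (1 + r)
}

#' Interpret a reliability coefficient
#'
#' Standard interpretation bands: below 0.4 poor, 0.4-0.7 fair, 0.7-0.9 good,
#' above 0.9 excellent; values exactly at a boundary map to the higher band
#' (0.4 is fair, 0.7 good, 0.9 excellent).
#'
#' @param r Coefficient in `[-1, 1]`.
#' @return `"poor"`, `"fair"`, `"good"` or `"excellent"`.
#' @export
interpret_reliability <- function(r) {
  stopifnot(all(r >= -1 & r <= 1))
  ifelse(r < 0.4, "poor", ifelse(r < 0.7, "fair", ifelse(r < 0.9, "good", "excellent")))
}

fisher_ci <- function(r, n, level = 0.95) {
  if (n <= 3 || abs(r) >= 1) return(c(NA_real_, NA_real_))
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - level) / 2)
  tanh(c(z - q * se, z + q * se))
}

reliability_report <- function(method, r, ci, n, corrected = NA_real_,
                               dropped = 0L) {
  structure(
    list(method = method, r = r, ci_low = ci[1], ci_high = ci[2], n = n,
         corrected = corrected, band = interpret_reliability(r),
         dropped = dropped),
    class = "reliability_report"
  )
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("<reliability_report> %s: r = %.3f [%.3f, %.3f], n = %d (%s)\n",
              x$method, x$r, x$ci_low, x$ci_high, x$n, x$band))
  if (is.finite(x$corrected)) {
    cat(sprintf("  Spearman-Brown corrected: %.3f\n", x$corrected))
  }
  if (x$dropped > 0) cat(sprintf("  subjects dropped: %d\n", x$dropped))
  invisible(x)
}

#' Split-half (odd/even) reliability of the model-based index
#'
#' Partitions each subject's stay rows by the parity of the stay trial's
#' index (the later trial of each lagged pair, within session), estimates the
#' MBI separately in each half, and Pearson-correlates the two per-subject
#' vectors; the confidence interval is Fisher-z. Subjects with fewer than
#' `min_rows` rows in either half are dropped (count reported). The
#' Spearman-Brown correction of the coefficient is included in the report.
#'
#' @param trials Trial-record `data.frame` (ignored when `rows` given).
#' @param rows Optional pre-built stay rows from [build_stay_design()].
#' @param estimator `"pointwise"` (one ridge-logistic fit per subject and
#'   half) or `"hierarchical"` (one mixed model per half, per-subject
#'   empirical-Bayes MBIs).
#' @param min_rows Minimum rows per half per subject (default 2).
#' @param ridge Ridge for the pointwise estimator.
#' @return A `reliability_report` (method `"split_half"`).
#' @export
split_half_oddeven <- function(trials = NULL, rows = NULL,
                               estimator = c("pointwise", "hierarchical"),
                               min_rows = 2L, ridge = 1e-3) {
  estimator <- match.arg(estimator)
  if (is.null(rows)) rows <- build_stay_design(trials)
  half <- ifelse(rows$trial %% 2L == 0L, "even", "odd")
  counts <- table(rows$subject, half)
  ok <- rownames(counts)[counts[, "even"] >= min_rows & counts[, "odd"] >= min_rows]
  dropped <- length(unique(rows$subject)) - length(ok)
  if (length(ok) < 3L) stop("need >= 3 subjects with enough rows in both halves")
  rows <- rows[rows$subject %in% ok, , drop = FALSE]
  half <- ifelse(rows$trial %% 2L == 0L, "even", "odd")

  mbi_half <- function(r) {
    if (estimator == "pointwise") {
      extract_mbi(fit_pointwise_all(r, ridge))
    } else {
      extract_mbi(fit_hierarchical(r))
    }
  }
  m_even <- mbi_half(rows[half == "even", , drop = FALSE])
  m_odd <- mbi_half(rows[half == "odd", , drop = FALSE])
  common <- intersect(names(m_even), names(m_odd))
  r <- stats::cor(m_even[common], m_odd[common])
  reliability_report("split_half", r, fisher_ci(r, length(common)),
                     n = length(common),
                     corrected = if (r > -1) spearman_brown(r) else NA_real_,
                     dropped = dropped)
}

#' One-way intraclass correlation for test-retest agreement
#'
#' ICC(1,1) for two sessions: from the one-way ANOVA decomposition with
#' k = 2 measurements per subject, `(MSB - MSW) / (MSB + MSW)`. The
#' confidence interval is the standard F-based interval for the one-way ICC.
#'
#' @param x,y Per-subject scores for sessions 1 and 2, paired by position,
#'   length >= 3.
#' @param level Confidence level.
#' @return A `reliability_report` (method `"icc1"`).
#' @export
icc_oneway <- function(x, y, level = 0.95) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("x and y must be paired vectors of length >= 3")
  }
  n <- length(x)
  k <- 2
  m_i <- (x + y) / 2
  grand <- mean(c(x, y))
  ssb <- k * sum((m_i - grand)^2)
  ssw <- sum((x - m_i)^2 + (y - m_i)^2)
  if (ssb + ssw < 1e-14) stop("zero total variance; ICC undefined")
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  if (msw < 1e-14 && msb < 1e-14) stop("zero total variance; ICC undefined")
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  ci <- if (msw < 1e-14) c(NA_real_, NA_real_) else {
    f0 <- msb / msw
    a <- 1 - (1 - level) / 2
    fl <- f0 / stats::qf(a, n - 1, n * (k - 1))
    fu <- f0 * stats::qf(a, n * (k - 1), n - 1)
    c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  }
  reliability_report("icc1", icc, ci, n = n)
}

#' Export a reliability report as JSON
#'
#' @param report A `reliability_report`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_reliability <- function(report, path) {
  stopifnot(inherits(report, "reliability_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
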