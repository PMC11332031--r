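#' Build the lagged stay/switch design
#'
#' One row per consecutive pair of non-missed trials within a block: the
#' outcome is whether the later trial repeated the earlier trial's choice
#' (stay = 1, switch = 0), and the predictors are the earlier trial's reward
#' (unrewarded -1, rewarded +1) and transition (rare -1, common +1). Rows
#' never span block or session boundaries (a drift, and possibly difficulty,
#' change intervenes at block breaks), and a missed trial breaks the lag
#' chain: neither it nor its successor yields a row.
#'
#' @param trials Trial-record `data.frame`, sorted by
#'   (subject, session, block, trial).
#' @param include_hit Also code the earlier trial's diamond hit as
#'   `prev_hit` (+1 hit, -1 no hit; unrewarded trials cannot hit and keep -1).
#' @return A `data.frame` of stay rows with columns `subject`, `stay`,
#'   `prev_reward`, `prev_transition`, (`prev_hit`,) `session`, `block`,
#'   `trial` (index of the stay trial, i.e. the later trial of the pair).
#' @export
build_stay_design <- function(trials, include_hit = FALSE) {
  stopifnot(is.data.frame(trials))
  dt <- data.table::as.data.table(trials)
  ord <- order(dt$subject, dt$session, dt$block, dt$trial)
  if (!identical(ord, seq_len(nrow(dt)))) {
    stop("trials must be sorted by (subject, session, block, trial)")
  }
  prev <- function(x) data.table::shift(x)
  dt[, `:=`(
    p_choice = prev(choice), p_reward = prev(reward),
    p_transition = prev(transition), p_hit = prev(hit),
    p_missed = prev(missed)
  ), by = .(subject, session, block)]
  rows <- dt[!is.na(p_choice) & !missed & !p_missed]
  out <- data.frame(
    subject = rows$subject,
    stay = as.integer(rows$choice == rows$p_choice),
    prev_reward = 2L * rows$p_reward - 1L,
    prev_transition = ifelse(rows$p_transition == "common", 1L, -1L),
    session = rows$session, block = rows$block, trial = rows$trial,
    stringsAsFactors = FALSE
  )
  if (include_hit) {
    ph <- ifelse(is.na(rows$p_hit), 0L, rows$p_hit)
    out$prev_hit <- 2L * ph - 1L
    out <- out[, c("subject", "stay", "prev_reward", "prev_transition",
                   "prev_hit", "session", "block", "trial")]
  }
  out
}

# ---- pointwise (per-subject) logistic fits -------------------------------

stay_model_matrix <- function(rows) {
  cbind(`(Intercept)` = 1, prev_reward = rows$prev_reward,
        prev_transition = rows$prev_transition,
        `prev_reward:prev_transition` = rows$prev_reward * rows$prev_transition)
}

# Newton-Raphson on the (optionally ridge-penalised) Bernoulli-logit
# log-likelihood; penalty is lambda * sum(beta^2) on all four coefficients.
newton_logit <- function(X, y, ridge, max_iter = 100L, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    g <- drop(crossprod(X, y - p)) - 2 * ridge * beta
    if (sqrt(sum(g^2)) < tol) {
      return(list(beta = beta, converged = TRUE, iter = it))
    }
    w <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(X, X * w) + diag(2 * ridge, ncol(X))
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) return(list(beta = beta, converged = FALSE, iter = it))
    # dampen absurd steps (separation with ridge = 0)
    nrm <- sqrt(sum(step^2))
    if (!is.finite(nrm)) return(list(beta = beta, converged = FALSE, iter = it))
    if (nrm > 10) step <- step * 10 / nrm
    beta <- beta + step
    if (max(abs(beta)) > 50) {
      return(list(beta = beta, converged = FALSE, iter = it))
    }
  }
  list(beta = beta, converged = FALSE, iter = max_iter)
}

#' Per-subject logistic point estimate of the stay regression
#'
#' Maximises the (optionally ridge-penalised) Bernoulli-logit likelihood of
#' stay on `{1, prev_reward, prev_transition, prev_reward * prev_transition}`
#' by Newton iteration to gradient norm < 1e-8. The small default ridge keeps
#' estimates finite under the separation patterns common in short windows; a
#' subject whose unpenalised likelihood diverges is flagged.
#'
#' @param rows Stay rows for one subject (see [build_stay_design()]).
#' @param ridge Non-negative penalty on intercept and slopes (default 1e-3).
#' @return A `subject_coefficients` object: named coefficients
#'   (`stay_tendency`, `mfi`, `transition`, `mbi`), `source = "pointwise"`,
#'   `separation_flag`.
#' @export
fit_pointwise <- function(rows, ridge = 1e-3) {
  if (!nrow(rows)) stop("no stay rows supplied")
  if (ridge < 0) stop("ridge must be >= 0")
  X <- stay_model_matrix(rows)
  y <- rows$stay
  fit <- newton_logit(X, y, ridge)
  # regularisation was decisive iff the unpenalised problem diverges
  sep <- if (ridge > 0) {
    free <- newton_logit(X, y, ridge = 0, max_iter = 40L)
    !free$converged || max(abs(free$beta)) > 10
  } else {
    !fit$converged || max(abs(fit$beta)) > 10
  }
  beta <- unname(fit$beta)
  structure(
    list(coefficients = c(stay_tendency = beta[1], mfi = beta[2],
                          transition = beta[3], mbi = beta[4]),
         source = "pointwise", separation_flag = sep,
         n_rows = nrow(rows), converged = fit$converged),
    class = "subject_coefficients"
  )
}

#' @export
print.subject_coefficients <- function(x, ...) {
  cat(sprintf("<subject_coefficients> (%s%s, n = %d)\n", x$source,
              if (x$separation_flag) ", separation" else "", x$n_rows))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Pointwise fits for every subject
#'
#' @param rows Stay rows for any number of subjects.
#' @param ridge Ridge penalty passed to [fit_pointwise()].
#' @return A `data.frame` with one row per subject: `subject`,
#'   `stay_tendency`, `mfi`, `transition`, `mbi`, `separation_flag`, `n_rows`.
#' @export
fit_pointwise_all <- function(rows, ridge = 1e-3) {
  split_rows <- split(rows, rows$subject)
  res <- lapply(split_rows, function(r) {
    f <- fit_pointwise(r, ridge)
    data.frame(subject = r$subject[1], t(f$coefficients),
               separation_flag = f$separation_flag, n_rows = f$n_rows,
               stringsAsFactors = FALSE, check.names = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$subject), , drop = FALSE]
}

# ---- hierarchical fits ----------------------------------------------------

glmer_quiet <- function(formula, data, diagonal = FALSE) {
  ctrl <- lme4::glmerControl(optimizer = "bobyqa", calc.derivs = FALSE,
                             optCtrl = list(maxfun = 2e5),
                             check.conv.singular = "ignore")
  warn <- character()
  fit <- withCallingHandlers(
    tryCatch(
      lme4::glmer(formula, data = data, family = stats::binomial(),
                  control = ctrl, nAGQ = 1L),
      error = function(e) e
    ),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  list(fit = fit, failed = inherits(fit, "error"),
       conv_warning = any(grepl("converge", warn, ignore.case = TRUE)))
}

finalize_hier_fit <- function(fit, converged, rows) {
  sm <- summary(fit)$coefficients
  fixed <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      z = sm[, 3], p = 2 * stats::pnorm(-abs(sm[, 3])),
                      row.names = NULL, stringsAsFactors = FALSE)
  vc <- lme4::VarCorr(fit)$subject
  ranef_cov <- matrix(as.numeric(vc), nrow(vc), ncol(vc),
                      dimnames = dimnames(vc))
  ce <- stats::coef(fit)$subject     # fixed effects + conditional modes
  structure(
    list(fixed = fixed, ranef_cov = ranef_cov,
         subject_effects = ce,
         n_subjects = length(unique(rows$subject)), n_rows = nrow(rows),
         loglik = as.numeric(stats::logLik(fit)), converged = converged,
         model = fit),
    class = "hier_fit"
  )
}

run_hier <- function(form_full, form_diag, data, rows) {
  r1 <- glmer_quiet(form_full, data)
  if (!r1$failed && !r1$conv_warning) {
    return(finalize_hier_fit(r1$fit, TRUE, rows))
  }
  r2 <- glmer_quiet(form_diag, data, diagonal = TRUE)
  if (r2$failed) {
    if (r1$failed) stop("hierarchical fit failed: ", conditionMessage(r1$fit))
    return(finalize_hier_fit(r1$fit, FALSE, rows))
  }
  finalize_hier_fit(r2$fit, !r2$conv_warning && !r1$failed, rows)
}

hier_data <- function(rows) {
  data.frame(stay = rows$stay,
             prev_reward = as.numeric(rows$prev_reward),
             prev_transition = as.numeric(rows$prev_transition),
             subject = factor(rows$subject),
             stringsAsFactors = FALSE)
}

#' Hierarchical (mixed-effects) logistic stay regression
#'
#' The primary estimator: a binomial-logit mixed model of stay on previous
#' reward, previous transition, and their interaction, with a per-subject
#' random intercept and all three random slopes under an unstructured
#' covariance (Laplace-approximate marginal likelihood, as in `lme4`). The
#' per-subject coefficients are fixed effects plus conditional modes
#' (empirical-Bayes estimates); fixed-effect inference is Wald. On a
#' convergence failure the model is refit with a diagonal random-effect
#' covariance, and `converged` is set `FALSE` if that also fails to converge.
#'
#' @param rows Stay rows for >= 2 subjects (see [build_stay_design()]).
#' @return A `hier_fit` object: `fixed` (term/estimate/se/z/p), `ranef_cov`,
#'   `subject_effects` (per-subject coefficient quadruples), `n_subjects`,
#'   `n_rows`, `loglik`, `converged`, and the underlying `merMod` as `model`.
#' @export
fit_hierarchical <- function(rows) {
  check_hier_input(rows)
  d <- hier_data(rows)
  run_hier(
    stay ~ prev_reward * prev_transition +
      (1 + prev_reward * prev_transition | subject),
    stay ~ prev_reward * prev_transition +
      (1 + prev_reward * prev_transition || subject),
    d, rows
  )
}

check_hier_input <- function(rows) {
  if (!nrow(rows)) stop("no stay rows supplied")
  if (length(unique(rows$subject)) < 2L) {
    stop("hierarchical fit needs >= 2 subjects")
  }
}

#' Group-comparison hierarchical model
#'
#' Adds a per-subject group code (+1/-1) and its interactions with reward,
#' transition and reward x transition to the fixed effects, leaving the
#' random structure unchanged. Used for task, transition-ratio,
#' difficulty/order, and drift comparisons; the three-way
#' reward x transition x group term tests whether the model-based index
#' differs between groups.
#'
#' @param rows Stay rows.
#' @param group Named numeric vector (names = subjects, values +1/-1), or a
#'   `data.frame` with columns `subject` and `group`.
#' @return A `hier_fit`.
#' @export
fit_comparison <- function(rows, group) {
  check_hier_input(rows)
  if (is.data.frame(group)) group <- stats::setNames(group$group, group$subject)
  if (is.null(names(group))) stop("group must be named by subject")
  if (!all(unique(rows$subject) %in% names(group))) {
    stop("every subject needs exactly one group code")
  }
  g <- group[as.character(rows$subject)]
  if (!all(g %in% c(-1, 1))) stop("group codes must be +1/-1")
  if (length(unique(g)) < 2L) stop("both groups must be present")
  d <- hier_data(rows)
  d$group <- as.numeric(g)
  run_hier(
    stay ~ prev_reward * prev_transition * group +
      (1 + prev_reward * prev_transition | subject),
    stay ~ prev_reward * prev_transition * group +
      (1 + prev_reward * prev_transition || subject),
    d, rows
  )
}

#' Lagged diamond-hit hierarchical model
#'
#' Enters the previous trial's diamond hit (+1/-1) and its transition
#' interaction into the stay model, keeping the base random structure.
#'
#' Because a hit is only possible on rewarded trials, `prev_hit` is constant
#' (-1) on all previously-unrewarded rows, which makes the reward x hit and
#' reward x transition x hit columns exact linear combinations of the others
#' (`r*h = 1 - r + h` under the +/-1 coding, whatever coding is chosen).
#' Rather than letting the backend drop aliased columns silently, the model
#' is specified in its identified parametrization: the `prev_hit` main
#' effect is estimated from hit-vs-no-hit variation among previously
#' rewarded trials, and therefore carries the substantive
#' "reward-potentiation vs learning-interruption" contrast (negative =
#' reduced staying after a rewarded hit, i.e. interrupted learning);
#' `prev_transition:prev_hit` plays the same role for the model-based
#' component.
#'
#' @param rows Stay rows built with `include_hit = TRUE`.
#' @return A `hier_fit`.
#' @export
fit_hit_model <- function(rows) {
  check_hier_input(rows)
  if (is.null(rows$prev_hit)) stop("rows must be built with include_hit = TRUE")
  if (length(unique(rows$prev_hit)) < 2L) {
    stop("prev_hit is constant; hit model is not identified")
  }
  d <- hier_data(rows)
  d$prev_hit <- as.numeric(rows$prev_hit)
  run_hier(
    stay ~ prev_reward * prev_transition + prev_hit +
      prev_transition:prev_hit +
      (1 + prev_reward * prev_transition | subject),
    stay ~ prev_reward * prev_transition + prev_hit +
      prev_transition:prev_hit +
      (1 + prev_reward * prev_transition || subject),
    d, rows
  )
}

#' @export
print.hier_fit <- function(x, ...) {
  cat(sprintf("<hier_fit> %d subjects, %d rows, logLik = %.1f, converged = %s\n",
              x$n_subjects, x$n_rows, x$loglik, x$converged))
  print(transform(x$fixed, estimate = round(estimate, 3), se = round(se, 3),
                  z = round(z, 2), p = signif(p, 3)))
  invisible(x)
}

#' Extract per-subject model-based indices
#'
#' @param fit A `hier_fit`, a `data.frame` from [fit_pointwise_all()], or a
#'   list of `subject_coefficients`.
#' @return A named numeric vector, subject -> MBI, ordered by subject id.
#' @export
extract_mbi <- function(fit) {
  co <- extract_coefficients(fit)
  stats::setNames(co$mbi, co$subject)
}

#' Extract the full per-subject coefficient table
#'
#' For a hierarchical fit, per-subject coefficients are fixed effects plus
#' conditional modes.
#'
#' @inheritParams extract_mbi
#' @return `data.frame` with `subject`, `stay_tendency`, `mfi`, `transition`,
#'   `mbi`, ordered by subject id.
#' @export
extract_coefficients <- function(fit) {
  if (inherits(fit, "hier_fit")) {
    ce <- fit$subject_effects
    out <- data.frame(
      subject = rownames(ce),
      stay_tendency = ce[["(Intercept)"]],
      mfi = ce[["prev_reward"]],
      transition = ce[["prev_transition"]],
      mbi = ce[["prev_reward:prev_transition"]],
      stringsAsFactors = FALSE
    )
  } else if (is.data.frame(fit)) {
    out <- data.frame(subject = fit$subject, stay_tendency = fit$stay_tendency,
                      mfi = fit$mfi, transition = fit$transition,
                      mbi = fit$mbi, stringsAsFactors = FALSE)
  } else if (is.list(fit) && all(vapply(fit, inherits, TRUE, "subject_coefficients"))) {
    out <- do.call(rbind, lapply(seq_along(fit), function(i) {
      co <- fit[[i]]$coefficients
      data.frame(subject = names(fit)[i] %||% as.character(i),
                 stay_tendency = co[["stay_tendency"]], mfi = co[["mfi"]],
                 transition = co[["transition"]], mbi = co[["mbi"]],
                 stringsAsFactors = FALSE)
    }))
  } else {
    stop("unsupported fit object")
  }
  out <- out[order(out$subject), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a hierarchical fit summary as JSON
#'
#' @param fit A `hier_fit`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_hier_fit <- function(fit, path) {
  stopifnot(inherits(fit, "hier_fit"))
  jsonlite::write_json(
    list(fixed = fit$fixed, ranef_cov = fit$ranef_cov,
         n_subjects = fit$n_subjects, n_rows = fit$n_rows,
         loglik = fit$loglik, converged = fit$converged),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
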