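#' Block specification
#'
#' One block of the task: a trial count, a difficulty level (which sets the
#' per-trial probability of hitting the diamond given a good ball), and a
#' drift — either a concrete [drift_series()] or a generator description that
#' is re-randomised per session (mirroring random drift assignment per block).
#'
#' @param n_trials Positive integer.
#' @param difficulty `"easy"`, `"medium"` or `"hard"`.
#' @param drift A [drift_series()] of length `n_trials`, or a list such as
#'   `list(kind = "random_walk", sd = 0.025, lower = 0.25, upper = 0.75)`,
#'   `list(kind = "target_moments", mean_purple = , ...)` or
#'   `list(kind = "preset", which = "A")`.
#' @return A `block_spec` object.
#' @export
block_spec <- function(n_trials = 100L, difficulty = c("easy", "medium", "hard"),
                       drift = list(kind = "random_walk")) {
  difficulty <- match.arg(difficulty)
  n_trials <- as.integer(n_trials)
  if (n_trials < 1L) stop("n_trials must be > 0")
  if (inherits(drift, "drift_series") && length(drift) != n_trials) {
    stop("drift length must equal n_trials")
  }
  structure(list(n_trials = n_trials, difficulty = difficulty, drift = drift),
            class = "block_spec")
}

#' Task configuration
#'
#' The default configuration matches the deployed first-play game: an 80:20
#' transition structure and 200 trials split into two 100-trial blocks, the
#' first easy, the second medium. Default hit rates are the deployed blocks'
#' average hit rates (easy 52%, medium 45%); the hard level existed only in
#' free play with no published rate, so 30% is this package's choice.
#'
#' @param p_common Common-transition probability in `(0.5, 1]` (0.8 or 0.7 in
#'   the deployed variants).
#' @param blocks List of [block_spec()] objects.
#' @param hit_rates Named vector mapping difficulty to the per-trial hit
#'   probability (given a good ball), all in `[0, 1]`. Hitting is modelled as
#'   a pure Bernoulli draw; aiming skill is not simulated.
#' @param miss_rate Probability a trial is recorded as missed (contamination
#'   knob for exclusion testing; default 0).
#' @return A `task_config` object.
#' @export
task_config <- function(p_common = 0.8,
                        blocks = list(
                          block_spec(100L, "easy"),
                          block_spec(100L, "medium")
                        ),
                        hit_rates = c(easy = 0.52, medium = 0.45, hard = 0.30),
                        miss_rate = 0) {
  if (!(p_common > 0.5 && p_common <= 1)) stop("p_common must be in (0.5, 1]")
  if (!length(blocks) || !all(vapply(blocks, inherits, TRUE, "block_spec"))) {
    stop("blocks must be a non-empty list of block_spec objects")
  }
  if (any(hit_rates < 0 | hit_rates > 1)) stop("hit_rates must be in [0, 1]")
  if (miss_rate < 0 || miss_rate > 1) stop("miss_rate must be in [0, 1]")
  diffs <- unique(vapply(blocks, `[[`, "", "difficulty"))
  if (!all(diffs %in% names(hit_rates))) {
    stop("hit_rates must cover every difficulty used by the blocks")
  }
  structure(list(p_common = p_common, blocks = blocks, hit_rates = hit_rates,
                 miss_rate = miss_rate),
            class = "task_config")
}

#' @export
print.task_config <- function(x, ...) {
  n <- sum(vapply(x$blocks, `[[`, 1L, "n_trials"))
  cat(sprintf("<task_config> p_common = %.2f, %d blocks, %d trials, miss_rate = %.2f\n",
              x$p_common, length(x$blocks), n, x$miss_rate))
  invisible(x)
}

#' Simulate one session of the task for one agent
#'
#' Per non-missed trial: the agent chooses a container; the transition is
#' common with probability `p_common`; the outcome colour is the chosen
#' container's majority colour iff the transition is common; reward is
#' Bernoulli in the current value of that colour's drift; given a reward, a
#' diamond hit is Bernoulli in the block difficulty's hit rate; the agent is
#' then updated. Missed trials (injected at `miss_rate`) record no choice,
#' transition, or outcome and do not update the agent.
#'
#' @param agent An agent from [hybrid_agent()] or [degenerate_agent()].
#' @param config A [task_config()].
#' @param seed Optional integer seed (`NULL` = current RNG stream). The full
#'   log is reproducible given (agent, config, seed).
#' @param subject,session Identifiers stamped into the log.
#' @return A `data.frame` of trial records with columns `subject`, `session`,
#'   `block`, `trial` (0-based within session), `choice`, `transition`,
#'   `outcome_colour`, `reward`, `hit`, `difficulty`, `missed`.
#' @export
simulate_session <- function(agent, config = task_config(), seed = NULL,
                             subject = "s01", session = 1L) {
  if (!inherits(agent, "twostep_agent")) stop("agent must be a twostep_agent")
  if (!inherits(config, "task_config")) stop("config must be a task_config")
  if (!is.null(seed)) set.seed(seed)

  n_total <- sum(vapply(config$blocks, `[[`, 1L, "n_trials"))
  choice <- character(n_total); transition <- character(n_total)
  colour <- character(n_total); reward <- integer(n_total)
  hit <- integer(n_total); missed <- logical(n_total)
  blk <- integer(n_total); diffs <- character(n_total)

  state <- agent_init_state(agent)
  i <- 0L
  for (b in seq_along(config$blocks)) {
    spec <- config$blocks[[b]]
    drift <- resolve_drift(spec$drift, spec$n_trials)
    hr <- config$hit_rates[[spec$difficulty]]
    for (t in seq_len(spec$n_trials)) {
      i <- i + 1L
      blk[i] <- b
      diffs[i] <- spec$difficulty
      if (config$miss_rate > 0 && stats::runif(1) < config$miss_rate) {
        missed[i] <- TRUE
        choice[i] <- NA_character_; transition[i] <- NA_character_
        colour[i] <- NA_character_; reward[i] <- NA_integer_; hit[i] <- NA_integer_
        next
      }
      ch <- agent_choose(agent, state, config$p_common)
      if (!ch %in% c("left", "right")) {
        stop("agent returned an invalid choice; protocol error")
      }
      common <- stats::runif(1) < config$p_common
      oc <- if (common) majority_colour(ch) else minority_colour(ch)
      q <- if (oc == "purple") drift$q_purple[t] else drift$q_pink[t]
      r <- as.integer(stats::runif(1) < q)
      h <- if (r == 1L) as.integer(stats::runif(1) < hr) else 0L
      choice[i] <- ch
      transition[i] <- if (common) "common" else "rare"
      colour[i] <- oc; reward[i] <- r; hit[i] <- h
      state <- agent_update(agent, state, ch, oc, r, h)
    }
  }
  data.frame(
    subject = subject, session = as.integer(session), block = blk,
    trial = seq_len(n_total) - 1L, choice = choice, transition = transition,
    outcome_colour = colour, reward = reward, hit = hit,
    difficulty = diffs, missed = missed,
    stringsAsFactors = FALSE
  )
}

#' Simulate a cohort of agents
#'
#' One session per agent, with per-subject seeds drawn from the master seed so
#' the whole cohort is reproducible.
#'
#' @param agents List of agents; names (or `sprintf("s%04d", i)`) become
#'   subject identifiers.
#' @param config A [task_config()].
#' @param seed Master integer seed.
#' @param session Session number stamped on every log.
#' @return A single `data.frame` of trial records (rbind of sessions).
#' @export
simulate_cohort <- function(agents, config = task_config(), seed = 1L,
                            session = 1L) {
  if (!length(agents)) stop("agents must be non-empty")
  set.seed(seed)
  ids <- names(agents)
  if (is.null(ids)) ids <- sprintf("s%04d", seq_along(agents))
  seeds <- sample.int(.Machine$integer.max, length(agents))
  out <- vector("list", length(agents))
  for (i in seq_along(agents)) {
    out[[i]] <- simulate_session(agents[[i]], config, seed = seeds[i],
                                 subject = ids[i], session = session)
  }
  data.table::setDF(data.table::rbindlist(out))
}

trial_columns <- c("subject", "session", "block", "trial", "choice",
                   "transition", "outcome_colour", "reward", "hit",
                   "difficulty", "missed")

#' Write / read trial logs as CSV
#'
#' CSV with exactly the trial-record columns; choice/transition/colour as
#' lower-case strings; missing fields (missed trials) as empty cells.
#'
#' @param trials Trial-record `data.frame`.
#' @param path File path.
#' @return `write_trials` returns `path` invisibly; `read_trials` returns the
#'   trial `data.frame`.
#' @export
write_trials <- function(trials, path) {
  stopifnot(all(trial_columns %in% names(trials)))
  data.table::fwrite(trials[, trial_columns], path, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  dt <- data.table::fread(
    path, na.strings = "",
    colClasses = list(character = c("subject", "choice", "transition",
                                    "outcome_colour", "difficulty"),
                      integer = c("session", "block", "trial", "reward", "hit"),
                      logical = "missed")
  )
  stopifnot(all(trial_columns %in% names(dt)))
  data.table::setDF(dt[, trial_columns, with = FALSE])
}
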