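# Cohort builders shared across tests. All draw from the caller's RNG state
# unless a seed is passed, so tests stay reproducible under set.seed.

make_hybrid_cohort <- function(n, w, n_trials = 200L, beta_temp = 5,
                               alpha = 0.5, stickiness = 0.2, seed = 1L,
                               p_common = 0.8, prefix = "s") {
  blocks <- if (n_trials == 200L) {
    list(block_spec(100L, "easy"), block_spec(100L, "medium"))
  } else {
    list(block_spec(n_trials, "easy"))
  }
  config <- task_config(p_common = p_common, blocks = blocks)
  ws <- if (length(w) == 1L) rep(w, n) else w
  agents <- lapply(seq_len(n), function(i) {
    hybrid_agent(w = ws[i], alpha = alpha, beta_temp = beta_temp,
                 stickiness = stickiness)
  })
  names(agents) <- sprintf("%s%04d", prefix, seq_len(n))
  simulate_cohort(agents, config, seed = seed)
}

make_degenerate_cohort <- function(n, kind, n_trials = 200L, seed = 1L,
                                   prefix = "s") {
  config <- task_config(blocks = list(block_spec(n_trials, "easy")))
  agents <- lapply(seq_len(n), function(i) degenerate_agent(kind))
  names(agents) <- sprintf("%s%04d", prefix, seq_len(n))
  simulate_cohort(agents, config, seed = seed)
}

# Deterministic 10-subject exclusion fixture: subjects 1-7 clean, 8 misses
# 21/100 trials, 9 chooses left 96/100 times, 10 misses 30/100.
make_exclusion_fixture <- function() {
  mk <- function(id, n_miss = 0L, n_left = 50L) {
    n <- 100L
    missed <- rep(FALSE, n)
    if (n_miss > 0) missed[seq_len(n_miss)] <- TRUE
    choice <- rep(NA_character_, n)
    live <- which(!missed)
    n_live <- length(live)
    nl <- min(n_left, n_live)
    choice[live] <- c(rep("left", nl), rep("right", n_live - nl))
    data.frame(
      subject = id, session = 1L, block = 1L, trial = 0:(n - 1L),
      choice = choice,
      transition = ifelse(missed, NA_character_, "common"),
      outcome_colour = ifelse(missed, NA_character_,
                              ifelse(choice == "left", "purple", "pink")),
      reward = ifelse(missed, NA_integer_, 1L),
      hit = ifelse(missed, NA_integer_, 0L),
      difficulty = "easy", missed = missed, stringsAsFactors = FALSE
    )
  }
  rbind(
    do.call(rbind, lapply(1:7, function(i) mk(sprintf("clean%02d", i)))),
    mk("miss21", n_miss = 21L),
    mk("left96", n_left = 96L),
    mk("miss30", n_miss = 30L)
  )
}
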