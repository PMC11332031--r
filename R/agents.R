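#' Hybrid model-based / model-free agent
#'
#' The community-standard generative stand-in for a human player of a
#' single-choice two-step task. On each trial the agent mixes a model-based
#' valuation (propagating learned colour values through the displayed
#' transition structure) with a model-free container value, and samples its
#' choice from a softmax with an additive choice-repetition (stickiness)
#' bonus.
#'
#' Valuation: `Q_mb(a) = p * v(majority colour of a) + (1 - p) * v(minority)`
#' with `p = p_common_belief`; `Q_net = w * Q_mb + (1 - w) * q_mf`;
#' `P(left) = plogis(beta_temp * (Q_net(left) - Q_net(right)) +
#' stickiness * rep)` where `rep` is +1/-1/0 for a previous left/right/no
#' choice. Because the transition structure is displayed on-screen in the
#' gamified task, `p_common_belief` defaults to the task's true `p_common`.
#'
#' There is no second choice stage, so the classic eligibility-trace
#' parameter is dropped, and one learning rate is shared by the model-free
#' container values and the colour values (both update from the same binary
#' reward).
#'
#' @param w Model-based weight in `[0, 1]`.
#' @param alpha Learning rate in `(0, 1]`.
#' @param beta_temp Inverse temperature (>= 0, finite).
#' @param stickiness Additive choice-repetition bonus (any real).
#' @param p_common_belief Transition probability used in model-based
#'   valuation; `NULL` (default) means "use the task's true p_common".
#' @param hit_distraction Multiplier in `[0, 1]` applied to `alpha` on trials
#'   where the secondary reward (diamond hit) occurred, emulating hits
#'   interrupting learning. 1 (default) disables the mechanism.
#' @return An agent object usable with [simulate_session()].
#' @export
hybrid_agent <- function(w = 0.5, alpha = 0.5, beta_temp = 5, stickiness = 0,
                         p_common_belief = NULL, hit_distraction = 1) {
  if (w < 0 || w > 1) stop("w must be in [0, 1]")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (!is.finite(beta_temp) || beta_temp < 0) stop("beta_temp must be finite and >= 0")
  if (!is.finite(stickiness)) stop("stickiness must be finite")
  if (hit_distraction < 0 || hit_distraction > 1) {
    stop("hit_distraction must be in [0, 1]")
  }
  structure(
    list(w = w, alpha = alpha, beta_temp = beta_temp, stickiness = stickiness,
         p_common_belief = p_common_belief, hit_distraction = hit_distraction),
    class = c("hybrid_agent", "twostep_agent")
  )
}

#' Degenerate agents for calibration and exclusion testing
#'
#' * `uniform_random`: chooses left/right with probability 0.5, ignoring
#'   history (null agent; its stay behaviour carries no reward or transition
#'   signal).
#' * `fixed_side`: always chooses one container (mirrors the perseverative
#'   responders targeted by the same-choice exclusion rule).
#' * `win_stay_lose_shift`: repeats its previous choice after a reward,
#'   switches after a non-reward (purely model-free heuristic).
#'
#' @param kind One of `"uniform_random"`, `"fixed_side"`,
#'   `"win_stay_lose_shift"`.
#' @param side For `fixed_side`, which container (`"left"` or `"right"`).
#' @return An agent object usable with [simulate_session()].
#' @export
degenerate_agent <- function(kind = c("uniform_random", "fixed_side",
                                      "win_stay_lose_shift"),
                             side = "left") {
  kind <- match.arg(kind)
  if (!side %in% c("left", "right")) stop("side must be 'left' or 'right'")
  structure(list(kind = kind, side = side),
            class = c("degenerate_agent", "twostep_agent"))
}

# Container -> majority colour mapping: the left container holds mostly
# purple balls, the right mostly pink.
majority_colour <- function(choice) ifelse(choice == "left", "purple", "pink")
minority_colour <- function(choice) ifelse(choice == "left", "pink", "purple")

#' Initial agent state
#'
#' Values start at 0.5 (unbiased for Bernoulli rewards) with no previous
#' choice.
#'
#' @param agent An agent object.
#' @return A state list with `q_mf`, `v_colour`, `last_choice`, `last_reward`.
#' @export
agent_init_state <- function(agent) {
  list(q_mf = c(left = 0.5, right = 0.5),
       v_colour = c(purple = 0.5, pink = 0.5),
       last_choice = NA_character_,
       last_reward = NA_real_)
}

#' Probability that the agent chooses the left container
#'
#' @param agent An agent object.
#' @param state State from [agent_init_state()] / [agent_update()].
#' @param p_common The task's true common-transition probability (used when
#'   the agent has no explicit `p_common_belief`).
#' @return `P(left)` in `[0, 1]`.
#' @export
agent_choice_prob <- function(agent, state, p_common = 0.8) {
  UseMethod("agent_choice_prob")
}

#' @export
agent_choice_prob.hybrid_agent <- function(agent, state, p_common = 0.8) {
  p <- agent$p_common_belief %||% p_common
  v <- state$v_colour
  q_mb <- c(left = p * v[["purple"]] + (1 - p) * v[["pink"]],
            right = p * v[["pink"]] + (1 - p) * v[["purple"]])
  q_net <- agent$w * q_mb + (1 - agent$w) * state$q_mf
  rep_code <- if (is.na(state$last_choice)) 0 else if (state$last_choice == "left") 1 else -1
  stats::plogis(agent$beta_temp * (q_net[["left"]] - q_net[["right"]]) +
                  agent$stickiness * rep_code)
}

#' @export
agent_choice_prob.degenerate_agent <- function(agent, state, p_common = 0.8) {
  switch(agent$kind,
    uniform_random = 0.5,
    fixed_side = if (agent$side == "left") 1 else 0,
    win_stay_lose_shift = {
      if (is.na(state$last_choice)) 0.5
      else {
        stay <- !is.na(state$last_reward) && state$last_reward == 1
        want <- if (stay) state$last_choice else
          if (state$last_choice == "left") "right" else "left"
        if (want == "left") 1 else 0
      }
    }
  )
}

#' Sample the agent's choice
#'
#' @inheritParams agent_choice_prob
#' @return `"left"` or `"right"`, drawn from the current RNG stream.
#' @export
agent_choose <- function(agent, state, p_common = 0.8) {
  p_left <- agent_choice_prob(agent, state, p_common)
  if (stats::runif(1) < p_left) "left" else "right"
}

#' Update the agent after a (non-missed) trial
#'
#' Delta-rule updates: `v(outcome_colour) += alpha * (reward - v)` and
#' `q_mf(choice) += alpha * (reward - q_mf)`; other entries unchanged;
#' `last_choice` is set. When the agent has `hit_distraction < 1` and the
#' trial produced a diamond hit, the effective learning rate for that trial
#' is `alpha * hit_distraction`.
#'
#' @param agent An agent object.
#' @param state Current state.
#' @param choice `"left"` or `"right"`.
#' @param outcome_colour `"purple"` or `"pink"`.
#' @param reward 0 or 1.
#' @param hit 0 or 1 (secondary reward on this trial).
#' @return The updated state.
#' @export
agent_update <- function(agent, state, choice, outcome_colour, reward,
                         hit = 0) {
  UseMethod("agent_update")
}

#' @export
agent_update.hybrid_agent <- function(agent, state, choice, outcome_colour,
                                      reward, hit = 0) {
  a <- agent$alpha
  if (!is.na(hit) && hit == 1) a <- a * agent$hit_distraction
  state$v_colour[[outcome_colour]] <-
    state$v_colour[[outcome_colour]] + a * (reward - state$v_colour[[outcome_colour]])
  state$q_mf[[choice]] <- state$q_mf[[choice]] + a * (reward - state$q_mf[[choice]])
  state$last_choice <- choice
  state$last_reward <- reward
  state
}

#' @export
agent_update.degenerate_agent <- function(agent, state, choice, outcome_colour,
                                          reward, hit = 0) {
  state$last_choice <- choice
  state$last_reward <- reward
  state
}

#' @export
print.twostep_agent <- function(x, ...) {
  if (inherits(x, "hybrid_agent")) {
    cat(sprintf(
      "<hybrid_agent> w = %.2f, alpha = %.2f, beta = %.2f, stickiness = %.2f\n",
      x$w, x$alpha, x$beta_temp, x$stickiness))
  } else {
    cat(sprintf("<degenerate_agent> kind = %s\n", x$kind))
  }
  invisible(x)
}
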