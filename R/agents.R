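#' @title Subject-side strategies
#' @description
#' The strategies a player can follow in iterated matching pennies: the Nash
#' random player, Tit-for-Tat (copy the opponent's previous action),
#' win-stay/lose-switch (WSLS, the XNOR of previous reward and previous own
#' action), a graded stochastic WSLS, a softmax reinforcement learner, general
#' l-step Markov policy tables, and a mid-session strategy switcher. All
#' strategies consume a uniform interface: the recent trial history plus a
#' reproducible random stream.
#' @name agents
NULL

.AGENT_KINDS <- c("random", "tft", "wsls", "stochastic_wsls", "softmax_rl",
                  "markov_table", "switch")

#' Agent specification
#'
#' @param kind One of `"random"` (Bernoulli, param `p_right`), `"tft"`,
#'   `"wsls"`, `"stochastic_wsls"` (params `p_stay_win`, `p_switch_lose`),
#'   `"softmax_rl"` (params `beta`, `learning_rate`, `q0`), `"markov_table"`
#'   (params `variables`, `table`), or `"switch"` (params `first`, `second`,
#'   `at`).
#' @param order Memory depth l (trials of history the strategy reads);
#'   defaulted per kind, at most 4 for table agents.
#' @param params Strategy-specific parameter list (see `kind`).
#' @param seed Optional seed recorded with the spec (session-level seeding is
#'   handled by [simulate_session()]).
#' @return An object of class `agent_spec`.
#' @examples
#' agent_spec("wsls")
#' agent_spec("stochastic_wsls", params = list(p_stay_win = 0.8, p_switch_lose = 0.8))
#' @export
agent_spec <- function(kind, order = NULL, params = list(), seed = NULL) {
  kind <- match.arg(kind, .AGENT_KINDS)
  if (is.null(order)) {
    order <- switch(kind,
                    random = 0L, tft = 1L, wsls = 1L, stochastic_wsls = 1L,
                    softmax_rl = 1L, markov_table = NULL, switch = NA_integer_)
    if (kind == "markov_table") {
      stop("markov_table agents must declare their order")
    }
  }
  order <- as.integer(order)
  if (kind == "markov_table" && (is.na(order) || order < 0L || order > 4L)) {
    stop("table agent order must be between 0 and 4")
  }
  for (pn in c("p_right", "p_stay_win", "p_switch_lose")) {
    if (!is.null(params[[pn]]) &&
        (params[[pn]] < 0 || params[[pn]] > 1)) {
      stop(pn, " must lie in [0, 1]")
    }
  }
  if (kind == "markov_table") {
    if (is.null(params$variables) || is.null(params$table)) {
      stop("markov_table agents need params$variables and params$table")
    }
    if (!all(params$variables %in% c("subject", "opponent", "reward"))) {
      stop("markov_table variables must be among subject, opponent, reward")
    }
    if (any(params$table < 0 | params$table > 1)) {
      stop("policy probabilities must lie in [0, 1]")
    }
  }
  if (kind == "switch") {
    if (!inherits(params$first, "agent_spec") || !inherits(params$second, "agent_spec")) {
      stop("switch agents need params$first and params$second agent_specs")
    }
    if (is.null(params$at) || params$at < 1) stop("switch agents need params$at >= 1")
  }
  structure(list(kind = kind, order = order, params = params, seed = seed),
            class = "agent_spec")
}

#' @export
print.agent_spec <- function(x, ...) {
  cat("agent_spec:", x$kind, "(order", x$order, ")\n")
  invisible(x)
}

#' Tit-for-Tat choice rule
#'
#' Copies the opponent's previous action unchanged.
#'
#' @param prev_opponent_action The opponent's action on the previous trial.
#' @return The action to play next.
#' @export
tft_choice <- function(prev_opponent_action) {
  bit_action(action_bit(prev_opponent_action))
}

#' Win-stay/lose-switch choice rule
#'
#' Repeat the previous own action after a reward, switch after a loss: the
#' XNOR of the previous reward bit and the previous own-action bit. Under the
#' matching-pennies reward gate this rule coincides with Tit-for-Tat.
#'
#' @param prev_reward Previous reward (0/1).
#' @param prev_own_action Previous own action label.
#' @return The action to play next.
#' @export
wsls_choice <- function(prev_reward, prev_own_action) {
  if (!all(prev_reward %in% c(0L, 1L))) stop("reward must be 0 or 1")
  b <- action_bit(prev_own_action)
  bit_action(ifelse(prev_reward == 1L, b, 1L - b))
}

#' Stochastic win-stay/lose-switch
#'
#' A graded WSLS: after a win, stay with probability `p_stay_win`; after a
#' loss, switch with probability `p_switch_lose`. Both probabilities 1
#' reproduce [wsls_choice()] exactly; both 0.5 is a fair coin.
#'
#' @inheritParams wsls_choice
#' @param p_stay_win,p_switch_lose Probabilities in \[0, 1\].
#' @param rng An [rng_stream()].
#' @return The action to play next.
#' @export
stochastic_wsls_choice <- function(prev_reward, prev_own_action,
                                   p_stay_win, p_switch_lose, rng) {
  if (p_stay_win < 0 || p_stay_win > 1 || p_switch_lose < 0 || p_switch_lose > 1) {
    stop("probabilities must lie in [0, 1]")
  }
  if (!prev_reward %in% c(0L, 1L)) stop("reward must be 0 or 1")
  p_stay <- if (prev_reward == 1L) p_stay_win else 1 - p_switch_lose
  b <- action_bit(prev_own_action)
  if (rng_unif(rng) < p_stay) bit_action(b) else bit_action(1L - b)
}

#' Reinforcement-learner state
#'
#' Value estimates for the two targets together with the softmax
#' inverse-temperature `beta` and the Rescorla-Wagner step size.
#'
#' @param q_left,q_right Initial value estimates Q(L), Q(R).
#' @param beta Inverse temperature (>= 0); 0 gives indifferent choice.
#' @param learning_rate Update step in (0, 1].
#' @return An object of class `rl_state`.
#' @export
rl_state <- function(q_left = 0.5, q_right = 0.5, beta = 3, learning_rate = 0.2) {
  if (!is.finite(q_left) || !is.finite(q_right)) stop("value estimates must be finite")
  if (!is.finite(beta) || beta < 0) stop("beta must be finite and >= 0")
  if (learning_rate <= 0 || learning_rate > 1) stop("learning_rate must be in (0, 1]")
  structure(list(q_left = q_left, q_right = q_right, beta = beta,
                 learning_rate = learning_rate), class = "rl_state")
}

#' Softmax choice probability
#'
#' P(R) = exp(beta Q(R)) / (exp(beta Q(R)) + exp(beta Q(L))), computed through
#' the overflow-safe logistic of beta (Q(R) - Q(L)).
#'
#' @param state An [rl_state()].
#' @return Probability of choosing Right.
#' @examples
#' softmax_prob(rl_state(q_left = 0, q_right = 1, beta = 1))  # 1/(1+exp(-1))
#' @export
softmax_prob <- function(state) {
  stopifnot(inherits(state, "rl_state"))
  d <- state$beta * (state$q_right - state$q_left)
  1 / (1 + exp(-d))
}

#' Rescorla-Wagner value update
#'
#' Moves the chosen action's value toward the obtained reward by a fraction
#' `learning_rate`; the unchosen value is untouched.
#'
#' @param state An [rl_state()].
#' @param action The action just taken.
#' @param reward The reward obtained (0/1).
#' @return The updated `rl_state`.
#' @export
rl_update <- function(state, action, reward) {
  stopifnot(inherits(state, "rl_state"))
  if (!reward %in% c(0L, 1L)) stop("reward must be 0 or 1")
  if (action_bit(action) == 1L) {
    state$q_right <- state$q_right + state$learning_rate * (reward - state$q_right)
  } else {
    state$q_left <- state$q_left + state$learning_rate * (reward - state$q_left)
  }
  state
}

# Context key for a markov policy: the last `order` trials, oldest first, each
# reduced to the declared variables ("subject","opponent","reward" order),
# trials joined by ".". Order 0 uses the empty key "".
.mk_context <- function(history, order, variables) {
  n <- length(history$subject)
  if (order == 0L) return("")
  if (n < order) stop("history shorter than the policy order")
  idx <- (n - order + 1L):n
  toks <- rep("", order)
  if ("subject" %in% variables) toks <- paste0(toks, history$subject[idx])
  if ("opponent" %in% variables) toks <- paste0(toks, history$opponent[idx])
  if ("reward" %in% variables) toks <- paste0(toks, history$reward[idx])
  paste(toks, collapse = ".")
}

#' Build a Markov policy table
#'
#' Enumerates every context of the given depth over the declared variables and
#' fills in the probability of choosing Right from a rule function.
#'
#' @param order Memory depth l (0..4).
#' @param variables Subset of `c("subject", "opponent", "reward")` the policy
#'   conditions on.
#' @param p_right_fun Function taking a data frame of the `order` context
#'   trials (columns `subject`, `opponent`, `reward`; oldest row first) and
#'   returning the probability of choosing Right.
#' @return A policy list with elements `order`, `variables`, `table` (named
#'   probability vector), directly usable as `markov_table` agent params.
#' @examples
#' # deterministic alternation: switch own previous action
#' markov_policy(1, "subject", function(ctx) as.numeric(ctx$subject == "L"))
#' @export
markov_policy <- function(order, variables, p_right_fun) {
  order <- as.integer(order)
  stopifnot(order >= 0L, order <= 4L)
  if (order == 0L) {
    p <- p_right_fun(data.frame(subject = character(0), opponent = character(0),
                                reward = integer(0)))
    return(list(order = 0L, variables = variables, table = stats::setNames(p, "")))
  }
  combos <- expand.grid(rep(list(seq_len(4L)), order))  # 4 game-consistent triples
  triples <- data.frame(subject = c("L", "L", "R", "R"),
                        opponent = c("L", "R", "L", "R"),
                        stringsAsFactors = FALSE)
  triples$reward <- reward_gate(triples$subject, triples$opponent)
  tab <- numeric(nrow(combos))
  keys <- character(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    ctx <- triples[as.integer(combos[i, ]), , drop = FALSE]
    keys[i] <- .mk_context(list(subject = ctx$subject, opponent = ctx$opponent,
                                reward = ctx$reward), order, variables)
    tab[i] <- p_right_fun(ctx)
  }
  keep <- !duplicated(keys)  # contexts equal after variable truncation
  list(order = order, variables = variables,
       table = stats::setNames(tab[keep], keys[keep]))
}

#' Choose from a Markov policy table
#'
#' Samples Right with the probability the table assigns to the realized
#' context of the most recent `order` trials.
#'
#' @param policy A policy list (`order`, `variables`, `table`), e.g. from
#'   [markov_policy()].
#' @param history List with vectors `subject`, `opponent`, `reward` (most
#'   recent trial last); must be at least `order` long.
#' @param rng An [rng_stream()].
#' @return The sampled action label.
#' @export
markov_table_choice <- function(policy, history, rng) {
  key <- .mk_context(history, policy$order, policy$variables)
  hit <- match(key, names(policy$table))  # [[ cannot address an empty name
  if (is.na(hit)) stop("no policy entry for context '", key, "'")
  p <- policy$table[[hit]]
  bit_action(as.integer(rng_unif(rng) < p))
}

#' Initialize an agent's internal state
#'
#' @param spec An [agent_spec()].
#' @return The strategy's initial internal state (an [rl_state()] for the
#'   reinforcement learner, counters for the switcher, `NULL` otherwise).
#' @export
agent_init <- function(spec) {
  stopifnot(inherits(spec, "agent_spec"))
  switch(spec$kind,
         softmax_rl = rl_state(
           q_left = spec$params$q0 %||% 0.5,
           q_right = spec$params$q0 %||% 0.5,
           beta = spec$params$beta %||% 3,
           learning_rate = spec$params$learning_rate %||% 0.2),
         switch = list(n_seen = 0L,
                       first = agent_init(spec$params$first),
                       second = agent_init(spec$params$second)),
         NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Advance an agent by one trial
#'
#' Uniform strategy interface: dispatches to the spec's choice rule, handling
#' the first trial(s) (insufficient history) by a uniform random draw, the
#' package-wide initialization convention matching the Nash mixed strategy.
#' Deterministic given (spec, state, history, rng state).
#'
#' @param spec An [agent_spec()].
#' @param state Internal state from [agent_init()] or a previous step.
#' @param last_trials List with vectors `subject`, `opponent`, `reward` of the
#'   most recent trials (most recent last); may be empty on the first trial.
#' @param rng An [rng_stream()].
#' @return `list(action = <label>, state = <new state>)`.
#' @export
agent_step <- function(spec, state, last_trials, rng) {
  stopifnot(inherits(spec, "agent_spec"))
  n_hist <- length(last_trials$subject)
  need <- if (spec$kind == "markov_table") spec$order else
    switch(spec$kind, random = 0L, switch = 0L, 1L)
  if (spec$kind != "switch" && n_hist < need) {
    return(list(action = bit_action(as.integer(rng_unif(rng) < 0.5)), state = state))
  }
  last <- n_hist
  action <- switch(
    spec$kind,
    random = bit_action(as.integer(rng_unif(rng) < (spec$params$p_right %||% 0.5))),
    tft = tft_choice(last_trials$opponent[last]),
    wsls = wsls_choice(last_trials$reward[last], last_trials$subject[last]),
    stochastic_wsls = stochastic_wsls_choice(
      last_trials$reward[last], last_trials$subject[last],
      spec$params$p_stay_win %||% 1, spec$params$p_switch_lose %||% 1, rng),
    softmax_rl = {
      state <- rl_update(state, last_trials$subject[last], last_trials$reward[last])
      bit_action(as.integer(rng_unif(rng) < softmax_prob(state)))
    },
    markov_table = markov_table_choice(
      list(order = spec$order, variables = spec$params$variables,
           table = spec$params$table), last_trials, rng),
    switch = {
      t_now <- state$n_seen + 1L
      if (t_now < spec$params$at) {
        res <- agent_step(spec$params$first, state$first, last_trials, rng)
        state$first <- res$state
      } else {
        res <- agent_step(spec$params$second, state$second, last_trials, rng)
        state$second <- res$state
      }
      state$n_seen <- t_now
      res$action
    },
    stop("unknown strategy kind: ", spec$kind))
  list(action = action, state = state)
}
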