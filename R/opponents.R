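#' @title Adaptive computer opponents
#' @description
#' The three computer opponents the subject plays against. Algorithm 0 plays
#' the Nash mixed strategy (fair independent coin). Algorithm 1 accumulates
#' the subject's choice history and, at every trial, tests whether the
#' conditional probability of choosing Right -- given the previous n own
#' choices, n = 0..4 -- deviates from 0.5; if any realized context is
#' significantly biased it predicts the subject's next choice from the most
#' deviant such context and plays the mismatching action. Algorithm 2 adds
#' hypotheses conditioned jointly on previous (reward, choice) pairs at depths
#' 1..4, which also catches strategies (such as win-stay/lose-switch) that are
#' invisible to choice-only statistics against a fair opponent.
#' @name opponents
NULL

#' Opponent specification
#'
#' @param algorithm 0 (Nash random), 1 (choice-history exploiter) or 2
#'   (choice+reward-history exploiter).
#' @param max_order Maximum conditioning depth (0..4; reward-conditioned
#'   hypotheses use depths 1..`max_order`).
#' @param alpha Significance level of the exact binomial bias test.
#' @param min_count Minimum observations in a context before it is tested.
#' @param deterministic_counter If `TRUE`, predict the subject's modal action
#'   instead of sampling the prediction from the estimated probability.
#' @param seed Optional seed recorded with the spec.
#' @return An object of class `opponent_spec`.
#' @export
opponent_spec <- function(algorithm, max_order = 4L, alpha = 0.05,
                          min_count = 10L, deterministic_counter = FALSE,
                          seed = NULL) {
  if (!algorithm %in% 0:2) stop("algorithm must be 0, 1 or 2")
  max_order <- as.integer(max_order)
  if (max_order < 0L || max_order > 4L) stop("max_order must be in 0..4")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (min_count < 1L) stop("min_count must be >= 1")
  structure(list(algorithm = as.integer(algorithm), max_order = max_order,
                 alpha = alpha, min_count = as.integer(min_count),
                 deterministic_counter = isTRUE(deterministic_counter),
                 seed = seed),
            class = "opponent_spec")
}

#' @export
print.opponent_spec <- function(x, ...) {
  cat("opponent_spec: Algorithm", x$algorithm,
      "(max_order", x$max_order, ", alpha", x$alpha, ")\n")
  invisible(x)
}

#' Algorithm 0 choice: fair independent draw
#'
#' @param rng An [rng_stream()].
#' @return An action label, Right with probability exactly 0.5, independent of
#'   any history.
#' @export
algo0_choice <- function(rng) {
  bit_action(as.integer(rng_unif(rng) < 0.5))
}

# Two-sided exact binomial p-value for H0: p = 0.5, vectorized.
# Symmetric null, so p = P(|X - n/2| >= |k - n/2|) = 2 P(X <= min(k, n-k)),
# capped at 1 (equals stats::binom.test's p-value for p = 0.5).
.binom_pval_half <- function(k, n) {
  m <- pmin(k, n - k)
  p <- 2 * stats::pbinom(m, n, 0.5)
  p[2 * m == n] <- 1
  pmin(p, 1)
}

#' Empirical conditional choice probabilities
#'
#' For every realized conditioning context of the stated depth -- the previous
#' `order` own choices, or previous (reward, choice) pairs -- estimates the
#' probability that the subject chose Right on the following trial.
#'
#' @param history A session (or data frame with columns `monkey_choice`,
#'   `reward`).
#' @param order Conditioning depth (0..4).
#' @param condition_on `"choices"` or `"choices_rewards"`.
#' @return Data frame with columns `context` (oldest-to-newest, `,`-joined;
#'   reward-conditioned symbols are `<reward><choice>`), `p_hat`, `count`.
#'   Contexts never realized are absent. Counts over all contexts sum to
#'   `nrow(history) - order`.
#' @export
estimate_conditional <- function(history, order,
                                 condition_on = c("choices", "choices_rewards")) {
  condition_on <- match.arg(condition_on)
  order <- as.integer(order)
  if (order < 0L || order > 4L) stop("order must be in 0..4")
  if (condition_on == "choices_rewards" && order < 1L) {
    stop("reward-conditioned hypotheses need order >= 1")
  }
  n <- nrow(history)
  if (is.null(n) || n <= order) {
    return(data.frame(context = character(0), p_hat = numeric(0),
                      count = integer(0), stringsAsFactors = FALSE))
  }
  b <- as.integer(history$monkey_choice == "R")
  toks <- if (condition_on == "choices") history$monkey_choice else
    paste0(history$reward, history$monkey_choice)
  if (order == 0L) {
    ctx <- rep("", n)
    outcome <- b
  } else {
    em <- embed(toks, order + 1L)           # row t-order: (tok_t, ..., tok_{t-order})
    ctx <- do.call(paste, c(lapply(rev(seq_len(order) + 1L), function(j) em[, j]),
                            sep = ","))     # oldest first
    outcome <- b[(order + 1L):n]
  }
  cnt <- tapply(outcome, ctx, length)
  ph <- tapply(outcome, ctx, mean)
  data.frame(context = names(cnt), p_hat = as.numeric(ph),
             count = as.integer(cnt), row.names = NULL, stringsAsFactors = FALSE)
}

#' Test the per-context equal-choice hypotheses
#'
#' Runs a two-sided exact binomial test of P(Right) = 0.5 for every realized
#' context with at least `min_count` observations, at every depth 0..
#' `max_order` over the choice-history variable set and (for the
#' choice+reward set) depths 1..`max_order`.
#'
#' @param history A session (or compatible data frame); may be empty.
#' @param spec An [opponent_spec()] providing `max_order`, `alpha`,
#'   `min_count`.
#' @param variables Which hypothesis families to test.
#' @return Data frame with one row per (variable set, order, context):
#'   columns `set`, `order`, `context`, `p_hat`, `count`, `p_value`,
#'   `significant`.
#' @export
test_bias_hypotheses <- function(history, spec,
                                 variables = c("choices", "choices_rewards")) {
  variables <- match.arg(variables, several.ok = TRUE)
  out <- list()
  for (set in variables) {
    orders <- if (set == "choices") 0:spec$max_order else
      seq_len(spec$max_order)
    for (k in orders) {
      ec <- estimate_conditional(history, k, set)
      if (nrow(ec) == 0L) next
      ec <- ec[ec$count >= spec$min_count, , drop = FALSE]
      if (nrow(ec) == 0L) next
      pv <- .binom_pval_half(round(ec$p_hat * ec$count), ec$count)
      out[[length(out) + 1L]] <- data.frame(
        set = set, order = k, context = ec$context, p_hat = ec$p_hat,
        count = ec$count, p_value = pv,
        significant = pv < spec$alpha, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(set = character(0), order = integer(0),
                      context = character(0), p_hat = numeric(0),
                      count = integer(0), p_value = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# ---- incremental opponent state (hot path of the session loop) -------------
#
# Counts are kept per order as flat vectors indexed by a rolling context code:
# choice contexts in base 2 over the last k choice bits, reward contexts in
# base 4 over the last k (reward, choice) symbols. Codes update in O(1) per
# trial; the per-trial decision looks only at the currently realized context
# of each order (the only contexts informative about the next choice).

.opp_new <- function(spec) {
  st <- new.env(parent = emptyenv())
  st$spec <- spec
  st$t <- 0L
  ko <- spec$max_order
  st$cn <- lapply(0:ko, function(k) integer(2^k))  # totals per choice context
  st$cr <- lapply(0:ko, function(k) integer(2^k))  # Rights per choice context
  st$ctx_c <- integer(ko + 1L)                     # rolling codes, index k+1
  if (spec$algorithm == 2L && ko >= 1L) {
    st$un <- lapply(seq_len(ko), function(k) integer(4^k))
    st$ur <- lapply(seq_len(ko), function(k) integer(4^k))
    st$ctx_u <- integer(ko)
  }
  st
}

.opp_observe <- function(st, subject_bit, reward) {
  spec <- st$spec
  ko <- spec$max_order
  for (k in 0:ko) {
    if (st$t >= k) {
      i <- st$ctx_c[k + 1L] + 1L
      st$cn[[k + 1L]][i] <- st$cn[[k + 1L]][i] + 1L
      st$cr[[k + 1L]][i] <- st$cr[[k + 1L]][i] + subject_bit
    }
  }
  if (spec$algorithm == 2L && ko >= 1L) {
    for (k in seq_len(ko)) {
      if (st$t >= k) {
        i <- st$ctx_u[k] + 1L
        st$un[[k]][i] <- st$un[[k]][i] + 1L
        st$ur[[k]][i] <- st$ur[[k]][i] + subject_bit
      }
    }
    sym <- reward * 2L + subject_bit
    for (k in seq_len(ko)) {
      st$ctx_u[k] <- (st$ctx_u[k] * 4L + sym) %% 4L^k
    }
  }
  for (k in seq_len(ko)) {
    st$ctx_c[k + 1L] <- (st$ctx_c[k + 1L] * 2L + subject_bit) %% 2L^k
  }
  st$t <- st$t + 1L
  invisible(st)
}

# Decide the computer's next action bit given the accumulated statistics.
.opp_choose <- function(st, rng) {
  spec <- st$spec
  if (spec$algorithm == 0L) {
    return(as.integer(rng_unif(rng) < 0.5))
  }
  best_dev <- -1
  best_phat <- NA_real_
  ko <- spec$max_order
  for (k in 0:ko) {                       # lowest order wins ties
    if (st$t < k) next
    i <- st$ctx_c[k + 1L] + 1L
    n <- st$cn[[k + 1L]][i]
    if (n >= spec$min_count) {
      r <- st$cr[[k + 1L]][i]
      if (.binom_pval_half(r, n) < spec$alpha) {
        dev <- abs(r / n - 0.5)
        if (dev > best_dev + 1e-12) {
          best_dev <- dev
          best_phat <- r / n
        }
      }
    }
    if (spec$algorithm == 2L && k >= 1L) {  # choice set precedes reward set
      i <- st$ctx_u[k] + 1L
      n <- st$un[[k]][i]
      if (n >= spec$min_count) {
        r <- st$ur[[k]][i]
        if (.binom_pval_half(r, n) < spec$alpha) {
          dev <- abs(r / n - 0.5)
          if (dev > best_dev + 1e-12) {
            best_dev <- dev
            best_phat <- r / n
          }
        }
      }
    }
  }
  if (is.na(best_phat)) {
    return(as.integer(rng_unif(rng) < 0.5))
  }
  predicted <- if (spec$deterministic_counter) {
    as.integer(best_phat > 0.5)
  } else {
    as.integer(rng_unif(rng) < best_phat)
  }
  1L - predicted                           # mismatch denies the subject reward
}

# Replay a recorded history into a fresh opponent state.
.opp_replay <- function(history, spec) {
  st <- .opp_new(spec)
  if (!is.null(history) && nrow(history) > 0L) {
    b <- as.integer(history$monkey_choice == "R")
    u <- as.integer(history$reward)
    for (t in seq_along(b)) .opp_observe(st, b[t], u[t])
  }
  st
}

#' Algorithm 1 / Algorithm 2 choice from a recorded history
#'
#' Convenience wrappers that replay the history into the opponent's running
#' statistics and return its next choice. If no realized context shows a
#' significant bias the draw is fair; otherwise the subject's next choice is
#' predicted from the most deviant significantly biased realized context and
#' the computer plays the mismatching action.
#'
#' @param history A session (or compatible data frame) of past trials.
#' @param spec An [opponent_spec()] with the matching `algorithm`.
#' @param rng An [rng_stream()].
#' @return An action label.
#' @export
algo1_choice <- function(history, spec, rng) {
  if (spec$algorithm != 1L) stop("spec$algorithm must be 1")
  bit_action(.opp_choose(.opp_replay(history, spec), rng))
}

#' @rdname algo1_choice
#' @export
algo2_choice <- function(history, spec, rng) {
  if (spec$algorithm != 2L) stop("spec$algorithm must be 2")
  bit_action(.opp_choose(.opp_replay(history, spec), rng))
}
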