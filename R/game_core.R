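#' @title Matching-pennies game logic
#' @description
#' The matching-pennies game is a zero-sum 2x2 game: the matcher (here, the
#' subject) is rewarded when both players pick the same target, the mismatcher
#' (the computer) when they differ. Actions are labelled `"L"` and `"R"` with
#' the fixed bit encoding L = 0, R = 1 used throughout the package; the reward
#' rule is then the XNOR gate on the two action bits.
#' @name game_core
NULL

# Canonical action labels; bit encoding L=0, R=1 is fixed package-wide.
.ACTIONS <- c("L", "R")

#' Action labels and bit encoding
#'
#' @return `actions()` returns the two action labels, in bit order (L = 0,
#'   R = 1).
#' @export
actions <- function() .ACTIONS

#' @rdname actions
#' @param action Character vector of action labels (`"L"`/`"R"`).
#' @return `action_bit()` returns the integer bit(s) of the given label(s).
#' @export
action_bit <- function(action) {
  b <- match(action, .ACTIONS) - 1L
  if (anyNA(b)) stop("invalid action label: ", paste(unique(action[is.na(b)]), collapse = ", "))
  b
}

#' @rdname actions
#' @param bit Integer vector of 0/1 bits.
#' @return `bit_action()` returns the action label(s) for the given bit(s).
#' @export
bit_action <- function(bit) {
  if (!all(bit %in% c(0L, 1L))) stop("action bit must be 0 or 1")
  .ACTIONS[bit + 1L]
}

#' Matching-pennies payoff
#'
#' The subject (matcher) receives utility 1 when the two actions match and 0
#' otherwise; the opponent receives the complement, so the stage game is
#' zero-sum over \{0, 1\} utilities.
#'
#' @param subject_action,opponent_action Action labels (`"L"`/`"R"`).
#' @return Named integer vector `c(subject = , opponent = )`.
#' @examples
#' payoff("L", "L")  # subject matched: c(subject = 1, opponent = 0)
#' @export
payoff <- function(subject_action, opponent_action) {
  u <- reward_gate(subject_action, opponent_action)
  c(subject = u, opponent = 1L - u)
}

#' Reward gate (XNOR of the action bits)
#'
#' The subject's reward is 1 exactly when the two actions agree, i.e. the XNOR
#' of the two action bits under the L=0/R=1 encoding. This single rule links
#' the three trial variables: u_n = XNOR(a^m_n, a^c_n).
#'
#' @param subject_action,opponent_action Action labels (vectorized).
#' @return Integer 0/1 reward(s).
#' @export
reward_gate <- function(subject_action, opponent_action) {
  as.integer(action_bit(subject_action) == action_bit(opponent_action))
}

#' @rdname reward_gate
#' @return `xor_gate()` is the negation of `reward_gate()` (the mismatcher's
#'   utility).
#' @export
xor_gate <- function(subject_action, opponent_action) {
  1L - reward_gate(subject_action, opponent_action)
}

#' Check a session's internal consistency
#'
#' Verifies that every trial satisfies the reward rule (reward equals the XNOR
#' of the action bits) and that trial indices run 1..N consecutively.
#' Violations are returned, not raised.
#'
#' @param trials A session data frame with columns `trial`, `monkey_choice`,
#'   `computer_choice`, `reward` (see [simulate_session()]).
#' @return A data frame with columns `trial` and `problem`, one row per
#'   violation; zero rows when the session is valid (including when empty).
#' @export
validate_session <- function(trials) {
  out <- data.frame(trial = integer(0), problem = character(0),
                    stringsAsFactors = FALSE)
  if (is.null(trials) || nrow(trials) == 0L) return(out)
  req <- c("trial", "monkey_choice", "computer_choice", "reward")
  miss <- setdiff(req, names(trials))
  if (length(miss)) stop("session is missing column(s): ", paste(miss, collapse = ", "))
  expected <- reward_gate(trials$monkey_choice, trials$computer_choice)
  bad <- which(trials$reward != expected)
  if (length(bad)) {
    out <- rbind(out, data.frame(
      trial = trials$trial[bad],
      problem = "reward inconsistent with actions (XNOR rule)",
      stringsAsFactors = FALSE))
  }
  gaps <- which(trials$trial != seq_len(nrow(trials)))
  if (length(gaps)) {
    out <- rbind(out, data.frame(
      trial = trials$trial[gaps],
      problem = "trial index not consecutive from 1",
      stringsAsFactors = FALSE))
  }
  out[order(out$trial), , drop = FALSE]
}
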