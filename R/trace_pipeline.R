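#' @title Sliding-window information traces
#' @description
#' The analysis proper: windowed plug-in information measures between the
#' trial-n state triple S_n = (own choice, computer choice, reward) and the
#' next choice a^m_(n+1). Covers the total information I(S_n : a^m_(n+1)),
#' the three pairwise traces (active memory, reward following, opponent
#' copying), the higher-order statistic delta-I, the exact decomposition
#' identities that follow from the reward gate, the two-step memory measure
#' I(S_(n-1) : a^m_(n+1) | S_n), time-shift surrogate baselines, and
#' log-normal fits of trace value distributions.
#'
#' All traces use the same window convention: window k covers the `width`
#' state/next-choice pairs starting at trial k and slides by `step`, so a
#' one-step trace over an N-trial session has N - width values at step 1.
#' @name trace_pipeline
NULL

#' Sliding-window specification
#'
#' @param width Trials per window (default 500, the width used throughout the
#'   analysis).
#' @param step Slide increment in trials (default 1).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(width = 500L, step = 1L) {
  width <- as.integer(width)
  step <- as.integer(step)
  if (width < 2L) stop("width must be >= 2")
  if (step < 1L) stop("step must be >= 1")
  structure(list(width = width, step = step), class = "window_spec")
}

.session_bits <- function(session) {
  list(am = as.integer(session$monkey_choice == "R"),
       ac = as.integer(session$computer_choice == "R"),
       u = as.integer(session$reward))
}

# Per-window counts of a discrete code series via cumulative sums:
# one row per window, one column per symbol.
.sliding_counts <- function(code, nlev, width, step) {
  n <- length(code)
  if (n < width) stop("session too short for the window width")
  starts <- seq.int(1L, n - width + 1L, by = step)
  cs <- matrix(0, n + 1L, nlev)
  for (j in seq_len(nlev)) cs[-1L, j] <- cumsum(code == j - 1L)
  list(counts = cs[starts + width, , drop = FALSE] -
         cs[starts, , drop = FALSE],
       starts = starts)
}

# Entropy (bits) of each row of a count matrix with fixed row total `width`.
.H_rows <- function(counts, width) {
  cl <- counts
  pos <- cl > 0
  cl[pos] <- cl[pos] * log2(cl[pos])
  log2(width) - rowSums(cl) / width
}

# Marginal counts over the variables selected by `mask` (bitwise, columns of
# a 2^B-symbol joint code).
.margin_counts <- function(W, mask) {
  nlev <- ncol(W)
  grp <- bitwAnd(0:(nlev - 1L), mask)
  t(rowsum(t(W), group = grp))
}

# Windowed counts of the (a^m_n, a^c_n, u_n, a^m_(n+lag)) joint code.
# Bits: a^m_n = 1, a^c_n = 2, u_n = 4, a^m_(n+lag) = 8.
.win16 <- function(session, window, lag = 1L) {
  b <- .session_bits(session)
  n <- length(b$am)
  if (n < window$width + lag) stop("session too short for the window width")
  idx <- seq_len(n - lag)
  code <- b$am[idx] + 2L * b$ac[idx] + 4L * b$u[idx] + 8L * b$am[idx + lag]
  .sliding_counts(code, 16L, window$width, window$step)
}

.AM <- 1L; .AC <- 2L; .U <- 4L; .AP <- 8L

# All one-step window measures from the 16-symbol count matrix.
.measures16 <- function(W, width) {
  H <- function(mask) .H_rows(.margin_counts(W, mask), width)
  h_am <- H(.AM); h_ap <- H(.AP); h_u <- H(.U); h_ac <- H(.AC)
  h_s <- H(.AM + .AC + .U); h_all <- H(15L)
  h_am_ap <- H(.AM + .AP)
  h_u_ap <- H(.U + .AP)
  total <- h_s + h_ap - h_all
  memory <- h_am + h_ap - h_am_ap
  reward <- h_u + h_ap - h_u_ap
  opponent <- h_ac + h_ap - H(.AC + .AP)
  list(
    total = total, memory = memory, reward = reward, opponent = opponent,
    delta = total - memory - reward - opponent,
    te_opponent = H(.AC + .AM) + h_am_ap - H(.AC + .AM + .AP) - h_am,
    te_reward = H(.U + .AM) + h_am_ap - H(.U + .AM + .AP) - h_am,
    cmi_opponent_reward = H(.AC + .U) + h_u_ap - H(.AC + .U + .AP) - h_u,
    cmi_memory_reward = H(.AM + .U) + h_u_ap - H(.AM + .U + .AP) - h_u,
    synergy = (H(.AM + .U) + h_ap - H(.AM + .U + .AP)) - memory - reward)
}

.info_trace <- function(starts, values, measure, window, lag = 1L) {
  structure(data.frame(window_start = starts, bits = values),
            measure = measure, width = window$width, step = window$step,
            lag = lag, class = c("info_trace", "data.frame"))
}

#' @export
print.info_trace <- function(x, ...) {
  cat("info_trace '", attr(x, "measure"), "': ", nrow(x),
      " windows (width ", attr(x, "width"), ", step ", attr(x, "step"),
      "), median ", format(stats::median(x$bits), digits = 4), " bits\n",
      sep = "")
  invisible(x)
}

#' Total one-step information trace
#'
#' Windowed plug-in mutual information between the state triple S_n and the
#' subject's next choice, I(S_n : a^m_(n+1)) -- the strict upper bound on the
#' information available to the subject from the previous trial.
#'
#' @param session An `mp_session` (or data frame with the session columns).
#' @param window A [window_spec()].
#' @return An `info_trace` data frame (`window_start`, `bits`).
#' @export
total_information_trace <- function(session, window = window_spec()) {
  w <- .win16(session, window)
  m <- .measures16(w$counts, window$width)
  .info_trace(w$starts, m$total, "total", window)
}

#' Pairwise one-step information traces
#'
#' The three windowed pairwise mutual informations with the next choice:
#' active memory I(a^m_n : a^m_(n+1)), reward following I(u_n : a^m_(n+1)),
#' and opponent copying I(a^c_n : a^m_(n+1)).
#'
#' @inheritParams total_information_trace
#' @return Named list of three `info_trace`s: `memory`, `reward`, `opponent`.
#' @export
pairwise_traces <- function(session, window = window_spec()) {
  w <- .win16(session, window)
  m <- .measures16(w$counts, window$width)
  list(memory = .info_trace(w$starts, m$memory, "memory", window),
       reward = .info_trace(w$starts, m$reward, "reward", window),
       opponent = .info_trace(w$starts, m$opponent, "opponent", window))
}

#' Higher-order interaction trace (delta-I)
#'
#' The signed statistic delta-I = I(S_n : a^m_(n+1)) minus the three pairwise
#' informations: a lower bound on beyond-pairwise interaction information.
#' Positive values indicate synergy between the state variables; negative
#' values are legitimate and indicate redundancy.
#'
#' @inheritParams total_information_trace
#' @return An `info_trace` (values may be negative).
#' @export
delta_information_trace <- function(session, window = window_spec()) {
  w <- .win16(session, window)
  m <- .measures16(w$counts, window$width)
  .info_trace(w$starts, m$delta, "delta", window)
}

#' Delta-I of a single joint distribution
#'
#' Table-level counterpart of [delta_information_trace()]: total information
#' from the three state variables minus the three pairwise terms, for an
#' explicit joint table over (own choice, computer choice, reward, next
#' choice).
#'
#' @param joint A [prob_table()] over exactly four variables, in the order
#'   (own choice, computer choice, reward, next choice).
#' @return Signed delta-I in bits.
#' @export
delta_information <- function(joint) {
  stopifnot(inherits(joint, "prob_table"))
  if (length(joint$variables) != 4L) {
    stop("delta_information needs a 4-variable joint table")
  }
  v <- joint$variables
  total <- mutual_information(collapse_vars(joint, v[1:3], "state"))
  total -
    mutual_information(marginal(joint, v[c(1L, 4L)])) -
    mutual_information(marginal(joint, v[c(2L, 4L)])) -
    mutual_information(marginal(joint, v[c(3L, 4L)]))
}

#' Pair synergy of (own choice, reward) onto the next choice
#'
#' Joint information I((a^m_n, u_n) : a^m_(n+1)) together with the two
#' pairwise terms and their difference (the synergy). For a deterministic
#' win-stay/lose-switch subject with uniform independent inputs the joint
#' information is exactly 1 bit while both pairwise terms are exactly 0: the
#' whole bit lives in the interaction.
#'
#' @param x Either an `mp_session` (the empirical joint over the whole
#'   session is used) or a [prob_table()] over (own choice, reward, next
#'   choice) in that order.
#' @return List with elements `joint`, `memory`, `reward`, `synergy` (bits).
#' @export
synergy_pair <- function(x) {
  joint <- if (inherits(x, "prob_table")) {
    if (length(x$variables) != 3L) {
      stop("synergy_pair needs a 3-variable table (own choice, reward, next choice)")
    }
    x
  } else {
    n <- nrow(x)
    if (n < 2L) stop("session too short")
    empirical_dist(
      list(own = x$monkey_choice[-n], reward = x$reward[-n],
           next_choice = x$monkey_choice[-1L]),
      support = list(own = .ACTIONS, reward = c("0", "1"), next_choice = .ACTIONS))
  }
  v <- joint$variables
  jmi <- mutual_information(collapse_vars(joint, v[1:2], "inputs"))
  mem <- mutual_information(marginal(joint, v[c(1L, 3L)]))
  rew <- mutual_information(marginal(joint, v[c(2L, 3L)]))
  list(joint = jmi, memory = mem, reward = rew, synergy = jmi - mem - rew)
}

#' Exact decomposition residuals
#'
#' Because the reward is a deterministic gate of the two actions, the total
#' one-step information decomposes exactly in four ways:
#' transfer entropy from the computer's choice plus active memory; transfer
#' entropy from the reward plus active memory; information from the
#' computer's choice conditional on the reward plus the reward term; and the
#' memory conditional on the reward plus the reward term. This function
#' computes, per window, the residual of the total against each right-hand
#' side; all four must vanish (to floating-point error) on any session that
#' satisfies the reward rule, which is checked first.
#'
#' @inheritParams total_information_trace
#' @return Data frame with `window_start` and the four residual columns
#'   `r_te_opponent`, `r_te_reward`, `r_cmi_opponent`, `r_cmi_memory` (bits).
#' @export
decomposition_residuals <- function(session, window = window_spec()) {
  v <- validate_session(session)
  if (nrow(v) > 0L) {
    stop("validation error: ", v$problem[1L], " at trial ", v$trial[1L],
         " (the decomposition identities require the reward gate)")
  }
  w <- .win16(session, window)
  m <- .measures16(w$counts, window$width)
  data.frame(window_start = w$starts,
             r_te_opponent = m$total - (m$te_opponent + m$memory),
             r_te_reward = m$total - (m$te_reward + m$memory),
             r_cmi_opponent = m$total - (m$cmi_opponent_reward + m$reward),
             r_cmi_memory = m$total - (m$cmi_memory_reward + m$reward))
}

#' Two-step memory trace
#'
#' Windowed plug-in conditional mutual information between the second-to-last
#' state and the next choice, conditioning out the intermediate state:
#' I(S_(n-1) : a^m_(n+1) | S_n). Nonzero values (above the surrogate
#' baseline) indicate non-Markovian strategy: information drawn from more
#' than the most recent trial.
#'
#' @inheritParams total_information_trace
#' @param lag Lead of the future-choice series (default 1, the real measure;
#'   larger values give the time-shift surrogate).
#' @return An `info_trace` with N - width - lag values at step 1.
#' @export
two_step_trace <- function(session, window = window_spec(), lag = 1L) {
  b <- .session_bits(session)
  n <- length(b$am)
  lag <- as.integer(lag)
  if (n < window$width + lag + 1L) stop("session too short for the window width")
  s_code <- b$am + 2L * b$ac + 4L * b$u
  idx <- 2L:(n - lag)                        # n-index of the current state
  code <- s_code[idx - 1L] + 8L * s_code[idx] + 64L * b$am[idx + lag]
  sc <- .sliding_counts(code, 128L, window$width, window$step)
  H <- function(mask) .H_rows(.margin_counts(sc$counts, mask), window$width)
  cmi <- H(7L + 56L) + H(56L + 64L) - H(127L) - H(56L)
  .info_trace(sc$starts, cmi, "two_step", window, lag = lag)
}

.MEASURES_1STEP <- c("total", "memory", "reward", "opponent", "delta", "synergy")

.measure_trace <- function(session, measure, window, lag = 1L) {
  if (measure == "two_step") {
    return(two_step_trace(session, window, lag = lag))
  }
  if (!measure %in% .MEASURES_1STEP) stop("unknown measure: ", measure)
  w <- .win16(session, window, lag = lag)
  m <- .measures16(w$counts, window$width)
  .info_trace(w$starts, m[[measure]], measure, window, lag = lag)
}

#' Time-shift surrogate baseline
#'
#' Recomputes a windowed measure with the future-choice series led by `lag`
#' trials instead of 1 (for example, active memory becomes
#' I(a^m_n : a^m_(n+lag))), giving a finite-sample null level for data with
#' the same marginal statistics but no genuine one-step relationship. The
#' baseline is summarized as the mean, standard deviation and mean + 2 SD
#' threshold over windows. Note the caveat that series with strong structure
#' at the surrogate lag itself (e.g. period-2 deterministic play with lag 2)
#' make the surrogate non-null.
#'
#' @inheritParams total_information_trace
#' @param measure One of `"total"`, `"memory"`, `"reward"`, `"opponent"`,
#'   `"delta"`, `"synergy"`, `"two_step"`.
#' @param lag Time shift of the future-choice series (default 3).
#' @return An object of class `surrogate_baseline`: list with `measure`,
#'   `lag`, `mu`, `sigma`, `threshold` (mu + 2 sigma), `n_windows`.
#' @export
surrogate_baseline <- function(session, measure = "memory",
                               window = window_spec(), lag = 3L) {
  lag <- as.integer(lag)
  if (lag < 1L) stop("lag must be >= 1")
  tr <- .measure_trace(session, measure, window, lag = lag)
  mu <- mean(tr$bits)
  sigma <- stats::sd(tr$bits)
  structure(list(measure = measure, lag = lag, mu = mu, sigma = sigma,
                 threshold = mu + 2 * sigma, n_windows = nrow(tr)),
            class = "surrogate_baseline")
}

#' @export
print.surrogate_baseline <- function(x, ...) {
  cat("surrogate_baseline (", x$measure, ", lag ", x$lag, "): mu = ",
      format(x$mu, digits = 4), ", sigma = ", format(x$sigma, digits = 4),
      ", threshold mu+2sigma = ", format(x$threshold, digits = 4),
      " bits over ", x$n_windows, " windows\n", sep = "")
  invisible(x)
}

#' Maximum-likelihood log-normal fit
#'
#' Fits a log-normal distribution to a sample of positive trace values by
#' closed-form maximum likelihood (mean and MLE standard deviation of the
#' logs). Values <= 0 -- e.g. exactly-zero information windows -- are dropped
#' and counted.
#'
#' @param values Numeric vector; at least 10 strictly positive values must
#'   remain after dropping nonpositive ones, and they must not all be equal.
#' @return An object of class `lognormal_fit`: `meanlog`, `sdlog`, `n`,
#'   `n_dropped`, and standard errors `se_meanlog`, `se_sdlog`.
#' @export
fit_lognormal <- function(values) {
  x <- values[is.finite(values)]
  n_dropped <- sum(x <= 0)
  x <- x[x > 0]
  n <- length(x)
  if (n < 10L) stop("need at least 10 strictly positive values (got ", n, ")")
  lx <- log(x)
  meanlog <- mean(lx)
  sdlog <- sqrt(mean((lx - meanlog)^2))
  if (sdlog == 0) stop("all usable values are equal; log-normal scale is degenerate")
  structure(list(meanlog = meanlog, sdlog = sdlog, n = n,
                 n_dropped = n_dropped,
                 se_meanlog = sdlog / sqrt(n),
                 se_sdlog = sdlog / sqrt(2 * n)),
            class = "lognormal_fit")
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat("lognormal_fit: meanlog ", format(x$meanlog, digits = 4), " (se ",
      format(x$se_meanlog, digits = 3), "), sdlog ", format(x$sdlog, digits = 4),
      " (se ", format(x$se_sdlog, digits = 3), "), n = ", x$n,
      if (x$n_dropped > 0) paste0(" (", x$n_dropped, " nonpositive dropped)"),
      "\n", sep = "")
  invisible(x)
}

#' Per-session strategy signature
#'
#' Aggregates the pipeline's measures into a fingerprint: the median of each
#' windowed trace (total, the three pairwise terms, delta-I, pair synergy,
#' two-step memory) together with its time-shift surrogate threshold.
#' Behaviourally equivalent strategies -- Tit-for-Tat and win-stay/
#' lose-switch under the matching-pennies gate -- produce equal signatures up
#' to estimation noise.
#'
#' @inheritParams total_information_trace
#' @param surrogate_lag Lag of the surrogate baselines (default 3).
#' @return Data frame with one row per measure: `measure`, `median_bits`,
#'   `surrogate_mu`, `surrogate_threshold`.
#' @export
strategy_signature <- function(session, window = window_spec(),
                               surrogate_lag = 3L) {
  w <- .win16(session, window)
  m <- .measures16(w$counts, window$width)
  ws <- .win16(session, window, lag = surrogate_lag)
  ms <- .measures16(ws$counts, window$width)
  two <- two_step_trace(session, window)$bits
  two_s <- two_step_trace(session, window, lag = surrogate_lag)$bits
  meas <- c(.MEASURES_1STEP, "two_step")
  med <- c(vapply(.MEASURES_1STEP, function(k) stats::median(m[[k]]), 0),
           stats::median(two))
  mu <- c(vapply(.MEASURES_1STEP, function(k) mean(ms[[k]]), 0), mean(two_s))
  thr <- c(vapply(.MEASURES_1STEP,
                  function(k) mean(ms[[k]]) + 2 * stats::sd(ms[[k]]), 0),
           mean(two_s) + 2 * stats::sd(two_s))
  data.frame(measure = meas, median_bits = med, surrogate_mu = mu,
             surrogate_threshold = thr, row.names = NULL,
             stringsAsFactors = FALSE)
}
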