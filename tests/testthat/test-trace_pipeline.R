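test_that("window spec and trace indexing follow the sliding convention", {
  expect_error(window_spec(width = 1), "width")
  expect_error(window_spec(step = 0), "step")
  s <- session_wsls_algo0()
  n <- nrow(s)
  w <- window_spec(500, 1)
  expect_identical(nrow(total_information_trace(s, w)), n - 500L)
  expect_identical(nrow(two_step_trace(s, w)), n - 501L)
  w5 <- window_spec(500, 5)
  expect_identical(nrow(total_information_trace(s, w5)),
                   as.integer(floor((n - 500 - 1) / 5) + 1))
  expect_error(total_information_trace(s[1:100, ], w), "too short")
})

test_that("a WSLS session carries one bit, all of it in the opponent channel", {
  s <- session_wsls_algo0()
  tot <- total_information_trace(s)
  pw <- pairwise_traces(s)
  expect_lt(abs(stats::median(tot$bits) - 1), 0.02)
  expect_lt(abs(stats::median(pw$opponent$bits) - 1), 0.02)
  expect_lt(stats::median(pw$memory$bits), 0.02)
  expect_lt(stats::median(pw$reward$bits), 0.02)
  # pairwise components never exceed the total
  for (tr in pw) expect_true(all(tr$bits <= tot$bits + 1e-9))
  # binary ceiling and non-negativity
  expect_true(all(tot$bits >= -1e-12 & tot$bits <= 1 + 1e-9))
})

test_that("an i.i.d. random session shows no information anywhere", {
  s <- session_random_algo0()
  tot <- total_information_trace(s)
  sb <- surrogate_baseline(s, "total", lag = 3)
  expect_lt(stats::median(tot$bits), sb$threshold + 0.01)
  expect_lt(stats::median(tot$bits), 0.02)
})

test_that("delta-I separates synergy from redundancy", {
  # alternation: total and memory both 1 bit, other channels 0, delta ~ 0
  s <- session_alternate_algo0()
  d <- delta_information_trace(s)
  pw <- pairwise_traces(s)
  expect_lt(abs(stats::median(pw$memory$bits) - 1), 0.02)
  expect_lt(abs(stats::median(d$bits)), 0.02)

  # WSLS: the (own, reward) synergy is absorbed by the opponent channel
  dw <- delta_information_trace(session_wsls_algo0())
  expect_lt(abs(stats::median(dw$bits)), 0.02)

  # redundant construction: subject repeats, computer always matches;
  # memory and opponent channels each carry the same single bit -> delta = -1
  arr <- array(0, c(2, 2, 2, 2),
               dimnames = list(own = c("L", "R"), computer = c("L", "R"),
                               reward = c("0", "1"), next_choice = c("L", "R")))
  arr["L", "L", "1", "L"] <- 0.5
  arr["R", "R", "1", "R"] <- 0.5
  expect_equal(delta_information(prob_table(arr)), -1, tolerance = 1e-12)
})

test_that("synergy_pair recovers the exact XNOR decomposition", {
  sp <- synergy_pair(exact_wsls_table())
  expect_identical(sp$joint, 1)
  expect_identical(sp$memory, 0)
  expect_identical(sp$reward, 0)
  expect_identical(sp$synergy, 1)

  # random play: no information in the input pair
  expect_lt(synergy_pair(session_random_algo0())$joint, 0.005)

  # stochastic WSLS at 0.8: joint MI equals the 8-outcome enumeration value
  q <- 0.8
  arr <- array(0, c(2, 2, 2), dimnames = list(own = c("L", "R"),
                                              reward = c("0", "1"),
                                              next_choice = c("L", "R")))
  for (own in c("L", "R")) for (u in c("0", "1")) {
    stay <- wsls_choice(as.integer(u), own)
    other <- setdiff(c("L", "R"), stay)
    arr[own, u, stay] <- 0.25 * q
    arr[own, u, other] <- 0.25 * (1 - q)
  }
  sp8 <- synergy_pair(prob_table(arr))
  h_q <- -(q * log2(q) + (1 - q) * log2(1 - q))
  expect_equal(sp8$joint, 1 - h_q, tolerance = 1e-12)
  expect_equal(sp8$memory, 0, tolerance = 1e-12)
  expect_equal(sp8$reward, 0, tolerance = 1e-12)

  # and the closed-loop session estimate agrees with the analytic value
  s <- simulate_session(
    agent_spec("stochastic_wsls", params = list(p_stay_win = q, p_switch_lose = q)),
    opponent_spec(0), 10000, seed = 31)
  expect_lt(abs(synergy_pair(s)$joint - (1 - h_q)), 0.02)
})

test_that("the four decomposition identities hold exactly on valid sessions", {
  hs <- hand_session()
  r <- decomposition_residuals(hs, window_spec(width = 7))
  expect_identical(nrow(r), 1L)
  expect_lt(max(abs(as.matrix(r[, -1]))), 1e-12)

  for (s in list(session_wsls_algo0(), session_random_algo0(),
                 session_alternate_algo0())) {
    res <- decomposition_residuals(s, window_spec(500, 50))
    expect_lt(max(abs(as.matrix(res[, -1]))), 1e-10)
  }

  bad <- session_random_algo0()
  bad$reward[123] <- 1L - bad$reward[123]
  expect_error(decomposition_residuals(bad), "trial 123")
})

test_that("the two-step measure separates 1-step from 2-step strategies", {
  s1 <- session_wsls_algo0()
  ts1 <- two_step_trace(s1)
  sb1 <- surrogate_baseline(s1, "two_step", lag = 3)
  expect_gte(mean(ts1$bits < sb1$threshold), 0.95)

  s2 <- session_copy_opp2_algo0()
  ts2 <- two_step_trace(s2)
  expect_gt(stats::median(ts2$bits), 0.9)   # ~1 bit from two steps back

  # random play: window values and surrogate values overlap in location
  s3 <- session_random_algo0()
  real <- two_step_trace(s3)$bits
  surr <- two_step_trace(s3, lag = 3)$bits
  pick <- seq(1, length(real), by = 500)    # thin to near-independent windows
  wt <- stats::wilcox.test(real[pick], surr[pick])
  expect_gt(wt$p.value, 0.01)
})

test_that("surrogate baselines are null for i.i.d. play but not for period-2", {
  s <- session_random_algo0()
  for (m in c("memory", "total")) {
    sb <- surrogate_baseline(s, m, lag = 3)
    expect_gte(sb$threshold, sb$mu)
    expect_lt(sb$threshold, 0.02)
  }
  # the two-step null sits higher (12 effective degrees of freedom, not 1-3)
  sb_two <- surrogate_baseline(s, "two_step", lag = 3)
  expect_gte(sb_two$threshold, sb_two$mu)
  expect_lt(sb_two$threshold, 0.06)
  # documented caveat: alternation at the surrogate's own lag is not null
  alt <- session_alternate_algo0()
  sb2 <- surrogate_baseline(alt, "memory", lag = 2)
  expect_gt(sb2$mu, 0.9)
  expect_error(surrogate_baseline(s, "memory", lag = 0), "lag")
})

test_that("log-normal ML fitting recovers, errors and rescales correctly", {
  rng <- rng_stream(7)
  x <- stats::qlnorm(rng_unif(rng, 10000), meanlog = 0.5, sdlog = 0.3)
  fit <- fit_lognormal(x)
  expect_lt(abs(fit$meanlog - 0.5), 3 * fit$se_meanlog)
  expect_lt(abs(fit$sdlog - 0.3), 3 * fit$se_sdlog)

  # independent cross-check against MASS::fitdistr on a small sample
  y <- x[1:200]
  md <- MASS::fitdistr(y, "lognormal")
  fy <- fit_lognormal(y)
  expect_equal(fy$meanlog, unname(md$estimate["meanlog"]), tolerance = 1e-6)
  expect_equal(fy$sdlog, unname(md$estimate["sdlog"]), tolerance = 1e-6)

  # scaling by c shifts the log-location by log(c), scale untouched
  f2 <- fit_lognormal(10 * y)
  expect_equal(f2$meanlog, fy$meanlog + log(10), tolerance = 1e-12)
  expect_equal(f2$sdlog, fy$sdlog, tolerance = 1e-12)

  expect_error(fit_lognormal(rep(2, 100)), "equal")
  expect_error(fit_lognormal(c(1, 2, 3)), "at least 10")
  # nonpositive values are dropped and counted
  f3 <- fit_lognormal(c(y, 0, -1))
  expect_identical(f3$n_dropped, 2L)
  expect_identical(f3$n, 200L)
})

test_that("strategy signatures are stable across seeds", {
  sigs <- lapply(1:6, function(i) {
    s <- simulate_session(agent_spec("wsls"), opponent_spec(0), 10000,
                          seed = 200 + i)
    strategy_signature(s)$median_bits
  })
  m <- do.call(rbind, sigs)
  expect_true(all(apply(m, 2, stats::sd) < 0.02))
})
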