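# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

session_wsls_algo0 <- function() cached("wsls_algo0",
  simulate_session(agent_spec("wsls"), opponent_spec(0), 10000, seed = 101))

session_tft_algo0 <- function() cached("tft_algo0",
  simulate_session(agent_spec("tft"), opponent_spec(0), 10000, seed = 102))

session_random_algo0 <- function() cached("random_algo0",
  simulate_session(agent_spec("random"), opponent_spec(0), 10000, seed = 103))

# Deterministic alternation: switch own previous action every trial.
policy_alternate <- function() {
  markov_policy(1, "subject", function(ctx) as.numeric(ctx$subject == "L"))
}

# Deterministic repetition: repeat own previous action.
policy_stay <- function() {
  markov_policy(1, "subject", function(ctx) as.numeric(ctx$subject == "R"))
}

# Two-step copy of the opponent: play the computer's action from two trials
# back (the oldest row of the order-2 context).
policy_copy_opp2 <- function() {
  markov_policy(2, "opponent", function(ctx) as.numeric(ctx$opponent[1] == "R"))
}

session_alternate_algo0 <- function() cached("alternate_algo0",
  simulate_session(agent_spec("markov_table", order = 1, params = policy_alternate()),
                   opponent_spec(0), 10000, seed = 104))

session_copy_opp2_algo0 <- function() cached("copy_opp2_algo0",
  simulate_session(agent_spec("markov_table", order = 2, params = policy_copy_opp2()),
                   opponent_spec(0), 10000, seed = 105))

# Exact 4-outcome table over (own choice, reward, WSLS next choice) with
# uniform independent inputs.
exact_wsls_table <- function() {
  ins <- expand.grid(own = c("L", "R"), reward = c(0L, 1L),
                     stringsAsFactors = FALSE)
  nxt <- wsls_choice(ins$reward, ins$own)
  empirical_dist(
    list(own = ins$own, reward = ins$reward, next_choice = nxt),
    support = list(own = c("L", "R"), reward = c("0", "1"),
                   next_choice = c("L", "R")))
}

# Game-consistent deterministic 8-trial session (WSLS against an alternating
# computer), for hand-checkable window computations.
hand_session <- function() {
  am <- c("L", "L", "R", "R", "L", "L", "R", "R")
  ac <- c("L", "R", "L", "R", "L", "R", "L", "R")
  u <- reward_gate(am, ac)
  s <- data.frame(trial = 1:8, monkey_choice = am, computer_choice = ac,
                  reward = u, stringsAsFactors = FALSE)
  class(s) <- c("mp_session", "data.frame")
  s
}
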