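#' @title Session simulation and serialization
#' @description
#' Closes the loop between a subject-side strategy and a computer opponent to
#' produce fully reproducible synthetic sessions, emulating the behavioural
#' protocol the analysis assumes: both players commit simultaneously at each
#' trial, the opponent sees all past subject choices and rewards, and the
#' reward is the matching-pennies gate of the two actions. Sessions serialize
#' to TSV with a `#`-prefixed metadata header.
#' @name session_sim
NULL

.new_session <- function(trial, monkey_choice, computer_choice, reward,
                         agent_spec, opponent_spec, seed) {
  s <- data.frame(trial = trial, monkey_choice = monkey_choice,
                  computer_choice = computer_choice, reward = reward,
                  stringsAsFactors = FALSE)
  attr(s, "agent_spec") <- agent_spec
  attr(s, "opponent_spec") <- opponent_spec
  attr(s, "seed") <- seed
  class(s) <- c("mp_session", "data.frame")
  s
}

#' Simulate a matching-pennies session
#'
#' Plays `n_trials` rounds between an agent and an opponent. Per trial both
#' sides choose from their own history views (neither sees the other's
#' current action), the reward is the XNOR gate of the two actions, and the
#' opponent then updates its running statistics. A single master seed is
#' split into independent agent and opponent streams, so changing the agent
#' spec never perturbs the opponent's randomness at equal seeds.
#'
#' @param agent_spec An [agent_spec()].
#' @param opponent_spec An [opponent_spec()].
#' @param n_trials Number of trials (>= 1); sessions of several tens of
#'   thousands of trials run at desk scale.
#' @param seed Master seed (integer).
#' @return An `mp_session`: a data frame with columns `trial`,
#'   `monkey_choice`, `computer_choice`, `reward` and attributes
#'   `agent_spec`, `opponent_spec`, `seed`.
#' @examples
#' s <- simulate_session(agent_spec("wsls"), opponent_spec(0), 200, seed = 1)
#' mean(s$reward)
#' @export
simulate_session <- function(agent_spec, opponent_spec, n_trials, seed) {
  stopifnot(inherits(agent_spec, "agent_spec"),
            inherits(opponent_spec, "opponent_spec"))
  n_trials <- as.integer(n_trials)
  if (n_trials < 1L) stop("n_trials must be >= 1")
  arng <- rng_stream(.derive_seed(seed, 1L))
  orng <- rng_stream(.derive_seed(seed, 2L))
  astate <- agent_init(agent_spec)
  ost <- .opp_new(opponent_spec)

  am <- character(n_trials)
  ac <- character(n_trials)
  u <- integer(n_trials)
  depth <- 6L  # history slice passed to the agent (max order 4, plus slack)
  for (t in seq_len(n_trials)) {
    j0 <- max(1L, t - depth)
    lt <- if (t == 1L) {
      list(subject = character(0), opponent = character(0), reward = integer(0))
    } else {
      idx <- j0:(t - 1L)
      list(subject = am[idx], opponent = ac[idx], reward = u[idx])
    }
    res <- agent_step(agent_spec, astate, lt, arng)
    astate <- res$state
    a_bit <- if (res$action == "R") 1L else 0L
    c_bit <- .opp_choose(ost, orng)
    r <- as.integer(a_bit == c_bit)
    .opp_observe(ost, a_bit, r)
    am[t] <- res$action
    ac[t] <- if (c_bit == 1L) "R" else "L"
    u[t] <- r
  }
  .new_session(seq_len(n_trials), am, ac, u, agent_spec, opponent_spec,
               as.integer(seed))
}

#' Simulate a session with a mid-course strategy switch
#'
#' The agent follows `spec_a` on trials before `switch_at` and `spec_b` from
#' trial `switch_at` onward (so `switch_at = 1` is `spec_b` throughout);
#' otherwise identical to [simulate_session()]. Useful as a nonstationarity
#' fixture: the windowed traces change across the switch, smeared over one
#' window width.
#'
#' @param spec_a,spec_b [agent_spec()]s before/after the switch.
#' @param switch_at Trial index in 1..`n_trials` at which `spec_b` takes over.
#' @inheritParams simulate_session
#' @return An `mp_session`.
#' @export
make_switching_session <- function(spec_a, spec_b, switch_at, opponent_spec,
                                   n_trials, seed) {
  switch_at <- as.integer(switch_at)
  n_trials <- as.integer(n_trials)
  if (switch_at < 1L || switch_at > n_trials) {
    stop("switch_at must lie in 1..n_trials")
  }
  sw <- agent_spec("switch", params = list(first = spec_a, second = spec_b,
                                           at = switch_at))
  simulate_session(sw, opponent_spec, n_trials, seed)
}

# ---- serialization ---------------------------------------------------------

.spec_to_meta <- function(x) {
  if (inherits(x, "agent_spec")) {
    m <- list(kind = x$kind, order = x$order, seed = x$seed)
    p <- x$params
    if (!is.null(p$first)) p$first <- .spec_to_meta(p$first)
    if (!is.null(p$second)) p$second <- .spec_to_meta(p$second)
    if (!is.null(p$table)) p$table <- as.list(p$table)
    m$params <- p
    m
  } else if (inherits(x, "opponent_spec")) {
    unclass(x)
  } else {
    x
  }
}

.meta_to_agent <- function(m) {
  if (is.null(m)) return(NULL)
  p <- m$params %||% list()
  if (!is.null(p$first)) p$first <- .meta_to_agent(p$first)
  if (!is.null(p$second)) p$second <- .meta_to_agent(p$second)
  if (!is.null(p$table)) p$table <- unlist(p$table)
  agent_spec(m$kind, order = m$order, params = p, seed = m$seed)
}

.meta_to_opponent <- function(m) {
  if (is.null(m)) return(NULL)
  opponent_spec(m$algorithm, max_order = m$max_order %||% 4L,
                alpha = m$alpha %||% 0.05, min_count = m$min_count %||% 10L,
                deterministic_counter = m$deterministic_counter %||% FALSE,
                seed = m$seed)
}

#' Write / read a session file
#'
#' The on-disk format (version 1) is a plain TSV with columns `trial`,
#' `monkey_choice` (L/R), `computer_choice` (L/R), `reward` (0/1), preceded
#' by a `#`-prefixed header carrying the format version plus the agent spec,
#' opponent spec and master seed as YAML, so the round trip is lossless.
#'
#' @param session An `mp_session`.
#' @param path File path.
#' @return `write_session()` returns `path` invisibly; `read_session()`
#'   returns the reconstructed `mp_session` (erroring on malformed files and
#'   on sessions violating the reward rule, naming the offending trial).
#' @export
write_session <- function(session, path) {
  meta <- list(format = "mp-session/1",
               seed = attr(session, "seed"),
               agent = .spec_to_meta(attr(session, "agent_spec")),
               opponent = .spec_to_meta(attr(session, "opponent_spec")))
  hdr <- paste0("# ", strsplit(yaml::as.yaml(meta), "\n", fixed = TRUE)[[1]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(c("trial", "monkey_choice", "computer_choice", "reward"),
                   collapse = "\t"), con)
  body <- paste(session$trial, session$monkey_choice, session$computer_choice,
                session$reward, sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  n_meta <- if (any(!is_meta)) which(!is_meta)[1L] - 1L else length(lines)
  meta <- yaml::yaml.load(paste(sub("^# ?", "", lines[seq_len(n_meta)]),
                                collapse = "\n"))
  body <- lines[(n_meta + 1L):length(lines)]
  df <- tryCatch(
    utils::read.table(text = body, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e)))
  req <- c("trial", "monkey_choice", "computer_choice", "reward")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("parse error in ", path, " (line ", n_meta + 1L,
         "): missing column(s) ", paste(miss, collapse = ", "))
  }
  bad_lab <- which(!(df$monkey_choice %in% .ACTIONS) |
                     !(df$computer_choice %in% .ACTIONS))
  if (length(bad_lab)) {
    stop("parse error in ", path, " (line ", n_meta + 1L + bad_lab[1L],
         "): invalid action label")
  }
  s <- .new_session(as.integer(df$trial), df$monkey_choice, df$computer_choice,
                    as.integer(df$reward),
                    .meta_to_agent(meta$agent), .meta_to_opponent(meta$opponent),
                    if (!is.null(meta$seed)) as.integer(meta$seed) else NULL)
  v <- validate_session(s)
  if (nrow(v) > 0L) {
    stop("validation error in ", path, ": ", v$problem[1L],
         " at trial ", v$trial[1L])
  }
  s
}

#' @export
print.mp_session <- function(x, ...) {
  a <- attr(x, "agent_spec")
  o <- attr(x, "opponent_spec")
  cat("mp_session:", nrow(x), "trials",
      if (!is.null(a)) paste0("| agent ", a$kind),
      if (!is.null(o)) paste0("| Algorithm ", o$algorithm),
      if (!is.null(attr(x, "seed"))) paste0("| seed ", attr(x, "seed")), "\n")
  cat("subject reward rate:", format(mean(x$reward), digits = 4), "\n")
  invisible(x)
}
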