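#' Task configuration for the reversal-learning interception design
#'
#' Defines the probabilistic reversal structure: trials are organised in
#' blocks within which one colour-bounce regime holds with probability
#' `p_consistent`; the regime reverses after a block length drawn
#' uniformly from `block_len_range`, `switches_per_session` times per
#' session, and the room colour co-switches with every reversal. The
#' defaults reproduce the study conditions: 2 sessions of 80 trials, an
#' 87/13 contingency, reversals after 20-30 trials, four switches per
#' session.
#'
#' When `switches_per_session * min(block_len_range)` does not leave room
#' for a non-empty final block (the default design sits exactly at this
#' boundary: 4 x 20 = 80), the drawn block lengths are compressed,
#' largest-first, until the reversals fit; some blocks then fall slightly
#' below the nominal minimum. A configuration whose reversals cannot fit
#' even with one-trial blocks is rejected.
#'
#' @param n_sessions Number of sessions (default 2).
#' @param trials_per_session Trials per session (default 80).
#' @param p_consistent Contingency strength in (0.5, 1] (default 0.87;
#'   1 is the degenerate noiseless contingency).
#' @param block_len_range Integer pair `c(min, max)` of trials between
#'   reversals (default `c(20, 30)`).
#' @param switches_per_session Reversals per session (default 4).
#' @param seed Optional integer seed recorded in the config and used by
#'   [generate_design()] when no explicit seed is given.
#' @param pink_is_state1 Context-cue coding: if `TRUE` (default) the pink
#'   room corresponds to the regime coded 1 (green bouncy / red flat).
#' @return A `task_config` list.
#' @examples
#' cfg <- task_config(seed = 1)
#' @export
task_config <- function(n_sessions = 2, trials_per_session = 80,
                        p_consistent = 0.87, block_len_range = c(20, 30),
                        switches_per_session = 4, seed = NULL,
                        pink_is_state1 = TRUE) {
  stopifnot(
    n_sessions >= 1, trials_per_session >= 1,
    p_consistent > 0.5, p_consistent <= 1,
    length(block_len_range) == 2, block_len_range[1] >= 1,
    block_len_range[1] <= block_len_range[2],
    switches_per_session >= 0
  )
  if (switches_per_session + 1 > trials_per_session) {
    stop("cannot fit ", switches_per_session,
         " reversals in a session of ", trials_per_session, " trials",
         call. = FALSE)
  }
  structure(
    list(
      n_sessions = as.integer(n_sessions),
      trials_per_session = as.integer(trials_per_session),
      p_consistent = p_consistent,
      block_len_range = as.integer(block_len_range),
      switches_per_session = as.integer(switches_per_session),
      seed = if (!is.null(seed)) as.integer(seed),
      pink_is_state1 = isTRUE(pink_is_state1)
    ),
    class = "task_config"
  )
}

# Block lengths for one session: uniform draws from the configured range,
# compressed largest-first so that `switches` reversal points fit with at
# least `min_tail` trials after the last one.
draw_block_lengths <- function(n_trials, switches, range, min_tail = 1) {
  if (switches == 0) return(integer(0))
  g <- sample(seq(range[1], range[2]), switches, replace = TRUE)
  excess <- sum(g) - (n_trials - min_tail)
  while (excess > 0) {
    i <- which.max(g)
    take <- min(excess, g[i] - 1)
    if (take == 0) stop("reversals cannot fit in the session", call. = FALSE)
    g[i] <- g[i] - take
    excess <- excess - take
  }
  g
}

#' Generate a trial sequence with probabilistic reversal structure
#'
#' Draws a complete per-trial design: a latent binary regime
#' (`true_state`, 1 = green-bouncy/red-flat) that reverses at block
#' boundaries, a 50/50 ball colour per trial, a bounce outcome drawn from
#' the colour-regime contingency, a room colour constant within a block
#' and flipping at every reversal, and the recoded binaries `u` (1 exactly
#' when the outcome matches the state-1 mapping: green ball bouncing high
#' or red ball staying low) and `c` (1 when the room colour corresponds to
#' state 1). The regime carries over between sessions and a reversal may
#' fall on a session boundary (except at the very end of the experiment,
#' so that every programmed reversal is observable).
#'
#' @param config A [task_config()].
#' @param seed Integer seed; defaults to `config$seed`. The output is
#'   bit-identical across runs for a given seed.
#' @return A `trial_design` tibble with columns `trial`, `session`,
#'   `block`, `true_state`, `ball_color`, `bounce`, `room_color`, `u`, `c`
#'   and the config stored as attribute `"config"`.
#' @examples
#' des <- generate_design(task_config(seed = 1))
#' mean(des$u == des$true_state) # close to 0.87
#' @export
generate_design <- function(config = task_config(), seed = config$seed) {
  stopifnot(inherits(config, "task_config"))
  with_seed_(seed, {
    n_tot <- config$n_sessions * config$trials_per_session
    state0 <- sample(0:1, 1)
    # reversal points: trial indices after which the regime flips
    rev_points <- integer(0)
    for (s in seq_len(config$n_sessions)) {
      tail_free <- if (s == config$n_sessions) 1L else 0L
      g <- draw_block_lengths(config$trials_per_session,
                              config$switches_per_session,
                              config$block_len_range, min_tail = tail_free)
      rev_points <- c(rev_points, (s - 1L) * config$trials_per_session + cumsum(g))
    }
    flips <- integer(n_tot)
    flips[rev_points] <- 1L
    # state of trial k flips after each reversal point < k
    true_state <- (state0 + c(0L, cumsum(flips)[-n_tot])) %% 2L
    block <- 1L + c(0L, cumsum(flips)[-n_tot])
    session <- rep(seq_len(config$n_sessions), each = config$trials_per_session)
    ball_color <- sample(c("green", "red"), n_tot, replace = TRUE)
    # in state 1: green bounces high w.p. p_consistent, red low w.p. p_consistent
    p_high <- ifelse(true_state == 1,
                     ifelse(ball_color == "green", config$p_consistent, 1 - config$p_consistent),
                     ifelse(ball_color == "green", 1 - config$p_consistent, config$p_consistent))
    bounce <- ifelse(runif(n_tot) < p_high, "high", "low")
    u <- as.integer((ball_color == "green" & bounce == "high") |
                      (ball_color == "red" & bounce == "low"))
    state1_room <- if (config$pink_is_state1) "pink" else "orange"
    other_room <- setdiff(c("pink", "orange"), state1_room)
    room_color <- ifelse(true_state == 1, state1_room, other_room)
    cc <- as.integer(room_color == state1_room)
    out <- tibble::tibble(
      trial = seq_len(n_tot), session = session, block = block,
      true_state = true_state, ball_color = ball_color, bounce = bounce,
      room_color = room_color, u = u, c = cc
    )
    attr(out, "config") <- config
    attr(out, "seed") <- if (!is.null(seed)) as.integer(seed)
    class(out) <- c("trial_design", class(out))
    out
  })
}

#' Three-block reversal demonstration protocol
#'
#' A minimal sequence for the state-switching demonstration: the
#' contingency runs at `p_consistent`, flips to `1 - p_consistent`, and
#' flips back, with the context cue co-switching. Useful for comparing
#' abrupt versus continuous belief updates on a controlled input.
#'
#' @param block_len Trials per block (default 40).
#' @param p_consistent Contingency strength (default 0.87).
#' @param seed Optional seed.
#' @return A `trial_design` tibble (three blocks, states 1, 0, 1).
#' @export
reversal_protocol <- function(block_len = 40, p_consistent = 0.87,
                              seed = NULL) {
  with_seed_(seed, {
    true_state <- rep(c(1L, 0L, 1L), each = block_len)
    n <- length(true_state)
    consistent <- runif(n) < p_consistent
    u <- ifelse(consistent, true_state, 1L - true_state)
    ball_color <- sample(c("green", "red"), n, replace = TRUE)
    # reconstruct a bounce consistent with u and the colour coding
    bounce <- ifelse((u == 1) == (ball_color == "green"), "high", "low")
    out <- tibble::tibble(
      trial = seq_len(n), session = 1L,
      block = rep(1:3, each = block_len), true_state = true_state,
      ball_color = ball_color, bounce = bounce,
      room_color = ifelse(true_state == 1, "pink", "orange"),
      u = as.integer(u), c = true_state
    )
    attr(out, "config") <- task_config(
      n_sessions = 1, trials_per_session = n,
      p_consistent = p_consistent, block_len_range = c(block_len, block_len),
      switches_per_session = 2
    )
    class(out) <- c("trial_design", class(out))
    out
  })
}

#' Simulate an agent's binary responses from any model in the space
#'
#' Runs the chosen learner forward over the recoded observations `u` (and
#' the context cue `c` for the network variants), maps its one-step-ahead
#' prediction through the unit-square sigmoid with decision noise `zeta`,
#' and samples a binary response per trial.
#'
#' @param seq A `trial_design` tibble from [generate_design()] (or any
#'   tibble with columns `u`, and `c` for network models).
#' @param model One of `"rw"`, `"sk1"`, `"hgf2"`, `"hgf3"`, `"hgf4"`,
#'   `"context"`, `"nocontext"`.
#' @param params Named list of model parameters passed to the filter
#'   (e.g. `list(alpha = 0.3)` for `"rw"`, `list(omega = -4)` for
#'   `"hgf3"`, `list(lambda_2 = 0.5, lambda_4 = 1, omega_4 = -2)` for the
#'   network variants). `zeta` (default 1) sets the decision noise.
#' @param seed Optional seed for the response draws.
#' @return A list of class `agent_sim` with elements `responses` (tibble
#'   `trial`, `p_y`, `y`) and `trajectory` (the model's
#'   `belief_trajectory`).
#' @examples
#' des <- generate_design(task_config(seed = 1))
#' sim <- simulate_agent(des, "rw", list(alpha = 0.3, zeta = 3), seed = 2)
#' @export
simulate_agent <- function(seq, model, params = list(), seed = NULL) {
  zeta <- params$zeta %||% 1
  traj <- run_model(model, seq, params)
  p <- unitsq_sigmoid(traj$muhat_1, zeta)
  y <- with_seed_(seed, as.integer(runif(length(p)) < p))
  structure(
    list(
      responses = tibble::tibble(trial = seq_len(length(p)), p_y = p, y = y),
      trajectory = traj,
      model = model, params = params
    ),
    class = "agent_sim"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Dispatch a model id to its filter, returning a belief_trajectory whose
# muhat_1 column is the one-step-ahead prediction of u = 1 (the readout
# node's prediction for the network variants).
run_model <- function(model, seq, params = list()) {
  u <- if (is.data.frame(seq)) seq$u else seq
  switch(model,
    rw = rw_filter(u, v0 = params$v0 %||% 0.5, alpha = params$alpha %||% 0.5),
    sk1 = sk1_filter(u, v0 = params$v0 %||% 0.5,
                     alpha0 = params$alpha0 %||% 0.5,
                     eta = params$eta %||% 0.1),
    hgf2 = ,
    hgf3 = ,
    hgf4 = {
      n <- as.integer(substr(model, 4, 4))
      hgf_filter(u, n_levels = n,
                 omega = params$omega %||% -5.6,
                 theta = params$theta %||% -4,
                 kappa = params$kappa %||% 1,
                 mu2_0 = params$mu2_0 %||% 0,
                 sigma2_0 = params$sigma2_0 %||% 0.1,
                 mu3_0 = params$mu3_0 %||% 1,
                 sigma3_0 = params$sigma3_0 %||% 1,
                 mu4_0 = params$mu4_0 %||% 1,
                 sigma4_0 = params$sigma4_0 %||% 1)
    },
    context = ,
    nocontext = {
      net <- build_network(
        variant = model,
        lambda_2 = params$lambda_2 %||% 1,
        lambda_4 = params$lambda_4 %||% 1,
        omega_4 = params$omega_4 %||% -5,
        omega_2 = params$omega_2 %||% -5.6,
        theta = params$theta %||% -4,
        include_volatility = params$include_volatility %||% TRUE,
        cue_reliability = params$cue_reliability %||% 0.87
      )
      run_forward(net, seq)
    },
    stop("unknown model id: ", model, call. = FALSE)
  )
}

#' Simulate per-trial gaze pitch angles from a belief trajectory
#'
#' Emits the pre-bounce fixation pitch implied by the agent's beliefs:
#' `pitch = baseline + gain * p(high bounce | ball colour) + noise`, where
#' the probability of a high bounce for the trial's colour is obtained by
#' folding the belief that the regime is state 1 through the contingency
#' strength of the design.
#'
#' @param seq A `trial_design` tibble.
#' @param beliefs A `belief_trajectory` over the same trials (its
#'   `muhat_1` column is the predicted probability that the regime is
#'   state 1).
#' @param gain Degrees of pitch per unit probability of a high bounce
#'   (default 10).
#' @param baseline Pitch in degrees at zero probability (default 15).
#' @param noise_sd Gaussian noise SD in degrees (default 0.5).
#' @param seed Optional seed for the noise draws.
#' @return Tibble with `trial`, `ball_color`, `p_high`, `pitch`.
#' @export
generate_gaze <- function(seq, beliefs, gain = 10, baseline = 15,
                          noise_sd = 0.5, seed = NULL) {
  stopifnot(nrow(beliefs) == nrow(seq))
  cfg <- attr(seq, "config")
  p_cons <- if (!is.null(cfg)) cfg$p_consistent else 0.87
  m <- beliefs$muhat_1
  p_high <- ifelse(seq$ball_color == "green",
                   m * p_cons + (1 - m) * (1 - p_cons),
                   m * (1 - p_cons) + (1 - m) * p_cons)
  noise <- with_seed_(seed, rnorm(nrow(seq), 0, noise_sd))
  tibble::tibble(
    trial = seq$trial, ball_color = seq$ball_color,
    p_high = p_high, pitch = baseline + gain * p_high + noise
  )
}

#' Read and write trial sequences as CSV
#'
#' The on-disk schema is one row per trial with columns `trial`,
#' `session`, `block`, `true_state`, `ball_color`, `bounce`, `room_color`,
#' `u`, `c` (binaries as 0/1 integers, 1-based trial index).
#' `write_trials()` also writes a JSON sidecar `<path>.json` recording the
#' generating config and seed when present.
#'
#' @param seq A `trial_design` tibble.
#' @param path CSV file path.
#' @return `read_trials()` returns a `trial_design` tibble;
#'   `write_trials()` returns `path` invisibly.
#' @export
write_trials <- function(seq, path) {
  readr::write_csv(as.data.frame(seq), path)
  cfg <- attr(seq, "config")
  meta <- list(seed = attr(seq, "seed"))
  if (!is.null(cfg)) meta$config <- unclass(cfg)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      trial = "i", session = "i", block = "i", true_state = "i",
      ball_color = "c", bounce = "c", room_color = "c", u = "i", c = "i"
    )
  )
  stopifnot(all(out$u %in% 0:1), all(out$c %in% 0:1))
  class(out) <- c("trial_design", class(out))
  out
}

#' Read a task configuration from YAML
#'
#' @param path YAML file with any subset of the [task_config()] fields.
#' @return A `task_config`.
#' @export
read_task_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$block_len_range)) {
    vals$block_len_range <- as.integer(unlist(vals$block_len_range))
  }
  do.call(task_config, vals)
}
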