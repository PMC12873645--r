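# Independent oracles used across the suite. These deliberately use
# naive, transparent computations (explicit window scans, step-by-step
# scalar recursions) so they share no code with the implementation.

# Exhaustive window-scan fixation oracle: from each start index grow the
# window by brute force, recomputing the dispersion of the whole window
# with max/min each step; emit maximal windows meeting the duration
# threshold, then continue after the window (greedy, non-overlapping).
brute_force_fixations <- function(t, p, valid = rep(TRUE, length(t)),
                                  dispersion = 3, min_duration = 0.1) {
  n <- length(t)
  out <- list()
  i <- 1
  while (i <= n) {
    if (!valid[i]) {
      i <- i + 1
      next
    }
    best_j <- i
    j <- i
    while (j < n && valid[j + 1] &&
           (max(p[i:(j + 1)]) - min(p[i:(j + 1)])) <= dispersion) {
      j <- j + 1
      best_j <- j
    }
    if (t[best_j] - t[i] >= min_duration) {
      out[[length(out) + 1]] <- data.frame(
        t_start = t[i], t_end = t[best_j],
        mean_pitch = mean(p[i:best_j])
      )
      i <- best_j + 1
    } else {
      i <- i + 1
    }
  }
  if (length(out) == 0) {
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      mean_pitch = numeric(0)))
  }
  do.call(rbind, out)
}

# Scalar step-by-step Rescorla-Wagner recursion.
rw_oracle <- function(u, v0, alpha) {
  v <- v0
  muhat <- numeric(length(u))
  for (k in seq_along(u)) {
    muhat[k] <- v
    v <- v + alpha * (u[k] - v)
  }
  list(muhat = muhat, v_final = v)
}

# A small cohort of designs + simulated responses without the pipeline
# helpers (used where a test wants raw materials quickly).
make_sim <- function(model, params, seed) {
  des <- generate_design(task_config(seed = seed))
  sim <- simulate_agent(des, model, params, seed = seed + 1)
  list(des = des, y = sim$responses$y, sim = sim)
}
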