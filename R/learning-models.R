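# Flat and hierarchical learners run as trial-by-trial filters over the
# recoded binary observations u. Every filter returns a belief_trajectory
# tibble whose muhat_1 column is the one-step-ahead predicted probability
# of u = 1 (computed before the trial's input is absorbed), so trajectory
# prefixes depend only on the inputs seen so far.

new_belief_trajectory <- function(df, model, params) {
  attr(df, "model") <- model
  attr(df, "params") <- params
  class(df) <- c("belief_trajectory", class(df))
  df
}

check_binary_input <- function(u) {
  u <- if (is.data.frame(u)) u$u else u
  stopifnot(is.numeric(u), all(u %in% c(0, 1)))
  as.numeric(u)
}

#' Rescorla-Wagner filter
#'
#' Constant-learning-rate delta rule on the outcome probability:
#' `v[k+1] = v[k] + alpha * (u[k] - v[k])`. The prediction for trial `k`
#' is the value before `u[k]` is seen.
#'
#' @param u Binary observation series (vector, or tibble with column `u`).
#' @param v0 Initial value in (0, 1) (default 0.5).
#' @param alpha Learning rate in `[0, 1]`.
#' @return A `belief_trajectory` tibble with columns `trial`, `u`,
#'   `muhat_1`, `delta_1`, `value`, `surprise`.
#' @examples
#' rw_filter(c(1, 1, 0), alpha = 0.5)
#' @export
rw_filter <- function(u, v0 = 0.5, alpha = 0.5) {
  u <- check_binary_input(u)
  stopifnot(alpha >= 0, alpha <= 1, v0 > 0, v0 < 1)
  res <- .rw_filter_c(u, v0, alpha)
  df <- tibble::tibble(
    trial = seq_along(u), u = u,
    muhat_1 = res$muhat_1, delta_1 = res$delta_1, value = res$value,
    surprise = binary_surprise(u, res$muhat_1)
  )
  new_belief_trajectory(df, "rw", list(v0 = v0, alpha = alpha))
}

#' Sutton K1 filter (adaptive-gain delta rule)
#'
#' Delta rule whose gain tracks the magnitude of recent prediction
#' errors: `v[k+1] = v[k] + alpha[k] * delta[k]` followed by
#' `alpha[k+1] = alpha[k] + eta * (|delta[k]| - alpha[k])`, with the gain
#' clipped to `[0, 1]`. With `eta = 0` it reduces to Rescorla-Wagner with
#' `alpha = alpha0`.
#'
#' @inheritParams rw_filter
#' @param alpha0 Initial gain in `[0, 1]`.
#' @param eta Positive gain-adaptation constant.
#' @return A `belief_trajectory` tibble (adds column `alpha_k`, the gain
#'   after trial `k`).
#' @export
sk1_filter <- function(u, v0 = 0.5, alpha0 = 0.5, eta = 0.1) {
  u <- check_binary_input(u)
  stopifnot(alpha0 >= 0, alpha0 <= 1, eta >= 0, v0 > 0, v0 < 1)
  res <- .sk1_filter_c(u, v0, alpha0, eta)
  df <- tibble::tibble(
    trial = seq_along(u), u = u,
    muhat_1 = res$muhat_1, delta_1 = res$delta_1, value = res$value,
    alpha_k = res$alpha_k,
    surprise = binary_surprise(u, res$muhat_1)
  )
  new_belief_trajectory(df, "sk1", list(v0 = v0, alpha0 = alpha0, eta = eta))
}

#' Binary hierarchical Gaussian filter (2, 3 or 4 levels)
#'
#' Trial-by-trial variational inversion of a hierarchy of Gaussian random
#' walks over a binary outcome. Level 1 is the outcome; level 2 its
#' log-odds tendency, whose step variance is `exp(kappa * mu_3 + omega)`
#' when a volatility level is present (`exp(omega)` for the two-level
#' model); levels 3 (and 4) track log-volatility, the top level's own
#' step variance being the constant `exp(theta)`. Updates are
#' precision-weighted prediction errors: the level-2 posterior precision
#' adds the Bernoulli information `muhat_1 * (1 - muhat_1)`, and
#' volatility levels are driven by standard volatility prediction errors.
#' In the four-level model `omega` is shared by both intermediate levels.
#'
#' @inheritParams rw_filter
#' @param n_levels 2, 3 or 4.
#' @param omega Tonic volatility of the intermediate level(s), in
#'   log-variance units (default -5.6).
#' @param theta Top-level tonic volatility (default -4; fixed in the
#'   study configuration).
#' @param kappa Inter-level coupling strength (default 1, fixed).
#' @param mu2_0,sigma2_0,mu3_0,sigma3_0,mu4_0,sigma4_0 Starting means and
#'   variances of the Gaussian levels; defaults are the study's prior
#'   means. Starting values above `n_levels` are ignored.
#' @return A `belief_trajectory` tibble with columns `trial`, `u`,
#'   `muhat_1`, `delta_1`, `surprise` and per Gaussian level `i`:
#'   `mu_i`, `sigma_i`, `muhat_i`, `pihat_i`, `delta_i` (the volatility
#'   prediction error at level `i`).
#' @examples
#' hgf_filter(c(1, 1, 0, 1, 0), n_levels = 3)
#' @export
hgf_filter <- function(u, n_levels = 3, omega = -5.6, theta = -4, kappa = 1,
                       mu2_0 = 0, sigma2_0 = 0.1, mu3_0 = 1, sigma3_0 = 1,
                       mu4_0 = 1, sigma4_0 = 1) {
  u <- check_binary_input(u)
  stopifnot(n_levels %in% 2:4, sigma2_0 > 0, sigma3_0 > 0, sigma4_0 > 0)
  mu0 <- c(mu2_0, mu3_0, mu4_0)[seq_len(n_levels - 1)]
  sigma0 <- c(sigma2_0, sigma3_0, sigma4_0)[seq_len(n_levels - 1)]
  res <- .hgf_filter_c(u, as.integer(n_levels), omega, theta, kappa,
                       mu0, sigma0)
  if (res$bad_trial > 0) {
    stop("hgf_filter: non-positive posterior variance at trial ",
         res$bad_trial, ", level ", res$bad_level,
         " (belief update diverged)", call. = FALSE)
  }
  df <- tibble::tibble(
    trial = seq_along(u), u = u,
    muhat_1 = res$muhat_1, delta_1 = res$delta_1,
    surprise = binary_surprise(u, res$muhat_1)
  )
  for (j in seq_len(n_levels - 1)) {
    lev <- j + 1
    df[[paste0("mu_", lev)]] <- res$mu[, j]
    df[[paste0("sigma_", lev)]] <- res$sigma[, j]
    df[[paste0("muhat_", lev)]] <- res$muhat[, j]
    df[[paste0("pihat_", lev)]] <- res$pihat[, j]
    df[[paste0("delta_", lev)]] <- res$da[, j]
  }
  new_belief_trajectory(df, paste0("hgf", n_levels),
                        list(omega = omega, theta = theta, kappa = kappa,
                             mu0 = mu0, sigma0 = sigma0))
}

#' Serialize a belief trajectory to long format
#'
#' @param traj A `belief_trajectory`.
#' @return Tibble with columns `trial`, `quantity`, `value`, suitable for
#'   CSV export.
#' @export
trajectory_long <- function(traj) {
  tidyr::pivot_longer(
    tibble::as_tibble(traj), -dplyr::all_of("trial"),
    names_to = "quantity", values_to = "value"
  )
}
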