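# Fitting the context-network free parameters (autoconnection strengths
# lambda_2, lambda_4 and tonic volatility omega_4) by minimizing the
# surprise of the observed behaviour plus the negative log prior:
# omega_4 ~ Normal(-5, 2^2), lambda_2 and lambda_4 ~ Beta(1, 1)
# (uniform on [0, 1], carried into logit space with its Jacobian).

context_free_spec <- function() {
  tibble::tribble(
    ~parameter,  ~transform, ~prior,
    "lambda_2",  "logit",    "beta11",
    "lambda_4",  "logit",    "beta11",
    "omega_4",   "identity", "normal"
  )
}

context_log_prior <- function(name, transform, x) {
  if (name == "omega_4") return(dnorm(x, -5, 2, log = TRUE))
  # Beta(1,1) on the natural scale; in logit space the density is the
  # Jacobian d lambda / d x = lambda (1 - lambda)
  l <- plogis(x)
  log(l) + log(1 - l)
}

#' Fit the context-network free parameters to a response series
#'
#' Optimizes the three network parameters (`lambda_2`, `lambda_4`,
#' `omega_4`) by minimizing the total behavioural surprise of the binary
#' responses under the network's readout probability, plus the negative
#' log prior, with multistart BFGS in transformed space. Optionally
#' draws from the (unnormalized) posterior with a random-walk Metropolis
#' sampler started at the optimum, reporting a split-chain convergence
#' diagnostic.
#'
#' @param variant `"context"` or `"nocontext"`.
#' @param seq Trial sequence (columns `u`, `c`).
#' @param y Binary response series.
#' @param include_volatility Build the network with (default) or without
#'   the volatility node.
#' @param free Parameters to optimize (subset of `lambda_2`, `lambda_4`,
#'   `omega_4`); the rest are held at `fixed` values.
#' @param fixed Named list of values for parameters not in `free`
#'   (defaults: `lambda_2 = 1`, `lambda_4 = 1`, `omega_4 = -5`).
#' @param n_restarts Optimizer starts (default 5).
#' @param n_draws If positive, number of posterior draws per chain (2
#'   chains) from the random-walk Metropolis sampler.
#' @param seed Optional seed (restart jitter and sampler).
#' @return A `context_fit`: list with `params_hat`, `surprise`
#'   (total behavioural surprise at the optimum), `log_joint`
#'   (`-surprise + log prior`), `trajectory`, `converged`,
#'   `n_restarts_used`, and when sampled, `draws` (tibble) and `rhat`.
#' @export
fit_context_params <- function(variant = c("context", "nocontext"), seq, y,
                               include_volatility = TRUE,
                               free = c("lambda_2", "lambda_4", "omega_4"),
                               fixed = list(), n_restarts = 5, n_draws = 0,
                               seed = NULL) {
  variant <- match.arg(variant)
  y <- if (is.data.frame(y)) y$y else y
  stopifnot(length(y) == nrow(seq), all(y %in% c(0, 1)))
  spec <- context_free_spec()
  free <- intersect(spec$parameter, free)
  d <- length(free)
  defaults <- list(lambda_2 = 1, lambda_4 = 1, omega_4 = -5)
  defaults[names(fixed)] <- fixed
  spec <- spec[match(free, spec$parameter), ]

  build <- function(params) {
    build_network(variant, lambda_2 = params$lambda_2,
                  lambda_4 = params$lambda_4, omega_4 = params$omega_4,
                  include_volatility = include_volatility)
  }
  params_of <- function(x) {
    params <- defaults
    for (i in seq_len(d)) {
      params[[free[i]]] <- transform_fun(spec$transform[i])$from(x[i])
    }
    params
  }
  objective <- function(x) {       # log joint (to maximize)
    params <- params_of(x)
    traj <- tryCatch(run_forward(build(params), seq), error = function(e) NULL)
    if (is.null(traj) || any(!is.finite(traj$muhat_1))) return(-Inf)
    s <- behavioral_surprise(traj, y)$total
    lp <- if (d) sum(vapply(seq_len(d), function(i) {
      context_log_prior(free[i], spec$transform[i], x[i])
    }, numeric(1))) else 0
    -s + lp
  }
  neg_obj <- function(x) {
    v <- objective(x)
    if (!is.finite(v)) 1e12 else -v
  }

  bounds <- param_bounds()
  start0 <- vapply(seq_len(d), function(i) {
    transform_fun(spec$transform[i])$to(
      c(lambda_2 = 0.5, lambda_4 = 0.5, omega_4 = -5)[[free[i]]]
    )
  }, numeric(1))
  starts <- with_seed_(seed, {
    s <- list(start0)
    if (n_restarts > 1 && d > 0) {
      for (r in seq_len(n_restarts - 1)) {
        s[[r + 1]] <- vapply(seq_len(d), function(i) {
          b <- bounds[bounds$parameter == free[i], ]
          transform_fun(spec$transform[i])$to(runif(1, b$lower, b$upper))
        }, numeric(1))
      }
    }
    s
  })

  best <- NULL
  n_used <- 0
  for (x0 in starts) {
    n_used <- n_used + 1
    if (d == 0) {
      best <- list(par = numeric(0), value = -objective(numeric(0)),
                   convergence = 0L)
      break
    }
    opt <- tryCatch(
      optim(x0, neg_obj, method = "BFGS",
            control = list(maxit = 300, reltol = 1e-10)),
      error = function(e) NULL
    )
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  converged <- !is.null(best) && is.finite(best$value) && best$value < 1e11
  if (is.null(best)) best <- list(par = start0, value = Inf, convergence = 99L)

  params_hat <- params_of(best$par)
  traj <- if (converged) run_forward(build(params_hat), seq) else NULL
  surprise <- if (!is.null(traj)) behavioral_surprise(traj, y)$total else NA_real_

  fit <- structure(
    list(variant = variant, params_hat = params_hat, theta_hat = best$par,
         log_joint = -best$value, surprise = surprise, trajectory = traj,
         converged = converged, n_restarts_used = n_used, free = free,
         include_volatility = include_volatility, n_trials = nrow(seq),
         objective = objective),
    class = "context_fit"
  )
  if (n_draws > 0 && converged && d > 0) {
    # scale proposals by the Laplace posterior spread at the optimum
    H <- tryCatch(optimHess(best$par, neg_obj), error = function(e) NULL)
    sds <- if (!is.null(H) && all(is.finite(H)) && all(diag(H) > 0)) {
      sqrt(1 / diag(H))
    } else {
      rep(0.3, d)
    }
    fit[c("draws", "rhat")] <- mh_sample(objective, best$par, free,
                                         n_draws, child_seed(seed, 17),
                                         step = pmin(sds, 2))
  }
  fit
}

# Random-walk Metropolis in transformed space, 2 chains, with a
# split-chain potential-scale-reduction diagnostic.
mh_sample <- function(log_post, x_hat, names, n_draws, seed = NULL,
                      step = NULL) {
  d <- length(x_hat)
  step <- (step %||% rep(0.15, d)) * 2.4 / sqrt(d)
  with_seed_(seed, {
    chains <- lapply(1:2, function(ch) {
      x <- x_hat + rnorm(d, 0, 0.1)
      lp <- log_post(x)
      out <- matrix(NA_real_, n_draws, d)
      for (i in seq_len(n_draws)) {
        prop <- x + rnorm(d, 0, step)
        lp_prop <- log_post(prop)
        if (is.finite(lp_prop) && log(runif(1)) < lp_prop - lp) {
          x <- prop
          lp <- lp_prop
        }
        out[i, ] <- x
      }
      out
    })
    draws <- do.call(rbind, chains)
    colnames(draws) <- names
    rhat <- vapply(seq_len(d), function(j) {
      split_rhat(cbind(chains[[1]][, j], chains[[2]][, j]))
    }, numeric(1))
    list(
      draws = dplyr::bind_cols(
        tibble::tibble(chain = rep(1:2, each = n_draws),
                       iteration = rep(seq_len(n_draws), 2)),
        tibble::as_tibble(draws)
      ),
      rhat = setNames(rhat, names)
    )
  })
}

# Split-chain R-hat (each chain halved, between/within variance ratio).
split_rhat <- function(sims) {
  n <- nrow(sims)
  half <- floor(n / 2)
  sub <- cbind(sims[seq_len(half), , drop = FALSE],
               sims[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  B <- half * stats::var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' @export
print.context_fit <- function(x, ...) {
  cat("<context_fit> ", x$variant,
      if (!x$include_volatility) " (no volatility node)", "\n", sep = "")
  est <- unlist(x$params_hat[x$free])
  if (length(est)) {
    cat("  estimates:",
        paste(sprintf("%s = %.4g", names(est), est), collapse = ", "), "\n")
  }
  cat(sprintf("  behavioural surprise = %.3f nats  converged = %s\n",
              x$surprise, x$converged))
  if (!is.null(x$rhat)) {
    cat("  split-Rhat:",
        paste(sprintf("%s = %.3f", names(x$rhat), x$rhat), collapse = ", "),
        "\n")
  }
  invisible(x)
}
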