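# MAP estimation of the flat/HGF model family under the study priors,
# with Laplace-approximate log model evidence. Optimization runs in
# transformed space (log for positive parameters, logit for rates and
# probabilities, identity for log-volatilities) with multistart
# quasi-Newton search; filter divergence during search is treated as an
# objective of -Inf, not an error.

transform_fun <- function(tr) {
  switch(tr,
         identity = list(to = identity, from = identity),
         log = list(to = log, from = exp),
         logit = list(to = qlogis, from = plogis),
         stop("unknown transform: ", tr, call. = FALSE))
}

#' Prior specification for a model family
#'
#' Returns the default prior table for a model: one row per parameter
#' with its transform, prior mean and variance in transformed space, a
#' `fixed` flag (fixed parameters have zero prior variance), and the
#' natural-space default value. The values follow the study
#' configuration: HGF tonic volatility `omega ~ N(-5.6, 8)`, top-level
#' `theta = -4` and coupling `kappa = 1` fixed, starting means
#' `N(0 or 1, 8)`, starting variances log-normal around their defaults;
#' associative-model learning rate and initial value centred on 0.5 on
#' the logit scale; decision noise `log(zeta) ~ N(0, 1)`.
#'
#' @param model One of `"rw"`, `"sk1"`, `"hgf2"`, `"hgf3"`, `"hgf4"`.
#' @return Tibble with columns `parameter`, `transform`, `prior_mean`,
#'   `prior_var`, `fixed`, `natural_mean`.
#' @export
model_priors <- function(model) {
  pr <- function(parameter, transform, prior_mean, prior_var) {
    tibble::tibble(parameter = parameter, transform = transform,
                   prior_mean = prior_mean, prior_var = prior_var)
  }
  tab <- switch(model,
    rw = dplyr::bind_rows(
      pr("alpha", "logit", 0, 1),
      pr("v0", "logit", 0, 1),
      pr("zeta", "log", 0, 1)
    ),
    sk1 = dplyr::bind_rows(
      pr("alpha0", "logit", 0, 1),
      pr("v0", "logit", 0, 1),
      pr("eta", "log", log(0.1), 1),
      pr("zeta", "log", 0, 1)
    ),
    hgf2 = ,
    hgf3 = ,
    hgf4 = {
      n <- as.integer(substr(model, 4, 4))
      out <- dplyr::bind_rows(
        pr("kappa", "identity", 1, 0),
        pr("omega", "identity", -5.6, 8),
        pr("theta", "identity", -4, 0),
        pr("mu2_0", "identity", 0, 8),
        pr("sigma2_0", "log", log(0.1), 1),
        pr("mu3_0", "identity", 1, 8),
        pr("sigma3_0", "log", 0, 1),
        pr("mu4_0", "identity", 1, 8),
        pr("sigma4_0", "log", 0, 1),
        pr("zeta", "log", 0, 1)
      )
      keep <- c("kappa", "omega", "theta", "zeta",
                paste0(c("mu", "sigma"), rep(2:n, each = 2), "_0"))
      out[out$parameter %in% keep, ]
    },
    stop("unknown model id: ", model, call. = FALSE)
  )
  tab$fixed <- tab$prior_var == 0
  tab$natural_mean <- purrr::map2_dbl(
    tab$prior_mean, tab$transform, ~ transform_fun(.y)$from(.x)
  )
  tab
}

# Parameters estimated by default. Starting uncertainties and the fixed
# structural parameters are held at their prior means: a single 160-trial
# binary series does not identify starting variances.
default_free <- function(model) {
  switch(model,
         rw = c("alpha", "v0", "zeta"),
         sk1 = c("alpha0", "v0", "eta", "zeta"),
         hgf2 = , hgf3 = , hgf4 = c("omega", "mu2_0", "zeta"),
         stop("unknown model id: ", model, call. = FALSE))
}

# Natural-space bounds defining the numerically stable region used for
# multistart jitter and for truncating prior draws of generating
# parameters in the recovery harnesses. The bounds are roughly 3-sigma
# truncations of the priors, tightened only where the binary HGF
# diverges (tonic volatility approaching 0 blows up the level-2
# variance) or a parameter leaves its meaningful range (rates in (0,1)).
param_bounds <- function() {
  tibble::tribble(
    ~parameter,  ~lower, ~upper,
    "alpha",     0.05,   0.95,
    "alpha0",    0.05,   0.95,
    "v0",        0.05,   0.95,
    "eta",       0.005,  1,
    "omega",     -12,    -1,
    "mu2_0",     -8.5,   8.5,
    "mu3_0",     -7.5,   4,
    "sigma2_0",  0.005,  2,
    "sigma3_0",  0.05,   7,
    "mu4_0",     -7.5,   4,
    "sigma4_0",  0.05,   7,
    "zeta",      0.05,   20,
    "lambda_2",  0.05,   0.95,
    "lambda_4",  0.05,   0.95,
    "omega_4",   -11,    -1
  )
}

# Fast path: one-step-ahead predictions of u = 1 without tibble packaging.
model_muhat <- function(model, u, params) {
  if (model == "rw") {
    if (params$alpha < 0 || params$alpha > 1 ||
        params$v0 <= 0 || params$v0 >= 1) return(NULL)
    return(.rw_filter_c(u, params$v0, params$alpha)$muhat_1)
  }
  if (model == "sk1") {
    if (params$alpha0 < 0 || params$alpha0 > 1 || params$eta < 0 ||
        params$v0 <= 0 || params$v0 >= 1) return(NULL)
    return(.sk1_filter_c(u, params$v0, params$alpha0, params$eta)$muhat_1)
  }
  if (model %in% c("hgf2", "hgf3", "hgf4")) {
    n <- as.integer(substr(model, 4, 4))
    mu0 <- c(params$mu2_0, params$mu3_0 %||% 1, params$mu4_0 %||% 1)[seq_len(n - 1)]
    sigma0 <- c(params$sigma2_0, params$sigma3_0 %||% 1,
                params$sigma4_0 %||% 1)[seq_len(n - 1)]
    if (any(sigma0 <= 0)) return(NULL)
    res <- .hgf_filter_c(u, n, params$omega, params$theta, params$kappa,
                         mu0, sigma0)
    if (res$bad_trial > 0) return(NULL)
    return(res$muhat_1)
  }
  stop("unknown model id: ", model, call. = FALSE)
}

bernoulli_loglik <- function(y, p1) {
  p1 <- clip_prob(p1)
  sum(y * log(p1) + (1 - y) * log(1 - p1))
}

#' Fit a learning model to binary responses by MAP estimation
#'
#' Maximizes the response log-likelihood under the unit-square sigmoid
#' observation model plus the log prior over the free parameters, in
#' transformed space, by multistart BFGS (first start at the prior
#' means, the rest drawn uniformly from the stable parameter region).
#' Filter failures during the search yield an objective of `-Inf` and
#' are skipped, not raised.
#'
#' @param model Model id (`"rw"`, `"sk1"`, `"hgf2"`, `"hgf3"`, `"hgf4"`).
#' @param seq Trial sequence (tibble with column `u`, or a plain 0/1
#'   vector).
#' @param y Binary response series (vector or tibble with column `y`).
#' @param priors Prior table from [model_priors()]; rows with zero prior
#'   variance are held fixed at their means.
#' @param free Character vector of parameters to estimate (defaults to
#'   the identifiable set: `omega`, `mu2_0`, `zeta` for the HGF family;
#'   learning rate, initial value (and `eta`) plus `zeta` for the
#'   associative models). Parameters whose prior variance is zero are
#'   dropped from `free`.
#' @param n_restarts Number of optimizer starts (default 5).
#' @param seed Optional seed making the restart jitter reproducible.
#' @return A `model_fit` object: list with `model`, `params_hat`
#'   (natural space, all parameters), `theta_hat` (transformed free
#'   parameters), `log_joint`, `loglik`, `lme` (Laplace approximation,
#'   see [laplace_lme()]), `trajectory` (at the optimum),
#'   `n_restarts_used`, `converged`, `free`, `priors`.
#' @examples
#' des <- generate_design(task_config(seed = 1))
#' sim <- simulate_agent(des, "rw", list(alpha = 0.3, zeta = 3), seed = 2)
#' fit <- map_fit("rw", des, sim$responses, seed = 3)
#' @export
map_fit <- function(model, seq, y, priors = model_priors(model),
                    free = default_free(model), n_restarts = 5,
                    seed = NULL) {
  u <- check_binary_input(seq)
  y <- if (is.data.frame(y)) y$y else y
  stopifnot(length(y) == length(u), all(y %in% c(0, 1)))
  y <- as.numeric(y)
  free <- intersect(free, priors$parameter[!priors$fixed])
  d <- length(free)
  base <- setNames(as.list(priors$natural_mean), priors$parameter)
  ptab <- priors[match(free, priors$parameter), ]

  objective <- function(x) {
    params <- base
    for (i in seq_len(d)) {
      params[[free[i]]] <- transform_fun(ptab$transform[i])$from(x[i])
    }
    muhat <- model_muhat(model, u, params)
    if (is.null(muhat) || any(!is.finite(muhat))) return(-Inf)
    ll <- bernoulli_loglik(y, unitsq_sigmoid(muhat, params$zeta))
    lp <- if (d) sum(dnorm(x, ptab$prior_mean, sqrt(ptab$prior_var),
                           log = TRUE)) else 0
    ll + lp
  }
  neg_obj <- function(x) {
    v <- objective(x)
    if (!is.finite(v)) 1e12 else -v
  }

  bounds <- param_bounds()
  starts <- with_seed_(seed, {
    s <- list(ptab$prior_mean)
    if (n_restarts > 1 && d > 0) {
      for (r in seq_len(n_restarts - 1)) {
        x0 <- vapply(seq_len(d), function(i) {
          b <- bounds[bounds$parameter == free[i], ]
          nat <- if (nrow(b)) runif(1, b$lower, b$upper) else
            rnorm(1, ptab$prior_mean[i], sqrt(ptab$prior_var[i]))
          if (nrow(b)) transform_fun(ptab$transform[i])$to(nat) else nat
        }, numeric(1))
        s[[r + 1]] <- x0
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

  converged <- !is.null(best) && is.finite(best$value) &&
    best$value < 1e11 && (best$convergence %in% c(0L, 1L))
  if (is.null(best)) {
    best <- list(par = ptab$prior_mean, value = Inf, convergence = 99L)
  }

  params_hat <- base
  for (i in seq_len(d)) {
    params_hat[[free[i]]] <- transform_fun(ptab$transform[i])$from(best$par[i])
  }
  traj <- if (converged) {
    tryCatch(run_model(model, u, params_hat), error = function(e) NULL)
  }
  fit <- structure(
    list(model = model, params_hat = params_hat, theta_hat = best$par,
         log_joint = -best$value,
         loglik = if (converged && !is.null(traj)) {
           bernoulli_loglik(y, unitsq_sigmoid(traj$muhat_1, params_hat$zeta))
         } else NA_real_,
         trajectory = traj, n_restarts_used = n_used,
         converged = converged, free = free, priors = priors,
         n_trials = length(u), objective = objective),
    class = "model_fit"
  )
  fit$lme <- laplace_lme(fit)
  fit
}

#' Laplace-approximate log model evidence
#'
#' Approximates the log marginal likelihood at a MAP optimum:
#' `lme = log_joint + d/2 * log(2*pi) - 1/2 * log det(H)` with `H` the
#' negative Hessian of the transformed-space objective at the optimum
#' (computed numerically). If `H` is not positive definite the function
#' falls back to a BIC-style penalty `log_joint - d/2 * log(K)` with a
#' warning. Fixed parameters contribute zero dimensions.
#'
#' @param fit A `model_fit` (or any object with `objective`,
#'   `theta_hat`, `log_joint`, `n_trials`, `converged`).
#' @return Log model evidence in nats (`NA` for non-converged fits).
#' @export
laplace_lme <- function(fit) {
  if (!isTRUE(fit$converged)) return(NA_real_)
  d <- length(fit$theta_hat)
  if (d == 0) return(fit$log_joint)
  H <- tryCatch(
    -optimHess(fit$theta_hat, function(x) {
      v <- fit$objective(x)
      if (!is.finite(v)) -1e12 else v
    }),
    error = function(e) NULL
  )
  ok <- !is.null(H) && all(is.finite(H))
  if (ok) {
    ev <- tryCatch(eigen(H, symmetric = TRUE, only.values = TRUE)$values,
                   error = function(e) NULL)
    ok <- !is.null(ev) && all(ev > 0)
  }
  if (!ok) {
    warning("laplace_lme: Hessian not positive definite; ",
            "falling back to BIC-style penalty", call. = FALSE)
    return(fit$log_joint - d / 2 * log(fit$n_trials))
  }
  fit$log_joint + d / 2 * log(2 * pi) -
    0.5 * sum(log(eigen(H, symmetric = TRUE, only.values = TRUE)$values))
}

#' @export
print.model_fit <- function(x, ...) {
  cat("<model_fit> ", x$model, "\n", sep = "")
  cat("  free:", paste(x$free, collapse = ", "), "\n")
  est <- unlist(x$params_hat[x$free])
  if (length(est)) {
    cat("  estimates:",
        paste(sprintf("%s = %.4g", names(est), est), collapse = ", "), "\n")
  }
  cat(sprintf("  log_joint = %.3f  lme = %.3f  converged = %s\n",
              x$log_joint, x$lme, x$converged))
  invisible(x)
}
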