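# broom-style tidiers: tidy() returns one row per estimated quantity,
# glance() a one-row model summary.

#' Tidy a MAP model fit
#'
#' @param x A `model_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter: `parameter`, `estimate`
#'   (natural space), `transform`, `prior_mean`, `prior_var`, `fixed`.
#' @export
tidy.model_fit <- function(x, ...) {
  pr <- x$priors
  tibble::tibble(
    parameter = pr$parameter,
    estimate = unlist(x$params_hat[pr$parameter]),
    transform = pr$transform,
    prior_mean = pr$prior_mean,
    prior_var = pr$prior_var,
    fixed = !(pr$parameter %in% x$free)
  )
}

#' @rdname tidy.model_fit
#' @export
glance.model_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, n_free = length(x$free), log_joint = x$log_joint,
    loglik = x$loglik, lme = x$lme, converged = x$converged,
    n_restarts_used = x$n_restarts_used, n_trials = x$n_trials
  )
}

#' Tidy a context-network fit
#'
#' @param x A `context_fit`.
#' @param ... Unused.
#' @return One row per free parameter with the point estimate (and
#'   posterior quantiles when the sampler was run).
#' @export
tidy.context_fit <- function(x, ...) {
  out <- tibble::tibble(
    parameter = x$free,
    estimate = unlist(x$params_hat[x$free])
  )
  if (!is.null(x$draws)) {
    qs <- purrr::map(x$free, function(p) {
      nat <- if (p == "omega_4") x$draws[[p]] else plogis(x$draws[[p]])
      # draws are stored in sampling (transformed) space for omega only
      tibble::tibble(q2.5 = quantile(nat, 0.025),
                     q97.5 = quantile(nat, 0.975))
    })
    out <- dplyr::bind_cols(out, dplyr::bind_rows(qs),
                            tibble::tibble(rhat = unname(x$rhat[x$free])))
  }
  out
}

#' @rdname tidy.context_fit
#' @export
glance.context_fit <- function(x, ...) {
  tibble::tibble(
    variant = x$variant, include_volatility = x$include_volatility,
    n_free = length(x$free), surprise = x$surprise,
    log_joint = x$log_joint, converged = x$converged,
    n_restarts_used = x$n_restarts_used, n_trials = x$n_trials
  )
}

#' Tidy a Bayesian model selection result
#'
#' @param x A `bms_result`.
#' @param ... Unused.
#' @return Tibble with `model`, `alpha`, `expected_freq`, `xp`, `pxp`.
#' @export
tidy.bms_result <- function(x, ...) {
  tibble::tibble(
    model = names(x$alpha), alpha = unname(x$alpha),
    expected_freq = unname(x$expected_freq),
    xp = unname(x$xp), pxp = unname(x$pxp)
  )
}

#' @rdname tidy.bms_result
#' @export
glance.bms_result <- function(x, ...) {
  tibble::tibble(n_models = length(x$alpha), bor = x$bor, n_iter = x$n_iter)
}

#' Tidy a parameter-recovery report
#'
#' @param x A `recovery_report`.
#' @param ... Unused.
#' @return The per-parameter correlation table.
#' @export
tidy.recovery_report <- function(x, ...) x$correlations

#' @rdname tidy.recovery_report
#' @export
glance.recovery_report <- function(x, ...) {
  tibble::tibble(model = x$model, n_datasets = x$n_datasets,
                 mean_r = x$mean_r, n_failed = x$n_failed,
                 unreliable = x$unreliable)
}

#' Tidy a model-recovery confusion report
#'
#' @param x A `confusion_report`.
#' @param ... Unused.
#' @return The confusion-matrix counts in long form.
#' @export
tidy.confusion_report <- function(x, ...) x$confusion

#' @rdname tidy.confusion_report
#' @export
glance.confusion_report <- function(x, ...) {
  out <- tibble::tibble(overall = x$overall, n_failed = x$n_failed)
  for (i in seq_len(nrow(x$rates))) {
    out[[paste0("rate_", x$rates$true_family[i])]] <- x$rates$rate[i]
  }
  out
}

#' Tidy a paired surprise comparison
#'
#' @param x A `paired_comparison`.
#' @param ... Unused.
#' @return One-row tibble with `mean_diff`, `conf.low`, `conf.high`,
#'   `n`, `n_boot`.
#' @export
tidy.paired_comparison <- function(x, ...) {
  tibble::tibble(mean_diff = x$mean_diff, conf.low = x$ci[1],
                 conf.high = x$ci[2], n = length(x$diffs),
                 n_boot = x$n_boot)
}
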