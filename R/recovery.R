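# Identifiability harnesses: parameter recovery (simulate with known
# parameters, refit, correlate) and model recovery (simulate from each
# family, fit every family, tabulate the confusion matrix of
# highest-evidence selections).

# Draw generating values for the free parameters: prior draws truncated
# to the numerically stable region of param_bounds() (rejection
# sampling; uniform for flat priors).
draw_free_params <- function(model, free, priors = model_priors(model)) {
  bounds <- param_bounds()
  out <- list()
  for (p in free) {
    row <- priors[priors$parameter == p, ]
    b <- bounds[bounds$parameter == p, ]
    f <- transform_fun(row$transform)
    val <- NA_real_
    for (i in 1:200) {
      val <- f$from(rnorm(1, row$prior_mean, sqrt(row$prior_var)))
      if (!nrow(b) || (val >= b$lower && val <= b$upper)) break
      val <- NA_real_
    }
    if (is.na(val)) val <- f$from(row$prior_mean)
    out[[p]] <- val
  }
  out
}

#' Parameter recovery for a learning model
#'
#' Simulates `n_datasets` response series from the model with free
#' parameters drawn from their priors (truncated to the stable region),
#' on freshly generated task designs, refits each with [map_fit()], and
#' correlates true against recovered values per parameter. The report's
#' `mean_r` is the arithmetic mean of the per-parameter Pearson
#' correlations.
#'
#' @param model Model id (default `"hgf3"`).
#' @param n_datasets Number of simulated datasets (default 80).
#' @param config Task configuration for the generated designs.
#' @param free Free parameters (defaults as in [map_fit()]).
#' @param n_restarts Optimizer starts per fit.
#' @param seed Seed driving designs, parameter draws, responses and
#'   restart jitter.
#' @return A `recovery_report`: list with `estimates` (tibble `dataset`,
#'   `parameter`, `true`, `recovered`), `correlations` (per-parameter
#'   `r`), `mean_r`, `n_failed`, `unreliable` (flagged when more than
#'   20% of fits failed), `model`, `n_datasets`.
#' @examples
#' \donttest{
#' rep <- parameter_recovery("rw", n_datasets = 10, seed = 1)
#' rep$mean_r
#' }
#' @export
parameter_recovery <- function(model = "hgf3", n_datasets = 80,
                               config = task_config(),
                               free = default_free(model),
                               n_restarts = 5, seed = NULL) {
  stopifnot(n_datasets >= 2)
  if (n_datasets < 10) {
    warning("parameter_recovery: correlations over fewer than 10 datasets ",
            "are unstable", call. = FALSE)
  }
  priors <- model_priors(model)
  rows <- list()
  n_failed <- 0
  for (i in seq_len(n_datasets)) {
    s <- child_seed(seed, i)
    des <- generate_design(config, seed = s)
    truth <- with_seed_(child_seed(s, 1),
                        draw_free_params(model, free, priors))
    sim <- tryCatch(
      simulate_agent(des, model, truth, seed = child_seed(s, 2)),
      error = function(e) NULL
    )
    fit <- if (is.null(sim)) NULL else tryCatch(
      map_fit(model, des, sim$responses, priors = priors, free = free,
              n_restarts = n_restarts, seed = child_seed(s, 3)),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged) {
      n_failed <- n_failed + 1
      next
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      dataset = i, parameter = free,
      true = unlist(truth[free]),
      recovered = unlist(fit$params_hat[free])
    )
  }
  estimates <- dplyr::bind_rows(rows)
  correlations <- estimates |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(r = cor(.data$true, .data$recovered), .groups = "drop")
  structure(
    list(estimates = estimates, correlations = correlations,
         mean_r = mean(correlations$r), n_failed = n_failed,
         unreliable = n_failed > 0.2 * n_datasets,
         model = model, n_datasets = n_datasets, seed = seed),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report> ", x$model, ", ", x$n_datasets, " datasets (",
      x$n_failed, " failed fits", if (x$unreliable) "; UNRELIABLE", ")\n",
      sep = "")
  print(x$correlations)
  cat(sprintf("mean r = %.3f\n", x$mean_r))
  invisible(x)
}

model_family <- function(model) {
  ifelse(model %in% c("hgf2", "hgf3", "hgf4"), "hgf", "rl")
}

#' Model recovery (confusion matrix of family identification)
#'
#' Simulates datasets from each family (members round-robin within a
#' family) with prior-drawn parameters, fits every candidate model to
#' every dataset, selects per dataset the family whose best member has
#' the highest log model evidence (ties broken uniformly at random,
#' seeded), and tabulates the confusion matrix.
#'
#' @param families Named list of model ids per family (default the HGF
#'   family `hgf2/hgf3/hgf4` versus the associative family `rw/sk1`).
#' @param n_per_family Simulated datasets per generating family.
#' @param config Task configuration for the generated designs.
#' @param n_restarts Optimizer starts per fit.
#' @param selection `"lme"` (highest log model evidence; default).
#' @param seed Seed.
#' @return A `confusion_report`: list with `confusion` (tibble
#'   `true_family` x `selected_family` counts), `rates` (per-family
#'   recovery), `overall` (trace over total), `details`, `n_failed`.
#' @export
model_recovery <- function(families = list(hgf = c("hgf2", "hgf3", "hgf4"),
                                           rl = c("rw", "sk1")),
                           n_per_family = 50, config = task_config(),
                           n_restarts = 5, selection = "lme", seed = NULL) {
  stopifnot(length(families) >= 1, selection == "lme")
  fam_names <- names(families)
  all_models <- unique(unlist(families, use.names = FALSE))
  details <- list()
  n_failed <- 0
  idx <- 0
  for (fam in fam_names) {
    members <- families[[fam]]
    for (i in seq_len(n_per_family)) {
      idx <- idx + 1
      gen_model <- members[((i - 1) %% length(members)) + 1]
      s <- child_seed(seed, 1000 + idx)
      des <- generate_design(config, seed = s)
      truth <- with_seed_(child_seed(s, 1),
                          draw_free_params(gen_model, default_free(gen_model)))
      sim <- tryCatch(
        simulate_agent(des, gen_model, truth, seed = child_seed(s, 2)),
        error = function(e) NULL
      )
      if (is.null(sim)) {
        n_failed <- n_failed + 1
        next
      }
      lmes <- vapply(all_models, function(m) {
        fit <- tryCatch(
          map_fit(m, des, sim$responses, n_restarts = n_restarts,
                  seed = child_seed(s, 3 + match(m, all_models))),
          error = function(e) NULL
        )
        if (is.null(fit) || !fit$converged || !is.finite(fit$lme)) {
          NA_real_
        } else {
          fit$lme
        }
      }, numeric(1))
      if (all(is.na(lmes))) {
        n_failed <- n_failed + 1
        next
      }
      fam_lme <- vapply(families, function(m) {
        suppressWarnings(max(lmes[m], na.rm = TRUE))
      }, numeric(1))
      fam_lme[!is.finite(fam_lme)] <- -Inf
      best <- which(fam_lme == max(fam_lme))
      sel <- if (length(best) > 1) {
        with_seed_(child_seed(s, 99), sample(best, 1))
      } else {
        best
      }
      details[[length(details) + 1]] <- tibble::tibble(
        dataset = idx, true_family = fam, gen_model = gen_model,
        selected_family = fam_names[sel],
        !!!setNames(as.list(lmes), paste0("lme_", all_models))
      )
    }
  }
  details <- dplyr::bind_rows(details)
  confusion <- details |>
    dplyr::count(.data$true_family, .data$selected_family) |>
    tidyr::complete(true_family = fam_names, selected_family = fam_names,
                    fill = list(n = 0L))
  rates <- details |>
    dplyr::group_by(.data$true_family) |>
    dplyr::summarise(
      rate = mean(.data$selected_family == .data$true_family),
      n = dplyr::n(), .groups = "drop"
    )
  structure(
    list(confusion = confusion, rates = rates,
         overall = mean(details$selected_family == details$true_family),
         details = details, n_failed = n_failed,
         unreliable = n_failed > 0.2 * length(fam_names) * n_per_family,
         selection = selection, seed = seed),
    class = "confusion_report"
  )
}

#' @export
print.confusion_report <- function(x, ...) {
  cat("<confusion_report> overall recovery ",
      sprintf("%.1f%%", 100 * x$overall),
      " (", x$n_failed, " failed datasets)\n", sep = "")
  print(tidyr::pivot_wider(x$confusion, names_from = "selected_family",
                           values_from = "n"))
  invisible(x)
}
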