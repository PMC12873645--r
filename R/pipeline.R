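# End-to-end orchestration: generate or load a cohort, fit the model
# space per participant, run Bayesian model selection, compare the
# context and no-context networks on behavioural and observational
# surprise (with and without the volatility node), and optionally run
# the recovery harnesses. Every stage is a pure function of
# (inputs, config, seed); rerunning with the same seeds reproduces the
# summary exactly.

#' Simulate a cohort of participants
#'
#' Generates one task design and one simulated agent per participant.
#' Per-participant parameters are drawn from the model priors truncated
#' to the stable region (or fixed via `params`).
#'
#' @param n_participants Cohort size.
#' @param model Generating model id for the agents.
#' @param config Task configuration.
#' @param params Optional named list fixing the generating parameters
#'   for every participant; when `NULL` they are drawn per participant.
#' @param seed Seed.
#' @return A `cohort`: tibble with `participant` and list-columns `seq`
#'   (designs), `responses`, `truth` (generating parameters).
#' @export
simulate_cohort <- function(n_participants, model = "hgf3",
                            config = task_config(), params = NULL,
                            seed = NULL) {
  rows <- purrr::map(seq_len(n_participants), function(i) {
    s <- child_seed(seed, 500 + i)
    des <- generate_design(config, seed = s)
    drawn <- draw_stable_agent(des, model, params, s)
    tibble::tibble(participant = i, seq = list(des),
                   responses = list(drawn$sim$responses),
                   truth = list(drawn$truth))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "model") <- model
  class(out) <- c("cohort", class(out))
  out
}

# Draw agent parameters and simulate responses, rejecting the rare prior
# draws whose own filter diverges (they cannot generate data).
draw_stable_agent <- function(des, model, params, s) {
  for (attempt in 0:29) {
    truth <- if (is.null(params)) {
      with_seed_(child_seed(s, 1 + 100 * attempt),
                 draw_free_params(model, default_free_any(model)))
    } else {
      params
    }
    sim <- tryCatch(
      simulate_agent(des, model, truth, seed = child_seed(s, 2)),
      error = function(e) NULL
    )
    if (!is.null(sim)) return(list(truth = truth, sim = sim))
    if (!is.null(params)) break
  }
  stop("simulate_cohort: could not simulate a stable agent for model ",
       model, call. = FALSE)
}

# free-parameter defaults extended to the network variants
default_free_any <- function(model) {
  if (model %in% c("context", "nocontext")) {
    c("lambda_2", "lambda_4", "omega_4")
  } else {
    default_free(model)
  }
}

#' Build a cohort manifest of trial CSV files
#'
#' @param participants Unique participant ids.
#' @param trial_files Character vector of trial CSV paths (same length),
#'   each readable by [read_trials()], or `NA` for participants to be
#'   generated from `config`.
#' @param seeds Integer per participant.
#' @return A `cohort_manifest` tibble.
#' @export
cohort_manifest <- function(participants, trial_files = NA, seeds = NULL) {
  stopifnot(!anyDuplicated(participants))
  trial_files <- rep_len(trial_files, length(participants))
  real <- trial_files[!is.na(trial_files)]
  missing <- real[!file.exists(real)]
  if (length(missing)) {
    stop("manifest references missing files: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    participant = participants, trial_file = trial_files,
    seed = seeds %||% seq_along(participants)
  )
  class(out) <- c("cohort_manifest", class(out))
  out
}

#' Run the full analysis over a cohort
#'
#' Per participant: fit the five-model space ([map_fit()]), then the
#' context and no-context networks ([fit_context_params()]), both with
#' and without the volatility node. Across participants: random-effects
#' model selection over the five LMEs, paired bootstrap comparisons of
#' behavioural surprise (no-context minus context) and of observational
#' surprise under both fitted networks. Stage outputs land in
#' `out_dir` when given (CSV/JSON), and the returned summary collects
#' everything.
#'
#' @param cohort A `cohort` from [simulate_cohort()], or a
#'   `cohort_manifest` (trial files plus simulated responses are then
#'   generated from `sim_model`).
#' @param models Model ids for the comparison stage.
#' @param config Task configuration used when generating from a
#'   manifest.
#' @param sim_model Generating model for manifest participants without
#'   data files.
#' @param n_boot Bootstrap resamples for the paired comparisons.
#' @param n_recovery Datasets for the recovery stage (0 skips it).
#' @param n_restarts Optimizer starts per fit.
#' @param out_dir Optional output directory for per-stage artifacts.
#' @param seed Seed.
#' @return An `analysis_report`: list with `fits` (per-participant
#'   glance tibble), `lme` matrix, `bms`, `context_fits`,
#'   `behavioral_comparison`, `behavioral_comparison_novol`,
#'   `observational_comparison`, `recovery` (or `NULL`), `seed`.
#' @export
run_full_analysis <- function(cohort,
                              models = c("rw", "sk1", "hgf2", "hgf3", "hgf4"),
                              config = task_config(), sim_model = "hgf3",
                              n_boot = 2000, n_recovery = 0,
                              n_restarts = 5, out_dir = NULL, seed = NULL) {
  if (inherits(cohort, "cohort_manifest")) {
    cohort <- manifest_to_cohort(cohort, config, sim_model, seed)
  }
  stopifnot(inherits(cohort, "cohort"))
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  n <- nrow(cohort)

  # --- stage 1: model-space fits
  fit_rows <- list()
  lme <- matrix(NA_real_, n, length(models),
                dimnames = list(NULL, models))
  for (i in seq_len(n)) {
    for (m in models) {
      fit <- map_fit(m, cohort$seq[[i]], cohort$responses[[i]],
                     n_restarts = n_restarts,
                     seed = child_seed(seed, i * 100 + match(m, models)))
      if (!fit$converged) {
        stop("model fitting failed for participant ",
             cohort$participant[i], ", model ", m, call. = FALSE)
      }
      lme[i, m] <- fit$lme
      fit_rows[[length(fit_rows) + 1]] <-
        dplyr::bind_cols(tibble::tibble(participant = cohort$participant[i]),
                         glance(fit))
    }
  }
  fits <- dplyr::bind_rows(fit_rows)
  if (!is.null(out_dir)) {
    readr::write_csv(fits, file.path(out_dir, "model_fits.csv"))
    write_lme(lme, file.path(out_dir, "lme.csv"))
  }

  # --- stage 2: Bayesian model selection
  bms_res <- bms(lme, seed = child_seed(seed, 2))

  # --- stage 3: context vs no-context networks
  ctx_rows <- list()
  surprise <- list()
  for (vol in c(TRUE, FALSE)) {
    for (variant in c("nocontext", "context")) {
      key <- paste0(variant, if (!vol) "_novol")
      tot_beh <- tot_obs <- numeric(n)
      for (i in seq_len(n)) {
        cf <- fit_context_params(
          variant, cohort$seq[[i]], cohort$responses[[i]],
          include_volatility = vol, n_restarts = n_restarts,
          seed = child_seed(seed, 3000 + i * 10 + (variant == "context") +
                              2 * vol)
        )
        tot_beh[i] <- cf$surprise
        tot_obs[i] <- observational_surprise(cf$trajectory,
                                             cohort$seq[[i]]$u)$total
        ctx_rows[[length(ctx_rows) + 1]] <- tibble::tibble(
          participant = cohort$participant[i], variant = variant,
          include_volatility = vol,
          lambda_2 = cf$params_hat$lambda_2,
          lambda_4 = cf$params_hat$lambda_4,
          omega_4 = cf$params_hat$omega_4,
          behavioral_surprise = cf$surprise,
          observational_surprise = tot_obs[i]
        )
      }
      surprise[[key]] <- list(behavioral = tot_beh, observational = tot_obs)
    }
  }
  context_fits <- dplyr::bind_rows(ctx_rows)
  if (!is.null(out_dir)) {
    readr::write_csv(context_fits, file.path(out_dir, "context_fits.csv"))
  }

  behavioral_comparison <- paired_surprise_compare(
    surprise$nocontext$behavioral, surprise$context$behavioral,
    n_boot = n_boot, seed = child_seed(seed, 4)
  )
  behavioral_comparison_novol <- paired_surprise_compare(
    surprise$nocontext_novol$behavioral, surprise$context_novol$behavioral,
    n_boot = n_boot, seed = child_seed(seed, 5)
  )
  observational_comparison <- paired_surprise_compare(
    surprise$context$observational, surprise$nocontext$observational,
    n_boot = n_boot, seed = child_seed(seed, 6)
  )

  # --- stage 4 (optional): recovery harnesses
  recovery <- NULL
  if (n_recovery > 0) {
    recovery <- parameter_recovery("hgf3", n_datasets = n_recovery,
                                   config = config,
                                   seed = child_seed(seed, 7))
  }

  report <- structure(
    list(fits = fits, lme = lme, bms = bms_res,
         context_fits = context_fits,
         behavioral_comparison = behavioral_comparison,
         behavioral_comparison_novol = behavioral_comparison_novol,
         observational_comparison = observational_comparison,
         recovery = recovery, n_participants = n, models = models,
         seed = seed),
    class = "analysis_report"
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(summarize_report(report),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

manifest_to_cohort <- function(manifest, config, sim_model, seed) {
  rows <- purrr::map(seq_len(nrow(manifest)), function(i) {
    s <- manifest$seed[i]
    des <- if (!is.na(manifest$trial_file[i])) {
      read_trials(manifest$trial_file[i])
    } else {
      generate_design(config, seed = s)
    }
    drawn <- draw_stable_agent(des, sim_model, NULL, s)
    tibble::tibble(participant = manifest$participant[i], seq = list(des),
                   responses = list(drawn$sim$responses),
                   truth = list(drawn$truth))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "model") <- sim_model
  class(out) <- c("cohort", class(out))
  out
}

summarize_report <- function(report) {
  list(
    n_participants = report$n_participants,
    models = report$models,
    bms = list(expected_freq = as.list(report$bms$expected_freq),
               pxp = as.list(report$bms$pxp), bor = report$bms$bor),
    behavioral_comparison = list(
      mean_diff = report$behavioral_comparison$mean_diff,
      ci = report$behavioral_comparison$ci
    ),
    behavioral_comparison_novol = list(
      mean_diff = report$behavioral_comparison_novol$mean_diff,
      ci = report$behavioral_comparison_novol$ci
    ),
    observational_comparison = list(
      mean_diff = report$observational_comparison$mean_diff,
      ci = report$observational_comparison$ci
    ),
    recovery = if (!is.null(report$recovery)) {
      list(mean_r = report$recovery$mean_r)
    },
    seed = report$seed
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report> ", x$n_participants, " participants, models: ",
      paste(x$models, collapse = ", "), "\n", sep = "")
  cat("protected exceedance probabilities:\n")
  print(round(x$bms$pxp, 4))
  cat(sprintf(
    "behavioural surprise (nocontext - context): %.2f [%.2f, %.2f]\n",
    x$behavioral_comparison$mean_diff, x$behavioral_comparison$ci[1],
    x$behavioral_comparison$ci[2]
  ))
  cat(sprintf(
    "observational surprise (context - nocontext): %.2f [%.2f, %.2f]\n",
    x$observational_comparison$mean_diff, x$observational_comparison$ci[1],
    x$observational_comparison$ci[2]
  ))
  invisible(x)
}

#' Expected-minus-unexpected performance difference
#'
#' Classifies each trial as expected when its bounce outcome is
#' consistent with the block's dominant colour-bounce mapping (which is
#' exactly `u == true_state`) and returns the mean radial error on
#' expected trials minus the mean on unexpected trials. A positive value
#' indicates worse returns on expected trials; a negative value the
#' usual surprise cost on unexpected trials.
#'
#' @param seq A `trial_design` tibble.
#' @param perf Tibble with per-trial `radial_error` in metres (>= 0),
#'   aligned with `seq`.
#' @return List with `e_ue` (metres), `n_expected`, `n_unexpected` and
#'   the per-trial `expected` flag.
#' @export
compute_eue <- function(seq, perf) {
  err <- if (is.data.frame(perf)) perf$radial_error else perf
  stopifnot(length(err) == nrow(seq), all(err >= 0))
  expected <- seq$u == seq$true_state
  if (!any(expected) || all(expected)) {
    stop("compute_eue: need at least one expected and one unexpected trial",
         call. = FALSE)
  }
  list(e_ue = mean(err[expected]) - mean(err[!expected]),
       n_expected = sum(expected), n_unexpected = sum(!expected),
       expected = expected)
}
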