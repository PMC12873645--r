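# Random-effects Bayesian model selection over per-participant log model
# evidences: variational Dirichlet scheme with uniform prior counts,
# Monte-Carlo exceedance probabilities, and the Bayes omnibus risk that
# all models are equally frequent in the population (used to protect the
# exceedance probabilities).

#' Random-effects Bayesian model selection
#'
#' Treats the generating model as a random variable across participants
#' with unknown population frequencies `r ~ Dirichlet(alpha)`. The
#' variational scheme alternates posterior model assignments and
#' Dirichlet counts until the counts change by less than `tol`.
#' Exceedance probabilities (`xp`, the probability each model is the
#' most frequent) are estimated from seeded Dirichlet Monte-Carlo draws;
#' the Bayes omnibus risk (`bor`) compares the free energy of the
#' random-effects model against the null of equal frequencies, and the
#' protected exceedance probabilities are
#' `pxp = (1 - bor) * xp + bor / K`.
#'
#' @param lme Numeric matrix or data frame of log model evidences, rows
#'   participants, columns models (finite; column names become model
#'   names).
#' @param alpha0 Dirichlet prior count per model (default 1, uniform).
#' @param n_samples Monte-Carlo draws for the exceedance probabilities
#'   (default 1e6).
#' @param tol Convergence tolerance of the variational iteration.
#' @param seed Optional seed for the Monte-Carlo step.
#' @return A `bms_result`: list with `alpha` (posterior Dirichlet
#'   counts), `expected_freq`, `xp`, `bor`, `pxp`, `g` (posterior model
#'   assignment matrix) and `n_iter`.
#' @examples
#' lme <- cbind(m1 = c(-100, -102, -98), m2 = c(-104, -101, -103))
#' bms(lme, seed = 1)
#' @export
bms <- function(lme, alpha0 = 1, n_samples = 1e6, tol = 1e-6, seed = NULL) {
  lme <- as.matrix(lme)
  if (any(!is.finite(lme))) {
    bad <- which(!is.finite(lme), arr.ind = TRUE)
    stop("bms: non-finite log model evidence at [",
         paste(apply(bad, 1, paste, collapse = ","), collapse = "; "),
         "] (participant, model)", call. = FALSE)
  }
  n <- nrow(lme)
  K <- ncol(lme)
  stopifnot(K >= 2)
  models <- colnames(lme) %||% paste0("model", seq_len(K))

  a0 <- rep(alpha0, K)
  alpha <- a0
  g <- matrix(0, n, K)
  n_iter <- 0
  repeat {
    n_iter <- n_iter + 1
    lw <- sweep(lme, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    lw <- lw - apply(lw, 1, max)
    g <- exp(lw) / rowSums(exp(lw))
    alpha_new <- a0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < tol || n_iter > 500) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  expected_freq <- alpha / sum(alpha)

  xp <- with_seed_(seed, {
    counts <- integer(K)
    remaining <- n_samples
    while (remaining > 0) {
      nb <- min(remaining, 250000L)
      draws <- matrix(rgamma(nb * K, shape = rep(alpha, each = nb)), nb, K)
      best <- max.col(draws, ties.method = "first")
      counts <- counts + tabulate(best, K)
      remaining <- remaining - nb
    }
    counts / n_samples
  })

  bor <- bms_bor(lme, g, alpha, a0)
  pxp <- (1 - bor) * xp + bor / K

  structure(
    list(alpha = setNames(alpha, models),
         expected_freq = setNames(expected_freq, models),
         xp = setNames(xp, models), bor = bor,
         pxp = setNames(pxp, models), g = g, n_iter = n_iter),
    class = "bms_result"
  )
}

# Bayes omnibus risk: P(H0 | data) where H0 fixes equal model
# frequencies. F1 is the variational free energy of the random-effects
# model, F0 the evidence under equal frequencies.
bms_bor <- function(lme, g, alpha, a0) {
  n <- nrow(lme)
  K <- ncol(lme)
  # F0: each participant's model drawn uniformly
  F0 <- sum(apply(lme, 1, function(r) {
    m <- max(r)
    m + log(mean(exp(r - m)))
  }))
  dig <- digamma(alpha) - digamma(sum(alpha))
  elog <- sum(g * sweep(lme, 2, dig, "+"))
  ent <- -sum(g[g > 0] * log(g[g > 0]))
  kl <- lgamma(sum(alpha)) - sum(lgamma(alpha)) -
    lgamma(sum(a0)) + sum(lgamma(a0)) +
    sum((alpha - a0) * (digamma(alpha) - digamma(sum(alpha))))
  F1 <- elog + ent - kl
  1 / (1 + exp(F1 - F0))
}

#' @export
print.bms_result <- function(x, ...) {
  cat("<bms_result> ", length(x$alpha), " models, bor = ",
      sprintf("%.4f", x$bor), "\n", sep = "")
  print(tidy(x), ...)
  invisible(x)
}

#' Paired bootstrap comparison of per-participant surprise totals
#'
#' Descriptive stand-in for a group-level inferential model: reports the
#' mean of the per-participant differences `a - b` with a seeded
#' nonparametric bootstrap percentile confidence interval. This is a
#' summary of the cohort at hand, not a hierarchical posterior.
#'
#' @param a,b Numeric vectors of per-participant surprise totals under
#'   the two models (equal length, >= 2).
#' @param n_boot Bootstrap resamples (default 2000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional seed.
#' @return A `paired_comparison`: list with `mean_diff`, `ci`, `diffs`,
#'   `n_boot`, `level`.
#' @export
paired_surprise_compare <- function(a, b, n_boot = 2000, level = 0.95,
                                    seed = NULL) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  diffs <- a - b
  boots <- with_seed_(seed, {
    vapply(seq_len(n_boot), function(i) {
      mean(diffs[sample.int(length(diffs), replace = TRUE)])
    }, numeric(1))
  })
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- unname(quantile(boots, probs))
  # percentile CIs need not bracket the point estimate in tiny samples;
  # widen to include it so the interval always contains mean_diff
  ci[1] <- min(ci[1], mean(diffs))
  ci[2] <- max(ci[2], mean(diffs))
  structure(
    list(mean_diff = mean(diffs), ci = ci, diffs = diffs,
         n_boot = n_boot, level = level),
    class = "paired_comparison"
  )
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf(
    "<paired_comparison> mean difference = %.4f, %g%% bootstrap CI [%.4f, %.4f] (n = %d)\n",
    x$mean_diff, 100 * x$level, x$ci[1], x$ci[2], length(x$diffs)
  ))
  invisible(x)
}

#' Read or write a log-model-evidence matrix as CSV
#'
#' Rows are participants (column `participant`), remaining columns one
#' model each.
#'
#' @param lme Matrix of LMEs (rows participants, columns models).
#' @param path CSV path.
#' @export
write_lme <- function(lme, path) {
  df <- tibble::as_tibble(as.data.frame(lme))
  df <- dplyr::bind_cols(tibble::tibble(participant = seq_len(nrow(df))), df)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_lme
#' @export
read_lme <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols())
  as.matrix(df[setdiff(names(df), "participant")])
}
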