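# Shared numerical helpers. Probabilities are clipped to [eps, 1 - eps]
# before any log; belief variances must stay strictly positive.

.prob_eps <- 1e-8

sgm <- function(x) 1 / (1 + exp(-x))

clip_prob <- function(p, eps = .prob_eps) pmin(pmax(p, eps), 1 - eps)

#' Unit-square sigmoid observation model
#'
#' Maps a predicted probability of the outcome coded 1 into a response
#' probability via the decision-noise exponent `zeta`:
#' `p(y = 1) = muhat^zeta / (muhat^zeta + (1 - muhat)^zeta)`.
#' `zeta = 1` is the identity map, `zeta -> Inf` deterministic responding,
#' `zeta = 0` unbiased guessing.
#'
#' @param muhat Predicted probability (vectorised). Values at 0 or 1 are
#'   clipped to `[1e-8, 1 - 1e-8]`.
#' @param zeta Non-negative decision-noise exponent.
#' @return Probability of responding 1, same length as `muhat`.
#' @examples
#' unitsq_sigmoid(0.87, 2)
#' @export
unitsq_sigmoid <- function(muhat, zeta) {
  stopifnot(zeta >= 0)
  m <- clip_prob(muhat)
  # compute in log space for numerical safety at large zeta
  a <- zeta * log(m)
  b <- zeta * log(1 - m)
  1 / (1 + exp(b - a))
}

#' Binary surprise (negative log predictive probability)
#'
#' Surprise in nats of observing the binary outcome `x` under the
#' predicted probability `muhat` of `x = 1`: `-log(muhat)` if `x = 1`,
#' `-log(1 - muhat)` if `x = 0`. Summed over trials this equals the
#' negative predictive log-likelihood of the series.
#'
#' @param x Binary outcome(s), 0 or 1.
#' @param muhat Predicted probability of `x = 1` (clipped away from 0/1).
#' @return Surprise in nats, always non-negative.
#' @examples
#' binary_surprise(0, 0.87) # -log(0.13)
#' @export
binary_surprise <- function(x, muhat) {
  stopifnot(all(x %in% c(0, 1)))
  m <- clip_prob(muhat)
  -ifelse(x == 1, log(m), log(1 - m))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`
# (restores the caller's RNG afterwards). seed = NULL runs unseeded.
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed, kept inside 32-bit range.
child_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}
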