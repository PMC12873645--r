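test_that("parameter transforms round-trip", {
  for (m in c("rw", "sk1", "hgf2", "hgf3", "hgf4")) {
    pr <- model_priors(m)
    for (i in seq_len(nrow(pr))) {
      f <- gazehgf:::transform_fun(pr$transform[i])
      x <- pr$prior_mean[i] + 0.37
      expect_equal(f$to(f$from(x)), x, tolerance = 1e-12)
    }
    # fixed rows are exactly the zero-variance rows
    expect_identical(pr$fixed, pr$prior_var == 0)
  }
})

test_that("MAP fitting recovers a generating RW learning rate", {
  alphas <- numeric(20)
  for (i in 1:20) {
    dat <- make_sim("rw", list(alpha = 0.3, zeta = 3), seed = 100 + i)
    fit <- map_fit("rw", dat$des, dat$y, seed = 200 + i)
    expect_true(fit$converged)
    alphas[i] <- fit$params_hat$alpha
  }
  expect_true(all(alphas > 0.10 & alphas < 0.50))
  expect_lt(abs(mean(alphas) - 0.3), 0.08)
})

test_that("degenerate priors pin the estimates at the prior means", {
  dat <- make_sim("rw", list(alpha = 0.6, zeta = 2), seed = 1)
  pr <- model_priors("rw")
  pr$prior_var <- 0
  pr$fixed <- TRUE
  fit <- map_fit("rw", dat$des, dat$y, priors = pr, seed = 2)
  expect_equal(fit$params_hat$alpha, 0.5)
  expect_equal(fit$params_hat$v0, 0.5)
  expect_equal(fit$params_hat$zeta, 1)
  expect_equal(length(fit$free), 0)
  expect_equal(fit$lme, fit$log_joint)
})

test_that("more restarts never lose ground on the same data", {
  dat <- make_sim("hgf3", list(omega = -3, zeta = 2), seed = 5)
  f2 <- map_fit("hgf3", dat$des, dat$y, n_restarts = 2, seed = 9)
  f6 <- map_fit("hgf3", dat$des, dat$y, n_restarts = 6, seed = 9)
  expect_gte(f6$log_joint + 1e-9, f2$log_joint)
})

test_that("fits are reproducible bit-for-bit given a seed", {
  dat <- make_sim("hgf3", list(omega = -4, zeta = 3), seed = 3)
  f1 <- map_fit("hgf3", dat$des, dat$y, seed = 11)
  f2 <- map_fit("hgf3", dat$des, dat$y, seed = 11)
  expect_identical(f1$theta_hat, f2$theta_hat)
  expect_identical(f1$log_joint, f2$log_joint)
  expect_identical(f1$lme, f2$lme)
})

test_that("the response likelihood equals negative behavioural surprise at
          unit decision noise", {
  dat <- make_sim("hgf3", list(omega = -4, zeta = 1), seed = 6)
  traj <- hgf_filter(dat$des$u, n_levels = 3)
  ll <- gazehgf:::bernoulli_loglik(dat$y, unitsq_sigmoid(traj$muhat_1, 1))
  expect_equal(ll, -behavioral_surprise(traj, dat$y)$total,
               tolerance = 1e-9)
})

test_that("the Laplace evidence matches the 1-D Gaussian closed form", {
  # quadratic objective log f(x) = c - (x - m)^2 / (2 s^2):
  # log integral = c + 0.5 log(2 pi s^2)
  cc <- -12.3
  m <- 0.7
  s <- 0.35
  fake <- list(
    objective = function(x) cc - (x - m)^2 / (2 * s^2),
    theta_hat = m, log_joint = cc, converged = TRUE, n_trials = 100
  )
  expect_equal(laplace_lme(fake), cc + 0.5 * log(2 * pi * s^2),
               tolerance = 1e-6)
})

test_that("an irrelevant free parameter pays an Occam penalty on average", {
  diffs <- numeric(20)
  for (i in 1:20) {
    # data generated at the prior mean of mu2_0, so freeing it adds
    # flexibility without explanatory value
    dat <- make_sim("hgf3", list(omega = -4, mu2_0 = 0, zeta = 2),
                    seed = 400 + i)
    f_small <- map_fit("hgf3", dat$des, dat$y, free = c("omega", "zeta"),
                       seed = 500 + i)
    f_big <- map_fit("hgf3", dat$des, dat$y,
                     free = c("omega", "mu2_0", "zeta"), seed = 500 + i)
    diffs[i] <- f_big$lme - f_small$lme
  }
  expect_lt(mean(diffs), 0)
})

test_that("filter failures during search are handled, not raised", {
  # an objective region where the HGF diverges must not crash the fit
  dat <- make_sim("hgf3", list(omega = -3, zeta = 2), seed = 7)
  fit <- map_fit("hgf3", dat$des, dat$y, n_restarts = 6, seed = 8)
  expect_true(fit$converged)
  expect_true(is.finite(fit$lme))
})

test_that("context-network fitting honours its contracts", {
  des <- generate_design(task_config(seed = 21))
  sim <- simulate_agent(des, "context",
                        c(context_demo_params(), list(zeta = 2)),
                        seed = 22)
  y <- sim$responses$y
  K <- nrow(des)

  # flat-belief degenerate case: everything frozen at a flat readout
  flat <- fit_context_params("nocontext", des, y, include_volatility = FALSE,
                             free = character(0),
                             fixed = list(lambda_2 = 0, lambda_4 = 1,
                                          omega_4 = -5))
  expect_equal(flat$surprise, K * log(2), tolerance = 1e-6)

  fit <- fit_context_params("context", des, y, seed = 23)
  expect_true(fit$converged)
  expect_true(all(unlist(fit$params_hat[c("lambda_2", "lambda_4")]) >= 0))
  # optimizer contract: no worse than the default starting point
  start_surprise <- behavioral_surprise(
    run_forward(build_network("context", lambda_2 = 0.5, lambda_4 = 0.5,
                              omega_4 = -5), des), y)$total
  expect_lte(fit$surprise, start_surprise + 1e-6)
  # the fitted context model explains switching behaviour far better than
  # the no-context fit
  noc <- fit_context_params("nocontext", des, y, seed = 24)
  expect_lt(fit$surprise, noc$surprise)
})

test_that("context parameters are recoverable in direction", {
  truths <- seq(0.1, 0.9, length.out = 12)
  rec <- numeric(12)
  for (i in seq_along(truths)) {
    des <- generate_design(task_config(seed = 700 + i))
    sim <- simulate_agent(des, "context",
                          list(lambda_2 = truths[i], lambda_4 = 1,
                               omega_4 = -1, zeta = 4),
                          seed = 800 + i)
    fit <- fit_context_params("context", des, sim$responses$y,
                              n_restarts = 3, seed = 900 + i)
    rec[i] <- fit$params_hat$lambda_2
  }
  expect_gt(cor(truths, rec), 0.5)
})

test_that("posterior draws pass the split-chain diagnostic", {
  des <- generate_design(task_config(seed = 31))
  sim <- simulate_agent(des, "context",
                        c(context_demo_params(), list(zeta = 2)),
                        seed = 32)
  fit <- fit_context_params("context", des, sim$responses$y,
                            n_draws = 1500, seed = 33)
  expect_s3_class(fit$draws, "tbl_df")
  expect_equal(nrow(fit$draws), 3000)
  expect_true(all(fit$rhat < 1.1))
  td <- tidy(fit)
  expect_true(all(c("q2.5", "q97.5", "rhat") %in% names(td)))
})

test_that("tidiers summarise fits in broom style", {
  dat <- make_sim("rw", list(alpha = 0.4, zeta = 2), seed = 41)
  fit <- map_fit("rw", dat$des, dat$y, seed = 42)
  td <- tidy(fit)
  expect_setequal(td$parameter, c("alpha", "v0", "zeta"))
  expect_false(any(td$fixed))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("model", "lme", "log_joint", "converged") %in% names(gl)))
})
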