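test_that("Rescorla-Wagner updates match the delta rule", {
  tr <- rw_filter(c(1), v0 = 0.5, alpha = 0.5)
  expect_equal(tr$value, 0.75)
  expect_equal(tr$muhat_1, 0.5)
  # zero learning rate freezes the value
  tr0 <- rw_filter(rbinom(50, 1, 0.5), v0 = 0.3, alpha = 0)
  expect_true(all(tr0$value == 0.3))
  # 40-step iteration against the scalar oracle (20 ones then 20 zeros)
  u <- rep(c(1, 0), each = 20)
  tr40 <- rw_filter(u, v0 = 0.5, alpha = 0.1)
  expect_equal(tail(tr40$value, 1), 0.114186213120, tolerance = 1e-10)
  expect_equal(tr40$muhat_1, rw_oracle(u, 0.5, 0.1)$muhat, tolerance = 1e-12)
})

test_that("Sutton K1 reduces to RW at eta = 0 and adapts its gain to
          surprises", {
  u <- rbinom(60, 1, 0.7)
  expect_equal(sk1_filter(u, alpha0 = 0.4, eta = 0)$muhat_1,
               rw_filter(u, alpha = 0.4)$muhat_1, tolerance = 1e-12)
  # frozen 10-step oracle: one disconfirming outcome mid-sequence
  u10 <- c(1, 1, 1, 1, 1, 0, 1, 1, 1, 1)
  tr <- sk1_filter(u10, v0 = 0.5, alpha0 = 0.3, eta = 0.2)
  expect_equal(tail(tr$value, 1), 0.9439016229, tolerance = 1e-9)
  expect_equal(tail(tr$alpha_k, 1), 0.2476762463, tolerance = 1e-9)
  # gain peaks right after the surprise at trial 6
  expect_equal(which.max(tr$alpha_k[2:10]) + 1, 6)
  # long confirmation decays the gain toward zero
  trc <- sk1_filter(rep(1, 300), v0 = 0.5, alpha0 = 0.5, eta = 0.1)
  expect_lt(tail(trc$alpha_k, 1), 0.01)
})

test_that("binary HGF trajectories match the step-by-step oracle", {
  # frozen values from an independent scalar step-through of the update
  # equations with the default starting configuration
  tr <- hgf_filter(c(1, 1, 0, 1, 0), n_levels = 3)
  expect_equal(tr$muhat_1,
               c(0.5, 0.5133849336, 0.5272084813, 0.5113953775, 0.5267766073),
               tolerance = 1e-9)
  expect_equal(tr$mu_2,
               c(0.0535525293, 0.1089415429, 0.0455894046, 0.1072089977,
                 0.0378357567),
               tolerance = 1e-9)
  expect_equal(tr$sigma_2,
               c(0.1071050587, 0.1138251102, 0.1201652488, 0.1261134060,
                 0.1316938527),
               tolerance = 1e-9)
  expect_equal(tr$mu_3,
               c(0.9999667993, 0.9998675830, 0.9999711317, 0.9998750448,
                 0.9999746817),
               tolerance = 1e-9)
  expect_equal(tr$sigma_3,
               c(1.0139809710, 1.0283049282, 1.0431180297, 1.0580017707,
                 1.0732619850),
               tolerance = 1e-9)
})

test_that("constant input drives the HGF prediction monotonically toward
          certainty", {
  for (n in 2:4) {
    tr <- hgf_filter(rep(1, 80), n_levels = n)
    expect_true(all(diff(tr$muhat_1) > 0))
    expect_lt(tail(tr$muhat_1, 1), 1)
  }
})

test_that("the two-level HGF update is the Kalman-like gain form", {
  tr <- hgf_filter(c(1, 0, 1), n_levels = 2, omega = -2, mu2_0 = 0.2,
                   sigma2_0 = 0.5)
  # one-step closed form: pihat = 1/(sigma + exp(omega)); the posterior
  # adds the Bernoulli information and the mean moves by delta / pi
  pihat <- 1 / (0.5 + exp(-2))
  m1 <- plogis(0.2)
  pi2 <- pihat + m1 * (1 - m1)
  expect_equal(tr$mu_2[1], 0.2 + (1 - m1) / pi2, tolerance = 1e-12)
  expect_equal(tr$sigma_2[1], 1 / pi2, tolerance = 1e-12)
})

test_that("freezing the volatility level reduces HGF3 to HGF2", {
  u <- rbinom(120, 1, 0.6)
  # volatility belief pinned at its starting value: its step variance and
  # top-level drift are switched off, leaving exp(kappa * mu3_0 + omega)
  h3 <- hgf_filter(u, n_levels = 3, omega = -5.6, theta = -40,
                   mu3_0 = 1, sigma3_0 = 1e-12)
  h2 <- hgf_filter(u, n_levels = 2, omega = -5.6 + 1)
  expect_equal(h3$muhat_1, h2$muhat_1, tolerance = 1e-8)
  expect_equal(h3$mu_2, h2$mu_2, tolerance = 1e-8)
})

test_that("filters are online: prefixes depend only on seen inputs", {
  u <- rbinom(40, 1, 0.5)
  for (fit in list(
    function(x) rw_filter(x, alpha = 0.3),
    function(x) sk1_filter(x, alpha0 = 0.3, eta = 0.1),
    function(x) hgf_filter(x, n_levels = 3),
    function(x) hgf_filter(x, n_levels = 4)
  )) {
    full <- fit(u)
    half <- fit(u[1:20])
    expect_equal(as.data.frame(full[1:20, names(half)]), as.data.frame(half),
                 tolerance = 1e-12)
  }
})

test_that("total surprise equals the negative predictive log-likelihood", {
  u <- rbinom(100, 1, 0.7)
  tr <- hgf_filter(u, n_levels = 3)
  nll <- -sum(log(ifelse(u == 1, tr$muhat_1, 1 - tr$muhat_1)))
  expect_equal(sum(tr$surprise), nll, tolerance = 1e-10)
})

test_that("RW tracks the running contingency on stationary blocks", {
  des <- generate_design(task_config(trials_per_session = 1500,
                                     switches_per_session = 0,
                                     n_sessions = 1, seed = 3))
  tr <- rw_filter(des$u, alpha = 0.1)
  v_late <- tail(tr$value, 500)
  p_eff <- if (des$true_state[1] == 1) 0.87 else 0.13
  expect_lt(max(abs(mean(v_late) - p_eff)), 0.1)
})

test_that("the unit-square sigmoid has its closed-form limits", {
  expect_equal(unitsq_sigmoid(0.5, 0), 0.5)
  expect_equal(unitsq_sigmoid(0.5, 7.3), 0.5)
  p <- runif(20)
  expect_equal(unitsq_sigmoid(p, 1), p, tolerance = 1e-9)
  expect_equal(unitsq_sigmoid(0.87, 2), 0.87^2 / (0.87^2 + 0.13^2),
               tolerance = 1e-12)
  expect_equal(round(unitsq_sigmoid(0.87, 2), 4), 0.9782)
  # boundary values are clipped, not propagated
  expect_true(is.finite(unitsq_sigmoid(1, 5)))
  expect_gt(unitsq_sigmoid(1, 5), 0.999)
})

test_that("binary surprise is the negative log predicted probability", {
  expect_equal(binary_surprise(1, 0.5), log(2), tolerance = 1e-12)
  expect_equal(round(binary_surprise(0, 0.5), 4), 0.6931)
  expect_equal(binary_surprise(0, 0.87), -log(0.13), tolerance = 1e-12)
  expect_equal(round(binary_surprise(0, 0.87), 4), 2.0402)
  expect_lt(binary_surprise(1, 1 - 1e-9), 1e-6)
  expect_true(all(binary_surprise(rbinom(50, 1, 0.5), runif(50)) >= 0))
})

test_that("divergent HGF settings raise a located filtering error", {
  # a pathological volatility belief overflows the step variance; the
  # filter must fail loudly naming the trial and level, never silently
  expect_error(
    hgf_filter(rep(c(1, 0), 200), n_levels = 3, mu3_0 = 800),
    "trial.*level"
  )
})

test_that("trajectories serialize to long format", {
  tr <- rw_filter(c(1, 0, 1), alpha = 0.5)
  long <- trajectory_long(tr)
  expect_setequal(unique(long$quantity),
                  setdiff(names(tr), "trial"))
  expect_equal(nrow(long), 3 * (ncol(tr) - 1))
})
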