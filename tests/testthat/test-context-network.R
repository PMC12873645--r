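test_that("network builds have the canonical topology", {
  noc <- build_network("nocontext")
  ctx <- build_network("context")
  # the context build is the no-context build plus the cross-arm edge
  cross <- dplyr::anti_join(ctx$edges, noc$edges,
                            by = c("child", "parent", "coupling"))
  expect_equal(nrow(cross), 1)
  expect_equal(cross$child, "assoc")
  expect_equal(cross$parent, "ctx")
  expect_equal(cross$coupling, "value")
  expect_identical(dplyr::anti_join(noc$edges, ctx$edges,
                                    by = c("child", "parent", "coupling")) |>
                     nrow(), 0L)
  # three-level ball arm: binary input, binary state, association node,
  # volatility parent
  expect_setequal(
    noc$nodes$node_id,
    c("u_input", "ball_bin", "assoc", "c_input", "ctx_bin", "ctx",
      "assoc_vol")
  )
  expect_true(any(noc$edges$coupling == "volatility"))
  # the robustness variant strips volatility parents everywhere
  novol <- build_network("context", include_volatility = FALSE)
  expect_false(any(novol$edges$coupling == "volatility"))
  expect_false("assoc_vol" %in% novol$nodes$node_id)
  expect_error(build_network("something"), "arg")
})

test_that("the no-context build reproduces the three-level HGF exactly", {
  for (s in 1:100) {
    des <- generate_design(task_config(seed = s))
    fwd <- run_forward(build_network("nocontext"), des)
    ref <- hgf_filter(des$u, n_levels = 3)
    expect_lt(max(abs(fwd$muhat_1 - ref$muhat_1)), 1e-8)
    expect_lt(max(abs(fwd$mu_assoc - ref$mu_2)), 1e-8)
    expect_lt(max(abs(fwd$sigma_assoc - ref$sigma_2)), 1e-8)
    expect_lt(max(abs(fwd$mu_assoc_vol - ref$mu_3)), 1e-8)
  }
})

test_that("run_forward agrees with iterated propagate_trial", {
  des <- generate_design(task_config(seed = 8))[1:25, ]
  for (variant in c("context", "nocontext")) {
    net <- build_network(variant, lambda_2 = 0.4, lambda_4 = 0.9,
                         omega_4 = -2)
    fwd <- run_forward(net, des)
    state <- NULL
    for (k in seq_len(nrow(des))) {
      state <- propagate_trial(net, list(u = des$u[k], c = des$c[k]),
                               state, trial = k)
      expect_equal(unname(state$mu["assoc"]), fwd$mu_assoc[k],
                   tolerance = 1e-12)
      expect_equal(unname(state$mu["ctx"]), fwd$mu_ctx[k],
                   tolerance = 1e-12)
      expect_equal(unname(state$record$muhat_bin["ball_bin"]),
                   fwd$muhat_1[k], tolerance = 1e-12)
    }
  }
})

test_that("removing the cross-arm edge leaves the context arm unchanged", {
  des <- generate_design(task_config(seed = 13))
  ctx <- run_forward(build_network("context", lambda_2 = 0.3,
                                   lambda_4 = 0.9, omega_4 = -2), des)
  noc <- run_forward(build_network("nocontext", lambda_2 = 0.3,
                                   lambda_4 = 0.9, omega_4 = -2), des)
  expect_equal(ctx$mu_ctx, noc$mu_ctx, tolerance = 1e-12)
  expect_equal(ctx$sigma_ctx, noc$sigma_ctx, tolerance = 1e-12)
  # but the ball arm differs through the top-down term
  expect_gt(max(abs(ctx$mu_assoc - noc$mu_assoc)), 0.1)
})

test_that("zero autoconnection pins the association prediction to its
          parent", {
  des <- generate_design(task_config(seed = 14))
  fwd <- run_forward(build_network("context", lambda_2 = 0,
                                   lambda_4 = 1, omega_4 = -2), des)
  # prediction = lagged context mean, regardless of the node's own history
  expect_equal(fwd$muhat_assoc[-1], fwd$mu_ctx[-nrow(fwd)],
               tolerance = 1e-12)
  expect_equal(fwd$muhat_assoc[1], 0)
})

test_that("an isolated node with full autoconnection filters its input", {
  # the context arm alone: lambda = 1, near-zero tonic volatility gives
  # a shrinking-gain running filter whose uncertainty contracts
  des <- tibble::tibble(u = rep(0L, 150), c = rep(1L, 150))
  fwd <- run_forward(build_network("nocontext", lambda_4 = 1,
                                   omega_4 = -12, cue_reliability = 1), des)
  expect_true(all(diff(fwd$sigma_ctx) < 0))
  expect_true(all(diff(fwd$mu_ctx) > 0))
  expect_gt(tail(plogis(fwd$mu_ctx), 1), 0.7)
})

test_that("behavioural and observational surprise score the readout", {
  # flat readout: lambda_2 = 0 with a flat context arm keeps p at one half
  des <- generate_design(task_config(seed = 15))
  K <- nrow(des)
  net <- build_network("nocontext", lambda_2 = 0,
                       include_volatility = FALSE)
  net$nodes$mu0[net$nodes$node_id == "ctx"] <- 0
  fwd <- run_forward(net, des)
  expect_true(all(abs(fwd$muhat_1 - 0.5) < 1e-12))
  y <- rbinom(K, 1, 0.5)
  bs <- behavioral_surprise(fwd, y)
  expect_equal(bs$total, K * log(2), tolerance = 1e-9)

  # closed form at a constant confident readout
  muhat <- rep(0.87, K)
  fake <- fwd
  fake$muhat_1 <- muhat
  best <- behavioral_surprise(fake, as.integer(muhat > 0.5))
  expect_equal(best$total, K * -log(0.87), tolerance = 1e-9)
  expect_equal(round(best$total / K, 4), 0.1393)

  # observational surprise is the same functional applied to u
  obs <- observational_surprise(fwd, des$u)
  beh <- behavioral_surprise(fwd, des$u)
  expect_equal(obs$total, beh$total)
  expect_true(all(obs$per_trial >= 0))
  expect_equal(obs$total, sum(obs$per_trial))

  # five-trial hand check
  m5 <- c(0.5, 0.6, 0.7, 0.2, 0.9)
  y5 <- c(1, 0, 1, 0, 1)
  fake5 <- tibble::tibble(muhat_1 = m5)
  expect_equal(behavioral_surprise(fake5, y5)$total,
               -(log(0.5) + log(0.4) + log(0.7) + log(0.8) + log(0.9)),
               tolerance = 1e-12)

  # perfect foresight has (clipped) zero surprise
  sharp <- fake
  sharp$muhat_1 <- ifelse(des$u == 1, 1, 0)
  expect_lt(observational_surprise(sharp, des$u)$total, 1e-4)
})

test_that("network filtering stays finite across many random designs", {
  for (s in 1:150) {
    des <- generate_design(task_config(seed = 3000 + s))
    ctx <- run_forward(do.call(build_network,
                               c(list("context"), context_demo_params())),
                       des)
    noc <- run_forward(build_network("nocontext"), des)
    expect_equal(nrow(ctx), nrow(des))
    expect_true(all(is.finite(ctx$muhat_1)) && all(is.finite(noc$muhat_1)))
    expect_true(all(ctx$sigma_assoc > 0) && all(ctx$sigma_ctx > 0))
  }
})

test_that("a diverging network names the node and trial", {
  des <- generate_design(task_config(seed = 2))
  expect_error(
    run_forward(build_network("context", lambda_2 = 0.9, lambda_4 = 1,
                              omega_4 = -2, cue_reliability = 1), des),
    "node 'assoc_vol', trial"
  )
})

test_that("network topologies serialize to JSON", {
  net <- build_network("context", lambda_2 = 0.5)
  path <- withr::local_tempfile(fileext = ".json")
  write_network(net, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$variant, "context")
  expect_setequal(back$nodes$node_id, net$nodes$node_id)
  expect_equal(back$cue_reliability, 0.87)
})
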