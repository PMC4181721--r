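test_that("pairwise loss has the stated algebraic structure", {
  draws <- rbind(c(1, 1), c(exp(1), 1), c(2, 3))
  L <- pairwise_loss(draws, "squared_log_ratio")
  expect_equal(diag(L), rep(0, 3))
  expect_equal(L, t(L))
  expect_equal(L[1, 2], 1) # log(e)^2
  expect_true(all(L >= 0))
  Le <- pairwise_loss(draws, "squared_euclidean")
  expect_equal(Le[1, 3], (1 - 2)^2 + (1 - 3)^2)
  expect_error(pairwise_loss(rbind(c(1, -1)), "squared_log_ratio"), "positive")
})

test_that("baseline risk is the mean pairwise loss", {
  two <- sample_from_draws(rbind(c(1, 1), c(exp(1), 1)))
  expect_equal(baseline_risk(two), 1 / 2) # (l12 + l21) / 4
  same <- sample_from_draws(rbind(c(2, 3), c(2, 3)))
  expect_equal(baseline_risk(same), 0)
  # permutation invariance
  d <- matrix(exp(rnorm(10)), 5, 2)
  expect_equal(
    baseline_risk(sample_from_draws(d)),
    baseline_risk(sample_from_draws(d[5:1, ]))
  )
})

test_that("weight matrices are row-stochastic for random problems", {
  cat1 <- enumerate_design_space(net1, "single_protein")
  withr::with_seed(77, {
    for (case in 1:20) {
      draws <- draw_prior(prior_spec(net1, sigma_log = 1), 6,
        seed = sample.int(1e6, 1)
      )
      ps <- sample_from_draws(draws)
      row <- cat1[sample(which(cat1$type == "assay"), 1), ]
      W <- weight_matrix(row, ps, net1, m = 3, seed = sample.int(1e6, 1))
      expect_lt(max(abs(rowSums(W) - 1)), 1e-12)
      expect_true(all(W >= 0))
    }
  })
})

test_that("an uninformative experiment scores exactly the baseline risk", {
  # draws differ only in the promoter of gene b; purchasing the constants
  # of a reaction that is identical across draws yields identical predicted
  # observations, so W = 1/N exactly and the risk equals the baseline
  netr <- gene_network(
    c("a", "b"),
    data.frame(regulator = "a", target = "b", sign = "activation")
  )
  base <- make_params(netr, promoter = c(2, 1), K = 1.5, h = 2)
  draws <- t(vapply(c(0.5, 1, 2, 4), function(f) {
    th <- base
    th["promoter_b"] <- th[["promoter_b"]] * f
    th
  }, base))
  ps <- sample_from_draws(draws)
  catr <- enumerate_design_space(netr, "single_protein")
  purchase <- catr[catr$type == "purchase", ]
  r <- expected_risk(purchase, ps, netr, m = 10, seed = 3)
  expect_equal(r, baseline_risk(ps), tolerance = 1e-12)
  W <- weight_matrix(purchase, ps, netr, m = 10, seed = 3)
  expect_equal(W, matrix(1 / 4, 4, 4), tolerance = 1e-12, ignore_attr = TRUE)
  # an assay whose signal is unaffected by the varying parameter is
  # uninformative up to solver tolerance
  prot_a <- catr[catr$action_kind %in% "wildtype" & catr$obs_kind %in% "protein_single" &
    catr$obs_targets %in% "a", ]
  r_assay <- expected_risk(prot_a, ps, netr, m = 10, seed = 3)
  expect_equal(r_assay, baseline_risk(ps), tolerance = 1e-4)
})

test_that("a perfectly separating experiment has near-zero risk", {
  # hugely different promoter strengths with negligible noise
  draws <- t(vapply(c(0.1, 1, 10, 100), function(f) {
    th <- theta1
    th["promoter_a"] <- f
    th
  }, theta1))
  ps <- sample_from_draws(draws)
  cat1 <- enumerate_design_space(net1, "single_protein")
  prot <- cat1[cat1$action_kind %in% "wildtype" & cat1$obs_kind %in% "protein_single", ]
  tiny_noise <- noise_model(sigma_add = 1e-6, sigma_mult = 1e-6)
  r <- expected_risk(prot, ps, net1, noise = tiny_noise, m = 10, seed = 4)
  expect_lt(r, 1e-6)
})

test_that("a single draw has zero risk and degenerate noise reproduces the signal", {
  one <- sample_from_draws(matrix(theta1, 1, dimnames = list(NULL, names(theta1))))
  cat1 <- enumerate_design_space(net1, "single_protein")
  prot <- cat1[cat1$action_kind %in% "wildtype" & cat1$obs_kind %in% "protein_single", ]
  expect_equal(expected_risk(prot, one, net1, m = 5, seed = 1), 0)
  # zero noise sds: every simulated observation equals the ideal signal
  sig <- circuitdesign:::predicted_signals(one, prot, net1)
  nm0 <- noise_model(0, 0)
  O <- corrupt_signal(sig$S[1, ], nm0, seed = 9)
  expect_identical(O, sig$S[1, ])
})

test_that("risks are sandwiched between zero and the largest pairwise loss", {
  draws <- draw_prior(prior_spec(net1, sigma_log = 1), 8, seed = 101)
  ps <- sample_from_draws(draws)
  cat1 <- enumerate_design_space(net1, "single_protein")
  L <- pairwise_loss(ps, "squared_log_ratio")
  for (i in c(1, 7, 12)) {
    r <- expected_risk(cat1[i, ], ps, net1, m = 10, seed = i)
    expect_gte(r, 0)
    expect_lte(r, max(L))
  }
})

test_that("per-action simulations are shared across observables", {
  ps <- sample_from_draws(draw_prior(prior_spec(net2, sigma_log = 0.5), 5, seed = 8))
  cat2 <- enumerate_design_space(net2, "single_protein")
  wt <- cat2[cat2$action_kind %in% "wildtype", ]
  cache <- new.env(parent = emptyenv())
  s1 <- circuitdesign:::predicted_signals(ps, wt[1, ], net2, cache)
  expect_length(ls(cache), 1L) # one cached action
  s2 <- circuitdesign:::predicted_signals(ps, wt[3, ], net2, cache)
  expect_length(ls(cache), 1L) # second observable reused the simulations
  expect_true(all(s1$ok) && all(s2$ok))
})

test_that("ranking orders separating experiments above uninformative ones", {
  # gene b varies across draws; observing protein b separates, protein a not
  draws <- t(vapply(c(0.2, 1, 5, 25), function(f) {
    th <- theta2
    th["promoter_b"] <- th[["promoter_b"]] * f
    th
  }, theta2))
  ps <- sample_from_draws(draws)
  cat2 <- enumerate_design_space(net2, "single_protein")
  keep <- cat2[cat2$action_kind %in% "wildtype" & cat2$obs_kind %in% "protein_single", ]
  rt <- rank_experiments(ps, keep, net2, m = 20, seed = 5)
  expect_s3_class(rt, "risk_table")
  expect_identical(rt$obs_targets[1], "b")
  expect_lt(rt$risk[1], rt$risk[2])
  expect_equal(attr(rt, "baseline"), baseline_risk(ps))
  # excluded (purchased) experiments are absent
  rt2 <- rank_experiments(ps, keep, net2, m = 20, seed = 5, exclude = keep$id[1])
  expect_false(keep$id[1] %in% rt2$id)
  expect_identical(nrow(rt2), nrow(keep) - 1L)
})

test_that("risk estimates agree with brute-force enumeration on a discrete model", {
  # three parameter values, two outcomes with closed-form probabilities:
  # the integral over observations in the expected-risk definition becomes
  # a finite sum that can be enumerated exactly
  p_heads <- c(0.1, 0.5, 0.9) # P(o = 1 | theta_i)
  thetas <- matrix(c(1, 2, 4), ncol = 1)
  N <- 3
  L <- pairwise_loss(thetas, "squared_log_ratio")
  # exact: w*_ij = sum_o P(o|i) P(o|j) / sum_k P(o|k); R = (1/N) sum L w*
  w_exact <- matrix(0, N, N)
  for (o in 0:1) {
    po <- if (o == 1) p_heads else 1 - p_heads
    w_exact <- w_exact + outer(po, po) / sum(po)
  }
  r_exact <- sum(L * w_exact) / N
  # Monte-Carlo route through the package estimator
  M <- 1e5
  draws_o <- withr::with_seed(
    99,
    lapply(p_heads, function(p) stats::rbinom(M, 1, p))
  )
  loglik <- matrix(NA_real_, N * M, N)
  for (i in 1:N) {
    o <- draws_o[[i]]
    for (j in 1:N) {
      loglik[((i - 1) * M + 1):(i * M), j] <-
        log(ifelse(o == 1, p_heads[j], 1 - p_heads[j]))
    }
  }
  W <- risk_weights(loglik, N, M)
  r_mc <- sum(L * W) / N
  expect_lt(max(abs(rowSums(W) - 1)), 1e-12)
  expect_equal(r_mc, r_exact, tolerance = 0.01)
})

test_that("lower observation noise never increases the estimated risk", {
  draws <- draw_prior(prior_spec(net1, sigma_log = 1), 10, seed = 15)
  ps <- sample_from_draws(draws)
  cat1 <- enumerate_design_space(net1, "single_protein")
  prot <- cat1[cat1$action_kind %in% "wildtype" & cat1$obs_kind %in% "protein_single", ]
  r_hi <- expected_risk(prot, ps, net1,
    noise = noise_model(0.5, 0.4), m = 200, seed = 6
  )
  r_lo <- expected_risk(prot, ps, net1,
    noise = noise_model(0.05, 0.04), m = 200, seed = 6
  )
  expect_lte(r_lo, r_hi * 1.05) # MC slack
})
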