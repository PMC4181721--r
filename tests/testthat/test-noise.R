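test_that("corruption is reproducible and has the stated variance structure", {
  y <- rep(1, 1e5)
  a <- corrupt_signal(y, noise_model(), seed = 4)
  b <- corrupt_signal(y, noise_model(), seed = 4)
  expect_identical(a, b)
  # var at y = 1 is 0.1^2 + 0.2^2 = 0.05; MC check within 3 sd of the
  # sampling distribution of the variance estimate
  v_hat <- stats::var(a - 1)
  se <- sqrt(2 / (1e5 - 1)) * 0.05
  expect_lt(abs(v_hat - 0.05), 3 * se)
  # at y = 0 only the additive component remains
  z <- corrupt_signal(rep(0, 1e5), noise_model(), seed = 5)
  expect_lt(abs(stats::var(z) - 0.01), 3 * sqrt(2 / (1e5 - 1)) * 0.01)
})

test_that("log-likelihood matches the Gaussian closed form", {
  expect_identical(log_likelihood(theta1, list(), net1), 0)
  cat1 <- enumerate_design_space(net1, "single_protein")
  prot <- cat1[cat1$action_kind %in% "wildtype" & cat1$obs_kind %in% "protein_single", ]
  ds <- generate_dataset(prot, net1, theta1, seed = 8)
  # closed form: sum over points of N(o; y, 0.1^2 + (0.2 y)^2) log-density
  traj <- simulate_circuit(net1, theta1)
  y <- observation_operator(traj, prot)$value
  v <- 0.1^2 + (0.2 * y)^2
  manual <- sum(dnorm(ds$data$value, y, sqrt(v), log = TRUE))
  expect_equal(log_likelihood(theta1, list(ds), net1), manual, tolerance = 1e-10)
  # independence: two datasets add
  ds2 <- generate_dataset(prot, net1, theta1, seed = 9)
  expect_equal(
    log_likelihood(theta1, list(ds, ds2), net1),
    log_likelihood(theta1, list(ds), net1) + log_likelihood(theta1, list(ds2), net1),
    tolerance = 1e-10
  )
})

test_that("noise variance strictly increases with the signal", {
  nm <- noise_model()
  y <- seq(0, 10, by = 0.5)
  v <- circuitdesign:::noise_var(y, nm)
  expect_true(all(diff(v) > 0))
})

test_that("the likelihood is maximized when observation equals prediction", {
  cat1 <- enumerate_design_space(net1, "single_protein")
  prot <- cat1[cat1$action_kind %in% "wildtype" & cat1$obs_kind %in% "protein_single", ]
  ds <- generate_dataset(prot, net1, theta1, seed = 8)
  traj <- simulate_circuit(net1, theta1)
  ideal <- observation_operator(traj, prot)
  ds_ideal <- circuitdesign:::new_observation_dataset(prot, ideal)
  ll_ideal <- log_likelihood(theta1, list(ds_ideal), net1)
  for (s in 1:5) {
    ds_s <- circuitdesign:::new_observation_dataset(
      prot, corrupt_signal(ideal, seed = s)
    )
    expect_gt(ll_ideal, log_likelihood(theta1, list(ds_s), net1))
  }
})

test_that("purchase terms are centered at the measurement and additive", {
  th <- theta_subnet
  lk <- purchase_log_likelihood(
    th, subnet, "r1", log(th[["K_r1"]]), log(th[["h_r1"]])
  )
  # zero quadratic part at the measured values: any other theta scores lower
  th_off <- th
  th_off["K_r1"] <- th[["K_r1"]] * 1.2
  expect_gt(lk, purchase_log_likelihood(
    th_off, subnet, "r1", log(th[["K_r1"]]), log(th[["h_r1"]])
  ))
  expect_error(
    purchase_log_likelihood(th, subnet, "r99", 0, 0), "r99"
  )
  # via datasets: purchases of different reactions add
  net <- gene_network(
    c("a", "b", "c"),
    data.frame(
      regulator = c("a", "b"), target = c("b", "c"),
      sign = c("activation", "inhibition")
    )
  )
  thn <- make_params(net, K = c(1, 2), h = c(2, 3))
  catn <- enumerate_design_space(net, "single_protein")
  p1 <- generate_dataset(catn[catn$reaction %in% "r1", ], net, thn, seed = 1)
  p2 <- generate_dataset(catn[catn$reaction %in% "r2", ], net, thn, seed = 2)
  expect_equal(
    log_likelihood(thn, list(p1, p2), net),
    log_likelihood(thn, list(p1), net) + log_likelihood(thn, list(p2), net)
  )
})

test_that("tight purchase noise concentrates the likelihood at the measurement", {
  th <- theta_subnet
  measured_k <- log(3.3)
  ll_at <- function(kval, sd) {
    th2 <- th
    th2["K_r1"] <- kval
    purchase_log_likelihood(th2, subnet, "r1", measured_k, log(th[["h_r1"]]),
      purchase_sd = sd
    )
  }
  # as sd -> 0 the density ratio against any off-measurement value diverges
  gap_loose <- ll_at(3.3, 0.1) - ll_at(3.0, 0.1)
  gap_tight <- ll_at(3.3, 0.001) - ll_at(3.0, 0.001)
  expect_gt(gap_tight, gap_loose * 100)
})
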