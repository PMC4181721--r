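test_that("mode finding recovers the optimum of a concave quadratic", {
  # -(x - c)' (x - c) in 3 dimensions
  ctr <- c(1, -2, 0.5)
  obj <- function(x) -sum((x - ctr)^2)
  sampler <- function(n) matrix(rnorm(n * 3, sd = 3), n, 3)
  res <- find_modes(obj, sampler, n_starts = 10, seed = 3)
  expect_identical(nrow(res$modes), 1L) # all starts merge into one mode
  expect_lt(max(abs(res$modes[1, ] - ctr)), 1e-4)
})

test_that("mode finding recovers both wells of a double-well density", {
  a <- 2.5
  logdens <- function(x) log(exp(-20 * (x - a)^2) + exp(-20 * (x + a)^2))
  sampler <- function(n) matrix(rnorm(n, sd = 4), n, 1)
  res <- find_modes(logdens, sampler, n_starts = 50, seed = 7)
  expect_identical(nrow(res$modes), 2L)
  expect_equal(sort(res$modes[, 1]), c(-a, a), tolerance = 1e-3)
})

test_that("mode finding errors when every start is infeasible", {
  expect_error(
    find_modes(function(x) -Inf, function(n) matrix(rnorm(n), n, 1),
      n_starts = 3, seed = 1
    ),
    "n_starts"
  )
})

test_that("the Metropolis-Hastings chain recovers standard-normal moments", {
  target <- function(x) -0.5 * x^2
  ch <- mh_chain(target, 0,
    n_iter = 1e5, sd_iso = 1, sd_coord = 1,
    prob_iso = 0.5, burn_in = 5000, thin = 5, seed = 21
  )
  x <- ch$draws[, 1]
  expect_lt(abs(mean(x)), 0.05)
  expect_lt(abs(stats::var(x) - 1), 0.1)
  expect_gt(ch$accept_rate, 0.1)
  expect_lt(ch$accept_rate, 0.9)
})

test_that("chains are reproducible and respect burn-in/thinning bookkeeping", {
  target <- function(x) -0.5 * sum(x^2)
  a <- mh_chain(target, c(0, 0), n_iter = 500, burn_in = 100, thin = 10, seed = 5)
  b <- mh_chain(target, c(0, 0), n_iter = 500, burn_in = 100, thin = 10, seed = 5)
  expect_identical(a, b)
  expect_identical(nrow(a$draws), 40L) # (500 - 100) / 10
  expect_error(mh_chain(target, c(Inf, 0), 100), "finite")
})

test_that("chain recombination weights balance chains on a shared target", {
  target <- function(x) -0.5 * sum(x^2)
  chains <- lapply(1:2, function(s) {
    mh_chain(target, rnorm(2), n_iter = 2e4, sd_iso = 0.8, sd_coord = 0.8,
      burn_in = 2000, thin = 10, seed = 100 + s
    )
  })
  ps <- recombine_chains(chains, param_names = c("x1", "x2"))
  expect_equal(sum(ps$weights), 1)
  expect_true(all(ps$weights >= 0))
  per_chain <- tapply(ps$weights, ps$provenance$chain, sum)
  # two chains exploring the same unimodal target share the weight evenly
  expect_lt(abs(per_chain[1] - per_chain[2]), 0.1)
})

test_that("dispersion diagnostic is 1 on identical samples and small on disjoint ones", {
  base <- matrix(rnorm(200), 100, 2)
  d <- dispersion_diagnostic(list(base, base, base))
  expect_equal(d$ratios$ratio, c(1, 1), tolerance = 1e-12)
  expect_true(d$pass)
  # clusters separated far beyond their width: within-sd << total sd
  shifted <- lapply(c(-50, 0, 50), function(mu) base + mu)
  d2 <- dispersion_diagnostic(shifted)
  expect_true(all(d2$ratios$ratio < 0.1))
  expect_false(d2$pass)
  expect_error(dispersion_diagnostic(list(base)), "at least 2")
})

test_that("with no data the posterior sample reproduces the prior", {
  spec <- prior_spec(net1, sigma_log = 2)
  st <- quick_settings(
    n_starts = 3, max_modes = 1, n_iter = 20000, burn_in = 2000,
    thin = 10, n_draws = 500, sd_iso = 1.5, sd_coord = 3
  )
  ps <- sample_posterior(list(), net1, spec, settings = st, seed = 13)
  lm <- colMeans(ps$draws_log)
  ls <- apply(ps$draws_log, 2, sd)
  expect_lt(max(abs(lm)), 0.45)
  expect_lt(max(abs(ls - 2)), 0.5)
})

test_that("posterior sampling is reproducible and shrinks purchased parameters", {
  cat3 <- enumerate_design_space(subnet, "single_protein")
  purchase <- cat3[cat3$type == "purchase", ]
  ds <- generate_dataset(purchase, subnet, theta_subnet, seed = 17, purchase_sd = 0.05)
  spec <- prior_spec(subnet)
  st <- quick_settings(n_iter = 3000, burn_in = 500, n_draws = 150)
  ps <- sample_posterior(list(ds), subnet, spec, settings = st, seed = 19)
  ps2 <- sample_posterior(list(ds), subnet, spec, settings = st, seed = 19)
  expect_identical(ps$draws, ps2$draws)
  # the purchased K and h marginals shrink at least 10x below the prior sd
  post_sd <- apply(ps$draws_log, 2, sd)
  expect_lt(post_sd[["K_r1"]], spec$sigma_log[["K_r1"]] / 10)
  expect_lt(post_sd[["h_r1"]], spec$sigma_log[["h_r1"]] / 10)
  # and center on the measured values
  expect_equal(mean(ps$draws_log[, "K_r1"]),
    ds$data$value[ds$data$species == "log_K"],
    tolerance = 0.05
  )
})

test_that("sparse data leave parameters spread while predictions stay tight", {
  # observing wildtype mRNA and protein g8 pins the g8 protein trajectory
  # prediction while e.g. the unobserved ribosomal strengths of g6/g7 stay
  # essentially at the prior
  cat3 <- enumerate_design_space(subnet, "single_protein")
  rows <- cat3[(cat3$action_kind %in% "wildtype" &
    cat3$obs_kind %in% "mrna_all" & cat3$obs_resolution %in% "low") |
    (cat3$action_kind %in% "wildtype" & cat3$obs_kind %in% "protein_single" &
      cat3$obs_targets %in% "g8"), ]
  datasets <- lapply(seq_len(nrow(rows)), function(i) {
    generate_dataset(rows[i, ], subnet, theta_subnet, seed = 500 + i)
  })
  st <- quick_settings(n_iter = 2000, burn_in = 400, n_draws = 60, max_modes = 3)
  ps <- sample_posterior(datasets, subnet, settings = st, seed = 29)
  sims <- circuitdesign:::sims_for_action(
    ps$draws, perturbation("wildtype"), subnet
  )
  prot <- vapply(
    sims$mats[sims$ok],
    function(m) m[-1, "protein_g8"],
    numeric(40)
  )
  cv_traj <- mean(apply(prot, 1, sd) / (abs(apply(prot, 1, mean)) + 1e-9))
  spread_param <- apply(ps$draws_log, 2, sd)
  # the widest parameter marginal (log scale) dwarfs the relative spread of
  # the predicted observed trajectory
  expect_gt(max(spread_param), 5 * cv_traj)
})
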