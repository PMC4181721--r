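#' Sampler settings
#'
#' Tuning knobs for the posterior-exploration pipeline: multi-start BFGS
#' mode finding, per-mode Metropolis-Hastings chains, mixture-based
#' recombination and the final resampling size. Defaults target quality on
#' the small presets; scale them down for quick exploratory runs.
#'
#' @param n_starts Number of BFGS starting points drawn from the prior.
#' @param max_modes Maximum number of distinct modes to seed chains from.
#' @param n_iter Metropolis-Hastings iterations per chain.
#' @param burn_in Iterations discarded at the start of each chain.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param prob_iso Probability of an isotropic (all-coordinate) proposal;
#'   otherwise a single random coordinate is perturbed.
#' @param sd_iso Isotropic proposal sd (log-parameter scale).
#' @param sd_coord Single-coordinate proposal sd (log-parameter scale).
#' @param n_draws Size N of the final equally-weighted posterior sample.
#' @param m_noise Monte-Carlo sample size M per posterior draw when
#'   estimating experiment risks.
#' @param maxit BFGS iteration cap per start.
#' @param dedup_tol Euclidean log-space distance below which two local
#'   optima are considered the same mode.
#' @return A `sampler_settings` list.
#' @export
sampler_settings <- function(n_starts = 30, max_modes = 5, n_iter = 20000,
                             burn_in = 5000, thin = 10, prob_iso = 0.5,
                             sd_iso = 0.1, sd_coord = 0.5, n_draws = 200,
                             m_noise = 100, maxit = 100, dedup_tol = 0.5) {
  structure(
    list(
      n_starts = n_starts, max_modes = max_modes, n_iter = n_iter,
      burn_in = burn_in, thin = thin, prob_iso = prob_iso, sd_iso = sd_iso,
      sd_coord = sd_coord, n_draws = n_draws, m_noise = m_noise,
      maxit = maxit, dedup_tol = dedup_tol
    ),
    class = "sampler_settings"
  )
}

#' Locate posterior modes by multi-start quasi-Newton optimization
#'
#' Runs BFGS (with finite-difference gradients) from `n_starts` starting
#' points in log-parameter space and deduplicates the resulting local
#' maxima: optima closer than `dedup_tol` in Euclidean log distance are
#' merged, keeping the higher objective value. Starts with non-finite
#' objective are redrawn from `sampler` until finite (up to 50 attempts
#' each).
#'
#' @param log_target Function of a log-parameter vector returning the
#'   objective (a log-density) to maximize.
#' @param sampler Function `n -> n x p` matrix of candidate starting points
#'   (log scale), e.g. Gaussian prior draws.
#' @param n_starts Number of starts.
#' @param seed Integer seed.
#' @param maxit BFGS iteration cap.
#' @param dedup_tol Mode-merging distance.
#' @param max_modes Keep at most this many modes (highest objective first).
#' @param extra_starts Optional matrix of additional starting points (one
#'   per row), used verbatim before the sampled starts — e.g. warm starts
#'   from a previous round of a sequential design.
#' @return List with `modes` (matrix, one row per mode, best first) and
#'   `values` (objective at each mode).
#' @export
find_modes <- function(log_target, sampler, n_starts = 30, seed = 1,
                       maxit = 100, dedup_tol = 0.5, max_modes = Inf,
                       extra_starts = NULL) {
  starts <- withr::with_seed(seed, {
    out <- vector("list", n_starts)
    for (s in seq_len(n_starts)) {
      x <- NULL
      for (try_i in 1:50) {
        cand <- drop(sampler(1))
        if (is.finite(log_target(cand))) {
          x <- cand
          break
        }
      }
      out[[s]] <- x
    }
    out
  })
  starts <- starts[!vapply(starts, is.null, logical(1))]
  if (!is.null(extra_starts)) {
    extra <- lapply(seq_len(nrow(extra_starts)), function(i) extra_starts[i, ])
    extra <- extra[vapply(extra, function(x) is.finite(log_target(x)), logical(1))]
    starts <- c(extra, starts)
  }
  if (length(starts) == 0) {
    abort("No finite starting point found; raise `n_starts` or widen the sampler.")
  }
  opts <- purrr::map(starts, function(x0) {
    fit <- try(
      optim(x0,
        fn = function(x) {
          v <- log_target(x)
          if (!is.finite(v)) 1e10 else -v
        },
        method = "BFGS", control = list(maxit = maxit)
      ),
      silent = TRUE
    )
    if (inherits(fit, "try-error") || !is.finite(fit$value) || fit$value >= 1e9) {
      return(NULL)
    }
    list(x = fit$par, value = -fit$value)
  })
  opts <- purrr::compact(opts)
  if (length(opts) == 0) {
    abort("All optimization starts failed; raise `n_starts`.")
  }
  ord <- order(vapply(opts, `[[`, numeric(1), "value"), decreasing = TRUE)
  opts <- opts[ord]
  modes <- list(opts[[1]])
  for (o in opts[-1]) {
    dists <- vapply(modes, function(m) sqrt(sum((m$x - o$x)^2)), numeric(1))
    if (all(dists >= dedup_tol)) modes <- c(modes, list(o))
  }
  modes <- head(modes, max_modes)
  list(
    modes = do.call(rbind, purrr::map(modes, "x")),
    values = vapply(modes, `[[`, numeric(1), "value")
  )
}

#' Random-walk Metropolis-Hastings chain
#'
#' Symmetric random-walk sampler in log-parameter space mixing two move
#' types: with probability `prob_iso` an isotropic Gaussian perturbation of
#' all coordinates (sd `sd_iso`), otherwise a Gaussian perturbation of one
#' uniformly chosen coordinate (sd `sd_coord`). Proposals being symmetric,
#' the acceptance probability is `min(1, exp(delta log target))`.
#'
#' @param log_target Log-density function of the state vector.
#' @param init Initial state (finite log-target required).
#' @param n_iter Total iterations.
#' @param sd_iso,sd_coord,prob_iso Proposal parameters.
#' @param burn_in Discarded initial iterations.
#' @param thin Keep every `thin`-th retained draw.
#' @param seed Integer seed.
#' @return List with `draws` (matrix), `log_target` (vector, one per
#'   retained draw) and `accept_rate`.
#' @export
mh_chain <- function(log_target, init, n_iter = 20000, sd_iso = 0.1,
                     sd_coord = 0.5, prob_iso = 0.5, burn_in = 5000,
                     thin = 10, seed = 1) {
  init <- as.double(init)
  p <- length(init)
  lp0 <- log_target(init)
  if (!is.finite(lp0)) abort("`init` must have finite log target.")
  if (burn_in >= n_iter) abort("`burn_in` must be smaller than `n_iter`.")
  withr::with_seed(seed, {
    move_iso <- runif(n_iter) < prob_iso
    coord <- sample.int(p, n_iter, replace = TRUE)
    z_iso <- matrix(rnorm(n_iter * p, sd = sd_iso), n_iter, p)
    z_coord <- rnorm(n_iter, sd = sd_coord)
    log_u <- log(runif(n_iter))
    x <- init
    lp <- lp0
    keep_idx <- seq(burn_in + thin, n_iter, by = thin)
    draws <- matrix(NA_real_, length(keep_idx), p)
    lps <- numeric(length(keep_idx))
    accepted <- 0L
    k <- 1L
    for (it in seq_len(n_iter)) {
      prop <- x
      if (move_iso[it]) {
        prop <- prop + z_iso[it, ]
      } else {
        prop[coord[it]] <- prop[coord[it]] + z_coord[it]
      }
      lp_prop <- log_target(prop)
      if (is.finite(lp_prop) && log_u[it] <= lp_prop - lp) {
        x <- prop
        lp <- lp_prop
        accepted <- accepted + 1L
      }
      if (k <= length(keep_idx) && it == keep_idx[k]) {
        draws[k, ] <- x
        lps[k] <- lp
        k <- k + 1L
      }
    }
    list(
      draws = draws, log_target = lps,
      accept_rate = accepted / n_iter
    )
  })
}

new_posterior_sample <- function(draws_log, weights, log_target, provenance,
                                 param_names, accept_rates = numeric()) {
  stopifnot(nrow(draws_log) >= 1)
  weights <- weights / sum(weights)
  theta <- exp(draws_log)
  colnames(theta) <- param_names
  colnames(draws_log) <- param_names
  structure(
    list(
      draws = theta, draws_log = draws_log, weights = weights,
      log_target = log_target, provenance = provenance,
      accept_rates = accept_rates
    ),
    class = "posterior_sample"
  )
}

#' @export
print.posterior_sample <- function(x, ...) {
  cat(
    "<posterior_sample> ", nrow(x$draws), " draws of ", ncol(x$draws),
    " parameters (", dplyr::n_distinct(x$provenance$chain), " chain(s))\n",
    sep = ""
  )
  invisible(x)
}

# Diagonal-Gaussian component fitted by moments to one chain's draws.
fit_chain_component <- function(draws) {
  mu <- colMeans(draws)
  sdv <- pmax(apply(draws, 2, sd), 1e-3)
  list(mu = mu, sd = sdv)
}

mixture_log_density <- function(x_mat, components, log_w) {
  per_comp <- vapply(seq_along(components), function(c) {
    comp <- components[[c]]
    log_w[c] + rowSums(
      dnorm(x_mat, rep(comp$mu, each = nrow(x_mat)),
        rep(comp$sd, each = nrow(x_mat)),
        log = TRUE
      )
    )
  }, numeric(nrow(x_mat)))
  per_comp <- matrix(per_comp, nrow = nrow(x_mat))
  mx <- apply(per_comp, 1, max)
  mx + log(rowSums(exp(per_comp - mx)))
}

#' Recombine Metropolis-Hastings chains into one weighted sample
#'
#' Chains seeded at different posterior modes each explore their own
#' region; naively pooling them over-represents modes that received more
#' chains. A Gaussian-mixture approximation of the pooled sample (one
#' diagonal-covariance component per chain, fitted by moments) serves as
#' the effective instrumental density, and each pooled draw `x` receives
#' the self-normalized importance weight
#' `w(x) proportional to exp(log_target(x)) / mixture(x)`. Degenerate fits
#' (non-finite weights) fall back to uniform weights with a warning.
#'
#' @param chains List of [mh_chain()] results (each with `draws` and
#'   `log_target`).
#' @param param_names Parameter names for the columns.
#' @return A `posterior_sample` with normalized weights.
#' @export
recombine_chains <- function(chains, param_names = NULL) {
  stopifnot(length(chains) >= 1)
  sizes <- vapply(chains, function(ch) nrow(ch$draws), integer(1))
  if (any(sizes == 0)) abort("Every chain must contain at least one draw.")
  pooled <- do.call(rbind, purrr::map(chains, "draws"))
  lps <- unlist(purrr::map(chains, "log_target"))
  if (is.null(param_names)) {
    param_names <- colnames(pooled) %||% paste0("x", seq_len(ncol(pooled)))
  }
  provenance <- tibble(
    draw = seq_len(nrow(pooled)),
    chain = rep(seq_along(chains), sizes),
    mode = rep(seq_along(chains), sizes)
  )
  components <- purrr::map(chains, function(ch) fit_chain_component(ch$draws))
  log_w_comp <- log(sizes / sum(sizes))
  log_mix <- mixture_log_density(pooled, components, log_w_comp)
  log_wts <- lps - log_mix
  log_wts <- log_wts - max(log_wts)
  wts <- exp(log_wts)
  if (any(!is.finite(wts)) || sum(wts) <= 0) {
    warn("Degenerate mixture fit; falling back to uniform weights.")
    wts <- rep(1, nrow(pooled))
  }
  new_posterior_sample(
    pooled, wts, lps, provenance, param_names,
    accept_rates = vapply(chains, function(ch) ch$accept_rate %||% NA_real_, numeric(1))
  )
}

#' Multi-seed sampling dispersion diagnostic
#'
#' Draws from the same posterior obtained with different seeds should
#' overlap: for each parameter, the average within-sample standard
#' deviation (log scale) divided by the standard deviation of all samples
#' concatenated should be close to 1. Ratios well below 1 indicate chains
#' stuck in disjoint regions.
#'
#' @param samples List (length >= 2) of `posterior_sample` objects, or of
#'   log-scale draw matrices, from independent seeds (conventionally 10).
#' @param epsilon Tolerance: the diagnostic passes when every ratio lies in
#'   `[1 - epsilon, 1 + epsilon]` (default 0.2).
#' @return List with `ratios` (tibble: `parameter`, `ratio`), `pass`
#'   (logical) and `epsilon`.
#' @export
dispersion_diagnostic <- function(samples, epsilon = 0.2) {
  if (length(samples) < 2) {
    abort("Need at least 2 samples from different seeds.")
  }
  mats <- purrr::map(samples, function(s) {
    if (inherits(s, "posterior_sample")) s$draws_log else as.matrix(s)
  })
  pooled <- do.call(rbind, mats)
  # population (1/n) standard deviations, so that identical samples give a
  # ratio of exactly one
  sd_pop <- function(m) {
    sqrt(colMeans(sweep(m, 2, colMeans(m), "-")^2))
  }
  total_sd <- sd_pop(pooled)
  within_sd <- Reduce(`+`, purrr::map(mats, sd_pop)) / length(mats)
  ratio <- within_sd / total_sd
  nm <- colnames(pooled) %||% paste0("x", seq_len(ncol(pooled)))
  list(
    ratios = tibble(parameter = nm, ratio = unname(ratio)),
    pass = all(ratio >= 1 - epsilon & ratio <= 1 + epsilon),
    epsilon = epsilon
  )
}

#' Draw a posterior sample for the current datasets
#'
#' The full exploration pipeline: (1) multi-start BFGS in log-parameter
#' space on the penalized (optimization-mode) posterior to locate up to
#' `max_modes` distinct modes; (2) one Metropolis-Hastings chain per mode
#' targeting the unpenalized (sampling-mode) posterior; (3) mixture-based
#' recombination of the chains into a weighted sample; (4) weighted
#' resampling down to `n_draws` equally weighted draws for downstream risk
#' evaluation.
#'
#' @param datasets List of observation datasets (possibly empty).
#' @param network A [gene_network()].
#' @param spec A [prior_spec()] (default: wide log-normal for `network`).
#' @param noise A [noise_model()].
#' @param settings A [sampler_settings()].
#' @param seed Integer master seed; all stage seeds derive from it.
#' @param purchase_sd Purchase noise sd, log scale.
#' @param extra_starts Optional matrix of log-scale warm-start points
#'   passed to [find_modes()] in addition to the prior draws (used by the
#'   sequential design loop to carry the previous round's solution).
#' @return A `posterior_sample` of `settings$n_draws` equally weighted
#'   draws; diagnostics (modes found, acceptance rates) attached.
#' @export
sample_posterior <- function(datasets, network, spec = prior_spec(network),
                             noise = noise_model(),
                             settings = sampler_settings(), seed = 1,
                             purchase_sd = 0.05, extra_starts = NULL) {
  target_opt <- make_log_target(datasets, network, spec, noise,
    mode = "optimization", purchase_sd = purchase_sd
  )
  target_samp <- make_log_target(datasets, network, spec, noise,
    mode = "sampling", purchase_sd = purchase_sd
  )
  p <- length(spec$params)
  prior_sampler <- function(n) {
    m <- matrix(rnorm(n * p), n, p)
    sweep(sweep(m, 2, spec$sigma_log, "*"), 2, spec$mu, "+")
  }
  modes <- find_modes(
    target_opt, prior_sampler,
    n_starts = settings$n_starts, seed = derive_seed(seed, 1),
    maxit = settings$maxit, dedup_tol = settings$dedup_tol,
    max_modes = settings$max_modes, extra_starts = extra_starts
  )
  chains <- purrr::map(seq_len(nrow(modes$modes)), function(k) {
    init <- modes$modes[k, ]
    if (!is.finite(target_samp(init))) init <- spec$mu
    mh_chain(
      target_samp, init,
      n_iter = settings$n_iter, sd_iso = settings$sd_iso,
      sd_coord = settings$sd_coord, prob_iso = settings$prob_iso,
      burn_in = settings$burn_in, thin = settings$thin,
      seed = derive_seed(seed, 2, k)
    )
  })
  combined <- recombine_chains(chains, param_names = spec$params)
  idx <- withr::with_seed(
    derive_seed(seed, 3),
    sample.int(nrow(combined$draws_log), settings$n_draws,
      replace = TRUE, prob = combined$weights
    )
  )
  out <- new_posterior_sample(
    combined$draws_log[idx, , drop = FALSE],
    rep(1, length(idx)),
    combined$log_target[idx],
    combined$provenance[idx, ],
    spec$params,
    accept_rates = combined$accept_rates
  )
  attr(out, "modes") <- modes
  out
}
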