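#' Log-normal prior specification
#'
#' Independent log-normal priors on every kinetic parameter, wide enough to
#' cover physically plausible scales: with the default location 0 (median 1)
#' and log-scale sd `3 * log(10)`, three prior standard deviations span
#' `1e-9` to `1e9`. The prior is proper by construction — improper priors
#' combined with non-identifiable likelihoods yield improper posteriors
#' that MCMC cannot sample. A trajectory-smoothness penalty (weight
#' `lambda`) discourages parameter regions with abrupt concentration jumps;
#' it is applied only during mode finding, not during posterior sampling.
#'
#' @param network A [gene_network()].
#' @param mu Log-scale location(s); length 1 or one per parameter.
#' @param sigma_log Log-scale sd(s), strictly positive; length 1 or one per
#'   parameter.
#' @param lambda Smoothness penalty weight (1/concentration^2), default
#'   1e-3, small relative to the likelihood.
#' @return A `prior_spec` object.
#' @export
prior_spec <- function(network, mu = 0, sigma_log = 3 * log(10), lambda = 1e-3) {
  nm <- param_names(network)
  p <- length(nm)
  mu <- setNames(rep_len(as.double(mu), p), nm)
  sigma_log <- setNames(rep_len(as.double(sigma_log), p), nm)
  if (any(sigma_log <= 0)) abort("`sigma_log` must be strictly positive.")
  if (lambda < 0) abort("`lambda` must be non-negative.")
  structure(
    list(mu = mu, sigma_log = sigma_log, lambda = lambda, params = nm),
    class = "prior_spec"
  )
}

#' Log-density of the prior
#'
#' Sum of independent log-normal log-densities. Any non-positive entry is
#' outside the support and yields `-Inf`.
#'
#' @param theta Parameter vector (natural scale).
#' @param spec A [prior_spec()].
#' @return Scalar log-density.
#' @export
log_prior <- function(theta, spec) {
  if (any(theta <= 0) || any(!is.finite(theta))) return(-Inf)
  sum(stats::dlnorm(theta, spec$mu, spec$sigma_log, log = TRUE))
}

# Gaussian prior density of x = log(theta); the log-normal prior on theta
# with the change-of-variables Jacobian folded in. This is the prior used
# for all optimization and sampling in log space.
log_prior_x <- function(x, spec) {
  sum(dnorm(x, spec$mu, spec$sigma_log, log = TRUE))
}

#' Draw parameter vectors from the prior
#'
#' @param spec A [prior_spec()].
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return `n x p` matrix of positive parameter values (named columns).
#' @export
draw_prior <- function(spec, n, seed = 1) {
  p <- length(spec$mu)
  x <- withr::with_seed(seed, matrix(rnorm(n * p), n, p))
  x <- sweep(sweep(x, 2, spec$sigma_log, "*"), 2, spec$mu, "+")
  theta <- exp(x)
  colnames(theta) <- spec$params
  theta
}

#' Trajectory-smoothness penalty
#'
#' Simulates the unperturbed (wildtype) system at `theta` on the fine
#' 41-point grid and returns `-lambda` times the largest squared increment
#' of any species between consecutive grid times. Parameter regions whose
#' dynamics jump abruptly — typically very stiff systems that are poor
#' models of reality and can defeat the integrator — are thereby
#' penalized. Solver failure returns `-Inf`.
#'
#' @param theta Parameter vector.
#' @param network A [gene_network()].
#' @param lambda Penalty weight.
#' @param times Simulation grid (default the fine grid).
#' @return Non-positive scalar (`-Inf` on solver failure).
#' @export
smoothness_penalty <- function(theta, network, lambda, times = time_grid("high")) {
  m <- tryCatch(
    sim_matrix(network, theta, perturbation("wildtype"), times),
    circuit_solver_error = function(e) NULL
  )
  if (is.null(m)) return(-Inf)
  -lambda * max(apply(m, 2, function(y) max(diff(y)^2)))
}

#' Unnormalized log-posterior
#'
#' `log_prior + log_likelihood`, plus the smoothness penalty when
#' `mode = "optimization"`. The penalty is used only while locating modes;
#' the Monte-Carlo exploration targets the unpenalized posterior.
#'
#' @param theta Parameter vector (natural scale).
#' @param datasets List of observation datasets (may be empty).
#' @param network A [gene_network()].
#' @param spec A [prior_spec()].
#' @param noise A [noise_model()].
#' @param mode `"sampling"` (default) or `"optimization"`.
#' @param purchase_sd Purchase noise sd, log scale.
#' @return Scalar unnormalized log-density (`-Inf` propagates).
#' @export
log_posterior <- function(theta, datasets, network, spec,
                          noise = noise_model(),
                          mode = c("sampling", "optimization"),
                          purchase_sd = 0.05) {
  mode <- match.arg(mode)
  lp <- log_prior(theta, spec)
  if (!is.finite(lp)) return(-Inf)
  ll <- log_likelihood(theta, datasets, network, noise, purchase_sd)
  out <- lp + ll
  if (mode == "optimization" && is.finite(out)) {
    out <- out + smoothness_penalty(theta, network, spec$lambda)
  }
  out
}

# Log-target on x = log(theta) for optimization/sampling. Uses the Gaussian
# prior in x (Jacobian included) so that MH on x samples exactly the
# log-normal-prior posterior on theta.
make_log_target <- function(datasets, network, spec, noise = noise_model(),
                            mode = c("sampling", "optimization"),
                            purchase_sd = 0.05) {
  mode <- match.arg(mode)
  prep <- prepare_dataset_evals(datasets, network)
  penalize <- (mode == "optimization" && spec$lambda > 0)
  wt_plan <- if (penalize) make_sim_plan(network, perturbation("wildtype"))
  times <- time_grid("high")
  mu <- unname(spec$mu)
  sig <- unname(spec$sigma_log)
  function(x) {
    if (any(!is.finite(x))) return(-Inf)
    lp <- sum(dnorm(x, mu, sig, log = TRUE))
    theta <- exp(x)
    if (any(!is.finite(theta)) || any(theta == 0)) return(-Inf)
    ll <- log_likelihood_prepared(theta, prep, noise, purchase_sd)
    out <- lp + ll
    if (penalize && is.finite(out)) {
      m <- tryCatch(
        sim_plan_run(wt_plan, theta, times),
        circuit_solver_error = function(e) NULL
      )
      if (is.null(m)) return(-Inf)
      out <- out - spec$lambda * max(apply(m, 2, function(y) max(diff(y)^2)))
    }
    out
  }
}
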