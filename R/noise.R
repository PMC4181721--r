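#' Heteroscedastic measurement-noise model
#'
#' A measured concentration `y` is reported as `y + z1 + z2` with
#' independent centered Gaussians `z1 ~ N(0, sigma_add^2)` and
#' `z2 ~ N(0, (sigma_mult * y)^2)`: an additive floor plus a relative
#' component that grows with the signal, so high concentrations are noisier
#' in absolute terms. Observations are not truncated at zero.
#'
#' @param sigma_add Additive standard deviation (concentration units),
#'   default 0.1.
#' @param sigma_mult Multiplicative standard-deviation factor
#'   (dimensionless), default 0.2.
#' @return A `noise_model` object.
#' @export
noise_model <- function(sigma_add = 0.1, sigma_mult = 0.2) {
  if (sigma_add < 0 || sigma_mult < 0) abort("Noise sds must be non-negative.")
  structure(
    list(sigma_add = sigma_add, sigma_mult = sigma_mult),
    class = "noise_model"
  )
}

noise_var <- function(y, noise) noise$sigma_add^2 + (noise$sigma_mult * y)^2

#' Corrupt an ideal signal with measurement noise
#'
#' @param signal Tibble with a `value` column (e.g. the output of
#'   [observation_operator()]), or a numeric vector/matrix.
#' @param noise A [noise_model()].
#' @param seed Integer seed; the same seed reproduces the same corruption.
#' @return Same shape as `signal`, with values replaced by noisy ones.
#' @examples
#' corrupt_signal(c(0, 1, 2), noise_model(), seed = 1)
#' @export
corrupt_signal <- function(signal, noise = noise_model(), seed = 1) {
  y <- if (is.data.frame(signal)) signal$value else signal
  z <- withr::with_seed(seed, {
    rnorm(length(y), sd = noise$sigma_add) +
      rnorm(length(y), sd = noise$sigma_mult * abs(y))
  })
  out <- y + z
  if (is.data.frame(signal)) {
    signal$value <- out
    signal
  } else {
    out_attr <- signal
    out_attr[] <- out
    out_attr
  }
}

new_observation_dataset <- function(experiment, data) {
  structure(
    list(experiment = as_tibble(experiment), data = as_tibble(data)),
    class = "observation_dataset"
  )
}

#' @export
print.observation_dataset <- function(x, ...) {
  cat(
    "<observation_dataset> ", x$experiment$label, " (", nrow(x$data),
    " values)\n",
    sep = ""
  )
  invisible(x)
}

#' Generate the dataset an experiment would return
#'
#' Simulates the hidden truth under the experiment's action, applies the
#' observation operator, and corrupts the result with measurement noise.
#' For a parameter purchase, the reported binding affinity and Hill
#' coefficient are the true constants perturbed on the natural-log scale
#' with standard deviation `purchase_sd`.
#'
#' @param experiment One catalogue row.
#' @param network A [gene_network()].
#' @param theta_star True parameter vector.
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @param purchase_sd Log-scale sd of purchased constants (default 0.05).
#' @return An `observation_dataset`.
#' @export
generate_dataset <- function(experiment, network, theta_star,
                             noise = noise_model(), seed = 1,
                             purchase_sd = 0.05) {
  experiment <- as_tibble(experiment)
  stopifnot(nrow(experiment) == 1)
  if (experiment$type == "purchase") {
    true_k <- theta_star[[paste0("K_", experiment$reaction)]]
    true_h <- theta_star[[paste0("h_", experiment$reaction)]]
    meas <- withr::with_seed(
      seed,
      c(log(true_k), log(true_h)) + rnorm(2, sd = purchase_sd)
    )
    data <- tibble(
      species = c("log_K", "log_h"), time = NA_real_, value = meas
    )
    return(new_observation_dataset(experiment, data))
  }
  traj <- simulate_circuit(
    network, theta_star, experiment_action(experiment)
  )
  ideal <- observation_operator(traj, experiment)
  new_observation_dataset(experiment, corrupt_signal(ideal, noise, seed))
}

#' Likelihood contribution of a purchased pair of reaction constants
#'
#' Independent Gaussian terms on `log K` and `log h` of the purchased
#' reaction, centered at the measured values.
#'
#' @param theta Parameter vector.
#' @param network A [gene_network()].
#' @param reaction Reaction id (e.g. `"r1"`).
#' @param measured_log_k,measured_log_h Measured constants, natural-log
#'   scale.
#' @param purchase_sd Standard deviation of the purchase noise on the log
#'   scale (default 0.05).
#' @return Log-likelihood contribution (scalar).
#' @export
purchase_log_likelihood <- function(theta, network, reaction,
                                    measured_log_k, measured_log_h,
                                    purchase_sd = 0.05) {
  if (!(reaction %in% network$reactions$id)) {
    abort(paste0("Unknown reaction \"", reaction, "\"."))
  }
  dnorm(log(theta[[paste0("K_", reaction)]]), measured_log_k, purchase_sd, log = TRUE) +
    dnorm(log(theta[[paste0("h_", reaction)]]), measured_log_h, purchase_sd, log = TRUE)
}

# Precompile datasets for repeated likelihood evaluation: one simulation
# plan per distinct action, plus index matrices mapping dataset rows into
# the simulated trajectory. `theta` indices for purchases are resolved to
# positions in the canonical parameter vector.
prepare_dataset_evals <- function(datasets, network, times = time_grid("high")) {
  if (inherits(datasets, "observation_dataset")) datasets <- list(datasets)
  full_names <- param_names(network)
  plans <- list()
  evals <- vector("list", length(datasets))
  for (k in seq_along(datasets)) {
    ds <- datasets[[k]]
    if (ds$experiment$type == "purchase") {
      r <- ds$experiment$reaction
      if (!(r %in% network$reactions$id)) {
        abort(paste0("Unknown reaction \"", r, "\"."))
      }
      evals[[k]] <- list(
        type = "purchase",
        idx_k = match(paste0("K_", r), full_names),
        idx_h = match(paste0("h_", r), full_names),
        log_k = ds$data$value[ds$data$species == "log_K"],
        log_h = ds$data$value[ds$data$species == "log_h"]
      )
    } else {
      pert <- experiment_action(ds$experiment)
      key <- paste0(pert$kind, ":", pert$target %||% "")
      if (is.null(plans[[key]])) plans[[key]] <- make_sim_plan(network, pert)
      plan <- plans[[key]]
      idx <- cbind(
        match(ds$data$time, times),
        match(ds$data$species, plan$species)
      )
      if (anyNA(idx)) {
        abort("Dataset rows do not match the simulated trajectory layout.")
      }
      evals[[k]] <- list(
        type = "assay", key = key, idx = idx, obs = ds$data$value
      )
    }
  }
  list(evals = evals, plans = plans, times = times)
}

# Log-likelihood from precompiled evals; one simulation per distinct action.
log_likelihood_prepared <- function(theta, prep, noise, purchase_sd = 0.05) {
  total <- 0
  sims <- list()
  for (ev in prep$evals) {
    if (ev$type == "purchase") {
      total <- total +
        dnorm(log(theta[ev$idx_k]), ev$log_k, purchase_sd, log = TRUE) +
        dnorm(log(theta[ev$idx_h]), ev$log_h, purchase_sd, log = TRUE)
    } else {
      m <- sims[[ev$key]]
      if (is.null(m)) {
        m <- tryCatch(
          sim_plan_run(prep$plans[[ev$key]], theta, prep$times),
          circuit_solver_error = function(e) NULL
        )
        if (is.null(m)) return(-Inf)
        sims[[ev$key]] <- m
      }
      y <- m[ev$idx]
      v <- noise_var(y, noise)
      total <- total + sum(dnorm(ev$obs, y, sqrt(v), log = TRUE))
    }
  }
  total
}

#' Log-likelihood of purchased datasets
#'
#' Sums, over all data points of all datasets, the Gaussian log-density of
#' the observed value around the model prediction `y(theta)`, with variance
#' `sigma_add^2 + (sigma_mult * y(theta))^2` (the generative noise model
#' evaluated at the predicted signal). Datasets are independent. Parameter
#' purchases contribute through [purchase_log_likelihood()]. If the ODE
#' solver fails at `theta`, the point is excluded by returning `-Inf`.
#'
#' @param theta Parameter vector.
#' @param datasets List of `observation_dataset` objects (may be empty).
#' @param network A [gene_network()].
#' @param noise A [noise_model()].
#' @param purchase_sd Purchase noise sd, log scale.
#' @return Scalar log-likelihood (0 for no data, `-Inf` on solver failure).
#' @export
log_likelihood <- function(theta, datasets, network, noise = noise_model(),
                           purchase_sd = 0.05) {
  if (length(datasets) == 0) return(0)
  validate_params(theta, network)
  prep <- prepare_dataset_evals(datasets, network)
  log_likelihood_prepared(unname(theta), prep, noise, purchase_sd)
}
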