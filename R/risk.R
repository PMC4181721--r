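#' Pairwise loss matrix of a posterior sample
#'
#' `L[i, j] = loss(theta_i, theta_j)` for every pair of draws. The
#' squared log-ratio loss `sum(log(theta_i / theta_j)^2)` is the default
#' for positive kinetic parameters; the squared Euclidean distance is the
#' natural-scale alternative. Both are symmetric, non-negative and zero on
#' the diagonal.
#'
#' @param sample A `posterior_sample`, or a matrix of draws (rows).
#' @param loss `"squared_log_ratio"` or `"squared_euclidean"`.
#' @return `N x N` symmetric matrix with zero diagonal.
#' @export
pairwise_loss <- function(sample, loss = c("squared_log_ratio", "squared_euclidean")) {
  loss <- match.arg(loss)
  draws <- if (inherits(sample, "posterior_sample")) sample$draws else as.matrix(sample)
  if (loss == "squared_log_ratio") {
    if (any(draws <= 0)) {
      abort("squared_log_ratio loss requires strictly positive draws.")
    }
    draws <- log(draws)
  }
  L <- as.matrix(dist(draws))^2
  dimnames(L) <- NULL
  L
}

loss_to_point <- function(draws, theta_star, loss) {
  if (loss == "squared_log_ratio") {
    rowSums(log(sweep(draws, 2, theta_star, "/"))^2)
  } else {
    rowSums(sweep(draws, 2, theta_star, "-")^2)
  }
}

#' Baseline risk of a posterior sample
#'
#' The mean pairwise loss `(1/N^2) * sum(L)` — the expected loss with no
#' further experiment, used as the reference that candidate experiments
#' must improve upon.
#'
#' @inheritParams pairwise_loss
#' @return Non-negative scalar.
#' @export
baseline_risk <- function(sample, loss = c("squared_log_ratio", "squared_euclidean")) {
  L <- pairwise_loss(sample, loss)
  sum(L) / nrow(L)^2
}

# Simulate every draw of the sample under one action, caching by action key.
# Returns list(mats = list of trajectory matrices or NULL, ok = logical).
sims_for_action <- function(draws, pert, network, cache = NULL) {
  key <- paste0("sim:", pert$kind, ":", pert$target %||% "")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  plan <- make_sim_plan(network, pert)
  times <- time_grid("high")
  mats <- vector("list", nrow(draws))
  ok <- logical(nrow(draws))
  for (i in seq_len(nrow(draws))) {
    m <- tryCatch(
      sim_plan_run(plan, draws[i, ], times),
      circuit_solver_error = function(e) NULL
    )
    mats[[i]] <- m
    ok[i] <- !is.null(m)
  }
  out <- list(mats = mats, ok = ok)
  if (!is.null(cache)) cache[[key]] <- out
  out
}

# Predicted observation vector (length d) per draw for one experiment:
# list(S = N x d matrix, sd_const = scalar sd for purchases or NULL,
#      ok = logical vector of draws that simulated successfully).
predicted_signals <- function(sample, experiment, network, cache = NULL,
                              purchase_sd = 0.05) {
  draws <- sample$draws
  N <- nrow(draws)
  if (experiment$type == "purchase") {
    r <- experiment$reaction
    S <- cbind(
      log(draws[, paste0("K_", r)]),
      log(draws[, paste0("h_", r)])
    )
    return(list(S = S, sd_const = purchase_sd, ok = rep(TRUE, N)))
  }
  pert <- experiment_action(experiment)
  if (pert$kind == "delete" && length(network$genes) == 1) {
    # deleting the only gene leaves nothing to observe: empty signal,
    # scored as exactly uninformative downstream
    return(list(S = matrix(NA_real_, N, 0), sd_const = NULL, ok = rep(TRUE, N)))
  }
  sims <- sims_for_action(draws, pert, network, cache)
  first_ok <- which(sims$ok)[1]
  if (is.na(first_ok)) abort("Every posterior draw failed to simulate.")
  surviving <- colnames(sims$mats[[first_ok]])
  layout <- obs_layout(experiment, surviving, quiet = TRUE)
  times <- attr(sims$mats[[first_ok]], "time")
  idx <- cbind(match(layout$time, times), match(layout$species, surviving))
  S <- matrix(NA_real_, N, nrow(layout))
  for (i in which(sims$ok)) S[i, ] <- sims$mats[[i]][idx]
  list(S = S, sd_const = NULL, ok = sims$ok)
}

log_row_sum_exp <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Confusability weights from a log-likelihood matrix
#'
#' Core estimator behind [weight_matrix()], exposed so that custom
#' observation models can reuse it. Row block `i` of `loglik` holds, for
#' each of the `M` observations simulated from draw `i`, the log-likelihood
#' of that observation under every draw `j` (columns). Each observation row
#' is normalized over the draws (softmax, computed by log-sum-exp) and the
#' `M` rows of a block are averaged, yielding the row-stochastic matrix
#' `W[i, j]`: the posterior mass that an observation generated under draw
#' `i` would place on draw `j`.
#'
#' @param loglik `(N * M) x N` matrix, rows grouped by generating draw.
#' @param n Number of draws `N`.
#' @param m Observations per draw `M`.
#' @return `N x N` row-stochastic matrix.
#' @export
risk_weights <- function(loglik, n, m) {
  stopifnot(nrow(loglik) == n * m, ncol(loglik) == n)
  probs <- exp(loglik - log_row_sum_exp(loglik))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    rows <- ((i - 1) * m + 1):(i * m)
    W[i, ] <- colMeans(probs[rows, , drop = FALSE])
  }
  W
}

# Build the (N*M) x N log-likelihood matrix for an experiment from predicted
# signals S (N x d) with per-draw observation noise, then the weights.
weight_matrix_impl <- function(S, noise, sd_const, m, seed) {
  N <- nrow(S)
  d <- ncol(S)
  # an experiment observing nothing (e.g. its only species was deleted)
  # is exactly uninformative
  if (d == 0) return(matrix(1 / N, N, N))
  V <- if (is.null(sd_const)) noise_var(S, noise) else {
    matrix(sd_const^2, N, d)
  }
  Srep <- S[rep(seq_len(N), each = m), , drop = FALSE]
  O <- withr::with_seed(seed, {
    if (is.null(sd_const)) {
      Srep + matrix(rnorm(N * m * d, sd = noise$sigma_add), ncol = d) +
        matrix(rnorm(N * m * d), ncol = d) * (noise$sigma_mult * abs(Srep))
    } else {
      Srep + matrix(rnorm(N * m * d, sd = sd_const), ncol = d)
    }
  })
  # loglik[u, j] = -sum_t (O[u,t]-S[j,t])^2/(2V[j,t]) - 0.5*sum_t log(2 pi V[j,t])
  A <- t(1 / (2 * V))                     # d x N
  B <- t(S / V)                            # d x N
  cj <- colSums(B * t(S)) / 2 + 0.5 * colSums(log(2 * pi * t(V)))
  loglik <- -(O^2 %*% A) + O %*% B -
    matrix(cj, nrow(O), N, byrow = TRUE)
  risk_weights(loglik, N, m)
}

#' Monte-Carlo confusability weight matrix of an experiment
#'
#' For each posterior draw `theta_i`, the experiment's outcome distribution
#' is sampled `m` times (one deterministic simulation per draw, `m`
#' independent noise corruptions) and each simulated observation is scored
#' against the predicted signals of all draws. The resulting `W[i, j]`
#' measures how easily the experiment confuses `theta_i` with `theta_j`:
#' rows sum to one exactly, an uninformative experiment gives the uniform
#' matrix `1/N`, and a perfectly separating one approaches the identity.
#' Draws whose simulation fails are dropped (all computations then run on
#' the surviving subset, which keeps `W` row-stochastic).
#'
#' @param experiment One catalogue row (assay or purchase).
#' @param sample A `posterior_sample`.
#' @param network A [gene_network()].
#' @param noise A [noise_model()].
#' @param m Monte-Carlo observations per draw.
#' @param seed Integer seed.
#' @param purchase_sd Purchase noise sd, log scale.
#' @param cache Optional environment shared across experiments to reuse
#'   per-action simulations.
#' @return `N x N` row-stochastic matrix; attribute `"ok"` flags the draws
#'   that survived.
#' @export
weight_matrix <- function(experiment, sample, network, noise = noise_model(),
                          m = 100, seed = 1, purchase_sd = 0.05,
                          cache = NULL) {
  experiment <- as_tibble(experiment)
  stopifnot(nrow(experiment) == 1)
  sig <- predicted_signals(sample, experiment, network, cache, purchase_sd)
  if (!all(sig$ok)) {
    warn(sprintf("%d draw(s) failed to simulate; dropped.", sum(!sig$ok)))
  }
  S <- sig$S[sig$ok, , drop = FALSE]
  W <- weight_matrix_impl(S, noise, sig$sd_const, m, seed)
  attr(W, "ok") <- sig$ok
  W
}

#' Expected risk of a candidate experiment
#'
#' Monte-Carlo estimate of the expected posterior loss after performing the
#' experiment: `R = (1/N) * sum(L * W)` where `L` is the pairwise loss
#' matrix and `W` the confusability [weight_matrix()]. With this
#' normalization an uninformative experiment scores exactly the
#' [baseline_risk()], and a perfectly separating experiment scores 0.
#'
#' @inheritParams weight_matrix
#' @param loss Loss kind, see [pairwise_loss()].
#' @return Non-negative scalar.
#' @export
expected_risk <- function(experiment, sample, network,
                          loss = c("squared_log_ratio", "squared_euclidean"),
                          noise = noise_model(), m = 100, seed = 1,
                          purchase_sd = 0.05, cache = NULL) {
  loss <- match.arg(loss)
  W <- weight_matrix(experiment, sample, network, noise, m, seed,
    purchase_sd, cache
  )
  ok <- attr(W, "ok")
  draws <- sample$draws[ok, , drop = FALSE]
  L <- pairwise_loss(draws, loss)
  sum(L * W) / nrow(L)
}

subset_sample <- function(sample, keep) {
  new_posterior_sample(
    sample$draws_log[keep, , drop = FALSE],
    sample$weights[keep],
    sample$log_target[keep],
    sample$provenance[keep, , drop = FALSE],
    colnames(sample$draws),
    sample$accept_rates
  )
}

#' Score every candidate experiment
#'
#' Evaluates [expected_risk()] for each unpurchased catalogue entry using
#' one shared posterior sample and a shared per-action simulation cache
#' (each distinct action is simulated once per draw, regardless of how many
#' observables it is combined with). Draws that fail to simulate under any
#' required action are dropped once, for the whole round. Rows are sorted
#' by ascending risk with ties broken by lower cost, then catalogue order.
#'
#' @param sample A `posterior_sample`.
#' @param catalogue A design-space tibble from [enumerate_design_space()].
#' @param network A [gene_network()].
#' @param loss Loss kind.
#' @param noise A [noise_model()].
#' @param m Monte-Carlo observations per draw.
#' @param seed Integer seed (per-experiment streams derive from it and the
#'   catalogue position, so scoring a subset reproduces the full run).
#' @param purchase_sd Purchase noise sd.
#' @param exclude Character vector of already-purchased experiment ids.
#' @return A tibble of class `risk_table` (columns `id`, `risk`, `cost`,
#'   `type`, `label`, plus action/observable descriptors), sorted ascending
#'   by risk; the baseline risk of the (surviving) sample is attached as
#'   attribute `"baseline"`.
#' @export
rank_experiments <- function(sample, catalogue, network,
                             loss = c("squared_log_ratio", "squared_euclidean"),
                             noise = noise_model(), m = 100, seed = 1,
                             purchase_sd = 0.05, exclude = NULL) {
  loss <- match.arg(loss)
  candidates <- filter(catalogue, !(.data$id %in% exclude))
  if (nrow(candidates) == 0) abort("No candidate experiments left to score.")
  cache <- new.env(parent = emptyenv())
  # first pass: simulate all distinct actions, collect draws that fail
  assay_rows <- filter(candidates, .data$type == "assay")
  actions <- distinct(assay_rows, .data$action_kind, .data$action_target)
  ok <- rep(TRUE, nrow(sample$draws))
  for (a in seq_len(nrow(actions))) {
    pert <- experiment_action(actions[a, ])
    ok <- ok & sims_for_action(sample$draws, pert, network, cache)$ok
  }
  if (!all(ok)) {
    warn(sprintf(
      "%d posterior draw(s) failed to simulate and were dropped for this round.",
      sum(!ok)
    ))
    sample <- subset_sample(sample, ok)
    cache <- new.env(parent = emptyenv())
  }
  L <- pairwise_loss(sample, loss)
  risks <- purrr::map_dbl(seq_len(nrow(candidates)), function(r) {
    exp_row <- candidates[r, ]
    W <- weight_matrix(
      exp_row, sample, network, noise, m,
      seed = derive_seed(seed, 10, exp_row$catalogue_order),
      purchase_sd = purchase_sd, cache = cache
    )
    sum(L * W) / nrow(L)
  })
  out <- candidates
  out$risk <- risks
  out <- arrange(out, .data$risk, .data$cost, .data$catalogue_order)
  out <- select(
    out, "id", "risk", "cost", "type", "action_kind", "action_target",
    "obs_kind", "obs_resolution", "obs_targets", "reaction", "label",
    "catalogue_order"
  )
  attr(out, "baseline") <- sum(L) / nrow(L)^2
  attr(out, "n_draws") <- nrow(sample$draws)
  class(out) <- c("risk_table", class(out))
  out
}
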