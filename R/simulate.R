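CIRCUIT_PARMS_LEN <- 256L

#' Observation time grids
#'
#' The design horizon is `[0, 20]` time units. Low resolution samples 11
#' equally spaced points (the grid of the cheap mRNA assay and of all
#' protein assays); high resolution samples 41 points, which is also the
#' grid used for simulation so that every observation grid is a sub-grid.
#'
#' @param resolution `"low"` or `"high"`.
#' @param horizon Upper end of the time window (default 20).
#' @return Numeric vector of time points starting at 0.
#' @export
time_grid <- function(resolution = c("high", "low"), horizon = 20) {
  resolution <- match.arg(resolution)
  n <- if (resolution == "low") 11L else 41L
  seq(0, horizon, length.out = n)
}


solver_error <- function(message) {
  abort(message, class = "circuit_solver_error")
}

# lsoda's Fortran core prints diagnostics straight to the console when a
# hopeless parameter point defeats it; those points are expected during
# prior exploration and are handled via conditions, so the chatter is
# discarded through a persistent null-device sink.
.quiet_env <- new.env(parent = emptyenv())

with_muffled_console <- function(expr) {
  con <- .quiet_env$null_con
  if (is.null(con) || !isOpen(con)) {
    con <- file(nullfile(), open = "wt")
    .quiet_env$null_con <- con
  }
  sink(con)
  on.exit(sink())
  expr
}

# Precompute everything needed to simulate one (network, perturbation)
# combination for many parameter vectors: the packed constant template and
# the positions to fill from theta (with per-entry scale factors, e.g. the
# 10-fold ribosomal decrease). This keeps the per-evaluation cost of the
# optimization and MCMC loops down to the lsoda call itself.
make_sim_plan <- function(network, pert = perturbation("wildtype")) {
  full_names <- param_names(network)
  ones <- setNames(rep(1, length(full_names)), full_names)
  eff <- apply_perturbation(ones, network, pert)
  net2 <- eff$network
  g <- net2$genes
  G <- length(g)
  rxn <- net2$reactions
  R <- nrow(rxn)
  silenced <- attr(eff$params, "silenced_promoters") %||% character()
  template <- rep(0, CIRCUIT_PARMS_LEN)
  template[1] <- G
  template[2] <- R
  fill_pos <- 3L
  fill_name <- "delta_p"
  fill_scale <- 1
  for (i in seq_len(G)) {
    base <- 3L + 3L * (i - 1L)
    if (!(g[i] %in% silenced)) {
      fill_pos <- c(fill_pos, base + 1L)
      fill_name <- c(fill_name, paste0("promoter_", g[i]))
      fill_scale <- c(fill_scale, 1)
    }
    fill_pos <- c(fill_pos, base + 2L)
    fill_name <- c(fill_name, paste0("ribosomal_", g[i]))
    fill_scale <- c(fill_scale, unname(eff$params[paste0("ribosomal_", g[i])]))
    template[base + 3L] <- net2$mrna_degradation[[g[i]]]
  }
  rb <- 3L + 3L * G
  for (r in seq_len(R)) {
    base <- rb + 5L * (r - 1L)
    template[base + 1L] <- match(rxn$regulator[r], g) - 1L
    template[base + 2L] <- match(rxn$target[r], g) - 1L
    template[base + 3L] <- if (rxn$sign[r] == "activation") 1 else -1
    fill_pos <- c(fill_pos, base + 4L, base + 5L)
    fill_name <- c(fill_name, paste0("K_", rxn$id[r]), paste0("h_", rxn$id[r]))
    fill_scale <- c(fill_scale, 1, 1)
  }
  list(
    template = template,
    fill_pos = fill_pos,
    fill_idx = match(fill_name, full_names),
    fill_scale = fill_scale,
    species = species_names(net2),
    y0 = rep(0, 2 * G),
    deleted = eff$deleted
  )
}

# Fast trajectory for a prepared plan. `theta` must be the full parameter
# vector in canonical order (names optional).
sim_plan_run <- function(plan, theta, times = time_grid("high"),
                         rtol = 1e-6, atol = 1e-8) {
  pvec <- plan$template
  pvec[plan$fill_pos] <- theta[plan$fill_idx] * plan$fill_scale
  out <- with_muffled_console(try(
    suppressWarnings(deSolve::lsoda(
      plan$y0, times, func = "circuit_deriv", parms = pvec,
      dllname = "circuitdesign", initfunc = "circuit_init",
      rtol = rtol, atol = atol, maxsteps = 2000
    )),
    silent = TRUE
  ))
  if (inherits(out, "try-error")) solver_error("ODE integration failed.")
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1] < 0) {
    solver_error(sprintf("ODE solver did not converge (istate %d).", istate[1]))
  }
  m <- unclass(out)[, -1, drop = FALSE]
  if (nrow(m) != length(times) || any(!is.finite(m))) {
    solver_error("ODE solution incomplete or non-finite.")
  }
  colnames(m) <- plan$species
  rownames(m) <- NULL
  attr(m, "time") <- times
  attr(m, "deleted") <- plan$deleted
  m
}

# Deterministic trajectory matrix (rows = times, cols = species) of the
# perturbed system. Raises a catchable `circuit_solver_error` on integration
# failure so that callers can treat the parameter point as invalid.
sim_matrix <- function(network, params, pert = perturbation("wildtype"),
                       times = time_grid("high"), initial_state = NULL,
                       rtol = 1e-6, atol = 1e-8) {
  validate_params(params, network)
  if (times[1] != 0) abort("Time grid must start at 0.")
  plan <- make_sim_plan(network, pert)
  if (!is.null(initial_state)) {
    plan$y0 <- unname(initial_state[plan$species])
    if (anyNA(plan$y0)) abort("`initial_state` must name every surviving species.")
  }
  sim_plan_run(plan, unname(params), times, rtol, atol)
}

#' Simulate a perturbed gene circuit
#'
#' Integrates the mRNA/protein ODE system deterministically with a
#' stiff-capable solver (lsoda, rtol 1e-6, atol 1e-8) from an all-zero
#' initial state (fresh induction) unless `initial_state` is given.
#' Deleted species are removed from the system, not zeroed.
#'
#' @param network A [gene_network()].
#' @param params Named parameter vector (see [make_params()]).
#' @param pert A [perturbation()] (default wildtype).
#' @param times Increasing time grid starting at 0 (default the 41-point
#'   high-resolution grid, see [time_grid()]).
#' @param initial_state Optional named vector of initial concentrations for
#'   the surviving species.
#' @return A tibble of class `circuit_trajectory` with columns `time`,
#'   `species`, `value`.
#' @examples
#' net <- network_preset("subnet3")
#' traj <- simulate_circuit(net, preset_parameters(net))
#' head(traj)
#' @export
simulate_circuit <- function(network, params, pert = perturbation("wildtype"),
                             times = time_grid("high"), initial_state = NULL) {
  m <- sim_matrix(network, params, pert, times, initial_state)
  out <- tibble(
    time = rep(attr(m, "time"), times = ncol(m)),
    species = rep(colnames(m), each = nrow(m)),
    value = as.vector(m)
  )
  class(out) <- c("circuit_trajectory", class(out))
  out
}
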