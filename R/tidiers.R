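#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a posterior sample
#'
#' @param x A `posterior_sample`.
#' @param log_scale Return values on the natural-log scale (default FALSE).
#' @param ... Unused.
#' @return Long tibble: `draw`, `chain`, `parameter`, `value`, `weight`.
#' @export
tidy.posterior_sample <- function(x, log_scale = FALSE, ...) {
  draws <- if (log_scale) x$draws_log else x$draws
  tibble(
    draw = rep(seq_len(nrow(draws)), times = ncol(draws)),
    chain = rep(x$provenance$chain, times = ncol(draws)),
    parameter = rep(colnames(draws), each = nrow(draws)),
    value = as.vector(draws),
    weight = rep(x$weights, times = ncol(draws))
  )
}

#' One-row summary of a posterior sample
#'
#' @param x A `posterior_sample`.
#' @param ... Unused.
#' @return Tibble with draw/chain counts, mean acceptance rate and the
#'   range of the log target over the retained draws.
#' @export
glance.posterior_sample <- function(x, ...) {
  tibble(
    n_draws = nrow(x$draws),
    n_parameters = ncol(x$draws),
    n_chains = dplyr::n_distinct(x$provenance$chain),
    mean_accept_rate = mean(x$accept_rates),
    log_target_min = min(x$log_target),
    log_target_max = max(x$log_target)
  )
}

#' Tidy a design run
#'
#' @param x A `design_state` from [run_design_loop()].
#' @param ... Unused.
#' @return The per-round trace tibble.
#' @export
tidy.design_state <- function(x, ...) x$trace

#' One-row summary of a design run
#'
#' @param x A `design_state`.
#' @param ... Unused.
#' @return Tibble with strategy, purchases, spend and final risks.
#' @export
glance.design_state <- function(x, ...) {
  tibble(
    strategy = x$strategy,
    n_purchases = nrow(x$trace) - 1L,
    budget = x$budget,
    budget_spent = x$budget - x$remaining,
    initial_true_risk = x$trace$true_risk[1],
    final_true_risk = utils::tail(x$trace$true_risk, 1)
  )
}

#' Posterior summary statistics per parameter
#'
#' @param sample A `posterior_sample`.
#' @return Tibble: `parameter`, posterior mean/sd on the natural scale and
#'   on the log scale, and central 90% quantiles.
#' @export
summarize_posterior <- function(sample) {
  stopifnot(inherits(sample, "posterior_sample"))
  draws <- sample$draws
  tibble(
    parameter = colnames(draws),
    mean = colMeans(draws),
    sd = apply(draws, 2, sd),
    log_mean = colMeans(sample$draws_log),
    log_sd = apply(sample$draws_log, 2, sd),
    q05 = apply(draws, 2, stats::quantile, 0.05),
    q95 = apply(draws, 2, stats::quantile, 0.95)
  )
}
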