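#' Pick the next experiment by cost-normalized risk reduction
#'
#' Among affordable, not-yet-purchased candidates, selects the one
#' maximizing `(baseline - risk) / cost` — the expected risk reduction per
#' credit. Ties go to the lower cost, then to catalogue order.
#'
#' @param risk_table A `risk_table` from [rank_experiments()].
#' @param baseline Baseline risk of the current posterior (defaults to the
#'   value attached to `risk_table`).
#' @param budget Remaining credits.
#' @param purchased Character vector of already-purchased experiment ids.
#' @return The selected catalogue row (1-row tibble), or `NULL` when no
#'   candidate is affordable.
#' @export
select_next <- function(risk_table, baseline = attr(risk_table, "baseline"),
                        budget = Inf, purchased = character()) {
  cand <- filter(risk_table, !(.data$id %in% purchased), .data$cost <= budget)
  if (nrow(cand) == 0) return(NULL)
  cand <- mutate(cand, score = (baseline - .data$risk) / .data$cost)
  cand <- arrange(cand, dplyr::desc(.data$score), .data$cost, .data$catalogue_order)
  as_tibble(cand[1, ])
}

#' True risk of a posterior sample
#'
#' Mean loss between the posterior draws and the hidden ground truth —
#' computable only in simulation, where `theta_star` is known. Uses the
#' sample weights when they are not uniform.
#'
#' @param sample A `posterior_sample` (or matrix of draws).
#' @param theta_star True parameter vector.
#' @param loss Loss kind, see [pairwise_loss()].
#' @return Non-negative scalar.
#' @export
true_risk <- function(sample, theta_star,
                      loss = c("squared_log_ratio", "squared_euclidean")) {
  loss <- match.arg(loss)
  if (inherits(sample, "posterior_sample")) {
    draws <- sample$draws
    w <- sample$weights
  } else {
    draws <- as.matrix(sample)
    w <- rep(1 / nrow(draws), nrow(draws))
  }
  sum(w * loss_to_point(draws, theta_star, loss))
}

#' Run the budgeted sequential design loop
#'
#' Closed-loop simulation of the design process. The loop starts from a
#' free low-resolution wildtype mRNA dataset (the corresponding catalogue
#' entry is marked purchased at no charge), then repeats: draw a posterior
#' sample given all data so far; record the true risk; choose the next
#' experiment (`"oed"`: cost-normalized greedy choice via
#' [rank_experiments()] and [select_next()]; `"random"`: uniform among
#' affordable unpurchased candidates); buy it, i.e. simulate the hidden
#' truth under its action and corrupt with noise; subtract its cost. The
#' loop stops when nothing affordable remains. Fully reproducible from
#' `seed` (all per-round seeds derive from it).
#'
#' @param network A [gene_network()].
#' @param theta_star Hidden true parameter vector (must be simulable).
#' @param strategy `"oed"` or `"random"`.
#' @param budget Initial credits (default 5000).
#' @param catalogue Optional [enumerate_design_space()] tibble (default:
#'   single-protein observables for up to 3 genes, protein pairs
#'   otherwise).
#' @param spec,noise,settings Prior, noise model and sampler settings.
#' @param loss Loss kind.
#' @param seed Integer master seed.
#' @param purchase_sd Purchase noise sd.
#' @param keep_risk_tables Keep each round's risk table in the result
#'   (OED only).
#' @return A `design_state` object: list with `trace` (tibble: round,
#'   purchase, cost, budget_spent, budget_remaining, true_risk, baseline),
#'   `purchased` ids, `datasets`, final `sample`, and bookkeeping fields.
#' @export
run_design_loop <- function(network, theta_star, strategy = c("oed", "random"),
                            budget = 5000, catalogue = NULL,
                            spec = prior_spec(network),
                            noise = noise_model(),
                            settings = sampler_settings(),
                            loss = c("squared_log_ratio", "squared_euclidean"),
                            seed = 1, purchase_sd = 0.05,
                            keep_risk_tables = FALSE) {
  strategy <- match.arg(strategy)
  loss <- match.arg(loss)
  validate_params(theta_star, network)
  tryCatch(
    sim_matrix(network, theta_star),
    circuit_solver_error = function(e) {
      abort("`theta_star` must be simulable under the wildtype condition.")
    }
  )
  if (is.null(catalogue)) {
    mode <- if (length(network$genes) <= 3) "single_protein" else "protein_pair"
    catalogue <- enumerate_design_space(network, mode)
  }
  if (budget <= 0) abort("`budget` must be positive.")

  free_row <- filter(
    catalogue, .data$type == "assay", .data$action_kind == "wildtype",
    .data$obs_kind == "mrna_all", .data$obs_resolution == "low"
  )
  purchased <- character()
  datasets <- list()
  if (nrow(free_row) >= 1) {
    free_row <- free_row[1, ]
    datasets <- list(generate_dataset(
      free_row, network, theta_star, noise,
      seed = derive_seed(seed, 0), purchase_sd = purchase_sd
    ))
    purchased <- free_row$id
  }

  remaining <- budget
  trace <- list()
  risk_tables <- list()
  round_k <- 0L
  sample_k <- NULL
  warm <- NULL
  repeat {
    sample_k <- sample_posterior(
      datasets, network, spec, noise, settings,
      seed = derive_seed(seed, 100, round_k), purchase_sd = purchase_sd,
      extra_starts = warm
    )
    # carry the best draw of this round as a warm start for the next one
    warm <- sample_k$draws_log[which.max(sample_k$log_target), , drop = FALSE]
    tr <- true_risk(sample_k, theta_star, loss)
    base <- baseline_risk(sample_k, loss)
    trace[[length(trace) + 1]] <- tibble(
      round = round_k,
      purchase = if (round_k == 0) NA_character_ else last_purchase$id,
      label = if (round_k == 0) NA_character_ else last_purchase$label,
      cost = if (round_k == 0) 0 else last_purchase$cost,
      budget_spent = budget - remaining,
      budget_remaining = remaining,
      baseline = base,
      true_risk = tr
    )
    affordable <- filter(
      catalogue, !(.data$id %in% purchased), .data$cost <= remaining
    )
    if (nrow(affordable) == 0) break
    if (strategy == "oed") {
      rt <- rank_experiments(
        sample_k, catalogue, network, loss, noise,
        m = settings$m_noise, seed = derive_seed(seed, 200, round_k),
        purchase_sd = purchase_sd, exclude = purchased
      )
      if (keep_risk_tables) risk_tables[[length(risk_tables) + 1]] <- rt
      choice <- select_next(rt, budget = remaining, purchased = purchased)
    } else {
      pick <- withr::with_seed(
        derive_seed(seed, 300, round_k),
        sample.int(nrow(affordable), 1)
      )
      choice <- affordable[pick, ]
    }
    if (is.null(choice)) break
    ds <- generate_dataset(
      catalogue[catalogue$id == choice$id, ], network, theta_star, noise,
      seed = derive_seed(seed, 400, round_k), purchase_sd = purchase_sd
    )
    datasets <- c(datasets, list(ds))
    purchased <- c(purchased, choice$id)
    remaining <- remaining - choice$cost
    last_purchase <- choice
    round_k <- round_k + 1L
  }
  structure(
    list(
      trace = bind_rows(trace),
      purchased = purchased,
      datasets = datasets,
      sample = sample_k,
      risk_tables = risk_tables,
      strategy = strategy,
      budget = budget,
      remaining = remaining,
      seed = seed
    ),
    class = "design_state"
  )
}

#' @export
print.design_state <- function(x, ...) {
  cat(
    "<design_state> strategy ", x$strategy, ": ",
    nrow(x$trace) - 1, " purchase(s), ", x$budget - x$remaining,
    " of ", x$budget, " credits spent, final true risk ",
    signif(utils::tail(x$trace$true_risk, 1), 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' Compare design strategies over repeated runs
#'
#' Runs [run_design_loop()] for each strategy and repeat with distinct
#' derived seeds and stacks the traces, ready for plotting true risk
#' against budget spent.
#'
#' @inheritParams run_design_loop
#' @param strategies Character vector of strategies to run.
#' @param repeats Number of independent repeats per strategy.
#' @return A tibble of class `strategy_comparison`: the union of traces
#'   with `strategy` and `repeat` columns.
#' @export
compare_strategies <- function(network, theta_star, budget = 5000,
                               repeats = 10,
                               strategies = c("oed", "random"),
                               catalogue = NULL,
                               spec = prior_spec(network),
                               noise = noise_model(),
                               settings = sampler_settings(),
                               loss = c("squared_log_ratio", "squared_euclidean"),
                               seed = 1, purchase_sd = 0.05) {
  loss <- match.arg(loss)
  if (repeats < 1) abort("`repeats` must be at least 1.")
  grid <- tidyr::expand_grid(strategy = strategies, rep = seq_len(repeats))
  out <- purrr::pmap(grid, function(strategy, rep) {
    st <- run_design_loop(
      network, theta_star,
      strategy = strategy, budget = budget,
      catalogue = catalogue, spec = spec, noise = noise,
      settings = settings, loss = loss,
      seed = derive_seed(seed, match(strategy, strategies), rep),
      purchase_sd = purchase_sd
    )
    mutate(st$trace, strategy = strategy, rep = rep, .before = 1)
  })
  out <- bind_rows(out)
  class(out) <- c("strategy_comparison", class(out))
  out
}
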