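#' Observable quantities of a network
#'
#' Measurements come in three kinds: all mRNA concentrations at either of
#' two time resolutions, a single protein time course, or a pair of protein
#' time courses. Protein assays have a single (low) resolution. The
#' `single_protein` mode is the natural choice for small circuits; the
#' `protein_pair` mode mirrors the full-challenge setting where protein
#' measurements come in pairs (`choose(G, 2)` choices).
#'
#' @param network A [gene_network()].
#' @param mode `"single_protein"` or `"protein_pair"`.
#' @return Tibble with columns `obs_id`, `obs_kind`, `obs_resolution`,
#'   `obs_targets` (comma-separated gene ids, `NA` for mRNA) and
#'   `obs_label`.
#' @examples
#' nrow(observables(network_preset("full9"), "protein_pair")) # 38
#' @export
observables <- function(network, mode = c("single_protein", "protein_pair")) {
  mode <- match.arg(mode)
  g <- network$genes
  mrna <- tibble(
    obs_kind = "mrna_all",
    obs_resolution = c("low", "high"),
    obs_targets = NA_character_,
    obs_label = c("mRNA all (low res)", "mRNA all (high res)")
  )
  prot <- if (mode == "single_protein") {
    tibble(
      obs_kind = "protein_single",
      obs_resolution = "low",
      obs_targets = g,
      obs_label = paste0("protein ", g)
    )
  } else {
    if (length(g) < 2) abort("protein_pair mode needs at least 2 genes.")
    pairs <- combn(g, 2)
    tibble(
      obs_kind = "protein_pair",
      obs_resolution = "low",
      obs_targets = paste(pairs[1, ], pairs[2, ], sep = ","),
      obs_label = paste0("proteins ", pairs[1, ], "+", pairs[2, ])
    )
  }
  out <- bind_rows(mrna, prot)
  mutate(out, obs_id = paste0("o", dplyr::row_number()), .before = 1)
}

#' Experiment cost table
#'
#' Costs are credits. An assay's cost is the sum of its action cost and its
#' observable cost; estimating the kinetic constants of one reaction (a
#' parameter purchase) has a flat cost. The defaults are package fixtures
#' chosen so that the four perturbation-plus-protein-pair combinations total
#' 1200 (delete), 850 (RBS decrease), 750 (knockdown) and 500 (wildtype)
#' credits.
#'
#' @param action_costs Named numeric: `wildtype`, `delete`, `knockdown`,
#'   `rbs_decrease`.
#' @param observable_costs Named numeric: `mrna_low`, `mrna_high`,
#'   `protein_single`, `protein_pair`.
#' @param purchase_cost Cost of one parameter purchase.
#' @return A `cost_table` object.
#' @export
cost_table <- function(action_costs = c(
                         wildtype = 0, delete = 700,
                         knockdown = 250, rbs_decrease = 350
                       ),
                       observable_costs = c(
                         mrna_low = 200, mrna_high = 400,
                         protein_single = 300, protein_pair = 500
                       ),
                       purchase_cost = 400) {
  needed_a <- c("wildtype", "delete", "knockdown", "rbs_decrease")
  needed_o <- c("mrna_low", "mrna_high", "protein_single", "protein_pair")
  if (!all(needed_a %in% names(action_costs)) ||
    !all(needed_o %in% names(observable_costs))) {
    abort("Cost table is missing entries.")
  }
  costs <- structure(
    list(
      action_costs = action_costs[needed_a],
      observable_costs = observable_costs[needed_o],
      purchase_cost = purchase_cost
    ),
    class = "cost_table"
  )
  all_costs <- c(
    costs$action_costs + min(costs$observable_costs),
    costs$purchase_cost
  )
  if (any(all_costs <= 0)) abort("Every purchasable experiment must have positive cost.")
  costs
}

experiment_cost <- function(costs, action_kind, obs_kind, obs_resolution) {
  obs_key <- ifelse(
    obs_kind == "mrna_all", paste0("mrna_", obs_resolution), obs_kind
  )
  unname(costs$action_costs[action_kind] + costs$observable_costs[obs_key])
}

#' Enumerate the purchasable experiment catalogue
#'
#' Actions are the wildtype plus three perturbations (delete, knockdown,
#' RBS decrease) per gene, giving `1 + 3G` actions. Every action can be
#' combined with every observable; in addition the kinetic constants
#' (binding affinity and Hill coefficient) of each reaction can be
#' purchased directly. The ordering is deterministic: assays action-major
#' (wildtype first, then per gene delete/knockdown/rbs_decrease) over the
#' [observables()] ordering, followed by one purchase row per reaction.
#'
#' @param network A [gene_network()].
#' @param mode Observable mode, see [observables()].
#' @param costs A [cost_table()].
#' @return A tibble of class `design_space`: columns `id`, `type`
#'   (`"assay"` or `"purchase"`), `action_kind`, `action_target`,
#'   `obs_id`, `obs_kind`, `obs_resolution`, `obs_targets`, `reaction`,
#'   `cost`, `label`.
#' @examples
#' cat3 <- enumerate_design_space(network_preset("subnet3"), "single_protein")
#' sum(cat3$type == "assay") # 50
#' @export
enumerate_design_space <- function(network,
                                   mode = c("single_protein", "protein_pair"),
                                   costs = cost_table()) {
  mode <- match.arg(mode)
  g <- network$genes
  actions <- bind_rows(
    tibble(action_kind = "wildtype", action_target = NA_character_),
    tidyr::expand_grid(
      action_target = g,
      action_kind = c("delete", "knockdown", "rbs_decrease")
    )[, c("action_kind", "action_target")]
  )
  obs <- observables(network, mode)
  assays <- tidyr::crossing(
    actions = seq_len(nrow(actions)), obs_row = seq_len(nrow(obs))
  )
  assays <- bind_cols(
    actions[assays$actions, ], obs[assays$obs_row, ]
  )
  assays <- mutate(
    assays,
    type = "assay",
    reaction = NA_character_,
    cost = experiment_cost(costs, .data$action_kind, .data$obs_kind, .data$obs_resolution),
    label = paste0(
      ifelse(.data$action_kind == "wildtype", "wildtype",
        paste0(.data$action_kind, " ", .data$action_target)
      ),
      " / ", .data$obs_label
    )
  )
  purchases <- if (nrow(network$reactions) > 0) {
    tibble(
      type = "purchase",
      action_kind = NA_character_, action_target = NA_character_,
      obs_id = NA_character_, obs_kind = NA_character_,
      obs_resolution = NA_character_, obs_targets = NA_character_,
      obs_label = NA_character_,
      reaction = network$reactions$id,
      cost = costs$purchase_cost,
      label = paste0(
        "purchase constants of ", network$reactions$id, " (",
        network$reactions$regulator,
        ifelse(network$reactions$sign == "activation", " -> ", " -| "),
        network$reactions$target, ")"
      )
    )
  } else {
    NULL
  }
  out <- bind_rows(assays, purchases)
  out <- mutate(out,
    id = paste0("e", dplyr::row_number()),
    catalogue_order = dplyr::row_number(), .before = 1
  )
  out <- select(
    out, "id", "catalogue_order", "type", "action_kind", "action_target",
    "obs_id", "obs_kind", "obs_resolution", "obs_targets", "reaction",
    "cost", "label"
  )
  class(out) <- c("design_space", class(out))
  out
}

experiment_action <- function(exp_row) {
  if (exp_row$action_kind == "wildtype") {
    perturbation("wildtype")
  } else {
    perturbation(exp_row$action_kind, exp_row$action_target)
  }
}

# Species/time layout selected by an observable on a (possibly reduced) set
# of surviving species. Returns a tibble (species, time); deleted species
# are dropped (with a note) rather than failing the whole observation.
obs_layout <- function(exp_row, surviving_species, quiet = FALSE) {
  grid <- time_grid(exp_row$obs_resolution)
  sp <- if (exp_row$obs_kind == "mrna_all") {
    grep("^mRNA_", surviving_species, value = TRUE)
  } else {
    paste0("protein_", strsplit(exp_row$obs_targets, ",")[[1]])
  }
  missing <- setdiff(sp, surviving_species)
  if (length(missing) > 0) {
    if (!quiet) {
      inform(paste0(
        "Observable species not in system (deleted): ",
        paste(missing, collapse = ", ")
      ))
    }
    sp <- setdiff(sp, missing)
  }
  tidyr::expand_grid(species = sp, time = grid)
}

#' Extract the ideal signal an experiment would observe
#'
#' Pure selection: picks the observable's species at the observable's time
#' grid from a simulated trajectory. Species removed by a deletion are
#' dropped (the remaining species are still observed).
#'
#' @param traj A `circuit_trajectory` tibble from [simulate_circuit()].
#' @param experiment One catalogue row (see [enumerate_design_space()]) of
#'   type `"assay"`.
#' @return Tibble with columns `species`, `time`, `value`.
#' @export
observation_operator <- function(traj, experiment) {
  experiment <- as_tibble(experiment)
  if (nrow(experiment) != 1 || experiment$type != "assay") {
    abort("`experiment` must be a single assay catalogue row.")
  }
  layout <- obs_layout(experiment, unique(traj$species))
  out <- left_join(layout, traj, by = c("species", "time"))
  if (anyNA(out$value)) {
    abort("Observation grid is not a sub-grid of the simulated trajectory.")
  }
  out
}
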