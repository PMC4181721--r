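#' Read a network specification from YAML or JSON
#'
#' The file holds `genes` (list of identifiers), `reactions` (list of
#' `[regulator, target, sign]` triples or of mappings with those keys) and
#' optionally `mrna_degradation` (mapping gene -> rate).
#'
#' @param path Path to a `.yaml`/`.yml` (or YAML-compatible JSON) file.
#' @return A [gene_network()].
#' @export
read_network <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$genes)) abort("Network file must define `genes`.")
  rxn <- NULL
  if (!is.null(cfg$reactions) && length(cfg$reactions) > 0) {
    rxn <- purrr::map_dfr(cfg$reactions, function(r) {
      if (is.null(names(r))) {
        tibble(regulator = r[[1]], target = r[[2]], sign = r[[3]])
      } else {
        tibble(regulator = r$regulator, target = r$target, sign = r$sign)
      }
    })
  }
  md <- if (is.null(cfg$mrna_degradation)) 1 else unlist(cfg$mrna_degradation)
  gene_network(unlist(cfg$genes), rxn, mrna_degradation = md)
}

#' Write a network specification to YAML
#'
#' @param network A [gene_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  yaml::write_yaml(
    list(
      genes = as.list(network$genes),
      reactions = purrr::pmap(
        network$reactions[, c("regulator", "target", "sign")], list
      ),
      mrna_degradation = as.list(network$mrna_degradation)
    ),
    path
  )
  invisible(path)
}

#' Read a cost table from YAML
#'
#' Expects keys `action_costs`, `observable_costs`, `purchase_cost`
#' matching [cost_table()].
#'
#' @param path Path to a YAML file.
#' @return A [cost_table()].
#' @export
read_cost_table <- function(path) {
  cfg <- yaml::read_yaml(path)
  cost_table(
    action_costs = unlist(cfg$action_costs),
    observable_costs = unlist(cfg$observable_costs),
    purchase_cost = cfg$purchase_cost %||% 400
  )
}

#' Serialize observation datasets to CSV
#'
#' One row per data point: `experiment_id`, `species`, `time`, `value`
#' (purchase rows use `species` `"log_K"`/`"log_h"` and `NA` time).
#'
#' @param datasets List of `observation_dataset` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_datasets <- function(datasets, path) {
  rows <- purrr::map_dfr(datasets, function(ds) {
    mutate(ds$data, experiment_id = ds$experiment$id, .before = 1)
  })
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read observation datasets from CSV
#'
#' @param path CSV written by [write_datasets()].
#' @param catalogue The design-space tibble the experiment ids refer to.
#' @return List of `observation_dataset` objects.
#' @export
read_datasets <- function(path, catalogue) {
  rows <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  purrr::map(split(rows, rows$experiment_id), function(chunk) {
    exp_row <- filter(catalogue, .data$id == chunk$experiment_id[1])
    if (nrow(exp_row) != 1) {
      abort(paste0("Dataset references unknown experiment ", chunk$experiment_id[1]))
    }
    new_observation_dataset(
      exp_row, select(chunk, "species", "time", "value")
    )
  })
}
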