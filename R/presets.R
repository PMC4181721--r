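#' Built-in network presets
#'
#' Two in-silico circuits in the style of the DREAM7 parameter-inference
#' challenge ship with the package.
#'
#' `"subnet3"` is the 3-gene cascade subnetwork (genes g6, g7, g8) with a
#' single inhibitory reaction g7 -| g8; it has 6 state variables and 9 free
#' parameters.
#'
#' `"full9"` is a 9-gene circuit with exactly 13 signed reactions and 45
#' free parameters. Its edge list is a synthetic reconstruction: it is
#' constrained to the published scale (9 genes, 13 reactions, 18 species),
#' to the cascade position of gene 7 (unregulated, at the top), to the
#' inhibition g7 -| g8, and to protein 8 inhibiting protein 5; the remaining
#' edges are plausible fill-in and carry no claim of matching the original
#' challenge topology.
#'
#' @param name `"subnet3"` or `"full9"`.
#' @return A [gene_network()].
#' @examples
#' network_preset("subnet3")
#' count_parameters(network_preset("full9"))
#' @export
network_preset <- function(name = c("subnet3", "full9")) {
  name <- match.arg(name)
  if (name == "subnet3") {
    return(gene_network(
      genes = c("g6", "g7", "g8"),
      reactions = tibble(
        regulator = "g7", target = "g8", sign = "inhibition"
      )
    ))
  }
  genes <- paste0("g", 1:9)
  # synthetic 13-edge cascade; induced subgraph on {g6, g7, g8} is g7 -| g8
  reactions <- tibble(
    regulator = c("g7", "g7", "g8", "g8", "g6", "g3", "g4", "g9", "g1",
                  "g2", "g3", "g1", "g5"),
    target    = c("g8", "g4", "g5", "g3", "g1", "g2", "g9", "g2", "g9",
                  "g4", "g5", "g3", "g2"),
    sign = c(
      "inhibition", "activation", "inhibition", "activation", "activation",
      "activation", "activation", "inhibition", "activation", "inhibition",
      "activation", "inhibition", "activation"
    )
  )
  gene_network(genes, reactions)
}

#' Ground-truth parameters for a preset network
#'
#' Deterministic, biologically plausible kinetic values used as the hidden
#' truth in simulation studies: promoter strengths of order 1-3
#' concentration/time, ribosomal strengths of order 1, binding affinities
#' near the operating protein concentrations, Hill coefficients 2 or 4 and
#' a shared protein degradation rate of 0.5/time.
#'
#' @param network A preset [gene_network()] (any network works; values are
#'   assigned deterministically by position).
#' @return Named parameter vector.
#' @export
preset_parameters <- function(network) {
  G <- length(network$genes)
  nr <- nrow(network$reactions)
  promoter <- rep(c(1.5, 2.5, 2.0, 1.2, 3.0, 1.8, 2.2, 1.4, 2.8), length.out = G)
  ribosomal <- rep(c(1.2, 0.8, 1.5, 1.0, 0.9, 1.3, 1.1, 1.6, 0.7), length.out = G)
  K <- if (nr > 0) rep(c(2.0, 3.5, 1.5, 4.0, 2.5), length.out = nr) else numeric()
  h <- if (nr > 0) rep(c(2, 4, 2, 2, 4), length.out = nr) else numeric()
  make_params(network,
    promoter = promoter, ribosomal = ribosomal,
    K = K, h = h, delta_p = 0.5
  )
}
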