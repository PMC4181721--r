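# Shared fixtures: tiny circuits and quick sampler settings used across
# test files. Everything is built in code at test time.

subnet <- network_preset("subnet3")
theta_subnet <- preset_parameters(subnet)

# single unregulated gene: closed-form steady state available
net1 <- gene_network("a")
theta1 <- make_params(net1, promoter = 2, ribosomal = 1.5, delta_p = 0.5)

# two independent genes: handy for uninformative-experiment constructions
net2 <- gene_network(c("a", "b"))
theta2 <- make_params(net2, promoter = c(2, 1), ribosomal = c(1, 1), delta_p = 0.5)

quick_settings <- function(...) {
  defaults <- sampler_settings(
    n_starts = 4, max_modes = 2, n_iter = 800, burn_in = 200, thin = 5,
    n_draws = 40, m_noise = 20, maxit = 40
  )
  mods <- list(...)
  defaults[names(mods)] <- mods
  defaults
}

# a small equally-weighted posterior-sample stand-in built from explicit draws
sample_from_draws <- function(draws) {
  draws <- as.matrix(draws)
  circuitdesign:::new_posterior_sample(
    log(draws), rep(1, nrow(draws)), rep(0, nrow(draws)),
    tibble::tibble(
      draw = seq_len(nrow(draws)), chain = 1L, mode = 1L
    ),
    colnames(draws)
  )
}
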