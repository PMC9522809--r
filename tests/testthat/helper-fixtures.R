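# Shared fixtures: all data is generated in code at test time.

# small but structured dataset: 6 archetypes x 10 molecules
tiny_generator <- function(seed = 42L, n_molecules = 60L,
                           n_archetypes = 6L) {
  generator_config(n_molecules = n_molecules, n_archetypes = n_archetypes,
                   seed = seed)
}

# a toy autoencoder with seeded random weights, for gradient checks
toy_ae_model <- function(input_dim = 6L, hidden1 = 4L, hidden2 = 2L,
                         lambda = 0.01, beta = 0.5, rho = 0.1,
                         sparsity_layers = "bottleneck", seed = 7L) {
  cfg <- ae_config(input_dim = input_dim, hidden1 = hidden1,
                   hidden2 = hidden2, lambda = lambda, beta = beta,
                   rho = rho, seed = seed,
                   sparsity_layers = sparsity_layers)
  set.seed(seed)
  ae_init(cfg)
}

# flatten / restore model parameters, for finite-difference oracles
ae_params_flat <- function(model) {
  unlist(c(lapply(model$W, as.numeric), lapply(model$b, as.numeric)))
}

ae_set_params_flat <- function(model, theta) {
  i <- 1L
  for (l in seq_along(model$W)) {
    k <- length(model$W[[l]])
    model$W[[l]][] <- theta[i:(i + k - 1L)]
    i <- i + k
  }
  for (l in seq_along(model$b)) {
    k <- length(model$b[[l]])
    model$b[[l]][] <- theta[i:(i + k - 1L)]
    i <- i + k
  }
  model
}

# small random SOM grid with a fixed codebook (no training), for oracles
toy_grid <- function(width = 6L, height = 4L, d = 5L, seed = 11L,
                     topology = "hexagonal") {
  cfg <- som_config(width = width, height = height, topology = topology,
                    iterations = 1L, seed = seed)
  set.seed(seed)
  structure(list(config = cfg,
                 codebook = matrix(rnorm(width * height * d),
                                   width * height, d),
                 positions = som_positions(cfg)),
            class = "som_grid")
}
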