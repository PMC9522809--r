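# Five-layer sparse autoencoder: 212 -> 90 -> 50 -> 90 -> 212 with sigmoid
# units throughout, trained by mini-batch gradient descent on the cost
#   E = (1/N) sum_n sum_k (y_kn - x_kn)^2
#     + (lambda/2) * sum of squared weights (biases included)
#     + beta * sum_j KL(rho || rhohat_j)
# where rhohat_j is the mean bottleneck activation of unit j over the batch.

#' Autoencoder configuration
#'
#' Defaults are the optimized hyperparameters of the reference pipeline:
#' hidden layers 90 and 50 (bottleneck), learning rate 0.01, L2 coefficient
#' 1e-4, sparsity coefficient 1, 1000 epochs. The sparsity target `rho` is
#' the mean activation the KL penalty pulls each bottleneck unit toward.
#'
#' @param input_dim Number of input channels (default 212).
#' @param hidden1 Size of the first/last hidden layer (default 90).
#' @param hidden2 Bottleneck size, i.e. the latent dimension (default 50).
#' @param eta Learning rate for gradient descent (default 0.01).
#' @param lambda L2 regularization coefficient (default 1e-4).
#' @param beta Sparsity regularization coefficient (default 1).
#' @param rho Sparsity target in (0, 1) (default 0.05).
#' @param epochs Training epochs (default 1000).
#' @param batch_size Mini-batch size (default 32).
#' @param seed Integer seed controlling weight init and batch shuffling.
#' @param sparsity_layers Which hidden layers the KL penalty covers:
#'   `"bottleneck"` (default) or `"all_hidden"`.
#' @return An object of class `ae_config`; `layer_sizes` holds the full
#'   symmetric architecture `c(input_dim, hidden1, hidden2, hidden1,
#'   input_dim)`.
#' @export
ae_config <- function(input_dim = 212L, hidden1 = 90L, hidden2 = 50L,
                      eta = 0.01, lambda = 1e-4, beta = 1, rho = 0.05,
                      epochs = 1000L, batch_size = 32L, seed = 1L,
                      sparsity_layers = c("bottleneck", "all_hidden")) {
  sparsity_layers <- match.arg(sparsity_layers)
  stopifnot(input_dim >= 1, hidden1 >= 1, hidden2 >= 1, hidden2 < input_dim,
            eta > 0, lambda >= 0, beta >= 0, rho > 0, rho < 1,
            epochs >= 1, batch_size >= 1)
  structure(list(layer_sizes = as.integer(c(input_dim, hidden1, hidden2,
                                            hidden1, input_dim)),
                 eta = eta, lambda = lambda, beta = beta, rho = rho,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 sparsity_layers = sparsity_layers),
            class = "ae_config")
}

#' @export
print.ae_config <- function(x, ...) {
  cat("<ae_config> layers ", paste(x$layer_sizes, collapse = "-"),
      ", eta ", x$eta, ", lambda ", x$lambda, ", beta ", x$beta,
      ", rho ", x$rho, ", ", x$epochs, " epochs\n", sep = "")
  invisible(x)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Initialize an untrained autoencoder
#'
#' Glorot-style seeded uniform weight init (biases start at zero). Called
#' by [ae_train()]; exposed for building toy models and for gradient
#' checking. Uses the current RNG state; seed it with `set.seed()` or go
#' through [ae_train()] for the config-seeded path.
#'
#' @param config An [ae_config()].
#' @return An untrained `ae_model`.
#' @export
ae_init <- function(config) {
  ls <- config$layer_sizes
  W <- vector("list", length(ls) - 1L)
  b <- vector("list", length(ls) - 1L)
  for (l in seq_along(W)) {
    lim <- sqrt(6 / (ls[l] + ls[l + 1L]))
    W[[l]] <- matrix(stats::runif(ls[l] * ls[l + 1L], -lim, lim),
                     ls[l], ls[l + 1L])
    b[[l]] <- numeric(ls[l + 1L])
  }
  structure(list(W = W, b = b, config = config,
                 training_history = numeric()),
            class = "ae_model")
}

#' @export
print.ae_model <- function(x, ...) {
  cat("<ae_model> layers ", paste(x$config$layer_sizes, collapse = "-"), sep = "")
  if (length(x$training_history))
    cat(", trained ", length(x$training_history), " epochs, final loss ",
        signif(utils::tail(x$training_history, 1L), 6), sep = "")
  cat("\n")
  invisible(x)
}

as_input_matrix <- function(data) {
  if (inherits(data, "spectrum_matrix")) data$values
  else if (is.matrix(data)) data
  else stop("expected a spectrum_matrix or a numeric matrix")
}

#' Forward pass through the autoencoder
#'
#' All hidden layers and the output layer use the logistic sigmoid, so the
#' latent code and the reconstruction both lie in (0, 1), matching the
#' base-peak-normalized input range.
#'
#' @param model An `ae_model`.
#' @param batch A `spectrum_matrix` or numeric matrix whose column count
#'   equals the input layer size.
#' @return A list with `activations` (per-layer matrices, input first),
#'   `latent` (bottleneck activations) and `reconstruction`.
#' @export
ae_forward <- function(model, batch) {
  X <- as_input_matrix(batch)
  ls <- model$config$layer_sizes
  if (ncol(X) != ls[1L])
    stop("input has ", ncol(X), " columns but the model expects ", ls[1L])
  A <- vector("list", length(ls))
  A[[1L]] <- X
  for (l in seq_along(model$W))
    A[[l + 1L]] <- sigmoid(sweep(A[[l]] %*% model$W[[l]], 2L,
                                 model$b[[l]], "+"))
  bottleneck <- (length(ls) + 1L) %/% 2L
  list(activations = A, latent = A[[bottleneck]],
       reconstruction = A[[length(ls)]])
}

kl_bernoulli <- function(rho, rhohat) {
  eps <- 1e-12
  clamped <- pmin(pmax(rhohat, eps), 1 - eps)
  if (any(rhohat <= 0 | rhohat >= 1))
    warning("mean activation at 0 or 1 clamped to [1e-12, 1 - 1e-12] ",
            "in the sparsity penalty")
  sum(rho * log(rho / clamped) + (1 - rho) * log((1 - rho) / (1 - clamped)))
}

sparsity_layer_indices <- function(config) {
  n_layers <- length(config$layer_sizes)
  bottleneck <- (n_layers + 1L) %/% 2L
  if (config$sparsity_layers == "bottleneck") bottleneck
  else setdiff(seq_len(n_layers), c(1L, n_layers))
}

#' Autoencoder cost and its decomposition
#'
#' Total cost = mean-over-samples summed-over-channels squared
#' reconstruction error + (lambda/2) x sum of squared weights and biases +
#' beta x KL sparsity penalty on the mean activations of the penalized
#' hidden layer(s). Each part is nonnegative and the total is their sum.
#'
#' @param model An `ae_model`.
#' @param batch Input matrix or `spectrum_matrix`.
#' @param fwd Optional result of [ae_forward()] on `batch` (recomputed if
#'   missing).
#' @return A list with `total`, `reconstruction`, `l2` and `sparsity`
#'   (the latter two already scaled by lambda and beta).
#' @export
ae_loss <- function(model, batch, fwd = NULL) {
  X <- as_input_matrix(batch)
  if (is.null(fwd)) fwd <- ae_forward(model, X)
  cfg <- model$config
  n <- nrow(X)
  recon <- sum((fwd$reconstruction - X)^2) / n
  l2 <- cfg$lambda / 2 *
    (sum(vapply(model$W, function(w) sum(w^2), numeric(1))) +
     sum(vapply(model$b, function(v) sum(v^2), numeric(1))))
  sparsity <- 0
  if (cfg$beta > 0) {
    for (li in sparsity_layer_indices(cfg)) {
      rhohat <- colMeans(fwd$activations[[li]])
      sparsity <- sparsity + kl_bernoulli(cfg$rho, rhohat)
    }
    sparsity <- cfg$beta * sparsity
  }
  list(total = recon + l2 + sparsity,
       reconstruction = recon, l2 = l2, sparsity = sparsity)
}

#' Analytic gradient of the autoencoder cost
#'
#' Backpropagation through the sigmoid layers, including the L2 term (on
#' weights and biases) and the KL sparsity term on the penalized layer(s).
#' Exposed so the gradient can be checked against finite differences.
#'
#' @param model An `ae_model`.
#' @param batch Input matrix or `spectrum_matrix`.
#' @return A list with per-layer gradient lists `W` and `b`.
#' @export
ae_gradient <- function(model, batch) {
  X <- as_input_matrix(batch)
  fwd <- ae_forward(model, X)
  cfg <- model$config
  A <- fwd$activations
  n <- nrow(X)
  n_weights <- length(model$W)
  sp_layers <- if (cfg$beta > 0) sparsity_layer_indices(cfg) else integer()
  gW <- vector("list", n_weights)
  gb <- vector("list", n_weights)
  # delta at the output layer: d(recon)/dA * sigmoid'
  delta <- (2 / n) * (fwd$reconstruction - X) *
    fwd$reconstruction * (1 - fwd$reconstruction)
  for (l in n_weights:1) {
    gW[[l]] <- crossprod(A[[l]], delta) + cfg$lambda * model$W[[l]]
    gb[[l]] <- colSums(delta) + cfg$lambda * model$b[[l]]
    if (l > 1L) {
      upstream <- delta %*% t(model$W[[l]])
      if (l %in% sp_layers) {
        rhohat <- colMeans(A[[l]])
        eps <- 1e-12
        rhohat <- pmin(pmax(rhohat, eps), 1 - eps)
        kl_grad <- (-cfg$rho / rhohat + (1 - cfg$rho) / (1 - rhohat)) / n
        upstream <- upstream +
          cfg$beta * matrix(kl_grad, n, length(kl_grad), byrow = TRUE)
      }
      delta <- upstream * A[[l]] * (1 - A[[l]])
    }
  }
  list(W = gW, b = gb)
}

#' Train the autoencoder
#'
#' Mini-batch gradient descent with a fixed learning rate. The per-epoch
#' full-data cost is recorded in `training_history`. Training is fully
#' deterministic given `config$seed`.
#'
#' @param config An [ae_config()].
#' @param data A `spectrum_matrix` or numeric matrix (N >= 2 rows).
#' @return A trained `ae_model`.
#' @export
ae_train <- function(config, data) {
  stopifnot(inherits(config, "ae_config"))
  X <- as_input_matrix(data)
  if (nrow(X) < 2L) stop("need at least 2 training samples")
  if (ncol(X) != config$layer_sizes[1L])
    stop("data has ", ncol(X), " channels but config expects ",
         config$layer_sizes[1L])
  set.seed(config$seed)
  model <- ae_init(config)
  n <- nrow(X)
  bs <- min(config$batch_size, n)
  history <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    for (start in seq(1L, n, by = bs)) {
      idx <- perm[start:min(start + bs - 1L, n)]
      g <- ae_gradient(model, X[idx, , drop = FALSE])
      for (l in seq_along(model$W)) {
        model$W[[l]] <- model$W[[l]] - config$eta * g$W[[l]]
        model$b[[l]] <- model$b[[l]] - config$eta * g$b[[l]]
      }
    }
    history[epoch] <- ae_loss(model, X)$total
    if (!is.finite(history[epoch]))
      stop("non-finite training loss at epoch ", epoch,
           "; reduce the learning rate")
  }
  model$training_history <- history
  model
}

#' Encode spectra to the latent space
#'
#' @param model A trained `ae_model`.
#' @param data A `spectrum_matrix` or numeric matrix.
#' @return An object of class `latent_matrix`: `molecule_ids` plus an
#'   N x bottleneck `values` matrix of bottleneck activations.
#' @export
ae_encode <- function(model, data) {
  X <- as_input_matrix(data)
  ids <- if (inherits(data, "spectrum_matrix")) data$molecule_ids
         else rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  latent <- ae_forward(model, X)$latent
  rownames(latent) <- ids
  structure(list(molecule_ids = ids, values = latent),
            class = "latent_matrix")
}

#' @export
print.latent_matrix <- function(x, ...) {
  cat("<latent_matrix> ", length(x$molecule_ids), " molecules x ",
      ncol(x$values), " latent dimensions\n", sep = "")
  invisible(x)
}

# Per-sample summed squared reconstruction error, averaged over samples;
# the regularization terms are deliberately excluded from this metric.
ae_reconstruction_error <- function(model, data) {
  X <- as_input_matrix(data)
  sum((ae_forward(model, X)$reconstruction - X)^2) / nrow(X)
}

#' K-fold cross-validated reconstruction error
#'
#' Splits the data into `folds` disjoint parts by a seeded shuffle, trains
#' on all but one fold and scores the held-out fold by mean per-sample
#' summed squared reconstruction error (regularization excluded from the
#' metric). The conventional protocol uses five folds: four for training,
#' one for evaluation.
#'
#' @param config An [ae_config()].
#' @param data `spectrum_matrix` or matrix with at least `folds` rows.
#' @param folds Number of folds (default 5).
#' @return A list with `fold_errors` (length `folds`), `mean_error`, and
#'   `fold_of` (the fold index assigned to each row).
#' @export
ae_cross_validate <- function(config, data, folds = 5L) {
  stopifnot(inherits(config, "ae_config"), folds >= 2L)
  X <- as_input_matrix(data)
  n <- nrow(X)
  if (n < folds) stop("need at least ", folds, " samples for ", folds,
                      "-fold CV")
  set.seed(config$seed)
  fold_of <- sample(rep_len(seq_len(folds), n))
  fold_errors <- numeric(folds)
  for (f in seq_len(folds)) {
    train_cfg <- config
    train_cfg$seed <- config$seed + f  # distinct init per fold
    m <- ae_train(train_cfg, X[fold_of != f, , drop = FALSE])
    fold_errors[f] <- ae_reconstruction_error(m, X[fold_of == f, ,
                                                   drop = FALSE])
  }
  list(fold_errors = fold_errors, mean_error = mean(fold_errors),
       fold_of = fold_of)
}

#' Rank candidate configurations by cross-validated error
#'
#' @param configs List of [ae_config()] objects.
#' @param data `spectrum_matrix` or matrix.
#' @param folds Number of CV folds (default 5).
#' @return A data.frame with one row per config, ranked by `cv_error`
#'   ascending; ties broken by smaller bottleneck then listing order.
#'   The `config` column is a list column of the original objects.
#' @export
ae_grid_search <- function(configs, data, folds = 5L) {
  stopifnot(is.list(configs), length(configs) >= 1L)
  errs <- vapply(configs, function(cfg)
    ae_cross_validate(cfg, data, folds)$mean_error, numeric(1))
  bottleneck <- vapply(configs, function(cfg)
    cfg$layer_sizes[(length(cfg$layer_sizes) + 1L) %/% 2L], integer(1))
  ord <- order(errs, bottleneck, seq_along(configs))
  out <- data.frame(rank = seq_along(configs),
                    hidden1 = vapply(configs, function(cfg)
                      cfg$layer_sizes[2L], integer(1))[ord],
                    hidden2 = bottleneck[ord],
                    eta = vapply(configs, `[[`, numeric(1), "eta")[ord],
                    lambda = vapply(configs, `[[`, numeric(1), "lambda")[ord],
                    beta = vapply(configs, `[[`, numeric(1), "beta")[ord],
                    cv_error = errs[ord])
  out$config <- configs[ord]
  out
}

#' Read an autoencoder configuration from a YAML file
#'
#' Recognized keys: `hidden1`, `hidden2`, `eta`, `lambda`, `beta`, `rho`,
#' `epochs`, `batch_size`, `seed`, `input_dim`, `sparsity_layers`; missing
#' keys take the [ae_config()] defaults.
#'
#' @param path Path to a YAML file.
#' @return An `ae_config`.
#' @export
read_ae_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(ae_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown autoencoder config keys: ",
                        paste(bad, collapse = ", "))
  do.call(ae_config, vals)
}

#' Save / load a model or grid checkpoint
#'
#' Checkpoints are self-describing single-object files (weights, config
#' and seed for models; codebook and config for maps) with exact
#' round-trip.
#'
#' @param object An `ae_model`, `som_grid`, or any serializable object.
#' @param path Checkpoint path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the stored object.
#' @export
save_checkpoint <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  readRDS(path)
}
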