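# Self-organizing map on the autoencoder latent codes: hexagonal lattice,
# Gaussian neighborhood, sample-wise competitive updates.
#
# Lattice geometry: neurons are stored in row-major order (row = V, column
# = H, both 0-based). Hexagon centers use odd-row offset coordinates,
#   x = H + 0.5 * (V %% 2),   y = V * sqrt(3) / 2,
# so the 6 neighbors of an interior neuron are at planar distance exactly 1.

#' SOM configuration
#'
#' Defaults mirror the reference training conditions: a 30 x 20 hexagonal
#' map, Gaussian neighborhood of radius 1, 500 iterations, learning rate
#' 0.5. One iteration draws one random sample and updates the whole
#' codebook toward it.
#'
#' @param width,height Lattice dimensions (defaults 30 and 20).
#' @param topology `"hexagonal"` (default) or `"rectangular"`.
#' @param sigma Gaussian neighborhood radius in planar lattice units
#'   (default 1).
#' @param iterations Number of single-sample updates (default 500).
#' @param alpha Initial learning rate (default 0.5).
#' @param decay `"asymptotic"` (default): alpha and sigma decay as
#'   `a0 / (1 + t / (T/2))` over iterations t = 0..T-1; `"none"` keeps
#'   both fixed.
#' @param seed Integer seed for codebook init and sample draws.
#' @return An object of class `som_config`.
#' @export
som_config <- function(width = 30L, height = 20L,
                       topology = c("hexagonal", "rectangular"),
                       sigma = 1, iterations = 500L, alpha = 0.5,
                       decay = c("asymptotic", "none"), seed = 1L) {
  topology <- match.arg(topology)
  decay <- match.arg(decay)
  stopifnot(width >= 1L, height >= 1L, width * height >= 2L,
            sigma > 0, iterations >= 1L, alpha > 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 topology = topology, neighborhood = "gaussian",
                 sigma = sigma, iterations = as.integer(iterations),
                 alpha = alpha, decay = decay, seed = as.integer(seed)),
            class = "som_config")
}

#' Planar coordinates of the lattice neuron centers
#'
#' @param config A `som_config` (only width/height/topology are used).
#' @return A (width x height) x 2 matrix of planar `x`, `y` hexagon (or
#'   square) center coordinates in row-major neuron order; attributes
#'   `H` and `V` give the integer lattice coordinates of each neuron.
#' @export
som_positions <- function(config) {
  H <- rep(seq_len(config$width) - 1L, times = config$height)
  V <- rep(seq_len(config$height) - 1L, each = config$width)
  if (config$topology == "hexagonal") {
    x <- H + 0.5 * (V %% 2L)
    y <- V * sqrt(3) / 2
  } else {
    x <- as.numeric(H)
    y <- as.numeric(V)
  }
  pos <- cbind(x = x, y = y)
  attr(pos, "H") <- H
  attr(pos, "V") <- V
  pos
}

unit_index <- function(config, H, V) V * config$width + H + 1L

#' @export
print.som_grid <- function(x, ...) {
  cat("<som_grid> ", x$config$width, " x ", x$config$height, " ",
      x$config$topology, " lattice, codebook dimension ", ncol(x$codebook),
      "\n", sep = "")
  invisible(x)
}

as_latent_values <- function(data) {
  if (inherits(data, "latent_matrix")) data$values
  else if (inherits(data, "spectrum_matrix")) data$values
  else if (is.matrix(data)) data
  else stop("expected a latent_matrix, spectrum_matrix or numeric matrix")
}

#' Best matching unit for one vector
#'
#' The neuron whose codebook vector has the smallest Euclidean distance to
#' the query (the winner node). Exact ties are broken by the smallest
#' row-major linear index.
#'
#' @param grid A `som_grid`.
#' @param vector Numeric vector matching the codebook dimension.
#' @return Named integer vector `c(H = , V = )`, 0-based lattice
#'   coordinates.
#' @export
find_bmu <- function(grid, vector) {
  stopifnot(inherits(grid, "som_grid"))
  if (length(vector) != ncol(grid$codebook))
    stop("query has length ", length(vector), " but the codebook dimension is ",
         ncol(grid$codebook))
  if (any(!is.finite(vector))) stop("non-finite query vector")
  d2 <- rowSums(sweep(grid$codebook, 2L, vector, "-")^2)
  i <- which.min(d2)  # first minimum = smallest row-major index
  c(H = (i - 1L) %% grid$config$width,
    V = (i - 1L) %/% grid$config$width)
}

#' BMU assignments for a whole dataset
#'
#' @param grid A `som_grid`.
#' @param data A `latent_matrix` or numeric matrix.
#' @return An object of class `bmu_assignment`: a data.frame with columns
#'   `molecule_id`, `H`, `V`, `distance` (Euclidean distance to the BMU),
#'   carrying the grid width/height as attributes.
#' @export
bmu_assignments <- function(grid, data) {
  X <- as_latent_values(data)
  ids <- if (inherits(data, "latent_matrix")) data$molecule_ids
         else if (!is.null(rownames(X))) rownames(X)
         else as.character(seq_len(nrow(X)))
  # all pairwise squared distances at once: |x|^2 - 2 x.c + |c|^2
  cb <- grid$codebook
  d2 <- outer(rowSums(X^2), rowSums(cb^2), "+") - 2 * X %*% t(cb)
  d2[d2 < 0] <- 0
  best <- apply(d2, 1L, which.min)
  # recompute the winning distance by direct subtraction: the expanded
  # form loses exactness to cancellation when a sample sits on its BMU
  dist <- sqrt(rowSums((X - cb[best, , drop = FALSE])^2))
  out <- data.frame(molecule_id = ids,
                    H = (best - 1L) %% grid$config$width,
                    V = (best - 1L) %/% grid$config$width,
                    distance = dist,
                    stringsAsFactors = FALSE)
  attr(out, "width") <- grid$config$width
  attr(out, "height") <- grid$config$height
  class(out) <- c("bmu_assignment", "data.frame")
  out
}

#' Gaussian neighborhood weights around a neuron
#'
#' `h(u) = exp(-d^2(u, bmu) / (2 sigma^2))` with `d` the Euclidean
#' distance between hexagon-center planar positions, so `h(bmu) = 1` and
#' at radius 1 every lattice neighbor of an interior neuron gets
#' `exp(-1/2)`.
#'
#' @param grid A `som_grid`.
#' @param bmu `c(H, V)` 0-based lattice coordinates.
#' @param sigma Positive neighborhood radius.
#' @return Numeric vector of weights in (0, 1], one per neuron in
#'   row-major order.
#' @export
neighborhood_weights <- function(grid, bmu, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  cfg <- grid$config
  H <- as.integer(bmu[[1L]]); V <- as.integer(bmu[[2L]])
  if (H < 0L || H >= cfg$width || V < 0L || V >= cfg$height)
    stop("BMU (", H, ",", V, ") outside the ", cfg$width, "x", cfg$height,
         " lattice")
  center <- grid$positions[unit_index(cfg, H, V), ]
  d2 <- (grid$positions[, 1L] - center[1L])^2 +
        (grid$positions[, 2L] - center[2L])^2
  exp(-d2 / (2 * sigma^2))
}

#' Train a self-organizing map
#'
#' Codebook vectors are initialized uniformly at random within each data
#' dimension's range, then updated by `iterations` single-sample draws:
#' each draw finds its BMU and moves every codebook vector toward the
#' sample by `alpha(t) * h(u)`. With `decay = "asymptotic"` both the
#' learning rate and the radius shrink as `a0 / (1 + t / (T/2))`.
#' Fully deterministic given `config$seed`.
#'
#' @param config A [som_config()].
#' @param data A `latent_matrix` or numeric matrix (N >= 1 rows).
#' @return An object of class `som_grid` with the trained `codebook`
#'   ((width x height) x d, row-major), neuron `positions`, and `config`.
#' @export
som_train <- function(config, data) {
  stopifnot(inherits(config, "som_config"))
  X <- as_latent_values(data)
  if (nrow(X) == 0L) stop("empty training data")
  set.seed(config$seed)
  n_units <- config$width * config$height
  d <- ncol(X)
  lo <- apply(X, 2L, min); hi <- apply(X, 2L, max)
  codebook <- matrix(stats::runif(n_units * d), n_units, d)
  codebook <- sweep(sweep(codebook, 2L, hi - lo, "*"), 2L, lo, "+")
  grid <- structure(list(config = config, codebook = codebook,
                         positions = som_positions(config)),
                    class = "som_grid")
  draws <- sample.int(nrow(X), config$iterations, replace = TRUE)
  T_half <- config$iterations / 2
  for (t in seq_len(config$iterations)) {
    x <- X[draws[t], ]
    fac <- if (config$decay == "asymptotic") 1 / (1 + (t - 1) / T_half) else 1
    alpha_t <- config$alpha * fac
    sigma_t <- config$sigma * fac
    h <- neighborhood_weights(grid, find_bmu(grid, x), sigma_t)
    delta <- sweep(-grid$codebook, 2L, x, "+")  # x - codebook, row-wise
    grid$codebook <- grid$codebook + (alpha_t * h) * delta
  }
  grid
}

#' Quantization error of a map
#'
#' Mean over samples of the Euclidean distance from each sample to its
#' BMU's codebook vector; the standard goodness-of-fit metric used to
#' choose the map size.
#'
#' @param grid A `som_grid`.
#' @param data A `latent_matrix` or numeric matrix.
#' @return Nonnegative scalar.
#' @export
quantization_error <- function(grid, data) {
  X <- as_latent_values(data)
  if (nrow(X) == 0L) stop("empty data")
  mean(bmu_assignments(grid, X)$distance)
}

# row-major indices of the lattice neighbors of each neuron: all units at
# planar center distance 1 (6 for interior hexagonal units, 4 for
# rectangular, fewer at edges).
lattice_neighbors <- function(grid) {
  pos <- grid$positions
  n <- nrow(pos)
  lapply(seq_len(n), function(i) {
    d2 <- (pos[, 1L] - pos[i, 1L])^2 + (pos[, 2L] - pos[i, 2L])^2
    which(d2 > 1e-12 & d2 < 1 + 1e-9)
  })
}

#' Unified-distance matrix of a trained map
#'
#' For each neuron, the mean Euclidean codebook distance to its lattice
#' neighbors (6 for an interior hexagonal neuron, fewer at edges). High
#' values mark cluster boundaries.
#'
#' @param grid A `som_grid`.
#' @return Numeric vector, one nonnegative value per neuron in row-major
#'   order, with attribute `neighbor_counts`.
#' @export
u_matrix <- function(grid) {
  stopifnot(inherits(grid, "som_grid"))
  nb <- lattice_neighbors(grid)
  vals <- vapply(seq_along(nb), function(i) {
    if (length(nb[[i]]) == 0L) return(0)
    diffs <- sweep(grid$codebook[nb[[i]], , drop = FALSE], 2L,
                   grid$codebook[i, ], "-")
    mean(sqrt(rowSums(diffs^2)))
  }, numeric(1))
  attr(vals, "neighbor_counts") <- lengths(nb)
  vals
}

#' Scan candidate map sizes by quantization error
#'
#' Trains one seeded SOM per size and reports its quantization error and
#' the number of empty neurons (units that are no molecule's BMU). Larger
#' maps reduce QE but strand more blank lattice units; the working size is
#' chosen by balancing the two.
#'
#' @param data A `latent_matrix` or numeric matrix.
#' @param sizes List of `c(width, height)` pairs.
#' @param config Template [som_config()]; width/height are overridden per
#'   size.
#' @return A data.frame with columns `width`, `height`, `units`, `qe`,
#'   `empty_neurons`.
#' @export
map_size_scan <- function(data, sizes, config = som_config()) {
  stopifnot(length(sizes) >= 1L)
  rows <- lapply(sizes, function(sz) {
    cfg <- config
    cfg$width <- as.integer(sz[[1L]]); cfg$height <- as.integer(sz[[2L]])
    grid <- som_train(cfg, data)
    asg <- bmu_assignments(grid, data)
    occupied <- unique(unit_index(cfg, asg$H, asg$V))
    data.frame(width = cfg$width, height = cfg$height,
               units = cfg$width * cfg$height,
               qe = quantization_error(grid, data),
               empty_neurons = cfg$width * cfg$height - length(occupied))
  })
  do.call(rbind, rows)
}

#' Write BMU assignments to CSV
#'
#' @param assignments A `bmu_assignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignments_csv <- function(assignments, path) {
  stopifnot(inherits(assignments, "bmu_assignment"))
  utils::write.csv(as.data.frame(assignments), path, row.names = FALSE)
  invisible(path)
}
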