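# Sparse autoencoder: forward pass, cost decomposition, gradients,
# training, cross-validation and grid search.

test_that("ae_config builds the symmetric 5-layer architecture", {
  cfg <- ae_config()
  expect_equal(cfg$layer_sizes, c(212L, 90L, 50L, 90L, 212L))
  expect_error(ae_config(input_dim = 10, hidden2 = 10), "hidden2")
  expect_error(ae_config(rho = 0), "rho")
})

test_that("forward pass is a sigmoid chain with the bottleneck as latent", {
  model <- toy_ae_model()
  # zero weights and biases: every activation is sigmoid(0) = 0.5
  zero <- ae_set_params_flat(model, rep(0, length(ae_params_flat(model))))
  X <- matrix(runif(18), 3, 6)
  fz <- ae_forward(zero, X)
  expect_true(all(fz$reconstruction == 0.5))
  expect_true(all(fz$latent == 0.5))

  # purity: repeated calls identical
  f1 <- ae_forward(model, X); f2 <- ae_forward(model, X)
  expect_identical(f1$reconstruction, f2$reconstruction)

  # independent hand-rolled sigmoid chain oracle
  sig <- function(z) 1 / (1 + exp(-z))
  a <- X[1, , drop = FALSE]
  for (l in seq_along(model$W))
    a <- sig(a %*% model$W[[l]] + matrix(model$b[[l]], 1))
  expect_equal(unname(f1$reconstruction[1, ]), unname(a[1, ]),
               tolerance = 1e-12)
  expect_true(all(f1$reconstruction > 0 & f1$reconstruction < 1))
  expect_error(ae_forward(model, matrix(0.5, 2, 5)), "columns")
})

test_that("cost decomposes into reconstruction + L2 + sparsity parts", {
  model <- toy_ae_model(lambda = 0.02, beta = 0.7, rho = 0.08)
  X <- matrix(runif(5 * 6), 5, 6)
  parts <- ae_loss(model, X)
  expect_gte(parts$reconstruction, 0)
  expect_gte(parts$l2, 0)
  expect_gte(parts$sparsity, 0)
  expect_equal(parts$total,
               parts$reconstruction + parts$l2 + parts$sparsity,
               tolerance = 1e-10)

  # lambda = beta = 0 reduces to plain mean summed squared error
  plain <- toy_ae_model(lambda = 0, beta = 0)
  fw <- ae_forward(plain, X)
  expect_equal(ae_loss(plain, X)$total,
               sum((fw$reconstruction - X)^2) / nrow(X),
               tolerance = 1e-12)

  # L2 part equals the closed form over weights AND biases
  expect_equal(parts$l2,
               0.02 / 2 * (sum(unlist(model$W)^2) + sum(unlist(model$b)^2)),
               tolerance = 1e-12)
})

test_that("sparsity part matches the scalar KL oracle and vanishes at rho", {
  # independent Bernoulli-KL oracle at rhohat = (0.1, 0.2), rho = 0.05
  kl <- function(p, q) p * log(p / q) + (1 - p) * log((1 - p) / (1 - q))
  expected <- kl(0.05, 0.1) + kl(0.05, 0.2)
  # craft a model whose bottleneck activations average exactly (0.1, 0.2):
  # one sample, zero weights into the bottleneck, biases = logit(target)
  model <- toy_ae_model(input_dim = 3L, hidden1 = 2L, hidden2 = 2L,
                        lambda = 0, beta = 1, rho = 0.05)
  model <- ae_set_params_flat(model,
                              rep(0, length(ae_params_flat(model))))
  model$b[[2]] <- log(c(0.1, 0.2) / (1 - c(0.1, 0.2)))
  X <- matrix(0.5, 1, 3)
  expect_equal(ae_loss(model, X)$sparsity, expected, tolerance = 1e-10)

  # rhohat == rho gives zero penalty
  model$b[[2]] <- rep(log(0.05 / 0.95), 2)
  expect_equal(ae_loss(model, X)$sparsity, 0, tolerance = 1e-12)
})

test_that("penalty parts are monotone in their coefficients", {
  base <- toy_ae_model(lambda = 0.01, beta = 0.5)
  X <- matrix(runif(4 * 6), 4, 6)
  p1 <- ae_loss(base, X)
  up <- base
  up$config$lambda <- 0.1
  up$config$beta <- 2
  p2 <- ae_loss(up, X)
  expect_gte(p2$l2, p1$l2)
  expect_gte(p2$sparsity, p1$sparsity)
})

test_that("analytic gradients match central finite differences", {
  # seeded toy nets, including the all-hidden sparsity variant
  for (case in list(list(seed = 7L, sp = "bottleneck"),
                    list(seed = 8L, sp = "all_hidden"),
                    list(seed = 9L, sp = "bottleneck"))) {
    model <- toy_ae_model(input_dim = 6L, hidden1 = 4L, hidden2 = 2L,
                          lambda = 0.01, beta = 0.5, rho = 0.1,
                          sparsity_layers = case$sp, seed = case$seed)
    set.seed(case$seed)
    X <- matrix(runif(5 * 6), 5, 6)
    g <- ae_gradient(model, X)
    analytic <- unlist(c(lapply(g$W, as.numeric), lapply(g$b, as.numeric)))
    theta <- ae_params_flat(model)
    h <- 1e-6
    numeric_g <- vapply(seq_along(theta), function(i) {
      tp <- theta; tp[i] <- tp[i] + h
      tm <- theta; tm[i] <- tm[i] - h
      (ae_loss(ae_set_params_flat(model, tp), X)$total -
       ae_loss(ae_set_params_flat(model, tm), X)$total) / (2 * h)
    }, numeric(1))
    rel <- sqrt(sum((analytic - numeric_g)^2)) /
      max(sqrt(sum(analytic^2)), sqrt(sum(numeric_g^2)))
    expect_lt(rel, 1e-5)
  }
})

test_that("training reduces the cost and is deterministic given the seed", {
  data <- window_and_normalize(sample_dataset(tiny_generator())$spectra)
  cfg <- ae_config(hidden1 = 20L, hidden2 = 8L, epochs = 60L, seed = 5L)
  m1 <- ae_train(cfg, data)
  expect_length(m1$training_history, 60L)
  expect_lt(tail(m1$training_history, 1), m1$training_history[1])
  m2 <- ae_train(cfg, data)
  expect_identical(m1$training_history, m2$training_history)
  expect_identical(m1$W, m2$W)
  # training aborts on a divergent configuration rather than returning NaN
  expect_error(
    suppressWarnings(ae_train(ae_config(hidden1 = 4L, hidden2 = 2L,
                                        input_dim = 6L, eta = 1e200,
                                        epochs = 5L),
                              matrix(runif(60), 10, 6))),
    "non-finite.*epoch")
})

test_that("encode returns bottleneck activations with preserved ids", {
  data <- window_and_normalize(sample_dataset(tiny_generator())$spectra)
  cfg <- ae_config(hidden1 = 16L, hidden2 = 6L, epochs = 15L, seed = 2L)
  model <- ae_train(cfg, data)
  lat <- ae_encode(model, data)
  expect_equal(dim(lat$values), c(length(data$molecule_ids), 6L))
  expect_identical(lat$molecule_ids, data$molecule_ids)
  expect_identical(lat$values, ae_encode(model, data)$values)
  # consistency with the forward pass's bottleneck slice
  expect_equal(unname(lat$values),
               unname(ae_forward(model, data)$latent))
})

test_that("cross-validation partitions the data and matches a manual loop", {
  set.seed(1)
  X <- matrix(runif(10 * 6), 10, 6)
  cfg <- ae_config(input_dim = 6L, hidden1 = 4L, hidden2 = 2L,
                   epochs = 10L, seed = 3L)
  cv <- ae_cross_validate(cfg, X, folds = 5L)
  expect_length(cv$fold_errors, 5L)
  expect_equal(as.vector(table(cv$fold_of)), rep(2L, 5L))  # disjoint, size 2
  expect_equal(cv$mean_error, mean(cv$fold_errors))

  # re-implementation oracle: same split, direct train + evaluate calls
  manual <- vapply(1:5, function(f) {
    tc <- cfg; tc$seed <- cfg$seed + f
    m <- ae_train(tc, X[cv$fold_of != f, , drop = FALSE])
    Xi <- X[cv$fold_of == f, , drop = FALSE]
    sum((ae_forward(m, Xi)$reconstruction - Xi)^2) / nrow(Xi)
  }, numeric(1))
  expect_equal(cv$fold_errors, manual, tolerance = 1e-12)
  expect_error(ae_cross_validate(cfg, X[1:3, ], folds = 5L), "at least")
})

test_that("duplicated samples close the generalization gap", {
  set.seed(4)
  row <- runif(6)
  X <- matrix(rep(row, 12), 12, 6, byrow = TRUE)
  cfg <- ae_config(input_dim = 6L, hidden1 = 4L, hidden2 = 2L,
                   epochs = 300L, eta = 0.5, lambda = 0, beta = 0,
                   seed = 6L)
  cv <- ae_cross_validate(cfg, X, folds = 3L)
  m <- ae_train(cfg, X)
  train_err <- sum((ae_forward(m, X)$reconstruction - X)^2) / nrow(X)
  expect_lt(abs(cv$mean_error - train_err), 0.05)
})

test_that("grid search ranks configs by CV error with stable tie-breaks", {
  set.seed(2)
  X <- matrix(runif(12 * 6), 12, 6)
  sane <- ae_config(input_dim = 6L, hidden1 = 4L, hidden2 = 2L,
                    epochs = 20L, seed = 1L)
  corrupt <- sane
  corrupt$eta <- 50           # diverging learning rate
  ranked <- ae_grid_search(list(corrupt, sane), X, folds = 3L)
  expect_equal(ranked$cv_error, sort(ranked$cv_error))
  expect_equal(ranked$eta[1], sane$eta)

  single <- ae_grid_search(list(sane), X, folds = 3L)
  expect_equal(nrow(single), 1L)
  expect_equal(single$rank, 1L)

  # ranking equals a sort of independently collected CV errors
  errs <- vapply(list(corrupt, sane), function(cfg)
    ae_cross_validate(cfg, X, folds = 3L)$mean_error, numeric(1))
  expect_equal(ranked$cv_error, sort(errs), tolerance = 1e-12)
})

test_that("latent codes separate archetypes better than chance", {
  # parameter-recovery property: same-archetype pairs closer in latent
  # space than cross-archetype pairs
  ds <- sample_dataset(tiny_generator(seed = 9L, n_molecules = 60L,
                                      n_archetypes = 6L))
  data <- window_and_normalize(ds$spectra)
  cfg <- ae_config(hidden1 = 24L, hidden2 = 8L, epochs = 120L, seed = 10L)
  lat <- ae_encode(ae_train(cfg, data), data)
  arch <- ds$truth$archetype_id[match(lat$molecule_ids,
                                      ds$truth$molecule_id)]
  D <- as.matrix(dist(lat$values))
  same <- outer(arch, arch, "==") & upper.tri(D)
  diff <- outer(arch, arch, "!=") & upper.tri(D)
  expect_lt(mean(D[same]), mean(D[diff]))
})

test_that("config YAML and model checkpoints round-trip", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(hidden1 = 30, hidden2 = 10, eta = 0.05,
                        lambda = 0.001, beta = 2, epochs = 50,
                        seed = 4), path)
  cfg <- read_ae_config(path)
  expect_equal(cfg$layer_sizes, c(212L, 30L, 10L, 30L, 212L))
  expect_equal(cfg$eta, 0.05)
  expect_equal(cfg$rho, 0.05)  # default fills in

  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(hidden1 = 30, learnrate = 1), bad)
  expect_error(read_ae_config(bad), "unknown")

  model <- toy_ae_model()
  ck <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, ck)
  expect_identical(load_checkpoint(ck), model)
})
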