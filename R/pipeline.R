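# Staged pipeline wiring: preprocess -> autoencoder -> SOM -> lattice
# labels, with checkpointed artifacts and a single top-level seed fanned
# out deterministically to every stochastic stage.

#' Pipeline configuration
#'
#' Bundles the stage configurations and file paths for an end-to-end run.
#' A single top-level `seed` is fanned out to the autoencoder (`seed + 1`)
#' and the SOM (`seed + 2`) so one integer reproduces the whole run.
#'
#' @param spectra_path MSP file of input spectra.
#' @param descriptors_path Descriptor CSV (either dialect).
#' @param out_dir Output/checkpoint directory.
#' @param window Length-2 integer m/z window (default `c(51, 262)`).
#' @param ae An [ae_config()] (its seed is overridden by `seed`).
#' @param som A [som_config()] (its seed is overridden by `seed`).
#' @param exclude_descriptors Labels to drop when labeling the lattice.
#' @param cv_folds Cross-validation folds for the reported reconstruction
#'   error; 0 skips CV (default 0, since CV retrains the model per fold).
#' @param seed Top-level integer seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(spectra_path, descriptors_path, out_dir,
                            window = c(51L, 262L),
                            ae = ae_config(), som = som_config(),
                            exclude_descriptors = character(),
                            cv_folds = 0L, seed = 1L) {
  stopifnot(length(window) == 2L, window[1L] < window[2L],
            inherits(ae, "ae_config"), inherits(som, "som_config"),
            cv_folds == 0L || cv_folds >= 2L)
  ae$seed <- as.integer(seed + 1L)
  som$seed <- as.integer(seed + 2L)
  structure(list(spectra_path = spectra_path,
                 descriptors_path = descriptors_path,
                 out_dir = out_dir, window = as.integer(window),
                 ae = ae, som = som,
                 exclude_descriptors = exclude_descriptors,
                 cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

pipeline_log <- function(verbose, ...) {
  if (verbose) message("[scentmap] ", ...)
}

#' Generate and write a synthetic fixture dataset
#'
#' Wraps [sample_dataset()] and [write_fixture()].
#'
#' @param config A [generator_config()].
#' @param directory Output directory.
#' @return The generated `odor_dataset`, invisibly; files `spectra.msp`,
#'   `descriptors.csv` and `truth.csv` are written to `directory`.
#' @export
run_simulate <- function(config = generator_config(), directory) {
  dataset <- sample_dataset(config)
  write_fixture(dataset, directory)
  invisible(dataset)
}

#' Run the full extraction pipeline
#'
#' Executes window-and-normalize, autoencoder training and encoding, SOM
#' training, BMU assignment and lattice labeling, persisting every stage
#' artifact under `config$out_dir` (`ae_model.rds`, `som_grid.rds`,
#' `assignments.csv`, `labels.csv`, `summary.yaml`). When checkpoints from
#' a previous run exist and `resume = TRUE`, the trained stages are loaded
#' instead of retrained.
#'
#' @param config A [pipeline_config()].
#' @param resume Reuse existing checkpoints when present (default TRUE).
#' @param verbose Emit per-stage log messages (default TRUE).
#' @return An object of class `pipeline_result`: `matrix`
#'   (spectrum_matrix), `model`, `latent`, `grid`, `assignments`,
#'   `labels`, `summary` (named list: n_molecules, n_excluded, cv_error,
#'   final_loss, quantization_error, empty_neurons).
#' @export
run_pipeline <- function(config, resume = TRUE, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  ckpt <- function(f) file.path(config$out_dir, f)

  pipeline_log(verbose, "stage preprocess: reading ", config$spectra_path)
  spectra <- read_msp(config$spectra_path)
  table <- read_descriptor_csv(config$descriptors_path)
  mat <- window_and_normalize(spectra, config$window[1L], config$window[2L])
  pipeline_log(verbose, "stage preprocess: N = ", length(mat$molecule_ids),
               " molecules, ", length(mat$channels), " channels, ",
               length(mat$excluded), " excluded")

  cv_error <- NA_real_
  if (config$cv_folds >= 2L) {
    cv <- ae_cross_validate(config$ae, mat, config$cv_folds)
    cv_error <- cv$mean_error
    pipeline_log(verbose, "stage autoencoder: ", config$cv_folds,
                 "-fold CV mean reconstruction error = ",
                 signif(cv_error, 6))
  }

  if (resume && file.exists(ckpt("ae_model.rds"))) {
    model <- load_checkpoint(ckpt("ae_model.rds"))
    pipeline_log(verbose, "stage autoencoder: resumed from checkpoint")
  } else {
    model <- ae_train(config$ae, mat)
    save_checkpoint(model, ckpt("ae_model.rds"))
    pipeline_log(verbose, "stage autoencoder: trained ", config$ae$epochs,
                 " epochs, final loss = ",
                 signif(utils::tail(model$training_history, 1L), 6))
  }
  latent <- ae_encode(model, mat)

  if (resume && file.exists(ckpt("som_grid.rds"))) {
    grid <- load_checkpoint(ckpt("som_grid.rds"))
    pipeline_log(verbose, "stage som: resumed from checkpoint")
  } else {
    grid <- som_train(config$som, latent)
    save_checkpoint(grid, ckpt("som_grid.rds"))
  }
  assignments <- bmu_assignments(grid, latent)
  qe <- quantization_error(grid, latent)
  occupied <- length(unique(paste(assignments$H, assignments$V)))
  empty <- grid$config$width * grid$config$height - occupied
  pipeline_log(verbose, "stage som: quantization error = ", signif(qe, 6),
               ", empty neurons = ", empty)

  labels <- label_lattice(assignments, table,
                          exclude = config$exclude_descriptors)
  write_assignments_csv(assignments, ckpt("assignments.csv"))
  utils::write.csv(lattice_label_table(labels), ckpt("labels.csv"),
                   row.names = FALSE)

  summary <- list(n_molecules = length(mat$molecule_ids),
                  n_excluded = length(mat$excluded),
                  cv_error = cv_error,
                  final_loss = unname(utils::tail(model$training_history,
                                                  1L)),
                  quantization_error = qe,
                  empty_neurons = empty)
  yaml::write_yaml(summary, ckpt("summary.yaml"))
  structure(list(matrix = mat, model = model, latent = latent, grid = grid,
                 assignments = assignments, labels = labels,
                 summary = summary, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> N =", x$summary$n_molecules,
      "| final AE loss", signif(x$summary$final_loss, 5),
      "| QE", signif(x$summary$quantization_error, 5),
      "| empty neurons", x$summary$empty_neurons, "\n")
  invisible(x)
}

#' Query a trained pipeline for a scent impression
#'
#' Supports three query kinds against a [run_pipeline()] result (or a
#' checkpoint directory): a single descriptor, a descriptor pair, or a
#' molecule id. Descriptor queries locate the matching neurons and
#' inverse-map each; molecule queries locate the molecule's BMU and
#' inverse-map it with the molecule itself as the similarity reference
#' (unless another `reference_id` is given).
#'
#' @param pipeline A `pipeline_result`.
#' @param descriptor Single descriptor label, or length-2 character vector
#'   for a pair query.
#' @param molecule_id Molecule identifier (alternative to `descriptor`).
#' @param mode Pair-query mode, see [neurons_for_descriptor_pair()].
#' @param reference_id Optional reference molecule for similarity scores.
#' @return List of `extraction_result` objects (one per matching neuron).
#' @export
run_query <- function(pipeline, descriptor = NULL, molecule_id = NULL,
                      mode = c("both_on_neuron", "both_on_molecule"),
                      reference_id = NULL) {
  stopifnot(inherits(pipeline, "pipeline_result"))
  mode <- match.arg(mode)
  if (is.null(descriptor) == is.null(molecule_id))
    stop("give exactly one of `descriptor` or `molecule_id`")
  labels <- pipeline$labels
  if (!is.null(molecule_id)) {
    neuron <- locate_molecule(labels, molecule_id)
    ref <- if (is.null(reference_id)) molecule_id else reference_id
    return(list(inverse_map(labels, pipeline$latent, neuron,
                            reference_id = ref)))
  }
  coords <- if (length(descriptor) == 1L) {
    neurons_for_descriptor(labels, descriptor)
  } else if (length(descriptor) == 2L) {
    neurons_for_descriptor_pair(labels, descriptor[1L], descriptor[2L],
                                mode = mode)
  } else {
    stop("`descriptor` must have length 1 or 2")
  }
  lapply(seq_len(nrow(coords)), function(i)
    inverse_map(labels, pipeline$latent, coords[i, ],
                reference_id = reference_id))
}

#' Duo-trio panel report
#'
#' Thin wrapper over [duo_trio_test()] for the command line.
#'
#' @inheritParams duo_trio_test
#' @return A `duo_trio_result`, printed.
#' @export
run_duotrio <- function(k, n, p0 = 0.5, alpha = 0.05) {
  print(duo_trio_test(k, n, p0 = p0, alpha = alpha))
}
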