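# Generator of odorant-like datasets: spectra built from "functional-group
# archetype" fragment ladders (homologous CH2 series, step 14 m/z) with
# per-molecule intensity jitter and spurious minor peaks, plus overlapping
# binary odor-descriptor sets per archetype. Emulates the statistical
# structure of an EI spectral library paired with a flavor-descriptor
# database, so the full pipeline is testable without licensed data.

default_descriptor_pool <- function() {
  c("peach", "minty", "vanilla", "spicy", "warm", "coconut", "floral",
    "green", "woody", "citrus", "balsamic", "herbal", "camphoraceous",
    "roast", "honey", "pineapple", "strawberry", "cooling", "smoky",
    "earthy")
}

#' Synthetic odorant dataset configuration
#'
#' @param n_molecules Number of molecules to generate (default 300).
#' @param n_archetypes Number of functional-group archetypes, i.e. ground
#'   truth clusters (default 12).
#' @param mz_lo,mz_hi m/z window of the generated peaks (defaults 51 and
#'   262).
#' @param peaks_per_archetype Peaks in each archetype's fragment ladder
#'   (default 8).
#' @param ladder_step m/z spacing of the ladder (default 14, the CH2
#'   homologous-series increment of EI spectra).
#' @param intensity_jitter Lognormal sigma of per-molecule, per-peak
#'   intensity noise (default 0.3).
#' @param spurious_peak_rate Poisson mean of extra minor peaks per
#'   molecule, each at most 10% of the base peak (default 2).
#' @param descriptor_pool Character vector of available odor descriptors
#'   (default: 20 common flavor labels).
#' @param descriptors_per_archetype Length-2 integer range for the number
#'   of descriptors per archetype (default `c(2, 4)`).
#' @param descriptor_overlap Fraction of an archetype's descriptors shared
#'   with the previous archetype (default 0.25), so descriptor sets
#'   overlap across archetypes as real odorants' do.
#' @param descriptor_dropout Probability each inherited descriptor is
#'   dropped from a molecule's annotation (default 0.1), emulating
#'   annotation sparsity.
#' @param seed Integer seed; the whole dataset is deterministic given it.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_molecules = 300L, n_archetypes = 12L,
                             mz_lo = 51L, mz_hi = 262L,
                             peaks_per_archetype = 8L, ladder_step = 14L,
                             intensity_jitter = 0.3,
                             spurious_peak_rate = 2,
                             descriptor_pool = default_descriptor_pool(),
                             descriptors_per_archetype = c(2L, 4L),
                             descriptor_overlap = 0.25,
                             descriptor_dropout = 0.1,
                             seed = 1L) {
  stopifnot(n_molecules >= 1L, n_archetypes >= 1L,
            n_archetypes <= n_molecules, mz_lo < mz_hi,
            peaks_per_archetype >= 1L, ladder_step >= 1L,
            intensity_jitter >= 0, spurious_peak_rate >= 0,
            length(descriptor_pool) >= 1L,
            length(descriptors_per_archetype) == 2L,
            descriptors_per_archetype[1L] <= descriptors_per_archetype[2L],
            descriptors_per_archetype[2L] <= length(descriptor_pool),
            descriptor_overlap >= 0, descriptor_overlap <= 1,
            descriptor_dropout >= 0, descriptor_dropout < 1)
  structure(list(n_molecules = as.integer(n_molecules),
                 n_archetypes = as.integer(n_archetypes),
                 mz_lo = as.integer(mz_lo), mz_hi = as.integer(mz_hi),
                 peaks_per_archetype = as.integer(peaks_per_archetype),
                 ladder_step = as.integer(ladder_step),
                 intensity_jitter = intensity_jitter,
                 spurious_peak_rate = spurious_peak_rate,
                 descriptor_pool = normalize_descriptors(descriptor_pool),
                 descriptors_per_archetype =
                   as.integer(descriptors_per_archetype),
                 descriptor_overlap = descriptor_overlap,
                 descriptor_dropout = descriptor_dropout,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# archetype construction without seeding, so sample_dataset can share one
# RNG stream with it
make_archetypes_impl <- function(config) {
  step <- config$ladder_step
  p <- config$peaks_per_archetype
  if (config$mz_lo + step > config$mz_hi)
    stop("m/z window [", config$mz_lo, ", ", config$mz_hi,
         "] too small for a ladder of step ", step)
  dr <- config$descriptors_per_archetype
  pool <- config$descriptor_pool
  archetypes <- vector("list", config$n_archetypes)
  used <- character()
  prev_set <- character()
  for (a in seq_len(config$n_archetypes)) {
    base <- sample(config$mz_lo:(config$mz_hi - step), 1L)
    mz <- base + step * (0:(p - 1L))
    mz <- mz[mz <= config$mz_hi]           # ladder clipped to the window
    rel <- 0.7^(seq_along(mz) - 1L) * stats::runif(length(mz), 0.6, 1)
    intensity <- 999 * rel / max(rel)      # NIST-style base peak 999
    k <- if (dr[1L] == dr[2L]) dr[1L] else sample(dr[1L]:dr[2L], 1L)
    n_shared <- min(round(config$descriptor_overlap * k), length(prev_set))
    shared <- if (n_shared > 0)
      sample(prev_set, n_shared) else character()
    fresh_pool <- setdiff(pool, used)      # keeps sets disjoint at overlap 0
    if (length(fresh_pool) < k - n_shared)
      fresh_pool <- setdiff(pool, c(shared, prev_set))
    if (length(fresh_pool) < k - n_shared)
      fresh_pool <- setdiff(pool, shared)
    fresh <- sample(fresh_pool, k - n_shared)
    desc <- sort(c(shared, fresh))
    used <- union(used, desc)
    prev_set <- desc
    archetypes[[a]] <- list(archetype_id = a, mz = mz,
                            intensity = intensity, descriptors = desc)
  }
  archetypes
}

#' Generate the archetype templates
#'
#' Each archetype is a template spectrum — a fragment ladder of
#' `peaks_per_archetype` peaks at `base + k * ladder_step` (clipped to the
#' m/z window) with geometrically decaying intensities — plus a descriptor
#' set drawn from the pool with the configured overlap between archetype
#' `i` and `i + 1`.
#'
#' @param config A [generator_config()].
#' @return List of archetypes, each with fields `archetype_id`, `mz`,
#'   `intensity`, `descriptors`.
#' @export
make_archetypes <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  make_archetypes_impl(config)
}

#' Sample a synthetic odorant dataset
#'
#' Molecules are assigned round-robin to archetypes. Each molecule's
#' spectrum is its archetype template with per-peak lognormal intensity
#' jitter plus a Poisson number of spurious minor peaks (uniform random
#' m/z, intensity at most 10% of the base peak). Each molecule inherits
#' its archetype's descriptors, each independently dropped with the
#' configured dropout probability. Fully deterministic given the seed.
#'
#' @param config A [generator_config()].
#' @return An object of class `odor_dataset`: `spectra` (list of
#'   [mass_spectrum]), `descriptors` (a `descriptor_table`), `truth`
#'   (data.frame `molecule_id`, `archetype_id` — for evaluation only,
#'   never consumed by the pipeline) and `archetypes`.
#' @export
sample_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  archetypes <- make_archetypes_impl(config)
  n <- config$n_molecules
  arch_of <- ((seq_len(n) - 1L) %% config$n_archetypes) + 1L
  ids <- sprintf("MOL%04d", seq_len(n))
  spectra <- vector("list", n)
  desc_sets <- vector("list", n)
  for (i in seq_len(n)) {
    a <- archetypes[[arch_of[i]]]
    intensity <- a$intensity *
      exp(stats::rnorm(length(a$mz), 0, config$intensity_jitter))
    mz <- a$mz
    n_sp <- stats::rpois(1L, config$spurious_peak_rate)
    if (n_sp > 0L) {
      sp_mz <- sample(config$mz_lo:config$mz_hi, n_sp, replace = TRUE)
      sp_int <- stats::runif(n_sp, 0, 0.1) * max(intensity)
      mz <- c(mz, sp_mz)
      intensity <- c(intensity, sp_int)
    }
    keep <- stats::runif(length(a$descriptors)) >= config$descriptor_dropout
    desc_sets[[i]] <- a$descriptors[keep]
    spectra[[i]] <- mass_spectrum(ids[i], mz, intensity,
                                  descriptors = desc_sets[[i]])
  }
  structure(list(spectra = spectra,
                 descriptors = descriptor_table_from_sets(ids, desc_sets),
                 truth = data.frame(molecule_id = ids,
                                    archetype_id = arch_of,
                                    stringsAsFactors = FALSE),
                 archetypes = archetypes),
            class = "odor_dataset")
}

#' @export
print.odor_dataset <- function(x, ...) {
  cat("<odor_dataset> ", length(x$spectra), " molecules from ",
      length(x$archetypes), " archetypes, ",
      length(x$descriptors$descriptor_names), " descriptors\n", sep = "")
  invisible(x)
}

#' Archetype recovery of a labeled lattice
#'
#' Evaluation of the full inverse pipeline against the generator's ground
#' truth: for each archetype, its first descriptor (alphabetical) is
#' queried on the lattice and the query succeeds if at least one matching
#' neuron's members are majority-drawn from that archetype. Consumes
#' `truth` only for scoring — the pipeline itself never sees it.
#'
#' @param dataset The `odor_dataset` the pipeline was run on.
#' @param labels The `lattice_labels` produced by the pipeline.
#' @return A list with `per_archetype` (named logical vector) and
#'   `fraction` (the recovered share).
#' @export
archetype_recovery <- function(dataset, labels) {
  stopifnot(inherits(dataset, "odor_dataset"),
            inherits(labels, "lattice_labels"))
  arch_of <- stats::setNames(dataset$truth$archetype_id,
                             dataset$truth$molecule_id)
  recovered <- vapply(dataset$archetypes, function(a) {
    d <- a$descriptors[1L]
    coords <- suppressWarnings(neurons_for_descriptor(labels, d))
    if (nrow(coords) == 0L) return(FALSE)
    any(vapply(seq_len(nrow(coords)), function(i) {
      n <- labels$neurons[[coords[i, "V"] * labels$width +
                             coords[i, "H"] + 1L]]
      counts <- table(arch_of[n$members])
      a$archetype_id %in% as.integer(names(counts)[counts == max(counts)])
    }, logical(1)))
  }, logical(1))
  names(recovered) <- vapply(dataset$archetypes, function(a)
    a$descriptors[1L], character(1))
  list(per_archetype = recovered, fraction = mean(recovered))
}

#' Write a dataset to fixture files
#'
#' Emits `spectra.msp` (NIST-style MSP), `descriptors.csv` (wide binary
#' dialect) and `truth.csv` (molecule_id, archetype_id; evaluation only)
#' into a directory. Reading the files back through the spectra I/O layer
#' reproduces the dataset.
#'
#' @param dataset An `odor_dataset`.
#' @param directory Output directory (created if missing).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_fixture <- function(dataset, directory) {
  stopifnot(inherits(dataset, "odor_dataset"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  paths <- c(spectra = file.path(directory, "spectra.msp"),
             descriptors = file.path(directory, "descriptors.csv"),
             truth = file.path(directory, "truth.csv"))
  write_msp(dataset$spectra, paths[["spectra"]])
  write_descriptor_csv(dataset$descriptors, paths[["descriptors"]],
                       dialect = "wide")
  utils::write.csv(dataset$truth, paths[["truth"]], row.names = FALSE)
  invisible(paths)
}
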