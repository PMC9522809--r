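# Inverse retrieval: write odor descriptors onto the trained lattice, find
# the neurons matching a desired scent impression, and inverse-map a neuron
# back to the co-clustered molecules and their latent spectra.
#
# Coordinate convention throughout: (H, V) = (column, row), 0-based.

#' Label the lattice with odor descriptors
#'
#' Each neuron's member list holds every molecule whose BMU it is; its
#' label set is the union of its members' descriptor sets. Molecules
#' absent from the descriptor table (or with empty sets) contribute to
#' membership but not to labels.
#'
#' @param assignments A `bmu_assignment` from [bmu_assignments()].
#' @param table A `descriptor_table` (molecules missing from it get empty
#'   descriptor sets).
#' @param exclude Optional character vector of descriptor labels to drop
#'   from all label sets (e.g. over-familiar impressions one does not want
#'   to query on).
#' @return An object of class `lattice_labels`: per-neuron member ids,
#'   per-member descriptor sets and the union label set, plus the lattice
#'   dimensions.
#' @export
label_lattice <- function(assignments, table, exclude = character()) {
  stopifnot(inherits(assignments, "bmu_assignment"),
            inherits(table, "descriptor_table"))
  if (anyDuplicated(assignments$molecule_id))
    stop("duplicate molecule_id in BMU assignments: ",
         paste(unique(assignments$molecule_id[
           duplicated(assignments$molecule_id)]), collapse = ", "))
  exclude <- normalize_descriptors(exclude)
  width <- attr(assignments, "width"); height <- attr(assignments, "height")
  neurons <- vector("list", width * height)
  for (i in seq_along(neurons)) {
    neurons[[i]] <- list(H = (i - 1L) %% width, V = (i - 1L) %/% width,
                         members = character(),
                         member_descriptors = list(),
                         labels = character())
  }
  for (r in seq_len(nrow(assignments))) {
    id <- assignments$molecule_id[r]
    i <- assignments$V[r] * width + assignments$H[r] + 1L
    desc <- setdiff(descriptors_of(table, id), exclude)
    neurons[[i]]$members <- c(neurons[[i]]$members, id)
    neurons[[i]]$member_descriptors[[id]] <- desc
    neurons[[i]]$labels <- sort(union(neurons[[i]]$labels, desc))
  }
  structure(list(width = width, height = height, neurons = neurons),
            class = "lattice_labels")
}

#' @export
print.lattice_labels <- function(x, ...) {
  occ <- sum(vapply(x$neurons, function(n) length(n$members) > 0L,
                    logical(1)))
  cat("<lattice_labels> ", x$width, " x ", x$height, " lattice, ",
      occ, " occupied neurons, ",
      sum(vapply(x$neurons, function(n) length(n$members), integer(1))),
      " molecules\n", sep = "")
  invisible(x)
}

label_neuron_index <- function(labels, H, V) {
  H <- as.integer(H); V <- as.integer(V)
  if (H < 0L || H >= labels$width || V < 0L || V >= labels$height)
    stop("neuron (", H, ",", V, ") outside the ", labels$width, "x",
         labels$height, " lattice")
  V * labels$width + H + 1L
}

#' Neurons carrying a descriptor
#'
#' All lattice neurons whose label set contains the queried odor
#' descriptor, i.e. the neurons where that scent impression is "written".
#'
#' @param labels A `lattice_labels`.
#' @param descriptor Odor descriptor label (case-insensitive).
#' @return Integer matrix with columns `H`, `V`, one row per matching
#'   neuron in row-major order; zero rows (with a warning) if the
#'   descriptor occurs nowhere.
#' @export
neurons_for_descriptor <- function(labels, descriptor) {
  stopifnot(inherits(labels, "lattice_labels"))
  descriptor <- normalize_descriptors(descriptor)
  hit <- vapply(labels$neurons, function(n) descriptor %in% n$labels,
                logical(1))
  if (!any(hit))
    warning("descriptor '", descriptor, "' not found on any neuron")
  coords_matrix(labels$neurons[hit])
}

coords_matrix <- function(neurons) {
  cbind(H = vapply(neurons, `[[`, integer(1), "H"),
        V = vapply(neurons, `[[`, integer(1), "V"))
}

#' Neurons carrying two descriptors
#'
#' Narrows the query to a scent impression described by two descriptors at
#' once. `both_on_neuron` returns neurons whose (union) label set contains
#' both; `both_on_molecule` is stricter and requires at least one member
#' molecule annotated with both.
#'
#' @param labels A `lattice_labels`.
#' @param d1,d2 Descriptor labels.
#' @param mode `"both_on_neuron"` (default) or `"both_on_molecule"`.
#' @return Integer matrix with columns `H`, `V` in row-major order (the
#'   `both_on_molecule` set is always a subset of the `both_on_neuron`
#'   set).
#' @export
neurons_for_descriptor_pair <- function(labels, d1, d2,
                                        mode = c("both_on_neuron",
                                                 "both_on_molecule")) {
  stopifnot(inherits(labels, "lattice_labels"))
  mode <- match.arg(mode)
  d1 <- normalize_descriptors(d1); d2 <- normalize_descriptors(d2)
  hit <- vapply(labels$neurons, function(n) {
    if (mode == "both_on_neuron") {
      d1 %in% n$labels && d2 %in% n$labels
    } else {
      any(vapply(n$member_descriptors, function(ds)
        d1 %in% ds && d2 %in% ds, logical(1)))
    }
  }, logical(1))
  coords_matrix(labels$neurons[hit])
}

#' Locate a molecule's neuron
#'
#' @param labels A `lattice_labels`.
#' @param molecule_id Molecule identifier (exact match; close matches are
#'   suggested in the error message on a miss).
#' @return Named integer vector `c(H = , V = )` of the molecule's BMU.
#' @export
locate_molecule <- function(labels, molecule_id) {
  stopifnot(inherits(labels, "lattice_labels"))
  for (n in labels$neurons)
    if (molecule_id %in% n$members) return(c(H = n$H, V = n$V))
  all_ids <- unlist(lapply(labels$neurons, `[[`, "members"))
  near <- utils::head(agrep(molecule_id, all_ids, ignore.case = TRUE,
                            value = TRUE), 5L)
  stop("molecule '", molecule_id, "' not found",
       if (length(near)) paste0("; did you mean: ",
                                paste(near, collapse = ", "), "?") else "")
}

#' Inverse-map a neuron to its molecules
#'
#' The core retrieval step: given a neuron selected for a desired scent
#' impression, return every molecule whose BMU is that neuron together
#' with its latent spectrum (same dimension as the autoencoder
#' bottleneck). If a reference molecule is named, each member's cosine
#' similarity to the reference's latent vector is attached.
#'
#' @param labels A `lattice_labels`.
#' @param latents A `latent_matrix` covering the member molecules.
#' @param neuron `c(H, V)` 0-based lattice coordinates.
#' @param reference_id Optional member-set molecule id to score the
#'   members against.
#' @return An object of class `extraction_result` with fields `query`,
#'   `neuron`, `member_ids`, `member_latents`, `member_descriptors`, and
#'   `similarity_to_reference` (NULL unless `reference_id` is given).
#'   Empty neurons give an empty result with a warning.
#' @export
inverse_map <- function(labels, latents, neuron, reference_id = NULL) {
  stopifnot(inherits(labels, "lattice_labels"),
            inherits(latents, "latent_matrix"))
  n <- labels$neurons[[label_neuron_index(labels, neuron[[1L]],
                                          neuron[[2L]])]]
  if (length(n$members) == 0L)
    warning("neuron (", n$H, ",", n$V, ") has no member molecules")
  missing <- setdiff(n$members, latents$molecule_ids)
  if (length(missing))
    stop("member molecules missing from the latent matrix: ",
         paste(missing, collapse = ", "))
  member_latents <- latents$values[n$members, , drop = FALSE]
  sim <- NULL
  if (!is.null(reference_id) && length(n$members)) {
    if (!reference_id %in% latents$molecule_ids)
      stop("reference molecule '", reference_id,
           "' missing from the latent matrix")
    ref <- latents$values[reference_id, ]
    sim <- apply(member_latents, 1L, cosine_similarity, b = ref)
  }
  structure(list(query = list(neuron = c(H = n$H, V = n$V),
                              reference_id = reference_id),
                 neuron = c(H = n$H, V = n$V),
                 member_ids = n$members,
                 member_latents = member_latents,
                 member_descriptors = n$member_descriptors,
                 similarity_to_reference = sim),
            class = "extraction_result")
}

#' @export
print.extraction_result <- function(x, ...) {
  cat("<extraction_result> neuron (", x$neuron[["H"]], ",", x$neuron[["V"]],
      "): ", length(x$member_ids), " molecule(s)\n", sep = "")
  for (id in x$member_ids) {
    cat("  ", id, sep = "")
    ds <- x$member_descriptors[[id]]
    if (length(ds)) cat(" [", paste(ds, collapse = ", "), "]", sep = "")
    if (!is.null(x$similarity_to_reference))
      cat(sprintf("  sim=%.4f", x$similarity_to_reference[[id]]))
    cat("\n")
  }
  invisible(x)
}

#' Nearest neuron satisfying a label predicate
#'
#' Searches outward (in hexagon-center planar distance) from a starting
#' neuron for the closest other neuron whose label set satisfies the
#' predicate — e.g. the nearest neuron carrying only one of two queried
#' descriptors, for contrasting extractions. Ties are broken by smallest
#' row-major index.
#'
#' @param grid A `som_grid` (supplies the lattice geometry).
#' @param labels A matching `lattice_labels`.
#' @param from `c(H, V)` starting neuron (always excluded from the
#'   result).
#' @param predicate Function taking a neuron's label set (character
#'   vector) and returning TRUE/FALSE.
#' @return Named integer vector `c(H = , V = )`.
#' @export
nearest_neuron <- function(grid, labels, from, predicate) {
  stopifnot(inherits(grid, "som_grid"), inherits(labels, "lattice_labels"),
            is.function(predicate))
  from_i <- label_neuron_index(labels, from[[1L]], from[[2L]])
  ok <- vapply(labels$neurons, function(n) isTRUE(predicate(n$labels)),
               logical(1))
  ok[from_i] <- FALSE
  if (!any(ok)) stop("no neuron other than the start satisfies the predicate")
  pos <- grid$positions
  d2 <- (pos[, 1L] - pos[from_i, 1L])^2 + (pos[, 2L] - pos[from_i, 2L])^2
  d2[!ok] <- Inf
  i <- which.min(d2)
  c(H = (i - 1L) %% labels$width, V = (i - 1L) %/% labels$width)
}

#' Dump lattice labels to a data.frame
#'
#' One row per neuron: `H`, `V`, member count and the sorted label list
#' (`;`-separated). Suitable for CSV export and inspection.
#'
#' @param labels A `lattice_labels`.
#' @return A data.frame in row-major neuron order.
#' @export
lattice_label_table <- function(labels) {
  stopifnot(inherits(labels, "lattice_labels"))
  data.frame(
    H = vapply(labels$neurons, `[[`, integer(1), "H"),
    V = vapply(labels$neurons, `[[`, integer(1), "V"),
    n_members = vapply(labels$neurons, function(n) length(n$members),
                       integer(1)),
    labels = vapply(labels$neurons, function(n)
      paste(sort(n$labels), collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
}

#' Extraction result as a report data.frame
#'
#' @param result An `extraction_result`.
#' @return A data.frame with one row per member molecule: id, neuron
#'   coordinates, descriptor list and (if computed) similarity to the
#'   reference.
#' @export
extraction_report <- function(result) {
  stopifnot(inherits(result, "extraction_result"))
  if (length(result$member_ids) == 0L)
    return(data.frame(molecule_id = character(), H = integer(),
                      V = integer(), descriptors = character(),
                      similarity_to_reference = numeric()))
  data.frame(
    molecule_id = result$member_ids,
    H = result$neuron[["H"]], V = result$neuron[["V"]],
    descriptors = vapply(result$member_ids, function(id)
      paste(result$member_descriptors[[id]], collapse = ";"), character(1)),
    similarity_to_reference = if (is.null(result$similarity_to_reference))
      NA_real_ else unname(result$similarity_to_reference),
    row.names = NULL, stringsAsFactors = FALSE)
}
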