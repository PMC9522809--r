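# Mass-spectral similarity scoring and principal-component closeness
# checks for extracted molecule sets.

#' Cosine similarity of two intensity vectors
#'
#' `cos(theta)` between the two spectra viewed as vectors — the plain
#' spectral similarity score, with no m/z weighting. Scale-invariant and
#' symmetric; identical or proportional spectra score exactly 1, spectra
#' with no shared channel score 0. Works equally on raw windowed 212-channel
#' spectra and on 50-d latent codes (with sigmoid latents all entries are
#' positive, so pipeline scores lie in \[0, 1\]).
#'
#' @param a,b Numeric vectors of equal length, each with positive norm.
#' @return Scalar in \[-1, 1\] (\[0, 1\] for nonnegative vectors).
#' @examples
#' cosine_similarity(c(1, 2, 3), c(2, 4, 6))  # 1: proportional spectra
#' cosine_similarity(c(1, 0), c(0, 1))        # 0: disjoint peaks
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b))
    stop("vectors differ in length (", length(a), " vs ", length(b), ")")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("non-finite intensity values")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero-norm vector has no direction")
  min(max(sum(a * b) / (na * nb), -1), 1)  # guard float overshoot
}

align_channels <- function(reference, query) {
  if (inherits(reference, "mass_spectrum") &&
      inherits(query, "mass_spectrum")) {
    channels <- sort(union(reference$mz, query$mz))
    ref_v <- qry_v <- numeric(length(channels))
    ref_v[match(reference$mz, channels)] <- reference$intensity
    qry_v[match(query$mz, channels)] <- query$intensity
    list(channels = channels, reference = ref_v, query = qry_v,
         reference_id = reference$molecule_id,
         query_id = query$molecule_id)
  } else if (is.numeric(reference) && is.numeric(query)) {
    if (length(reference) != length(query))
      stop("latent vectors differ in length")
    list(channels = seq_along(reference),
         reference = as.numeric(reference), query = as.numeric(query),
         reference_id = "reference", query_id = "query")
  } else {
    stop("reference and query must be two mass_spectrum objects or two ",
         "numeric vectors of the same representation")
  }
}

#' Head-to-tail comparison of two spectra
#'
#' Aligns the reference and query on a common channel axis and returns
#' the data for a mirror plot: reference intensities positive-up, query
#' intensities negated, plus the cosine similarity score. Accepts either
#' two [mass_spectrum] objects (aligned on the union of their m/z values)
#' or two equal-length numeric vectors (e.g. latent codes).
#'
#' @param reference Reference spectrum (drawn upward).
#' @param query Query spectrum (drawn downward).
#' @return An object of class `similarity_report` with fields
#'   `reference_id`, `query_id`, `score` and `head_to_tail` (a data.frame
#'   with columns `channel`, `reference`, `query`, the latter
#'   nonpositive).
#' @export
head_to_tail <- function(reference, query) {
  al <- align_channels(reference, query)
  structure(list(reference_id = al$reference_id, query_id = al$query_id,
                 score = cosine_similarity(al$reference, al$query),
                 head_to_tail = data.frame(channel = al$channels,
                                           reference = al$reference,
                                           query = -al$query)),
            class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat("<similarity_report> ", x$reference_id, " vs ", x$query_id,
      ": score ", sprintf("%.4f", x$score), ", ",
      nrow(x$head_to_tail), " aligned channels\n", sep = "")
  invisible(x)
}

#' Pairwise cosine similarity matrix
#'
#' @param data A `latent_matrix`, `spectrum_matrix` or numeric matrix
#'   (rows = molecules).
#' @return Symmetric N x N matrix of cosine scores with unit diagonal.
#' @export
similarity_matrix <- function(data) {
  X <- as_latent_values(data)
  norms <- sqrt(rowSums(X^2))
  if (any(norms == 0)) stop("zero-norm row(s) in similarity input")
  S <- (X %*% t(X)) / outer(norms, norms)
  S[S > 1] <- 1; S[S < -1] <- -1
  diag(S) <- 1
  S
}

#' Principal-component projection for closeness checks
#'
#' Mean-centered (unscaled) PCA used to visualize how tightly a set of
#' extracted spectra cluster. The sign of each axis is fixed by making its
#' largest-magnitude loading positive, so projections are reproducible.
#'
#' @param vectors N x d numeric matrix (N >= 2) with nonzero total
#'   variance.
#' @param components Number of leading components (default 2); at most
#'   `min(N - 1, d)`.
#' @return A list with `scores` (N x components), `explained_variance`
#'   (fractions, summing to at most 1) and `rotation` (d x components
#'   loadings).
#' @export
pca_project <- function(vectors, components = 2L) {
  X <- as_latent_values(vectors)
  if (nrow(X) < 2L) stop("need at least 2 rows for PCA")
  components <- as.integer(components)
  if (components < 1L || components > min(nrow(X) - 1L, ncol(X)))
    stop("components must be in 1..min(N-1, d)")
  if (all(abs(sweep(X, 2L, colMeans(X))) < 1e-15))
    stop("constant data: zero variance, no principal axes")
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  rot <- p$rotation[, seq_len(components), drop = FALSE]
  scores <- p$x[, seq_len(components), drop = FALSE]
  for (j in seq_len(components)) {       # deterministic sign convention
    k <- which.max(abs(rot[, j]))
    if (rot[k, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores,
       explained_variance = (p$sdev^2 / sum(p$sdev^2))[seq_len(components)],
       rotation = rot)
}

#' Write a similarity matrix to CSV
#'
#' @param S Matrix from [similarity_matrix()].
#' @param ids Row/column identifiers (defaults to rownames).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity_csv <- function(S, path, ids = rownames(S)) {
  if (is.null(ids)) ids <- as.character(seq_len(nrow(S)))
  df <- data.frame(molecule_id = ids, S, check.names = FALSE)
  colnames(df) <- c("molecule_id", ids)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
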