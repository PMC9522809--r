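# Data model and I/O for odorant mass spectra and binary odor-descriptor tables.

#' Construct a mass spectrum
#'
#' A single molecule's electron-ionization peak list. Fractional m/z values
#' are rounded to the nearest integer (unit-mass binning); duplicate m/z
#' values are merged by summing their intensities; peaks are stored in
#' strictly increasing m/z order.
#'
#' @param molecule_id Character scalar identifying the molecule (unique
#'   within a dataset).
#' @param mz Numeric vector of m/z values (rounded to integers).
#' @param intensity Numeric vector of nonnegative intensities, same length
#'   as `mz`; at least one must be positive.
#' @param descriptors Character vector of odor descriptor labels (may be
#'   empty). Lower-cased and trimmed.
#' @param annotations Optional named character vector of opaque metadata
#'   (e.g. CAS, SMILES) carried through MSP round-trips.
#' @return An object of class `mass_spectrum` with fields `molecule_id`,
#'   `mz` (integer), `intensity`, `descriptors`, `annotations`.
#' @examples
#' s <- mass_spectrum("mol1", c(55, 70, 70), c(999, 50, 70))
#' s$intensity[s$mz == 70]  # 120: duplicate m/z merged by summing
#' @export
mass_spectrum <- function(molecule_id, mz, intensity,
                          descriptors = character(),
                          annotations = character()) {
  stopifnot(is.character(molecule_id), length(molecule_id) == 1L,
            nzchar(molecule_id))
  if (length(mz) != length(intensity))
    stop("mz and intensity lengths differ for '", molecule_id, "'")
  if (length(mz) == 0L)
    stop("spectrum '", molecule_id, "' has no peaks")
  if (any(!is.finite(mz)) || any(!is.finite(intensity)))
    stop("non-finite peak data in '", molecule_id, "'")
  if (any(intensity < 0))
    stop("negative intensity in '", molecule_id, "'")
  mzi <- as.integer(round(mz))
  if (any(mzi <= 0L)) stop("non-positive m/z in '", molecule_id, "'")
  # merge duplicate bins by summing, then sort ascending
  agg <- rowsum(as.numeric(intensity), group = mzi)
  mz_out <- as.integer(rownames(agg))
  ord <- order(mz_out)
  mz_out <- mz_out[ord]
  int_out <- as.numeric(agg[ord, 1L])
  if (all(int_out == 0)) stop("spectrum '", molecule_id, "' is all-zero")
  structure(
    list(molecule_id = molecule_id,
         mz = mz_out,
         intensity = int_out,
         descriptors = normalize_descriptors(descriptors),
         annotations = annotations),
    class = "mass_spectrum")
}

normalize_descriptors <- function(x) {
  x <- tolower(trimws(as.character(x)))
  unique(x[nzchar(x)])
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat("<mass_spectrum> ", x$molecule_id, ": ", length(x$mz), " peaks, m/z ",
      min(x$mz), "-", max(x$mz), ", base peak ", x$mz[which.max(x$intensity)],
      sep = "")
  if (length(x$descriptors))
    cat(" [", paste(x$descriptors, collapse = ", "), "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Read spectra from a NIST-style MSP text file
#'
#' Records are delimited by blank lines. Each record must contain a
#' `Name:` line and a `Num Peaks:` line followed by that many
#' "m/z intensity" pairs (several pairs per line, separated by `;` or
#' whitespace, are accepted). Other `Key: value` header lines (CAS,
#' SMILES, Comment, ...) are kept as annotations. Duplicate m/z within a
#' record are merged by summing.
#'
#' @param path Path to an MSP file.
#' @return A list of [mass_spectrum] objects (empty list for an empty file).
#' @seealso [write_msp()]
#' @export
read_msp <- function(path) {
  if (!file.exists(path)) stop("MSP file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  # split into records on blank lines
  blank <- grepl("^\\s*$", lines)
  if (all(blank)) return(list())
  rec_id <- cumsum(c(TRUE, blank[-length(blank)]))
  out <- list()
  for (grp in split(lines[!blank], rec_id[!blank])) {
    out[[length(out) + 1L]] <- parse_msp_record(grp)
  }
  out
}

parse_msp_record <- function(rec_lines) {
  header_pat <- "^([A-Za-z][A-Za-z0-9 _/-]*):\\s*(.*)$"
  np_idx <- grep("^num\\s*peaks\\s*:", rec_lines, ignore.case = TRUE)
  name_idx <- grep("^name\\s*:", rec_lines, ignore.case = TRUE)
  name <- if (length(name_idx)) {
    trimws(sub(header_pat, "\\2", rec_lines[name_idx[1L]]))
  } else "<unnamed>"
  if (length(np_idx) == 0L)
    stop("malformed MSP record '", name, "': missing 'Num Peaks:' line")
  np_idx <- np_idx[1L]
  n_peaks <- suppressWarnings(
    as.integer(trimws(sub(header_pat, "\\2", rec_lines[np_idx]))))
  if (is.na(n_peaks) || n_peaks < 1L)
    stop("malformed MSP record '", name, "': unreadable peak count")
  ann <- character()
  for (ln in rec_lines[seq_len(np_idx - 1L)]) {
    if (!grepl(header_pat, ln)) next
    key <- trimws(sub(header_pat, "\\1", ln))
    if (tolower(key) %in% c("name")) next
    ann[key] <- trimws(sub(header_pat, "\\2", ln))
  }
  peak_lines <- rec_lines[-seq_len(np_idx)]
  tokens <- unlist(strsplit(paste(peak_lines, collapse = " "),
                            "[;,[:space:]]+"))
  tokens <- tokens[nzchar(tokens)]
  vals <- suppressWarnings(as.numeric(tokens))
  if (any(is.na(vals)) || length(vals) %% 2L != 0L)
    stop("malformed MSP record '", name, "': unreadable peak list")
  mz <- vals[seq(1L, length(vals), by = 2L)]
  intensity <- vals[seq(2L, length(vals), by = 2L)]
  if (length(mz) != n_peaks)
    stop("malformed MSP record '", name, "': Num Peaks = ", n_peaks,
         " but ", length(mz), " peaks listed")
  mass_spectrum(name, mz, intensity, annotations = ann)
}

#' Write spectra to a NIST-style MSP text file
#'
#' @param spectra List of [mass_spectrum] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msp <- function(spectra, path) {
  stopifnot(is.list(spectra))
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    stopifnot(inherits(s, "mass_spectrum"))
    writeLines(paste0("Name: ", s$molecule_id), con)
    if (length(s$annotations))
      writeLines(paste0(names(s$annotations), ": ", s$annotations), con)
    writeLines(paste0("Num Peaks: ", length(s$mz)), con)
    writeLines(paste(s$mz, format(s$intensity, trim = TRUE, digits = 12),
                     sep = " "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a binary odor-descriptor table from CSV
#'
#' Two dialects are accepted and detected automatically:
#' \itemize{
#'   \item list dialect: columns `molecule_id` and `descriptors`, the
#'     latter a `;`-separated label list (may be empty);
#'   \item wide dialect: `molecule_id` plus one 0/1 column per descriptor.
#' }
#' Labels are lower-cased and whitespace-trimmed in both dialects.
#'
#' @param path Path to a CSV file.
#' @return An object of class `descriptor_table` with fields
#'   `molecule_ids`, `descriptor_names` and binary `matrix` (N x D).
#' @export
read_descriptor_csv <- function(path) {
  if (!file.exists(path)) stop("descriptor CSV not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"molecule_id" %in% names(df))
    stop("descriptor CSV must have a 'molecule_id' column: ", path)
  ids <- as.character(df$molecule_id)
  if (anyDuplicated(ids))
    stop("duplicate molecule_id in descriptor CSV: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  other <- setdiff(names(df), "molecule_id")
  if (identical(other, "descriptors")) {
    sets <- lapply(strsplit(ifelse(is.na(df$descriptors), "",
                                   df$descriptors), ";"),
                   normalize_descriptors)
    descriptor_table_from_sets(ids, sets)
  } else if (length(other) > 0 &&
             all(vapply(df[other], function(col)
               all(col %in% c(0L, 1L)), logical(1)))) {
    mat <- as.matrix(df[other])
    storage.mode(mat) <- "integer"
    colnames(mat) <- tolower(trimws(other))
    if (anyDuplicated(colnames(mat)))
      stop("duplicate descriptor columns in ", path)
    mat <- mat[, order(colnames(mat)), drop = FALSE]  # canonical order
    descriptor_table(ids, colnames(mat), mat)
  } else {
    stop("unknown descriptor CSV dialect in ", path,
         ": need a 'descriptors' list column or all-binary wide columns")
  }
}

#' Construct a descriptor table
#'
#' @param molecule_ids Character vector of N unique molecule identifiers.
#' @param descriptor_names Character vector of D unique descriptor labels.
#' @param matrix N x D matrix of 0/1 indicators.
#' @return An object of class `descriptor_table`.
#' @export
descriptor_table <- function(molecule_ids, descriptor_names, matrix) {
  molecule_ids <- as.character(molecule_ids)
  descriptor_names <- tolower(trimws(as.character(descriptor_names)))
  stopifnot(!anyDuplicated(molecule_ids), !anyDuplicated(descriptor_names),
            nrow(matrix) == length(molecule_ids),
            ncol(matrix) == length(descriptor_names))
  if (!all(matrix %in% c(0L, 1L)))
    stop("descriptor matrix entries must be 0 or 1")
  storage.mode(matrix) <- "integer"
  dimnames(matrix) <- list(molecule_ids, descriptor_names)
  structure(list(molecule_ids = molecule_ids,
                 descriptor_names = descriptor_names,
                 matrix = matrix),
            class = "descriptor_table")
}

descriptor_table_from_sets <- function(ids, sets) {
  names(sets) <- ids
  all_desc <- sort(unique(unlist(sets)))
  mat <- matrix(0L, length(ids), length(all_desc),
                dimnames = list(ids, all_desc))
  for (i in seq_along(ids)) mat[i, sets[[i]]] <- 1L
  descriptor_table(ids, all_desc, mat)
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat("<descriptor_table> ", length(x$molecule_ids), " molecules x ",
      length(x$descriptor_names), " descriptors (",
      sum(x$matrix), " annotations)\n", sep = "")
  invisible(x)
}

#' Descriptor set of one molecule
#'
#' @param table A `descriptor_table`.
#' @param molecule_id Molecule identifier; molecules absent from the table
#'   get an empty set.
#' @return Character vector of descriptor labels.
#' @export
descriptors_of <- function(table, molecule_id) {
  stopifnot(inherits(table, "descriptor_table"))
  if (!molecule_id %in% table$molecule_ids) return(character())
  table$descriptor_names[table$matrix[molecule_id, ] == 1L]
}

#' Write a descriptor table to CSV
#'
#' @param table A `descriptor_table`.
#' @param path Output path.
#' @param dialect `"wide"` (one 0/1 column per descriptor) or `"list"`
#'   (a single `;`-separated `descriptors` column).
#' @return `path`, invisibly.
#' @export
write_descriptor_csv <- function(table, path, dialect = c("wide", "list")) {
  stopifnot(inherits(table, "descriptor_table"))
  dialect <- match.arg(dialect)
  if (dialect == "wide") {
    df <- data.frame(molecule_id = table$molecule_ids,
                     table$matrix, check.names = FALSE)
  } else {
    lists <- apply(table$matrix, 1L, function(r)
      paste(table$descriptor_names[r == 1L], collapse = ";"))
    df <- data.frame(molecule_id = table$molecule_ids,
                     descriptors = unname(lists))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Window spectra to an m/z range and base-peak normalize
#'
#' Builds the N x (hi - lo + 1) intensity matrix used as autoencoder input:
#' channel c of row r holds molecule r's intensity at m/z = c (0 where no
#' peak), after which each row is divided by its own maximum so the base
#' peak within the window equals 1. The default window 51-262 gives the
#' 212 unit-mass channels of the standard pipeline; lower m/z is dominated
#' by fragments common to odorless molecules and is excluded by default.
#' Molecules with no in-window peak are dropped with a warning and listed
#' in the result's `excluded` field.
#'
#' @param spectra List of [mass_spectrum] objects.
#' @param lo,hi Integer m/z window bounds, inclusive (defaults 51 and 262).
#' @return An object of class `spectrum_matrix` with fields `molecule_ids`,
#'   `channels`, `values` (rows in input order, entries in \[0, 1\]) and
#'   `excluded` (ids with zero in-window signal).
#' @examples
#' s <- mass_spectrum("m", c(55, 100), c(200, 400))
#' m <- window_and_normalize(list(s))
#' m$values[1, "55"]   # 0.5
#' m$values[1, "100"]  # 1.0
#' @export
window_and_normalize <- function(spectra, lo = 51L, hi = 262L) {
  stopifnot(is.list(spectra), length(spectra) > 0L)
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (lo >= hi) stop("need lo < hi")
  channels <- lo:hi
  ids <- vapply(spectra, function(s) s$molecule_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate molecule_id among spectra: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- matrix(0, length(spectra), length(channels),
                 dimnames = list(ids, channels))
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    keep <- s$mz >= lo & s$mz <= hi
    vals[i, as.character(s$mz[keep])] <- s$intensity[keep]
  }
  rmax <- apply(vals, 1L, max)
  excluded <- ids[rmax <= 0]
  if (length(excluded)) {
    warning(length(excluded), " molecule(s) with no peak in m/z [", lo, ", ",
            hi, "] excluded: ", paste(excluded, collapse = ", "))
    vals <- vals[rmax > 0, , drop = FALSE]
    ids <- ids[rmax > 0]
    rmax <- rmax[rmax > 0]
  }
  if (nrow(vals) == 0L) stop("no molecule has any peak inside the window")
  vals <- vals / rmax  # row-wise: base peak of every row becomes 1
  structure(list(molecule_ids = ids, channels = channels, values = vals,
                 excluded = excluded),
            class = "spectrum_matrix")
}

#' @export
print.spectrum_matrix <- function(x, ...) {
  cat("<spectrum_matrix> ", length(x$molecule_ids), " molecules x ",
      length(x$channels), " channels (m/z ", min(x$channels), "-",
      max(x$channels), ")", sep = "")
  if (length(x$excluded)) cat(", ", length(x$excluded), " excluded", sep = "")
  cat("\n")
  invisible(x)
}

#' Write a spectrum matrix to CSV
#'
#' Header row of m/z channels, one row per molecule, first column
#' `molecule_id`. The inverse of [read_matrix_csv()].
#'
#' @param mat A `spectrum_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(mat, path) {
  stopifnot(inherits(mat, "spectrum_matrix"))
  df <- data.frame(molecule_id = mat$molecule_ids, mat$values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a spectrum matrix from CSV
#'
#' @param path Path written by [write_matrix_csv()].
#' @return A `spectrum_matrix`.
#' @export
read_matrix_csv <- function(path) {
  if (!file.exists(path)) stop("matrix CSV not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1L] != "molecule_id")
    stop("matrix CSV must start with a molecule_id column: ", path)
  channels <- as.integer(names(df)[-1L])
  if (any(is.na(channels))) stop("non-integer channel header in ", path)
  vals <- as.matrix(df[-1L])
  dimnames(vals) <- list(df$molecule_id, channels)
  structure(list(molecule_ids = as.character(df$molecule_id),
                 channels = channels, values = vals, excluded = character()),
            class = "spectrum_matrix")
}
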