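DNA_BASES <- c("A", "C", "G", "T")

#' Construct a barcode reference library
#'
#' A barcode library is the package's central container: an ordered set of
#' labelled barcode records, each with a free-text identifier, a species
#' label (the class the classifier predicts), and a nucleotide sequence.
#' It is represented as a data frame with columns \code{record_id},
#' \code{species} and \code{sequence} and class \code{barcode_library}.
#'
#' @param record_id character vector of record identifiers.
#' @param species character vector of species labels (may contain spaces);
#'   query records carry the sentinel label \code{"unknown"}.
#' @param sequence character vector of nucleotide strings.
#' @param ancestors optional named character vector of per-species ancestral
#'   sequences (attached by [generate_library()]).
#' @return a \code{barcode_library} object.
#' @export
barcode_library <- function(record_id, species, sequence, ancestors = NULL) {
  stopifnot(length(record_id) == length(species),
            length(species) == length(sequence))
  if (any(!nzchar(species)))
    stop("species labels must be non-empty")
  lib <- data.frame(record_id = as.character(record_id),
                    species = as.character(species),
                    sequence = as.character(sequence),
                    stringsAsFactors = FALSE)
  class(lib) <- c("barcode_library", "data.frame")
  if (!is.null(ancestors)) attr(lib, "ancestors") <- ancestors
  lib
}

#' @export
print.barcode_library <- function(x, ...) {
  cat(sprintf("Barcode library: %d records, %d species\n",
              nrow(x), length(unique(x$species))))
  tab <- table(x$species)
  cat(sprintf("  records per species: min %d, median %g, max %d\n",
              min(tab), stats::median(tab), max(tab)))
  invisible(x)
}

#' Per-species record counts
#' @param lib a \code{barcode_library}.
#' @return named integer vector, species in sorted order.
#' @export
species_counts <- function(lib) {
  tab <- table(lib$species)
  stats::setNames(as.integer(tab), names(tab))
}

#' Read labelled barcode sequences from FASTA
#'
#' Headers are expected in the BOLD pipe-delimited dialect: the record
#' identifier is the first \code{|}-separated token and the species label
#' the \code{species_field}-th. Query files (no labels) are read with
#' \code{species_field = NA}, which assigns every record the sentinel
#' label \code{"unknown"}.
#'
#' @param path path to a FASTA file (single- or multi-line sequence bodies).
#' @param species_field 1-based index of the pipe-delimited header field
#'   holding the species label (default 2), or \code{NA} for query files.
#' @return a [barcode_library()]. Sequences are returned verbatim; call
#'   [validate_library()] before encoding.
#' @export
read_barcode_fasta <- function(path, species_field = 2) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("FASTA file contains no sequences: ", path)
  headers <- names(seqs)
  fields <- strsplit(headers, "|", fixed = TRUE)
  record_id <- vapply(fields, `[`, character(1), 1L)
  if (is.na(species_field)) {
    species <- rep("unknown", length(seqs))
  } else {
    stopifnot(species_field >= 1)
    n_fields <- lengths(fields)
    bad <- n_fields < species_field
    if (any(bad))
      stop("header(s) with fewer than ", species_field, " pipe-delimited ",
           "fields: ", paste(utils::head(headers[bad], 5L), collapse = "; "))
    species <- vapply(fields, `[`, character(1), species_field)
  }
  barcode_library(record_id, species, as.character(seqs))
}

#' Write a barcode library to FASTA
#'
#' Headers are written as \code{record_id|species}, so a round trip through
#' [read_barcode_fasta()] with \code{species_field = 2} recovers the
#' library exactly.
#'
#' @param lib a \code{barcode_library}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_barcode_fasta <- function(lib, path) {
  seqs <- Biostrings::BStringSet(lib$sequence)
  names(seqs) <- paste(lib$record_id, lib$species, sep = "|")
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Validate one barcode record
#'
#' Normalizes the sequence to upper case and checks that it contains only
#' the standard bases A, C, G, T and is long enough (>= 2 bases) to form at
#' least one base pair. Ambiguity codes (N, R, Y, ...) and RNA U are
#' invalid. Validation is idempotent.
#'
#' @param record a list or one-row data frame with \code{record_id},
#'   \code{species}, \code{sequence}.
#' @param policy \code{"reject"} (error on an invalid record) or
#'   \code{"drop"} (return \code{NULL} with the reason as a message).
#' @return the validated record (sequence upper-cased), or \code{NULL}
#'   under the drop policy.
#' @export
validate_record <- function(record, policy = c("reject", "drop")) {
  policy <- match.arg(policy)
  seq <- toupper(record$sequence)
  reason <- NULL
  if (nchar(seq) < 2L) {
    reason <- "too short (< 2 bases, no base pair can be formed)"
  } else if (grepl("[^ACGT]", seq)) {
    bad <- unique(strsplit(gsub("[ACGT]", "", seq), "")[[1]])
    reason <- paste0("non-standard base ", paste(bad, collapse = ","))
  }
  if (!is.null(reason)) {
    msg <- sprintf("record '%s' excluded: %s", record$record_id, reason)
    if (policy == "reject") stop(msg)
    message(msg)
    return(NULL)
  }
  record$sequence <- seq
  record
}

#' Validate every record of a library
#'
#' Applies the standard-base filter used when assembling barcode reference
#' libraries: sequences are upper-cased, and records containing characters
#' outside A/C/G/T, or shorter than 2 bases, are dropped (default) or
#' cause an error.
#'
#' @param lib a \code{barcode_library}.
#' @param policy \code{"drop"} (default for library construction) or
#'   \code{"reject"}.
#' @return the validated library.
#' @export
validate_library <- function(lib, policy = c("drop", "reject")) {
  policy <- match.arg(policy)
  seqs <- toupper(lib$sequence)
  invalid <- grepl("[^ACGT]", seqs) | nchar(seqs) < 2L
  if (any(invalid) && policy == "reject") {
    stop("invalid record(s): ",
         paste(utils::head(lib$record_id[invalid], 5L), collapse = ", "))
  }
  if (any(invalid))
    message(sum(invalid), " record(s) dropped (non-standard bases or ",
            "length < 2)")
  out <- lib[!invalid, , drop = FALSE]
  if (nrow(out) == 0L) stop("no valid records remain after filtering")
  out$sequence <- seqs[!invalid]
  rownames(out) <- NULL
  class(out) <- class(lib)
  attr(out, "ancestors") <- attr(lib, "ancestors")
  out
}

#' Drop species with too few sequences
#'
#' Supervised identification needs several sequences per species; the
#' reference-library filter keeps only species represented by at least
#' \code{min_per_species} records (default 3).
#'
#' @param lib a \code{barcode_library}.
#' @param min_per_species minimum records a species must have (>= 1).
#' @return the filtered library.
#' @export
filter_min_sequences <- function(lib, min_per_species = 3L) {
  stopifnot(min_per_species >= 1L)
  tab <- species_counts(lib)
  keep_species <- names(tab)[tab >= min_per_species]
  removed <- length(tab) - length(keep_species)
  if (removed > 0L)
    message(removed, " species removed (fewer than ", min_per_species,
            " sequences)")
  if (length(keep_species) == 0L)
    stop("no species with at least ", min_per_species, " sequences")
  out <- lib[lib$species %in% keep_species, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(lib)
  attr(out, "ancestors") <- attr(lib, "ancestors")
  out
}

#' Subsample a library to exactly k sequences per species
#'
#' For each species with at least \code{k} records, draws exactly \code{k}
#' without replacement (seeded); species with fewer records are dropped
#' with a warning. This prepares the balanced datasets used for
#' species-stratified k-fold cross-validation.
#'
#' @param lib a \code{barcode_library}.
#' @param k records to retain per species (>= 1).
#' @param seed integer seed; the same seed yields the same selection.
#' @return the subsampled library (a subset of \code{lib}).
#' @export
subsample_k_per_species <- function(lib, k, seed = 1L) {
  stopifnot(k >= 1L)
  tab <- species_counts(lib)
  dropped <- names(tab)[tab < k]
  if (length(dropped) > 0L)
    warning(length(dropped), " species dropped (fewer than ", k,
            " sequences): ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            call. = FALSE)
  keep_species <- setdiff(names(tab), dropped)
  if (length(keep_species) == 0L)
    stop("no species has ", k, " or more sequences")
  keep_rows <- logical(nrow(lib))
  with_seed(seed, {
    for (sp in sort(keep_species)) {
      rows <- which(lib$species == sp)
      keep_rows[sample(rows, k)] <- TRUE
    }
  })
  out <- lib[keep_rows, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(lib)
  attr(out, "ancestors") <- attr(lib, "ancestors")
  out
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
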