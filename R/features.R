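# Sequence -> numeric encodings: g-spaced base-pair compositions and
# contiguous k-mer compositions. Column identity is fully deterministic:
# gap blocks in ascending g (16 ordered pairs each, lexicographic
# AA, AC, ..., TT), then k-mer blocks in ascending k (4^k lexicographic).

#' Declare a feature encoding
#'
#' A feature spec names the blocks of the numeric representation: a set of
#' gap sizes for g-spaced base-pair compositions and/or a set of orders
#' for contiguous k-mer compositions. The default is the five-gap spec
#' g = 1..5 (80 features); \code{include_gap0 = TRUE} adds the contiguous
#' dinucleotide block (g = 0), giving 96 features.
#'
#' @param gaps non-negative integers: gap sizes (positions skipped between
#'   the two bases of each ordered pair). Stored sorted ascending.
#' @param kmers positive integers: k-mer orders. Stored sorted ascending.
#' @param include_gap0 convenience flag prepending gap 0 to \code{gaps}.
#' @return a \code{feature_spec} object.
#' @export
feature_spec <- function(gaps = 1:5, kmers = integer(0),
                         include_gap0 = FALSE) {
  gaps <- as.integer(gaps)
  kmers <- as.integer(kmers)
  if (include_gap0) gaps <- c(0L, gaps)
  gaps <- sort(unique(gaps))
  kmers <- sort(unique(kmers))
  if (length(gaps) && any(gaps < 0L)) stop("gap sizes must be >= 0")
  if (length(kmers) && any(kmers < 1L)) stop("k-mer orders must be >= 1")
  if (!length(gaps) && !length(kmers))
    stop("feature spec must name at least one gap size or k-mer order")
  structure(list(gaps = gaps, kmers = kmers), class = "feature_spec")
}

#' @export
print.feature_spec <- function(x, ...) {
  blocks <- character(0)
  if (length(x$gaps))
    blocks <- c(blocks, paste0("g=", paste(x$gaps, collapse = "+")))
  if (length(x$kmers))
    blocks <- c(blocks, paste0("k=", paste(x$kmers, collapse = "+")))
  cat(sprintf("Feature spec: %s (%d features)\n",
              paste(blocks, collapse = ", "), feature_dim(x)))
  invisible(x)
}

#' Dimensionality of an encoding
#'
#' Each gap size contributes 16 features (the ordered base pairs); each
#' k-mer order contributes 4^k.
#'
#' @param spec a [feature_spec()].
#' @return integer, the number p of features.
#' @export
feature_dim <- function(spec) {
  as.integer(16L * length(spec$gaps) + sum(4^spec$kmers))
}

#' Column names of an encoding
#' @param spec a [feature_spec()].
#' @return character vector of length \code{feature_dim(spec)}, e.g.
#'   \code{"g1.AG"} for the pair A..G with one skipped base, \code{"k2.AG"}
#'   for the dimer AG.
#' @export
feature_names <- function(spec) {
  pair_names <- paste0(rep(DNA_BASES, each = 4L), rep(DNA_BASES, 4L))
  gap_cols <- unlist(lapply(spec$gaps, function(g)
    paste0("g", g, ".", pair_names)))
  kmer_cols <- unlist(lapply(spec$kmers, function(k)
    paste0("k", k, ".", all_kmers(k))))
  c(gap_cols, kmer_cols)
}

# All 4^k k-mers in lexicographic order (A < C < G < T).
all_kmers <- function(k) {
  out <- DNA_BASES
  if (k > 1L) for (i in 2L:k)
    out <- as.vector(t(outer(out, DNA_BASES, paste0)))
  out
}

# Map a sequence to integer base codes A=0, C=1, G=2, T=3; errors on any
# character outside the standard alphabet.
base_codes <- function(sequence) {
  raw <- utf8ToInt(sequence)
  codes <- integer(length(raw))
  codes[raw == utf8ToInt("A")] <- 0L
  codes[raw == utf8ToInt("C")] <- 1L
  codes[raw == utf8ToInt("G")] <- 2L
  codes[raw == utf8ToInt("T")] <- 3L
  known <- raw %in% utf8ToInt("ACGT")
  if (!all(known))
    stop("sequence contains non-standard base(s): ",
         paste(unique(intToUtf8(raw[!known], multiple = TRUE)),
               collapse = ","))
  codes
}

#' g-spaced base-pair composition of one sequence
#'
#' For a sequence of length N and gap size g, counts for every ordered
#' base pair (s, t) the positions i with sequence[i] = s and
#' sequence[i + g + 1] = t — i.e. exactly g bases are skipped between the
#' pair; g = 0 is the contiguous dinucleotide. Each count D_g(s, t) is
#' divided by N - 1, so the 16 values sum to max(0, N - 1 - g) / (N - 1).
#'
#' @param sequence a string over A/C/G/T, length >= 2.
#' @param g non-negative integer gap size.
#' @return named numeric vector of length 16 (pairs in lexicographic
#'   order AA, AC, ..., TT).
#' @export
gapped_pair_frequencies <- function(sequence, g) {
  stopifnot(length(sequence) == 1L, g >= 0L)
  v <- base_codes(sequence)
  n <- length(v)
  if (n < 2L)
    stop("sequence length must be >= 2 to form a base pair (got ", n, ")")
  counts <- numeric(16L)
  step <- g + 1L
  if (n > step) {
    idx <- 4L * v[seq_len(n - step)] + v[seq.int(step + 1L, n)] + 1L
    counts <- tabulate(idx, nbins = 16L)
  }
  stats::setNames(counts / (n - 1L),
                  paste0(rep(DNA_BASES, each = 4L), rep(DNA_BASES, 4L)))
}

#' Concatenated g-spaced encoding of one sequence
#'
#' @param sequence a string over A/C/G/T, length >= 2.
#' @param gaps gap sizes; blocks are concatenated in ascending-g order.
#' @return named numeric vector of length \code{16 * length(gaps)}.
#' @export
encode_gspaced <- function(sequence, gaps = 1:5) {
  gaps <- sort(unique(as.integer(gaps)))
  out <- unlist(lapply(gaps, function(g)
    gapped_pair_frequencies(sequence, g)))
  names(out) <- feature_names(feature_spec(gaps = gaps))
  out
}

#' Contiguous k-mer composition of one sequence
#'
#' Counts of the 4^k contiguous k-mers divided by the number of windows
#' N - k + 1; the values sum to 1.
#'
#' @param sequence a string over A/C/G/T with N >= k.
#' @param k positive integer k-mer order.
#' @return named numeric vector of length 4^k (lexicographic order).
#' @export
kmer_frequencies <- function(sequence, k) {
  stopifnot(length(sequence) == 1L, k >= 1L)
  base_codes(sequence)  # alphabet check
  n <- nchar(sequence)
  if (n < k) stop("sequence length ", n, " < k = ", k)
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString(sequence), width = k)
  counts / (n - k + 1L)
}

#' Encode one sequence under a feature spec
#' @param sequence a string over A/C/G/T.
#' @param spec a [feature_spec()].
#' @return named numeric vector of length \code{feature_dim(spec)}.
#' @export
encode_sequence <- function(sequence, spec) {
  parts <- list()
  if (length(spec$gaps))
    parts <- c(parts, list(encode_gspaced(sequence, spec$gaps)))
  for (k in spec$kmers)
    parts <- c(parts, list(kmer_frequencies(sequence, k)))
  out <- unlist(parts, use.names = FALSE)
  stats::setNames(out, feature_names(spec))
}

#' Encode a whole library as a feature matrix
#'
#' @param lib a validated \code{barcode_library}.
#' @param spec a [feature_spec()].
#' @return numeric matrix (records x p) with the record identifiers as row
#'   names, deterministic column names, and attributes \code{labels} (the
#'   per-row species) and \code{spec}.
#' @export
encode_dataset <- function(lib, spec = feature_spec()) {
  if (nrow(lib) == 0L) stop("cannot encode an empty library")
  p <- feature_dim(spec)
  rows <- lapply(seq_len(nrow(lib)), function(i) {
    tryCatch(encode_sequence(lib$sequence[i], spec),
             error = function(e)
               stop("record '", lib$record_id[i], "': ",
                    conditionMessage(e), call. = FALSE))
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- lib$record_id
  colnames(mat) <- feature_names(spec)
  attr(mat, "labels") <- lib$species
  attr(mat, "spec") <- spec
  mat
}

#' Export a feature matrix as TSV
#'
#' Writes one row per record: \code{record_id}, \code{species}, then the
#' p feature columns under their deterministic names.
#'
#' @param features a matrix from [encode_dataset()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_feature_tsv <- function(features, path) {
  df <- data.frame(record_id = rownames(features),
                   species = attr(features, "labels"),
                   features, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
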