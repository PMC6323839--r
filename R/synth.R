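# Seeded simulator of multi-species barcode reference libraries. Each
# species descends from an independent uniform-random ancestor (expected
# pairwise identity between species ~25% per base), and within-species
# variability is a uniform per-base substitution process (Jukes-Cantor
# flavour: a mutated base becomes one of the three other bases with equal
# probability), optionally with 1-base indels. The aim is controlled
# within- vs between-species divergence, not ITS sequence realism.

#' Simulation parameters for a synthetic reference library
#'
#' @param n_species number of species classes (>= 2 for classification).
#' @param seqs_per_species sequences emitted per species (the libraries
#'   used for k-fold evaluation carry 3-10).
#' @param length ancestor length in bases (default 600, ITS-like).
#' @param within_sub_rate per-base substitution probability applied
#'   independently to every copy of the species ancestor, in [0, 1).
#' @param indel_rate per-base probability of a 1-base insertion or
#'   deletion, in [0, 1); default 0 so Hamming-distance checks stay exact.
#' @param seed integer seed; the same seed reproduces the library exactly.
#' @param n_genera optional: number of genus-level ancestors. When set,
#'   species ancestors are mutated copies of genus ancestors (at
#'   \code{genus_sub_rate}), giving a harder two-level benchmark with
#'   related species. Default \code{NULL}: all ancestors independent.
#' @param genus_sub_rate per-base divergence of species ancestors from
#'   their genus ancestor (used only with \code{n_genera}).
#' @return a \code{sim_params} object.
#' @export
sim_params <- function(n_species = 20L, seqs_per_species = 5L,
                       length = 600L, within_sub_rate = 0.01,
                       indel_rate = 0, seed = 1L, n_genera = NULL,
                       genus_sub_rate = 0.10) {
  stopifnot(n_species >= 1L, seqs_per_species >= 1L, length >= 2L,
            within_sub_rate >= 0, within_sub_rate < 1,
            indel_rate >= 0, indel_rate < 1,
            genus_sub_rate >= 0, genus_sub_rate < 1)
  if (!is.null(n_genera)) stopifnot(n_genera >= 1L)
  structure(list(n_species = as.integer(n_species),
                 seqs_per_species = as.integer(seqs_per_species),
                 length = as.integer(length),
                 within_sub_rate = within_sub_rate,
                 indel_rate = indel_rate,
                 seed = as.integer(seed),
                 n_genera = if (!is.null(n_genera)) as.integer(n_genera),
                 genus_sub_rate = genus_sub_rate),
            class = "sim_params")
}

# Per-base substitution on a base-code vector (codes 0..3): each position
# mutates with probability `rate` to one of the three other bases.
mutate_codes <- function(codes, rate) {
  if (rate <= 0) return(codes)
  hit <- which(stats::runif(length(codes)) < rate)
  if (length(hit))
    codes[hit] <- (codes[hit] + sample.int(3L, length(hit),
                                           replace = TRUE)) %% 4L
  codes
}

# 1-base indels: each position independently deleted or followed by a
# random inserted base, each with probability rate/2.
apply_indels <- function(codes, rate) {
  if (rate <= 0) return(codes)
  u <- stats::runif(length(codes))
  del <- u < rate / 2
  ins <- u >= rate / 2 & u < rate
  out <- vector("list", length(codes))
  keep <- !del
  for (i in which(ins))
    out[[i]] <- sample.int(4L, 1L) - 1L
  merged <- unlist(mapply(function(b, extra, k) {
    c(if (k) b, extra)
  }, codes, out, keep, SIMPLIFY = FALSE))
  if (is.null(merged)) integer(0) else merged
}

codes_to_string <- function(codes) {
  paste(DNA_BASES[codes + 1L], collapse = "")
}

#' Generate a synthetic barcode reference library
#'
#' Draws one uniform-random ancestor per species and emits
#' \code{seqs_per_species} descendants by independent per-base
#' substitution (and optional indels). Species are labelled
#' \code{"sp0001"}, \code{"sp0002"}, ... and record identifiers
#' \code{"sp0001_1"} etc.; the per-species ancestors are retained in the
#' \code{ancestors} attribute for query generation.
#'
#' @param params a [sim_params()].
#' @return a \code{barcode_library} of
#'   \code{n_species * seqs_per_species} records.
#' @export
generate_library <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed, {
    sp_labels <- sprintf("sp%04d", seq_len(params$n_species))
    genus_anc <- NULL
    if (!is.null(params$n_genera)) {
      genus_anc <- lapply(seq_len(params$n_genera), function(i)
        sample.int(4L, params$length, replace = TRUE) - 1L)
      genus_of <- rep_len(seq_len(params$n_genera), params$n_species)
    }
    ancestors <- lapply(seq_len(params$n_species), function(i) {
      if (is.null(genus_anc))
        sample.int(4L, params$length, replace = TRUE) - 1L
      else
        mutate_codes(genus_anc[[genus_of[i]]], params$genus_sub_rate)
    })
    records <- lapply(seq_len(params$n_species), function(i) {
      vapply(seq_len(params$seqs_per_species), function(j) {
        codes <- mutate_codes(ancestors[[i]], params$within_sub_rate)
        codes <- apply_indels(codes, params$indel_rate)
        codes_to_string(codes)
      }, character(1))
    })
    lib <- barcode_library(
      record_id = unlist(lapply(seq_len(params$n_species), function(i)
        paste0(sp_labels[i], "_", seq_len(params$seqs_per_species)))),
      species = rep(sp_labels, each = params$seqs_per_species),
      sequence = unlist(records),
      ancestors = stats::setNames(
        vapply(ancestors, codes_to_string, character(1)), sp_labels))
    attr(lib, "params") <- params
    lib
  })
}

#' Generate labelled query sequences from a simulated library
#'
#' Emits \code{per_species} new mutants of each species' retained
#' ancestor at the given substitution rate; records carry the true
#' species label so predictions can be scored.
#'
#' @param lib a library from [generate_library()] (must carry the
#'   \code{ancestors} attribute).
#' @param per_species queries per species (>= 1).
#' @param within_sub_rate per-base substitution rate for the queries.
#' @param seed integer seed.
#' @return a \code{barcode_library} of query records with identifiers
#'   \code{"sp0001_q1"} etc.
#' @export
generate_query_set <- function(lib, per_species = 1L,
                               within_sub_rate = 0.01, seed = 1L) {
  stopifnot(per_species >= 1L, within_sub_rate >= 0, within_sub_rate < 1)
  ancestors <- attr(lib, "ancestors")
  if (is.null(ancestors))
    stop("library carries no species ancestors; generate it with ",
         "generate_library()")
  sp <- sort(unique(lib$species))
  missing <- setdiff(sp, names(ancestors))
  if (length(missing))
    stop("no ancestor retained for species: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  with_seed(seed, {
    seqs <- unlist(lapply(sp, function(s) {
      codes <- base_codes(ancestors[[s]])
      vapply(seq_len(per_species), function(j)
        codes_to_string(mutate_codes(codes, within_sub_rate)),
        character(1))
    }))
    barcode_library(
      record_id = unlist(lapply(sp, function(s)
        paste0(s, "_q", seq_len(per_species)))),
      species = rep(sp, each = per_species),
      sequence = seqs)
  })
}

#' Write the simulation provenance sidecar
#'
#' Records every generator parameter next to a simulated FASTA so the
#' library can be regenerated exactly.
#'
#' @param params a [sim_params()].
#' @param path output path for the sidecar.
#' @return \code{path}, invisibly.
#' @export
write_sim_provenance <- function(params, path) {
  fields <- params[!vapply(params, is.null, logical(1))]
  writeLines(paste0(names(fields), "\t",
                    vapply(fields, function(v) paste(v, collapse = ","),
                           character(1))), path)
  invisible(path)
}
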