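# Independent oracles and small fixture builders shared across tests.

BASES <- c("A", "C", "G", "T")
PAIRS <- paste0(rep(BASES, each = 4), rep(BASES, 4))

# Brute-force g-spaced composition: enumerate every ordered position pair
# (i, j) with j - i = g + 1 and count, then divide by N - 1. Deliberately
# naive and independent of the package's tabulation path.
brute_gapped <- function(sequence, g) {
  ch <- strsplit(sequence, "")[[1]]
  n <- length(ch)
  counts <- setNames(numeric(16), PAIRS)
  for (i in seq_len(n)) {
    j <- i + g + 1
    if (j <= n) {
      pair <- paste0(ch[i], ch[j])
      counts[pair] <- counts[pair] + 1
    }
  }
  counts / (n - 1)
}

# Brute-force k-mer composition via substring enumeration.
brute_kmer <- function(sequence, k) {
  n <- nchar(sequence)
  kmers <- vapply(seq_len(n - k + 1), function(i)
    substr(sequence, i, i + k - 1), character(1))
  lex <- BASES
  if (k > 1) for (i in 2:k) lex <- as.vector(t(outer(lex, BASES, paste0)))
  counts <- table(factor(kmers, levels = lex))
  as.numeric(counts) / (n - k + 1)
}

rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE),
                              collapse = "")

# A small in-code library: n_species species, each a block of identical
# (or near-identical) sequences -- handy where the full simulator is
# overkill.
toy_library <- function(counts, len = 60, seed = 42) {
  set.seed(seed)
  species <- rep(names(counts), counts)
  anc <- vapply(names(counts), function(s) rand_seq(len), character(1))
  barcode_library(record_id = paste0(species, "_", sequence(counts)),
                  species = species,
                  sequence = anc[species])
}

write_fasta_lines <- function(lines, path = tempfile(fileext = ".fa")) {
  writeLines(lines, path)
  path
}
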