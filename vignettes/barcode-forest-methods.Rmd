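---
title: "Methods: gapped base-pair features and random forests for barcode-based species identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gapped base-pair features and random forests for barcode-based species identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeForest)
```

## The model

`barcodeForest` treats barcode-based species identification as ordinary
multiclass supervised learning: each species in the reference library is
a class, each sequence is an observation, and a query is assigned the
label of the class that wins the most votes across a random-forest
ensemble. The pipeline makes only two substantive modelling commitments:

1. **The encoding.** A sequence is represented by where its bases sit
   relative to one another, not by an alignment. For gap size $g$, the
   feature for the ordered pair $(s, t)$ is
   $D_g(s,t)/(N-1)$, where $D_g(s,t)$ counts positions $i$ with base $s$
   at $i$ and base $t$ at $i+g+1$ — exactly $g$ bases skipped between
   the pair, so $g=0$ is the contiguous dinucleotide. Because the
   encoding is a composition, sequences of unequal length (rampant in
   ITS data) are directly comparable, and indels only perturb — rather
   than invalidate — the representation.
2. **The classifier.** A bootstrap ensemble of classification trees,
   each split drawing `mtry` candidate features. The forest is fitted by
   `randomForest::randomForest()`; what this package commits to is the
   contract (bootstrap resamples, restricted splits, out-of-bag error,
   majority vote with a deterministic tie-break), not a particular tree
   grower.

The key assumption is that within-species sequence variation is small
relative to between-species variation in the gapped-pair composition
space. That is plausible for barcodes by construction — a barcode locus
is chosen precisely because it separates species — but it is an
assumption, and the simulator below exists to probe where it breaks.

## Numerical and definitional choices

* **Gap semantics.** "$g$-spaced" means *exactly* $g$ skipped positions
  (pair $(i, i+g+1)$), not "up to $g$". Each gap size therefore
  contributes an independent 16-dimensional block.
* **Denominator $N-1$ for every gap.** Only $N-1-g$ pairs exist at gap
  $g$, so blocks with $g>0$ deliberately do not sum to 1: a single-$g$
  block sums to $\max(0, N-1-g)/(N-1)$. The formula is implemented as
  defined; the mild non-normalization is part of the feature definition,
  and tests assert the block sums exactly.
* **Column identity.** Gap blocks in ascending $g$; within a block the
  16 ordered pairs in lexicographic order (AA, AC, …, TT); k-mer blocks
  in ascending $k$, lexicographic within. Column names are deterministic
  (`g1.AG`, `k2.AG`, …) so a persisted model can refuse a query matrix
  encoded under any other spec.
* **The 80- vs 96-feature question.** The default gapped spec is
  $g = 1..5$ (80 features). The contiguous block can be added with
  `include_gap0 = TRUE`, giving 96 features — the representation whose
  default `mtry` is $\lfloor\sqrt{96}\rfloor = 9$. Both conventions are
  first-class; the default follows the five explicitly named gap sizes.
* **k-mer composition** uses the standard denominator $N-k+1$ (window
  count), computed via `Biostrings::oligonucleotideFrequency`, and sums
  to 1.
* **Integer rounding.** $\sqrt{p}$ and every term of the `mtry` grid
  $\{1, \sqrt{p}/2, \sqrt{p}, 2\sqrt{p}, 3\sqrt{p}, p/2, p\}$ are
  floored, then clamped to $[1, p]$ and de-duplicated. Flooring is the
  only integerization consistent with the stated default of 9 at
  $p = 96$.
* **Ties.** Vote ties go to the lexicographically smallest species
  label; `tune_mtry` ties go to the smallest candidate. Both choices are
  arbitrary but deterministic, which is what testing requires.
* **ntree stabilization.** The OOB curve is read incrementally from one
  growing forest (the error of the leading sub-ensemble of $t$ trees),
  and the "stabilized" size is the smallest $t$ from which every later
  error stays within 0.005 of the final error. Stabilization is often
  judged by eye; a fixed tolerance makes it computable and testable. The
  operational default remains `ntree = 500` regardless.
* **Degenerate inputs.** Sequences shorter than 2 bases cannot form a
  pair and are rejected; a gap larger than $N-2$ yields an all-zero
  block (not an error); single-class libraries refuse to train; a query
  matrix with the wrong columns refuses to predict; an all-zero query
  total is an error in `sisr()` rather than a silent `NaN`.

## Tunable parameters

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `gaps` | 1–5 | gap sizes (bases skipped); the five named sizes of the default representation |
| `include_gap0` | FALSE | add the contiguous dinucleotide block (96 features total) |
| `kmers` | none | contiguous k-mer orders for the comparison encoder (340 features for k = 1–4) |
| `ntree` | 500 | trees in the forest; the OOB curve flattens well before this |
| `mtry` | ⌊√p⌋ | candidate features per split; tuned over the seven-point grid by OOB error |
| `min_per_species` | 3 | reference-library filter: species need ≥ 3 sequences to be learnable |
| `k` (CV) | — | folds = sequences per species; each fold holds one sequence of every species |

Validation policy: for library construction, records with non-standard
bases (ambiguity codes, RNA `U`) or length < 2 are **dropped** with a
logged reason — the filter applied when assembling reference sets; for
single-record calls and query prediction the default is **reject**, so a
bad query is an explicit error naming the record rather than a silent
omission.

## What the simulator emulates — and what it does not

`generate_library()` draws one uniform-random ancestor per species
(expected pairwise identity between species ≈ 25 % per base) and emits
descendants by independent per-base substitution at `within_sub_rate`
(a mutated base becomes one of the other three uniformly), optionally
with 1-base indels. Defaults — length 600 (ITS-like), substitution rate
0.01, indels off — describe a library whose within-species divergence
(~1 %) is dwarfed by between-species divergence (~75 %), i.e. a clean
barcode marker. An optional two-level scheme (`n_genera`) derives
species ancestors from shared genus ancestors for harder, more related
classes.

This emulates the *structure* the classifier contract depends on — many
classes, few sequences per class, tunable within/between divergence —
and nothing else. It is not a coalescent simulator; it has no
phylogenetic signal by default, no compositional bias, no length
heterogeneity beyond the indel process, and no conserved/variable domain
architecture of real ITS. Passing tests on simulated libraries therefore
demonstrate that the encoder, tuning, CV accounting, and prediction
machinery are correct and that the method behaves as designed when its
core assumption holds; they do not certify accuracy on real fungal
libraries, where between-species distances can be far smaller and
label noise exists.

Indels default to off so that Hamming-distance oracles in the tests stay
exact; enabling them exercises the length-robustness of the composition
encoder.

## Evaluation design

Cross-validation is species-stratified: the library is first balanced to
exactly $k$ sequences per species (`subsample_k_per_species()`), each
species' sequences are dealt one per fold, and each fold is predicted by
a forest trained on the other $k-1$. SISR pools correct calls over
species, $\sum_h n_h / \sum_h N_h$; the reported accuracy is the mean of
the $k$ per-fold SISRs, with the sample standard deviation (denominator
$k-1$) over folds as the spread — a definitional choice, since a "±"
over folds could equally be a standard error. Species never predicted
correctly contribute $n_h = 0$; no smoothing, and no sequence-identity
pre-filtering between folds.

The test suite runs everything at desk scale, chosen so the full suite
finishes in well under a minute: simulated libraries of 2–20 species,
3–10 sequences per species, lengths 80–1000, forests of 40–200 trees;
the end-to-end accuracy checks use 20 species × 5 sequences at length
600 with ntree = 200. The bootstrap out-of-bag property is checked at
$n = 1000$ over 10 000 resamples against the $1/e \approx 36.8\,\%$
limit.

## Known limitations

* Accuracy claims transfer to real data only insofar as real
  within/between-species divergence resembles the simulated regime;
  closely related species with near-identical barcodes will confuse any
  composition-based encoder.
* No reverse-complement canonicalization: reference and query sequences
  must be on the same strand.
* No class weighting for imbalanced libraries — the CV design enforces
  balance by subsampling instead, which discards data from
  well-represented species.
* No probability calibration: vote fractions rank confidence but are
  not calibrated posterior probabilities.
* The forest is seeded and deterministic given a seed, but serialized
  models are R-version-bound binary blobs; the plain-text sidecar exists
  so a model's provenance outlives its serialization.
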