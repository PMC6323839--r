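# Species-stratified k-fold cross-validation and the SISR statistic.
# The CV design requires a balanced library (exactly k sequences per
# species); each fold then receives exactly one sequence of every
# species, so every training split holds k-1 per species.

#' Species identification success rate (SISR)
#'
#' SISR pools correct calls over species: with N_h query sequences of
#' species h and n_h of them correctly classified, SISR =
#' sum_h n_h / sum_h N_h.
#'
#' @param correct named non-negative counts n_h of correctly classified
#'   queries per species.
#' @param total named positive counts N_h of observed queries per species
#'   (same species set as \code{correct}).
#' @return SISR in [0, 1].
#' @export
sisr <- function(correct, total) {
  stopifnot(length(correct) == length(total))
  if (!is.null(names(correct)) && !is.null(names(total)))
    total <- total[names(correct)]
  if (any(correct < 0) || any(total < 0))
    stop("counts must be non-negative")
  if (any(correct > total))
    stop("correct count exceeds observed count for some species")
  if (sum(total) == 0) stop("no query sequences observed (sum N_h = 0)")
  sum(correct) / sum(total)
}

#' Build a species-stratified cross-validation plan
#'
#' Requires every species to have exactly \code{k} records (use
#' [subsample_k_per_species()] first). Each species' records are randomly
#' permuted (seeded) and dealt one per fold, so the k folds partition the
#' library and each fold holds one sequence of every species.
#'
#' @param lib a balanced \code{barcode_library}.
#' @param k number of folds = sequences per species.
#' @param seed integer seed; the same seed gives the same assignment.
#' @return a \code{cv_plan}: \code{k}, \code{fold} (integer in 1..k per
#'   record, aligned with \code{lib}), \code{seed}.
#' @export
make_folds <- function(lib, k, seed = 1L) {
  stopifnot(k >= 1L)
  tab <- species_counts(lib)
  bad <- names(tab)[tab != k]
  if (length(bad) > 0L)
    stop("species without exactly ", k, " records: ",
         paste(utils::head(bad, 5L), collapse = ", "),
         "; subsample the library first")
  fold <- integer(nrow(lib))
  with_seed(seed, {
    for (sp in sort(names(tab))) {
      rows <- which(lib$species == sp)
      fold[sample(rows)] <- seq_len(k)
    }
  })
  structure(list(k = as.integer(k), fold = fold, seed = as.integer(seed)),
            class = "cv_plan")
}

#' Run species-stratified k-fold cross-validation
#'
#' For each fold, trains on the records of the other k-1 folds and
#' predicts the held-out fold; per-fold SISR values are averaged into the
#' reported accuracy, and per-species observed/correct counts are pooled
#' over all folds.
#'
#' @param lib a balanced, validated \code{barcode_library} (exactly k
#'   records per species).
#' @param spec a [feature_spec()].
#' @param config a [forest_config()]; the fold index is added to its seed
#'   so each fold's forest is independent yet reproducible.
#' @param k number of folds = sequences per species.
#' @param seed integer seed for the fold assignment.
#' @param predictor optional function \code{(train_features, test_features,
#'   fold_seed) -> character vector} of predicted species for the test
#'   rows; defaults to the random-forest train/predict pair. Intended for
#'   testing the fold accounting with stub classifiers.
#' @return an \code{evaluation_result}: \code{per_fold_sisr} (length k),
#'   \code{mean_sisr}, \code{sd_sisr} (sample SD over folds),
#'   \code{per_species} (data frame: species, observed, correct), and
#'   \code{k}.
#' @export
run_cv <- function(lib, spec = feature_spec(), config = forest_config(),
                   k, seed = 1L, predictor = NULL) {
  plan <- make_folds(lib, k, seed)
  features <- encode_dataset(lib, spec)
  labels <- attr(features, "labels")
  if (is.null(predictor))
    predictor <- function(train_features, test_features, fold_seed) {
      model <- train_forest(train_features,
                            forest_config(config$ntree, config$mtry,
                                          fold_seed))
      predict(model, test_features)$predicted_species
    }
  species <- sort(unique(labels))
  observed <- stats::setNames(integer(length(species)), species)
  correct <- stats::setNames(integer(length(species)), species)
  per_fold <- numeric(k)
  for (f in seq_len(k)) {
    test_idx <- which(plan$fold == f)
    train_idx <- which(plan$fold != f)
    train_features <- features[train_idx, , drop = FALSE]
    attr(train_features, "labels") <- labels[train_idx]
    attr(train_features, "spec") <- spec
    test_features <- features[test_idx, , drop = FALSE]
    attr(test_features, "spec") <- spec
    pred <- predictor(train_features, test_features, config$seed + f)
    truth <- labels[test_idx]
    hits <- pred == truth
    per_fold[f] <- mean(hits)
    obs_f <- table(truth)
    hit_f <- table(truth[hits])
    observed[names(obs_f)] <- observed[names(obs_f)] + as.integer(obs_f)
    correct[names(hit_f)] <- correct[names(hit_f)] + as.integer(hit_f)
  }
  structure(list(per_fold_sisr = per_fold,
                 mean_sisr = mean(per_fold),
                 sd_sisr = stats::sd(per_fold),
                 per_species = data.frame(species = species,
                                          observed = unname(observed),
                                          correct = unname(correct),
                                          stringsAsFactors = FALSE),
                 k = as.integer(k),
                 seed = as.integer(seed)),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("%d-fold species-stratified CV: mean SISR %.4f +/- %.4f\n",
              x$k, x$mean_sisr, x$sd_sisr))
  cat(sprintf("  per-fold SISR: %s\n",
              paste(sprintf("%.4f", x$per_fold_sisr), collapse = " ")))
  invisible(x)
}

#' Write the per-species training-result table
#'
#' TSV with one row per reference species (species, observed, correct)
#' and a trailing summary row with the pooled SISR; this is the layout of
#' the tool's training-result file.
#'
#' @param result an \code{evaluation_result}, or any data frame with
#'   columns species/observed/correct plus optional \code{mean_sisr},
#'   \code{sd_sisr} values for the summary line.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_training_result <- function(result, path) {
  df <- result$per_species
  lines <- c("species\tobserved\tcorrect",
             sprintf("%s\t%d\t%d", df$species, df$observed, df$correct),
             sprintf("# pooled SISR\t%.4f\t", sisr(df$correct, df$observed)))
  if (!is.null(result$mean_sisr))
    lines <- c(lines,
               sprintf("# mean SISR over %d folds\t%.4f\t+/- %.4f",
                       result$k, result$mean_sisr, result$sd_sisr))
  writeLines(lines, path)
  invisible(path)
}
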