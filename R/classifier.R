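# Multiclass random-forest species predictor with out-of-bag (OOB) error
# as the tuning criterion. The ensemble itself is randomForest's CART
# forest (bootstrap resamples, mtry candidate features per split,
# majority vote); training, tuning, and prediction are all seeded so that
# identical inputs give identical models.

#' Forest configuration
#'
#' @param ntree number of trees (default 500, the operational optimum:
#'   OOB error stabilizes by ~400 trees and 500 leaves headroom).
#' @param mtry candidate features per split; \code{NULL} means the default
#'   rule \code{floor(sqrt(p))} applied at training time.
#' @param seed integer seed controlling the bootstrap and split streams.
#' @return a \code{forest_config} object.
#' @export
forest_config <- function(ntree = 500L, mtry = NULL, seed = 1L) {
  stopifnot(ntree >= 1L, is.null(mtry) || mtry >= 1L)
  structure(list(ntree = as.integer(ntree),
                 mtry = if (!is.null(mtry)) as.integer(mtry),
                 seed = as.integer(seed)),
            class = "forest_config")
}

#' Default mtry rule
#'
#' The square-root rule, floored: \code{floor(sqrt(p))}, never below 1.
#' For the 96-feature gapped representation this gives 9.
#'
#' @param p number of features (>= 1).
#' @return positive integer.
#' @export
default_mtry <- function(p) {
  stopifnot(p >= 1L)
  max(1L, as.integer(floor(sqrt(p))))
}

#' Candidate mtry grid
#'
#' The seven-point grid \{1, sqrt(p)/2, sqrt(p), 2*sqrt(p), 3*sqrt(p),
#' p/2, p\}, each value floored, clamped to [1, p], de-duplicated, and
#' sorted ascending.
#'
#' @param p number of features (>= 1).
#' @return increasing integer vector of candidate mtry values.
#' @export
mtry_grid <- function(p) {
  stopifnot(p >= 1L)
  s <- sqrt(p)
  vals <- floor(c(1, s / 2, s, 2 * s, 3 * s, p / 2, p))
  vals <- pmin(pmax(as.integer(vals), 1L), as.integer(p))
  sort(unique(vals))
}

#' Train the species classifier
#'
#' Fits a bootstrap ensemble of \code{ntree} classification trees on the
#' encoded library; each split examines \code{mtry} randomly drawn
#' features. The out-of-bag error (each record scored only by the trees
#' whose bootstrap resample excluded it) is stored as the model's internal
#' error estimate.
#'
#' @param features a matrix from [encode_dataset()] with at least two
#'   distinct species labels.
#' @param config a [forest_config()].
#' @return a \code{barcode_rf} model: the fitted forest, the ordered class
#'   labels, the configuration (with mtry resolved), the OOB error, the
#'   feature spec, and the per-tree OOB error curve.
#' @export
train_forest <- function(features, config = forest_config()) {
  labels <- attr(features, "labels")
  if (is.null(labels)) stop("feature matrix carries no species labels")
  if (length(unique(labels)) < 2L)
    stop("training requires at least 2 distinct species (got ",
         length(unique(labels)), ")")
  p <- ncol(features)
  mtry <- if (is.null(config$mtry)) default_mtry(p) else config$mtry
  if (mtry > p) stop("mtry (", mtry, ") exceeds the number of features (",
                     p, ")")
  y <- factor(labels)  # levels sorted: deterministic class order
  forest <- with_seed(config$seed,
    randomForest::randomForest(x = features, y = y, ntree = config$ntree,
                               mtry = mtry))
  oob_curve <- unname(forest$err.rate[, "OOB"])
  structure(list(forest = forest,
                 class_labels = levels(y),
                 config = forest_config(config$ntree, mtry, config$seed),
                 oob_error = oob_curve[config$ntree],
                 oob_curve = oob_curve,
                 feature_spec = attr(features, "spec")),
            class = "barcode_rf")
}

#' @export
print.barcode_rf <- function(x, ...) {
  cat(sprintf(paste0("Barcode random forest: %d species, %d features, ",
                     "ntree=%d, mtry=%d\n  OOB error: %.4f\n"),
              length(x$class_labels), length(feature_names(x$feature_spec)),
              x$config$ntree, x$config$mtry, x$oob_error))
  invisible(x)
}

#' Predict species for encoded query sequences
#'
#' Each tree votes for one species; a query is assigned the species with
#' the most votes, ties broken toward the lexicographically smallest
#' label. The winning vote fraction (votes for the winner over all trees)
#' accompanies each call.
#'
#' @param object a \code{barcode_rf} model.
#' @param features a matrix encoded with the model's own feature spec
#'   (same columns, same order).
#' @param ... unused.
#' @return data frame with columns \code{record_id},
#'   \code{predicted_species}, \code{vote_fraction}.
#' @export
predict.barcode_rf <- function(object, features, ...) {
  expected <- feature_names(object$feature_spec)
  if (!identical(colnames(features), expected))
    stop("feature columns do not match the model (expected ",
         length(expected), " columns encoded with the model's feature ",
         "spec)")
  votes <- stats::predict(object$forest, newdata = features, type = "vote",
                          norm.votes = TRUE)
  votes <- votes[, sort(colnames(votes)), drop = FALSE]
  win <- apply(votes, 1L, which.max)  # first max = smallest label
  data.frame(record_id = rownames(features),
             predicted_species = colnames(votes)[win],
             vote_fraction = votes[cbind(seq_len(nrow(votes)), win)],
             stringsAsFactors = FALSE)
}

#' Tune the forest size by the OOB error curve
#'
#' Grows one forest of \code{max_trees} trees and reads the OOB error of
#' every leading sub-ensemble (1..max_trees trees) from its incremental
#' error curve. The "best" size is the stabilization point: the smallest
#' t such that every error from t onward is within \code{tol} of the
#' error at \code{max_trees}.
#'
#' @param features a matrix from [encode_dataset()].
#' @param max_trees largest forest size examined (default 500).
#' @param mtry candidate features per split (\code{NULL}: default rule).
#' @param seed integer seed.
#' @param tol stabilization tolerance on the OOB error (default 0.005).
#' @return a \code{tuning_result}: \code{grid} (data frame of ntree and
#'   oob_error, one row per forest size) and \code{best}.
#' @export
tune_ntree <- function(features, max_trees = 500L, mtry = NULL, seed = 1L,
                       tol = 0.005) {
  model <- train_forest(features,
                        forest_config(ntree = max_trees, mtry = mtry,
                                      seed = seed))
  curve <- model$oob_curve
  final <- curve[max_trees]
  stable <- rev(cumprod(rev(abs(curve - final) <= tol))) == 1
  best <- which(stable)[1L]
  structure(list(grid = data.frame(ntree = seq_len(max_trees),
                                   oob_error = curve),
                 best = best,
                 criterion = "oob_stabilization"),
            class = "tuning_result")
}

#' Tune mtry over the seven-point grid
#'
#' Trains one forest per candidate in [mtry_grid()], all with the same
#' number of trees and seed, and selects the candidate with the lowest
#' OOB error (ties toward the smallest candidate).
#'
#' @param features a matrix from [encode_dataset()].
#' @param ntree forest size used for every candidate (default 500).
#' @param seed integer seed.
#' @return a \code{tuning_result}: \code{grid} (data frame of mtry and
#'   oob_error) and \code{best}.
#' @export
tune_mtry <- function(features, ntree = 500L, seed = 1L) {
  grid <- mtry_grid(ncol(features))
  oob <- vapply(grid, function(m) {
    train_forest(features,
                 forest_config(ntree = ntree, mtry = m,
                               seed = seed))$oob_error
  }, numeric(1))
  structure(list(grid = data.frame(mtry = grid, oob_error = oob),
                 best = grid[which.min(oob)],
                 criterion = "min_oob"),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  par <- names(x$grid)[1L]
  cat(sprintf("Tuning over %s (%d values): best %s = %d\n",
              par, nrow(x$grid), par, x$best))
  invisible(x)
}

#' Persist a trained model
#'
#' Writes the model as a serialized blob plus a plain-text sidecar
#' (\code{<path>.txt}) recording the feature spec, class labels,
#' configuration, and OOB error, so a prediction run is reproducible and
#' auditable across sessions.
#'
#' @param model a \code{barcode_rf}.
#' @param path output path for the model file.
#' @return \code{path}, invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  sidecar <- paste0(path, ".txt")
  lines <- c(
    paste0("package_version\t", as.character(utils::packageVersion("barcodeForest"))),
    paste0("gaps\t", paste(model$feature_spec$gaps, collapse = ",")),
    paste0("kmers\t", paste(model$feature_spec$kmers, collapse = ",")),
    paste0("n_features\t", feature_dim(model$feature_spec)),
    paste0("ntree\t", model$config$ntree),
    paste0("mtry\t", model$config$mtry),
    paste0("seed\t", model$config$seed),
    paste0("oob_error\t", format(model$oob_error, digits = 10)),
    paste0("n_species\t", length(model$class_labels)),
    paste0("species\t", paste(model$class_labels, collapse = "|")))
  writeLines(lines, sidecar)
  invisible(path)
}

#' Load a persisted model
#' @param path path written by [save_model()].
#' @return a \code{barcode_rf}.
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "barcode_rf"))
    stop("file does not contain a barcode_rf model: ", path)
  model
}

#' Simulate the out-of-bag fraction of bootstrap resampling
#'
#' Each tree of the forest is grown on a bootstrap resample of the n
#' training records; on average a fraction (1 - 1/n)^n -> 1/e (~36.8%)
#' of records are absent from a resample and serve as that tree's
#' out-of-bag test set. This utility measures the fraction empirically.
#'
#' @param n number of records per resample.
#' @param reps number of bootstrap resamples.
#' @param seed integer seed.
#' @return mean fraction of records absent from a resample, in [0, 1].
#' @export
oob_fraction <- function(n = 1000L, reps = 10000L, seed = 1L) {
  with_seed(seed, {
    mean(vapply(seq_len(reps), function(i) {
      1 - length(unique(sample.int(n, n, replace = TRUE))) / n
    }, numeric(1)))
  })
}
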