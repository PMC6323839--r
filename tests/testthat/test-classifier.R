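test_that("default mtry follows the floored square-root rule", {
  expect_equal(default_mtry(96), 9L)   # the 96-feature representation
  expect_equal(default_mtry(81), 9L)
  expect_equal(default_mtry(80), 8L)
  expect_equal(default_mtry(1), 1L)
})

test_that("the mtry grid is floored, clamped, de-duplicated, ascending", {
  expect_equal(mtry_grid(96), c(1L, 4L, 9L, 19L, 29L, 48L, 96L))
  expect_equal(mtry_grid(4), c(1L, 2L, 4L))
  expect_equal(mtry_grid(1), 1L)
  for (p in c(2, 16, 80, 340)) {
    g <- mtry_grid(p)
    expect_true(all(diff(g) > 0) && min(g) >= 1 && max(g) <= p)
  }
})

test_that("training separable species yields a low-OOB deterministic model", {
  lib <- generate_library(sim_params(n_species = 2, seqs_per_species = 10,
                                     length = 300, within_sub_rate = 0.02,
                                     seed = 21))
  fm <- encode_dataset(lib, feature_spec())
  m <- train_forest(fm, forest_config(ntree = 100, seed = 4))
  expect_lte(m$oob_error, 0.1)
  expect_true(m$oob_error >= 0 && m$oob_error <= 1)
  expect_equal(m$class_labels, c("sp0001", "sp0002"))
  expect_equal(m$config$mtry, default_mtry(80))

  # same seed twice: bit-identical OOB error and curve
  m2 <- train_forest(fm, forest_config(ntree = 100, seed = 4))
  expect_identical(m$oob_error, m2$oob_error)
  expect_identical(m$oob_curve, m2$oob_curve)

  # degenerate inputs
  one <- fm[attr(fm, "labels") == "sp0001", ]
  attr(one, "labels") <- rep("sp0001", nrow(one))
  attr(one, "spec") <- feature_spec()
  expect_error(train_forest(one), "at least 2 distinct species")
  expect_error(train_forest(fm, forest_config(mtry = 81)), "exceeds")
})

test_that("prediction returns in-vocabulary labels with vote fractions", {
  lib <- generate_library(sim_params(n_species = 4, seqs_per_species = 8,
                                     length = 300, within_sub_rate = 0.01,
                                     seed = 8))
  fm <- encode_dataset(lib, feature_spec())
  m <- train_forest(fm, forest_config(ntree = 100, seed = 2))
  pred <- predict(m, fm)
  expect_equal(nrow(pred), nrow(fm))
  expect_true(all(pred$predicted_species %in% m$class_labels))
  expect_true(all(pred$vote_fraction >= 0 & pred$vote_fraction <= 1))
  # cleanly separable training rows: own species with a majority of votes
  expect_equal(pred$predicted_species, attr(fm, "labels"))
  expect_true(all(pred$vote_fraction > 0.5))

  wrong <- encode_dataset(lib, feature_spec(gaps = 1:3))
  expect_error(predict(m, wrong), "do not match")
})

test_that("vote fractions over all classes sum to one per query", {
  lib <- generate_library(sim_params(n_species = 3, seqs_per_species = 5,
                                     length = 200, within_sub_rate = 0.05,
                                     seed = 31))
  fm <- encode_dataset(lib, feature_spec())
  m <- train_forest(fm, forest_config(ntree = 51, seed = 1))
  votes <- predict(m$forest, newdata = fm, type = "vote")
  expect_equal(unname(rowSums(votes)), rep(1, nrow(fm)))
})

test_that("ntree tuning exposes the incremental OOB curve and its plateau", {
  lib <- generate_library(sim_params(n_species = 5, seqs_per_species = 6,
                                     length = 250, within_sub_rate = 0.05,
                                     seed = 13))
  fm <- encode_dataset(lib, feature_spec())
  tr <- tune_ntree(fm, max_trees = 120, seed = 5)
  expect_equal(nrow(tr$grid), 120L)
  expect_true(tr$best >= 1 && tr$best <= 120)
  # everything from the stabilization point onward stays within tolerance
  tail_err <- tr$grid$oob_error[tr$best:120]
  expect_true(all(abs(tail_err - tr$grid$oob_error[120]) <= 0.005))

  # degenerate single-tree sweep
  t1 <- tune_ntree(fm, max_trees = 1, seed = 5)
  expect_equal(nrow(t1$grid), 1L)
  expect_equal(t1$best, 1L)

  # ensemble averaging: final OOB error no worse than the single-tree
  # error, across several seeds
  improved <- vapply(1:5, function(s) {
    cur <- tune_ntree(fm, max_trees = 80, seed = s)$grid$oob_error
    cur[80] <= cur[1]
  }, logical(1))
  expect_true(all(improved))
})

test_that("mtry tuning scans the grid and returns its argmin", {
  lib <- generate_library(sim_params(n_species = 5, seqs_per_species = 5,
                                     length = 200, within_sub_rate = 0.08,
                                     seed = 17))
  fm <- encode_dataset(lib, feature_spec())
  tr <- tune_mtry(fm, ntree = 60, seed = 3)
  expect_equal(tr$grid$mtry, mtry_grid(80))
  expect_true(tr$best %in% tr$grid$mtry)
  expect_equal(min(tr$grid$oob_error),
               tr$grid$oob_error[tr$grid$mtry == tr$best])
})

test_that("bootstrap resampling leaves about 1/e of records out of bag", {
  # modest size here; the full-scale check lives in the acceptance suite
  frac <- oob_fraction(n = 500, reps = 2000, seed = 9)
  expect_equal(frac, exp(-1), tolerance = 0.02)
  expect_identical(frac, oob_fraction(n = 500, reps = 2000, seed = 9))
})

test_that("a persisted model predicts identically after reload", {
  lib <- generate_library(sim_params(n_species = 3, seqs_per_species = 4,
                                     length = 150, within_sub_rate = 0.01,
                                     seed = 2))
  fm <- encode_dataset(lib, feature_spec(gaps = 1:3))
  m <- train_forest(fm, forest_config(ntree = 60, seed = 6))
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(predict(m2, fm), predict(m, fm))
  sidecar <- readLines(paste0(path, ".txt"))
  expect_true(any(grepl("^mtry\t", sidecar)))
  expect_true(any(grepl("^oob_error\t", sidecar)))
})
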