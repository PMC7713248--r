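test_that("baseline classifier separates a separable synthetic set", {
  set.seed(1)
  crops <- c(lapply(1:10, function(i) synth_crop(TRUE, i, 32)),
             lapply(11:20, function(i) synth_crop(FALSE, i, 32)))
  labels <- rep(c(TRUE, FALSE), each = 10)
  model <- suppressMessages(train_baseline(crops, labels))
  sc <- predict_baseline(model, crops)
  expect_equal(mean((sc >= 0.5) == labels), 1)
})

test_that("training is deterministic and validates its inputs", {
  crops <- c(lapply(1:6, function(i) synth_crop(TRUE, i, 32)),
             lapply(7:12, function(i) synth_crop(FALSE, i, 32)))
  labels <- rep(c(TRUE, FALSE), each = 6)
  m1 <- suppressMessages(train_baseline(crops, labels))
  m2 <- suppressMessages(train_baseline(crops, labels))
  expect_identical(predict_baseline(m1, crops), predict_baseline(m2, crops))
  expect_error(suppressMessages(train_baseline(crops, rep(TRUE, 12))),
               "both classes")
  expect_error(experiment_config(learning_rate = 0.5))
})

test_that("study-shaped experiment runs end to end with augmented counts", {
  ds <- study_shaped_crops(seed = 3, size = 32)
  aug_n <- augment(ds$train$crops[ds$train$labels],
                   augmentation_plan("nodular"))
  aug_b <- augment(ds$train$crops[!ds$train$labels],
                   augmentation_plan("non_nodular"))
  expect_length(aug_n, 256)
  expect_length(aug_b, 272)
  model <- suppressMessages(train_baseline(
    c(aug_n, aug_b),
    rep(c(TRUE, FALSE), c(256, 272))))
  m <- evaluate(predict_baseline(model, ds$test$crops), ds$test$labels)
  expect_equal(m$n, 25)
  expect_true(is.finite(m$accuracy))
  expect_true(!is.na(m$auc_roc))
  # the synthetic classes are genuinely learnable
  expect_gt(m$auc_roc, 0.7)
})

test_that("run_pipeline writes a deterministic results layout", {
  cfg <- list(n_patients = 8, nodular_fraction = 0.5, seed = 9,
              synth = list(width = 320, height = 240,
                           roi_semi = c(125, 90), nodule_semi = c(16, 11),
                           nodule_offset = c(-40, -15), delta_t = 1.2))
  out1 <- withr::local_tempdir()
  r1 <- suppressMessages(run_pipeline(cfg, out1))
  expect_true(file.exists(file.path(out1, "regions.json")))
  expect_true(file.exists(file.path(out1, "log.txt")))
  expect_false(is.null(r1$metrics))
  expect_true(file.exists(file.path(out1, "metrics.json")))
  doc <- jsonlite::read_json(file.path(out1, "metrics.json"))
  expect_true(all(c("tp", "fp", "fn", "tn", "accuracy", "precision",
                    "recall", "auc_roc", "auc_pr") %in% names(doc)))
  # rerun determinism: byte-identical metrics
  out2 <- withr::local_tempdir()
  suppressMessages(run_pipeline(cfg, out2))
  expect_identical(readLines(file.path(out1, "metrics.json")),
                   readLines(file.path(out2, "metrics.json")))
  # JSON config file input
  cfg_path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE)
  out3 <- withr::local_tempdir()
  r3 <- suppressMessages(run_pipeline(cfg_path, out3))
  expect_identical(readLines(file.path(out1, "metrics.json")),
                   readLines(file.path(out3, "metrics.json")))
})

test_that("symmetric null data yields zero candidates and no metrics", {
  cfg <- list(n_patients = 2, nodular_fraction = 0, seed = 4,
              synth = list(width = 320, height = 240,
                           roi_semi = c(125, 90), delta_t = 0,
                           benign_spots = 0, sigma = 0, drift_amp = 0))
  out <- withr::local_tempdir()
  r <- suppressMessages(run_pipeline(cfg, out))
  expect_null(r$metrics)
  expect_length(unlist(r$regions_per_patient), 0)
  expect_identical(jsonlite::read_json(file.path(out, "regions.json")),
                   list())
})
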