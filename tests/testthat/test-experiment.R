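small_sweep_config <- function(out_dir = NULL, seed = 21) {
  experiment_config(
    recordings = synthetic_config(n_channels = 2, fs = 200,
                                  movement_classes = 1:3,
                                  movement_s = 1, rest_s = 0.5, seed = 13),
    n_subjects = 2,
    window_ms_list = c(100, 200),
    threshold = 1e-3,
    classifier = list(epochs = 6, batch_size = 128),
    out_dir = out_dir,
    seed = seed)
}

test_that("a sweep produces one evaluated cell per subject and window size", {
  sw <- run_experiment(small_sweep_config())
  expect_s3_class(sw, "emg_sweep")
  expect_length(sw$cells, 4)
  for (cell in sw$cells) {
    expect_null(cell$error)
    expect_s3_class(cell$report, "emg_eval")
    expect_true(all(c(cell$report$overall_accuracy, cell$report$macro_recall,
                      cell$report$macro_precision, cell$report$macro_f1) >= 0))
  }
  # stride rule: 50 ms for the 100 ms window, 100 ms otherwise
  strides <- vapply(sw$cells, `[[`, numeric(1), "stride_ms")
  windows <- vapply(sw$cells, `[[`, numeric(1), "window_ms")
  expect_equal(strides[windows == 100], rep(50, sum(windows == 100)))
  expect_equal(strides[windows == 200], rep(100, sum(windows == 200)))
})

test_that("aggregate means are recomputable from the per-subject cells", {
  sw <- run_experiment(small_sweep_config())
  for (w in unique(sw$aggregate$window_ms)) {
    accs <- vapply(Filter(function(c) c$window_ms == w, sw$cells),
                   function(c) c$report$overall_accuracy, numeric(1))
    row <- sw$aggregate[sw$aggregate$window_ms == w, ]
    expect_equal(row$overall_accuracy_mean, mean(accs), tolerance = 1e-12)
    expect_equal(row$overall_accuracy_sd, sd(accs), tolerance = 1e-12)
    expect_equal(row$n_subjects, 2)
  }
})

test_that("sweeps are exactly reproducible under the master seed", {
  sw1 <- run_experiment(small_sweep_config(seed = 77))
  sw2 <- run_experiment(small_sweep_config(seed = 77))
  for (i in seq_along(sw1$cells)) {
    expect_identical(sw1$cells[[i]]$report$confusion,
                     sw2$cells[[i]]$report$confusion)
    expect_identical(sw1$cells[[i]]$report$macro_recall,
                     sw2$cells[[i]]$report$macro_recall)
  }
  expect_identical(sw1$aggregate, sw2$aggregate)
})

test_that("cells write JSON artifacts when an output directory is given", {
  dir <- withr::local_tempdir()
  sw <- run_experiment(small_sweep_config(out_dir = dir))
  files <- list.files(dir, pattern = "^cell_.*json$")
  expect_length(files, 4)
  j <- jsonlite::fromJSON(file.path(dir, files[1]))
  expect_true(all(c("overall_accuracy", "macro_recall", "confusion") %in%
                  names(j)))
})

test_that("standardizer statistics come from training repetitions only", {
  cfg <- small_sweep_config()
  cfg$window_ms_list <- 200
  cfg$recordings <- cfg$recordings[1]
  rec <- cfg$recordings[[1]]
  ws <- segment(rec, 200, 100)
  sp <- split_by_repetition(ws, cfg$train_reps, cfg$test_reps)
  tr_tab <- extract_features(sp$train, cfg$threshold)
  std <- fit_standardizer(tr_tab)
  z <- apply_standardizer(std, tr_tab)
  expect_lt(max(abs(colMeans(z$values))), 1e-9)

  # perturbing only samples strictly interior to test-repetition movement
  # blocks must leave the trained model untouched
  margin <- 40L  # one full 200 ms window at 200 Hz
  interior_test <- function(recording) {
    is_test <- recording$stimulus > 0L & recording$repetition %in% cfg$test_reps
    r <- rle(is_test)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    idx <- integer(0)
    for (b in which(r$values)) {
      lo <- starts[b] + margin; hi <- ends[b] - margin
      if (lo <= hi) idx <- c(idx, lo:hi)
    }
    idx
  }
  rec2 <- rec
  idx <- interior_test(rec2)
  expect_gt(length(idx), 0)
  rec2$emg[idx, ] <- rec2$emg[idx, ] * 10
  # the training split and its standardizer are bitwise unchanged: nothing
  # from the test repetitions influenced fitting
  ws2 <- segment(rec2, 200, 100)
  sp2 <- split_by_repetition(ws2, cfg$train_reps, cfg$test_reps)
  tr_tab2 <- extract_features(sp2$train, cfg$threshold)
  expect_identical(tr_tab2$values, tr_tab$values)
  expect_identical(fit_standardizer(tr_tab2), std)
  # while the test split did change
  te1 <- extract_features(sp$test, cfg$threshold)
  te2 <- extract_features(sp2$test, cfg$threshold)
  expect_false(identical(te1$values, te2$values))
})

test_that("the SHAP subset pipeline reduces the class set to seven", {
  cfg <- experiment_config(
    recordings = synthetic_config(n_channels = 2, fs = 200,
                                  movement_classes = shap_classes(),
                                  movement_s = 1, rest_s = 0.5, seed = 31),
    n_subjects = 1,
    window_ms_list = 200,
    threshold = 1e-3,
    classifier = list(epochs = 6, batch_size = 128),
    seed = 3)
  sw <- shap_subset_experiment(cfg)
  rep1 <- sw$cells[[1]]$report
  expect_equal(nrow(rep1$confusion), 7)  # six grasps + rest
  expect_setequal(as.integer(rep1$class_list), c(0, shap_classes()))
})

test_that("a missing SHAP class aborts the cell with a config message", {
  cfg <- experiment_config(
    recordings = synthetic_config(n_channels = 2, fs = 200,
                                  movement_classes = 1:3,
                                  movement_s = 1, rest_s = 0.5, seed = 31),
    window_ms_list = 200,
    threshold = 1e-3,
    classifier = list(epochs = 2),
    seed = 3)
  sw <- shap_subset_experiment(cfg)
  expect_false(is.null(sw$cells[[1]]$error))
  expect_match(sw$cells[[1]]$error, "absent")
})

test_that("balanced accuracy does not degrade with larger windows", {
  # moderate SNR so that longer windows genuinely reduce the variance of the
  # amplitude-feature estimates instead of saturating at the ceiling
  cfg <- experiment_config(
    recordings = synthetic_config(
      n_channels = 2, fs = 200, movement_classes = 1:3,
      movement_s = 2, rest_s = 1,
      activation = rbind(c(0.5, 0.1), c(0.1, 0.5), c(0.35, 0.35)),
      envelope_jitter_sd = 0.05, seed = 61),
    n_subjects = 2,
    window_ms_list = c(100, 400),
    threshold = 1e-3,
    classifier = list(epochs = 15, batch_size = 128),
    seed = 9)
  sw <- run_experiment(cfg)
  agg <- sw$aggregate
  small_w <- agg$macro_recall_mean[agg$window_ms == 100]
  large_w <- agg$macro_recall_mean[agg$window_ms == 400]
  expect_gte(large_w, small_w - 2)
})
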