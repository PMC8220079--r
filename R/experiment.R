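#' Configuration for an experiment sweep
#'
#' Describes a full sweep over subjects and decision-window sizes: for each
#' (subject, window) cell the pipeline segments, splits by repetition,
#' extracts features, fits the standardizer on the training split only,
#' trains one classifier per subject and evaluates on the held-out
#' repetitions. The default window list is 100, 200, 400, 800 and 1000 ms
#' with a 100 ms stride (50 ms for the 100 ms window).
#'
#' @param recordings List of [emg_recording()] objects (one per subject), or
#'   a [synthetic_config()] plus `n_subjects` to generate them.
#' @param n_subjects Number of synthetic subjects when `recordings` is a
#'   config.
#' @param window_ms_list Window sizes in ms.
#' @param stride_rule Function window_ms -> stride_ms; the default returns
#'   100 except 50 for the 100 ms window.
#' @param channel_index Channels used (default all).
#' @param threshold Noise threshold, or `"search"` to run
#'   [threshold_search()] on the training repetitions of each subject.
#' @param movements `"all"`, `"shap"` (the six SHAP prehensile classes), or
#'   an explicit label vector.
#' @param include_rest Keep rest windows when filtering movements.
#' @param train_reps,test_reps Repetition split (defaults {1,3,4,6} /
#'   {2,5}).
#' @param classifier Named list of [emg_dnn()] arguments.
#' @param exclude_rest_metrics Exclude the rest class at evaluation time.
#' @param out_dir Optional directory for per-cell JSON artifacts.
#' @param seed Master seed.
#' @return An object of class `emg_experiment_config`.
#' @export
experiment_config <- function(recordings, n_subjects = NULL,
                              window_ms_list = c(100, 200, 400, 800, 1000),
                              stride_rule = default_stride_rule,
                              channel_index = NULL,
                              threshold = 0.01,
                              movements = "all",
                              include_rest = TRUE,
                              train_reps = c(1, 3, 4, 6),
                              test_reps = c(2, 5),
                              classifier = list(),
                              exclude_rest_metrics = FALSE,
                              out_dir = NULL,
                              seed = 1L) {
  if (inherits(recordings, "emg_synth_config")) {
    if (is.null(n_subjects)) n_subjects <- 1L
    recordings <- generate_dataset(recordings, n_subjects)
  }
  if (inherits(recordings, "emg_recording")) recordings <- list(recordings)
  structure(
    list(recordings = recordings, window_ms_list = window_ms_list,
         stride_rule = stride_rule, channel_index = channel_index,
         threshold = threshold, movements = movements,
         include_rest = include_rest,
         train_reps = train_reps, test_reps = test_reps,
         classifier = classifier,
         exclude_rest_metrics = exclude_rest_metrics,
         out_dir = out_dir, seed = as.integer(seed)),
    class = "emg_experiment_config")
}

#' Stride rule used throughout: 100 ms, except 50 ms at the 100 ms window
#' size.
#'
#' @param window_ms Window size in ms.
#' @return Stride in ms.
#' @export
default_stride_rule <- function(window_ms) if (window_ms <= 100) 50 else 100

movement_subset <- function(movements, ws) {
  if (identical(movements, "all")) return(ws)
  keep <- if (identical(movements, "shap")) shap_classes() else as.integer(movements)
  missing <- setdiff(keep, unique(ws$labels))
  if (length(missing))
    emg_config_error(paste("movement classes absent from the data:",
                           paste(missing, collapse = " ")))
  filter_movements(ws, keep, include_rest = TRUE)
}

#' Run a full experiment sweep
#'
#' One model is trained per (subject, window size) cell — per-subject
#' modelling, matching per-participant training — and evaluated on the
#' held-out repetitions. Standardizer statistics and (when requested) the
#' noise-threshold search use only training repetitions, so no evaluation
#' data leaks into fitting. The run is deterministic given the master seed:
#' each cell's classifier seed is derived reproducibly from it.
#'
#' @param config An [experiment_config()].
#' @param verbose Print one line per completed cell.
#' @return An object of class `emg_sweep`: `cells` (list of per-cell
#'   results with `subject`, `window_ms`, `report`, or `error`), and
#'   `aggregate` (data.frame of mean and SD across subjects per window
#'   size for each metric).
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "emg_experiment_config"))
  if (!is.null(config$out_dir))
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  cell_seeds <- matrix(
    sample.int(2147483646L,
               length(config$recordings) * length(config$window_ms_list)),
    nrow = length(config$recordings))

  cells <- list()
  for (si in seq_along(config$recordings)) {
    rec <- config$recordings[[si]]
    for (wi in seq_along(config$window_ms_list)) {
      wms <- config$window_ms_list[wi]
      sms <- config$stride_rule(wms)
      cell <- tryCatch({
        ws <- segment(rec, wms, sms, config$channel_index)
        ws <- movement_subset(config$movements, ws)
        sp <- split_by_repetition(ws, config$train_reps, config$test_reps)

        thr <- config$threshold
        if (identical(thr, "search")) {
          inner <- setdiff(config$train_reps, max(config$train_reps))
          search <- threshold_search(
            rec, wms, sms,
            inner_train_reps = inner,
            score_reps = max(config$train_reps),
            spec = config$classifier)
          thr <- search$selected
        }

        train_tab <- extract_features(sp$train, thr)
        test_tab <- extract_features(sp$test, thr)
        std <- fit_standardizer(train_tab)
        args <- c(list(x = train_tab, standardizer = std),
                  config$classifier)
        args$seed <- cell_seeds[si, wi]
        model <- do.call(emg_dnn, args)
        report <- evaluate(model, test_tab,
                           exclude_rest = config$exclude_rest_metrics)
        if (verbose)
          message(sprintf("subject %d, %g ms: accuracy %.2f, balanced %.2f",
                          si, wms, report$overall_accuracy,
                          report$macro_recall))
        list(subject = si, window_ms = wms, stride_ms = sms,
             threshold = thr, report = report, error = NULL)
      }, error = function(e) {
        list(subject = si, window_ms = wms, stride_ms = sms,
             threshold = NA_real_, report = NULL,
             error = conditionMessage(e))
      })
      cells[[length(cells) + 1L]] <- cell
      if (!is.null(config$out_dir) && is.null(cell$error))
        jsonlite::write_json(
          report_to_list(cell$report,
                         subject = si, window_ms = wms, threshold = cell$threshold),
          file.path(config$out_dir,
                    sprintf("cell_s%d_w%g.json", si, wms)),
          auto_unbox = TRUE, digits = NA)
    }
  }

  structure(list(cells = cells, aggregate = aggregate_cells(cells),
                 config = config),
            class = "emg_sweep")
}

aggregate_cells <- function(cells) {
  ok <- Filter(function(c) is.null(c$error), cells)
  if (!length(ok))
    return(data.frame(window_ms = numeric(0)))
  df <- do.call(rbind, lapply(ok, function(c) data.frame(
    subject = c$subject, window_ms = c$window_ms,
    overall_accuracy = c$report$overall_accuracy,
    macro_recall = c$report$macro_recall,
    macro_precision = c$report$macro_precision,
    macro_f1 = c$report$macro_f1)))
  agg <- lapply(split(df, df$window_ms), function(d) {
    metrics <- c("overall_accuracy", "macro_recall", "macro_precision",
                 "macro_f1")
    out <- data.frame(window_ms = d$window_ms[1], n_subjects = nrow(d))
    for (m in metrics) {
      out[[paste0(m, "_mean")]] <- mean(d[[m]])
      out[[paste0(m, "_sd")]] <- stats::sd(d[[m]])
    }
    out
  })
  res <- do.call(rbind, agg)
  rownames(res) <- NULL
  res[order(res$window_ms), ]
}

report_to_list <- function(report, ...) {
  c(list(...),
    list(overall_accuracy = report$overall_accuracy,
         macro_recall = report$macro_recall,
         macro_precision = report$macro_precision,
         macro_f1 = report$macro_f1,
         per_class_recall = as.list(report$per_class_recall),
         recall_bands = report$recall_bands,
         confusion = unname(apply(report$confusion, 1, as.list))))
}

#' @export
print.emg_sweep <- function(x, ...) {
  n_err <- sum(vapply(x$cells, function(c) !is.null(c$error), logical(1)))
  cat(sprintf("Experiment sweep: %d cells (%d failed)\n",
              length(x$cells), n_err))
  print(x$aggregate, digits = 4)
  invisible(x)
}

#' Run the sweep restricted to the six SHAP prehensile movements
#'
#' Identical pipeline to [run_experiment()] on the window subset of classes
#' 27 (power sphere), 26 (writing tripod), 31 (prismatic pinch), 18 (large
#' diameter), 34 (lateral) and 36 (extension type), plus rest.
#'
#' @param config An [experiment_config()]; its movement subset is replaced
#'   by the SHAP classes.
#' @param verbose Passed through.
#' @return An `emg_sweep`.
#' @export
shap_subset_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "emg_experiment_config"))
  config$movements <- "shap"
  run_experiment(config, verbose = verbose)
}

#' Serialize an evaluation report as JSON
#'
#' @param report An `emg_eval` report.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "emg_eval"))
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
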