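#' Confusion matrix over an explicit class list
#'
#' Entry (i, j) counts samples whose true class is `class_list[i]` and
#' predicted class is `class_list[j]`.
#'
#' @param y_true,y_pred Equal-length integer label vectors; every label must
#'   be in `class_list`.
#' @param class_list Class labels ordering the rows/columns (default: sorted
#'   union of observed labels).
#' @return Integer `K x K` matrix with dimnames, rows = truth.
#' @export
confusion_matrix <- function(y_true, y_pred, class_list = NULL) {
  if (length(y_true) != length(y_pred))
    emg_input_error("y_true and y_pred must have equal length")
  if (is.null(class_list)) class_list <- sort(unique(c(y_true, y_pred)))
  if (!all(y_true %in% class_list) || !all(y_pred %in% class_list))
    emg_input_error("labels outside the class list")
  K <- length(class_list)
  cm <- matrix(0L, K, K, dimnames = list(truth = class_list,
                                         prediction = class_list))
  for (i in seq_along(y_true)) {
    r <- match(y_true[i], class_list)
    c <- match(y_pred[i], class_list)
    cm[r, c] <- cm[r, c] + 1L
  }
  cm
}

#' Imbalance-aware classification metrics from a confusion matrix
#'
#' Overall accuracy is `trace / total`. Macro recall — reported as the
#' balanced accuracy — is the mean over classes of `diagonal / row sum`;
#' macro precision the mean of `diagonal / column sum`; macro F1 the
#' harmonic mean of the two macro values (not the mean of per-class F1).
#' Classes absent from the truth (empty row) are excluded from the macro
#' averages, since their recall is undefined; classes present but never
#' predicted contribute precision 0. All metrics are percentages in
#' `[0, 100]`.
#'
#' @param confusion Count matrix from [confusion_matrix()].
#' @param per_class_recall Included in the returned report.
#' @return An object of class `emg_eval`: `confusion`, `overall_accuracy`,
#'   `macro_recall`, `macro_precision`, `macro_f1`, `per_class_recall`
#'   (fractions), `recall_bands`, `class_list`, `excluded_classes`.
#' @export
compute_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  total <- sum(confusion)
  if (total == 0) emg_input_error("confusion matrix has no counts")
  if (any(confusion < 0)) emg_input_error("confusion matrix counts must be non-negative")
  class_list <- rownames(confusion) %||% as.character(seq_len(nrow(confusion)))

  diagv <- diag(confusion)
  rowsum_ <- rowSums(confusion)
  colsum_ <- colSums(confusion)
  present <- rowsum_ > 0

  recall <- ifelse(present, diagv / rowsum_, NA_real_)
  precision_present <- ifelse(colsum_[present] > 0,
                              diagv[present] / colsum_[present], 0)

  overall <- 100 * sum(diagv) / total
  macro_recall <- 100 * mean(recall[present])
  macro_precision <- 100 * mean(precision_present)
  macro_f1 <- if (macro_precision + macro_recall > 0)
    2 * macro_precision * macro_recall / (macro_precision + macro_recall)
  else 0

  per_class <- recall
  names(per_class) <- class_list

  structure(
    list(confusion = confusion,
         overall_accuracy = overall,
         macro_recall = macro_recall,
         macro_precision = macro_precision,
         macro_f1 = macro_f1,
         per_class_recall = per_class,
         recall_bands = band_recalls(per_class[present]),
         class_list = class_list,
         excluded_classes = class_list[!present]),
    class = "emg_eval")
}

#' @export
print.emg_eval <- function(x, ...) {
  cat(sprintf("Evaluation over %d classes, %d windows\n",
              length(x$class_list), sum(x$confusion)))
  cat(sprintf("  overall accuracy   %6.2f %%\n", x$overall_accuracy))
  cat(sprintf("  balanced accuracy  %6.2f %% (macro recall)\n", x$macro_recall))
  cat(sprintf("  macro precision    %6.2f %%\n", x$macro_precision))
  cat(sprintf("  macro F1           %6.2f %%\n", x$macro_f1))
  for (b in names(x$recall_bands))
    cat(sprintf("  recall %s: %s\n", b,
                paste(x$recall_bands[[b]], collapse = " ")))
  if (length(x$excluded_classes))
    cat("  excluded from macro averages (absent from truth):",
        paste(x$excluded_classes, collapse = " "), "\n")
  invisible(x)
}

#' Group classes into recall bands
#'
#' Practical-use banding of per-class recalls: `>= 0.8` (practical to
#' classify), `[0.6, 0.8)`, and `< 0.6` (difficult to distinguish). A recall
#' of exactly 0.8 falls in the top band. Each class lands in exactly one
#' band.
#'
#' @param per_class_recall Named numeric vector of recalls in `[0, 1]`.
#' @return Named list of class-name character vectors:
#'   `">=0.8"`, `"0.6-0.8"`, `"<0.6"`.
#' @export
band_recalls <- function(per_class_recall) {
  r <- per_class_recall
  if (length(r) && (any(r < 0, na.rm = TRUE) || any(r > 1, na.rm = TRUE)))
    emg_input_error("recalls must lie in [0, 1]")
  nms <- names(r) %||% as.character(seq_along(r))
  list(">=0.8" = nms[!is.na(r) & r >= 0.8],
       "0.6-0.8" = nms[!is.na(r) & r >= 0.6 & r < 0.8],
       "<0.6" = nms[!is.na(r) & r < 0.6])
}

#' Evaluate a fitted classifier on a feature table
#'
#' @param model An [emg_dnn()] model.
#' @param features An `emg_features` table with true labels.
#' @param class_list Classes for the confusion matrix (default: union of
#'   model classes and observed labels).
#' @param exclude_rest Drop rest (label 0) rows before evaluating.
#' @return An `emg_eval` report (see [compute_metrics()]).
#' @export
evaluate <- function(model, features, class_list = NULL, exclude_rest = FALSE) {
  stopifnot(inherits(model, "emg_dnn"), inherits(features, "emg_features"))
  keep <- if (exclude_rest) features$labels != 0L else rep(TRUE, length(features$labels))
  truth <- features$labels[keep]
  pred <- predict(model, feature_table(
    features$values[keep, , drop = FALSE], truth,
    features$repetitions[keep], features$threshold_used))
  if (is.null(class_list))
    class_list <- sort(unique(c(model$class_list, truth)))
  compute_metrics(confusion_matrix(truth, pred, class_list))
}

#' Default noise-threshold search grid
#'
#' Nine candidate thresholds from 1e-4 down to 1e-12, decreasing by factors
#' of 10.
#'
#' @return Numeric vector of length 9.
#' @export
default_threshold_grid <- function() 10^seq(-4, -12)

#' Grid search for the zero-crossing / slope-sign-change noise threshold
#'
#' For each candidate threshold the full pipeline is run — segment, split,
#' extract features, standardize (inner-train statistics), train the
#' classifier — and scored by balanced accuracy (macro recall) on a
#' held-out part of the *training* repetitions, so the evaluation
#' repetitions never influence the choice. The default inner split trains on
#' repetitions {1, 3, 4} and scores on {6}. Setting `score_reps` to the test
#' repetitions reproduces a search scored directly on evaluation data.
#' Ties break towards the larger threshold.
#'
#' @param recording An [emg_recording()] (or list of recordings, pooled).
#' @param window_ms,stride_ms Windowing parameters.
#' @param grid Candidate thresholds (default [default_threshold_grid()]).
#' @param inner_train_reps,score_reps Disjoint repetition sets used to train
#'   and to score each candidate.
#' @param spec Named list of [emg_dnn()] arguments (epochs, hidden, seed,
#'   ...) used for the inner models.
#' @return An object of class `emg_threshold_search`: `grid`,
#'   `score_per_threshold` (balanced accuracy %, named by threshold),
#'   `selected`.
#' @export
threshold_search <- function(recording, window_ms = 200, stride_ms = 100,
                             grid = default_threshold_grid(),
                             inner_train_reps = c(1, 3, 4), score_reps = 6,
                             spec = list()) {
  if (length(grid) == 0L) emg_config_error("threshold grid must be non-empty")
  recordings <- if (inherits(recording, "emg_recording")) list(recording)
                else recording
  wsets <- lapply(recordings, segment, window_ms = window_ms,
                  stride_ms = stride_ms)

  scores <- vapply(grid, function(T) {
    res <- tryCatch({
      tr_tabs <- list(); sc_tabs <- list()
      for (ws in wsets) {
        sp <- split_by_repetition(ws, inner_train_reps, score_reps)
        tr_tabs[[length(tr_tabs) + 1L]] <- extract_features(sp$train, T)
        sc_tabs[[length(sc_tabs) + 1L]] <- extract_features(sp$test, T)
      }
      train_tab <- bind_feature_tables(tr_tabs)
      score_tab <- bind_feature_tables(sc_tabs)
      std <- fit_standardizer(train_tab)
      args <- c(list(x = train_tab, standardizer = std), spec)
      model <- do.call(emg_dnn, args)
      evaluate(model, score_tab)$macro_recall
    }, error = function(e) {
      emg_error("config", sprintf("threshold search failed at T = %g: %s",
                                  T, conditionMessage(e)))
    })
    res
  }, numeric(1))

  names(scores) <- format(grid, scientific = TRUE)
  best <- max(scores)
  # ties towards the larger threshold
  selected <- max(grid[scores >= best - 1e-12])
  structure(list(grid = grid, score_per_threshold = scores,
                 selected = selected),
            class = "emg_threshold_search")
}

#' @export
print.emg_threshold_search <- function(x, ...) {
  cat("Noise-threshold grid search (balanced accuracy %):\n")
  for (i in seq_along(x$grid))
    cat(sprintf("  T = %8s  %6.2f%s\n", format(x$grid[i], scientific = TRUE),
                x$score_per_threshold[i],
                if (x$grid[i] == x$selected) "  <- selected" else ""))
  invisible(x)
}

#' Concatenate feature tables row-wise
#'
#' Tables must share identical feature columns; thresholds must agree.
#'
#' @param tables List of `emg_features` tables.
#' @return One `emg_features` table.
#' @export
bind_feature_tables <- function(tables) {
  stopifnot(length(tables) >= 1L)
  cols <- colnames(tables[[1]]$values)
  for (tb in tables)
    if (!identical(colnames(tb$values), cols))
      emg_input_error("feature tables have mismatched columns")
  feature_table(do.call(rbind, lapply(tables, `[[`, "values")),
                unlist(lapply(tables, `[[`, "labels")),
                unlist(lapply(tables, `[[`, "repetitions")),
                tables[[1]]$threshold_used)
}
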