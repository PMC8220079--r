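# Independent naive-loop oracles, written directly from the feature and
# metric definitions. These deliberately share no code with the package.

oracle_zc <- function(x, T) {
  count <- 0L
  for (k in seq_len(length(x) - 1L)) {
    crosses <- (x[k] < 0 && x[k + 1] > 0) || (x[k] > 0 && x[k + 1] < 0)
    if (crosses && abs(x[k] - x[k + 1]) >= T) count <- count + 1L
  }
  count
}

oracle_ssc <- function(x, T) {
  count <- 0L
  for (k in 2:(length(x) - 1L)) {
    peak <- (x[k] > x[k - 1] && x[k] > x[k + 1]) ||
            (x[k] < x[k - 1] && x[k] < x[k + 1])
    if (peak && (abs(x[k] - x[k + 1]) >= T || abs(x[k] - x[k - 1]) >= T))
      count <- count + 1L
  }
  count
}

oracle_rms <- function(x) {
  s <- 0
  for (v in x) s <- s + v * v
  sqrt(s / length(x))
}

oracle_mav <- function(x) {
  s <- 0
  for (v in x) s <- s + abs(v)
  s / length(x)
}

oracle_wl <- function(x) {
  s <- 0
  for (k in seq_len(length(x) - 1L)) s <- s + abs(x[k + 1] - x[k])
  s
}

oracle_mavs <- function(x) {
  half <- ceiling(length(x) / 2)
  oracle_mav(x[(half + 1):length(x)]) - oracle_mav(x[1:half])
}

# Per-class loop over a confusion matrix; percentages.
oracle_metrics <- function(cm) {
  K <- nrow(cm)
  total <- 0; correct <- 0
  recalls <- c(); precisions <- c()
  for (i in 1:K) {
    row_n <- 0; col_n <- 0
    for (j in 1:K) {
      total <- total + cm[i, j]
      row_n <- row_n + cm[i, j]
      col_n <- col_n + cm[j, i]
    }
    correct <- correct + cm[i, i]
    if (row_n > 0) {
      recalls <- c(recalls, cm[i, i] / row_n)
      precisions <- c(precisions, if (col_n > 0) cm[i, i] / col_n else 0)
    }
  }
  mp <- 100 * mean(precisions)
  mr <- 100 * mean(recalls)
  list(overall = 100 * correct / total,
       macro_recall = mr,
       macro_precision = mp,
       macro_f1 = if (mp + mr > 0) 2 * mp * mr / (mp + mr) else 0)
}

# Enumerate sliding-window start offsets directly.
oracle_n_windows <- function(n, w, s) {
  count <- 0L
  start <- 0L
  while (start + w <= n) {
    count <- count + 1L
    start <- start + s
  }
  count
}
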