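#' Numerically stable softmax
#'
#' `p_k = exp(z_k) / sum_i exp(z_i)`, computed with max-subtraction so large
#' logits do not overflow. Adding a constant to all logits leaves the result
#' unchanged.
#'
#' @param logits Finite numeric vector, or matrix with one score row per
#'   sample.
#' @return Probability vector/matrix of the same shape; rows sum to 1.
#' @export
softmax_probabilities <- function(logits) {
  if (any(!is.finite(logits))) emg_input_error("logits must be finite")
  if (is.matrix(logits)) {
    z <- logits - apply(logits, 1, max)
    e <- exp(z)
    e / rowSums(e)
  } else {
    e <- exp(logits - max(logits))
    e / sum(e)
  }
}

#' Mean categorical cross-entropy
#'
#' `-sum_i t_i log(s_i)` averaged over the batch, where `t` is the one-hot
#' truth and `s` the predicted probabilities. Probabilities are clipped to
#' at least 1e-12 before the logarithm.
#'
#' @param probabilities Matrix of probability rows (or a single vector).
#' @param one_hot_targets Matrix/vector of the same shape with one-hot rows.
#' @return Non-negative scalar loss.
#' @export
cross_entropy <- function(probabilities, one_hot_targets) {
  p <- rbind(probabilities); t <- rbind(one_hot_targets)
  if (!all(dim(p) == dim(t)))
    emg_input_error("probabilities and targets must have the same shape")
  -mean(rowSums(t * log(pmax(p, 1e-12))))
}

he_uniform <- function(n_in, n_out) {
  limit <- sqrt(6 / n_in)
  matrix(stats::runif(n_in * n_out, -limit, limit), n_in, n_out)
}

# Architecture: input -> [dense -> batchnorm -> ReLU -> dropout] per hidden
# width -> dense -> softmax.
init_network <- function(n_in, hidden, n_out) {
  dims <- c(n_in, hidden)
  layers <- lapply(seq_along(hidden), function(l) {
    list(W = he_uniform(dims[l], dims[l + 1]),
         b = numeric(dims[l + 1]),
         gamma = rep(1, dims[l + 1]),
         beta = numeric(dims[l + 1]),
         run_mean = numeric(dims[l + 1]),
         run_var = rep(1, dims[l + 1]))
  })
  out <- list(W = he_uniform(dims[length(dims)], n_out), b = numeric(n_out))
  list(layers = layers, out = out, n_in = n_in, n_out = n_out)
}

BN_EPS <- 1e-3
BN_MOMENTUM <- 0.99

forward_pass <- function(net, X, dropout = 0, training = FALSE) {
  caches <- vector("list", length(net$layers))
  A <- X
  B <- nrow(X)
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    Z <- A %*% ly$W
    Z <- sweep(Z, 2, ly$b, `+`)
    if (training) {
      mu <- colMeans(Z)
      v <- colMeans(sweep(Z, 2, mu)^2)
      net$layers[[l]]$run_mean <- BN_MOMENTUM * ly$run_mean + (1 - BN_MOMENTUM) * mu
      net$layers[[l]]$run_var <- BN_MOMENTUM * ly$run_var + (1 - BN_MOMENTUM) * v
    } else {
      mu <- ly$run_mean
      v <- ly$run_var
    }
    invstd <- 1 / sqrt(v + BN_EPS)
    Zhat <- sweep(sweep(Z, 2, mu), 2, invstd, `*`)
    Y <- sweep(sweep(Zhat, 2, ly$gamma, `*`), 2, ly$beta, `+`)
    A_out <- pmax(Y, 0)
    mask <- NULL
    if (training && dropout > 0) {
      mask <- matrix(stats::runif(B * ncol(A_out)) >= dropout,
                     B, ncol(A_out)) / (1 - dropout)
      A_out <- A_out * mask
    }
    caches[[l]] <- list(A_in = A, Zhat = Zhat, invstd = invstd, Y = Y,
                        mask = mask)
    A <- A_out
  }
  logits <- sweep(A %*% net$out$W, 2, net$out$b, `+`)
  P <- softmax_probabilities(logits)
  list(net = net, P = P, A_last = A, caches = caches)
}

backward_pass <- function(net, fwd, Tmat) {
  B <- nrow(Tmat)
  grads <- list(layers = vector("list", length(net$layers)), out = NULL)
  dlogits <- (fwd$P - Tmat) / B
  grads$out <- list(W = crossprod(fwd$A_last, dlogits), b = colSums(dlogits))
  dA <- tcrossprod(dlogits, net$out$W)
  for (l in rev(seq_along(net$layers))) {
    ly <- net$layers[[l]]
    cache <- fwd$caches[[l]]
    if (!is.null(cache$mask)) dA <- dA * cache$mask
    dY <- dA * (cache$Y > 0)
    dgamma <- colSums(dY * cache$Zhat)
    dbeta <- colSums(dY)
    dZhat <- sweep(dY, 2, ly$gamma, `*`)
    mean_dZhat <- colMeans(dZhat)
    mean_dZhatZhat <- colMeans(dZhat * cache$Zhat)
    dZ <- sweep(dZhat, 2, mean_dZhat) -
      sweep(cache$Zhat, 2, mean_dZhatZhat, `*`)
    dZ <- sweep(dZ, 2, cache$invstd, `*`)
    grads$layers[[l]] <- list(W = crossprod(cache$A_in, dZ), b = colSums(dZ),
                              gamma = dgamma, beta = dbeta)
    dA <- tcrossprod(dZ, ly$W)
  }
  grads
}

adam_init <- function(net) {
  zero_like <- function(p) if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else numeric(length(p))
  state_of <- function(grp, nms) lapply(grp[nms], function(p)
    list(m = zero_like(p), v = zero_like(p)))
  list(layers = lapply(net$layers, state_of, nms = c("W", "b", "gamma", "beta")),
       out = state_of(net$out, c("W", "b")),
       t = 0L)
}

adam_step <- function(net, grads, state, lr, decay, decay_type,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1L
  t <- state$t
  lr_t <- if (decay_type == "lr") lr / (1 + decay * t) else lr
  upd <- function(p, g, st) {
    if (decay_type == "weight") g <- g + decay * p
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    list(p = p - lr_t * mhat / (sqrt(vhat) + eps), st = st)
  }
  for (l in seq_along(net$layers)) {
    for (nm in c("W", "b", "gamma", "beta")) {
      r <- upd(net$layers[[l]][[nm]], grads$layers[[l]][[nm]],
               state$layers[[l]][[nm]])
      net$layers[[l]][[nm]] <- r$p
      state$layers[[l]][[nm]] <- r$st
    }
  }
  for (nm in c("W", "b")) {
    r <- upd(net$out[[nm]], grads$out[[nm]], state$out[[nm]])
    net$out[[nm]] <- r$p
    state$out[[nm]] <- r$st
  }
  list(net = net, state = state)
}

#' Fit the feed-forward sEMG movement classifier
#'
#' Trains a fully connected network on standardized time-domain feature
#' vectors: three hidden layers of 512, 256 and 256 units by default, each
#' followed by batch normalization, ReLU activation and 20% dropout, with a
#' linear + softmax output over the movement classes (rest included as class
#' 0). Weights are He-uniform initialized and optimized with Adam
#' (learning rate 0.005, learning-rate decay 1e-5 per update) on the mean
#' categorical cross-entropy. All randomness (initialization, shuffling,
#' dropout) derives from `seed`, so identical calls give identical weights.
#'
#' @param x An `emg_features` table (see [extract_features()]) or a numeric
#'   feature matrix.
#' @param y Integer class labels per row; taken from the table when omitted.
#' @param hidden Hidden-layer widths.
#' @param dropout Dropout rate in `[0, 1)`.
#' @param learning_rate,decay Adam learning rate and decay. `decay_type
#'   = "lr"` (default) applies `lr / (1 + decay * t)` per update `t`;
#'   `"weight"` reads the value as L2 weight decay instead.
#' @param epochs,batch_size Training schedule; no early stopping and no
#'   validation split are used.
#' @param seed Integer seed for all training randomness.
#' @param standardizer An [fit_standardizer()] result to attach; when `NULL`
#'   one is fitted on `x` itself (flagged in the model as
#'   `standardized_internally`).
#' @param decay_type See `decay`.
#' @param verbose Print the loss every 10 epochs.
#' @return An object of class `emg_dnn`: the trained network, the class
#'   list (sorted labels seen in training), the attached standardizer and
#'   the per-epoch training-loss trace.
#' @seealso [predict.emg_dnn()], [evaluate()]
#' @export
emg_dnn <- function(x, y = NULL, hidden = c(512L, 256L, 256L), dropout = 0.2,
                    learning_rate = 0.005, decay = 1e-5,
                    epochs = 100L, batch_size = 256L, seed = 1L,
                    standardizer = NULL, decay_type = c("lr", "weight"),
                    verbose = FALSE) {
  decay_type <- match.arg(decay_type)
  if (any(hidden < 1L)) emg_config_error("hidden widths must be positive")
  if (dropout < 0 || dropout >= 1) emg_config_error("dropout must be in [0, 1)")

  if (inherits(x, "emg_features")) {
    if (is.null(y)) y <- x$labels
    feats <- x
  } else {
    if (is.null(y)) emg_input_error("y is required when x is a plain matrix")
    feats <- feature_table(as.matrix(x), y, rep(0L, nrow(x)))
  }
  y <- as.integer(y)
  class_list <- sort(unique(y))
  if (length(class_list) < 2L)
    emg_input_error("training data must contain at least 2 classes")

  standardized_internally <- is.null(standardizer)
  if (standardized_internally) standardizer <- fit_standardizer(feats)
  X <- apply_standardizer(standardizer, feats)$values
  n <- nrow(X)
  K <- length(class_list)
  Tmat <- matrix(0, n, K)
  Tmat[cbind(seq_len(n), match(y, class_list))] <- 1

  set.seed(seed)
  net <- init_network(ncol(X), as.integer(hidden), K)
  state <- adam_init(net)
  loss_trace <- numeric(epochs)

  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    batch_starts <- seq.int(1L, n, by = batch_size)
    losses <- numeric(length(batch_starts))
    for (bi in seq_along(batch_starts)) {
      idx <- ord[batch_starts[bi]:min(batch_starts[bi] + batch_size - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      Tb <- Tmat[idx, , drop = FALSE]
      fwd <- forward_pass(net, Xb, dropout = dropout, training = TRUE)
      net <- fwd$net  # updated running statistics
      losses[bi] <- cross_entropy(fwd$P, Tb)
      grads <- backward_pass(net, fwd, Tb)
      stepped <- adam_step(net, grads, state, learning_rate, decay, decay_type)
      net <- stepped$net
      state <- stepped$state
    }
    loss_trace[ep] <- mean(losses)
    if (verbose && ep %% 10L == 0L)
      message(sprintf("epoch %d/%d  loss %.4f", ep, epochs, loss_trace[ep]))
  }

  structure(
    list(net = net, class_list = class_list, standardizer = standardizer,
         standardized_internally = standardized_internally,
         loss_trace = loss_trace,
         spec = list(hidden = as.integer(hidden), dropout = dropout,
                     learning_rate = learning_rate, decay = decay,
                     decay_type = decay_type, epochs = as.integer(epochs),
                     batch_size = as.integer(batch_size), seed = as.integer(seed),
                     n_features = ncol(X), n_classes = K)),
    class = "emg_dnn")
}

model_feature_matrix <- function(object, newdata) {
  feats <- if (inherits(newdata, "emg_features")) newdata
           else feature_table(as.matrix(newdata),
                              rep(0L, nrow(as.matrix(newdata))),
                              rep(0L, nrow(as.matrix(newdata))))
  if (ncol(feats$values) != object$spec$n_features)
    emg_input_error(sprintf("model expects %d features, got %d",
                            object$spec$n_features, ncol(feats$values)))
  apply_standardizer(object$standardizer, feats)$values
}

#' Predict movement classes or class probabilities
#'
#' Features are standardized with the model's attached parameters before the
#' forward pass (batch normalization uses the running statistics, dropout is
#' off). `type = "class"` returns the highest-probability class per row;
#' exact ties break towards the lowest class index.
#'
#' @param object An [emg_dnn()] model.
#' @param newdata An `emg_features` table or raw feature matrix with the
#'   training feature columns.
#' @param type `"class"` (default) or `"prob"`.
#' @param ... Unused.
#' @return Integer labels, or a probability matrix with one column per
#'   class.
#' @export
predict.emg_dnn <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- model_feature_matrix(object, newdata)
  P <- forward_pass(object$net, X, training = FALSE)$P
  colnames(P) <- object$class_list
  if (type == "prob") return(P)
  object$class_list[max.col(P, ties.method = "first")]
}

#' @export
print.emg_dnn <- function(x, ...) {
  cat(sprintf("sEMG feed-forward classifier: %d -> %s -> %d classes\n",
              x$spec$n_features, paste(x$spec$hidden, collapse = " -> "),
              x$spec$n_classes))
  cat(sprintf("  dropout %.2f, Adam lr %g (%s decay %g), %d epochs, batch %d, seed %d\n",
              x$spec$dropout, x$spec$learning_rate, x$spec$decay_type,
              x$spec$decay, x$spec$epochs, x$spec$batch_size, x$spec$seed))
  cat(sprintf("  final training loss %.4f\n", utils::tail(x$loss_trace, 1)))
  invisible(x)
}

#' @export
summary.emg_dnn <- function(object, ...) {
  np <- n_parameters(object)
  cat(sprintf("Classes (%d): %s\n", object$spec$n_classes,
              paste(object$class_list, collapse = " ")))
  print(object)
  cat(sprintf("  %d trainable parameters; standardizer fitted %s\n", np,
              if (object$standardized_internally) "internally on the training table"
              else "externally"))
  invisible(object)
}

#' @export
coef.emg_dnn <- function(object, ...) {
  c(lapply(object$net$layers, function(l) l[c("W", "b", "gamma", "beta")]),
    list(output = object$net$out))
}

#' @export
plot.emg_dnn <- function(x, ...) {
  graphics::plot(seq_along(x$loss_trace), x$loss_trace, type = "l",
                 xlab = "epoch", ylab = "training cross-entropy",
                 main = "Training loss", ...)
  invisible(x)
}

#' Number of trainable parameters of a fitted classifier
#'
#' Dense weights and biases plus the batch-norm scale and shift of every
#' hidden layer.
#'
#' @param object An [emg_dnn()] model.
#' @return Integer count.
#' @export
n_parameters <- function(object) {
  net <- object$net
  n <- 0L
  for (l in net$layers)
    n <- n + length(l$W) + length(l$b) + length(l$gamma) + length(l$beta)
  n + length(net$out$W) + length(net$out$b)
}

#' Save / load a trained classifier
#'
#' The single-file archive holds the weights, architecture spec, attached
#' standardizer and class list; a small JSON manifest describing the model
#' is written alongside (same path with `.json` appended).
#'
#' @param object An [emg_dnn()] model.
#' @param path Archive path (e.g. `model.rds`).
#' @return `save_model`: `path`, invisibly. `load_model`: the restored
#'   `emg_dnn` model.
#' @export
save_model <- function(object, path) {
  stopifnot(inherits(object, "emg_dnn"))
  saveRDS(object, path)
  jsonlite::write_json(
    list(format = "emgmotion-dnn", n_features = object$spec$n_features,
         n_classes = object$spec$n_classes,
         class_list = object$class_list, hidden = object$spec$hidden,
         dropout = object$spec$dropout,
         learning_rate = object$spec$learning_rate,
         decay = object$spec$decay, epochs = object$spec$epochs,
         batch_size = object$spec$batch_size, seed = object$spec$seed,
         final_loss = utils::tail(object$loss_trace, 1)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  object <- readRDS(path)
  if (!inherits(object, "emg_dnn"))
    emg_format_error("file does not contain an emgmotion classifier")
  object
}
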