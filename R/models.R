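#' Build an untrained network of a named family
#'
#' Four small families over fixed-length 1-D sequences:
#' \describe{
#'   \item{CNN_LSTM}{conv(9 filters) -> BN -> conv(64) -> BN -> conv(32) ->
#'     BN -> LSTM(8, sequences) -> LSTM(4, 20\% dropout) -> dense ->
#'     softmax(2). The serial CNN->LSTM stack lets the convolutions distil
#'     local spectral patterns that the recurrent layers then read in time
#'     order.}
#'   \item{BiLSTM}{BiLSTM(128) -> BiLSTM(64) -> dense(64, ReLU) ->
#'     dense(32, ReLU) -> softmax(2).}
#'   \item{CNN}{conv(9) -> BN -> conv(64) -> BN -> conv(32) -> BN -> global
#'     average pool -> softmax(2).}
#'   \item{BiGRU}{as BiLSTM with GRU cells.}
#' }
#' All convolutions are 1-D over the time axis with a fixed kernel size
#' (default 9) and same-padding; 9/64/32 are filter counts.
#'
#' @param family One of `"CNN_LSTM"`, `"BiLSTM"`, `"CNN"`, `"BiGRU"`.
#' @param input_shape Integer vector `c(timesteps, channels)`.
#' @param kernel Convolution kernel size (default 9).
#' @param filters Filter counts of the three convolution layers.
#' @param seed Seed for weight initialization.
#' @return An untrained `network` object.
#' @export
build_network <- function(family = c("CNN_LSTM", "BiLSTM", "CNN", "BiGRU"),
                          input_shape, kernel = 9, filters = c(9, 64, 32),
                          seed = 1L) {
  if (!is.character(family) || !family[1] %in% c("CNN_LSTM", "BiLSTM", "CNN", "BiGRU")) {
    stop("unknown network family: ", family[1], call. = FALSE)
  }
  family <- match.arg(family)
  T_ <- as.integer(input_shape[1]); C <- as.integer(input_shape[2])
  with_seed(seed, {
    layers <- switch(family,
      CNN_LSTM = list(
        layer_conv1d(C, filters[1], kernel), layer_batchnorm(filters[1]),
        layer_conv1d(filters[1], filters[2], kernel), layer_batchnorm(filters[2]),
        layer_conv1d(filters[2], filters[3], kernel), layer_batchnorm(filters[3]),
        layer_rnn("lstm", filters[3], 8L, return_seq = TRUE),
        layer_rnn("lstm", 8L, 4L, return_seq = FALSE, dropout = 0.2),
        layer_dense(4L, 2L)),
      BiLSTM = list(
        layer_rnn("lstm", C, 128L, return_seq = TRUE, bidirectional = TRUE),
        layer_rnn("lstm", 256L, 64L, return_seq = FALSE, bidirectional = TRUE),
        layer_dense(128L, 64L, act = "relu"),
        layer_dense(64L, 32L, act = "relu"),
        layer_dense(32L, 2L)),
      CNN = list(
        layer_conv1d(C, filters[1], kernel), layer_batchnorm(filters[1]),
        layer_conv1d(filters[1], filters[2], kernel), layer_batchnorm(filters[2]),
        layer_conv1d(filters[2], filters[3], kernel), layer_batchnorm(filters[3]),
        layer_gap(),
        layer_dense(filters[3], 2L)),
      BiGRU = list(
        layer_rnn("gru", C, 128L, return_seq = TRUE, bidirectional = TRUE),
        layer_rnn("gru", 256L, 64L, return_seq = FALSE, bidirectional = TRUE),
        layer_dense(128L, 64L, act = "relu"),
        layer_dense(64L, 32L, act = "relu"),
        layer_dense(32L, 2L)))
    structure(list(family = family, layers = layers,
                   input_shape = c(T_, C)),
              class = "network")
  })
}

#' @export
print.network <- function(x, ...) {
  cat(sprintf("<network %s: input (%d x %d), %d layers>\n", x$family,
              x$input_shape[1], x$input_shape[2], length(x$layers)))
  invisible(x)
}

#' Training configuration
#'
#' @param split Train fraction of the stratified train/test split
#'   (default 0.7, i.e. a 70-30 split).
#' @param epochs Maximum epochs (default 100).
#' @param batch_size Minibatch size (default 32).
#' @param lr Adam learning rate (default 1e-3).
#' @param patience Early-stopping patience on validation loss (default 10).
#' @param val_fraction Fraction of the training partition held out for the
#'   early-stopping validation loss (default 0.15).
#' @param seed Seed governing the split, shuffling and dropout.
#' @return A `train_config`.
#' @export
train_config <- function(split = 0.7, epochs = 100, batch_size = 32,
                         lr = 1e-3, patience = 10, val_fraction = 0.15,
                         seed = 1L) {
  if (split <= 0 || split >= 1) stop("split must lie in (0, 1)", call. = FALSE)
  structure(list(split = split, epochs = epochs, batch_size = batch_size,
                 lr = lr, patience = patience, val_fraction = val_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

# Coerce input to a (n, T, C) array; plain matrices become single-channel
# sequences.
as_seq_array <- function(X) {
  if (is.array(X) && length(dim(X)) == 3L) return(X)
  X <- as.matrix(X)
  array(X, c(nrow(X), ncol(X), 1L))
}

# Stratified index split: `fraction` of each class, deterministic under the
# current RNG stream. The floor is taken with a small guard so that exact
# decimal products (e.g. 730 * 0.7 = 511) are not pushed down by binary
# floating-point representation.
stratified_split <- function(y, fraction) {
  train_idx <- integer(0)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    n_tr <- floor(length(idx) * fraction + 1e-9)
    train_idx <- c(train_idx, sample(idx, n_tr))
  }
  sort(train_idx)
}

#' Train a two-class network
#'
#' Stratified 70-30 train/test split under the config seed (the held-out
#' test indices are returned for evaluation, never touched during fitting),
#' per-dimension standardization computed on the training partition, Adam
#' minibatch training with cross-entropy loss and early stopping on a
#' validation slice of the training partition.
#'
#' @param net An untrained `network` from [build_network()], or a family name.
#' @param X Inputs: `(n, T, C)` array or an `n x D` matrix (treated as
#'   single-channel length-`D` sequences).
#' @param y Two-level factor (or vector coercible to one) of class labels.
#' @param cfg A [train_config()].
#' @return A `trained_classifier`: the fitted network, `classes` (level
#'   order of the probability columns), `center`/`scale` standardization,
#'   `test_idx` (held-out row indices), `history` (per-epoch losses) and the
#'   config.
#' @export
train_classifier <- function(net, X, y, cfg = train_config()) {
  X <- as_seq_array(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) stop("y must contain exactly two classes", call. = FALSE)
  if (min(table(y)) < 2L) stop("need at least 2 examples per class", call. = FALSE)
  if (is.character(net)) net <- build_network(net, input_shape = dim(X)[2:3],
                                              seed = cfg$seed)
  if (!all(dim(X)[2:3] == net$input_shape)) {
    stop(sprintf("input shape (%d x %d) does not match network (%d x %d)",
                 dim(X)[2], dim(X)[3], net$input_shape[1], net$input_shape[2]),
         call. = FALSE)
  }
  n <- dim(X)[1]
  with_seed(cfg$seed, {
    train_idx <- stratified_split(y, cfg$split)
    test_idx <- setdiff(seq_len(n), train_idx)
    # standardization fitted on the training partition only
    Xtr <- X[train_idx, , , drop = FALSE]
    D <- prod(dim(X)[2:3])
    flat <- matrix(Xtr, length(train_idx), D)
    center <- colMeans(flat)
    scale_ <- pmax(apply(flat, 2, stats::sd), 1e-8)
    std <- function(A) {
      m <- matrix(A, dim(A)[1], D)
      m <- sweep(sweep(m, 2, center, "-"), 2, scale_, "/")
      array(m, dim(A))
    }
    Xtr <- std(Xtr)
    ytr <- y[train_idx]
    # validation slice for early stopping
    val_local <- stratified_split(ytr, cfg$val_fraction)
    fit_local <- setdiff(seq_along(train_idx), val_local)
    Xval <- Xtr[val_local, , , drop = FALSE]; yval <- ytr[val_local]
    Xfit <- Xtr[fit_local, , , drop = FALSE]; yfit <- ytr[fit_local]
    onehot <- function(yy) {
      m <- matrix(0, length(yy), 2L)
      m[cbind(seq_along(yy), as.integer(yy))] <- 1
      m
    }
    Yfit <- onehot(yfit); Yval <- onehot(yval)
    state <- adam_init(net)
    step <- 0L
    best <- list(loss = Inf, net = net, epoch = 0L)
    history <- data.frame(epoch = integer(), train_loss = numeric(),
                          val_loss = numeric())
    wait <- 0L
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(nrow(Yfit))
      ep_loss <- 0; n_b <- 0L
      for (b0 in seq(1, length(ord), by = cfg$batch_size)) {
        idx <- ord[b0:min(b0 + cfg$batch_size - 1L, length(ord))]
        res <- nn_forward(net, Xfit[idx, , , drop = FALSE], train = TRUE)
        ce <- softmax_ce(res$logits, Yfit[idx, , drop = FALSE])
        net <- nn_backward(res$net, ce$dLogits)
        step <- step + 1L
        upd <- adam_step(net, state, step, lr = cfg$lr)
        net <- upd$net; state <- upd$state
        ep_loss <- ep_loss + ce$loss; n_b <- n_b + 1L
      }
      val_res <- nn_forward(net, Xval, train = FALSE)
      val_loss <- if (nrow(Yval) > 0) {
        softmax_ce(val_res$logits, Yval)$loss
      } else ep_loss / n_b
      net <- val_res$net  # keep refreshed BN running stats
      history <- rbind(history, data.frame(epoch = ep,
                                           train_loss = ep_loss / n_b,
                                           val_loss = val_loss))
      if (val_loss < best$loss - 1e-6) {
        best <- list(loss = val_loss, net = nn_clear_cache(net), epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
    structure(list(net = best$net, family = net$family,
                   classes = levels(y), center = center, scale = scale_,
                   input_shape = net$input_shape, test_idx = test_idx,
                   train_idx = train_idx, history = history,
                   best_epoch = best$epoch, config = cfg),
              class = "trained_classifier")
  })
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat(sprintf("<trained_classifier %s: classes [%s], best epoch %d (val loss %.4f)>\n",
              x$family, paste(x$classes, collapse = ", "), x$best_epoch,
              min(x$history$val_loss)))
  invisible(x)
}

#' Class probabilities from a trained classifier
#'
#' @param clf A `trained_classifier`.
#' @param X Inputs with the training shape (array `(n, T, C)` or matrix).
#' @return `n x 2` matrix of softmax probabilities; columns named by
#'   `clf$classes`, rows summing to 1.
#' @export
predict_proba <- function(clf, X) {
  stopifnot(inherits(clf, "trained_classifier"))
  X <- as_seq_array(X)
  if (!all(dim(X)[2:3] == clf$input_shape)) {
    stop(sprintf("input shape (%d x %d) does not match training shape (%d x %d)",
                 dim(X)[2], dim(X)[3], clf$input_shape[1], clf$input_shape[2]),
         call. = FALSE)
  }
  D <- prod(clf$input_shape)
  m <- matrix(X, dim(X)[1], D)
  m <- sweep(sweep(m, 2, clf$center, "-"), 2, clf$scale, "/")
  Xs <- array(m, dim(X))
  n <- dim(Xs)[1]
  # predict in chunks to bound the im2col workspace for large batches
  chunk <- 512L
  p <- matrix(0, n, 2L)
  for (b0 in seq(1L, n, by = chunk)) {
    idx <- b0:min(b0 + chunk - 1L, n)
    p[idx, ] <- softmax_rows(
      nn_forward(clf$net, Xs[idx, , , drop = FALSE], train = FALSE)$logits)
  }
  colnames(p) <- clf$classes
  p
}
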