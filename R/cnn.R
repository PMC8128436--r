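# Convolutional regressor of basal gene-regulatory activity.
#
# Architecture (applied to the L_max x 2 x 2 x 8 binary tensor):
#   (a) 2 x 2 x 2 convolution over (row, side, stemloop), stride 1, valid
#       padding, rectified linear activation; each window sees a group of
#       eight adjacent nucleotide cells across all 8 channels,
#   (b) 25% dropout,
#   (c) flatten,
#   (d) fully connected layer with rectified linear activation,
#   (e) 50% dropout,
#   (f) fully connected layer reducing to one value.
# Trained with Adam on mean squared error. Implemented directly with
# matrix operations (the convolution is an im2col matrix product), with
# hand-derived backpropagation; a finite-difference check in the test suite
# guards the gradients.

#' Configuration for the convolutional regressor
#'
#' @param n_filters convolution filters.
#' @param conv_activation `"linear"` (default; the rectifier acts only in
#'   the dense layer, so the dense layer forms feature conjunctions across
#'   the whole grid) or `"relu"`.
#' @param dense_units width of the fully connected hidden layer.
#' @param dropout_conv dropout fraction after the convolution.
#' @param dropout_dense dropout fraction after the hidden layer.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam learning rate.
#' @param seed integer seed controlling weight initialisation, shuffling and
#'   dropout masks; a fixed seed makes training reproducible.
#' @return list of class `az_cnn_config`.
#' @export
cnn_config <- function(n_filters = 32L, conv_activation = c("linear", "relu"),
                       dense_units = 128L,
                       dropout_conv = 0.25, dropout_dense = 0.5,
                       epochs = 100L, batch_size = 128L,
                       learning_rate = 1e-3, seed = 1L) {
  conv_activation <- match.arg(conv_activation)
  stopifnot(dropout_conv >= 0, dropout_conv < 1,
            dropout_dense >= 0, dropout_dense < 1, epochs >= 1)
  structure(list(
    conv_kernel = c(2L, 2L, 2L), conv_stride = 1L,
    n_filters = as.integer(n_filters), conv_activation = conv_activation,
    dense_units = as.integer(dense_units),
    dropout_conv = dropout_conv, dropout_dense = dropout_dense,
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    learning_rate = learning_rate, seed = as.integer(seed)
  ), class = "az_cnn_config")
}

# im2col index map: column j of the returned matrix lists the 64 flattened
# feature indices seen by convolution window j (windows run over rows
# 1..L-1; the 2x2x2 kernel spans both sides, both stem-loops, 8 channels).
conv_index_map <- function(L_max) {
  idx <- array(seq_len(L_max * 2L * 2L * 8L), dim = c(L_max, 2L, 2L, 8L))
  P <- L_max - 1L
  im <- matrix(0L, nrow = 64L, ncol = P)
  for (p in seq_len(P)) {
    im[, p] <- as.vector(idx[p:(p + 1L), , , ])
  }
  im
}

# X (n x D) -> im2col matrix ((n*P) x 64), rows ordered sample-fastest.
im2col <- function(X, im) {
  n <- nrow(X)
  P <- ncol(im)
  A <- X[, as.vector(im), drop = FALSE]       # n x (64*P), k fastest
  dim(A) <- c(n, 64L, P)
  B <- aperm(A, c(1L, 3L, 2L))                # n x P x 64
  dim(B) <- c(n * P, 64L)
  B
}

relu <- function(x) (x > 0) * x

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

cnn_init <- function(L_max, config) {
  P <- L_max - 1L
  Fl <- config$n_filters
  H <- config$dense_units
  list(
    Wc = glorot(64L, Fl), bc = numeric(Fl),
    W1 = glorot(P * Fl, H), b1 = numeric(H),
    W2 = glorot(H, 1L), b2 = numeric(1L)
  )
}

cnn_forward <- function(X, par, im, config, train = FALSE) {
  n <- nrow(X)
  P <- ncol(im)
  Fl <- config$n_filters
  B <- im2col(X, im)
  Zc <- sweep(B %*% par$Wc, 2L, par$bc, "+")
  Hc <- if (identical(config$conv_activation, "relu")) relu(Zc) else Zc
  if (train && config$dropout_conv > 0) {
    m1 <- matrix(runif(length(Hc)) >= config$dropout_conv, nrow(Hc), ncol(Hc))
    Hd <- Hc * m1 / (1 - config$dropout_conv)
  } else {
    m1 <- NULL
    Hd <- Hc
  }
  Fm <- Hd
  dim(Fm) <- c(n, P * Fl)                      # flatten (row index was sample-fastest)
  Z1 <- sweep(Fm %*% par$W1, 2L, par$b1, "+")
  H1 <- relu(Z1)
  if (train && config$dropout_dense > 0) {
    m2 <- matrix(runif(length(H1)) >= config$dropout_dense, nrow(H1), ncol(H1))
    H1d <- H1 * m2 / (1 - config$dropout_dense)
  } else {
    m2 <- NULL
    H1d <- H1
  }
  yhat <- drop(H1d %*% par$W2) + par$b2
  list(B = B, Zc = Zc, m1 = m1, Fm = Fm, Z1 = Z1, H1 = H1, m2 = m2,
       H1d = H1d, yhat = yhat, n = n, P = P)
}

cnn_backward <- function(fw, y, par, config) {
  n <- fw$n
  dy <- matrix(2 * (fw$yhat - y) / n, ncol = 1L)
  gW2 <- crossprod(fw$H1d, dy)
  gb2 <- sum(dy)
  dH1d <- dy %*% t(par$W2)
  dH1 <- if (is.null(fw$m2)) dH1d else dH1d * fw$m2 / (1 - config$dropout_dense)
  dZ1 <- dH1 * (fw$Z1 > 0)
  gW1 <- crossprod(fw$Fm, dZ1)
  gb1 <- colSums(dZ1)
  dFm <- dZ1 %*% t(par$W1)
  dHd <- dFm
  dim(dHd) <- c(n * fw$P, config$n_filters)
  dHc <- if (is.null(fw$m1)) dHd else dHd * fw$m1 / (1 - config$dropout_conv)
  dZc <- if (identical(config$conv_activation, "relu")) dHc * (fw$Zc > 0) else dHc
  gWc <- crossprod(fw$B, dZc)
  gbc <- colSums(dZc)
  list(Wc = gWc, bc = gbc, W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
}

adam_state <- function(par) {
  list(m = lapply(par, function(p) p * 0), v = lapply(par, function(p) p * 0),
       t = 0L)
}

adam_step <- function(par, grad, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  for (k in names(par)) {
    st$m[[k]] <- beta1 * st$m[[k]] + (1 - beta1) * grad[[k]]
    st$v[[k]] <- beta2 * st$v[[k]] + (1 - beta2) * grad[[k]]^2
    mhat <- st$m[[k]] / (1 - beta1^st$t)
    vhat <- st$v[[k]] / (1 - beta2^st$t)
    par[[k]] <- par[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = st)
}

check_encoded_matrix <- function(X) {
  meta <- attr(X, "encoder")
  if (is.null(meta)) {
    az_stop("az_metadata_error", "input matrix lacks encoder metadata (use batch_encode())")
  }
  if (ncol(X) != meta$L_max * 32L) {
    az_stop("az_shape_error", "feature count %d inconsistent with L_max = %d",
            ncol(X), meta$L_max)
  }
  meta
}

#' Train the convolutional activity regressor
#'
#' Fits the 3D-convolution network to encoded stem-loop tensors and measured
#' (or surrogate) basal activities, minimising mean squared error with Adam.
#' The per-epoch training loss is recorded in the returned model
#' (`model$history`), and a fixed `config$seed` makes the run reproducible.
#'
#' @param X encoded feature matrix from [batch_encode()] (one flattened
#'   tensor per row, encoder metadata attached).
#' @param y numeric vector of activity labels, `log10(GFP/mCherry)`.
#' @param config an [cnn_config()] object.
#' @return an `az_model` of kind `"cnn"`; use [predict.az_model()] on new
#'   encoded batches.
#' @export
train_cnn <- function(X, y, config = cnn_config()) {
  meta <- check_encoded_matrix(X)
  if (nrow(X) != length(y)) {
    az_stop("az_shape_error", "nrow(X) = %d but length(y) = %d", nrow(X), length(y))
  }
  if (nrow(X) < 2L) az_stop("az_shape_error", "need at least 2 training records")
  if (any(!is.finite(y))) az_stop("az_label_error", "labels must be finite")
  im <- conv_index_map(meta$L_max)
  n <- nrow(X)
  with_seed(config$seed, function() {
    par <- cnn_init(meta$L_max, config)
    st <- adam_state(par)
    history <- numeric(config$epochs)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        Xb <- X[idx, , drop = FALSE]
        yb <- y[idx]
        fw <- cnn_forward(Xb, par, im, config, train = TRUE)
        losses <- c(losses, mean((fw$yhat - yb)^2))
        gr <- cnn_backward(fw, yb, par, config)
        upd <- adam_step(par, gr, st, config$learning_rate)
        par <- upd$par
        st <- upd$state
      }
      history[epoch] <- mean(losses)
    }
    structure(list(
      kind = "cnn", par = par, config = config, meta = meta,
      history = data.frame(epoch = seq_len(config$epochs), train_loss = history)
    ), class = "az_model")
  })
}

#' Predict basal activity for encoded ribozymes
#'
#' Inference is deterministic (dropout disabled) and invariant to batch
#' size. The encoder metadata of `newdata` must match the metadata the
#' model was trained with; a mismatch raises `az_metadata_error`.
#'
#' @param object an `az_model` from [train_cnn()] or [train_baseline()].
#' @param newdata encoded feature matrix from [batch_encode()].
#' @param ... unused.
#' @return numeric vector of predicted `log10(GFP/mCherry)` values.
#' @export
predict.az_model <- function(object, newdata, ...) {
  meta <- check_encoded_matrix(newdata)
  if (!identical(meta$L_max, object$meta$L_max) ||
      !identical(meta$channels, object$meta$channels) ||
      !identical(meta$stem_depth, object$meta$stem_depth) ||
      !identical(meta$layout, object$meta$layout)) {
    az_stop("az_metadata_error", "encoder metadata of newdata does not match the model")
  }
  if (nrow(newdata) == 0L) return(numeric(0))
  switch(object$kind,
    cnn = {
      im <- conv_index_map(meta$L_max)
      fw <- cnn_forward(newdata, object$par, im, object$config, train = FALSE)
      unname(fw$yhat)
    },
    lasso = {
      drop(stats::predict(object$fit, newx = newdata, s = "lambda.min"))
    },
    svm = {
      unname(stats::predict(object$fit, newdata))
    },
    random_forest = {
      unname(stats::predict(object$fit, newdata))
    },
    az_stop("az_shape_error", "unknown model kind '%s'", object$kind)
  )
}

#' @export
print.az_model <- function(x, ...) {
  cat(sprintf("<az_model kind='%s'> L_max = %d", x$kind, x$meta$L_max))
  if (!is.null(x$history)) {
    cat(sprintf(", %d epochs, final train MSE %.4f",
                nrow(x$history), x$history$train_loss[nrow(x$history)]))
  }
  cat("\n")
  invisible(x)
}
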