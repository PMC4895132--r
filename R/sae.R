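# Stacked (denoising) autoencoder classifier.
#
# Each layer is an autoencoder h = sigmoid(W1 x + b1),
# xhat = sigmoid(W2 h + b2) trained to minimize the mean squared
# reconstruction error of clean inputs from (optionally) mask-corrupted
# copies. Layers are pretrained greedily — layer k is trained on the
# encoded output of layers 1..k-1 — then a 2-class softmax top layer is
# added and the whole encoder stack is fine-tuned by cross-entropy
# gradient descent. Plain minibatch SGD throughout; all randomness
# (weight init, shuffling, corruption) flows from the config seed, so the
# full train-predict pipeline is bit-reproducible.

#' Training configuration for the stacked autoencoder
#'
#' @param epochs_pretrain,epochs_finetune epoch counts (>= 1).
#' @param learning_rate SGD step size (> 0).
#' @param batch_size minibatch size (>= 1).
#' @param corruption_p masking-noise probability in \[0, 1\]; each input
#'   coordinate is independently zeroed with this probability during
#'   pretraining (0 gives a plain, non-denoising autoencoder).
#' @param l2 weight-decay coefficient (>= 0; applied to weights, not
#'   biases).
#' @param seed integer seed controlling initialization, shuffling and
#'   corruption.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs_pretrain = 200, epochs_finetune = 400,
                         learning_rate = 2, batch_size = 32,
                         corruption_p = 0.1, l2 = 0, seed = 1) {
  if (epochs_pretrain < 1 || epochs_finetune < 1)
    stop_input("epoch counts must be >= 1")
  if (learning_rate <= 0) stop_input("learning_rate must be > 0")
  if (batch_size < 1) stop_input("batch_size must be >= 1")
  if (corruption_p < 0 || corruption_p > 1)
    stop_input("corruption_p must be in [0, 1]")
  if (l2 < 0) stop_input("l2 must be >= 0")
  structure(list(epochs_pretrain = as.integer(epochs_pretrain),
                 epochs_finetune = as.integer(epochs_finetune),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 corruption_p = corruption_p, l2 = l2,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Numerically stable logistic sigmoid
#'
#' @param z numeric scalar, vector or matrix.
#' @return `1 / (1 + exp(-z))`, elementwise, in (0, 1); saturates cleanly
#'   (without overflow warnings) for |z| up to at least 1e3.
#' @export
sigmoid <- function(z) {
  out <- z
  pos <- z >= 0
  out[pos] <- 1 / (1 + exp(-z[pos]))
  ez <- exp(z[!pos])
  out[!pos] <- ez / (1 + ez)
  out
}

as_row_matrix <- function(x, d) {
  if (is.null(dim(x))) x <- matrix(x, ncol = length(x))
  if (ncol(x) != d) stop_input("input dimension mismatch: expected ", d,
                               " columns, got ", ncol(x))
  x
}

#' Encode / decode with one autoencoder layer
#'
#' @param x input vector or row-matrix (cases in rows).
#' @param p autoencoder parameters: list with `W1` (hidden x input), `b1`,
#'   `W2` (input x hidden), `b2`.
#' @return `encode` returns `sigmoid(x W1' + b1)` per row; `decode`
#'   returns `sigmoid(h W2' + b2)`.
#' @export
encode <- function(x, p) {
  x <- as_row_matrix(x, ncol(p$W1))
  sigmoid(sweep(x %*% t(p$W1), 2, p$b1, "+"))
}

#' @rdname encode
#' @param h hidden vector or row-matrix.
#' @export
decode <- function(h, p) {
  h <- as_row_matrix(h, ncol(p$W2))
  sigmoid(sweep(h %*% t(p$W2), 2, p$b2, "+"))
}

#' Mean reconstruction error of a batch
#'
#' @param X row-matrix of inputs scaled to \[0, 1\].
#' @param p autoencoder parameters.
#' @return mean over rows of `0.5 * ||decode(encode(x)) - x||^2`.
#' @export
reconstruction_error <- function(X, p) {
  X <- as_row_matrix(X, ncol(p$W1))
  Xh <- decode(encode(X, p), p)
  mean(rowSums((Xh - X)^2)) / 2
}

#' Masking corruption
#'
#' Independently zeroes each coordinate with probability `p` (the
#' denoising-autoencoder masking noise).
#'
#' @param x numeric vector or matrix.
#' @param p corruption probability in \[0, 1\].
#' @param seed optional seed; if `NULL`, the current RNG stream is used
#'   (as during training).
#' @return corrupted copy of `x`.
#' @export
corrupt <- function(x, p, seed = NULL) {
  if (p < 0 || p > 1) stop_input("p must be in [0, 1]")
  if (p == 0) return(x)
  draw <- function() x * (runif(length(x)) >= p)
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Glorot-style uniform initialization.
init_ae_params <- function(input, hidden) {
  r1 <- sqrt(6 / (input + hidden))
  list(W1 = matrix(runif(hidden * input, -r1, r1), hidden, input),
       b1 = rep(0, hidden),
       W2 = matrix(runif(input * hidden, -r1, r1), input, hidden),
       b2 = rep(0, input))
}

# Loss and analytic gradients of the denoising reconstruction objective
# for one batch (corrupted input Xc, clean target X).
ae_grad <- function(X, Xc, p, l2 = 0) {
  n <- nrow(X)
  H <- encode(Xc, p)
  Xh <- decode(H, p)
  loss <- mean(rowSums((Xh - X)^2)) / 2 +
    l2 / 2 * (sum(p$W1^2) + sum(p$W2^2))
  d2 <- (Xh - X) * Xh * (1 - Xh) / n
  d1 <- (d2 %*% p$W2) * H * (1 - H)
  list(loss = loss,
       gW2 = t(d2) %*% H + l2 * p$W2, gb2 = colSums(d2),
       gW1 = t(d1) %*% Xc + l2 * p$W1, gb1 = colSums(d1))
}

#' Train one denoising autoencoder layer
#'
#' Minibatch stochastic gradient descent on the reconstruction error of
#' corrupted inputs against clean targets.
#'
#' @param X row-matrix of inputs scaled to \[0, 1\].
#' @param hidden number of hidden units (>= 1).
#' @param cfg a [train_config()].
#' @return list with `params` (the trained autoencoder parameters) and
#'   `loss` (the per-epoch mean batch loss curve).
#' @export
train_autoencoder <- function(X, hidden, cfg = train_config()) {
  X <- as_row_matrix(X, ncol(X))
  if (hidden < 1) stop_input("hidden must be >= 1")
  with_seed(cfg$seed, train_autoencoder_impl(X, hidden, cfg))
}

train_autoencoder_impl <- function(X, hidden, cfg) {
  n <- nrow(X)
  p <- init_ae_params(ncol(X), hidden)
  lr <- cfg$learning_rate
  losses <- numeric(cfg$epochs_pretrain)
  for (epoch in seq_len(cfg$epochs_pretrain)) {
    perm <- sample.int(n)
    for (start in seq(1, n, by = cfg$batch_size)) {
      idx <- perm[start:min(start + cfg$batch_size - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      Xc <- corrupt(Xb, cfg$corruption_p)
      g <- ae_grad(Xb, Xc, p, cfg$l2)
      if (!is.finite(g$loss))
        stop("non-finite pretraining loss at epoch ", epoch,
             "; reduce the learning rate")
      p$W1 <- p$W1 - lr * g$gW1; p$b1 <- p$b1 - lr * g$gb1
      p$W2 <- p$W2 - lr * g$gW2; p$b2 <- p$b2 - lr * g$gb2
    }
    # training curve: clean full-data reconstruction error at epoch end
    losses[epoch] <- reconstruction_error(X, p)
  }
  list(params = p, loss = losses)
}

#' Greedy layer-wise pretraining of an autoencoder stack
#'
#' Trains the first layer on the inputs, then each subsequent layer on the
#' encoded output of the layers before it.
#'
#' @param X row-matrix of inputs scaled to \[0, 1\].
#' @param layer_sizes hidden-unit counts, e.g. `c(200, 200)`.
#' @param cfg a [train_config()]; layer k trains with derived seed
#'   `seed + k`.
#' @return list with `layers` (one parameter set per hidden layer) and
#'   `loss` (list of per-layer training curves).
#' @export
stack_pretrain <- function(X, layer_sizes, cfg = train_config()) {
  if (length(layer_sizes) == 0) stop_input("layer_sizes must be nonempty")
  layers <- vector("list", length(layer_sizes))
  curves <- vector("list", length(layer_sizes))
  A <- as_row_matrix(X, ncol(X))
  for (k in seq_along(layer_sizes)) {
    cfg_k <- cfg
    cfg_k$seed <- cfg$seed + k
    fit <- train_autoencoder(A, layer_sizes[k], cfg_k)
    layers[[k]] <- fit$params
    curves[[k]] <- fit$loss
    A <- encode(A, fit$params)
  }
  list(layers = layers, loss = curves)
}

# Forward pass through the encoder stack; returns activations per layer
# (A[[1]] = input).
stack_forward <- function(X, layers) {
  A <- vector("list", length(layers) + 1L)
  A[[1]] <- X
  for (k in seq_along(layers)) A[[k + 1]] <- encode(A[[k]], layers[[k]])
  A
}

softmax_rows <- function(L) {
  m <- apply(L, 1, max)
  E <- exp(L - m)
  E / rowSums(E)
}

# Cross-entropy loss and gradients through softmax and all encoder layers.
softmax_grad <- function(layers, Ws, bs, X, y, l2 = 0) {
  n <- nrow(X)
  A <- stack_forward(X, layers)
  top <- A[[length(A)]]
  L <- sweep(top %*% t(Ws), 2, bs, "+")
  P <- softmax_rows(L)
  Y <- cbind(1 - y, y)
  eps <- 1e-12
  loss <- -mean(log(P[cbind(seq_len(n), y + 1L)] + eps)) +
    l2 / 2 * (sum(Ws^2) + sum(vapply(layers, function(p) sum(p$W1^2),
                                     numeric(1))))
  dL <- (P - Y) / n
  gWs <- t(dL) %*% top + l2 * Ws
  gbs <- colSums(dL)
  gW1 <- vector("list", length(layers))
  gb1 <- vector("list", length(layers))
  delta <- (dL %*% Ws) * top * (1 - top)
  for (k in rev(seq_along(layers))) {
    gW1[[k]] <- t(delta) %*% A[[k]] + l2 * layers[[k]]$W1
    gb1[[k]] <- colSums(delta)
    if (k > 1)
      delta <- (delta %*% layers[[k]]$W1) * A[[k]] * (1 - A[[k]])
  }
  list(loss = loss, gWs = gWs, gbs = gbs, gW1 = gW1, gb1 = gb1)
}

#' Supervised fine-tuning of a pretrained stack
#'
#' Adds a 2-class softmax on top of the encoder stack (decoders are
#' discarded) and minimizes the cross-entropy by minibatch SGD through all
#' encoder layers.
#'
#' @param stack result of [stack_pretrain()] (or its `layers` element).
#' @param X row-matrix of inputs scaled to \[0, 1\].
#' @param y binary labels (both classes must be present).
#' @param cfg a [train_config()].
#' @param feature_names optional column names recorded in the model.
#' @param scaler optional min-max scaler recorded in the model (as fitted
#'   by [sae_train()]).
#' @return an object of class `sae_classifier`.
#' @export
fine_tune <- function(stack, X, y, cfg = train_config(),
                      feature_names = NULL, scaler = NULL) {
  layers <- if (!is.null(stack$layers)) stack$layers else stack
  X <- as_row_matrix(X, ncol(layers[[1]]$W1))
  y <- check_labels(y)
  if (length(unique(y)) < 2)
    stop_input("y must contain both classes")
  if (length(y) != nrow(X)) stop_input("X and y sizes differ")
  if (is.null(feature_names)) feature_names <- colnames(X)
  if (is.null(scaler))
    scaler <- list(min = rep(0, ncol(X)), range = rep(1, ncol(X)))
  hid <- nrow(layers[[length(layers)]]$W1)
  with_seed(cfg$seed + 104729L, {
    Ws <- matrix(0, 2, hid); bs <- rep(0, 2)
    n <- nrow(X)
    lr <- cfg$learning_rate
    # Polyak tail averaging: parameters are averaged over the final
    # quarter of fine-tuning epochs, the standard variance-reduction for
    # constant-step SGD.
    tail_from <- max(1L, ceiling(0.75 * cfg$epochs_finetune))
    navg <- 0
    avg <- NULL
    for (epoch in seq_len(cfg$epochs_finetune)) {
      perm <- sample.int(n)
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- perm[start:min(start + cfg$batch_size - 1L, n)]
        Xb <- corrupt(X[idx, , drop = FALSE], cfg$corruption_p)
        g <- softmax_grad(layers, Ws, bs, Xb, y[idx], cfg$l2)
        if (!is.finite(g$loss))
          stop("non-finite fine-tuning loss at epoch ", epoch,
               "; reduce the learning rate")
        Ws <- Ws - lr * g$gWs; bs <- bs - lr * g$gbs
        for (k in seq_along(layers)) {
          layers[[k]]$W1 <- layers[[k]]$W1 - lr * g$gW1[[k]]
          layers[[k]]$b1 <- layers[[k]]$b1 - lr * g$gb1[[k]]
        }
      }
      if (epoch >= tail_from) {
        snap <- list(Ws = Ws, bs = bs,
                     W1 = lapply(layers, `[[`, "W1"),
                     b1 = lapply(layers, `[[`, "b1"))
        if (is.null(avg)) {
          avg <- snap
        } else {
          wmix <- function(a, b) a + (b - a) / (navg + 1)
          avg$Ws <- wmix(avg$Ws, snap$Ws)
          avg$bs <- wmix(avg$bs, snap$bs)
          for (k in seq_along(layers)) {
            avg$W1[[k]] <- wmix(avg$W1[[k]], snap$W1[[k]])
            avg$b1[[k]] <- wmix(avg$b1[[k]], snap$b1[[k]])
          }
        }
        navg <- navg + 1
      }
    }
    Ws <- avg$Ws; bs <- avg$bs
    for (k in seq_along(layers)) {
      layers[[k]]$W1 <- avg$W1[[k]]
      layers[[k]]$b1 <- avg$b1[[k]]
    }
    structure(list(layers = layers, softmax_W = Ws, softmax_b = bs,
                   layer_sizes = c(ncol(layers[[1]]$W1),
                                   vapply(layers, function(p) nrow(p$W1),
                                          integer(1))),
                   scaler = scaler,
                   feature_names = as.character(feature_names),
                   train_config = cfg),
              class = "sae_classifier")
  })
}

# Min-max scaler fitted on training data; constant columns get range 1 so
# they map to 0.
fit_scaler <- function(X) {
  mn <- apply(X, 2, min)
  rg <- apply(X, 2, max) - mn
  rg[rg < .Machine$double.eps] <- 1
  list(min = mn, range = rg)
}

apply_scaler <- function(X, scaler) {
  sweep(sweep(X, 2, scaler$min), 2, scaler$range, "/")
}

#' Train a stacked denoising autoencoder classifier
#'
#' End-to-end training: fits a min-max scaler on the training data (all
#' inputs are mapped to \[0, 1\] using training-set statistics only),
#' greedily pretrains the autoencoder stack, then fine-tunes with a
#' softmax top layer.
#'
#' @param X numeric feature matrix (cases in rows).
#' @param y binary labels.
#' @param hidden hidden-layer sizes, e.g. `c(200, 200)`.
#' @param cfg a [train_config()].
#' @return an `sae_classifier`; use [predict_proba()] or
#'   [predict.sae_classifier()] on new data.
#' @export
sae_train <- function(X, y, hidden = c(200, 200), cfg = train_config()) {
  X <- as_row_matrix(X, ncol(X))
  y <- check_labels(y)
  scaler <- fit_scaler(X)
  Xs <- apply_scaler(X, scaler)
  stack <- stack_pretrain(Xs, hidden, cfg)
  model <- fine_tune(stack, Xs, y, cfg, feature_names = colnames(X),
                     scaler = scaler)
  model$pretrain_loss <- stack$loss   # per-layer training curves
  model
}

#' Class probabilities from a stacked-autoencoder classifier
#'
#' @param model an `sae_classifier`.
#' @param X feature matrix on the original (unscaled) feature scale.
#' @return matrix with one row per case and columns `benign`,
#'   `malignant`; rows sum to 1.
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "sae_classifier"))
  X <- as_row_matrix(X, model$layer_sizes[1])
  Xs <- apply_scaler(X, model$scaler)
  A <- stack_forward(Xs, model$layers)
  P <- softmax_rows(sweep(A[[length(A)]] %*% t(model$softmax_W), 2,
                          model$softmax_b, "+"))
  colnames(P) <- c("benign", "malignant")
  P
}

#' Predict from a stacked-autoencoder classifier
#'
#' @param object an `sae_classifier`.
#' @param newdata feature matrix.
#' @param type `"class"` (hard 0/1 labels at the 0.5 threshold),
#'   `"prob"` (probability matrix) or `"score"` (malignant probability).
#' @param ... unused.
#' @export
predict.sae_classifier <- function(object, newdata,
                                   type = c("class", "prob", "score"),
                                   ...) {
  type <- match.arg(type)
  P <- predict_proba(object, newdata)
  switch(type,
         prob = P,
         score = P[, "malignant"],
         class = as.integer(P[, "malignant"] > 0.5))
}

#' @export
print.sae_classifier <- function(x, ...) {
  cat(sprintf("sae_classifier: layers [%s], %d input features\n",
              paste(x$layer_sizes[-1], collapse = ", "),
              x$layer_sizes[1]))
  invisible(x)
}
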