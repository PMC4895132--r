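# Stacked denoising autoencoder: primitives, gradients, training.

test_that("sigmoid is correct, symmetric and saturation-stable", {
  expect_equal(sigmoid(0), 0.5)
  for (z in c(1, 5, 50)) expect_equal(sigmoid(-z), 1 - sigmoid(z))
  expect_equal(sigmoid(1000), 1)
  expect_equal(sigmoid(-1000), 0)
  expect_false(any(is.nan(sigmoid(c(-1e3, 1e3)))))
  expect_equal(sigmoid(1), 0.7310586, tolerance = 1e-6)
})

test_that("encode/decode implement the sigmoid affine maps", {
  p <- list(W1 = matrix(0, 3, 4), b1 = rep(0, 3),
            W2 = matrix(0, 4, 3), b2 = rep(0, 4))
  expect_equal(as.numeric(encode(rep(2, 4), p)), rep(0.5, 3))
  expect_equal(as.numeric(decode(rep(2, 3), p)), rep(0.5, 4))
  p1 <- list(W1 = matrix(2, 1, 1), b1 = -1, W2 = matrix(1, 1, 1), b2 = 0)
  expect_equal(as.numeric(encode(1, p1)), sigmoid(1))
  expect_error(encode(rep(1, 5), p), class = "mammocad_input_error")
  h <- decode(matrix(runif(6), 2, 3), p)
  expect_true(all(h > 0 & h < 1))
  expect_equal(ncol(h), 4)  # reconstruction has the input dimension
})

test_that("reconstruction error matches the closed form and ignores row order", {
  p <- list(W1 = matrix(0, 2, 2), b1 = c(10, 10),
            W2 = matrix(0, 2, 2), b2 = c(0, 0))
  # decode always gives 0.5: error for x = (1, 0) is 0.25
  expect_equal(reconstruction_error(matrix(c(1, 0), 1, 2), p), 0.25)
  X <- matrix(runif(20), 10, 2)
  expect_equal(reconstruction_error(X, p),
               reconstruction_error(X[10:1, ], p))
})

test_that("masking corruption hits the requested fraction", {
  x <- rep(1, 1e4)
  expect_identical(corrupt(x, 0, seed = 1), x)
  expect_identical(corrupt(x, 1, seed = 1), rep(0, 1e4))
  frac <- mean(corrupt(x, 0.3, seed = 7) == 0)
  expect_lt(abs(frac - 0.3), 0.02)
  expect_identical(corrupt(x, 0.3, seed = 7), corrupt(x, 0.3, seed = 7))
})

test_that("analytic pretraining gradients match central finite differences", {
  set.seed(13)
  X <- matrix(runif(4 * 5), 4, 5)
  Xc <- corrupt(X, 0.3, seed = 2)
  p <- mammocad:::init_ae_params(5, 3)
  g <- mammocad:::ae_grad(X, Xc, p, l2 = 0.01)
  for (nm in c("W1", "b1", "W2", "b2")) {
    loss_at <- function(v) {
      p2 <- p; p2[[nm]] <- array(v, dim = if (is.null(dim(p[[nm]])))
        length(p[[nm]]) else dim(p[[nm]]))
      if (is.null(dim(p[[nm]]))) p2[[nm]] <- as.numeric(p2[[nm]])
      mammocad:::ae_grad(X, Xc, p2, l2 = 0.01)$loss
    }
    gn <- finite_diff(loss_at, p[[nm]])
    ga <- g[[paste0("g", nm)]]
    expect_lt(max(abs(gn - ga)) / max(abs(ga)), 1e-5)
  }
})

test_that("analytic fine-tuning gradients match central finite differences", {
  set.seed(19)
  X <- matrix(runif(6 * 5), 6, 5)
  y <- c(0L, 1L, 1L, 0L, 1L, 0L)
  layers <- list(mammocad:::init_ae_params(5, 4),
                 mammocad:::init_ae_params(4, 3))
  Ws <- matrix(rnorm(6, sd = 0.3), 2, 3)
  bs <- rnorm(2, sd = 0.1)
  g <- mammocad:::softmax_grad(layers, Ws, bs, X, y, l2 = 0.01)
  # softmax weights
  gn <- finite_diff(function(v) {
    mammocad:::softmax_grad(layers, matrix(v, 2, 3), bs, X, y, 0.01)$loss
  }, as.numeric(Ws))
  expect_lt(max(abs(gn - as.numeric(g$gWs))) / max(abs(g$gWs)), 1e-5)
  # every encoder layer
  for (k in 1:2) {
    gn1 <- finite_diff(function(v) {
      l2c <- layers; l2c[[k]]$W1 <- matrix(v, nrow(layers[[k]]$W1),
                                           ncol(layers[[k]]$W1))
      mammocad:::softmax_grad(l2c, Ws, bs, X, y, 0.01)$loss
    }, as.numeric(layers[[k]]$W1))
    expect_lt(max(abs(gn1 - as.numeric(g$gW1[[k]]))) /
                max(abs(g$gW1[[k]])), 1e-5)
    gnb <- finite_diff(function(v) {
      l2c <- layers; l2c[[k]]$b1 <- v
      mammocad:::softmax_grad(l2c, Ws, bs, X, y, 0.01)$loss
    }, layers[[k]]$b1)
    expect_lt(max(abs(gnb - g$gb1[[k]])) / max(abs(g$gb1[[k]])), 1e-5)
  }
})

test_that("pretraining reduces reconstruction error and is seed-reproducible", {
  set.seed(23)
  X <- matrix(runif(100 * 10), 100, 10)
  cfg <- train_config(epochs_pretrain = 100, epochs_finetune = 5,
                      learning_rate = 0.1, corruption_p = 0, seed = 4)
  fit <- train_autoencoder(X, 6, cfg)
  expect_lt(tail(fit$loss, 1), fit$loss[1])
  expect_identical(fit, train_autoencoder(X, 6, cfg))
  # epoch-averaged loss is non-increasing over the last half (1e-3 band)
  tailcurve <- fit$loss[(length(fit$loss) %/% 2):length(fit$loss)]
  expect_true(all(diff(tailcurve) < 1e-3))
})

test_that("stacked pretraining chains layer dimensions and reduces error", {
  tab <- simulate_feature_table(60, 15, "linear", 2, seed = 9)
  Xs <- mammocad:::apply_scaler(tab$x, mammocad:::fit_scaler(tab$x))
  cfg <- train_config(epochs_pretrain = 25, epochs_finetune = 5,
                      learning_rate = 1, seed = 5)
  st <- stack_pretrain(Xs, c(12, 7), cfg)
  expect_length(st$layers, 2)
  expect_identical(dim(st$layers[[1]]$W1), c(12L, 15L))
  expect_identical(dim(st$layers[[2]]$W1), c(7L, 12L))
  for (k in 1:2) expect_lt(tail(st$loss[[k]], 1), st$loss[[k]][1])
  h2 <- encode(encode(Xs, st$layers[[1]]), st$layers[[2]])
  expect_true(all(h2 > 0 & h2 < 1))
})

test_that("the full pipeline is deterministic and learns a separable toy", {
  tab <- simulate_feature_table(200, 15, "linear", 4, seed = 12)
  cfg <- train_config(epochs_pretrain = 20, epochs_finetune = 60, seed = 3)
  m <- sae_train(tab$x, tab$y, hidden = c(10, 10), cfg = cfg)
  m2 <- sae_train(tab$x, tab$y, hidden = c(10, 10), cfg = cfg)
  expect_identical(m, m2)
  expect_gte(mean(predict(m, tab$x) == tab$y), 0.95)
  P <- predict_proba(m, tab$x)
  expect_equal(rowSums(P), rep(1, 200), tolerance = 1e-12)
  expect_identical(as.integer(P[, "malignant"] > 0.5),
                   predict(m, tab$x, type = "class"))
  expect_error(fine_tune(m$layers, tab$x, rep(1L, 200), cfg),
               class = "mammocad_input_error")
})

test_that("the stored scaler reproduces the training matrix exactly", {
  tab <- simulate_feature_table(50, 26, "linear", 2, seed = 8)
  sc <- mammocad:::fit_scaler(tab$x)
  Xs <- mammocad:::apply_scaler(tab$x, sc)
  expect_true(all(Xs >= 0 & Xs <= 1))
  expect_identical(Xs, mammocad:::apply_scaler(tab$x, sc))
})
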