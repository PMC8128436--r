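# The convolutional regressor is implemented from scratch, so the first
# tests guard the machinery itself (gradients, determinism) before the
# behavioural ones.

encoded_fixture <- function(n, L_max = 10, seed = 1) {
  l1 <- random_loops(n, 4, 6, seed = seed)
  l2 <- random_loops(n, 4, 6, seed = seed + 1000)
  encode_loop_pairs(l1, l2, az_scaffold_fx, L_max = L_max)
}

test_that("backpropagated gradients match finite differences", {
  for (act in c("linear", "relu")) {
    cfg <- cnn_config(n_filters = 3, conv_activation = act, dense_units = 5,
                      dropout_conv = 0, dropout_dense = 0, epochs = 1, seed = 1)
    L_max <- 10
    enc <- encoded_fixture(5, L_max = L_max, seed = 3)
    X <- enc$X
    y <- withr::with_seed(4, rnorm(nrow(X)))
    im <- aptazyme:::conv_index_map(L_max)
    par <- withr::with_seed(5, aptazyme:::cnn_init(L_max, cfg))
    # move biases off zero so no pre-activation sits exactly at the relu kink
    par <- withr::with_seed(7, lapply(par, function(p) p + rnorm(length(p), sd = 0.05)))
    loss_at <- function(par) {
      fw <- aptazyme:::cnn_forward(X, par, im, cfg, train = FALSE)
      mean((fw$yhat - y)^2)
    }
    fw <- aptazyme:::cnn_forward(X, par, im, cfg, train = FALSE)
    gr <- aptazyme:::cnn_backward(fw, y, par, cfg)
    eps <- 1e-6
    for (nm in names(par)) {
      probe <- withr::with_seed(6, sample(length(par[[nm]]),
                                          min(5, length(par[[nm]]))))
      for (j in probe) {
        pp <- par; pp[[nm]][j] <- pp[[nm]][j] + eps
        pm <- par; pm[[nm]][j] <- pm[[nm]][j] - eps
        fd <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
        expect_equal(gr[[nm]][j], fd, tolerance = 1e-4,
                     label = sprintf("%s grad %s[%d]", act, nm, j))
      }
    }
  }
})

test_that("training on constant labels converges to that constant", {
  enc <- encoded_fixture(60, seed = 11)
  y <- rep(0.42, nrow(enc$X))
  m <- train_cnn(enc$X, y, cnn_config(epochs = 150, batch_size = 8, seed = 2))
  expect_true(all(abs(predict(m, enc$X) - 0.42) < 0.05))
})

test_that("the recorded loss trace descends and training is seeded", {
  enc <- encoded_fixture(120, seed = 12)
  y <- withr::with_seed(13, rnorm(nrow(enc$X), sd = 0.3))
  cfg <- cnn_config(epochs = 15, batch_size = 32, seed = 7)
  m1 <- train_cnn(enc$X, y, cfg)
  m2 <- train_cnn(enc$X, y, cfg)
  expect_lte(m1$history$train_loss[nrow(m1$history)], m1$history$train_loss[1])
  expect_identical(predict(m1, enc$X), predict(m2, enc$X))
})

test_that("inference is deterministic and batch-size invariant", {
  enc <- encoded_fixture(50, seed = 14)
  y <- withr::with_seed(15, rnorm(nrow(enc$X)))
  m <- train_cnn(enc$X, y, cnn_config(epochs = 5, seed = 3))
  p1 <- predict(m, enc$X)
  p2 <- predict(m, enc$X)
  expect_identical(p1, p2)
  # batch prediction equals concatenated single-record predictions
  singles <- vapply(seq_len(10), function(i) {
    predict(m, as_encoded(enc$X[i, , drop = FALSE], enc$X))
  }, numeric(1))
  expect_equal(singles, p1[1:10], tolerance = 1e-12)
})

test_that("model artifacts round-trip bit-identically", {
  enc <- encoded_fixture(40, seed = 16)
  y <- withr::with_seed(17, rnorm(nrow(enc$X)))
  m <- train_cnn(enc$X, y, cnn_config(epochs = 3, seed = 4))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  m2 <- load_model(path)
  expect_identical(predict(m, enc$X), predict(m2, enc$X))
})

test_that("encoder metadata mismatches are refused", {
  enc8 <- encoded_fixture(30, L_max = 10, seed = 18)
  enc16 <- encoded_fixture(30, L_max = 16, seed = 18)
  y <- withr::with_seed(19, rnorm(30))
  m <- train_cnn(enc8$X, y, cnn_config(epochs = 2, seed = 1))
  expect_error(predict(m, enc16$X), class = "az_metadata_error")
  Xbare <- enc8$X
  attr(Xbare, "encoder") <- NULL
  expect_error(predict(m, Xbare), class = "az_metadata_error")
  expect_error(train_cnn(enc8$X, y[1:10]), class = "az_shape_error")
  expect_error(train_cnn(enc8$X, c(y[-1], NA)), class = "az_label_error")
})

test_that("lasso recovers a realisable linear target", {
  enc <- encoded_fixture(300, seed = 20)
  beta <- withr::with_seed(21, rnorm(ncol(enc$X), sd = 0.2) *
                             (runif(ncol(enc$X)) < 0.05))
  y <- drop(enc$X %*% beta)
  m <- train_baseline("lasso", enc$X, y, seed = 2)
  expect_gt(r_squared(predict(m, enc$X), y)$r2_pearson, 0.99)
})

test_that("lasso on pure-noise labels selects a near-constant model", {
  enc <- encoded_fixture(200, seed = 22)
  y <- withr::with_seed(23, rnorm(nrow(enc$X)))
  m <- train_baseline("lasso", enc$X, y, seed = 2)
  co <- coef(m$fit, s = "lambda.1se")
  expect_lt(sum(abs(co[-1])), 0.1)
})

test_that("forest and svm baselines are seeded and reproducible", {
  enc <- encoded_fixture(80, seed = 24)
  y <- withr::with_seed(25, rnorm(nrow(enc$X)))
  for (kind in c("random_forest", "svm")) {
    m1 <- train_baseline(kind, enc$X, y, seed = 5)
    m2 <- train_baseline(kind, enc$X, y, seed = 5)
    expect_identical(predict(m1, enc$X), predict(m2, enc$X))
  }
})

test_that("the convolutional model beats lasso on the interaction surrogate", {
  tab <- generate_training_set(4000, loop_lengths = 5:8, seed = 31)
  enc <- encode_loop_pairs(tab$loop1, tab$loop2, az_scaffold_fx, L_max = 16)
  y <- tab$activity[enc$kept]
  sp <- split_train_test(length(y), 0.75, seed = 32)
  Xtr <- as_encoded(enc$X[sp$train, ], enc$X)
  Xte <- as_encoded(enc$X[sp$test, ], enc$X)
  cnn <- train_cnn(Xtr, y[sp$train], cnn_config(epochs = 40, seed = 6))
  lasso <- train_baseline("lasso", Xtr, y[sp$train], seed = 6)
  r2_cnn <- r_squared(predict(cnn, Xte), y[sp$test])$r2_pearson
  r2_lasso <- r_squared(predict(lasso, Xte), y[sp$test])$r2_pearson
  expect_gt(r2_cnn, r2_lasso)
})
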