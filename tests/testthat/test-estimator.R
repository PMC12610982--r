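test_that("mixup is an exact convex combination with exact endpoints", {
  set.seed(61)
  x_i <- array(rnorm(24), c(2, 3, 4))
  x_j <- array(rnorm(24), c(2, 3, 4))
  y_i <- runif(4); y_j <- runif(4)

  m1 <- mixup(x_i, x_j, y_i, y_j, lambda = 1)
  expect_identical(m1$x, x_i)
  expect_identical(m1$y, y_i)
  m0 <- mixup(x_i, x_j, y_i, y_j, lambda = 0)
  expect_identical(m0$x, x_j)
  expect_identical(m0$y, y_j)

  ms <- mixup(4, 8, 1, 0, lambda = 0.25)
  expect_equal(ms$x, 7)
  expect_equal(ms$y, 0.25)

  for (lam in runif(20)) {
    m <- mixup(x_i, x_j, y_i, y_j, lam)
    expect_true(all(m$x >= pmin(x_i, x_j) - 1e-12))
    expect_true(all(m$x <= pmax(x_i, x_j) + 1e-12))
    expect_true(all(m$y >= pmin(y_i, y_j) - 1e-12))
    expect_true(all(m$y <= pmax(y_i, y_j) + 1e-12))
  }
  expect_error(mixup(x_i, x_j[, , 1:3], y_i, y_j, 0.5), "shape")
  expect_error(mixup(x_i, x_j, y_i, y_j, 1.5), "lambda")
})

test_that("lambda draws follow Beta(alpha, alpha)", {
  set.seed(62)
  lam1 <- replicate(1e4, sample_lambda(mixup_config(alpha = 1)))
  expect_true(all(lam1 >= 0 & lam1 <= 1))
  expect_lt(abs(mean(lam1) - 0.5), 0.015)
  lam02 <- replicate(1e4, sample_lambda(mixup_config(alpha = 0.2)))
  expect_gt(var(lam02), var(lam1))
})

rand_tensor <- function(M = 7, WL = 4, Fd = 12, mask = NULL) {
  x <- array(rnorm(M * WL * Fd), c(M, WL, Fd))
  if (is.null(mask)) mask <- matrix(TRUE, M, WL)
  structure(x, mask = mask, motions = fma_motions()[seq_len(M)],
            class = "fmaue_tensor")
}

grad_cfg <- model_config(input_size = 12, encoder_hidden = 5, latent = 4,
                         predictor_hidden = 4, epochs = 1, lr = 1e-3)

test_that("the forward pass honours the shape contract", {
  model <- init_estimator(grad_cfg, n_motions = 7, seed = 3)
  tens <- rand_tensor()
  lat <- encode(model, tens)
  expect_equal(dim(lat), c(7, 4))
  out <- predict_from_latent(model, lat)
  expect_equal(dim(out), c(1, 4))
  expect_equal(predict(model, tens), out)
  # inference is deterministic (dropout inactive)
  expect_identical(predict(model, tens), predict(model, tens))
})

test_that("motions are encoded independently and order matters downstream", {
  model <- init_estimator(grad_cfg, n_motions = 7, seed = 4)
  t1 <- rand_tensor()
  t2 <- t1
  t2[7, , ] <- rnorm(4 * 12)
  l1 <- encode(model, t1)
  l2 <- encode(model, t2)
  expect_lt(max(abs(l1[1:6, ] - l2[1:6, ])), 1e-12)
  expect_gt(max(abs(l1[7, ] - l2[7, ])), 1e-6)

  # permuting the motion axis changes the prediction in general
  perm <- c(2, 1, 3, 4, 5, 7, 6)
  t3 <- structure(unclass(t1)[perm, , ], mask = attr(t1, "mask")[perm, ],
                  motions = attr(t1, "motions")[perm],
                  class = "fmaue_tensor")
  expect_gt(max(abs(predict(model, t1) - predict(model, t3))), 1e-8)
})

test_that("padded window slots are excluded from the pooled latent", {
  model <- init_estimator(grad_cfg, n_motions = 7, seed = 5)
  full <- rand_tensor(WL = 6)
  # pad motion 2 from 4 real windows to 6 by repeating the last window
  padded <- full
  padded[2, 5, ] <- padded[2, 4, ]
  padded[2, 6, ] <- padded[2, 4, ]
  mask <- attr(padded, "mask")
  mask[2, 5:6] <- FALSE
  attr(padded, "mask") <- mask

  truncated <- full
  truncated[2, 5, ] <- rnorm(12)  # junk in masked slots must not matter
  truncated[2, 6, ] <- rnorm(12)
  attr(truncated, "mask") <- mask

  expect_lt(max(abs(encode(model, padded) - encode(model, truncated))),
            1e-6)
})

test_that("analytic gradients match finite differences", {
  set.seed(66)
  cfg <- grad_cfg
  model <- init_estimator(cfg, n_motions = 7, seed = 7)
  par <- model$params
  B <- 2; M <- 7; WL <- 3; Fd <- 12
  X <- array(rnorm(B * M * WL * Fd), c(B, M, WL, Fd))
  mask <- array(TRUE, c(B, M, WL))
  mask[1, 2, 3] <- FALSE
  y <- matrix(runif(B * 4), B, 4)

  lg <- fmaue:::estimator_loss_grads(par, X, mask, y, cfg)
  eps <- 1e-6
  for (nm in names(par)) {
    idx <- sample(length(par[[nm]]), min(5, length(par[[nm]])))
    for (i in idx) {
      pp <- par; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- par; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (fmaue:::estimator_loss_grads(pp, X, mask, y, cfg)$loss -
              fmaue:::estimator_loss_grads(pm, X, mask, y, cfg)$loss) /
        (2 * eps)
      ana <- lg$grads[[nm]][i]
      expect_lt(abs(num - ana), 1e-6 + 1e-4 * abs(num))
    }
  }
})

test_that("training memorizes a single sample with mixup off", {
  set.seed(68)
  tens <- rand_tensor()
  y <- matrix(c(0.8, 0.3, 0.5, 0.1), 1, 4)
  cfg <- model_config(input_size = 12, encoder_hidden = 5, latent = 4,
                      predictor_hidden = 4, epochs = 500, lr = 5e-3,
                      dropout = 0, batch_size = 1)
  m <- train_estimator(list(tens), y, cfg, mixup_config(apply_prob = 0),
                       seed = 9)
  expect_lt(tail(m$history$mse, 1), 1e-3)
})

test_that("training is bit-reproducible per seed and loss descends", {
  set.seed(69)
  tensors <- lapply(1:6, function(i) rand_tensor())
  ys <- matrix(runif(24), 6, 4)
  cfg <- model_config(input_size = 12, encoder_hidden = 5, latent = 4,
                      predictor_hidden = 4, epochs = 30, lr = 2e-3,
                      batch_size = 4)
  m1 <- train_estimator(tensors, ys, cfg, mixup_config(), seed = 11)
  m2 <- train_estimator(tensors, ys, cfg, mixup_config(), seed = 11)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  expect_lt(tail(m1$history$mse, 1), m1$history$mse[1])
})

test_that("apply_prob = 0 reduces training to plain MSE regression", {
  set.seed(70)
  tensors <- lapply(1:4, function(i) rand_tensor())
  ys <- matrix(runif(16), 4, 4)
  cfg <- model_config(input_size = 12, encoder_hidden = 5, latent = 4,
                      predictor_hidden = 4, epochs = 5, lr = 2e-3,
                      dropout = 0, batch_size = 2)
  # alpha is irrelevant when no batch is ever mixed
  m1 <- train_estimator(tensors, ys, cfg,
                        mixup_config(alpha = 1, apply_prob = 0), seed = 2)
  m2 <- train_estimator(tensors, ys, cfg,
                        mixup_config(alpha = 9, apply_prob = 0), seed = 2)
  expect_identical(m1$history, m2$history)
})

test_that("checkpoints round-trip the estimator and its predictions", {
  set.seed(72)
  tens <- rand_tensor()
  cfg <- model_config(input_size = 12, encoder_hidden = 5, latent = 4,
                      predictor_hidden = 4, epochs = 3, lr = 1e-3,
                      batch_size = 1)
  m <- train_estimator(list(tens, rand_tensor()), matrix(runif(8), 2, 4),
                       cfg, mixup_config(), seed = 3)
  path <- withr::local_tempfile(fileext = ".rds")
  save_estimator(m, path)
  m2 <- load_estimator(path)
  expect_identical(predict(m2, tens), predict(m, tens))
  expect_identical(m2$history, m$history)
})

test_that("loss on a lambda = 1 mixed batch equals the unmixed loss", {
  set.seed(71)
  cfg <- grad_cfg
  par <- init_estimator(cfg, n_motions = 7, seed = 13)$params
  X <- array(rnorm(2 * 7 * 3 * 12), c(2, 7, 3, 12))
  Xj <- array(rnorm(2 * 7 * 3 * 12), c(2, 7, 3, 12))
  mask <- array(TRUE, c(2, 7, 3))
  y <- matrix(runif(8), 2, 4)
  yj <- matrix(runif(8), 2, 4)
  mixed <- mixup(X, Xj, y, yj, lambda = 1)
  l1 <- fmaue:::estimator_loss_grads(par, mixed$x, mask, mixed$y, cfg)$loss
  l2 <- fmaue:::estimator_loss_grads(par, X, mask, y, cfg)$loss
  expect_identical(l1, l2)
})
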