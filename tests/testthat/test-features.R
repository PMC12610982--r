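test_that("the feature registry is a stable 1530-entry bijection", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 1530)
  expect_length(channel_names(), 153)
  expect_false(anyDuplicated(reg$label) > 0)
  expect_equal(reg$index, seq_len(1530))
  # channel-major, statistic-minor: index maps back to (channel, statistic)
  i <- c(1, 10, 11, 777, 1530)
  expect_equal(reg$channel[i],
               channel_names()[(i - 1) %/% 10 + 1])
  expect_equal(reg$statistic[i],
               fmaue:::FEATURE_STATS[(i - 1) %% 10 + 1])
})

test_that("approximate entropy matches its definition", {
  expect_equal(approximate_entropy(rep(5, 50)), 0)

  periodic <- rep(c(1, 2), 50)
  sdv <- sqrt(mean((periodic - mean(periodic))^2))
  ap <- approximate_entropy(periodic, m = 2, r = 0.2 * sdv)
  expect_lt(ap, 0.05)
  expect_equal(ap, oracle_apen(periodic, 2, 0.2 * sdv), tolerance = 1e-10)

  set.seed(50)
  x <- rnorm(50)
  r <- 0.2 * sd(x)
  expect_lt(abs(approximate_entropy(x, 2, r) - oracle_apen(x, 2, r)), 1e-10)
  expect_error(approximate_entropy(c(1, 2, 3), m = 2), "too short")
})

test_that("window statistics agree with brute-force formulas", {
  # constant channel: closed forms
  w <- matrix(rnorm(200 * 153), 200, 153)
  w[, 7] <- 5
  fv <- window_features(w)
  expect_length(fv, 1530)
  expect_equal(fv[61:70],
               c(5, 0, 5, 0, 5, 5, 0, 0, 5, 0))

  # deterministic ramp and random channels against the oracle
  w[, 1] <- (1:200) / 200
  fv <- window_features(w)
  for (ch in c(1, 2, 100, 153)) {
    idx <- ((ch - 1) * 10 + 1):(ch * 10)
    expect_equal(unname(fv[idx]), unname(oracle_stats(w[, ch])),
                 tolerance = 1e-10)
  }
  expect_error(window_features(w[, 1:100]), "153")
})

test_that("features have no hidden positional dependence across channels", {
  set.seed(55)
  w <- matrix(rnorm(120 * 153), 120, 153)
  perm <- sample(153)
  fv <- window_features(w)
  fv_perm <- window_features(w[, perm])
  # permuting input channels permutes the 10-statistic blocks identically
  blocks <- function(v) lapply(seq_len(153), function(ch) {
    v[((ch - 1) * 10 + 1):(ch * 10)]
  })
  expect_equal(blocks(fv_perm), blocks(fv)[perm])
})

test_that("a static trial zeroes all derivative and relative channels", {
  tr <- static_trial()
  ch <- prepare_trial(tr, prep_config(filter = "none", target_hz = 50))
  stack <- build_channels(ch)
  expect_equal(ncol(stack), 153)
  reg_cols <- colnames(stack)
  derived <- grepl("\\.(oacc|adiff)\\.", reg_cols) |
    grepl("\\.d1$", reg_cols) | grepl("\\.incl\\.", reg_cols) |
    grepl("^joint\\.", reg_cols) | grepl("\\.gyro\\.", reg_cols)
  expect_gt(sum(derived), 100)
  expect_lt(max(abs(stack[, derived])), 1e-6)
})

test_that("equal forearm and trunk orientations zero the inclination ratio", {
  tr <- tiny_session(seed = 31)$trials$HTS
  # overwrite the forearm orientation with the trunk's
  for (ax in c("ox", "oy", "oz")) {
    tr$recordings$forearm[[ax]] <- tr$recordings$trunk[[ax]]
  }
  ch <- prepare_trial(tr, prep_config(filter = "none", target_hz = 50))
  stack <- build_channels(ch)
  cols <- paste("forearm.incl", c("x", "y", "z"), sep = ".")
  expect_lt(max(abs(stack[, cols])), 1e-9)
})

test_that("tensor assembly pads and crops around the target window count", {
  fv <- function(val) rep(val, 1530)
  mk <- function(k) lapply(seq_len(k), fv)
  per_motion <- stats::setNames(lapply(rep(9, 7), mk), fma_motions())

  tens <- assemble_tensor(per_motion, wl = 9)
  expect_equal(dim(tens), c(7, 9, 1530))
  expect_true(all(attr(tens, "mask")))
  expect_equal(tens[3, 5, 1], 5)

  # crop: 13 windows keep the central 9 (windows 3..11)
  per_motion$RU <- mk(13)
  tens <- assemble_tensor(per_motion, wl = 9)
  expect_equal(tens[1, 1, 1], 3)
  expect_equal(tens[1, 9, 1], 11)

  # pad: 7 windows repeat the last, mask flags two slots
  per_motion$RU <- mk(7)
  tens <- assemble_tensor(per_motion, wl = 9)
  expect_equal(tens[1, 8, 1], 7)
  expect_equal(tens[1, 9, 1], 7)
  expect_equal(sum(!attr(tens, "mask")[1, ]), 2)

  per_motion$RU <- list()
  expect_error(assemble_tensor(per_motion, wl = 9), "zero windows")
})

test_that("normalization fits on training windows and round-trips scores", {
  expect_equal(norm_scores(fma_scores(36, 10, 14, 6)), rep(1, 4))
  expect_equal(norm_scores(fma_scores(18, 5, 7, 3)), rep(0.5, 4))
  expect_equal(denorm_scores(c(0.5, 0.5, 0.5, 0.5)), c(18, 5, 7, 3))
  expect_equal(denorm_scores(c(1.2, -0.1, 0.5, 2)), c(36, 0, 7, 6))

  set.seed(41)
  tensors <- lapply(1:3, function(i) {
    x <- array(rnorm(7 * 5 * 1530, mean = i), c(7, 5, 1530))
    m <- matrix(TRUE, 7, 5)
    m[1, 5] <- FALSE  # one padded slot
    structure(x, mask = m, motions = fma_motions(),
              class = "fmaue_tensor")
  })
  nrm <- fit_norm(tensors)
  zt <- lapply(tensors, function(x) apply_norm(nrm, x))
  rows <- do.call(rbind, lapply(seq_along(zt), function(i) {
    d <- dim(zt[[i]])
    flat <- matrix(aperm(unclass(zt[[i]]), c(2, 1, 3)), d[1] * d[2], d[3])
    flat[as.vector(t(attr(tensors[[i]], "mask"))), ]
  }))
  mu <- colMeans(rows)
  sdv <- sqrt(colMeans(rows^2) - mu^2)
  expect_lt(max(abs(mu)), 1e-8)
  expect_lt(max(abs(sdv - 1)), 1e-6)

  bad <- nrm
  bad$fitted <- FALSE
  expect_error(apply_norm(bad, tensors[[1]]), "before fit")
})

test_that("featurized sessions have the contracted shape", {
  s <- tiny_session(seed = 32)
  tens <- featurize_session(s, prep_config(target_hz = 50),
                            aug_cfg = augment_config(copies_per_trial = 1),
                            wl = 9, seed = 3)
  expect_length(tens, 2)
  expect_equal(dim(tens[[1]]), c(7, 9, 1530))
  expect_true(all(is.finite(tens[[1]])))
  expect_true(all(is.finite(tens[[2]])))
})
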