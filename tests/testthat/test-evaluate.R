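make_folds <- function(truth, pred, parts = c("a", "b", "c", "d")) {
  n <- length(truth) / length(parts)
  tibble::tibble(
    subject = rep(sprintf("S%02d", seq_len(n)), each = length(parts)),
    part = rep(parts, times = n),
    truth = truth, pred = pred
  )
}

test_that("metrics match an independent recomputation on a toy set", {
  truth <- c(30, 8, 12, 5,   20, 5, 9, 3,   10, 2, 4, 1,   34, 9, 13, 6)
  pred <- c(28.5, 7.2, 12.8, 4.4,  22, 5.5, 8.1, 3.3,
            12.5, 2.9, 3.2, 1.8,   33, 9.6, 12.1, 5.5)
  folds <- make_folds(truth, pred)
  m <- compute_metrics(folds)
  expect_s3_class(m, "fmaue_metrics")
  expect_equal(m$part, c("a", "b", "c", "d", "total", "overall"))

  div <- fma_ranges()
  for (p in c("a", "b", "c", "d")) {
    i <- which(rep(c("a", "b", "c", "d"), 4) == p)
    o <- oracle_metrics(truth[i], pred[i], div[[p]])
    row <- m[m$part == p, ]
    expect_equal(c(row$r2, row$r, row$mae, row$nmae, row$rmse, row$nrmse),
                 unname(o), tolerance = 1e-10)
  }
  # total over summed parts, divisor 66
  tt <- colSums(matrix(truth, 4)); tp <- colSums(matrix(pred, 4))
  o <- oracle_metrics(tt, tp, 66)
  row <- m[m$part == "total", ]
  expect_equal(c(row$r2, row$r, row$mae, row$nmae, row$rmse, row$nrmse),
               unname(o), tolerance = 1e-10)
  # overall over pooled normalized pairs, divisor 1
  i <- rep(c("a", "b", "c", "d"), 4)
  o <- oracle_metrics(truth / div[i], pred / div[i], 1)
  row <- m[m$part == "overall", ]
  expect_equal(c(row$r2, row$r, row$mae, row$nmae, row$rmse, row$nrmse),
               unname(o), tolerance = 1e-10)
})

test_that("perfect predictions give perfect metrics", {
  truth <- c(30, 8, 12, 5, 20, 5, 9, 3, 10, 2, 4, 1)
  m <- compute_metrics(make_folds(truth, truth))
  expect_equal(m$r2, rep(1, 6))
  expect_equal(m$r, rep(1, 6))
  expect_equal(m$mae + m$rmse + m$nmae + m$nrmse, rep(0, 6))
})

test_that("NMAE and NRMSE are scale invariant", {
  set.seed(81)
  truth <- runif(8, 0, 36)
  pred <- truth + rnorm(8)
  a <- fmaue:::metric_row(truth, pred, 36, "x")
  b <- fmaue:::metric_row(truth * 3, pred * 3, 36 * 3, "x")
  expect_equal(a$nmae, b$nmae, tolerance = 1e-12)
  expect_equal(a$nrmse, b$nrmse, tolerance = 1e-12)
})

test_that("constant truth reports r as NA without NaN propagation", {
  truth <- rep(c(10, 5, 7, 3), 4)
  pred <- truth + rep(c(1, -1, 0.5, -0.5), 4)
  m <- compute_metrics(make_folds(truth, pred))
  expect_true(all(is.na(m$r[1:4])))
  expect_true(all(is.finite(m$mae)))
  expect_true(all(is.finite(m$nrmse)))
})

test_that("motion sets exclude exactly the named groups", {
  expect_equal(motion_set(c("A", "B", "C")),
               setdiff(fma_motions(), "RKN"))
  expect_equal(motion_set("B"), "WC")
  expect_length(ablation_presets(), 5)
  expect_equal(ablation_presets()[["__B*C*D*"]], c("WC", "HMFE", "RKN"))
  expect_error(motion_set(character(0)), "empty")
})

test_that("LOSOCV yields one disjoint fold per subject", {
  cohort <- tiny_cohort(n = 3, seed = 91)
  res <- losocv(cohort, model_cfg = tiny_model_cfg(),
                mix_cfg = mixup_config(),
                prep_cfg = prep_config(target_hz = 50),
                aug_cfg = NULL, seed = 91)
  expect_s3_class(res, "fmaue_losocv")
  expect_equal(nrow(res), 12)  # 3 subjects x 4 parts
  expect_length(attr(res, "failures"), 0)
  expect_setequal(unique(res$subject),
                  vapply(cohort, function(s) s$subject_id, character(1)))
  expect_equal(as.vector(table(res$subject)), rep(4, 3))
  expect_true(all(is.finite(res$pred)))
  # predictions are clipped to the valid score range
  rng <- rep(unname(fma_ranges()), 3)
  expect_true(all(res$pred >= 0 & res$pred <= rng))

  g <- glance(res)
  expect_equal(g$n_folds, 3)
  expect_true(all(c("total_r2", "overall_nrmse") %in% names(g)))
})

test_that("a two-subject cohort degenerates to two single-train folds", {
  cohort <- tiny_cohort(n = 2, seed = 92)
  res <- losocv(cohort, model_cfg = tiny_model_cfg(),
                prep_cfg = prep_config(target_hz = 50),
                aug_cfg = NULL, seed = 92)
  expect_equal(length(unique(res$subject)), 2)
  expect_equal(nrow(res), 8)
})

test_that("ablation restricts the motion axis and keys rows by set", {
  cohort <- tiny_cohort(n = 3, seed = 93)
  feats <- featurize_cohort(cohort, prep_config(target_hz = 50),
                            aug_cfg = NULL, seed = 93)
  sliced <- fmaue:::slice_motions(feats$tensors[[1]][[1]],
                                  match(motion_set(c("A", "B", "C")),
                                        fma_motions()))
  expect_equal(dim(sliced)[1], 6)

  tab <- ablate(cohort,
                sets = list("A*B*C*D*" = motion_set(c("A", "B", "C", "D")),
                            "A*B*C*__" = motion_set(c("A", "B", "C"))),
                model_cfg = tiny_model_cfg(),
                prep_cfg = prep_config(target_hz = 50),
                aug_cfg = NULL, seed = 93)
  expect_equal(unique(tab$set), c("A*B*C*D*", "A*B*C*__"))
  expect_equal(nrow(tab), 12)  # 6 metric rows per arm
  expect_true(all(c("set", "part", "r2", "r", "nmae", "nrmse") %in%
                    names(tab)))
  expect_error(ablate(cohort, sets = list(none = character(0))), "empty")
})

test_that("identity permutations give zero motion contribution", {
  cohort <- tiny_cohort(n = 3, seed = 94)
  feats <- featurize_cohort(cohort, prep_config(target_hz = 50),
                            aug_cfg = NULL, seed = 94)
  train_tensors <- lapply(feats$tensors, function(tl) tl[[1]])
  nrm <- fit_norm(train_tensors)
  ys <- do.call(rbind, lapply(seq_len(3),
                              function(i) norm_scores(feats$scores[i, ])))
  model <- train_estimator(lapply(train_tensors,
                                  function(x) apply_norm(nrm, x)),
                           ys, tiny_model_cfg(), mixup_config(), seed = 1)
  contrib <- motion_contribution(model, feats, nrm, n_repeats = 2,
                                 .perms = list(1:3, 1:3))
  expect_equal(dim(contrib), c(7, 4))
  expect_true(all(unclass(contrib) == 0))
  expect_setequal(attr(contrib, "unattributed"), c("a", "b", "c", "d"))
  expect_error(motion_contribution(model, feats, nrm, n_repeats = 0),
               "n_repeats")
})

test_that("random-permutation contributions normalize per part", {
  cohort <- tiny_cohort(n = 3, seed = 95)
  feats <- featurize_cohort(cohort, prep_config(target_hz = 50),
                            aug_cfg = NULL, seed = 95)
  train_tensors <- lapply(feats$tensors, function(tl) tl[[1]])
  nrm <- fit_norm(train_tensors)
  ys <- do.call(rbind, lapply(seq_len(3),
                              function(i) norm_scores(feats$scores[i, ])))
  model <- train_estimator(lapply(train_tensors,
                                  function(x) apply_norm(nrm, x)),
                           ys, tiny_model_cfg(epochs = 10), mixup_config(),
                           seed = 1)
  contrib <- motion_contribution(model, feats, nrm, n_repeats = 2, seed = 5)
  sums <- colSums(unclass(contrib))
  ok <- setdiff(c("a", "b", "c", "d"), attr(contrib, "unattributed"))
  expect_equal(unname(sums[ok]), rep(1, length(ok)), tolerance = 1e-12)
  expect_true(all(unclass(contrib) >= 0))
})

test_that("reports round-trip and are deterministic", {
  truth <- c(30, 8, 12, 5, 20, 5, 9, 3, 10, 2, 4, 1)
  pred <- truth + rep(c(1, -0.5, 0.3, 0.2), 3)
  folds <- make_folds(truth, pred)
  class(folds) <- c("fmaue_losocv", class(folds))
  dir <- withr::local_tempdir()
  paths <- report(folds, dir = dir, plots = FALSE)
  expect_true(all(file.exists(paths)))

  m_disk <- jsonlite::read_json(paths[["metrics_json"]],
                                simplifyVector = TRUE)
  m <- compute_metrics(folds)
  expect_equal(m_disk$nrmse, m$nrmse, tolerance = 1e-12)
  preds <- readr::read_csv(paths[["predictions_csv"]],
                           show_col_types = FALSE)
  expect_equal(nrow(preds), nrow(folds))

  before <- readLines(paths[["metrics_csv"]])
  report(folds, dir = dir, plots = FALSE)
  expect_identical(readLines(paths[["metrics_csv"]]), before)
})
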