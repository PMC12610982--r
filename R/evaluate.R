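#' Featurize a whole cohort
#'
#' Runs the feature pipeline once per subject (original plus augmented
#' copies). Augmented-copy seeds are derived per subject from the master
#' seed, independently of any cross-validation fold structure, so a
#' subject's copies can later serve either as training samples (when the
#' subject is in the training fold) or as its multiple test samples (when
#' held out) without recomputation.
#'
#' @param cohort List of `fmaue_session`.
#' @param prep_cfg A [prep_config()].
#' @param aug_cfg An [augment_config()] or `NULL`.
#' @param wl Windows per motion (default 9).
#' @param seed Master seed.
#' @return List of class `fmaue_features`: `subjects` (ids), `tensors`
#'   (per subject, list of raw feature tensors), `scores` (n x 4 matrix,
#'   clinical scale), `wl`.
#' @export
featurize_cohort <- function(cohort, prep_cfg = prep_config(),
                             aug_cfg = augment_config(), wl = 9,
                             seed = 1) {
  ids <- vapply(cohort, function(s) s$subject_id, character(1))
  tensors <- lapply(seq_along(cohort), function(i) {
    featurize_session(cohort[[i]], prep_cfg, aug_cfg, wl = wl,
                      seed = derive_seed(seed, 5000 + i))
  })
  scores <- t(vapply(cohort, function(s) as.numeric(unclass(s$scores)),
                     numeric(4)))
  colnames(scores) <- c("a", "b", "c", "d")
  structure(list(subjects = ids, tensors = tensors, scores = scores,
                 wl = wl),
            class = "fmaue_features")
}

slice_motions <- function(tensor, sel) {
  out <- unclass(tensor)[sel, , , drop = FALSE]
  structure(out, mask = attr(tensor, "mask")[sel, , drop = FALSE],
            motions = attr(tensor, "motions")[sel],
            class = "fmaue_tensor")
}

# LOSOCV over precomputed features; motions may be a subset for ablation
losocv_features <- function(feats, model_cfg = model_config(),
                            mix_cfg = mixup_config(), seed = 1,
                            motions = fma_motions(), progress = FALSE) {
  n <- length(feats$subjects)
  sel <- match(motions, attr(feats$tensors[[1]][[1]], "motions"))
  if (anyNA(sel)) abort("requested motion not present in features")
  if (length(sel) == 0) abort("empty motion set")
  rows <- list()
  failures <- list()
  for (k in seq_len(n)) {
    res <- tryCatch({
      train_idx <- setdiff(seq_len(n), k)
      train_tensors <- list()
      train_scores <- list()
      for (i in train_idx) {
        for (tns in feats$tensors[[i]]) {
          train_tensors[[length(train_tensors) + 1]] <-
            slice_motions(tns, sel)
          train_scores[[length(train_scores) + 1]] <-
            norm_scores(feats$scores[i, ])
        }
      }
      nrm <- fit_norm(train_tensors)
      train_tensors <- lapply(train_tensors, function(x) apply_norm(nrm, x))
      ys <- do.call(rbind, train_scores)
      model <- train_estimator(train_tensors, ys, model_cfg, mix_cfg,
                               seed = derive_seed(seed, 1000 + k))
      preds <- vapply(feats$tensors[[k]], function(tns) {
        as.numeric(predict(model, apply_norm(nrm, slice_motions(tns, sel))))
      }, numeric(4))
      pred <- denorm_scores(rowMeans(matrix(preds, nrow = 4)))
      tibble::tibble(subject = feats$subjects[k],
                     part = c("a", "b", "c", "d"),
                     truth = as.numeric(feats$scores[k, ]),
                     pred = pred,
                     fold_seed = derive_seed(seed, 1000 + k))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[feats$subjects[k]]] <- conditionMessage(res)
    } else {
      rows[[k]] <- res
    }
    if (progress) message("fold ", k, "/", n, " done")
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("fmaue_losocv", class(out)),
            motions = motions, failures = failures, seed = seed)
}

#' Leave-one-subject-out cross-validation
#'
#' For each subject: a fresh model is initialized, feature normalization
#' is fitted on the remaining subjects' samples only, the model is
#' trained on those samples (originals plus augmented copies), and the
#' held-out subject's samples are predicted; the subject's prediction is
#' the mean over its test samples, de-normalized and clipped to the valid
#' score range. Training and test data are strictly disjoint by subject.
#'
#' @param cohort List of `fmaue_session`.
#' @param model_cfg,mix_cfg,prep_cfg,aug_cfg Pipeline configurations.
#' @param wl Windows per motion (default 9).
#' @param motions Motion subset to use (default all seven).
#' @param seed Master seed; per-fold seeds are derived from it.
#' @param progress Print per-fold progress messages.
#' @return Tibble of class `fmaue_losocv` with one row per (subject,
#'   part): columns `subject`, `part`, `truth`, `pred`, `fold_seed`.
#'   Folds that fail are recorded in the `failures` attribute.
#' @export
losocv <- function(cohort, model_cfg = model_config(),
                   mix_cfg = mixup_config(), prep_cfg = prep_config(),
                   aug_cfg = augment_config(), wl = 9,
                   motions = fma_motions(), seed = 1, progress = FALSE) {
  feats <- featurize_cohort(cohort, prep_cfg, aug_cfg, wl = wl, seed = seed)
  losocv_features(feats, model_cfg, mix_cfg, seed = seed,
                  motions = motions, progress = progress)
}

metric_row <- function(truth, pred, divisor, label) {
  n <- length(truth)
  ss_tot <- sum((truth - mean(truth))^2)
  ss_res <- sum((truth - pred)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  if (stats::sd(truth) > 0 && stats::sd(pred) > 0) {
    ct <- cor.test(truth, pred, alternative = "two.sided")
    r <- unname(ct$estimate)
    p <- ct$p.value
  } else {
    r <- NA_real_
    p <- NA_real_
  }
  mae <- mean(abs(truth - pred))
  rmse <- sqrt(mean((truth - pred)^2))
  tibble::tibble(part = label, n = n, r2 = r2, r = r, p_value = p,
                 mae = mae, nmae = mae / divisor, rmse = rmse,
                 nrmse = rmse / divisor, divisor = divisor)
}

#' Metric suite over LOSOCV fold results
#'
#' Per part: R-squared (`1 - SS_res / SS_tot` over subjects), Pearson r
#' with a two-sided significance test, MAE, RMSE, and their normalized
#' forms NMAE = MAE / range and NRMSE = RMSE / range, with ranges
#' 36/10/14/6. The `total` row uses the summed parts with divisor 66;
#' the `overall` row pools the range-normalized (prediction, truth) pairs
#' of all parts (divisor 1). Constant truth makes r undefined; it is
#' reported as `NA`, never propagated as NaN.
#'
#' @param folds An `fmaue_losocv` tibble (columns `subject`, `part`,
#'   `truth`, `pred`).
#' @param divisors Named per-part score divisors (default [fma_ranges()]).
#' @return Tibble of class `fmaue_metrics`: one row per part plus
#'   `total` and `overall`.
#' @export
compute_metrics <- function(folds, divisors = fma_ranges()) {
  parts <- c("a", "b", "c", "d")
  rows <- lapply(parts, function(p) {
    d <- folds[folds$part == p, ]
    metric_row(d$truth, d$pred, divisors[[p]], p)
  })
  tot <- folds |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(truth = sum(.data$truth), pred = sum(.data$pred),
                     .groups = "drop")
  rows[[5]] <- metric_row(tot$truth, tot$pred, sum(divisors), "total")
  pooled_truth <- folds$truth / divisors[match(folds$part, parts)]
  pooled_pred <- folds$pred / divisors[match(folds$part, parts)]
  rows[[6]] <- metric_row(pooled_truth, pooled_pred, 1, "overall")
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("fmaue_metrics", class(out)))
}

#' Motion subsets by FMA-UE group
#'
#' Builds a motion set from the groups to include: `A` = RU, RKE, HTS,
#' EPS; `B` = WC; `C` = HMFE; `D` = RKN.
#'
#' @param groups Character subset of `c("A", "B", "C", "D")`.
#' @return Character vector of motions, in canonical order.
#' @export
#' @examples
#' motion_set(c("A", "B", "C"))  # excludes exactly RKN
motion_set <- function(groups) {
  if (length(groups) == 0) abort("empty motion set")
  groups <- match.arg(groups, c("A", "B", "C", "D"), several.ok = TRUE)
  sel <- unlist(fma_motion_groups()[groups], use.names = FALSE)
  intersect(fma_motions(), sel)
}

#' Named ablation presets
#'
#' The full set plus the four drop-one-group sets.
#'
#' @return Named list of motion vectors, named in the `A*B*C*D*` /
#'   `__B*C*D*` style.
#' @export
ablation_presets <- function() {
  list(
    "A*B*C*D*" = motion_set(c("A", "B", "C", "D")),
    "__B*C*D*" = motion_set(c("B", "C", "D")),
    "A*__C*D*" = motion_set(c("A", "C", "D")),
    "A*B*__D*" = motion_set(c("A", "B", "D")),
    "A*B*C*__" = motion_set(c("A", "B", "C"))
  )
}

#' Reduced-motion-set ablation
#'
#' One full LOSOCV per motion set, sharing a single featurization of the
#' cohort and paired fold seeds (derived from the same master seed), so
#' arms differ only in the motions available to the model.
#'
#' @param cohort List of `fmaue_session`.
#' @param sets Named list of motion vectors (default [ablation_presets()]).
#' @param model_cfg,mix_cfg,prep_cfg,aug_cfg,wl,seed As in [losocv()].
#' @param progress Print progress.
#' @return Tibble: metric rows of every arm, keyed by a `set` column.
#' @export
ablate <- function(cohort, sets = ablation_presets(),
                   model_cfg = model_config(), mix_cfg = mixup_config(),
                   prep_cfg = prep_config(), aug_cfg = augment_config(),
                   wl = 9, seed = 1, progress = FALSE) {
  if (any(lengths(sets) == 0)) abort("empty motion set")
  feats <- featurize_cohort(cohort, prep_cfg, aug_cfg, wl = wl, seed = seed)
  purrr::imap_dfr(sets, function(mset, nm) {
    res <- losocv_features(feats, model_cfg, mix_cfg, seed = seed,
                           motions = mset, progress = progress)
    met <- compute_metrics(res)
    met$set <- nm
    dplyr::relocate(met, "set")
  })
}

#' Motion contribution by permutation importance
#'
#' For each motion m and part k: the mean increase in absolute prediction
#' error for part k (clinical scale) when motion m's tensor rows are
#' permuted across subjects, averaged over `n_repeats` random
#' permutations. Negative raw importances are floored at zero, and each
#' part's column is normalized to sum 1 over the motions; a part whose
#' raw importances are all zero is left unnormalized and flagged.
#'
#' @param model A trained `fmaue_estimator`.
#' @param feats An `fmaue_features` (one tensor per subject is used: the
#'   unaugmented original).
#' @param norm The `fmaue_norm` the model was trained with.
#' @param n_repeats Number of random permutations (default 5).
#' @param seed Integer seed.
#' @param .perms Optional list (length `n_repeats`) of integer
#'   permutation vectors, for deterministic checks.
#' @return `n_motions x 4` matrix of class `fmaue_contribution` (rows =
#'   motions, columns = parts), with attribute `unattributed` naming
#'   parts whose importances were all zero.
#' @export
motion_contribution <- function(model, feats, norm, n_repeats = 5,
                                seed = 1, .perms = NULL) {
  if (n_repeats < 1) abort("n_repeats must be >= 1")
  n <- length(feats$subjects)
  tensors <- lapply(feats$tensors, function(tl) apply_norm(norm, tl[[1]]))
  motions <- attr(tensors[[1]], "motions")
  nm <- length(motions)
  base_pred <- t(vapply(tensors, function(x) {
    denorm_scores(as.numeric(predict(model, x)))
  }, numeric(4)))
  base_err <- abs(base_pred - feats$scores)
  imp <- matrix(0, nm, 4, dimnames = list(motions, c("a", "b", "c", "d")))
  with_seed(derive_seed(seed, 4242), {
    for (rep in seq_len(n_repeats)) {
      perm <- if (is.null(.perms)) sample(n) else .perms[[rep]]
      for (m in seq_len(nm)) {
        perm_pred <- t(vapply(seq_len(n), function(i) {
          x <- tensors[[i]]
          x[m, , ] <- tensors[[perm[i]]][m, , ]
          denorm_scores(as.numeric(predict(model, x)))
        }, numeric(4)))
        d_err <- abs(perm_pred - feats$scores) - base_err
        imp[m, ] <- imp[m, ] + colMeans(d_err)
      }
    }
  })
  imp <- pmax(imp / n_repeats, 0)
  sums <- colSums(imp)
  flagged <- colnames(imp)[sums == 0]
  for (j in seq_len(ncol(imp))) {
    if (sums[j] > 0) imp[, j] <- imp[, j] / sums[j]
  }
  structure(imp, unattributed = flagged, class = "fmaue_contribution")
}
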