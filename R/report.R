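#' Write evaluation outputs to a directory
#'
#' Writes `metrics.json` and `metrics.csv`, a per-fold `predictions.csv`
#' (one row per subject and part), and per-part predicted-vs-true scatter
#' plots (PNG). Output is deterministic: no timestamps are embedded, so
#' re-running on the same inputs overwrites identically.
#'
#' @param folds An `fmaue_losocv` tibble.
#' @param metrics An `fmaue_metrics` tibble (computed from `folds` when
#'   `NULL`).
#' @param dir Destination directory (created if needed).
#' @param plots Also write scatter plots (default TRUE).
#' @return Invisibly, the paths written.
#' @export
report <- function(folds, metrics = NULL, dir, plots = TRUE) {
  if (is.null(metrics)) metrics <- compute_metrics(folds)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    metrics_json = file.path(dir, "metrics.json"),
    metrics_csv = file.path(dir, "metrics.csv"),
    predictions_csv = file.path(dir, "predictions.csv")
  )
  jsonlite::write_json(as.data.frame(metrics), paths["metrics_json"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  readr::write_csv(tibble::as_tibble(metrics), paths["metrics_csv"],
                   progress = FALSE)
  readr::write_csv(tibble::as_tibble(folds)[
    c("subject", "part", "truth", "pred")],
    paths["predictions_csv"], progress = FALSE)
  if (plots) {
    p <- ggplot2::autoplot(folds)
    plot_path <- file.path(dir, "predicted_vs_true.png")
    grDevices::png(plot_path, width = 1600, height = 1100, res = 200)
    print(p)
    grDevices::dev.off()
    paths <- c(paths, scatter = plot_path)
  }
  invisible(paths)
}

#' Scatter of predicted versus true sub-scores
#'
#' Mirrors the usual per-part predicted-vs-true panels, one facet per
#' FMA-UE part plus the total score, with the identity line.
#'
#' @param object An `fmaue_losocv` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fmaue_losocv <- function(object, ...) {
  parts <- c("a", "b", "c", "d")
  tot <- tibble::as_tibble(object) |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(truth = sum(.data$truth), pred = sum(.data$pred),
                     .groups = "drop") |>
    dplyr::mutate(part = "total")
  d <- dplyr::bind_rows(
    tibble::as_tibble(object)[c("subject", "part", "truth", "pred")], tot)
  d$part <- factor(d$part, levels = c(parts, "total"),
                   labels = c("Part A (0-36)", "Part B (0-10)",
                              "Part C (0-14)", "Part D (0-6)",
                              "Total (0-66)"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$truth, y = .data$pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::facet_wrap(~part, scales = "free") +
    ggplot2::labs(x = "True score", y = "Estimated score") +
    ggplot2::theme_minimal()
}

#' Heatmap of motion contributions
#'
#' @param object An `fmaue_contribution` matrix.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fmaue_contribution <- function(object, ...) {
  d <- tibble::as_tibble(as.table(unclass(object)), .name_repair = "minimal")
  names(d) <- c("motion", "part", "contribution")
  d$motion <- factor(d$motion, levels = rev(rownames(object)))
  d$part <- factor(toupper(d$part), levels = c("A", "B", "C", "D"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$part, y = .data$motion,
                                  fill = .data$contribution)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "FMA-UE part", y = "Motion",
                  fill = "Contribution") +
    ggplot2::theme_minimal()
}

#' Training-loss curve
#'
#' @param object A trained `fmaue_estimator`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fmaue_estimator <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$epoch, y = .data$mse)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "Training MSE") +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy LOSOCV fold results
#'
#' @param x An `fmaue_losocv`.
#' @param ... Unused.
#' @return Tibble with one row per (subject, part).
#' @export
tidy.fmaue_losocv <- function(x, ...) {
  tibble::as_tibble(x)[c("subject", "part", "truth", "pred")]
}

#' One-row summary of a LOSOCV run
#'
#' @param x An `fmaue_losocv`.
#' @param ... Unused.
#' @return One-row tibble: fold count, total-score R-squared, Pearson r,
#'   NMAE and NRMSE, and overall NMAE/NRMSE.
#' @export
glance.fmaue_losocv <- function(x, ...) {
  m <- compute_metrics(x)
  tot <- m[m$part == "total", ]
  ov <- m[m$part == "overall", ]
  tibble::tibble(
    n_folds = length(unique(x$subject)),
    total_r2 = tot$r2, total_r = tot$r,
    total_nmae = tot$nmae, total_nrmse = tot$nrmse,
    overall_nmae = ov$nmae, overall_nrmse = ov$nrmse
  )
}

#' Tidy the training history of an estimator
#'
#' @param x An `fmaue_estimator`.
#' @param ... Unused.
#' @return Tibble with columns `epoch`, `mse`.
#' @export
tidy.fmaue_estimator <- function(x, ...) {
  x$history
}

#' One-row summary of a trained estimator
#'
#' @param x An `fmaue_estimator`.
#' @param ... Unused.
#' @return One-row tibble: motion count, parameter count, epochs trained
#'   and final training MSE.
#' @export
glance.fmaue_estimator <- function(x, ...) {
  tibble::tibble(
    n_motions = x$n_motions,
    n_parameters = sum(vapply(x$params, length, numeric(1))),
    epochs = nrow(x$history),
    final_mse = if (nrow(x$history)) tail(x$history$mse, 1) else NA_real_
  )
}
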