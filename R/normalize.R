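#' Fit feature and score normalization on training data
#'
#' Per-feature mean and population standard deviation computed over all
#' real (non-padded) windows of the supplied training tensors, plus the
#' fixed per-part score divisors (36, 10, 14, 6). Must be fitted on
#' training-fold data only; [apply_norm()] may then be used anywhere.
#'
#' @param tensors List of `fmaue_tensor`.
#' @return List of class `fmaue_norm`: `mu`, `sd` (length 1530, SD
#'   floored at 1e-8), `divisors`, `fitted = TRUE`.
#' @export
fit_norm <- function(tensors) {
  rows <- do.call(rbind, lapply(tensors, function(x) {
    mask <- attr(x, "mask")
    d <- dim(x)
    flat <- matrix(aperm(unclass(x), c(2, 1, 3)), d[1] * d[2], d[3])
    flat[as.vector(t(mask)), , drop = FALSE]
  }))
  mu <- colMeans(rows)
  sdv <- sqrt(pmax(colMeans(rows^2) - mu^2, 0))
  structure(list(mu = mu, sd = pmax(sdv, 1e-8),
                 divisors = fma_ranges(), fitted = TRUE),
            class = "fmaue_norm")
}

#' Apply fitted normalization to a feature tensor
#'
#' Z-scores every feature index with the training-fold statistics.
#'
#' @param stats An `fmaue_norm` from [fit_norm()].
#' @param tensor An `fmaue_tensor`.
#' @return Normalized tensor (same class and attributes).
#' @export
apply_norm <- function(stats, tensor) {
  if (!isTRUE(stats$fitted)) abort("normalization applied before fit")
  d <- dim(tensor)
  out <- unclass(tensor)
  mu <- array(rep(stats$mu, each = d[1] * d[2]), dim = d)
  sdv <- array(rep(stats$sd, each = d[1] * d[2]), dim = d)
  out <- (out - mu) / sdv
  attributes(out) <- attributes(tensor)
  out
}

#' Normalize scores to the unit interval
#'
#' Divides each part score by its range maximum (36, 10, 14, 6), so a
#' full score maps to 1.
#'
#' @param scores An `fmaue_scores` or numeric 4-vector (a, b, c, d).
#' @return Numeric 4-vector in \[0, 1\].
#' @export
#' @examples
#' norm_scores(fma_scores(18, 5, 7, 3))  # 0.5 0.5 0.5 0.5
norm_scores <- function(scores) {
  unname(as.numeric(unclass(scores)) / fma_ranges())
}

#' Map normalized scores back to the clinical scale
#'
#' Multiplies by the part ranges and, when `clip = TRUE` (reporting
#' convention), clips to `[0, range]`.
#'
#' @param x Numeric 4-vector of normalized scores.
#' @param clip Clip to the valid score range (default TRUE).
#' @return Numeric 4-vector on the 0-36/10/14/6 scales.
#' @export
denorm_scores <- function(x, clip = TRUE) {
  rng <- fma_ranges()
  out <- as.numeric(x) * rng
  if (clip) out <- pmin(pmax(out, 0), rng)
  unname(out)
}
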