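# The 1530-feature registry: 153 channels x 10 statistics.
#
# Channels per IMU segment (x4): six 3-axis families -- acceleration,
# gyroscope, orientation, orientation acceleration (second difference of
# orientation x rate^2), angular difference (first difference of
# orientation x rate), and inclination ratio (orientation minus the trunk
# orientation per axis; for the trunk itself, orientation minus its
# neutral pose) -- giving 18 base channels, each paired with its
# first-difference counterpart (36). Plus 9 joint-angle channels
# (wrist/elbow/shoulder x 3 axes): 4 x 36 + 9 = 153.

FEATURE_STATS <- c("mean", "std", "rms", "amplitude", "max", "min",
                   "range", "apen", "median", "iqr")

REGISTRY_VERSION <- "153x10-v1"

channel_families <- c("acc", "gyro", "orient", "oacc", "adiff", "incl")

#' Names of the 153 kinematic channels, in registry order
#'
#' @return Character vector of length 153.
#' @export
channel_names <- function() {
  axes <- c("x", "y", "z")
  out <- character(0)
  for (s in fma_segments()) {
    for (fam in channel_families) {
      for (ax in axes) {
        base <- paste(s, fam, ax, sep = ".")
        out <- c(out, base, paste0(base, ".d1"))
      }
    }
  }
  c(out, paste("joint", rep(c("wrist", "elbow", "shoulder"), each = 3),
               axes, sep = "."))
}

#' The feature registry: index to (channel, statistic) bijection
#'
#' Feature `i` (1-based) is statistic `(i - 1) %% 10 + 1` of channel
#' `(i - 1) %/% 10 + 1` (channel-major, statistic-minor ordering). The
#' ten statistics are mean, population standard deviation, RMS, amplitude
#' (`(max - min) / 2`), max, min, range (`max - min`), approximate
#' entropy, median, and interquartile range.
#'
#' @return Tibble with columns `index`, `channel`, `statistic`, `label`
#'   (`"channel::statistic"`), 1530 rows.
#' @export
#' @examples
#' nrow(feature_registry())  # 1530
feature_registry <- function() {
  ch <- channel_names()
  tibble::tibble(
    index = seq_len(length(ch) * length(FEATURE_STATS)),
    channel = rep(ch, each = length(FEATURE_STATS)),
    statistic = rep(FEATURE_STATS, times = length(ch)),
    label = paste(channel, statistic, sep = "::")
  )
}

#' Approximate entropy of a series
#'
#' Classical ApEn: `Phi_m(r) - Phi_(m+1)(r)` with Chebyshev distance and
#' self-matches included. Low values indicate regular, predictable
#' signals. Returns 0 for a constant series (all templates match at any
#' tolerance).
#'
#' @param x Numeric series of length >= m + 2.
#' @param m Embedding dimension (default 2).
#' @param r Match tolerance; defaults to `0.2 x` the population standard
#'   deviation of `x`.
#' @return Scalar ApEn.
#' @export
#' @examples
#' approximate_entropy(rep(1, 50))          # 0
#' approximate_entropy(sin(1:100))          # small: regular signal
approximate_entropy <- function(x, m = 2, r = NULL) {
  if (length(x) < m + 2) abort("series too short for approximate entropy")
  if (is.null(r)) {
    sdv <- sqrt(mean((x - mean(x))^2))
    if (sdv == 0) return(0)
    r <- 0.2 * sdv
  }
  if (r <= 0) return(0)
  apen_cpp(as.numeric(x), as.integer(m), r)
}

# forward difference with first-sample replication (length-preserving)
fdiff <- function(x) {
  d <- diff(x)
  c(d[1], d)
}

#' Build the 153-channel stack of a prepared trial
#'
#' Expands the 45 prepared channels (see [prepare_trial()]) into the full
#' registry: per segment the six base families (acceleration, gyro,
#' orientation, orientation acceleration, angular difference, inclination
#' ratio relative to the trunk) each paired with its first-difference
#' counterpart, plus the nine joint angles. Difference channels use
#' forward differences with first-sample replication so every column has
#' N rows.
#'
#' @param ch An `fmaue_channels` object from [prepare_trial()].
#' @return N x 153 matrix, columns in [channel_names()] order.
#' @export
build_channels <- function(ch) {
  d <- ch$data
  rate <- ch$rate
  n <- nrow(d)
  trunk_or <- d[, c("trunk_ox", "trunk_oy", "trunk_oz")]
  out <- matrix(0, n, 153)
  colnames(out) <- channel_names()
  axes <- c("x", "y", "z")
  for (s in fma_segments()) {
    for (j in 1:3) {
      ax <- axes[j]
      acc <- d[, paste0(s, "_a", ax)]
      gyr <- d[, paste0(s, "_g", ax)]
      ori <- d[, paste0(s, "_o", ax)]
      oacc <- fdiff(fdiff(ori)) * rate^2
      adiff <- fdiff(ori) * rate
      # inclination is neutral-referenced on both ends so it is zero at
      # the neutral pose and zero whenever the segment tracks the trunk
      if (s == "trunk") {
        incl <- ori - ch$neutral_orient["trunk", j]
      } else {
        incl <- (ori - ch$neutral_orient[s, j]) -
          (trunk_or[, j] - ch$neutral_orient["trunk", j])
      }
      fam_vals <- list(acc = acc, gyro = gyr, orient = ori,
                       oacc = oacc, adiff = adiff, incl = incl)
      for (fam in channel_families) {
        v <- fam_vals[[fam]]
        out[, paste(s, fam, ax, sep = ".")] <- v
        out[, paste(s, fam, ax, "d1", sep = ".")] <- fdiff(v)
      }
    }
  }
  joints <- c("wrist", "elbow", "shoulder")
  for (j in joints) {
    for (ax in axes) {
      out[, paste("joint", j, ax, sep = ".")] <- d[, paste(j, ax, sep = "_")]
    }
  }
  out
}

# type-7 quantile from a column-sorted matrix
sorted_quantile <- function(s, p) {
  n <- nrow(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  v <- s[lo, ]
  if (lo < n) v <- v + (h - lo) * (s[lo + 1, ] - s[lo, ])
  v
}

#' Compute the 1530-dimensional feature vector of one window
#'
#' Ten statistics (see [feature_registry()]) of each of the 153 channels,
#' ordered channel-major / statistic-minor. The standard deviation is the
#' population form; amplitude is `(max - min) / 2`, distinct from range
#' `max - min`; ApEn uses m = 2 and r = 0.2 x the window-channel SD.
#'
#' @param window A `win_len x 153` matrix from the channel stack.
#' @return Numeric vector of length 1530.
#' @export
window_features <- function(window) {
  if (ncol(window) != 153) abort("window must have exactly 153 channels")
  n <- nrow(window)
  mu <- colMeans(window)
  msq <- colMeans(window^2)
  std <- sqrt(pmax(msq - mu^2, 0))
  rms <- sqrt(msq)
  s <- apply(window, 2, sort)
  mx <- s[n, ]; mn <- s[1, ]
  rng <- mx - mn
  amp <- rng / 2
  med <- sorted_quantile(s, 0.5)
  iqr <- sorted_quantile(s, 0.75) - sorted_quantile(s, 0.25)
  ap <- apen_cols_cpp(window, 2L, 0.2)
  out <- rbind(mean = mu, std = std, rms = rms, amplitude = amp,
               max = mx, min = mn, range = rng, apen = ap,
               median = med, iqr = iqr)
  as.numeric(out)  # column-major: channel-major, statistic-minor
}

#' Assemble per-motion window features into the model input tensor
#'
#' Packs the per-motion lists of window feature vectors into a
#' `[n_motions, WL, 1530]` array. Motions with more than `wl` windows are
#' cropped centrally; motions with fewer are padded by repeating the last
#' window, and the padded slots are recorded in the `mask` attribute
#' (`TRUE` = real window).
#'
#' @param per_motion Named list (motion -> list of 1530-vectors), one
#'   entry per included motion, in canonical order.
#' @param wl Target window count (default 9; a 10 s trial at 100 Hz with
#'   2 s / 50% windows yields 9).
#' @return Array of class `fmaue_tensor`, dim `c(n_motions, wl, 1530)`,
#'   with attributes `mask` (n_motions x wl logical) and `motions`.
#' @export
assemble_tensor <- function(per_motion, wl = 9) {
  motions <- names(per_motion)
  nm <- length(motions)
  x <- array(0, dim = c(nm, wl, 1530))
  mask <- matrix(TRUE, nm, wl, dimnames = list(motions, NULL))
  for (i in seq_len(nm)) {
    fv <- per_motion[[i]]
    k <- length(fv)
    if (k == 0) abort(paste0("motion ", motions[i], " has zero windows"))
    if (k > wl) {
      start <- floor((k - wl) / 2) + 1
      fv <- fv[start:(start + wl - 1)]
    } else if (k < wl) {
      mask[i, (k + 1):wl] <- FALSE
      fv <- c(fv, rep(fv[k], wl - k))
    }
    for (t in seq_len(wl)) x[i, t, ] <- fv[[t]]
  }
  structure(x, mask = mask, motions = motions, class = "fmaue_tensor")
}

#' Featurize a subject session
#'
#' Runs the full feature pipeline: per motion, prepare (joint angles,
#' outlier replacement, filtering, resampling), optionally generate
#' augmented copies, build the 153-channel stack, window it (2 s / 50%),
#' and compute 1530 features per window; finally assemble one tensor per
#' copy. Copy `k` of the session combines copy `k` of every motion; copy
#' 0 is the unaugmented original.
#'
#' @param session An `fmaue_session`.
#' @param prep_cfg A [prep_config()].
#' @param aug_cfg An [augment_config()] or `NULL` for no augmentation.
#' @param wl Windows per motion in the tensor (default 9).
#' @param win_s,overlap Sliding-window parameters (default 2 s, 0.5).
#' @param seed Seed for the augmentation draws.
#' @return List of `fmaue_tensor` (length `1 + copies_per_trial`), the
#'   first unaugmented.
#' @export
featurize_session <- function(session, prep_cfg = prep_config(),
                              aug_cfg = NULL, wl = 9, win_s = 2,
                              overlap = 0.5, seed = 1) {
  copies <- if (is.null(aug_cfg)) 0 else aug_cfg$copies_per_trial
  per_copy <- lapply(seq_len(copies + 1), function(k) list())
  for (mi in seq_along(session$trials)) {
    m <- names(session$trials)[mi]
    ch <- prepare_trial(session$trials[[m]], prep_cfg)
    variants <- list(ch)
    if (copies > 0) {
      variants <- c(variants,
                    augment_channels(ch, aug_cfg, derive_seed(seed, mi)))
    }
    for (k in seq_along(variants)) {
      stack <- build_channels(variants[[k]])
      wnd <- window_trial(stack, variants[[k]]$rate, win_s, overlap)
      per_copy[[k]][[m]] <- lapply(wnd$windows, window_features)
    }
  }
  lapply(per_copy, assemble_tensor, wl = wl)
}
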