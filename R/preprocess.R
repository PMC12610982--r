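#' Replace outlier samples by the mean of the inliers
#'
#' Hampel-style detection: samples with
#' `|x - median| > z_thresh * 1.4826 * MAD` are replaced by the mean of
#' the non-outlier samples. A constant series has MAD 0 and is returned
#' unchanged (no finite deviation exceeds the threshold by convention).
#' If every sample is flagged the input is returned unchanged with a
#' warning.
#'
#' @param x Numeric series, length >= 3.
#' @param z_thresh Detection threshold in robust z units (default 3).
#' @return Series of the same length with outliers replaced.
#' @export
#' @examples
#' replace_outliers(c(1, 1, 1, 1, 100))  # spike replaced by 1
replace_outliers <- function(x, z_thresh = 3) {
  if (length(x) < 3) abort("series too short for outlier replacement")
  med <- median(x)
  mad <- median(abs(x - med))
  # strict inequality: with MAD 0 only samples that differ from the
  # median are flagged, so a constant series passes through unchanged
  out <- abs(x - med) > z_thresh * 1.4826 * mad
  if (!any(out)) return(x)
  if (all(out)) {
    warn("all samples flagged as outliers; series returned unchanged")
    return(x)
  }
  x[out] <- mean(x[!out])
  x
}

#' Named Butterworth filter presets
#'
#' `"paper"`: high-pass 10 Hz + low-pass 49.9 Hz, order 4 (a literal
#' reading of a 10-50 Hz band-pass at 100 Hz sampling, whose upper corner
#' sits at Nyquist). `"functional"`: 0.25-10 Hz band-pass, order 4, which
#' retains the sub-10 Hz band where voluntary upper-limb motion lives and
#' is the default for synthetic-recovery work. `"none"` disables
#' filtering.
#'
#' @param name Preset name.
#' @return List with elements `low_hz`, `high_hz`, `order` (or `NULL` for
#'   `"none"`).
#' @export
filter_preset <- function(name = c("functional", "paper", "none")) {
  name <- match.arg(name)
  switch(name,
    functional = list(low_hz = 0.25, high_hz = 10, order = 4),
    paper = list(low_hz = 10, high_hz = 49.9, order = 4),
    none = NULL
  )
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applied forward-backward (`signal::filtfilt`), so the output has no
#' phase lag and the same length as the input. The band-pass is realized
#' as a cascade of a high-pass at `low_hz` and a low-pass at `high_hz`
#' (numerically robust for corners far below Nyquist). With `low_hz = 0`
#' it degrades to a pure low-pass; with `high_hz >= rate/2` to a pure
#' high-pass.
#'
#' @param x Numeric series.
#' @param low_hz,high_hz Band corners in Hz, `0 <= low_hz < high_hz <=
#'   rate/2`.
#' @param order Filter order (default 4).
#' @param rate Sampling rate in Hz.
#' @return Filtered series, same length.
#' @export
butterworth_filter <- function(x, low_hz, high_hz, order = 4, rate = 100) {
  ny <- rate / 2
  if (low_hz < 0 || high_hz <= low_hz || high_hz > ny + 1e-9) {
    abort("need 0 <= low_hz < high_hz <= rate/2")
  }
  if (length(x) <= 3 * order) abort("too short to filter")
  out <- x
  if (low_hz > 0) {
    out <- filtfilt_sos(signal::butter(order, low_hz / ny, type = "high"),
                        out)
  }
  if (high_hz < ny * (1 - 1e-6)) {
    out <- filtfilt_sos(signal::butter(order, high_hz / ny, type = "low"),
                        out)
  }
  out
}

# zero-phase filtering through cascaded second-order sections built from
# the exact pole/zero pairs: numerically robust for corners close to DC
# or Nyquist, where the expanded transfer-function form loses precision
filtfilt_sos <- function(filt, x) {
  zpg <- signal::as.Zpg(filt)
  pair_up <- function(v) {
    v <- v[order(Im(v), Re(v))]
    cplx <- v[Im(v) > 1e-12]
    re <- Re(v[abs(Im(v)) <= 1e-12])
    secs <- lapply(cplx, function(p) c(p, Conj(p)))
    while (length(re) >= 2) {
      secs[[length(secs) + 1]] <- re[1:2]
      re <- re[-(1:2)]
    }
    if (length(re) == 1) secs[[length(secs) + 1]] <- re[1]
    secs
  }
  psecs <- pair_up(zpg$pole)
  zsecs <- pair_up(zpg$zero)
  n_sec <- max(length(psecs), length(zsecs))
  g <- abs(zpg$gain)^(1 / n_sec) * sign(Re(zpg$gain))
  for (k in seq_len(n_sec)) {
    a <- if (k <= length(psecs)) Re(poly_from_roots(psecs[[k]])) else 1
    b <- if (k <= length(zsecs)) Re(poly_from_roots(zsecs[[k]])) else 1
    x <- signal::filtfilt(signal::Arma(b * g, a), x)
  }
  x
}

poly_from_roots <- function(r) {
  p <- 1
  for (root in r) p <- c(p, 0) - c(0, p * root)
  p
}

#' Resample a series onto a uniform grid by linear interpolation
#'
#' @param x Numeric series.
#' @param t Timestamps in seconds, strictly increasing, same length.
#' @param target_hz Target rate (default 100).
#' @return Tibble with columns `t` (uniform grid spanning
#'   `[t[1], t[length(t)]]`) and `value`.
#' @export
resample_to <- function(x, t, target_hz = 100) {
  if (length(x) < 2) abort("need at least 2 samples to resample")
  if (any(diff(t) <= 0)) abort("timestamps must be strictly increasing")
  n_out <- floor((t[length(t)] - t[1]) * target_hz + 1e-9) + 1
  grid <- t[1] + (seq_len(n_out) - 1) / target_hz
  vals <- approx(t, x, xout = pmin(grid, t[length(t)]))$y
  tibble::tibble(t = grid, value = vals)
}

#' Sliding-window segmentation
#'
#' Cuts a multichannel series into windows of `win_s` seconds with the
#' given fractional overlap; the trailing partial window is dropped, so
#' the window count is `floor((N - win) / hop) + 1`.
#'
#' @param channels Numeric matrix, samples x channels (a vector is treated
#'   as one channel).
#' @param rate Sampling rate in Hz.
#' @param win_s Window length in seconds (default 2).
#' @param overlap Fractional overlap of consecutive windows (default 0.5).
#' @return List of class `fmaue_windows`: `windows` (list of
#'   `win_s * rate` x channels matrices), `win_samples`, `hop`, `rate`.
#' @export
#' @examples
#' w <- window_trial(matrix(rnorm(1000), ncol = 1), rate = 100)
#' length(w$windows)  # 9
window_trial <- function(channels, rate, win_s = 2, overlap = 0.5) {
  channels <- as.matrix(channels)
  n <- nrow(channels)
  win <- round(win_s * rate)
  hop <- round(win * (1 - overlap))
  if (n < win) abort("trial too short for one window")
  starts <- seq(1, n - win + 1, by = hop)
  structure(
    list(windows = lapply(starts, function(s) {
           channels[s:(s + win - 1), , drop = FALSE]
         }),
         win_samples = win, hop = hop, rate = rate),
    class = "fmaue_windows"
  )
}

#' Signal-level augmentation configuration
#'
#' Three transforms applied in order to each augmented copy: additive
#' Gaussian noise (sigma = `gaussian_sigma_rel` x per-channel SD), a
#' global time warp (scale factor drawn from `warp_range`, cubic
#' re-interpolation back onto the uniform grid), and amplitude scaling
#' about the per-channel mean (factor drawn from `amp_range`).
#'
#' @param gaussian_sigma_rel Noise SD as a fraction of channel SD
#'   (default 0.05).
#' @param warp_range Multiplicative time-scale interval containing 1
#'   (default `c(0.9, 1.1)`).
#' @param amp_range Amplitude factor interval containing 1 (default
#'   `c(0.8, 1.2)`).
#' @param copies_per_trial Number of augmented copies (default 3).
#' @return List of class `fmaue_augcfg`.
#' @export
augment_config <- function(gaussian_sigma_rel = 0.05,
                           warp_range = c(0.9, 1.1),
                           amp_range = c(0.8, 1.2),
                           copies_per_trial = 3) {
  stopifnot(gaussian_sigma_rel >= 0, copies_per_trial >= 0,
            warp_range[1] <= 1, warp_range[2] >= 1,
            amp_range[1] <= 1, amp_range[2] >= 1)
  structure(list(gaussian_sigma_rel = gaussian_sigma_rel,
                 warp_range = warp_range, amp_range = amp_range,
                 copies_per_trial = copies_per_trial),
            class = "fmaue_augcfg")
}

# noise -> warp -> amplitude scaling on one samples x channels matrix.
# warp and amp factors are shared across channels of one copy.
augment_matrix <- function(mat, rate, cfg, warp, amp) {
  n <- nrow(mat)
  out <- mat
  if (cfg$gaussian_sigma_rel > 0) {
    sds <- apply(mat, 2, stats::sd)
    out <- out + sapply(seq_len(ncol(mat)), function(j) {
      rnorm(n, sd = cfg$gaussian_sigma_rel * sds[j])
    })
  }
  if (warp != 1) {
    t_old <- (seq_len(n) - 1) / rate
    n_new <- max(2, round(n * warp))
    t_new <- (seq_len(n_new) - 1) / rate
    out <- sapply(seq_len(ncol(out)), function(j) {
      f <- splinefun(t_old, out[, j], method = "fmm")
      f(pmin(t_new / warp, t_old[n]))
    })
  }
  if (amp != 1) {
    mu <- colMeans(out)
    out <- sweep(sweep(out, 2, mu), 2, rep(amp, ncol(out)), `*`)
    out <- sweep(out, 2, mu, `+`)
  }
  out
}

#' Generate augmented copies of a motion trial
#'
#' Applies, in order, Gaussian noise, a smooth global time warp, and
#' amplitude scaling (see [augment_config()]) to every data channel of
#' every segment recording. Warp and amplitude factors are drawn once per
#' copy and shared across channels so the copy stays kinematically
#' coherent. Deterministic given `seed`.
#'
#' @param trial An `fmaue_trial`.
#' @param cfg An [augment_config()].
#' @param seed Integer seed.
#' @return List of `copies_per_trial` augmented `fmaue_trial`s.
#' @export
augment_trial <- function(trial, cfg = augment_config(), seed = 1) {
  rate <- attr(trial$recordings[[1]], "nominal_rate")
  with_seed(seed, {
    lapply(seq_len(cfg$copies_per_trial), function(k) {
      warp <- runif(1, cfg$warp_range[1], cfg$warp_range[2])
      amp <- runif(1, cfg$amp_range[1], cfg$amp_range[2])
      recs <- lapply(trial$recordings, function(r) {
        mat <- as.matrix(r[, c("ax", "ay", "az", "gx", "gy", "gz",
                               "ox", "oy", "oz")])
        new <- augment_matrix(mat, rate, cfg, warp, amp)
        t_new <- (seq_len(nrow(new)) - 1) / rate + r$t[1]
        segment_recording(attr(r, "segment"), t_new,
                          new[, 1:3], new[, 4:6], new[, 7:9],
                          nominal_rate = rate)
      })
      motion_trial(trial$motion, recs, repetitions = trial$repetitions)
    })
  })
}

#' Preprocessing configuration
#'
#' @param z_thresh Outlier threshold (robust z units, default 3).
#' @param filter A [filter_preset()] name or a list
#'   `list(low_hz=, high_hz=, order=)`; `"none"` disables filtering.
#' @param target_hz Resampling rate (default 100).
#' @param neutral_index Neutral-pose sample index (default 1).
#' @return List of class `fmaue_prepcfg`.
#' @export
prep_config <- function(z_thresh = 3, filter = "functional",
                        target_hz = 100, neutral_index = 1) {
  if (is.character(filter)) filter <- filter_preset(filter)
  structure(list(z_thresh = z_thresh, filter = filter,
                 target_hz = target_hz, neutral_index = neutral_index),
            class = "fmaue_prepcfg")
}

#' Prepare a motion trial for feature extraction
#'
#' Computes the nine joint-angle channels from the raw orientations, then
#' applies outlier replacement, zero-phase Butterworth filtering, and
#' resampling to every raw IMU channel and every joint-angle channel.
#' The result is a uniform-rate 45-channel matrix (4 segments x 9 raw
#' channels + 9 joint angles) plus the raw neutral-pose orientation of
#' each segment (the reference for trunk-relative inclination channels).
#'
#' @param trial An `fmaue_trial`.
#' @param cfg A [prep_config()].
#' @return List of class `fmaue_channels`: `motion`, `rate`, `data`
#'   (N x 45 named matrix), `neutral_orient` (4 x 3).
#' @export
prepare_trial <- function(trial, cfg = prep_config()) {
  angles <- compute_joint_angles(trial, cfg$neutral_index)
  raw_cols <- c("ax", "ay", "az", "gx", "gy", "gz", "ox", "oy", "oz")
  cols <- list()
  for (s in fma_segments()) {
    r <- trial$recordings[[s]]
    for (cc in raw_cols) {
      cols[[paste(s, cc, sep = "_")]] <- list(x = r[[cc]], t = r$t)
    }
  }
  t0 <- trial$recordings[[1]]$t
  for (j in names(angles)) {
    cols[[j]] <- list(x = angles[[j]], t = t0)
  }
  rate <- attr(trial$recordings[[1]], "nominal_rate")
  proc <- lapply(cols, function(ch) {
    x <- replace_outliers(ch$x, cfg$z_thresh)
    if (!is.null(cfg$filter)) {
      x <- butterworth_filter(x, cfg$filter$low_hz, cfg$filter$high_hz,
                              cfg$filter$order, rate)
    }
    resample_to(x, ch$t, cfg$target_hz)$value
  })
  n <- min(lengths(proc))
  data <- vapply(proc, function(x) x[seq_len(n)], numeric(n))
  neutral <- t(vapply(fma_segments(), function(s) {
    unlist(trial$recordings[[s]][cfg$neutral_index, c("ox", "oy", "oz")],
           use.names = FALSE)
  }, numeric(3)))
  rownames(neutral) <- fma_segments()
  structure(list(motion = trial$motion, rate = cfg$target_hz,
                 data = data, neutral_orient = neutral),
            class = "fmaue_channels")
}

# augmented copies of a prepared-channel object (same three transforms,
# applied after preprocessing, matching the processing order of the
# pipeline: clean first, then augment, then window)
augment_channels <- function(ch, cfg = augment_config(), seed = 1) {
  with_seed(seed, {
    lapply(seq_len(cfg$copies_per_trial), function(k) {
      warp <- runif(1, cfg$warp_range[1], cfg$warp_range[2])
      amp <- runif(1, cfg$amp_range[1], cfg$amp_range[2])
      out <- ch
      out$data <- augment_matrix(ch$data, ch$rate, cfg, warp, amp)
      colnames(out$data) <- colnames(ch$data)
      out
    })
  })
}
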