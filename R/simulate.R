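# Impairment-graded synthetic cohort simulator.
#
# Severity is a 4-vector s = (s_a, s_b, s_c, s_d) in [0,1]^4 (0 =
# unimpaired). Each motion couples the severity components through the
# weights in motion_specs(); the coupling-weighted severity ws = sum(w * s)
# scales movement amplitude down (1 - 0.8 ws), slows the repetition period
# (1 + ws), and drives 3-8 Hz tremor amplitude.

# run expr with a locally seeded RNG, restoring global RNG state after
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 65011 + 1) * 7919 + k * 104729) %% 2147483562L + 1L
}

#' Derive FMA-UE sub-scores from a severity profile
#'
#' Part k score = round((1 - s_k) * range_k) with part ranges 36/10/14/6.
#'
#' @param severity Named numeric 4-vector `c(a=, b=, c=, d=)`, each in
#'   \[0, 1\], 0 = unimpaired.
#' @return An [fma_scores()] object.
#' @export
#' @examples
#' severity_scores(c(a = 0.5, b = 0.5, c = 0.5, d = 0.5))  # 18 5 7 3
severity_scores <- function(severity) {
  severity <- check_severity(severity)
  v <- round((1 - severity) * fma_ranges())
  fma_scores(v[["a"]], v[["b"]], v[["c"]], v[["d"]])
}

check_severity <- function(severity) {
  if (is.null(names(severity))) names(severity) <- c("a", "b", "c", "d")
  severity <- severity[c("a", "b", "c", "d")]
  if (any(!is.finite(severity)) || any(severity < 0 | severity > 1)) {
    abort("severity components must lie in [0, 1]")
  }
  severity
}

# minimum-jerk position profile on [0,1]
mjerk <- function(s) 10 * s^3 - 15 * s^4 + 6 * s^5

# periodic 0 -> 1 -> 0 oscillation built from two minimum-jerk half-strokes
mj_wave <- function(t, period, phase = 0) {
  u <- ((t / period) + phase) %% 1
  ifelse(u < 0.5, mjerk(2 * u), mjerk(2 * (1 - u)))
}

neutral_pose <- function() {
  rbind(hand = c(25, 15, 5), forearm = c(20, 10, 5),
        upper_arm = c(10, 5, 0), trunk = c(0, 0, 0))
}

#' Simulate one motion trial under an impairment profile
#'
#' Generates a ~10 s trial of `repetitions` smooth minimum-jerk-profile
#' oscillations of the four segment orientations. Effective amplitude is
#' `base_amplitude * (1 - 0.8 ws)`, repetition period
#' `base_period * (1 + ws)` with `ws` the coupling-weighted severity, and
#' band-limited (3-8 Hz) tremor with standard deviation proportional to
#' `ws` is added to the orientation channels. Gyro is the time derivative
#' of orientation; acceleration is the gravity component along the segment
#' axes plus a movement term and white sensor noise. Deterministic given
#' `seed`.
#'
#' @param motion One of [fma_motions()].
#' @param severity Severity 4-vector (see [severity_scores()]).
#' @param rate Sampling rate in Hz (default 100).
#' @param seed Integer seed.
#' @param repetitions Repetition count (default 5).
#' @param specs Motion specification table ([motion_specs()]).
#' @param noise_acc,noise_gyro White sensor-noise standard deviations
#'   (0.01 g, 0.5 deg/s defaults).
#' @param tremor_gain Tremor amplitude in degrees at coupling-weighted
#'   severity 1 (default 2).
#' @return An `fmaue_trial`.
#' @export
simulate_trial <- function(motion, severity, rate = 100, seed = 1,
                           repetitions = 5, specs = motion_specs(),
                           noise_acc = 0.01, noise_gyro = 0.5,
                           tremor_gain = 2) {
  if (rate <= 0) abort("rate must be positive")
  severity <- check_severity(severity)
  motion <- match.arg(motion, fma_motions())
  sp <- specs[specs$motion == motion, ]
  w <- sp$coupling[[1]]
  ws <- sum(w * severity)
  amp <- sp$base_amplitude * (1 - 0.8 * ws)
  period <- sp$base_period * (1 + ws)
  duration <- repetitions * period
  n <- round(duration * rate)
  t <- (seq_len(n) - 1) / rate
  gain <- sp$segment_gain[[1]]
  phases <- c(x = 0, y = 0.25, z = 0.5)
  neutral <- neutral_pose()

  with_seed(seed, {
    recs <- list()
    for (s in fma_segments()) {
      orient <- matrix(0, n, 3)
      for (j in 1:3) {
        base <- mj_wave(t, period, phases[j]) - mj_wave(0, period, phases[j])
        orient[, j] <- neutral[s, j] + gain[s, j] * amp * base
        tremor_sd <- tremor_gain * ws * (0.25 + 0.75 * gain[s, j])
        if (tremor_sd > 0) {
          orient[, j] <- orient[, j] + band_noise(n, rate, tremor_sd)
        }
      }
      gyro <- apply(orient, 2, num_deriv, dt = 1 / rate) +
        matrix(rnorm(n * 3, sd = noise_gyro), n, 3)
      gyro <- pmin(pmax(gyro, -2000), 2000)
      S <- rotstack_from_euler(orient)
      grav <- cbind(S[, "r31"], S[, "r32"], S[, "r33"])
      omov <- apply(orient * DEG, 2,
                    function(x) num_deriv(num_deriv(x, 1 / rate), 1 / rate))
      acc <- grav + omov * 0.25 / 9.81 +
        matrix(rnorm(n * 3, sd = noise_acc), n, 3)
      acc <- pmin(pmax(acc, -8), 8)
      recs[[s]] <- segment_recording(s, t, acc, gyro, orient,
                                     nominal_rate = rate)
    }
    motion_trial(motion, recs, repetitions = repetitions)
  })
}

# band-limited (3-8 Hz) gaussian noise with target standard deviation
band_noise <- function(n, rate, sd_target) {
  x <- rnorm(n)
  ny <- rate / 2
  lo <- min(3 / ny, 0.95)
  hi <- min(8 / ny, 0.99)
  if (n > 30 && hi > lo) {
    bf <- signal::butter(2, c(lo, hi), type = "pass")
    x <- signal::filtfilt(bf, x)
  }
  s <- stats::sd(x)
  if (s == 0) return(rep(0, n))
  x / s * sd_target
}

# central-difference derivative, one-sided at the ends
num_deriv <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

#' Simulate a full subject session
#'
#' Seven trials (one per motion), with sub-scores derived from the
#' severity profile.
#'
#' @inheritParams simulate_trial
#' @param subject_id Identifier for the simulated subject.
#' @param tested_side `"left"` or `"right"`.
#' @param ... Passed on to [simulate_trial()] (e.g. `repetitions`,
#'   noise floors).
#' @return An `fmaue_session` with `is_synthetic = TRUE`.
#' @export
simulate_subject <- function(severity, rate = 100, seed = 1,
                             subject_id = "S01", tested_side = "right", ...) {
  severity <- check_severity(severity)
  trials <- list()
  for (i in seq_along(fma_motions())) {
    m <- fma_motions()[i]
    trials[[m]] <- simulate_trial(m, severity, rate = rate,
                                  seed = derive_seed(seed, i), ...)
  }
  subject_session(subject_id, trials, severity_scores(severity),
                  tested_side = tested_side, rate = rate,
                  is_synthetic = TRUE)
}

#' Sample severity profiles for a synthetic cohort
#'
#' Default sampler: each part severity is an independent Beta(2, 2) draw,
#' and with probability `p_healthy` the subject is unimpaired (all
#' severities 0), emulating a cohort in which roughly a fifth of subjects
#' are healthy controls.
#'
#' @param n Number of subjects.
#' @param seed Integer seed.
#' @param shape1,shape2 Beta shape parameters (default 2, 2).
#' @param p_healthy Probability of an unimpaired subject (default 0.2).
#' @return Tibble with columns `subject`, `s_a`, `s_b`, `s_c`, `s_d`.
#' @export
sample_severities <- function(n, seed = 1, shape1 = 2, shape2 = 2,
                              p_healthy = 0.2) {
  with_seed(seed, {
    healthy <- runif(n) < p_healthy
    s <- matrix(rbeta(4 * n, shape1, shape2), n, 4)
    s[healthy, ] <- 0
    tibble::tibble(
      subject = sprintf("S%02d", seq_len(n)),
      s_a = s[, 1], s_b = s[, 2], s_c = s[, 3], s_d = s[, 4]
    )
  })
}

#' Simulate a synthetic cohort
#'
#' @param n Cohort size (>= 2; leave-one-subject-out needs at least two).
#' @param seed Master seed; per-subject trial seeds are derived from it.
#' @param rate Sampling rate in Hz.
#' @param severities Optional tibble as produced by [sample_severities()];
#'   drawn with the default sampler when `NULL`.
#' @param ... Passed to [simulate_subject()] / [simulate_trial()].
#' @return List of `fmaue_session`, one per subject.
#' @export
#' @examples
#' cohort <- simulate_cohort(n = 2, seed = 7)
#' vapply(cohort, function(s) total_score(s$scores), numeric(1))
simulate_cohort <- function(n = 15, seed = 1, rate = 100,
                            severities = NULL, ...) {
  if (n < 2) abort("cohort size must be >= 2 (LOSOCV needs two subjects)")
  if (is.null(severities)) {
    severities <- sample_severities(n, seed = derive_seed(seed, 0))
  }
  lapply(seq_len(n), function(i) {
    sev <- c(a = severities$s_a[i], b = severities$s_b[i],
             c = severities$s_c[i], d = severities$s_d[i])
    simulate_subject(sev, rate = rate, seed = derive_seed(seed, i),
                     subject_id = severities$subject[i], ...)
  })
}
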