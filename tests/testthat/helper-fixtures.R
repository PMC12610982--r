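# Small fixtures built in code. Unit tests use short, low-rate sessions
# (3 repetitions at 50 Hz) so the whole pipeline stays fast; the
# acceptance tests use full-scale sessions.

tiny_session <- function(seed = 1, severity = c(a = 0.4, b = 0.3,
                                                c = 0.2, d = 0.5),
                         subject_id = "T01") {
  simulate_subject(severity, rate = 50, seed = seed,
                   subject_id = subject_id, repetitions = 3)
}

tiny_cohort <- function(n = 3, seed = 1) {
  sev <- sample_severities(n, seed = seed)
  lapply(seq_len(n), function(i) {
    simulate_subject(c(a = sev$s_a[i], b = sev$s_b[i], c = sev$s_c[i],
                       d = sev$s_d[i]),
                     rate = 50, seed = seed + i, repetitions = 3,
                     subject_id = sev$subject[i])
  })
}

tiny_model_cfg <- function(epochs = 2, lr = 1e-3) {
  model_config(input_size = 1530, encoder_hidden = 8, latent = 6,
               predictor_hidden = 6, epochs = epochs, lr = lr,
               batch_size = 4, dropout = 0.1)
}

# constant-orientation trial: every segment frozen at the neutral pose
static_trial <- function(motion = "RU", n = 300, rate = 50) {
  neutral <- fmaue:::neutral_pose()
  t <- (seq_len(n) - 1) / rate
  recs <- lapply(fma_segments(), function(s) {
    orient <- matrix(rep(neutral[s, ], each = n), n, 3)
    S <- fmaue:::rotstack_from_euler(orient)
    acc <- cbind(S[, "r31"], S[, "r32"], S[, "r33"])
    segment_recording(s, t, acc, matrix(0, n, 3), orient,
                      nominal_rate = rate)
  })
  motion_trial(motion, recs)
}

# ZYX Euler (degrees) -> unit quaternion (w, x, y, z)
euler_to_quat <- function(eul) {
  e <- as.matrix(eul) * pi / 360  # half angles in radians
  cx <- cos(e[, 1]); sx <- sin(e[, 1])
  cy <- cos(e[, 2]); sy <- sin(e[, 2])
  cz <- cos(e[, 3]); sz <- sin(e[, 3])
  cbind(w = cz * cy * cx + sz * sy * sx,
        x = cz * cy * sx - sz * sy * cx,
        y = cz * sy * cx + sz * cy * sx,
        z = sz * cy * cx - cz * sy * sx)
}

band_rms <- function(x, rate, low = 3, high = 8) {
  sqrt(mean(butterworth_filter(x, low, high, order = 2, rate = rate)^2))
}
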