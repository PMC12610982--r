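#' Construct a single-IMU segment recording
#'
#' One body-mounted IMU's synchronized streams for one motion trial: 3-axis
#' acceleration (g), 3-axis angular rate (degrees/s) and 3-axis orientation
#' angles (degrees; x = transverse, y = longitudinal, z = anteroposterior
#' axis of the segment).
#'
#' @param segment One of `fma_segments()`.
#' @param t Numeric vector of timestamps in seconds, strictly increasing.
#' @param acc N x 3 matrix of acceleration in g (sensor range +/- 8 g).
#' @param gyro N x 3 matrix of angular rate in degrees/s (range +/- 2000).
#' @param orient N x 3 matrix of orientation angles in degrees.
#' @param nominal_rate Nominal sampling rate in Hz (default 100).
#' @return A tibble with columns `t`, `ax`, `ay`, `az`, `gx`, `gy`, `gz`,
#'   `ox`, `oy`, `oz`, of class `fmaue_recording`, carrying `segment` and
#'   `nominal_rate` attributes.
#' @export
segment_recording <- function(segment, t, acc, gyro, orient,
                              nominal_rate = 100) {
  segment <- match.arg(segment, fma_segments())
  acc <- as.matrix(acc); gyro <- as.matrix(gyro); orient <- as.matrix(orient)
  n <- length(t)
  if (n < 2) abort("a recording needs at least 2 samples")
  for (m in list(acc, gyro, orient)) {
    if (nrow(m) != n || ncol(m) != 3) {
      abort("acc, gyro and orient must each be N x 3 with N = length(t)")
    }
  }
  out <- tibble::tibble(
    t = as.numeric(t),
    ax = acc[, 1], ay = acc[, 2], az = acc[, 3],
    gx = gyro[, 1], gy = gyro[, 2], gz = gyro[, 3],
    ox = orient[, 1], oy = orient[, 2], oz = orient[, 3]
  )
  attr(out, "segment") <- segment
  attr(out, "nominal_rate") <- nominal_rate
  class(out) <- c("fmaue_recording", class(out))
  out
}

#' Construct a motion trial from four segment recordings
#'
#' @param motion One of `fma_motions()`.
#' @param recordings List of exactly four `segment_recording` objects, one
#'   per segment (hand, forearm, upper_arm, trunk), in any order.
#' @param repetitions Nominal repetition count of the motion (default 5).
#' @return A list of class `fmaue_trial` with elements `motion`,
#'   `recordings` (named by segment) and `repetitions`.
#' @export
motion_trial <- function(motion, recordings, repetitions = 5) {
  motion <- match.arg(motion, fma_motions())
  segs <- vapply(recordings, function(r) attr(r, "segment"), character(1))
  if (anyDuplicated(segs)) abort("duplicate segment recordings in trial")
  missing <- setdiff(fma_segments(), segs)
  if (length(missing)) {
    abort(paste0("incomplete trial ", motion, ": missing segment ",
                 paste(missing, collapse = ", ")))
  }
  names(recordings) <- segs
  structure(
    list(motion = motion, recordings = recordings[fma_segments()],
         repetitions = repetitions),
    class = "fmaue_trial"
  )
}

#' Construct an FMA-UE sub-score set
#'
#' Integer sub-scores for the four FMA-UE parts: A shoulder/elbow (0-36),
#' B wrist (0-10), C hand (0-14), D coordination/speed (0-6).
#'
#' @param a,b,c,d Integer sub-scores.
#' @return Named numeric vector of class `fmaue_scores`.
#' @export
#' @examples
#' total_score(fma_scores(36, 10, 14, 6))  # 66
fma_scores <- function(a, b, c, d) {
  v <- c(a = a, b = b, c = c, d = d)
  rng <- fma_ranges()
  bad <- v < 0 | v > rng | v != round(v)
  if (any(bad)) {
    abort(paste0("score out of range: ", paste(names(v)[bad], collapse = ", "),
                 " (part maxima ", paste(rng, collapse = "/"), ")"))
  }
  structure(as.numeric(v), names = names(v), class = "fmaue_scores")
}

#' Total FMA-UE score
#'
#' Sum of the four sub-scores (0-66).
#'
#' @param scores An `fmaue_scores` object or any 4-vector of part scores.
#' @return Scalar total.
#' @export
total_score <- function(scores) {
  sum(unclass(scores))
}

#' Construct a subject session
#'
#' The per-subject unit of analysis: seven motion trials (one per motion)
#' plus the therapist-rated (or, for synthetic subjects, severity-derived)
#' FMA-UE sub-scores for the tested side.
#'
#' @param subject_id Character identifier.
#' @param trials List of seven `fmaue_trial` objects, one per motion.
#' @param scores `fmaue_scores`.
#' @param tested_side `"left"` or `"right"`.
#' @param rate Nominal sampling rate shared by all trials (Hz).
#' @param is_synthetic Logical flag; `TRUE` for simulator output.
#' @return A list of class `fmaue_session`.
#' @export
subject_session <- function(subject_id, trials, scores,
                            tested_side = c("left", "right"),
                            rate = 100, is_synthetic = FALSE) {
  tested_side <- match.arg(tested_side)
  if (length(trials) == 0) abort("empty trial list")
  mot <- vapply(trials, function(tr) tr$motion, character(1))
  if (anyDuplicated(mot)) abort("duplicate motion trials in session")
  missing <- setdiff(fma_motions(), mot)
  if (length(missing)) {
    abort(paste0("incomplete session: ", paste(missing, collapse = ", ")))
  }
  names(trials) <- mot
  structure(
    list(subject_id = as.character(subject_id),
         tested_side = tested_side,
         rate = rate,
         is_synthetic = isTRUE(is_synthetic),
         scores = scores,
         trials = trials[fma_motions()]),
    class = "fmaue_session"
  )
}

#' @export
print.fmaue_session <- function(x, ...) {
  cat("<fmaue_session> subject", x$subject_id, "(", x$tested_side, "side )\n")
  cat("  scores:", paste(names(x$scores), unclass(x$scores), sep = "=",
                         collapse = " "),
      "| total", total_score(x$scores), "\n")
  n <- vapply(x$trials, function(tr) nrow(tr$recordings[[1]]), numeric(1))
  cat("  trials:", paste(names(x$trials), n, sep = ":", collapse = " "),
      "samples @", x$rate, "Hz\n")
  invisible(x)
}

violation <- function(type, field, index = NA_integer_, message) {
  tibble::tibble(type = type, field = field, index = as.integer(index),
                 message = message)
}

#' Validate a subject session against the domain invariants
#'
#' Checks the session structure (7 motions, 4 segments each), stream
#' lengths, strict timestamp monotonicity, sensor ranges (+/- 8 g,
#' +/- 2000 degrees/s), trial time-span agreement across segments, and
#' score ranges. Reports rather than raises: it is total on arbitrary
#' input and never errors.
#'
#' @param session An `fmaue_session` (or any list-like imitation).
#' @return A tibble of violations with columns `type`, `field`, `index`,
#'   `message`; zero rows iff the session is well formed.
#' @export
validate_session <- function(session) {
  out <- list()
  add <- function(v) out[[length(out) + 1]] <<- v

  scores <- tryCatch(unclass(session$scores), error = function(e) NULL)
  rng <- fma_ranges()
  if (is.null(scores) || length(scores) != 4) {
    add(violation("scores", "scores", NA, "scores missing or not length 4"))
  } else {
    for (k in seq_along(rng)) {
      nm <- names(rng)[k]
      val <- scores[[k]]
      if (!is.finite(val) || val < 0 || val > rng[[k]]) {
        add(violation("score_range", paste0("part_", nm), k,
                      sprintf("part_%s out of range [0,%d]", nm, rng[[k]])))
      }
    }
  }

  trials <- session$trials
  mot <- names(trials)
  for (m in setdiff(fma_motions(), mot)) {
    add(violation("missing_motion", m, NA,
                  paste0("incomplete session: ", m)))
  }

  for (m in intersect(fma_motions(), mot)) {
    tr <- trials[[m]]
    recs <- tr$recordings
    segs <- names(recs)
    for (s in setdiff(fma_segments(), segs)) {
      add(violation("missing_segment", paste(m, s, sep = "/"), NA,
                    paste0("trial ", m, " missing segment ", s)))
    }
    spans <- vapply(recs, function(r) {
      if (is.null(r$t) || length(r$t) < 2) NA_real_ else diff(range(r$t))
    }, numeric(1))
    if (all(is.finite(spans)) && length(spans) > 1) {
      rate <- attr(recs[[1]], "nominal_rate") %||% session$rate %||% 100
      if (diff(range(spans)) > 1 / rate + 1e-9) {
        add(violation("span_mismatch", m, NA,
                      paste0("trial ", m,
                             " segment time spans differ by more than one",
                             " sample period")))
      }
    }
    for (s in intersect(fma_segments(), segs)) {
      r <- recs[[s]]
      fld <- paste(m, s, sep = "/")
      if (is.null(r$t) || length(r$t) < 2) {
        add(violation("too_short", fld, NA, "fewer than 2 samples"))
        next
      }
      if (any(diff(r$t) <= 0)) {
        idx <- which(diff(r$t) <= 0)[1]
        add(violation("non_monotone_time", fld, idx,
                      paste0(fld, ": timestamps not strictly increasing")))
      }
      am <- as.matrix(r[, c("ax", "ay", "az")])
      gm <- as.matrix(r[, c("gx", "gy", "gz")])
      if (any(!is.finite(am)) || any(abs(am) > 8 + 1e-9)) {
        add(violation("acc_range", fld, which(abs(am) > 8)[1] %% nrow(am),
                      paste0(fld, ": acceleration outside +/-8 g")))
      }
      if (any(!is.finite(gm)) || any(abs(gm) > 2000 + 1e-9)) {
        add(violation("gyro_range", fld, which(abs(gm) > 2000)[1] %% nrow(gm),
                      paste0(fld, ": gyro outside +/-2000 deg/s")))
      }
    }
  }
  if (length(out) == 0) {
    return(violation("x", "x", NA, "x")[0, ])
  }
  dplyr::bind_rows(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a subject session to a directory
#'
#' On-disk layout: one RFC-4180 CSV per (motion, segment) named
#' `<motion>_<segment>.csv` with columns `t, ax, ay, az, gx, gy, gz,
#' ox, oy, oz`, plus a `manifest.json` holding subject metadata and the
#' sub-scores. Units are g, degrees/s and degrees throughout.
#'
#' @param session A valid `fmaue_session`.
#' @param path Directory to create/write into.
#' @return Invisibly, the manifest path.
#' @export
write_session <- function(session, path) {
  bad <- validate_session(session)
  if (nrow(bad) > 0) {
    abort(paste0("refusing to write invalid session: ", bad$message[1]))
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (m in names(session$trials)) {
    tr <- session$trials[[m]]
    for (s in names(tr$recordings)) {
      readr::write_csv(tibble::as_tibble(tr$recordings[[s]]),
                       file.path(path, paste0(m, "_", s, ".csv")),
                       progress = FALSE)
    }
  }
  manifest <- list(
    subject_id = session$subject_id,
    tested_side = session$tested_side,
    scores = as.list(unclass(session$scores)),
    sample_rate_hz = session$rate,
    is_synthetic = session$is_synthetic,
    repetitions = lapply(session$trials, function(tr) tr$repetitions)
  )
  mpath <- file.path(path, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(mpath)
}

#' Read a subject session from a directory
#'
#' Inverse of [write_session()]. Orientation may alternatively be stored
#' as quaternion columns `qw, qx, qy, qz`; these are converted on read to
#' the intrinsic Z-Y-X Euler angles (degrees) used internally.
#'
#' @param path Directory containing `manifest.json` and one CSV per
#'   (motion, segment).
#' @return A validated `fmaue_session`.
#' @export
read_session <- function(path) {
  mpath <- file.path(path, "manifest.json")
  if (!file.exists(mpath)) abort(paste0("no manifest.json in ", path))
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  rate <- man$sample_rate_hz %||% 100
  trials <- list()
  for (m in fma_motions()) {
    recs <- list()
    for (s in fma_segments()) {
      f <- file.path(path, paste0(m, "_", s, ".csv"))
      if (!file.exists(f)) {
        if (s == fma_segments()[1]) {
          abort(paste0("incomplete session: ", m))
        }
        abort(paste0("incomplete session: ", m, " missing segment ", s))
      }
      d <- readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
      if (all(c("qw", "qx", "qy", "qz") %in% names(d)) &&
          !all(c("ox", "oy", "oz") %in% names(d))) {
        eul <- quat_to_euler(as.matrix(d[, c("qw", "qx", "qy", "qz")]))
        d$ox <- eul[, 1]; d$oy <- eul[, 2]; d$oz <- eul[, 3]
      }
      recs[[s]] <- segment_recording(
        s, d$t,
        as.matrix(d[, c("ax", "ay", "az")]),
        as.matrix(d[, c("gx", "gy", "gz")]),
        as.matrix(d[, c("ox", "oy", "oz")]),
        nominal_rate = rate
      )
    }
    reps <- man$repetitions[[m]] %||% 5
    trials[[m]] <- motion_trial(m, recs, repetitions = reps)
  }
  sc <- man$scores
  session <- subject_session(
    subject_id = man$subject_id,
    trials = trials,
    scores = fma_scores(sc$a, sc$b, sc$c, sc$d),
    tested_side = man$tested_side %||% "right",
    rate = rate,
    is_synthetic = isTRUE(man$is_synthetic)
  )
  bad <- validate_session(session)
  if (nrow(bad) > 0) {
    abort(paste0("session at ", path, " failed validation: ",
                 bad$message[1]))
  }
  session
}
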