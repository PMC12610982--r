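#' The seven specialized upper-limb motions
#'
#' The motion vocabulary, in the fixed order used along the first axis of
#' every feature tensor: reaching upward (RU), reaching contralateral knee to
#' ipsilateral ear (RKE), hand to lumbar spine (HTS), elbow
#' pronation-supination (EPS), wrist circumduction (WC), hand mass flexion
#' and extension (HMFE), and reaching knee to nose (RKN).
#'
#' @return Character vector of the seven motion codes, in canonical order.
#' @export
#' @examples
#' fma_motions()
fma_motions <- function() {
  c("RU", "RKE", "HTS", "EPS", "WC", "HMFE", "RKN")
}

#' The four IMU body segments
#'
#' @return Character vector: hand, forearm, upper_arm, trunk.
#' @export
fma_segments <- function() {
  c("hand", "forearm", "upper_arm", "trunk")
}

#' FMA-UE sub-score ranges
#'
#' Maximum attainable points per FMA-UE part: A (shoulder/elbow) 36,
#' B (wrist) 10, C (hand) 14, D (coordination/speed) 6; total 66.
#'
#' @return Named numeric vector with elements `a`, `b`, `c`, `d`.
#' @export
#' @examples
#' sum(fma_ranges())  # 66
fma_ranges <- function() {
  c(a = 36, b = 10, c = 14, d = 6)
}

#' Motion groups by the FMA-UE part they chiefly probe
#'
#' RU, RKE, HTS and EPS form the shoulder/elbow group (`A*`); WC is the
#' wrist group (`B*`); HMFE the hand group (`C*`); RKN the coordination
#' group (`D*`).
#'
#' @return Named list of character vectors keyed `A`, `B`, `C`, `D`.
#' @export
fma_motion_groups <- function() {
  list(
    A = c("RU", "RKE", "HTS", "EPS"),
    B = "WC",
    C = "HMFE",
    D = "RKN"
  )
}

#' Kinematic specification of each specialized motion
#'
#' One row per motion with the parameters the synthetic simulator uses:
#' the dominant FMA-UE part, the base orientation amplitude (degrees) and
#' repetition period (seconds) of an unimpaired performance, the coupling
#' weights of the four severity components on this motion (dominant part
#' 0.7, the remaining 0.3 split over the other parts the motion touches;
#' a motion touching only its dominant part gets weight 1), and per-segment
#' axis gains describing which segments move and on which axes.
#'
#' @return A tibble with columns `motion`, `dominant_part`,
#'   `base_amplitude`, `base_period`, `coupling` (list of named 4-vectors
#'   over parts a--d, non-negative, summing to 1) and `segment_gain`
#'   (list of 4 x 3 gain matrices, rows = segments, cols = x/y/z axes).
#' @export
#' @examples
#' motion_specs()
motion_specs <- function() {
  gain <- function(hand, forearm, upper_arm, trunk) {
    m <- rbind(hand = hand, forearm = forearm, upper_arm = upper_arm,
               trunk = trunk)
    colnames(m) <- c("x", "y", "z")
    m
  }
  w <- function(a = 0, b = 0, c = 0, d = 0) {
    v <- c(a = a, b = b, c = c, d = d)
    v / sum(v)
  }
  tibble::tibble(
    motion = fma_motions(),
    dominant_part = c("a", "a", "a", "a", "b", "c", "d"),
    base_amplitude = c(90, 80, 50, 80, 40, 50, 70),
    base_period = c(2, 2, 2, 2, 2, 2, 1.5),
    coupling = list(
      RU   = w(a = 1),
      RKE  = w(a = 1),
      HTS  = w(a = 1),
      EPS  = w(a = 1),
      WC   = w(a = 0.3, b = 0.7),
      HMFE = w(c = 1),
      RKN  = w(a = 0.3, d = 0.7)
    ),
    segment_gain = list(
      RU   = gain(c(0.5, 0.8, 0.1), c(0.5, 0.8, 0.1), c(0.4, 1.0, 0.2),
                  c(0.05, 0.05, 0.02)),
      RKE  = gain(c(0.6, 0.7, 0.2), c(0.6, 0.7, 0.2), c(0.5, 0.8, 0.4),
                  c(0.05, 0.08, 0.03)),
      HTS  = gain(c(0.4, 0.5, 0.3), c(0.4, 0.6, 0.3), c(0.3, 0.8, 0.2),
                  c(0.03, 0.05, 0.02)),
      EPS  = gain(c(1.0, 0.1, 0.1), c(1.0, 0.1, 0.1), c(0.05, 0.05, 0.05),
                  c(0.01, 0.01, 0.01)),
      WC   = gain(c(1.0, 0.8, 0.3), c(0.15, 0.1, 0.05), c(0.03, 0.03, 0.03),
                  c(0.01, 0.01, 0.01)),
      HMFE = gain(c(0.9, 0.4, 0.15), c(0.1, 0.05, 0.05), c(0.02, 0.02, 0.02),
                  c(0.01, 0.01, 0.01)),
      RKN  = gain(c(0.6, 0.7, 0.3), c(0.6, 0.7, 0.3), c(0.5, 0.8, 0.3),
                  c(0.05, 0.08, 0.03))
    )
  )
}
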