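# Rotation utilities. Orientation angles are intrinsic Z-Y-X Euler angles in
# degrees: R = Rz(z) %*% Ry(y) %*% Rx(x). All stack functions operate on
# N x 9 matrices with columns r11, r12, r13, r21, ..., r33 (row-major).

DEG <- pi / 180

rotstack_from_euler <- function(eul_deg) {
  e <- as.matrix(eul_deg) * DEG
  sa <- sin(e[, 1]); ca <- cos(e[, 1])  # x
  sb <- sin(e[, 2]); cb <- cos(e[, 2])  # y
  sc <- sin(e[, 3]); cc <- cos(e[, 3])  # z
  cbind(
    r11 = cb * cc,
    r12 = sa * sb * cc - ca * sc,
    r13 = ca * sb * cc + sa * sc,
    r21 = cb * sc,
    r22 = sa * sb * sc + ca * cc,
    r23 = ca * sb * sc - sa * cc,
    r31 = -sb,
    r32 = sa * cb,
    r33 = ca * cb
  )
}

rotstack_to_euler <- function(S) {
  r31 <- pmin(pmax(S[, "r31"], -1), 1)
  y <- asin(-r31)
  x <- atan2(S[, "r32"], S[, "r33"])
  z <- atan2(S[, "r21"], S[, "r11"])
  cbind(x = x, y = y, z = z) / DEG
}

# t(P) %*% D per sample, both N x 9 stacks
rotstack_tmult <- function(P, D) {
  out <- matrix(0, nrow(P), 9)
  colnames(out) <- colnames(P)
  for (i in 1:3) {
    for (j in 1:3) {
      acc <- 0
      for (k in 1:3) {
        acc <- acc + P[, 3 * (k - 1) + i] * D[, 3 * (k - 1) + j]
      }
      out[, 3 * (i - 1) + j] <- acc
    }
  }
  out
}

# t(R0) %*% S per sample, R0 a single 3 x 3 matrix
rotstack_tmult_const <- function(R0, S) {
  out <- matrix(0, nrow(S), 9)
  colnames(out) <- colnames(S)
  for (i in 1:3) {
    for (j in 1:3) {
      acc <- 0
      for (k in 1:3) {
        acc <- acc + R0[k, i] * S[, 3 * (k - 1) + j]
      }
      out[, 3 * (i - 1) + j] <- acc
    }
  }
  out
}

#' Convert unit quaternions to Z-Y-X Euler angles
#'
#' @param q N x 4 matrix with columns w, x, y, z.
#' @return N x 3 matrix of Euler angles in degrees (x, y, z), intrinsic
#'   Z-Y-X convention.
#' @export
quat_to_euler <- function(q) {
  q <- as.matrix(q)
  n <- sqrt(rowSums(q^2))
  q <- q / n
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  S <- cbind(
    r11 = 1 - 2 * (y^2 + z^2),
    r12 = 2 * (x * y - w * z),
    r13 = 2 * (x * z + w * y),
    r21 = 2 * (x * y + w * z),
    r22 = 1 - 2 * (x^2 + z^2),
    r23 = 2 * (y * z - w * x),
    r31 = 2 * (x * z - w * y),
    r32 = 2 * (y * z + w * x),
    r33 = 1 - 2 * (x^2 + y^2)
  )
  rotstack_to_euler(S)
}

#' Joint angles from relative segment orientations
#'
#' For each adjacent segment pair (hand-forearm = wrist, forearm-upper_arm
#' = elbow, upper_arm-trunk = shoulder) the relative rotation
#' `R_rel(t) = R_prox(t)^-1 R_dist(t)` is re-referenced by the neutral
#' sample, `R_joint(t) = R_rel(t0)^-1 R_rel(t)`, so all joint angles are
#' zero at the neutral pose, then decomposed into intrinsic Z-Y-X Euler
#' angles in degrees.
#'
#' @param trial An `fmaue_trial`.
#' @param neutral_index Index of the stationary neutral-pose sample
#'   (default 1, the start of the recording).
#' @return Tibble with N rows and columns `wrist_x` ... `shoulder_z`
#'   (9 angle channels, degrees).
#' @export
compute_joint_angles <- function(trial, neutral_index = 1) {
  pairs <- list(
    wrist = c(prox = "forearm", dist = "hand"),
    elbow = c(prox = "upper_arm", dist = "forearm"),
    shoulder = c(prox = "trunk", dist = "upper_arm")
  )
  n <- nrow(trial$recordings[[1]])
  if (neutral_index < 1 || neutral_index > n) {
    abort("neutral_index outside recording range")
  }
  stacks <- lapply(trial$recordings, function(r) {
    rotstack_from_euler(as.matrix(r[, c("ox", "oy", "oz")]))
  })
  out <- list()
  for (j in names(pairs)) {
    rel <- rotstack_tmult(stacks[[pairs[[j]]["prox"]]],
                          stacks[[pairs[[j]]["dist"]]])
    R0 <- matrix(rel[neutral_index, ], 3, 3, byrow = TRUE)
    if (abs(R0[3, 1]) > 1 - 1e-9) {
      abort(paste0("gimbal-degenerate neutral pose for joint ", j))
    }
    ang <- rotstack_to_euler(rotstack_tmult_const(R0, rel))
    out[[paste0(j, "_x")]] <- ang[, "x"]
    out[[paste0(j, "_y")]] <- ang[, "y"]
    out[[paste0(j, "_z")]] <- ang[, "z"]
  }
  tibble::as_tibble(out)
}
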