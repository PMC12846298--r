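#' Rotation trajectories and SO(3) utilities
#'
#' A `rotation_trajectory` stores a time series of segment-to-laboratory
#' orientations as an `n x 9` matrix whose rows are column-major vectorized
#' 3x3 rotation matrices (`r11, r21, r31, r12, ..., r33`). This layout keeps
#' whole-trajectory compositions vectorized (a fixed rotation applied to every
#' frame is a single matrix product).
#'
#' @param times Numeric vector of frame times, seconds, strictly increasing.
#' @param mats Either an `n x 9` matrix of column-major vectorized rotations or
#'   a list of 3x3 rotation matrices.
#' @param side Limb label (`"left"`/`"right"`), free text.
#' @param system Measurement system label (`"imu"` or `"camera"`).
#' @param check If `TRUE` (default), verify every frame is orthonormal with
#'   determinant +1 (tolerance `1e-6`).
#' @return An object of class `rotation_trajectory`.
#' @export
rotation_trajectory <- function(times, mats, side = "right", system = "camera",
                                check = TRUE) {
  if (is.list(mats)) mats <- do.call(rbind, lapply(mats, as.vector))
  mats <- as.matrix(mats)
  if (ncol(mats) != 9L)
    stop("`mats` must have 9 columns (vectorized 3x3 rotations)",
         call. = FALSE)
  if (length(times) != nrow(mats))
    stop("`times` length must equal the number of frames", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  if (check) {
    bad <- which(!rot9_valid(mats, tol = 1e-6))
    if (length(bad))
      stop(sprintf("frame %d is not a rotation matrix (orthonormality/det)",
                   bad[1L]), call. = FALSE)
  }
  structure(list(times = as.numeric(times), mats = mats,
                 side = side, system = system),
            class = "rotation_trajectory")
}

#' @export
print.rotation_trajectory <- function(x, ...) {
  cat(sprintf("<rotation_trajectory> %d frames, t = [%.3f, %.3f] s, %s/%s\n",
              length(x$times), min(x$times), max(x$times), x$system, x$side))
  invisible(x)
}

#' Extract one frame of a trajectory as a 3x3 matrix
#' @param traj A [rotation_trajectory()].
#' @param i Frame index.
#' @return 3x3 rotation matrix.
#' @export
traj_matrix <- function(traj, i) matrix(traj$mats[i, ], 3, 3)

# ---- internal vectorized SO(3) helpers (n x 9 column-major layout) ---------

rot9_valid <- function(mats, tol = 1e-8) {
  # RtR = I and det = +1, checked row-wise without forming 3x3 matrices
  c1 <- mats[, 1:3, drop = FALSE]
  c2 <- mats[, 4:6, drop = FALSE]
  c3 <- mats[, 7:9, drop = FALSE]
  dot <- function(a, b) rowSums(a * b)
  err <- pmax(abs(dot(c1, c1) - 1), abs(dot(c2, c2) - 1),
              abs(dot(c3, c3) - 1), abs(dot(c1, c2)),
              abs(dot(c1, c3)), abs(dot(c2, c3)))
  det <- c1[, 1] * (c2[, 2] * c3[, 3] - c2[, 3] * c3[, 2]) -
         c2[, 1] * (c1[, 2] * c3[, 3] - c1[, 3] * c3[, 2]) +
         c3[, 1] * (c1[, 2] * c2[, 3] - c1[, 3] * c2[, 2])
  err <= tol & abs(det - 1) <= sqrt(tol)
}

# per-frame product C_t = A_t %*% B_t
rot9_compose <- function(A, B) {
  out <- matrix(0, nrow(A), 9L)
  for (i in 1:3) for (j in 1:3) {
    col <- (j - 1L) * 3L + i
    out[, col] <- A[, i] * B[, (j - 1L) * 3L + 1L] +
      A[, 3L + i] * B[, (j - 1L) * 3L + 2L] +
      A[, 6L + i] * B[, (j - 1L) * 3L + 3L]
  }
  out
}

# fixed rotation applied frame-wise: R0 %*% B_t for all t
rot9_lcompose <- function(R0, B) B %*% t(kronecker(diag(3), R0))

# frame-wise right composition: A_t %*% R0 for all t
rot9_rcompose <- function(A, R0) A %*% kronecker(R0, diag(3))

rot9_transpose <- function(A) A[, c(1L, 4L, 7L, 2L, 5L, 8L, 3L, 6L, 9L),
                                drop = FALSE]

#' Project a matrix onto SO(3)
#'
#' Nearest rotation in Frobenius norm, via SVD with determinant correction.
#' Used to re-orthonormalize after averaging or accumulation.
#'
#' @param M A 3x3 matrix.
#' @return The closest 3x3 rotation matrix (det +1).
#' @export
project_so3 <- function(M) {
  s <- svd(M)
  if (min(s$d) < .Machine$double.eps^0.5 && s$d[2] < .Machine$double.eps^0.5)
    stop("degenerate (rank-deficient) matrix cannot be projected onto SO(3)",
         call. = FALSE)
  d <- det(s$u %*% t(s$v))
  s$u %*% diag(c(1, 1, sign(d))) %*% t(s$v)
}

#' Geodesic angle between two rotations
#'
#' @param R1,R2 3x3 rotation matrices.
#' @return Rotation angle of `t(R1) %*% R2` in degrees (in `[0, 180]`).
#' @export
rotation_angle_deg <- function(R1, R2 = diag(3)) {
  tr <- sum(diag(crossprod(R1, R2)))
  acos(pmin(1, pmax(-1, (tr - 1) / 2))) * 180 / pi
}

#' Chordal mean of a set of rotations
#'
#' Arithmetic mean of the matrices projected back onto SO(3); the standard
#' chordal L2 mean, appropriate for tightly clustered orientations such as a
#' short reference window at the start of a task.
#'
#' @param matrices A list of 3x3 rotation matrices, or an `n x 9` matrix of
#'   column-major vectorized rotations.
#' @return A 3x3 rotation matrix.
#' @export
mean_rotation <- function(matrices) {
  if (is.list(matrices)) {
    if (!length(matrices)) stop("no matrices to average", call. = FALSE)
    M <- Reduce(`+`, matrices) / length(matrices)
  } else {
    matrices <- as.matrix(matrices)
    if (!nrow(matrices)) stop("no matrices to average", call. = FALSE)
    M <- matrix(colMeans(matrices), 3, 3)
  }
  project_so3(M)
}

# ---- Euler conversions (intrinsic z-y'-x'': yaw, then pitch, then roll) ----

#' Convert Euler angles to a rotation matrix
#'
#' Intrinsic z-y'-x'' (yaw-pitch-roll) convention, angles in degrees:
#' `R = Rz(yaw) %*% Ry(pitch) %*% Rx(roll)`. The same convention is applied to
#' both measurement systems so that the choice cancels in range-of-motion
#' comparisons.
#'
#' @param roll,pitch,yaw Angles in degrees (scalars).
#' @return A 3x3 rotation matrix (orthonormal, det +1).
#' @export
euler_to_matrix <- function(roll, pitch, yaw) {
  matrix(euler_to_rot9(roll, pitch, yaw), 3, 3)
}

# vectorized: n angles -> n x 9
euler_to_rot9 <- function(roll, pitch, yaw) {
  r <- roll * pi / 180; p <- pitch * pi / 180; y <- yaw * pi / 180
  cr <- cos(r); sr <- sin(r); cp <- cos(p); sp <- sin(p)
  cy <- cos(y); sy <- sin(y)
  cbind(cy * cp,                 # r11
        sy * cp,                 # r21
        -sp,                     # r31
        cy * sp * sr - sy * cr,  # r12
        sy * sp * sr + cy * cr,  # r22
        cp * sr,                 # r32
        cy * sp * cr + sy * sr,  # r13
        sy * sp * cr - cy * sr,  # r23
        cp * cr)                 # r33
}

#' Recover Euler angles from a rotation matrix
#'
#' Inverse of [euler_to_matrix()] under the same intrinsic z-y'-x'' convention.
#' Within 0.1 degrees of gimbal lock (|pitch| > 89.9) the roll/yaw split is
#' undefined; roll is set to 0, the remaining freedom folded into yaw, and the
#' sample flagged via the `"gimbal_lock"` attribute.
#'
#' @param R A 3x3 rotation matrix (validated to 1e-6).
#' @return Named numeric vector `c(roll, pitch, yaw)` in degrees, with a
#'   logical `"gimbal_lock"` attribute.
#' @export
matrix_to_euler <- function(R) {
  if (!all(dim(R) == c(3L, 3L)) ||
      max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0)
    stop("input is not a valid rotation matrix", call. = FALSE)
  e <- rot9_to_euler(matrix(as.vector(R), 1L, 9L))
  out <- c(roll = e$roll, pitch = e$pitch, yaw = e$yaw)
  attr(out, "gimbal_lock") <- e$lock
  out
}

# vectorized: n x 9 -> list(roll, pitch, yaw, lock), degrees
rot9_to_euler <- function(mats) {
  r31 <- pmin(1, pmax(-1, mats[, 3]))
  pitch <- asin(-r31)
  lock <- abs(pitch) > 89.9 * pi / 180
  roll <- atan2(mats[, 6], mats[, 9])
  yaw <- atan2(mats[, 2], mats[, 1])
  if (any(lock)) {
    # at lock only roll -/+ yaw is determined (r12 = -+sin(roll -/+ yaw),
    # r22 = cos(roll -/+ yaw)); conventionally roll := 0, freedom into yaw
    roll[lock] <- 0
    yaw[lock] <- atan2(-mats[lock, 4], mats[lock, 5])
  }
  list(roll = roll * 180 / pi, pitch = pitch * 180 / pi,
       yaw = yaw * 180 / pi, lock = lock)
}

#' Write / read a rotation trajectory as CSV
#'
#' Interchange format: a `time_s` column plus nine columns `r11 ... r33` in
#' row-major order (`r11, r12, r13, r21, ...`), one row per frame.
#'
#' @param traj A [rotation_trajectory()].
#' @param path File path.
#' @return `write_rotation_csv()` returns `path` invisibly;
#'   `read_rotation_csv()` returns a [rotation_trajectory()].
#' @export
write_rotation_csv <- function(traj, path) {
  stopifnot(inherits(traj, "rotation_trajectory"))
  rowmajor <- traj$mats[, c(1, 4, 7, 2, 5, 8, 3, 6, 9), drop = FALSE]
  colnames(rowmajor) <- c("r11", "r12", "r13", "r21", "r22", "r23",
                          "r31", "r32", "r33")
  df <- data.frame(time_s = traj$times, rowmajor)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rotation_csv
#' @param side,system Labels attached to the trajectory read back.
#' @export
read_rotation_csv <- function(path, side = "right", system = "camera") {
  df <- utils::read.csv(path)
  need <- c("time_s", "r11", "r12", "r13", "r21", "r22", "r23",
            "r31", "r32", "r33")
  if (!all(need %in% names(df)))
    stop("rotation CSV must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  mats <- as.matrix(df[c("r11", "r21", "r31", "r12", "r22", "r32",
                         "r13", "r23", "r33")])
  rotation_trajectory(df$time_s, mats, side = side, system = system)
}
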