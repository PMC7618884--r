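# Core turning-angle computation: ground-plane joint-pair vectors, per-frame
# rotation increments, cumulative angle, angular speed, max angular velocity
# and 45-degree bin quantisation.

PAIR_JOINTS <- list(
  hip = c("left_hip", "right_hip"),
  knee = c("left_knee", "right_knee"),
  shoulder = c("left_shoulder", "right_shoulder")
)

# Degeneracy threshold, relative to the overall coordinate scale of the clip.
pair_epsilon <- function(seq) {
  s <- max(abs(seq$coords), na.rm = TRUE)
  1e-9 * max(s, 1)
}

# All frames at once: T x 2 matrix of left-minus-right ground-plane vectors
# plus a per-frame validity flag (both joints unmasked, norm above epsilon).
pair_vectors <- function(seq, pair) {
  pair <- match.arg(pair, names(PAIR_JOINTS))
  jl <- joint_index(seq, PAIR_JOINTS[[pair]][1])
  jr <- joint_index(seq, PAIR_JOINTS[[pair]][2])
  v <- seq$coords[, jl, 1:2, drop = FALSE] - seq$coords[, jr, 1:2, drop = FALSE]
  v <- matrix(v, ncol = 2)
  valid <- seq$valid_mask[, jl] & seq$valid_mask[, jr]
  nrm <- sqrt(rowSums(v^2))
  valid <- valid & is.finite(nrm) & nrm > pair_epsilon(seq)
  list(v = v, valid = valid)
}

#' Ground-plane joint-pair vector at one frame
#'
#' The left-minus-right joint-pair vector restricted to the two horizontal
#' axes (the vertical coordinate is dropped). These vectors lie in the body's
#' frontal plane and indicate facing direction; the hip vector is the primary
#' turning indicator.
#'
#' @param seq a `skeleton_sequence`.
#' @param frame 0-based frame index.
#' @param pair `"hip"`, `"knee"` or `"shoulder"`.
#' @return Numeric vector `c(vx, vy)` with attribute `valid` (`FALSE` when a
#'   joint is masked or the norm is below the degeneracy epsilon).
#' @export
pair_vector <- function(seq, frame, pair = c("hip", "knee", "shoulder")) {
  pair <- match.arg(pair)
  T_ <- n_frames(seq)
  if (frame < 0 || frame >= T_)
    tm_index_error(sprintf("frame %d out of range [0, %d)", frame, T_))
  pv <- pair_vectors(seq, pair)
  i <- frame + 1L
  out <- pv$v[i, ]
  names(out) <- c("vx", "vy")
  attr(out, "valid") <- pv$valid[i]
  out
}

#' Rotation between two ground-plane vectors
#'
#' The per-frame turning increment between consecutive joint-pair vectors.
#' In `"faithful"` mode this is arcsin of the normalised 2D cross product,
#' an unsigned angle in \[0, 90\] degrees; note that rotations beyond 90
#' degrees in a single step alias back (arcsin(sin x)), which is why turning
#' is accumulated frame by frame at video rates where steps stay small. In
#' `"signed"` mode the atan2-based signed angle in (-180, 180\] is returned
#' (positive = counter-clockwise seen from above in a z-up right-handed
#' frame).
#'
#' @param v_t,v_t1 numeric `c(vx, vy)` vectors at frames t and t+1.
#' @param mode `"faithful"` (default) or `"signed"`.
#' @return Angle in degrees.
#' @export
frame_increment <- function(v_t, v_t1, mode = c("faithful", "signed")) {
  mode <- match.arg(mode)
  n1 <- sqrt(sum(v_t^2)); n2 <- sqrt(sum(v_t1^2))
  if (!is.finite(n1) || !is.finite(n2) || n1 <= 0 || n2 <= 0)
    tm_degenerate_error("zero-norm or non-finite pair vector")
  cross <- v_t[1] * v_t1[2] - v_t[2] * v_t1[1]
  if (mode == "faithful") {
    asin(min(1, abs(cross) / (n1 * n2))) * 180 / pi
  } else {
    dot <- sum(v_t * v_t1)
    atan2(cross, dot) * 180 / pi
  }
}

# Vectorised increments for a T x 2 vector matrix (already carried forward).
increments_from_vectors <- function(v, mode) {
  T_ <- nrow(v)
  a <- v[-T_, , drop = FALSE]
  b <- v[-1, , drop = FALSE]
  cross <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  nn <- sqrt(rowSums(a^2)) * sqrt(rowSums(b^2))
  if (mode == "faithful") {
    asin(pmin(1, abs(cross) / nn)) * 180 / pi
  } else {
    dot <- rowSums(a * b)
    atan2(cross, dot) * 180 / pi
  }
}

# Last-observation-carried-forward over invalid frames; leading invalid
# frames take the first valid vector (their increments become zero). Errors
# if no frame is valid.
carry_forward <- function(pv, pair) {
  if (!any(pv$valid))
    tm_degenerate_error(paste0("no frame has a usable ", pair, " vector"))
  v <- pv$v
  idx <- which(pv$valid)
  # map every frame to the most recent valid frame (first valid for leaders)
  pos <- findInterval(seq_len(nrow(v)), idx)
  pos[pos == 0L] <- 1L
  list(v = v[idx[pos], , drop = FALSE], skipped = sum(!pv$valid))
}

#' Cumulative turning angle of a clip
#'
#' The turning angle of a trimmed clip: per frame pair, the rotation
#' increment of each selected joint-pair vector (hip, knee, shoulder) is
#' computed and the increments are averaged with equal weights across the
#' selected pairs; the cumulative angle is the sum over all frame pairs.
#' With the default `joint_sets = c("hip", "knee")` this is the mean of the
#' hip-vector and knee-vector rotations. Frames where a pair vector is
#' masked or degenerate are carried forward from the last valid frame (the
#' skipped count is reported and a warning issued).
#'
#' @param seq a `skeleton_sequence` with at least 2 frames.
#' @param joint_sets non-empty subset of `c("hip", "knee", "shoulder")`.
#' @param mode `"faithful"` (unsigned increments, default) or `"signed"`.
#' @param duration_s clip duration for the angular-speed denominator;
#'   defaults to `T / fps`.
#' @return A `turn_estimate`: list with `theta_deg` (cumulative angle),
#'   `increments_deg` (length T-1), `omega_deg_s` (mean angular speed),
#'   `wmax_deg_s` (maximum angular velocity), `duration_s`, `fps`,
#'   `joint_sets`, `mode`, `n_frames`, `skipped_frames`.
#' @export
cumulative_angle <- function(seq, joint_sets = c("hip", "knee"),
                             mode = c("faithful", "signed"),
                             duration_s = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(seq, "skeleton_sequence"))
  T_ <- n_frames(seq)
  if (T_ < 2L)
    tm_insufficient_frames("need at least 2 frames to measure rotation")
  joint_sets <- match.arg(joint_sets, names(PAIR_JOINTS), several.ok = TRUE)
  if (length(joint_sets) == 0L) tm_argument_error("`joint_sets` must be non-empty")

  skipped <- 0L
  inc <- matrix(0, nrow = T_ - 1L, ncol = length(joint_sets))
  for (k in seq_along(joint_sets)) {
    cf <- carry_forward(pair_vectors(seq, joint_sets[k]), joint_sets[k])
    skipped <- skipped + cf$skipped
    inc[, k] <- increments_from_vectors(cf$v, mode)
  }
  if (skipped > 0L)
    warning(sprintf("%d degenerate/masked joint-frames carried forward", skipped),
            call. = FALSE)
  increments <- rowMeans(inc)
  theta <- sum(increments)
  duration <- duration_s %||% (T_ / seq$fps)
  structure(
    list(theta_deg = theta,
         increments_deg = increments,
         omega_deg_s = angular_speed(theta, duration),
         wmax_deg_s = max_angular_velocity(increments, seq$fps),
         duration_s = duration,
         fps = seq$fps,
         joint_sets = joint_sets,
         mode = mode,
         n_frames = T_,
         skipped_frames = skipped),
    class = "turn_estimate"
  )
}

#' @export
print.turn_estimate <- function(x, ...) {
  cat(sprintf(
    "<turn_estimate> theta = %.2f deg over %.2f s (%s mode, joints: %s)\n",
    x$theta_deg, x$duration_s, x$mode, paste(x$joint_sets, collapse = "+")))
  cat(sprintf("  omega = %.2f deg/s, w_max = %.2f deg/s, %d frames",
              x$omega_deg_s, x$wmax_deg_s, x$n_frames))
  if (x$skipped_frames > 0) cat(sprintf(", %d skipped", x$skipped_frames))
  cat("\n")
  invisible(x)
}

#' Mean angular speed
#'
#' omega = theta / d: cumulative turning angle over clip duration.
#'
#' @param theta_deg cumulative angle in degrees.
#' @param duration_s clip duration in seconds, > 0.
#' @return Speed in degrees per second.
#' @export
angular_speed <- function(theta_deg, duration_s) {
  if (!is.numeric(duration_s) || length(duration_s) != 1L ||
      !is.finite(duration_s) || duration_s <= 0)
    tm_argument_error("`duration_s` must be a single positive number")
  theta_deg / duration_s
}

#' Maximum angular velocity
#'
#' The largest per-frame-pair rotation increment expressed per second:
#' `max(|theta_t|) / dt` with `dt = 1/fps`. (Dividing, not multiplying, by
#' the frame interval is what yields degrees per second; see the vignette's
#' note on the dimensional convention.) For a clip with at least two frames
#' this is always >= the mean speed computed over `(N-1)/fps`.
#'
#' @param increments_deg per-frame-pair increments theta_t in degrees.
#' @param fps frames per second, > 0.
#' @return Peak speed in degrees per second.
#' @export
max_angular_velocity <- function(increments_deg, fps) {
  if (length(increments_deg) == 0L)
    tm_insufficient_frames("need at least one frame-pair increment")
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    tm_argument_error("`fps` must be a single positive number")
  max(abs(increments_deg)) * fps
}

#' Quantise turning angles into 45-degree bins
#'
#' Assigns each angle to the nearest bin of the label set, the quantisation
#' clinicians use when rating turns by eye: e.g. any angle in 90 +/- 22.5
#' degrees is labelled 90. Ties at bin edges (e.g. exactly 112.5) round half
#' up to the larger bin. Angles below the smallest bin's lower edge are
#' sub-threshold: with `clamp = TRUE` (default) they map to the smallest
#' bin, otherwise they become `NA` and are flagged.
#'
#' @param theta_deg numeric vector of non-negative angles in degrees.
#' @param label_set permitted bins, multiples of 45 (default 45..360).
#' @param clamp map sub-threshold angles to the smallest bin? Default `TRUE`.
#' @return Numeric vector of bin labels (possibly `NA`), with attribute
#'   `sub_threshold`: logical vector marking angles below the smallest bin's
#'   lower edge.
#' @export
quantize_to_bin <- function(theta_deg, label_set = seq(45, 360, by = 45),
                            clamp = TRUE) {
  if (length(label_set) == 0L) tm_argument_error("`label_set` must be non-empty")
  if (any(label_set %% 45 != 0) || any(label_set <= 0))
    tm_argument_error("`label_set` must contain positive multiples of 45")
  if (any(theta_deg < 0, na.rm = TRUE))
    tm_argument_error("`theta_deg` must be non-negative")
  bins <- sort(unique(as.numeric(label_set)))
  half <- min(diff(c(0, bins))) / 2  # 22.5 for a 45-degree grid
  lower_edge <- bins[1] - half
  out <- vapply(theta_deg, function(th) {
    if (is.na(th)) return(NA_real_)
    d <- abs(th - bins)
    i <- which(d <= min(d) + 1e-9)  # ties -> larger bin (round half up)
    bins[max(i)]
  }, numeric(1))
  sub <- !is.na(theta_deg) & theta_deg < lower_edge - 1e-12
  if (!clamp) out[sub] <- NA_real_
  attr(out, "sub_threshold") <- sub
  out
}
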