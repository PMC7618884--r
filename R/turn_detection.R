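# Segmentation of turning episodes from continuous skeleton streams.
#
# A turning episode runs from the initiation of pelvis rotation to the
# completion of the movement. Operationalised as hysteresis thresholding of
# the signed hip-vector angular velocity: a segment opens when |velocity|
# reaches omega_start, extends backward and forward over contiguous frames
# with |velocity| >= omega_stop (tolerating up to max_gap_frames below),
# its boundaries are then refined outward to the surrounding angular-velocity
# floor (so slow initiation/termination ramps are not clipped), and it is
# kept only if the net accumulated rotation reaches threshold_deg.

#' Detect turning episodes in a skeleton stream
#'
#' Segments maximal non-overlapping turning episodes from a continuous
#' sequence using the signed hip-vector angular velocity (hip-only, since the
#' pelvis defines turn initiation), then keeps segments whose net rotation
#' magnitude is at least `threshold_deg` — 45 degrees by default, the
#' minimum rotation that counts as a turning motion (one bin width).
#'
#' @param seq a `skeleton_sequence` with at least 3 frames.
#' @param threshold_deg minimum net rotation for a segment to count as a
#'   turn (default 45).
#' @param omega_start angular speed (deg/s) that opens a segment (default 25).
#' @param omega_stop angular speed (deg/s) below which a segment ends;
#'   must be <= `omega_start` (default 10).
#' @param max_gap_frames frames allowed below `omega_stop` inside a segment
#'   before it closes; default `round(fps / 4)`.
#' @param omega_floor angular speed (deg/s) down to which detected segment
#'   boundaries are extended, capturing the slow start and end of a turn's
#'   velocity ramp (default 1).
#' @return A data.frame of class `turn_segments`, sorted by `start_frame`,
#'   with columns `start_frame`, `end_frame` (0-based, half-open interval),
#'   `accumulated_deg` (net signed-magnitude rotation), `direction`
#'   (`"ccw"`, `"cw"` or `"mixed"`) and `duration_s`.
#' @export
detect_turns <- function(seq, threshold_deg = 45,
                         omega_start = 25, omega_stop = 10,
                         max_gap_frames = NULL, omega_floor = 1) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  if (n_frames(seq) < 3L)
    tm_insufficient_frames("need at least 3 frames to detect turns")
  if (threshold_deg <= 0 || omega_start <= 0 || omega_stop <= 0)
    tm_argument_error("thresholds must be positive")
  if (omega_stop > omega_start)
    tm_argument_error("`omega_stop` must not exceed `omega_start`")
  if (omega_floor < 0 || omega_floor > omega_stop)
    tm_argument_error("`omega_floor` must be in [0, omega_stop]")
  max_gap_frames <- max_gap_frames %||% round(seq$fps / 4)

  cf <- carry_forward(pair_vectors(seq, "hip"), "hip")
  inc <- increments_from_vectors(cf$v, "signed")  # deg per frame-pair
  vel <- abs(inc) * seq$fps                       # deg/s
  n <- length(inc)

  active <- vel >= omega_stop
  strong <- vel >= omega_start

  # candidate runs: contiguous active stretches, merged across gaps of up to
  # max_gap_frames inactive increments; kept only if they contain a strong
  # increment (hysteresis opening condition)
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (!active[i]) { i <- i + 1L; next }
    start <- i
    end <- i
    j <- i + 1L
    gap <- 0L
    while (j <= n) {
      if (active[j]) { end <- j; gap <- 0L } else {
        gap <- gap + 1L
        if (gap > max_gap_frames) break
      }
      j <- j + 1L
    }
    runs[[length(runs) + 1L]] <- c(start, end)
    i <- j
  }

  segs <- list()
  prev_end <- 0L
  for (r in runs) {
    i0 <- r[1]; i1 <- r[2]
    if (!any(strong[i0:i1])) { prev_end <- max(prev_end, i1); next }
    # refine boundaries outward to the velocity floor: the episode starts at
    # the initiation of pelvis rotation, not where the hysteresis opened
    while (i0 > prev_end + 1L && vel[i0 - 1L] >= omega_floor) i0 <- i0 - 1L
    nxt <- runs[vapply(runs, function(q) q[1] > i1, TRUE)]
    upper <- if (length(nxt)) min(vapply(nxt, `[`, 1L, 1)) - 1L else n
    while (i1 < upper && vel[i1 + 1L] >= omega_floor) i1 <- i1 + 1L
    prev_end <- i1
    acc <- sum(inc[i0:i1])
    if (abs(acc) < threshold_deg) next
    pos <- sum(inc[i0:i1][inc[i0:i1] > 0])
    neg <- -sum(inc[i0:i1][inc[i0:i1] < 0])
    direction <- if (min(pos, neg) > 45) "mixed" else if (acc > 0) "ccw" else "cw"
    segs[[length(segs) + 1L]] <- data.frame(
      start_frame = i0 - 1L,          # increment i is between frames i-1, i (0-based)
      end_frame = i1 + 1L,            # half-open
      accumulated_deg = acc,
      direction = direction,
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(segs)) do.call(rbind, segs) else
    data.frame(start_frame = integer(), end_frame = integer(),
               accumulated_deg = numeric(), direction = character(),
               stringsAsFactors = FALSE)
  out <- out[order(out$start_frame), , drop = FALSE]
  rownames(out) <- NULL
  out$duration_s <- (out$end_frame - out$start_frame) / seq$fps
  class(out) <- c("turn_segments", "data.frame")
  out
}

#' Extract the frames of a turn segment as a clip
#'
#' @param seq a `skeleton_sequence`.
#' @param segment one row of a `turn_segments` data.frame, or any list with
#'   `start_frame` and `end_frame` (0-based, half-open).
#' @return A `skeleton_sequence` with `end_frame - start_frame` frames and
#'   the same fps.
#' @export
extract_clip <- function(seq, segment) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  s <- segment$start_frame; e <- segment$end_frame
  T_ <- n_frames(seq)
  if (length(s) != 1L || length(e) != 1L || is.na(s) || is.na(e))
    tm_argument_error("segment must carry scalar start_frame/end_frame")
  if (s < 0 || e > T_ || e <= s + 1L)
    tm_index_error(sprintf("segment [%d, %d) out of range for %d frames", s, e, T_))
  idx <- (s + 1L):e
  skeleton_sequence(seq$coords[idx, , , drop = FALSE], fps = seq$fps,
                    joint_names = seq$joint_names,
                    valid_mask = seq$valid_mask[idx, , drop = FALSE])
}

#' Per-bin summary of turn estimates
#'
#' Tabulates curated turn clips by quantisation bin: count, min/max/mean
#' angle and mean duration per occupied bin, plus a total row (averages
#' weighted by count, i.e. pooled over all clips).
#'
#' @param theta_deg estimated (continuous) turning angles in degrees.
#' @param duration_s optional clip durations in seconds.
#' @param label_set,clamp passed to [quantize_to_bin()].
#' @return data.frame with columns `bin_deg` (`"total"` row last), `n`,
#'   `min_deg`, `max_deg`, `mean_deg` and (if durations given)
#'   `mean_duration_s`. Empty bins are omitted.
#' @export
bin_summary <- function(theta_deg, duration_s = NULL,
                        label_set = seq(45, 360, by = 45), clamp = TRUE) {
  if (length(theta_deg) == 0L) tm_argument_error("no estimates supplied")
  bins <- quantize_to_bin(theta_deg, label_set, clamp = clamp)
  keep <- !is.na(bins)
  bins <- bins[keep]; theta <- theta_deg[keep]
  dur <- if (!is.null(duration_s)) duration_s[keep] else NULL
  levs <- sort(unique(bins))
  row_for <- function(sel, label) {
    r <- data.frame(bin_deg = label, n = sum(sel),
                    min_deg = min(theta[sel]), max_deg = max(theta[sel]),
                    mean_deg = mean(theta[sel]), stringsAsFactors = FALSE)
    if (!is.null(dur)) r$mean_duration_s <- mean(dur[sel])
    r
  }
  out <- do.call(rbind, lapply(levs, function(b) row_for(bins == b, as.character(b))))
  out <- rbind(out, row_for(rep(TRUE, length(bins)), "total"))
  rownames(out) <- NULL
  out
}
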