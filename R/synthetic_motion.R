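# Synthetic articulated-turn generator: 17-joint skeleton sequences
# executing turns of known angle and velocity profile, with gait-like limb
# swing, coordinate noise, optional shoulder lag (axial dissociation) and
# occlusion masking. Stands in for video-derived pose data in all tests;
# every sequence carries its exact ground truth.

# fixture body geometry (arbitrary units; angles are scale-invariant)
BODY <- list(hip_width = 0.3, shoulder_width = 0.4,
             z = c(pelvis = 1.0, hip = 0.95, knee = 0.5, ankle = 0.05,
                   spine = 1.2, thorax = 1.4, neck = 1.55, head = 1.7,
                   shoulder = 1.45, elbow = 1.15, wrist = 0.9))

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Specify a synthetic turn
#'
#' Generative parameters for one simulated turning episode.
#'
#' @param total_angle_deg target net rotation in degrees (>= 0).
#' @param duration_s turn duration in seconds.
#' @param fps frames per second.
#' @param profile yaw-rate shape: `"constant"`, `"trapezoid"` (ramp 25% /
#'   plateau 50% / ramp 25%) or `"sigmoid"` (logistic yaw, bell-shaped rate).
#' @param direction `"ccw"` (positive yaw) or `"cw"`.
#' @param noise_sd i.i.d. Gaussian coordinate noise SD, as a fraction of hip
#'   width (0 = noise-free).
#' @param swing_amp_deg sinusoidal knee/ankle swing amplitude about the yaw,
#'   emulating gait oscillation (degrees).
#' @param swing_hz swing frequency.
#' @param shoulder_lag_s delay of the shoulder girdle behind the pelvis yaw;
#'   0 gives a perfectly rigid (en-bloc) torso, > 0 emulates axial
#'   dissociation.
#' @param occlusion_rate per-frame-per-joint masking probability in \[0, 1).
#' @param seed integer seed; all randomness flows from it.
#' @return A validated `synthetic_turn_spec`.
#' @export
synthetic_turn_spec <- function(total_angle_deg, duration_s = 1.5, fps = 30,
                                profile = c("constant", "trapezoid", "sigmoid"),
                                direction = c("ccw", "cw"),
                                noise_sd = 0, swing_amp_deg = 0, swing_hz = 1,
                                shoulder_lag_s = 0, occlusion_rate = 0,
                                seed = NULL) {
  profile <- match.arg(profile)
  direction <- match.arg(direction)
  if (!is.finite(total_angle_deg) || total_angle_deg < 0)
    tm_validation_error("`total_angle_deg` must be >= 0")
  if (!is.finite(duration_s) || duration_s <= 0)
    tm_validation_error("`duration_s` must be > 0")
  if (!is.finite(fps) || fps <= 0) tm_validation_error("`fps` must be > 0")
  if (noise_sd < 0) tm_validation_error("`noise_sd` must be >= 0")
  if (occlusion_rate < 0 || occlusion_rate >= 1)
    tm_validation_error("`occlusion_rate` must be in [0, 1)")
  if (shoulder_lag_s < 0) tm_validation_error("`shoulder_lag_s` must be >= 0")
  structure(list(total_angle_deg = total_angle_deg, duration_s = duration_s,
                 fps = fps, profile = profile, direction = direction,
                 noise_sd = noise_sd, swing_amp_deg = swing_amp_deg,
                 swing_hz = swing_hz, shoulder_lag_s = shoulder_lag_s,
                 occlusion_rate = occlusion_rate, seed = seed),
            class = "synthetic_turn_spec")
}

# normalised yaw shape g(s), g(0) = 0, g(1) = 1
yaw_shape <- function(s, profile) {
  switch(profile,
    constant = s,
    trapezoid = {
      # integral of trapezoidal rate (ramps over [0,.25] and [.75,1])
      G <- ifelse(s < 0.25, 2 * s^2,
           ifelse(s <= 0.75, 0.125 + (s - 0.25),
                  0.75 - 2 * (1 - s)^2))
      G / 0.75
    },
    sigmoid = {
      f <- function(x) stats::plogis((x - 0.5) / 0.08)
      (f(s) - f(0)) / (f(1) - f(0))
    })
}

# Place the 17-joint body along a pelvis-yaw series. yaw in degrees, length
# T; t_s the frame times. Swing modulates the knee/ankle yaw; the shoulder
# girdle (shoulders, elbows, wrists) follows yaw delayed by lag seconds.
body_from_yaw <- function(yaw_deg, t_s, swing_amp_deg = 0, swing_hz = 1,
                          shoulder_lag_s = 0) {
  T_ <- length(yaw_deg)
  yaw_sh <- if (shoulder_lag_s > 0 && T_ > 1)
    stats::approx(t_s, yaw_deg, xout = pmax(t_s - shoulder_lag_s, t_s[1]),
                  rule = 2)$y
  else yaw_deg
  yaw_knee <- yaw_deg + swing_amp_deg * sin(2 * pi * swing_hz * t_s)

  coords <- array(0, dim = c(T_, length(H36M_JOINTS), 3))
  dimnames(coords)[[2]] <- H36M_JOINTS
  uleft <- function(psi_deg) {
    r <- psi_deg * pi / 180
    cbind(-sin(r), cos(r))
  }
  place_pair <- function(left, right, psi_deg, half_width, z) {
    u <- uleft(psi_deg)
    coords[, left, 1:2] <<- u * half_width
    coords[, left, 3] <<- z
    coords[, right, 1:2] <<- -u * half_width
    coords[, right, 3] <<- z
  }
  hw <- BODY$hip_width / 2; sw <- BODY$shoulder_width / 2
  place_pair("left_hip", "right_hip", yaw_deg, hw, BODY$z[["hip"]])
  place_pair("left_knee", "right_knee", yaw_knee, hw, BODY$z[["knee"]])
  place_pair("left_ankle", "right_ankle", yaw_knee, hw, BODY$z[["ankle"]])
  place_pair("left_shoulder", "right_shoulder", yaw_sh, sw, BODY$z[["shoulder"]])
  place_pair("left_elbow", "right_elbow", yaw_sh, sw, BODY$z[["elbow"]])
  place_pair("left_wrist", "right_wrist", yaw_sh, sw, BODY$z[["wrist"]])
  for (j in c("pelvis", "spine", "thorax", "neck", "head"))
    coords[, j, 3] <- BODY$z[[j]]
  coords
}

add_noise_and_mask <- function(coords, noise_sd, occlusion_rate) {
  T_ <- dim(coords)[1]; J <- dim(coords)[2]
  if (noise_sd > 0)
    coords <- coords + stats::rnorm(length(coords),
                                    sd = noise_sd * BODY$hip_width)
  mask <- matrix(TRUE, T_, J)
  if (occlusion_rate > 0)
    mask <- matrix(stats::runif(T_ * J) >= occlusion_rate, T_, J)
  list(coords = coords, mask = mask)
}

ground_truth <- function(yaw_deg, fps, turn_intervals) {
  structure(list(
    yaw_deg_t = yaw_deg,
    total_angle_deg = abs(yaw_deg[length(yaw_deg)] - yaw_deg[1]),
    omega_deg_s = abs(yaw_deg[length(yaw_deg)] - yaw_deg[1]) /
      (length(yaw_deg) / fps),
    wmax_deg_s = if (length(yaw_deg) > 1) max(abs(diff(yaw_deg))) * fps else 0,
    turn_intervals = turn_intervals), class = "turn_ground_truth")
}

#' Simulate one turning clip
#'
#' Generates a 17-joint articulated body executing the specified turn:
#' pelvis fixed at the origin, hips/knees/ankles and the shoulder girdle
#' rotating with the yaw profile (knee chain modulated by gait swing, the
#' shoulder girdle optionally lagging), axial joints on the rotation axis,
#' plus Gaussian coordinate noise and random occlusion masking. Fully
#' reproducible from the spec's seed.
#'
#' @param spec a [synthetic_turn_spec()].
#' @return List with `seq` (a `skeleton_sequence`) and `truth` (a
#'   `turn_ground_truth` with per-frame pelvis yaw, total angle, mean and
#'   max angular velocity, and the injected turn interval).
#' @export
simulate_turn <- function(spec) {
  stopifnot(inherits(spec, "synthetic_turn_spec"))
  with_seed(spec$seed, {
    T_ <- max(2L, round(spec$duration_s * spec$fps))
    s <- seq(0, 1, length.out = T_)
    sign <- if (spec$direction == "ccw") 1 else -1
    yaw <- sign * spec$total_angle_deg * yaw_shape(s, spec$profile)
    t_s <- (seq_len(T_) - 1L) / spec$fps
    coords <- body_from_yaw(yaw, t_s, spec$swing_amp_deg, spec$swing_hz,
                            spec$shoulder_lag_s)
    nm <- add_noise_and_mask(coords, spec$noise_sd, spec$occlusion_rate)
    seq <- skeleton_sequence(nm$coords, fps = spec$fps,
                             joint_names = H36M_JOINTS, valid_mask = nm$mask)
    truth <- ground_truth(yaw, spec$fps,
                          data.frame(start_frame = 0L, end_frame = T_,
                                     angle_deg = sign * spec$total_angle_deg))
    list(seq = seq, truth = truth)
  })
}

#' Simulate a continuous stream with injected turns
#'
#' Concatenates static standing intervals and turning episodes into one
#' continuous skeleton stream, recording the frame span and signed angle of
#' every injected turn. Yaw persists across episodes. Noise, swing, lag and
#' occlusion are stream-level parameters so that idle and turning intervals
#' share the same observation model.
#'
#' @param turn_specs list of [synthetic_turn_spec()] (all with equal fps).
#' @param gap_s seconds of idle standing before each turn and after the
#'   last; scalar or vector of length `length(turn_specs) + 1`. Negative
#'   gaps (an overlapping schedule) are rejected.
#' @param noise_sd,swing_amp_deg,swing_hz,shoulder_lag_s,occlusion_rate as
#'   in [synthetic_turn_spec()], applied to the whole stream.
#' @param seed integer seed.
#' @return List with `seq` and `truth`; `truth$turn_intervals` has one row
#'   per injected turn (`start_frame`, `end_frame` half-open, `angle_deg`
#'   signed).
#' @export
simulate_stream <- function(turn_specs, gap_s = 3, noise_sd = 0,
                            swing_amp_deg = 0, swing_hz = 1,
                            shoulder_lag_s = 0, occlusion_rate = 0,
                            seed = NULL) {
  if (length(turn_specs) > 0) {
    stopifnot(all(vapply(turn_specs, inherits, TRUE, "synthetic_turn_spec")))
    fps <- turn_specs[[1]]$fps
    if (!all(vapply(turn_specs, `[[`, 1, "fps") == fps))
      tm_validation_error("all turn specs in a stream must share one fps")
  } else fps <- 30
  n <- length(turn_specs)
  gaps <- rep_len(gap_s, n + 1L)
  if (any(gaps < 0)) tm_validation_error("overlapping schedule: negative gap")

  yaw <- numeric(0)
  intervals <- list()
  cur <- 0
  for (i in seq_len(n + 1L)) {
    g_frames <- round(gaps[i] * fps)
    yaw <- c(yaw, rep(cur, g_frames))
    if (i <= n) {
      sp <- turn_specs[[i]]
      T_i <- max(2L, round(sp$duration_s * sp$fps))
      sgn <- if (sp$direction == "ccw") 1 else -1
      seg <- cur + sgn * sp$total_angle_deg * yaw_shape(seq(0, 1, length.out = T_i),
                                                        sp$profile)
      intervals[[i]] <- data.frame(start_frame = length(yaw),
                                   end_frame = length(yaw) + T_i,
                                   angle_deg = sgn * sp$total_angle_deg)
      yaw <- c(yaw, seg)
      cur <- seg[T_i]
    }
  }
  if (length(yaw) < 2L) yaw <- rep(0, 2L)
  with_seed(seed, {
    t_s <- (seq_along(yaw) - 1L) / fps
    coords <- body_from_yaw(yaw, t_s, swing_amp_deg, swing_hz, shoulder_lag_s)
    nm <- add_noise_and_mask(coords, noise_sd, occlusion_rate)
    seq <- skeleton_sequence(nm$coords, fps = fps, joint_names = H36M_JOINTS,
                             valid_mask = nm$mask)
    ti <- if (length(intervals)) do.call(rbind, intervals) else
      data.frame(start_frame = integer(), end_frame = integer(),
                 angle_deg = numeric())
    list(seq = seq, truth = ground_truth(yaw, fps, ti))
  })
}

#' Simulate a two-group turning cohort
#'
#' Draws per-subject mean turning characteristics from group-level normal
#' distributions (the between-subject layer), then individual turns around
#' each subject's mean (the within-subject layer), producing turn-level
#' estimate and annotation tables for group-comparison studies. Defaults
#' emulate a 12-versus-12 PD/control free-living cohort: PD turning angle
#' 92.65 +/- 13.21 degrees and max angular velocity 127.86 +/- 29.77 deg/s
#' against control 103.75 +/- 16.75 degrees and 160.19 +/- 36.49 deg/s.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param group_params named list (`PD`, `control`) of lists with
#'   `theta_mean`, `theta_sd`, `wmax_mean`, `wmax_sd`: between-subject
#'   distributions of the per-subject means.
#' @param turns_per_subject turns recorded per subject.
#' @param within_sd_theta,within_sd_wmax within-subject SDs of individual
#'   turns around the subject mean.
#' @param seed integer seed.
#' @return List with `turns` (clip_id, subject_id, group, theta_deg,
#'   wmax_deg_s), `annotations` (the matching annotation table) and `truth`
#'   (the generating group differences `delta_theta`, `delta_wmax`,
#'   PD minus control).
#' @export
simulate_cohort <- function(n_per_group = 12,
                            group_params = list(
                              PD = list(theta_mean = 92.65, theta_sd = 13.21,
                                        wmax_mean = 127.86, wmax_sd = 29.77),
                              control = list(theta_mean = 103.75, theta_sd = 16.75,
                                             wmax_mean = 160.19, wmax_sd = 36.49)),
                            turns_per_subject = 10,
                            within_sd_theta = 20, within_sd_wmax = 40,
                            seed = NULL) {
  if (n_per_group < 2L) tm_argument_error("need at least 2 subjects per group")
  for (g in group_params)
    if (g$theta_sd <= 0 || g$wmax_sd <= 0)
      tm_validation_error("group SDs must be positive")
  if (within_sd_theta < 0 || within_sd_wmax < 0)
    tm_validation_error("within-subject SDs must be >= 0")
  with_seed(seed, {
    rows <- list()
    for (gname in names(group_params)) {
      gp <- group_params[[gname]]
      for (i in seq_len(n_per_group)) {
        sid <- sprintf("%s_%02d", gname, i)
        mu_t <- stats::rnorm(1, gp$theta_mean, gp$theta_sd)
        mu_w <- stats::rnorm(1, gp$wmax_mean, gp$wmax_sd)
        th <- pmax(1, stats::rnorm(turns_per_subject, mu_t, within_sd_theta))
        wm <- pmax(1, stats::rnorm(turns_per_subject, mu_w, within_sd_wmax))
        rows[[sid]] <- data.frame(
          clip_id = sprintf("%s_t%03d", sid, seq_len(turns_per_subject)),
          subject_id = sid, group = gname,
          theta_deg = th, wmax_deg_s = wm, stringsAsFactors = FALSE)
      }
    }
    turns <- do.call(rbind, rows)
    rownames(turns) <- NULL
    ann <- data.frame(
      clip_id = turns$clip_id,
      label_deg = as.numeric(quantize_to_bin(turns$theta_deg,
                                             seq(45, 360, 45), clamp = TRUE)),
      start_s = 0, end_s = 2,
      subject_id = turns$subject_id, group = turns$group,
      scenario = "free_living", location = "home",
      stringsAsFactors = FALSE)
    truth <- list(
      delta_theta = group_params$PD$theta_mean - group_params$control$theta_mean,
      delta_wmax = group_params$PD$wmax_mean - group_params$control$wmax_mean)
    list(turns = turns, annotations = ann, truth = truth)
  })
}
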