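test_that("pair_vector is left minus right on the ground plane", {
  coords <- array(0, c(1, 17, 3))
  jn <- turnmetry::H36M_JOINTS
  coords[1, match("left_hip", jn), ] <- c(1, 2, 5)
  coords[1, match("right_hip", jn), ] <- c(0, 0, 5)
  # keep the other paired joints non-degenerate
  for (p in c("knee", "shoulder")) {
    coords[1, match(paste0("left_", p), jn), ] <- c(0, 0.2, 1)
    coords[1, match(paste0("right_", p), jn), ] <- c(0, -0.2, 1)
  }
  seq <- skeleton_sequence(coords, fps = 30)
  v <- pair_vector(seq, 0, "hip")
  expect_equal(as.vector(v), c(1, 2))
  expect_true(attr(v, "valid"))

  # translation invariance
  seq2 <- skeleton_sequence(coords + 10, fps = 30)
  expect_equal(as.vector(pair_vector(seq2, 0, "hip")), c(1, 2))

  # coincident joints flag as degenerate
  coords[1, match("left_hip", jn), ] <- coords[1, match("right_hip", jn), ]
  seq3 <- skeleton_sequence(coords, fps = 30)
  expect_false(attr(pair_vector(seq3, 0, "hip"), "valid"))

  expect_error(pair_vector(seq, 5, "hip"), class = "tm_index_error")
})

test_that("frame_increment matches hand geometry in both modes", {
  expect_equal(frame_increment(c(1, 0), c(0, 1)), 90)
  expect_equal(frame_increment(c(1, 0), c(2, 0)), 0)
  # rotations beyond 90 degrees alias under the arcsin-of-cross formula
  v100 <- c(cos(100 * pi / 180), sin(100 * pi / 180))
  expect_equal(frame_increment(c(1, 0), v100, "faithful"), 80, tolerance = 1e-12)
  expect_equal(frame_increment(c(1, 0), v100, "signed"), 100, tolerance = 1e-12)
  expect_equal(frame_increment(c(1, 0), c(0, -1), "signed"), -90)
  expect_error(frame_increment(c(0, 0), c(1, 0)), class = "tm_degenerate_error")
})

test_that("cumulative_angle recovers rigid rotations exactly", {
  seq <- rigid_sequence(seq(0, 100, by = 10), fps = 30)
  est <- cumulative_angle(seq, c("hip", "knee"))
  expect_equal(est$theta_deg, 100, tolerance = 1e-9)
  expect_equal(sum(est$increments_deg), est$theta_deg, tolerance = 1e-9)
  expect_length(est$increments_deg, 10L)

  static <- rigid_sequence(rep(15, 8), fps = 30)
  for (js in list("hip", "knee", c("hip", "knee", "shoulder")))
    expect_equal(cumulative_angle(static, js)$theta_deg, 0)

  expect_error(cumulative_angle(rigid_sequence(0, fps = 30)),
               class = "tm_insufficient_frames")
})

test_that("increments average across joint sets with equal weights", {
  # hip pair rotates 10 deg/step, knee pair stays fixed -> 5 deg/step average
  yaw <- seq(0, 100, by = 10)
  seq <- rigid_sequence(yaw, fps = 30)
  fixed <- rigid_sequence(rep(0, length(yaw)), fps = 30)
  jn <- seq$joint_names
  for (j in c("left_knee", "right_knee"))
    seq$coords[, match(j, jn), ] <- fixed$coords[, match(j, jn), ]
  est <- cumulative_angle(seq, c("hip", "knee"))
  expect_equal(est$theta_deg, 50, tolerance = 1e-9)
  expect_equal(cumulative_angle(seq, "hip")$theta_deg, 100, tolerance = 1e-9)
})

test_that("angular_speed is theta over duration", {
  expect_equal(angular_speed(180, 2), 90)
  expect_equal(angular_speed(0, 3), 0)
  expect_equal(angular_speed(45, 1.5), 30)
  expect_error(angular_speed(90, 0), class = "tm_argument_error")
})

test_that("max_angular_velocity converts the peak increment to deg/s", {
  expect_equal(max_angular_velocity(c(1, 3, 2), 30), 90)
  expect_equal(max_angular_velocity(5, 1), 5)
  # constant-rate limit: peak equals mean speed over (N-1)/fps
  inc <- rep(2, 9)
  expect_equal(max_angular_velocity(inc, 10), 20)
  expect_equal(max_angular_velocity(inc, 10),
               angular_speed(sum(inc), length(inc) / 10))
  expect_error(max_angular_velocity(numeric(0), 30),
               class = "tm_insufficient_frames")
})

test_that("quantisation maps angles to the nearest 45-degree bin", {
  expect_equal(as.numeric(quantize_to_bin(100, seq(90, 360, 45))), 90)
  expect_equal(as.numeric(quantize_to_bin(112.5)), 135)  # tie rounds half up
  expect_equal(as.numeric(quantize_to_bin(380)), 360)    # clamps above the top bin

  q <- quantize_to_bin(20, clamp = FALSE)
  expect_true(is.na(q))
  expect_true(attr(q, "sub_threshold"))
  q2 <- quantize_to_bin(20, clamp = TRUE)
  expect_equal(as.numeric(q2), 45)
  expect_true(attr(q2, "sub_threshold"))
})

test_that("theta, omega and w_max are invariant to translation, scaling and rotation", {
  set.seed(7)
  yaw <- cumsum(c(0, runif(30, 2, 8)))  # irregular turn
  base <- cumulative_angle(rigid_sequence(yaw, fps = 30))
  variants <- list(
    rigid_sequence(yaw, fps = 30, translate = c(10, 10, 10)),
    rigid_sequence(yaw, fps = 30, scale = 3.7),
    rigid_sequence(yaw + 123.4, fps = 30)  # global vertical-axis rotation
  )
  for (v in variants) {
    est <- cumulative_angle(v)
    expect_lt(abs(est$theta_deg - base$theta_deg), 1e-6)
    expect_lt(abs(est$omega_deg_s - base$omega_deg_s), 1e-6)
    expect_lt(abs(est$wmax_deg_s - base$wmax_deg_s), 1e-6)
  }
})

test_that("clip concatenation is additive and w_max bounds omega", {
  yaw1 <- seq(0, 40, by = 4)
  yaw2 <- seq(44, 80, by = 4)
  th1 <- cumulative_angle(rigid_sequence(yaw1, fps = 30))$theta_deg
  th2 <- cumulative_angle(rigid_sequence(yaw2, fps = 30))$theta_deg
  whole <- cumulative_angle(rigid_sequence(c(yaw1, yaw2), fps = 30))
  expect_equal(th1 + th2 + 4, whole$theta_deg, tolerance = 1e-9)  # +4 joins the clips
  expect_gte(whole$wmax_deg_s, whole$omega_deg_s)

  set.seed(3)
  for (i in 1:20) {
    est <- cumulative_angle(rigid_sequence(cumsum(runif(10, 0, 15)), fps = 30))
    expect_gte(est$wmax_deg_s, est$omega_deg_s)
    expect_equal(sum(est$increments_deg), est$theta_deg, tolerance = 1e-9)
  }
})

test_that("signed and faithful modes agree with the analytic rotation", {
  set.seed(21)
  for (i in 1:10) {
    steps <- runif(25, 0, 80)
    dir <- sample(c(-1, 1), 1)
    yaw <- cumsum(c(0, dir * steps))
    seqs <- rigid_sequence(yaw, fps = 30)
    expect_lt(abs(cumulative_angle(seqs, mode = "faithful")$theta_deg - sum(steps)), 1e-6)
    expect_lt(abs(cumulative_angle(seqs, mode = "signed")$theta_deg - dir * sum(steps)), 1e-6)
  }
})

test_that("expected unsigned theta on a static noisy skeleton grows with noise", {
  mean_theta <- vapply(c(0.005, 0.02, 0.08), function(sd) {
    th <- vapply(1:100, function(s) {
      sim <- simulate_turn(synthetic_turn_spec(0, duration_s = 1, fps = 30,
                                               noise_sd = sd, seed = s))
      cumulative_angle(sim$seq)$theta_deg
    }, numeric(1))
    mean(th)
  }, numeric(1))
  expect_true(all(diff(mean_theta) > 0))
})

test_that("masked frames are carried forward with a warning, not dropped", {
  seq <- rigid_sequence(seq(0, 50, by = 5), fps = 30)
  seq$valid_mask[4, match("left_hip", seq$joint_names)] <- FALSE
  expect_warning(est <- cumulative_angle(seq, "hip"), "carried forward")
  # the 5-degree step lost at the masked frame is recovered at the next one
  expect_equal(est$theta_deg, 50, tolerance = 1e-9)
  expect_equal(est$skipped_frames, 1L)
})
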