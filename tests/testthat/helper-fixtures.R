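# Fixture builders and brute-force oracles, independent of the package's
# own generator where they back a correctness check.

# Hand-placed 17-joint base pose (z-up, facing +x): paired joints offset
# along the left-right (y) axis, axial joints on the rotation axis.
rigid_base_pose <- function() {
  J <- turnmetry::H36M_JOINTS
  z <- c(pelvis = 1, right_hip = 0.95, right_knee = 0.5, right_ankle = 0.05,
         left_hip = 0.95, left_knee = 0.5, left_ankle = 0.05,
         spine = 1.2, thorax = 1.4, neck = 1.55, head = 1.7,
         left_shoulder = 1.45, left_elbow = 1.15, left_wrist = 0.9,
         right_shoulder = 1.45, right_elbow = 1.15, right_wrist = 0.9)
  y <- c(pelvis = 0, right_hip = -0.15, right_knee = -0.15, right_ankle = -0.15,
         left_hip = 0.15, left_knee = 0.15, left_ankle = 0.15,
         spine = 0, thorax = 0, neck = 0, head = 0,
         left_shoulder = 0.2, left_elbow = 0.22, left_wrist = 0.22,
         right_shoulder = -0.2, right_elbow = -0.22, right_wrist = -0.22)
  cbind(x = rep(0, length(J)), y = unname(y[J]), z = unname(z[J]))
}

# Rigid body rotated about the vertical axis by yaw_deg[t] at frame t.
rigid_sequence <- function(yaw_deg, fps = 30, translate = c(0, 0, 0), scale = 1) {
  base <- rigid_base_pose() * scale
  T_ <- length(yaw_deg)
  coords <- array(0, c(T_, nrow(base), 3))
  for (t in seq_len(T_)) {
    r <- yaw_deg[t] * pi / 180
    R <- matrix(c(cos(r), sin(r), -sin(r), cos(r)), 2)
    xy <- base[, 1:2] %*% t(R)
    coords[t, , 1] <- xy[, 1] + translate[1]
    coords[t, , 2] <- xy[, 2] + translate[2]
    coords[t, , 3] <- base[, 3] + translate[3]
  }
  turnmetry::skeleton_sequence(coords, fps = fps)
}

# Brute-force weighted precision: materialise every bin explicitly.
brute_wprec <- function(pred, lab, zero_support = "zero") {
  bins <- sort(unique(c(pred, lab)))
  total <- 0
  wsum <- 0
  for (b in bins) {
    support <- sum(lab == b)
    npred <- sum(pred == b)
    if (support == 0) next
    if (npred == 0) {
      if (zero_support == "zero") wsum <- wsum + support
      next
    }
    total <- total + support * sum(pred == b & lab == b) / npred
    wsum <- wsum + support
  }
  100 * total / wsum
}

# Brute-force Cohen's kappa from the full agreement table.
brute_kappa <- function(a, b) {
  levs <- sort(unique(c(a, b)))
  n <- length(a)
  po <- sum(a == b) / n
  pe <- 0
  for (l1 in levs) pe <- pe + (sum(a == l1) / n) * (sum(b == l1) / n)
  (po - pe) / (1 - pe)
}

write_skeleton_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}
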