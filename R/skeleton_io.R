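#' @keywords internal
"_PACKAGE"

#' Canonical 17-joint skeleton joint names
#'
#' Joint labels for the 17-keypoint skeleton convention used by common
#' video-based 3D pose estimators (the Human3.6M layout): pelvis, right leg,
#' left leg, spine/head chain, left arm, right arm.
#'
#' @format Character vector of length 17.
#' @export
H36M_JOINTS <- c(
  "pelvis",
  "right_hip", "right_knee", "right_ankle",
  "left_hip", "left_knee", "left_ankle",
  "spine", "thorax", "neck", "head",
  "left_shoulder", "left_elbow", "left_wrist",
  "right_shoulder", "right_elbow", "right_wrist"
)

# The six paired joints every convention must map: they define the frontal
# plane and hence the facing direction used by all angle computations.
CANONICAL_PAIRED_JOINTS <- c(
  "left_hip", "right_hip",
  "left_knee", "right_knee",
  "left_shoulder", "right_shoulder"
)

#' Define a joint-order convention
#'
#' A joint convention maps canonical joint labels to column indices of the
#' coordinate tensor, so skeletons exported with different joint orderings
#' can be remapped to a common layout.
#'
#' @param name identifier for the convention.
#' @param index_map named integer vector mapping joint labels to 1-based
#'   column indices; must be injective and must cover the six paired joints
#'   (left/right hip, knee, shoulder).
#' @return An object of class `joint_convention`.
#' @export
joint_convention <- function(name, index_map) {
  if (!is.character(name) || length(name) != 1L)
    tm_argument_error("`name` must be a single string")
  idx <- as.integer(index_map)
  names(idx) <- names(index_map)
  if (is.null(names(idx)) || anyNA(idx) || any(idx < 1L))
    tm_validation_error("`index_map` must be a named vector of positive indices")
  if (anyDuplicated(idx))
    tm_validation_error("`index_map` must be injective (duplicate indices found)")
  if (anyDuplicated(names(idx)))
    tm_validation_error("`index_map` has duplicated joint labels")
  missing <- setdiff(CANONICAL_PAIRED_JOINTS, names(idx))
  if (length(missing))
    tm_schema_error(paste0("convention is missing canonical joint(s): ",
                           paste(missing, collapse = ", ")))
  structure(list(name = name, index_map = idx), class = "joint_convention")
}

#' The default 17-joint convention
#'
#' @return A `joint_convention` covering all 17 joints of [H36M_JOINTS] in
#'   their canonical order.
#' @export
h36m_convention <- function() {
  joint_convention("h36m17", stats::setNames(seq_along(H36M_JOINTS), H36M_JOINTS))
}

#' Construct a 3D skeleton sequence
#'
#' The central container: a `T x J x 3` coordinate tensor with a frame rate,
#' joint labels and a per-frame-per-joint validity mask. Coordinates are
#' unit-agnostic (every downstream quantity is an angle, which is
#' scale-invariant). Internally the vertical axis is always the third
#' coordinate; `up_axis = "y"` inputs (common in mocap exports) are rotated
#' to z-up at construction by the cyclic, handedness-preserving axis
#' permutation (x, y, z) -> (z, x, y).
#'
#' @param coords numeric array `T x J x 3`.
#' @param fps frames per second, > 0.
#' @param joint_names character vector of length J; must contain exactly one
#'   each of the six paired joints. Defaults to [H36M_JOINTS].
#' @param up_axis which input axis is vertical, `"z"` (default) or `"y"`.
#' @param valid_mask optional `T x J` logical matrix, `TRUE` = usable joint.
#'   Non-finite coordinates are always masked in addition.
#' @return An object of class `skeleton_sequence` with elements `coords`
#'   (z-up), `fps`, `joint_names`, `up_axis` (always `"z"` after
#'   construction) and `valid_mask`.
#' @export
skeleton_sequence <- function(coords, fps, joint_names = H36M_JOINTS,
                              up_axis = c("z", "y"), valid_mask = NULL) {
  up_axis <- match.arg(up_axis)
  if (!is.array(coords) || length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    tm_validation_error("`coords` must be a T x J x 3 array")
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    tm_validation_error("`fps` must be a single positive number")
  J <- dim(coords)[2]
  if (length(joint_names) != J)
    tm_validation_error(sprintf("`joint_names` has length %d but coords has %d joints",
                                length(joint_names), J))
  for (j in CANONICAL_PAIRED_JOINTS) {
    k <- sum(joint_names == j)
    if (k != 1L)
      tm_schema_error(sprintf("joint_names must contain exactly one '%s' (found %d)", j, k))
  }
  if (up_axis == "y") {
    # (x, y, z) -> (z, x, y): vertical moves to slot 3, handedness preserved
    coords <- coords[, , c(3L, 1L, 2L), drop = FALSE]
  }
  T_ <- dim(coords)[1]
  finite_mask <- apply(is.finite(coords), c(1, 2), all)
  if (is.null(valid_mask)) {
    valid_mask <- finite_mask
  } else {
    if (!is.logical(valid_mask) || !identical(dim(valid_mask), c(T_, J)))
      tm_validation_error("`valid_mask` must be a T x J logical matrix")
    valid_mask <- valid_mask & finite_mask
  }
  coords[!is.finite(coords)] <- NA_real_
  structure(
    list(coords = coords, fps = as.numeric(fps),
         joint_names = as.character(joint_names),
         up_axis = "z", valid_mask = valid_mask),
    class = "skeleton_sequence"
  )
}

#' @export
print.skeleton_sequence <- function(x, ...) {
  cat(sprintf("<skeleton_sequence> %d frames x %d joints @ %g fps (%.2f s)\n",
              n_frames(x), length(x$joint_names), x$fps, n_frames(x) / x$fps))
  nm <- sum(!x$valid_mask)
  if (nm > 0) cat(sprintf("  %d masked joint-frames\n", nm))
  invisible(x)
}

#' Number of frames in a skeleton sequence
#' @param seq a `skeleton_sequence`.
#' @return Integer frame count T.
#' @export
n_frames <- function(seq) dim(seq$coords)[1]

joint_index <- function(seq, joint) {
  i <- match(joint, seq$joint_names)
  if (is.na(i)) tm_schema_error(paste0("sequence has no joint named '", joint, "'"))
  i
}

#' Reorder joints to a target convention
#'
#' A pure permutation of the joint axis: remapping to a convention and back
#' reproduces the original tensor exactly.
#'
#' @param seq a `skeleton_sequence`.
#' @param convention a [joint_convention] whose `index_map` covers every
#'   joint of `seq`.
#' @return A `skeleton_sequence` with joints in the convention's order.
#' @export
remap_convention <- function(seq, convention) {
  stopifnot(inherits(seq, "skeleton_sequence"), inherits(convention, "joint_convention"))
  im <- convention$index_map
  missing <- setdiff(seq$joint_names, names(im))
  if (length(missing))
    tm_schema_error(paste0("convention '", convention$name, "' does not map joint(s): ",
                           paste(missing, collapse = ", ")))
  # target column im[j] holds joint j
  perm <- integer(length(seq$joint_names))
  perm[im[seq$joint_names]] <- seq_along(seq$joint_names)
  out <- seq
  out$coords <- seq$coords[, perm, , drop = FALSE]
  out$valid_mask <- seq$valid_mask[, perm, drop = FALSE]
  out$joint_names <- seq$joint_names[perm]
  out
}

#' Read a skeleton sequence from long-form CSV
#'
#' Expects the documented schema: columns `frame,joint,x,y,z`, 0-based
#' non-decreasing frame indices, one row per joint per frame, UTF-8 with a
#' mandatory header. Empty or non-finite coordinate fields become masked
#' entries, never silent zeros. A JSON sidecar (same path with `.json`
#' extension) may supply `fps`, `convention` and `up_axis`; explicit
#' arguments take precedence.
#'
#' @param path CSV file path.
#' @param convention a [joint_convention]; every mapped joint must be
#'   present in the file. Default [h36m_convention()].
#' @param fps frames per second; required unless the sidecar supplies it.
#' @param up_axis `"z"` or `"y"`; default from sidecar, else `"z"`.
#' @return A validated `skeleton_sequence`.
#' @export
read_skeleton <- function(path, convention = h36m_convention(),
                          fps = NULL, up_axis = NULL) {
  if (!file.exists(path)) tm_io_error(paste0("file not found: ", path))
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    fps <- fps %||% meta$fps
    up_axis <- up_axis %||% meta$up_axis
  }
  if (is.null(fps))
    tm_argument_error("`fps` not given and no JSON sidecar found")
  up_axis <- up_axis %||% "z"

  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("integer", "character",
                                       "numeric", "numeric", "numeric"))
  want <- c("frame", "joint", "x", "y", "z")
  if (!identical(names(df), want))
    tm_format_error(paste0("expected header 'frame,joint,x,y,z', got '",
                           paste(names(df), collapse = ","), "'"))
  if (nrow(df) == 0L) tm_format_error("skeleton CSV has no data rows")
  if (is.unsorted(df$frame))
    tm_format_error("frame indices must be non-decreasing")

  joints <- names(convention$index_map)[order(convention$index_map)]
  missing <- setdiff(joints, unique(df$joint))
  if (length(missing))
    tm_schema_error(paste0("skeleton CSV is missing joint(s): ",
                           paste(missing, collapse = ", ")))
  unknown <- setdiff(unique(df$joint), joints)
  if (length(unknown))
    tm_schema_error(paste0("skeleton CSV has joint(s) not in convention '",
                           convention$name, "': ", paste(unknown, collapse = ", ")))

  frames <- sort(unique(df$frame))
  T_ <- length(frames)
  J <- length(joints)
  coords <- array(NA_real_, dim = c(T_, J, 3))
  ti <- match(df$frame, frames)
  ji <- match(df$joint, joints)
  coords[cbind(ti, ji, 1L)] <- df$x
  coords[cbind(ti, ji, 2L)] <- df$y
  coords[cbind(ti, ji, 3L)] <- df$z
  skeleton_sequence(coords, fps = fps, joint_names = joints, up_axis = up_axis)
}

#' Write a skeleton sequence to long-form CSV
#'
#' Emits the schema read by [read_skeleton()] (columns `frame,joint,x,y,z`)
#' plus a JSON sidecar with `fps`, `convention`, `up_axis` and `source`.
#' Masked joint-frames are written with empty coordinate fields.
#' `read_skeleton(write_skeleton(seq))` reproduces coordinates to full
#' double precision and masks exactly.
#'
#' @param seq a `skeleton_sequence`.
#' @param path output CSV path; the sidecar is written next to it.
#' @param source free-text provenance string for the sidecar.
#' @return `path`, invisibly.
#' @export
write_skeleton <- function(seq, path, source = "turnmetry") {
  stopifnot(inherits(seq, "skeleton_sequence"))
  T_ <- n_frames(seq); J <- length(seq$joint_names)
  df <- data.frame(
    frame = rep(0:(T_ - 1L), each = J),
    joint = rep(seq$joint_names, times = T_),
    x = as.vector(t(seq$coords[, , 1])),
    y = as.vector(t(seq$coords[, , 2])),
    z = as.vector(t(seq$coords[, , 3])),
    stringsAsFactors = FALSE
  )
  masked <- as.vector(t(!seq$valid_mask))
  df$x[masked] <- NA; df$y[masked] <- NA; df$z[masked] <- NA
  num <- function(v) ifelse(is.na(v), "", formatC(v, format = "g", digits = 17))
  lines <- c("frame,joint,x,y,z",
             paste(df$frame, df$joint, num(df$x), num(df$y), num(df$z), sep = ","))
  ok <- tryCatch({ writeLines(lines, path); TRUE }, error = function(e) FALSE,
                 warning = function(w) FALSE)
  if (!ok) tm_io_error(paste0("cannot write to ", path))
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(
    list(fps = seq$fps, convention = "h36m17", up_axis = seq$up_axis,
         source = source),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read turn annotations from CSV
#'
#' Reads clinician-style turn annotations with the documented header
#' `clip_id,label_deg,start_s,end_s,subject_id,group,scenario,location`.
#' Labels outside the configured label set are rejected, never silently
#' binned; `end_s` must exceed `start_s`.
#'
#' @param path CSV file path.
#' @param label_set permitted bin labels in degrees (multiples of 45).
#' @return A data.frame of validated annotations, zero rows for a
#'   header-only file.
#' @export
read_annotations <- function(path, label_set = seq(45, 360, by = 45)) {
  if (!file.exists(path)) tm_io_error(paste0("file not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  want <- c("clip_id", "label_deg", "start_s", "end_s",
            "subject_id", "group", "scenario", "location")
  if (!identical(names(df), want))
    tm_format_error(paste0("expected header '", paste(want, collapse = ","),
                           "', got '", paste(names(df), collapse = ","), "'"))
  if (nrow(df) == 0L) return(df)
  validate_annotations(df, label_set)
}

#' Validate a turn-annotation table
#'
#' @param df data.frame with the annotation columns (see
#'   [read_annotations()]).
#' @param label_set permitted bin labels in degrees.
#' @return `df`, invisibly validated (types coerced).
#' @export
validate_annotations <- function(df, label_set = seq(45, 360, by = 45)) {
  df$label_deg <- as.numeric(df$label_deg)
  bad <- !df$label_deg %in% label_set
  if (any(bad))
    tm_validation_error(paste0("label_deg outside the configured label set: ",
                               paste(unique(df$label_deg[bad]), collapse = ", ")))
  bad_t <- !(df$end_s > df$start_s)
  if (any(bad_t))
    tm_validation_error(paste0("end_s must exceed start_s (offending clip_id: ",
                               paste(df$clip_id[bad_t], collapse = ", "), ")"))
  ok_group <- c("PD", "control")
  if (!all(df$group %in% ok_group))
    tm_validation_error(paste0("group must be one of ", paste(ok_group, collapse = "/")))
  ok_scen <- c("scripted", "clinical", "free_living", "other")
  if (!all(df$scenario %in% ok_scen))
    tm_validation_error(paste0("scenario must be one of ", paste(ok_scen, collapse = "/")))
  df
}

#' Write turn annotations to CSV
#' @param df annotation data.frame (validated first).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(df, path) {
  validate_annotations(df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
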