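# Run configuration and the end-to-end estimation pipeline behind the
# command-line interface. Pose estimators (video -> skeleton) are an
# external plugin boundary: anything that produces the documented skeleton
# CSV plugs in ahead of this pipeline.

#' Build a run configuration
#'
#' Resolves a pipeline configuration from an optional YAML file plus
#' explicit overrides (overrides win). Every numeric output of
#' [run_pipeline()] carries the MD5 hash of the resolved configuration for
#' provenance.
#'
#' @param file optional YAML file with any of the fields below.
#' @param joints joint sets used for the angle estimate.
#' @param mode `"faithful"` or `"signed"`.
#' @param bins quantisation label set in degrees.
#' @param clamp clamp sub-threshold angles to the smallest bin?
#' @param threshold_deg,omega_start,omega_stop,max_gap_frames turn-detection
#'   thresholds (see [detect_turns()]).
#' @param up_axis vertical axis of input files.
#' @param fps frame-rate override for inputs lacking a sidecar.
#' @param seed integer seed for any stochastic step.
#' @param output_dir directory for result files.
#' @return A `run_config` list with a `hash` field.
#' @export
run_config <- function(file = NULL, joints = c("hip", "knee"),
                       mode = "faithful", bins = seq(45, 360, by = 45),
                       clamp = TRUE, threshold_deg = 45,
                       omega_start = 25, omega_stop = 10,
                       max_gap_frames = NULL, up_axis = "z", fps = NULL,
                       seed = NULL, output_dir = ".") {
  cfg <- list(joints = joints, mode = mode, bins = bins, clamp = clamp,
              threshold_deg = threshold_deg, omega_start = omega_start,
              omega_stop = omega_stop, max_gap_frames = max_gap_frames,
              up_axis = up_axis, fps = fps, seed = seed,
              output_dir = output_dir)
  if (!is.null(file)) {
    if (!file.exists(file)) tm_io_error(paste0("config file not found: ", file))
    fromfile <- yaml::read_yaml(file)
    bad <- setdiff(names(fromfile), names(cfg))
    if (length(bad))
      tm_validation_error(paste0("unknown config field(s): ", paste(bad, collapse = ", ")))
    # flags/arguments override the file only where explicitly supplied
    supplied <- names(as.list(match.call())[-1])
    supplied <- setdiff(supplied, "file")
    for (k in setdiff(names(fromfile), supplied)) cfg[[k]] <- fromfile[[k]]
  }
  cfg$mode <- match.arg(cfg$mode, c("faithful", "signed"))
  cfg$joints <- match.arg(cfg$joints, c("hip", "knee", "shoulder"),
                          several.ok = TRUE)
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "run_config")
}

# stable MD5 of the resolved analytic configuration: output paths are
# excluded so the hash identifies the analysis, not where it is written
config_hash <- function(cfg) {
  cfg$hash <- NULL
  cfg$output_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg[order(names(cfg))], tmp, auto_unbox = TRUE,
                       digits = NA, null = "null")
  unname(tools::md5sum(tmp))
}

#' Run the turning-angle pipeline over skeleton files
#'
#' For each input skeleton CSV: estimate the turn (cumulative angle, mean
#' and max angular velocity), quantise to a bin, and write
#' `<clip>_estimate.json` to the configured output directory; a combined
#' `estimates.csv` is written as well. With annotations, an evaluation
#' report CSV is produced; with subject/group annotations, the group
#' comparison JSONs too. Angles are serialised at 6 decimal places and
#' percentages at 1, and every output embeds the resolved config hash, so a
#' rerun with identical config, inputs and seed is byte-identical.
#'
#' @param config a [run_config()].
#' @param inputs character vector of skeleton CSV paths.
#' @param annotations optional annotation CSV path (see
#'   [read_annotations()]); clip_id must equal the input file stem.
#' @return Invisibly, a list with `estimates` (data.frame) and the written
#'   file paths.
#' @export
run_pipeline <- function(config, inputs, annotations = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (length(inputs) == 0L) tm_argument_error("no input files")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(x) round(x, 6)

  rows <- list(); files <- character()
  for (path in inputs) {
    clip <- tools::file_path_sans_ext(basename(path))
    seq <- read_skeleton(path, fps = config$fps, up_axis = config$up_axis)
    est <- cumulative_angle(seq, joint_sets = config$joints, mode = config$mode)
    bin <- as.numeric(quantize_to_bin(abs(est$theta_deg), config$bins,
                                      clamp = config$clamp))
    rec <- list(clip_id = clip,
                theta_deg = fmt(est$theta_deg),
                omega_deg_s = fmt(est$omega_deg_s),
                wmax_deg_s = fmt(est$wmax_deg_s),
                duration_s = fmt(est$duration_s),
                bin_deg = bin,
                joints = paste(config$joints, collapse = "+"),
                mode = config$mode,
                n_frames = est$n_frames,
                skipped_frames = est$skipped_frames,
                config_hash = config$hash)
    out <- file.path(config$output_dir, paste0(clip, "_estimate.json"))
    jsonlite::write_json(rec, out, auto_unbox = TRUE, digits = NA, null = "null")
    files <- c(files, out)
    rows[[clip]] <- as.data.frame(rec, stringsAsFactors = FALSE)
  }
  estimates <- do.call(rbind, rows)
  rownames(estimates) <- NULL
  est_csv <- file.path(config$output_dir, "estimates.csv")
  utils::write.csv(estimates, est_csv, row.names = FALSE, quote = FALSE)
  files <- c(files, est_csv)

  if (!is.null(annotations)) {
    ann <- read_annotations(annotations, label_set = config$bins)
    rep <- grouped_report(estimates, ann, group_by = "group",
                          label_set = config$bins, clamp = config$clamp)
    tab <- report_table(rep)
    tab$accuracy_pct <- round(tab$accuracy_pct, 1)
    tab$wprec_pct <- round(tab$wprec_pct, 1)
    tab$mae_deg <- fmt(tab$mae_deg)
    tab$config_hash <- config$hash
    eval_csv <- file.path(config$output_dir, "evaluation.csv")
    utils::write.csv(tab, eval_csv, row.names = FALSE, quote = FALSE)
    files <- c(files, eval_csv)
  }
  invisible(list(estimates = estimates, files = files))
}
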