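# Scoring predicted turning angles against clinician-style bin annotations:
# bin accuracy, MAE (continuous prediction vs discrete label, so up to 22.5
# degrees of label quantisation error is part of the metric by design),
# weighted precision, and Cohen's kappa for annotation QC.

check_paired <- function(a, b, what = "inputs") {
  if (length(a) == 0L || length(b) == 0L)
    tm_argument_error(paste0(what, " must be non-empty"))
  if (length(a) != length(b))
    tm_argument_error(sprintf("%s have different lengths (%d vs %d)",
                              what, length(a), length(b)))
}

#' Bin classification accuracy
#'
#' Percentage of predicted bins that match their annotated bins.
#'
#' @param pred_bins,label_bins equal-length vectors of bin labels (degrees).
#' @return Percent in \[0, 100\].
#' @export
bin_accuracy <- function(pred_bins, label_bins) {
  check_paired(pred_bins, label_bins, "pred/label bins")
  100 * mean(pred_bins == label_bins)
}

#' Mean absolute angle error
#'
#' Mean of |predicted - label| in degrees, comparing continuous
#' (unquantised) predictions against the discrete bin labels.
#'
#' @param pred_deg continuous predicted angles (degrees).
#' @param label_deg annotated bin labels (degrees).
#' @return MAE in degrees.
#' @export
mae_angle <- function(pred_deg, label_deg) {
  check_paired(pred_deg, label_deg, "pred/label angles")
  mean(abs(pred_deg - label_deg))
}

#' Mean absolute speed error
#'
#' @param pred_omega,true_omega paired angular speeds in deg/s.
#' @return MAE in deg/s.
#' @export
mae_speed <- function(pred_omega, true_omega) {
  check_paired(pred_omega, true_omega, "pred/true speeds")
  mean(abs(pred_omega - true_omega))
}

#' Confusion matrix over bin labels
#'
#' @param pred_bins,label_bins paired bin labels.
#' @param levels bin levels for the table axes; default the sorted union.
#' @return Integer matrix, rows = true labels, columns = predictions.
#' @export
bin_confusion <- function(pred_bins, label_bins, levels = NULL) {
  check_paired(pred_bins, label_bins, "pred/label bins")
  levels <- levels %||% sort(unique(c(pred_bins, label_bins)))
  table(true = factor(label_bins, levels = levels),
        pred = factor(pred_bins, levels = levels))
}

#' Weighted precision across bins
#'
#' Per-bin precision (true positives over all predictions of that bin),
#' combined with weights proportional to each bin's true-label count. For a
#' turn predicted as 90 degrees, this is the probability that the actual
#' turn is 90 degrees, averaged over bins by prevalence. Bins that carry
#' true labels but are never predicted contribute precision 0 with their
#' full weight by default (`zero_support = "zero"`, penalising missed bins);
#' `zero_support = "drop"` instead renormalises the weights over predicted
#' bins.
#'
#' @param pred_bins,label_bins paired bin labels.
#' @param zero_support `"zero"` (default) or `"drop"`; treatment of bins
#'   with true labels that receive no predictions.
#' @return Percent in \[0, 100\].
#' @export
weighted_precision <- function(pred_bins, label_bins,
                               zero_support = c("zero", "drop")) {
  zero_support <- match.arg(zero_support)
  cm <- bin_confusion(pred_bins, label_bins)
  support <- rowSums(cm)            # true-label counts per bin
  predicted <- colSums(cm)          # prediction counts per bin
  tp <- diag(cm)
  prec <- ifelse(predicted > 0, tp / predicted, 0)
  w <- support
  if (zero_support == "drop") w[predicted == 0] <- 0
  if (sum(w) == 0) return(NA_real_)
  100 * sum(w * prec) / sum(w)
}

#' Cohen's kappa for inter-rater agreement
#'
#' Chance-corrected agreement (p_o - p_e) / (1 - p_e) with expected
#' agreement p_e from the product of marginals, as used to check agreement
#' between two clinicians assigning turn bins. When both raters are constant
#' and identical (p_e = 1), kappa is defined as 1 by convention.
#'
#' @param rater_a,rater_b paired categorical ratings.
#' @return Kappa in \[-1, 1\].
#' @export
cohen_kappa <- function(rater_a, rater_b) {
  check_paired(rater_a, rater_b, "rater vectors")
  levels <- sort(unique(c(rater_a, rater_b)))
  cm <- table(factor(rater_a, levels = levels), factor(rater_b, levels = levels))
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (abs(1 - pe) < .Machine$double.eps * 4) return(if (po >= 1) 1 else NA_real_)
  (po - pe) / (1 - pe)
}

#' Evaluation report for a set of turn predictions
#'
#' Computes the three headline metrics (bin accuracy, angle MAE, weighted
#' precision), optionally the speed MAE, and the confusion matrix.
#'
#' @param pred_deg continuous predicted angles (degrees).
#' @param label_deg annotated bin labels (degrees).
#' @param label_set,clamp passed to [quantize_to_bin()].
#' @param pred_omega,true_omega optional paired angular speeds (deg/s).
#' @param group_key optional grouping label carried in the report.
#' @param zero_support passed to [weighted_precision()].
#' @return An `eval_report`: list with `accuracy_pct`, `mae_deg`,
#'   `wprec_pct`, `mae_omega_deg_s` (or `NA`), `confusion`, `n`, `group_key`.
#' @export
evaluate_turns <- function(pred_deg, label_deg,
                           label_set = seq(45, 360, by = 45), clamp = TRUE,
                           pred_omega = NULL, true_omega = NULL,
                           group_key = NULL, zero_support = "zero") {
  check_paired(pred_deg, label_deg, "pred/label angles")
  pred_bins <- as.numeric(quantize_to_bin(pred_deg, label_set, clamp = clamp))
  mae_o <- if (!is.null(pred_omega) && !is.null(true_omega))
    mae_speed(pred_omega, true_omega) else NA_real_
  structure(
    list(accuracy_pct = bin_accuracy(pred_bins, label_deg),
         mae_deg = mae_angle(pred_deg, label_deg),
         wprec_pct = weighted_precision(pred_bins, label_deg,
                                        zero_support = zero_support),
         mae_omega_deg_s = mae_o,
         confusion = bin_confusion(pred_bins, label_deg),
         n = length(pred_deg),
         group_key = group_key),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  hdr <- if (is.null(x$group_key)) "" else paste0(" [", x$group_key, "]")
  cat(sprintf("<eval_report>%s n = %d\n", hdr, x$n))
  cat(sprintf("  accuracy = %.1f%%, MAE = %.1f deg, WPrec = %.1f%%",
              x$accuracy_pct, x$mae_deg, x$wprec_pct))
  if (!is.na(x$mae_omega_deg_s))
    cat(sprintf(", speed MAE = %.1f deg/s", x$mae_omega_deg_s))
  cat("\n")
  invisible(x)
}

#' Grouped evaluation report
#'
#' Joins estimates to annotations on `clip_id`, evaluates within each level
#' of the grouping variable, and appends two summary rows: `"Avg."`, the
#' unweighted mean of the per-group metrics (the across-group average used
#' in grouped result tables), and `"Overall"`, the pooled evaluation over
#' all samples (these differ whenever group sizes differ).
#'
#' @param estimates data.frame with `clip_id`, `theta_deg`, optionally
#'   `omega_deg_s`.
#' @param annotations data.frame with `clip_id`, `label_deg` and the
#'   grouping columns (see [read_annotations()]), optionally `omega_deg_s`
#'   ground truth named `true_omega_deg_s`.
#' @param group_by one of `"scenario"`, `"location"`, `"group"`,
#'   `"subject_id"`, `"label_bin"` (groups by the annotated bin).
#' @param label_set,clamp,zero_support passed to [evaluate_turns()].
#' @return Named list of `eval_report` objects: one per group value plus
#'   `"Avg."` and `"Overall"`. Use [report_table()] to flatten.
#' @export
grouped_report <- function(estimates, annotations,
                           group_by = c("scenario", "location", "group",
                                        "subject_id", "label_bin"),
                           label_set = seq(45, 360, by = 45), clamp = TRUE,
                           zero_support = "zero") {
  group_by <- match.arg(group_by)
  unmatched <- setdiff(estimates$clip_id, annotations$clip_id)
  if (length(unmatched))
    tm_join_error(paste0("estimates with no matching annotation: ",
                         paste(unmatched, collapse = ", ")))
  df <- merge(estimates, annotations, by = "clip_id")
  df$.group <- if (group_by == "label_bin") as.character(df$label_deg)
               else as.character(df[[group_by]])
  has_omega <- all(c("omega_deg_s", "true_omega_deg_s") %in% names(df))

  eval_rows <- function(rows, key) {
    evaluate_turns(rows$theta_deg, rows$label_deg,
                   label_set = label_set, clamp = clamp,
                   pred_omega = if (has_omega) rows$omega_deg_s,
                   true_omega = if (has_omega) rows$true_omega_deg_s,
                   group_key = key, zero_support = zero_support)
  }
  keys <- sort(unique(df$.group))
  reports <- lapply(keys, function(k) eval_rows(df[df$.group == k, ], k))
  names(reports) <- keys

  avg <- structure(list(
    accuracy_pct = mean(vapply(reports, `[[`, 1, "accuracy_pct")),
    mae_deg = mean(vapply(reports, `[[`, 1, "mae_deg")),
    wprec_pct = mean(vapply(reports, `[[`, 1, "wprec_pct")),
    mae_omega_deg_s = mean(vapply(reports, `[[`, 1, "mae_omega_deg_s")),
    confusion = NULL, n = nrow(df), group_key = "Avg."), class = "eval_report")
  overall <- eval_rows(df, "Overall")
  c(reports, list("Avg." = avg, "Overall" = overall))
}

#' Flatten a list of evaluation reports to a data.frame
#'
#' @param reports list of `eval_report` objects (e.g. from
#'   [grouped_report()]).
#' @return data.frame with one row per report.
#' @export
report_table <- function(reports) {
  if (inherits(reports, "eval_report")) reports <- list(reports)
  do.call(rbind, lapply(reports, function(r) data.frame(
    group = r$group_key %||% "", n = r$n,
    accuracy_pct = r$accuracy_pct, mae_deg = r$mae_deg,
    wprec_pct = r$wprec_pct, mae_omega_deg_s = r$mae_omega_deg_s,
    stringsAsFactors = FALSE)))
}
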