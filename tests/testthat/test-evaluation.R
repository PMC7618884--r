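test_that("bin accuracy is the percentage of matching bins", {
  expect_equal(bin_accuracy(c(90, 135), c(90, 135)), 100)
  expect_equal(bin_accuracy(c(90, 135, 135), c(90, 90, 135)), 100 * 2 / 3)
  expect_equal(bin_accuracy(c(45, 45), c(90, 135)), 0)
  expect_error(bin_accuracy(90, c(90, 135)), class = "tm_argument_error")
})

test_that("angle MAE compares continuous predictions to discrete labels", {
  expect_equal(mae_angle(c(100, 130), c(90, 135)), 7.5)
  expect_equal(mae_angle(c(90, 180), c(90, 180)), 0)
  expect_equal(mae_angle(70, 90), 20)
  expect_equal(mae_angle(c(130, 100), c(135, 90)), 7.5)  # pair-order invariant
  # predictions at exact bin centres: MAE = 45 x mean bin distance
  labels <- c(90, 90, 135, 180)
  preds <- c(90, 135, 225, 180)
  expect_equal(mae_angle(preds, labels),
               45 * mean(abs(preds - labels) / 45))
})

test_that("speed MAE is the mean absolute difference", {
  expect_equal(mae_speed(c(10, 20), c(12, 16)), 3)
  expect_equal(mae_speed(c(5, 5), c(5, 5)), 0)
  expect_equal(mae_speed(12, 30), 18)
})

test_that("weighted precision follows the worked confusion-table examples", {
  expect_equal(weighted_precision(c(90, 135), c(90, 135)), 100)
  # precision(90)=1 with weight 2/3, precision(135)=1/2 with weight 1/3
  expect_equal(weighted_precision(c(90, 135, 135), c(90, 90, 135)), 100 * 5 / 6)
  # all predictions in one bin, labels uniform over two: the never-predicted
  # bin contributes 0 with full weight by default, or is dropped on request
  expect_equal(weighted_precision(c(90, 90), c(90, 135), zero_support = "zero"), 25)
  expect_equal(weighted_precision(c(90, 90), c(90, 135), zero_support = "drop"), 50)
})

test_that("weighted precision equals the brute-force confusion enumeration", {
  set.seed(101)
  bins <- seq(45, 360, 45)
  for (i in 1:200) {
    n <- sample(3:40, 1)
    lab <- sample(bins, n, replace = TRUE)
    pred <- sample(bins, n, replace = TRUE)
    expect_equal(weighted_precision(pred, lab), brute_wprec(pred, lab))
    expect_equal(weighted_precision(pred, lab, "drop"),
                 brute_wprec(pred, lab, "drop"))
  }
})

test_that("accuracy equals the confusion-matrix trace over n", {
  set.seed(5)
  bins <- seq(45, 360, 45)
  lab <- sample(bins, 60, replace = TRUE)
  pred <- sample(bins, 60, replace = TRUE)
  cm <- bin_confusion(pred, lab)
  expect_equal(bin_accuracy(pred, lab), 100 * sum(diag(cm)) / sum(cm))
  expect_equal(sum(cm), 60)
  expect_lte(bin_accuracy(pred, lab), 100)
  # permutation invariance of all metrics
  p <- sample(60)
  expect_equal(bin_accuracy(pred[p], lab[p]), bin_accuracy(pred, lab))
  expect_equal(mae_angle(pred[p], lab[p]), mae_angle(pred, lab))
  expect_equal(weighted_precision(pred[p], lab[p]), weighted_precision(pred, lab))
})

test_that("Cohen's kappa matches hand computations and conventions", {
  expect_equal(cohen_kappa(c(90, 135, 90, 180), c(90, 135, 90, 180)), 1)
  # 4 ratings: p_o = 0.75, p_e = 5/16 -> kappa = 7/11
  expect_equal(cohen_kappa(c(90, 90, 135, 180), c(90, 135, 135, 180)), 7 / 11)
  expect_equal(round(cohen_kappa(c(90, 90, 135, 180), c(90, 135, 135, 180)), 3),
               0.636)
  # independent raters with balanced marginals: kappa near 0
  set.seed(8)
  a <- sample(c(90, 180), 4000, replace = TRUE)
  b <- sample(c(90, 180), 4000, replace = TRUE)
  expect_lt(abs(cohen_kappa(a, b)), 0.05)
  # constant identical raters: defined as 1 by convention
  expect_equal(cohen_kappa(rep(90, 5), rep(90, 5)), 1)
  # brute-force equivalence
  set.seed(9)
  for (i in 1:100) {
    x <- sample(seq(45, 225, 45), 30, replace = TRUE)
    y <- sample(seq(45, 225, 45), 30, replace = TRUE)
    expect_equal(cohen_kappa(x, y), brute_kappa(x, y))
  }
})

make_eval_tables <- function() {
  ann <- data.frame(
    clip_id = sprintf("c%d", 1:6),
    label_deg = c(90, 90, 135, 180, 90, 135),
    start_s = 0, end_s = 2,
    subject_id = c("s1", "s1", "s1", "s2", "s2", "s2"),
    group = c("PD", "PD", "PD", "control", "control", "control"),
    scenario = "free_living", location = "kitchen",
    stringsAsFactors = FALSE)
  est <- data.frame(
    clip_id = sprintf("c%d", 1:6),
    theta_deg = c(95, 120, 130, 185, 100, 85),
    stringsAsFactors = FALSE)
  list(ann = ann, est = est)
}

test_that("grouped reports carry per-group metrics plus Avg. and Overall rows", {
  tabs <- make_eval_tables()
  reps <- grouped_report(tabs$est, tabs$ann, group_by = "group")
  expect_setequal(names(reps), c("control", "PD", "Avg.", "Overall"))
  pd <- evaluate_turns(tabs$est$theta_deg[1:3], tabs$ann$label_deg[1:3])
  expect_equal(reps$PD$accuracy_pct, pd$accuracy_pct)
  expect_equal(reps$PD$mae_deg, pd$mae_deg)
  # Avg. is the unweighted mean across groups
  expect_equal(reps$`Avg.`$accuracy_pct,
               mean(c(reps$PD$accuracy_pct, reps$control$accuracy_pct)))
  # Overall pools all samples
  all_eval <- evaluate_turns(tabs$est$theta_deg, tabs$ann$label_deg)
  expect_equal(reps$Overall$accuracy_pct, all_eval$accuracy_pct)
  expect_equal(reps$Overall$n, 6L)

  # a single group reduces to the ungrouped report
  one <- grouped_report(tabs$est, tabs$ann, group_by = "scenario")
  expect_equal(one$free_living$accuracy_pct, all_eval$accuracy_pct)

  tab <- report_table(reps)
  expect_equal(nrow(tab), 4L)
  expect_setequal(tab$group, c("control", "PD", "Avg.", "Overall"))
})

test_that("two groups with accuracies 40 and 60 average to 50", {
  ann <- data.frame(
    clip_id = sprintf("c%d", 1:10),
    label_deg = rep(90, 10), start_s = 0, end_s = 1,
    subject_id = "s", group = rep(c("PD", "control"), each = 5),
    scenario = "free_living", location = "hall", stringsAsFactors = FALSE)
  # PD: 2/5 correct; control: 3/5 correct
  est <- data.frame(clip_id = ann$clip_id,
                    theta_deg = c(90, 90, 180, 180, 180, 90, 90, 90, 180, 180))
  reps <- grouped_report(est, ann, group_by = "group")
  expect_equal(reps$PD$accuracy_pct, 40)
  expect_equal(reps$control$accuracy_pct, 60)
  expect_equal(reps$`Avg.`$accuracy_pct, 50)
})

test_that("estimates without matching annotations raise a join error", {
  tabs <- make_eval_tables()
  tabs$est$clip_id[2] <- "orphan"
  expect_error(grouped_report(tabs$est, tabs$ann, group_by = "group"),
               "orphan", class = "tm_join_error")
})
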