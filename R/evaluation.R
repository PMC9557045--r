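# Ground-truth-best determination and accuracy analyses: exact and +/-1
# chart-ordinal agreement, fit of predicted vs best-possible sizes on the
# ground-truth geometry, clinical overhang threshold proportions, and rank
# correlation of correctness with age.

#' Ground-truth best sizes for a subject
#'
#' Runs the identical per-size fitting and selection on the subject's
#' ground-truth geometry; the best size per metric is the one with the
#' lowest error when fitted to the true anatomy (same downsize tie-break
#' as the predictions).
#'
#' @inheritParams predict_sizes
#' @return A `size_prediction` evaluated on the ground-truth meshes.
#' @export
ground_truth_best <- function(femur = NULL, tibia = NULL,
                              charts = load_size_charts(),
                              downsize_tiebreak_tol = 0.05) {
  predict_sizes(femur = femur, tibia = tibia, charts = charts,
                downsize_tiebreak_tol = downsize_tiebreak_tol)
}

metric_at_size <- function(pred_model, size_id, metric) {
  for (f in pred_model$all_fits) if (f$size_id == size_id) return(f[[metric]])
  NA_real_
}

ordinal_of <- function(pred_model, size_id) {
  for (f in pred_model$all_fits) if (f$size_id == size_id) return(f$ordinal)
  NA_integer_
}

#' Score size predictions against ground-truth bests
#'
#' For aligned lists of predictions (on reconstructed anatomy) and
#' ground-truth evaluations (on true anatomy), computes per model and
#' component: exact and +/-1 chart-ordinal accuracy for both metrics, the
#' mean RMSE and mean maximum over/underhang attained on the ground-truth
#' geometry by the ground-truth best and by the predicted sizes, and the
#' proportion of subjects below the clinically significant 3 mm maximum
#' overhang threshold under each. Also reports Spearman rank correlation
#' (midrank ties) of per-subject correctness against age, and accuracy
#' stratified by sex.
#'
#' @param preds list of `size_prediction` (tool predictions).
#' @param gts list of `size_prediction` evaluated on ground truth
#'   ([ground_truth_best()]), aligned with `preds`.
#' @param subjects data frame (or list of `synthetic_subject`) with `age`
#'   and `sex` per subject, aligned with `preds`.
#' @param ouh_threshold clinical overhang threshold in mm (default 3).
#' @return An `evaluation_report` with elements `by_model` (data frame),
#'   `spearman`, `by_sex`, `overall`.
#' @export
score_predictions <- function(preds, gts, subjects, ouh_threshold = 3) {
  if (length(preds) != length(gts))
    stop("preds and gts must have the same length")
  if (inherits(subjects, "data.frame")) {
    subj <- subjects
  } else {
    subj <- data.frame(age = vapply(subjects, `[[`, 0, "age"),
                       sex = vapply(subjects, `[[`, "", "sex"))
  }
  if (nrow(subj) != length(preds)) stop("subject list mismatch")

  keys <- names(preds[[1]]$models)
  rows <- list()
  for (key in keys) {
    for (s in seq_along(preds)) {
      pm <- preds[[s]]$models[[key]]
      gm <- gts[[s]]$models[[key]]
      if (is.null(pm) || is.null(gm)) stop("subject ", s, " lacks chart ", key)
      for (metric in c("rmse", "max_ouh")) {
        bfield <- if (metric == "rmse") "best_by_rmse" else "best_by_ouh"
        po <- ordinal_of(gm, pm[[bfield]])
        go <- ordinal_of(gm, gm[[bfield]])
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, manufacturer = pm$manufacturer, model = pm$model,
          component = pm$component, metric = metric,
          pred = pm[[bfield]], gt = gm[[bfield]],
          dord = po - go,
          gt_val = metric_at_size(gm, gm[[bfield]], metric),
          pred_val = metric_at_size(gm, pm[[bfield]], metric),
          gt_ouh = metric_at_size(gm, gm$best_by_ouh, "max_ouh"),
          pred_ouh = metric_at_size(gm, pm$best_by_ouh, "max_ouh"),
          age = subj$age[s], sex = subj$sex[s])
      }
    }
  }
  long <- do.call(rbind, rows)
  long$correct <- long$dord == 0L
  long$pm1 <- abs(long$dord) <= 1L

  agg <- function(d) {
    data.frame(
      manufacturer = d$manufacturer[1], model = d$model[1],
      component = d$component[1], n_sizes = NA_integer_,
      rmse_correct_pct = 100 * mean(d$correct[d$metric == "rmse"]),
      rmse_pm1_pct = 100 * mean(d$pm1[d$metric == "rmse"]),
      ouh_correct_pct = 100 * mean(d$correct[d$metric == "max_ouh"]),
      ouh_pm1_pct = 100 * mean(d$pm1[d$metric == "max_ouh"]),
      mean_gt_best_rmse = mean(d$gt_val[d$metric == "rmse"]),
      mean_pred_rmse = mean(d$pred_val[d$metric == "rmse"]),
      mean_gt_best_ouh = mean(d$gt_val[d$metric == "max_ouh"]),
      mean_pred_ouh = mean(d$pred_val[d$metric == "max_ouh"]),
      pct_under_3mm_gt = 100 * mean(d$gt_ouh[d$metric == "max_ouh"] <
                                      ouh_threshold),
      pct_under_3mm_pred = 100 * mean(d$pred_ouh[d$metric == "max_ouh"] <
                                        ouh_threshold))
  }
  split_key <- paste(long$manufacturer, long$component)
  by_model <- do.call(rbind, lapply(split(long, split_key), agg))
  rownames(by_model) <- NULL

  spearman <- do.call(rbind, lapply(
    split(long, paste(long$component, long$metric)), function(d)
      data.frame(component = d$component[1], metric = d$metric[1],
                 rho = suppressWarnings(
                   stats::cor(as.numeric(d$correct), d$age,
                              method = "spearman")))))
  rownames(spearman) <- NULL

  by_sex <- do.call(rbind, lapply(
    split(long, paste(long$component, long$metric, long$sex)), function(d)
      data.frame(component = d$component[1], metric = d$metric[1],
                 sex = d$sex[1], accuracy_pct = 100 * mean(d$correct),
                 n = length(unique(d$subject)))))
  rownames(by_sex) <- NULL

  overall <- vapply(split(long, paste(long$component, long$metric)),
                    function(d) c(accuracy_pct = 100 * mean(d$correct),
                                  pm1_pct = 100 * mean(d$pm1)),
                    numeric(2))
  structure(list(by_model = by_model, spearman = spearman, by_sex = by_sex,
                 overall = t(overall), long = long,
                 n_subjects = length(preds)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation over %d subjects\n\n", x$n_subjects))
  cat("Per-model accuracy and fit (on ground-truth geometry):\n")
  print(x$by_model, row.names = FALSE, digits = 4)
  cat("\nOverall accuracy (%):\n")
  print(round(x$overall, 2))
  cat("\nSpearman rho, correctness vs age:\n")
  print(x$spearman, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write an evaluation report as CSV and JSON
#'
#' @param report an `evaluation_report`.
#' @param csv_path,json_path output paths (`NULL` to skip either).
#' @return Invisibly, the report.
#' @export
write_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    atomic_write(csv_path, function(tmp)
      utils::write.csv(report$by_model, tmp, row.names = FALSE))
  }
  if (!is.null(json_path)) {
    atomic_write(json_path, function(tmp)
      jsonlite::write_json(list(by_model = report$by_model,
                                overall = as.data.frame(report$overall),
                                spearman = report$spearman,
                                by_sex = report$by_sex,
                                n_subjects = report$n_subjects),
                           tmp, auto_unbox = TRUE, digits = NA))
  }
  invisible(report)
}
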