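#' Pixel-level segmentation metrics
#'
#' Confusion counts and the five derived fractions: sensitivity
#' `tp/(tp+fn)`, specificity `tn/(tn+fp)`, precision `tp/(tp+fp)`, negative
#' predictive value `tn/(tn+fn)` and accuracy `(tp+tn)/total`. A metric with
#' a zero denominator is reported as `NA` (undefined) — never silently 0
#' or 1.
#'
#' @param pred,truth logical matrices of equal shape.
#' @return an `eval_report` list with counts and metrics.
#' @export
pixel_metrics <- function(pred, truth) {
  pred <- as_mask(pred); truth <- as_mask(truth)
  if (!all(dim(pred) == dim(truth)))
    stop("prediction and truth shapes differ")
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  fn <- sum(!pred & truth); tn <- sum(!pred & !truth)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    precision = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn),
    accuracy = ratio(tp + tn, tp + tn + fp + fn),
    n_objects_pred = NA_integer_, n_objects_truth = NA_integer_),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  cat(sprintf("  tp %d  fp %d  tn %d  fn %d\n", x$tp, x$fp, x$tn, x$fn))
  for (m in c("sensitivity", "specificity", "precision", "npv", "accuracy"))
    cat(sprintf("  %-12s %s\n", m,
                ifelse(is.na(x[[m]]), "undefined", sprintf("%.4f", x[[m]]))))
  if (!is.na(x$n_objects_pred))
    cat(sprintf("  objects: %d detected / %d truth\n",
                x$n_objects_pred, x$n_objects_truth))
  invisible(x)
}

#' Count labelled objects
#'
#' @param labels integer label matrix.
#' @return number of distinct non-zero labels.
#' @export
count_objects <- function(labels) {
  length(unique(labels[labels > 0L]))
}

#' Run the pipeline on a mock scene and score it against the ground truth
#'
#' Executes preprocessing plus the stage-1 segmentation (`stage =
#' "initial"`), the full two-stage pipeline (`stage = "full"`), or both from
#' one shared preprocessing pass (`stage = "both"`), then compares the
#' predicted foreground (`labels > 0`) with `scene$truth_mask`.
#'
#' @param scene a [mock_scene()].
#' @param stage `"initial"`, `"full"` or `"both"`.
#' @param config a [pipeline_config()] list.
#' @return an `eval_report` (for `"both"`: list with elements `initial` and
#'   `full`). The label matrix is attached as attribute `"labels"`.
#' @export
evaluate_run <- function(scene, stage = c("initial", "full", "both"),
                         config = pipeline_config()) {
  stage <- match.arg(stage)
  filtered <- preprocess_image(scene$image, config$filter,
                               probability_map_mode = config$probability_map_mode)
  lab1 <- initial_segment(filtered, config$watershed, config$cleanup,
                          dark_foreground = config$dark_foreground)
  score <- function(lab) {
    rep <- pixel_metrics(lab > 0L, scene$truth_mask)
    rep$n_objects_pred <- count_objects(lab)
    rep$n_objects_truth <- count_objects(scene$truth_labels)
    attr(rep, "labels") <- lab
    rep
  }
  if (stage == "initial") return(score(lab1))
  ref <- process_all_cells(lab1, filtered, config$refine)
  if (stage == "full") return(score(ref$labels))
  list(initial = score(lab1), full = score(ref$labels))
}

#' Evaluation sweep over smoothing radii and noise levels
#'
#' Generates one mock scene per combination of `smoothing_radii` and
#' `noise_sds` (all other generator settings from `base_params`) and scores
#' the requested stage(s), covering the standard smoothing x noise evaluation grid.
#'
#' @param stage `"initial"`, `"full"` or `"both"`.
#' @param smoothing_radii,noise_sds condition grids.
#' @param base_params a [mock_params()] list (seed included).
#' @param config a [pipeline_config()] list.
#' @return data frame: one row per stage x condition with the five metrics
#'   and object counts.
#' @export
mock_sweep <- function(stage = "both", smoothing_radii = c(3, 5),
                       noise_sds = c(6, 15, 30),
                       base_params = mock_params(),
                       config = pipeline_config()) {
  rows <- list()
  for (rad in smoothing_radii) {
    # layout is shared across noise levels of one radius: same seed
    for (sd in noise_sds) {
      p <- base_params
      p$smoothing_radius <- rad
      p$noise_sd <- sd
      scene <- mock_scene(p)
      res <- evaluate_run(scene, stage, config)
      reports <- if (identical(stage, "both")) res else
        stats::setNames(list(res), stage)
      for (nm in names(reports)) {
        r <- reports[[nm]]
        rows[[length(rows) + 1L]] <- data.frame(
          stage = nm, smoothing_radius = rad, noise_sd = sd,
          sensitivity = r$sensitivity, specificity = r$specificity,
          precision = r$precision, npv = r$npv, accuracy = r$accuracy,
          n_objects_pred = r$n_objects_pred,
          n_objects_truth = r$n_objects_truth,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
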