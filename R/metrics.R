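#' Binarize a likelihood volume
#'
#' A voxel becomes foreground iff its likelihood is greater than or equal to
#' the threshold (ties go to foreground).
#'
#' @param p likelihood volume or numeric array.
#' @param threshold scalar in (0, 1); default 0.5.
#' @return A [binary_volume()].
#' @export
binarize <- function(p, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  vals <- as.array(p)
  binary_volume(array(as.integer(vals >= threshold), dim(vals)), spacing(p))
}

#' Tree length detected rate
#'
#' The fraction of ground-truth skeleton voxels covered by the binarized
#' prediction: `sum(s * pred) / sum(s)` over voxels, where `s` is the
#' skeleton ground truth. A centerline-based measure of how much of the
#' tree's length the prediction recovers.
#'
#' @param skel_gt skeleton ground-truth volume (binary).
#' @param pred binarized prediction volume.
#' @return Scalar in `[0, 1]`.
#' @export
tree_length_rate <- function(skel_gt, pred) {
  s <- as.array(skel_gt); p <- as.array(pred)
  check_same_geometry(s, p, "skeleton and prediction")
  ns <- sum(s)
  if (ns == 0) stop("tree_length_rate: empty skeleton ground truth")
  sum(s * p) / ns
}

#' Branch detection rate
#'
#' For each ground-truth skeleton branch, the covered fraction
#' `sum(pred at branch voxels) / n_branch_voxels` is computed; with the
#' default `coverage = 1` the floor of that fraction is taken, so a branch
#' counts as detected only when every one of its voxels is predicted
#' foreground (the strict rule). `coverage < 1` relaxes detection to
#' "covered fraction >= coverage" (0.8 is common practice). The rate is the
#' mean over branches.
#'
#' @param branches a [branch_set()] of the ground-truth skeleton.
#' @param pred binarized prediction volume.
#' @param coverage detection rule, in (0, 1]; 1 = strict full coverage.
#' @return Scalar in `[0, 1]`.
#' @export
branch_detection_rate <- function(branches, pred, coverage = 1) {
  stopifnot(inherits(branches, "branch_set"), coverage > 0, coverage <= 1)
  if (branches$n_branches == 0)
    stop("branch_detection_rate: empty branch set")
  p <- as.array(pred)
  detected <- vapply(branches$branches, function(b) {
    frac <- sum(p[b]) / nrow(b)
    if (coverage >= 1) floor(frac) else as.numeric(frac >= coverage)
  }, numeric(1))
  mean(detected)
}

#' Voxel-wise precision, recall and F-measure
#'
#' True/false positives and false negatives are counted voxel-wise;
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F = 2*P*R/(P+R)`. When `TP = 0` and a denominator is 0, the affected
#' rate is defined as 0.
#'
#' @param pred,gt binary volumes of the same shape.
#' @return A list with `tp`, `fp`, `fn`, `precision`, `recall`, `f_measure`.
#' @export
voxel_scores <- function(pred, gt) {
  p <- as.array(pred); g <- as.array(gt)
  check_same_geometry(p, g, "prediction and ground truth")
  stopifnot(all(p %in% c(0, 1)), all(g %in% c(0, 1)))
  tp <- sum(p == 1 & g == 1)
  fp <- sum(p == 1 & g == 0)
  fn <- sum(p == 0 & g == 1)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(tp = tp, fp = fp, fn = fn,
       precision = precision, recall = recall, f_measure = f)
}

#' Full evaluation of a segmentation against tubular ground truth
#'
#' Combines the centerline metrics (tree length detected rate, branch
#' detection rate) with the voxel-wise scores into one report. If the
#' skeleton or branch decomposition of the ground truth is not supplied it
#' is computed with [skeletonize()] / [decompose_branches()].
#'
#' @param pred binarized prediction (or a likelihood volume, which is
#'   binarized at `threshold`).
#' @param gt ground-truth binary mask.
#' @param skel_gt optional precomputed skeleton ground truth.
#' @param branches optional precomputed [branch_set()].
#' @param threshold binarization threshold for likelihood input.
#' @param bd_coverage branch-detection rule (see
#'   [branch_detection_rate()]); 1 = strict.
#' @return An object of class `metrics_report`: a list with `tr`, `bd`,
#'   `precision`, `recall`, `f_measure`, `counts` and `n_branches`.
#' @export
evaluate_segmentation <- function(pred, gt, skel_gt = NULL, branches = NULL,
                                  threshold = 0.5, bd_coverage = 1) {
  if (inherits(pred, "likelihood_volume") ||
      (!all(as.array(pred) %in% c(0, 1))))
    pred <- binarize(pred, threshold)
  if (is.null(skel_gt)) skel_gt <- skeletonize(gt)
  if (is.null(branches)) branches <- decompose_branches(skel_gt)
  vs <- voxel_scores(pred, gt)
  structure(list(
    tr = tree_length_rate(skel_gt, pred),
    bd = branch_detection_rate(branches, pred, bd_coverage),
    precision = vs$precision, recall = vs$recall,
    f_measure = vs$f_measure,
    counts = c(tp = vs$tp, fp = vs$fp, fn = vs$fn),
    n_branches = branches$n_branches
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  cat(sprintf("  tree length detected rate : %.4f\n", x$tr))
  cat(sprintf("  branch detection rate     : %.4f (%d branches)\n",
              x$bd, x$n_branches))
  cat(sprintf("  precision / recall / F    : %.4f / %.4f / %.4f\n",
              x$precision, x$recall, x$f_measure))
  cat(sprintf("  TP / FP / FN              : %d / %d / %d\n",
              x$counts["tp"], x$counts["fp"], x$counts["fn"]))
  invisible(x)
}
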