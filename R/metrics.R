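#' Confusion counts inside the field of view
#'
#' @param seg Predicted [binary_segmentation()].
#' @param truth Ground-truth [binary_segmentation()] with the same FOV.
#' @return A `confusion_counts` list with `tp`, `tn`, `fp`, `fn` summing to
#'   the FOV pixel count.
#' @export
confusion_counts <- function(seg, truth) {
  stopifnot(inherits(seg, "binary_segmentation"),
            inherits(truth, "binary_segmentation"))
  if (!identical(dim(seg$labels), dim(truth$labels)) ||
      !identical(seg$fov, truth$fov))
    stop("segmentation and truth FOVs differ")
  s <- seg$labels[seg$fov]
  g <- truth$labels[seg$fov]
  structure(list(tp = sum(s & g), tn = sum(!s & !g),
                 fp = sum(s & !g), fn = sum(!s & g)),
            class = "confusion_counts")
}

#' Segmentation accuracy
#'
#' Fraction of correctly classified FOV pixels,
#' `ACC = (TP + TN) / (TP + TN + FP + FN)`; 1.0 for a perfect
#' segmentation.
#'
#' @param cc A [confusion_counts()] object.
#' @return Accuracy in \[0, 1\].
#' @export
accuracy <- function(cc) {
  total <- cc$tp + cc$tn + cc$fp + cc$fn
  if (total == 0) stop("degenerate input: empty FOV")
  (cc$tp + cc$tn) / total
}

#' Matthews correlation coefficient
#'
#' Balanced binary-classification quality in \[-1, 1\]:
#' `MCC = (TP * TN - FP * FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' +1 is a perfect prediction, 0 no better than random, -1 total
#' discordance. When any marginal factor is zero the value is 0 by the
#' standard convention.
#'
#' @param cc A [confusion_counts()] object.
#' @return MCC in \[-1, 1\].
#' @export
mcc <- function(cc) {
  tp <- as.numeric(cc$tp); tn <- as.numeric(cc$tn)
  fp <- as.numeric(cc$fp); fn <- as.numeric(cc$fn)
  if (tp + tn + fp + fn == 0) stop("degenerate input: empty FOV")
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' ROC curve and area under it
#'
#' Sweeps the decision threshold over every distinct response value inside
#' the FOV (plus sentinels so the curve touches (0,0) and (1,1)), records
#' (FPR, TPR) pairs, and integrates the area under the curve by the
#' trapezoidal rule. Computed on the gray-level response, not a binary
#' segmentation; invariant under strictly increasing transforms of the
#' response.
#'
#' @param resp An [enhanced_image()] (vessels bright).
#' @param truth Ground-truth [binary_segmentation()] containing both
#'   classes inside the FOV.
#' @return A `roc_curve` list with `auc`, `fpr`, `tpr`, `thresholds`.
#' @export
roc_auc <- function(resp, truth) {
  stopifnot(inherits(resp, "enhanced_image"),
            inherits(truth, "binary_segmentation"))
  fov <- resp$fov
  s <- resp$response[fov]
  g <- truth$labels[fov]
  npos <- sum(g); nneg <- sum(!g)
  if (npos == 0 || nneg == 0)
    stop("degenerate input: ground truth has a single class inside the FOV")
  o <- order(s, decreasing = TRUE)
  gs <- g[o]
  ss <- s[o]
  tp <- cumsum(gs)
  fp <- cumsum(!gs)
  last <- c(ss[-1] != ss[-length(ss)], TRUE)  # end of each tie block
  tpr <- c(0, tp[last] / npos, 1)
  fpr <- c(0, fp[last] / nneg, 1)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  structure(list(auc = auc, fpr = fpr, tpr = tpr,
                 thresholds = c(Inf, ss[last], -Inf)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC = %.4f over %d operating points\n",
              x$auc, length(x$fpr)))
  invisible(x)
}

#' Connectivity-Area-Length segmentation score
#'
#' Scores a segmentation `S` against a reference `S_G` as a connected
#' vascular tree rather than pixel-by-pixel:
#' * connectivity `C = 1 - min(1, |#c(S_G) - #c(S)| / #(S_G))` from
#'   8-connected component counts,
#' * area overlap
#'   `A = #((d_a(S) & S_G) | (S & d_a(S_G))) / #(S | S_G)` with `d_a`
#'   dilation by a disc of radius `alpha`,
#' * length coincidence
#'   `L = #((sk(S) & d_b(S_G)) | (d_b(S) & sk(S_G))) / #(sk(S) | sk(S_G))`
#'   with `sk` the pinned thinning skeleton and `d_b` dilation by radius
#'   `beta`.
#' The combined score is the product `CAL = C * A * L`. Radii default to 2.
#'
#' @param seg Predicted [binary_segmentation()].
#' @param truth Non-empty reference [binary_segmentation()].
#' @param alpha Dilation radius for the area factor (default 2).
#' @param beta Dilation radius for the length factor (default 2).
#' @return List with `connectivity`, `area_overlap`, `length_overlap`,
#'   `cal`, all in \[0, 1\].
#' @export
cal_score <- function(seg, truth, alpha = 2, beta = 2) {
  stopifnot(inherits(seg, "binary_segmentation"),
            inherits(truth, "binary_segmentation"))
  if (alpha < 0 || beta < 0) stop("`alpha` and `beta` must be >= 0")
  s <- seg$labels
  g <- truth$labels
  ng <- sum(g)
  if (ng == 0) stop("degenerate input: empty ground truth")
  if (!any(s))
    return(list(connectivity = 1 - min(1, max(label_components(g)) / ng),
                area_overlap = 0, length_overlap = 0, cal = 0))
  C <- 1 - min(1, abs(max(label_components(g)) - max(label_components(s))) /
                 ng)
  A <- sum((dilate_disc(s, alpha) & g) | (s & dilate_disc(g, alpha))) /
    sum(s | g)
  sks <- skeletonize(s)
  skg <- skeletonize(g)
  den <- sum(sks | skg)
  L <- if (den == 0) 1 else
    sum((sks & dilate_disc(g, beta)) | (dilate_disc(s, beta) & skg)) / den
  list(connectivity = C, area_overlap = A, length_overlap = L,
       cal = C * A * L)
}

#' Full evaluation report for one segmentation
#'
#' Bundles the pixel-wise scores (ACC, TPR, FPR, MCC), the tree-aware CAL
#' factors, and — when the gray-level response is supplied — the ROC AUC.
#'
#' @param seg Predicted [binary_segmentation()].
#' @param truth Ground-truth [binary_segmentation()].
#' @param resp Optional [enhanced_image()] (vessels bright) for the AUC.
#' @param alpha,beta CAL dilation radii (default 2).
#' @return A `metrics_report` list with `acc`, `tpr`, `fpr`, `mcc`, `auc`
#'   (or `NA`), `connectivity`, `area_overlap`, `length_overlap`, `cal`.
#' @export
evaluate_segmentation <- function(seg, truth, resp = NULL,
                                  alpha = 2, beta = 2) {
  cc <- confusion_counts(seg, truth)
  cal <- cal_score(seg, truth, alpha, beta)
  auc <- if (is.null(resp)) NA_real_ else roc_auc(resp, truth)$auc
  structure(list(
    acc = accuracy(cc),
    tpr = if (cc$tp + cc$fn > 0) cc$tp / (cc$tp + cc$fn) else NA_real_,
    fpr = if (cc$fp + cc$tn > 0) cc$fp / (cc$fp + cc$tn) else NA_real_,
    mcc = mcc(cc),
    auc = auc,
    connectivity = cal$connectivity,
    area_overlap = cal$area_overlap,
    length_overlap = cal$length_overlap,
    cal = cal$cal), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> ACC %.4f  TPR %.4f  FPR %.4f  MCC %.4f  AUC %s  CAL %.4f\n",
    x$acc, x$tpr, x$fpr, x$mcc,
    if (is.na(x$auc)) "-" else sprintf("%.4f", x$auc), x$cal))
  invisible(x)
}
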