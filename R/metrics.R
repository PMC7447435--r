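#' Contingency table between two labelings
#'
#' Joint voxel-count histogram over (segmentation label, ground-truth label).
#' Voxels with ground-truth label 0 (ignore/background) are excluded; the
#' segmentation may use any integer labels, including 0.
#'
#' @param seg predicted label volume.
#' @param gt ground-truth label volume, same shape.
#' @return an object of class \code{contingency}: list with \code{counts}
#'   (data.frame s, g, n), \code{row_sums}, \code{col_sums}, \code{n}.
#' @export
contingency <- function(seg, gt) {
  seg <- as_vol3d(seg, "seg"); gt <- as_vol3d(gt, "gt")
  assert_same_shape(seg, gt)
  keep <- gt > 0L
  if (!any(keep)) {
    warning("ground truth contains no positive labels; empty contingency table")
    return(structure(list(counts = data.frame(s = integer(), g = integer(),
                                              n = integer()),
                          row_sums = integer(), col_sums = integer(), n = 0L),
                     class = "contingency"))
  }
  s <- g <- n <- NULL  # data.table NSE
  dt <- data.table::data.table(s = as.integer(seg[keep]),
                               g = as.integer(gt[keep]))
  counts <- dt[, list(n = .N), by = list(s, g)]
  data.table::setkey(counts, s, g)
  rs <- counts[, list(n = sum(n)), by = s]
  cs <- counts[, list(n = sum(n)), by = g]
  structure(list(counts = as.data.frame(counts),
                 row_sums = stats::setNames(rs$n, rs$s),
                 col_sums = stats::setNames(cs$n, cs$g),
                 n = sum(counts$n)),
            class = "contingency")
}

# TRUE when the table describes two identical partitions (one nonzero entry
# per row and per column).
contingency_identical <- function(ct) {
  nrow(ct$counts) == length(ct$row_sums) &&
    nrow(ct$counts) == length(ct$col_sums)
}

#' Adjusted Rand error
#'
#' One minus the adjusted Rand index between the segmentation and the ground
#' truth (permutation-model chance correction, computed from the contingency
#' table; ground-truth label 0 excluded). 0 means the two labelings are
#' identical up to label permutation; values near 1 mean no correlation.
#' When the chance-adjustment denominator is 0 (degenerate tables) the error
#' is 0 if the labelings are identical, otherwise an error is raised.
#'
#' @param seg predicted label volume (or a \code{contingency} object).
#' @param gt ground-truth label volume.
#' @return scalar adjusted Rand error.
#' @export
arand_error <- function(seg, gt = NULL) {
  ct <- if (inherits(seg, "contingency")) seg else contingency(seg, gt)
  if (ct$n == 0L) stop("no foreground voxels: adjusted Rand error undefined")
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(as.numeric(ct$counts$n)))
  sum_a <- sum(ch2(as.numeric(ct$row_sums)))
  sum_b <- sum(ch2(as.numeric(ct$col_sums)))
  total <- ch2(as.numeric(ct$n))
  expected <- if (total > 0) sum_a * sum_b / total else 0
  max_index <- (sum_a + sum_b) / 2
  denom <- max_index - expected
  if (abs(denom) < .Machine$double.eps * max(1, max_index)) {
    if (contingency_identical(ct)) return(0)
    stop("degenerate contingency table: adjusted Rand index undefined")
  }
  1 - (sum_ij - expected) / denom
}

#' Variation of information (split and merge halves)
#'
#' Conditional entropies (natural logarithm) computed from the contingency
#' table: \code{voi_split = H(seg | GT)} quantifies split mistakes,
#' \code{voi_merge = H(GT | seg)} merge mistakes. Identical labelings give
#' (0, 0); their sum is the total variation of information.
#'
#' @inheritParams arand_error
#' @return named numeric vector \code{c(voi_split =, voi_merge =)}.
#' @export
voi <- function(seg, gt = NULL) {
  ct <- if (inherits(seg, "contingency")) seg else contingency(seg, gt)
  if (ct$n == 0L) stop("no foreground voxels: VOI undefined")
  n <- ct$n
  nij <- as.numeric(ct$counts$n)
  a <- as.numeric(ct$row_sums[as.character(ct$counts$s)])  # seg marginals
  b <- as.numeric(ct$col_sums[as.character(ct$counts$g)])  # gt marginals
  voi_split <- -sum(nij / n * log(nij / b))
  voi_merge <- -sum(nij / n * log(nij / a))
  c(voi_split = max(0, voi_split), voi_merge = max(0, voi_merge))
}

#' Boundary precision-recall curve
#'
#' Thresholds the predicted boundary map at each value of \code{thresholds}
#' and scores the binarization against a binary ground-truth boundary mask,
#' voxel-wise: precision = TP/(TP+FP), recall = TP/(TP+FN), and
#' F1 = 2PR/(P+R) (0 when P+R = 0). When nothing is predicted positive and
#' the ground truth has no positives, precision (and recall) are 1 by
#' convention; other 0/0 cases give 0. An optional spatial tolerance (in
#' voxels) relaxes the match: a predicted positive counts as correct if it
#' lies within \code{tolerance} of a true boundary voxel, and a true voxel
#' as recalled if a prediction lies within \code{tolerance} of it.
#'
#' @param pred predicted boundary probability map.
#' @param gt_boundary binary ground-truth boundary map, same shape.
#' @param thresholds probability thresholds in (0, 1).
#' @param tolerance matching tolerance in voxels (0 = strict voxel-wise).
#' @return data.frame with columns threshold, precision, recall, f1.
#' @export
boundary_pr_curve <- function(pred, gt_boundary,
                              thresholds = seq(0.1, 0.9, by = 0.1),
                              tolerance = 0) {
  pred <- assert_boundary_map(pred, "pred")
  gt_boundary <- as_vol3d(gt_boundary, "gt_boundary")
  assert_same_shape(pred, gt_boundary)
  if (!all(gt_boundary %in% c(0, 1))) stop("gt_boundary must be binary")
  if (any(thresholds <= 0 | thresholds >= 1)) stop("thresholds must be in (0, 1)")
  gt_pos <- gt_boundary == 1
  n_gt <- sum(gt_pos)
  if (tolerance > 0) {
    near_gt <- sqrt(cpp_edt_sq(array(as.integer(gt_pos), dim(pred)))) <= tolerance
  }
  res <- lapply(thresholds, function(th) {
    pos <- pred > th
    n_pos <- sum(pos)
    if (tolerance > 0) {
      tp_p <- sum(pos & near_gt)
      near_pred <- sqrt(cpp_edt_sq(array(as.integer(pos), dim(pred)))) <= tolerance
      tp_r <- sum(gt_pos & near_pred)
    } else {
      tp_p <- tp_r <- sum(pos & gt_pos)
    }
    precision <- if (n_pos == 0) (if (n_gt == 0) 1 else 0) else tp_p / n_pos
    recall <- if (n_gt == 0) (if (n_pos == 0) 1 else 0) else tp_r / n_gt
    f1 <- if (precision + recall == 0) 0 else
      2 * precision * recall / (precision + recall)
    c(threshold = th, precision = precision, recall = recall, f1 = f1)
  })
  as.data.frame(do.call(rbind, res))
}

#' Peak signal-to-noise ratio
#'
#' \code{10 * log10(data_range^2 / MSE)} in decibels; identical inputs give
#' \code{Inf}.
#'
#' @param image,reference arrays of the same shape.
#' @param data_range dynamic range of the data (e.g. 1 for \[0,1\] images).
#' @return PSNR in dB.
#' @export
psnr <- function(image, reference, data_range = 1) {
  image <- as_vol3d(image, "image"); reference <- as_vol3d(reference, "reference")
  assert_same_shape(image, reference)
  if (data_range <= 0) stop("data_range must be > 0")
  mse <- mean((image - reference)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

#' Structural similarity index (mean local SSIM)
#'
#' Sliding-window SSIM with a uniform window (default 7 voxels per axis;
#' singleton axes are skipped, so 2D images use a 7x7 window), sample
#' (n-1) covariance normalization and the standard constants
#' \code{C1 = (0.01 L)^2}, \code{C2 = (0.03 L)^2}. The map is averaged over
#' windows fully inside the volume. Identical inputs give exactly 1.
#'
#' @param image,reference arrays of the same shape, each axis (other than
#'   singletons) at least \code{window} voxels.
#' @param window odd window size per axis.
#' @param data_range dynamic range L of the data.
#' @return mean SSIM in \[-1, 1\].
#' @export
ssim <- function(image, reference, window = 7L, data_range = 1) {
  image <- as_vol3d(image, "image"); reference <- as_vol3d(reference, "reference")
  assert_same_shape(image, reference)
  d <- dim(image)
  active <- d > 1L
  if (any(d[active] < window)) {
    stop("volume smaller than the SSIM window (", window, ")")
  }
  r <- (window - 1L) %/% 2L
  nw <- as.integer(window)^sum(active)
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  bs <- function(x) cpp_boxsum3d(x, r)
  s1 <- bs(image); s2 <- bs(reference)
  s11 <- bs(image^2); s22 <- bs(reference^2); s12 <- bs(image * reference)
  mu1 <- s1 / nw; mu2 <- s2 / nw
  v1 <- (s11 - nw * mu1^2) / (nw - 1)
  v2 <- (s22 - nw * mu2^2) / (nw - 1)
  cov <- (s12 - nw * mu1 * mu2) / (nw - 1)
  smap <- ((2 * mu1 * mu2 + C1) * (2 * cov + C2)) /
          ((mu1^2 + mu2^2 + C1) * (v1 + v2 + C2))
  idx <- lapply(1:3, function(a) {
    if (!active[a]) seq_len(d[a]) else (r + 1L):(d[a] - r)
  })
  mean(smap[idx[[1]], idx[[2]], idx[[3]]])
}

#' Score a segmentation against ground truth
#'
#' Bundles the adjusted Rand error and the two variation-of-information
#' halves into one record, the per-volume quantities used to compare
#' partitioning strategies.
#'
#' @param seg predicted label volume.
#' @param gt ground-truth label volume.
#' @return data.frame with columns arand, voi_split, voi_merge.
#' @export
segmentation_scores <- function(seg, gt) {
  ct <- contingency(seg, gt)
  v <- voi(ct)
  data.frame(arand = arand_error(ct), voi_split = v[["voi_split"]],
             voi_merge = v[["voi_merge"]])
}
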