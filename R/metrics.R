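#' Hard overlap metrics between two binary masks
#'
#' Counts voxels of the reference set A and the estimate B and reports the
#' Jaccard coefficient IoU = |A n B| / |A u B|, the Dice similarity
#' coefficient DSC = 2|A n B| / (|A| + |B|), and the composite segmentation
#' loss 2 - (IoU + DSC). When both masks are empty the two sets agree
#' perfectly and DSC = IoU = 1, loss = 0.
#'
#' @param a,b binary arrays of identical shape (values 0/1 or logical).
#' @return An `overlap_result`: list with `size_a`, `size_b`, `intersection`,
#'   `union` voxel counts and `dsc`, `iou`, `loss`.
#' @export
overlap <- function(a, b) {
  if (!identical(dim(a) %||% length(a), dim(b) %||% length(b)))
    stop0("mask shapes differ")
  av <- as.numeric(a); bv <- as.numeric(b)
  if (!all(av %in% c(0, 1)) || !all(bv %in% c(0, 1)))
    stop0("masks must be binary (0/1)")
  na <- sum(av); nb <- sum(bv)
  ni <- sum(av * bv)
  nu <- na + nb - ni
  if (na + nb == 0) {
    dsc <- 1; iou <- 1
  } else {
    dsc <- 2 * ni / (na + nb)
    iou <- ni / nu
  }
  structure(list(size_a = na, size_b = nb, intersection = ni, union = nu,
                 dsc = dsc, iou = iou, loss = 2 - (iou + dsc)),
            class = "overlap_result")
}

#' Differentiable composite IoU + Dice loss
#'
#' Soft relaxation of the hard loss `2 - (IoU + DSC)` for probability maps:
#' with soft counts I = sum(p * g), |A| = sum(g), |B| = sum(p),
#' U = |A| + |B| - I, a smoothing epsilon enters both numerator and
#' denominator of each ratio so the loss is defined (and exactly 0 for a
#' perfect prediction) even on empty masks. On binary `p` the value agrees
#' with the hard loss up to epsilon-order terms.
#'
#' @param p numeric array of voxel probabilities in \[0, 1\].
#' @param g binary ground-truth array of the same shape.
#' @param eps smoothing constant.
#' @return Scalar loss in \[0, 2\].
#' @export
soft_loss <- function(p, g, eps = 1e-6) {
  if (!identical(dim(p) %||% length(p), dim(g) %||% length(g)))
    stop0("shapes differ")
  if (any(p < 0) || any(p > 1)) stop0("probabilities must lie in [0, 1]")
  gv <- as.numeric(g)
  if (!all(gv %in% c(0, 1))) stop0("ground truth must be binary (0/1)")
  i <- sum(p * gv)
  s <- sum(p) + sum(gv)
  u <- s - i
  2 - (i + eps) / (u + eps) - (2 * i + eps) / (s + eps)
}

#' Soft Dice similarity of a probability map against a binary mask
#' @inheritParams soft_loss
#' @return Scalar in \[0, 1\] (up to epsilon-order).
#' @export
soft_dsc <- function(p, g, eps = 1e-6) {
  gv <- as.numeric(g)
  (2 * sum(p * gv) + eps) / (sum(p) + sum(gv) + eps)
}

#' Cohort summary of per-case Dice coefficients
#'
#' Mean with sample standard deviation, a Student-t 95% confidence interval
#' for the mean, and the maximum, median and minimum — the summary layout
#' used to report segmentation techniques on a common test set.
#'
#' @param dscs numeric vector of per-case DSC values (length >= 2).
#' @param conf confidence level for the interval.
#' @return A `dsc_summary`: list with `n`, `mean`, `sd`, `ci_low`, `ci_high`,
#'   `max`, `median`, `min`.
#' @export
summarize_dsc <- function(dscs, conf = 0.95) {
  dscs <- as.numeric(dscs)
  n <- length(dscs)
  if (n < 2) stop0("at least 2 values are needed (the CI is undefined for n < 2)")
  if (any(dscs < 0) || any(dscs > 1)) stop0("DSC values must lie in [0, 1]")
  m <- mean(dscs); s <- sd(dscs)
  half <- qt(1 - (1 - conf) / 2, df = n - 1) * s / sqrt(n)
  structure(list(n = n, mean = m, sd = s,
                 ci_low = m - half, ci_high = m + half,
                 max = max(dscs), median = median(dscs), min = min(dscs)),
            class = "dsc_summary")
}

#' @export
print.dsc_summary <- function(x, ...) {
  cat(sprintf("DSC over %d cases: %.3f +/- %.3f (95%% CI %.3f-%.3f), max %.3f, median %.3f, min %.3f\n",
              x$n, x$mean, x$sd, x$ci_low, x$ci_high, x$max, x$median, x$min))
  invisible(x)
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("|A|=%g |B|=%g |AnB|=%g |AuB|=%g  DSC=%.4f IoU=%.4f loss=%.4f\n",
              x$size_a, x$size_b, x$intersection, x$union, x$dsc, x$iou, x$loss))
  invisible(x)
}
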