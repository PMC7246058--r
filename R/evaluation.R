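#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test on paired scores. Zero differences are dropped (the
#' classic treatment); tied absolute differences receive mean ranks. For
#' n <= `exact_max_n` remaining pairs the p-value is computed from the full
#' 2^n sign-permutation distribution of the rank sum (valid with ties);
#' otherwise a normal approximation with tie correction and, by default,
#' continuity correction is used.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param exact_max_n largest n for the exact-permutation path (default 12).
#' @param correct apply continuity correction in the asymptotic path.
#' @return List with `statistic` (V, the positive-rank sum), `p_value`, `n`
#'   (pairs after dropping zeros) and `method`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max_n = 12L, correct = TRUE) {
  if (length(x) != length(y)) stop0("x and y must have equal length")
  d <- as.numeric(x) - as.numeric(y)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop0("all differences are zero; the signed-rank test is undefined")
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  if (n <= exact_max_n) {
    vs <- numeric(2^n)
    for (m in seq_len(2^n) - 1L) {
      bits <- bitwAnd(m, 2L^(seq_len(n) - 1L)) > 0L
      vs[m + 1L] <- sum(r[bits])
    }
    p <- mean(abs(vs - mu) >= abs(v - mu) - 1e-9)
    method <- "exact permutation"
  } else {
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- v - mu
    if (correct) z <- z - sign(z) * 0.5
    z <- z / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- if (correct) "normal approximation with continuity correction"
      else "normal approximation"
  }
  list(statistic = v, p_value = p, n = n, method = method)
}

#' Per-case Dice scores of one segmentation technique
#'
#' @param name technique label.
#' @param case_ids unique case identifiers.
#' @param dsc per-case DSC values in \[0, 1\], aligned with `case_ids`.
#' @return A `technique_scores`.
#' @export
technique_scores <- function(name, case_ids, dsc) {
  if (length(case_ids) != length(dsc)) stop0("case_ids and dsc lengths differ")
  if (anyDuplicated(case_ids)) stop0("case ids must be unique")
  if (any(dsc < 0) || any(dsc > 1)) stop0("DSC values must lie in [0, 1]")
  structure(list(name = name, case_ids = as.character(case_ids),
                 dsc = as.numeric(dsc)),
            class = "technique_scores")
}

#' Score a set of predicted masks against ground truth
#'
#' @param name technique label.
#' @param predictions named list of binary arrays (names = case ids).
#' @param truths named list of binary ground-truth arrays covering the same
#'   ids.
#' @return A [technique_scores()] object.
#' @export
score_technique <- function(name, predictions, truths) {
  ids <- names(predictions)
  if (!all(ids %in% names(truths))) stop0("missing ground truth for some cases")
  dsc <- vapply(ids, function(id)
    overlap(truths[[id]], predictions[[id]])$dsc, numeric(1))
  technique_scores(name, ids, dsc)
}

#' Compare two segmentation techniques on a common test set
#'
#' Summarizes both techniques' per-case DSC (mean with SD, 95% CI, maximum,
#' median, minimum) and tests the paired difference with the Wilcoxon
#' signed-rank test. When every pair is identical the comparison is reported
#' as "no difference" with an undefined p-value rather than an error.
#'
#' @param a,b [technique_scores()] objects over the same case ids.
#' @param alpha significance level for the flag (default 0.05).
#' @param ... passed to [wilcoxon_signed_rank()].
#' @return A `technique_comparison`: list with a two-row `table` (technique,
#'   n, mean/sd/CI/max/median/min DSC, p-value vs the first technique),
#'   `p_value`, `significant`, and `note`.
#' @export
compare_techniques <- function(a, b, alpha = 0.05, ...) {
  stopifnot(inherits(a, "technique_scores"), inherits(b, "technique_scores"))
  if (!setequal(a$case_ids, b$case_ids))
    stop0("techniques were scored on different case sets")
  bd <- b$dsc[match(a$case_ids, b$case_ids)]
  w <- tryCatch(wilcoxon_signed_rank(a$dsc, bd, ...),
                error = function(e) NULL)
  note <- if (is.null(w)) "no difference between techniques" else NA_character_
  p <- if (is.null(w)) NA_real_ else w$p_value
  row <- function(ts, pval) {
    s <- summarize_dsc(ts$dsc)
    data.frame(technique = ts$name, n = s$n, mean_dsc = s$mean, sd_dsc = s$sd,
               ci_low = s$ci_low, ci_high = s$ci_high, max_dsc = s$max,
               median_dsc = s$median, min_dsc = s$min, p_value = pval,
               stringsAsFactors = FALSE)
  }
  tab <- rbind(row(a, NA_real_), row(b, p))
  structure(list(table = tab, p_value = p,
                 significant = !is.na(p) && p < alpha,
                 alpha = alpha, note = note),
            class = "technique_comparison")
}

#' @export
print.technique_comparison <- function(x, ...) {
  print(x$table, row.names = FALSE)
  if (!is.na(x$note)) cat(x$note, "\n")
  else cat(sprintf("Wilcoxon signed-rank p = %.4g (%ssignificant at %.2g)\n",
                   x$p_value, if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' Write a technique comparison as CSV
#' @param comparison a `technique_comparison`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(comparison, path) {
  write.csv(comparison$table, path, row.names = FALSE)
  invisible(path)
}

#' Binary dilation of a mask
#'
#' Iterated 6-neighbourhood (face-connected) dilation, used e.g. to build a
#' deliberately degraded segmentation that bleeds into the airway the way an
#' atlas tool over-segments the hilum.
#'
#' @param mask binary 3D array.
#' @param voxels number of dilation iterations.
#' @return Binary integer array.
#' @export
dilate_mask <- function(mask, voxels = 2L) {
  m <- mask != 0
  d <- dim(m)
  for (i in seq_len(voxels)) {
    out <- m
    out[-1, , ] <- out[-1, , ] | m[-d[1], , ]
    out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
    out[, -1, ] <- out[, -1, ] | m[, -d[2], ]
    out[, -d[2], ] <- out[, -d[2], ] | m[, -1, ]
    out[, , -1] <- out[, , -1] | m[, , -d[3]]
    out[, , -d[3]] <- out[, , -d[3]] | m[, , -1]
    m <- out
  }
  array(as.integer(m), d)
}
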