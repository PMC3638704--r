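#' Voxelwise confusion counts
#'
#' Tallies true/false positives and negatives of a predicted malignancy
#' mask against the ground-truth (primary reader) mask over an
#' evaluation universe, after removing excluded voxels (typically the
#' training and verification samples, to avoid an optimistic bias).
#'
#' @param pred_mask,truth_mask 3D logical arrays of identical shape.
#' @param exclusion_mask Optional 3D logical array of voxels to drop
#'   from the evaluation.
#' @param universe_mask Optional 3D logical array defining the
#'   evaluation universe (default: all voxels).
#' @return A `confusion_counts` object with `TP`, `FP`, `TN`, `FN` and
#'   `universe_size` (the four counts always partition it).
#' @examples
#' truth <- array(FALSE, c(3, 3, 1)); truth[1:2, 1, 1] <- TRUE
#' pred <- array(FALSE, c(3, 3, 1)); pred[2:3, 1, 1] <- TRUE; pred[1, 2, 1] <- TRUE
#' confusion_counts(pred, truth)
#' @export
confusion_counts <- function(pred_mask, truth_mask, exclusion_mask = NULL,
                             universe_mask = NULL) {
  stop_if_not_mask(pred_mask, "pred_mask")
  stop_if_not_mask(truth_mask, "truth_mask")
  if (!identical(dim(pred_mask), dim(truth_mask)))
    stop("mask shapes differ")
  u <- if (is.null(universe_mask)) array(TRUE, dim(pred_mask)) else universe_mask
  if (!identical(dim(u), dim(pred_mask))) stop("mask shapes differ")
  if (!is.null(exclusion_mask)) {
    if (!identical(dim(exclusion_mask), dim(pred_mask)))
      stop("mask shapes differ")
    u <- u & !exclusion_mask
  }
  p <- pred_mask[u]; t <- truth_mask[u]
  structure(list(TP = sum(p & t), FP = sum(p & !t),
                 TN = sum(!p & !t), FN = sum(!p & t),
                 universe_size = sum(u)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %d  FP %d  TN %d  FN %d  (universe %d)\n",
              x$TP, x$FP, x$TN, x$FN, x$universe_size))
  invisible(x)
}

#' True and false positive fractions
#'
#' TPF = TP / (TP + FN), FPF = FP / (FP + TN). An empty truth within the
#' universe leaves TPF undefined and it is reported as `NA` (missing),
#' never as 0.
#'
#' @param counts A `confusion_counts` object.
#' @return Named numeric vector `c(TPF, FPF)`.
#' @export
tpf_fpf <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tpf <- if (counts$TP + counts$FN > 0) counts$TP / (counts$TP + counts$FN) else NA_real_
  fpf <- if (counts$FP + counts$TN > 0) counts$FP / (counts$FP + counts$TN) else NA_real_
  c(TPF = tpf, FPF = fpf)
}

#' Threshold sweep evaluation of a score volume
#'
#' @param scores 3D score array in [0, 1].
#' @param truth_mask Ground-truth malignancy mask.
#' @param thresholds Decision thresholds (default [default_thresholds()]).
#' @param exclusion_mask,universe_mask Passed to [confusion_counts()].
#' @return Data frame with one row per threshold: the four counts, TPF
#'   and FPF.
#' @export
evaluate_thresholds <- function(scores, truth_mask,
                                thresholds = default_thresholds(),
                                exclusion_mask = NULL,
                                universe_mask = NULL) {
  rows <- lapply(thresholds, function(th) {
    cc <- confusion_counts(threshold_scores(scores, th), truth_mask,
                           exclusion_mask, universe_mask)
    tf <- tpf_fpf(cc)
    data.frame(threshold = th, TP = cc$TP, FP = cc$FP, TN = cc$TN,
               FN = cc$FN, TPF = tf[["TPF"]], FPF = tf[["FPF"]])
  })
  do.call(rbind, rows)
}

#' Long-format scatter table of classifier vs. second reader
#'
#' Combines the per-subject threshold sweep of the classifier with the
#' second reader's single operating point into one table suitable for a
#' TPF-vs-FPF scatter plot. Rows are ordered by subject then threshold,
#' classifier rows first, reader rows after.
#'
#' @param results Named list: subject -> data frame from
#'   [evaluate_thresholds()] (columns threshold, TPF, FPF).
#' @param reader2 Named list: subject -> numeric `c(TPF, FPF)`.
#' @return Data frame with columns subject, source, threshold, TPF, FPF.
#' @export
scatter_table <- function(results, reader2) {
  subjects <- names(results)
  if (!setequal(subjects, names(reader2)))
    stop("subject keys of 'results' and 'reader2' differ")
  subjects <- sort(subjects)
  cls <- do.call(rbind, lapply(subjects, function(s) {
    r <- results[[s]]
    data.frame(subject = s, source = "classifier",
               threshold = r$threshold, TPF = r$TPF, FPF = r$FPF,
               stringsAsFactors = FALSE)
  }))
  rdr <- do.call(rbind, lapply(subjects, function(s) {
    data.frame(subject = s, source = "reader2", threshold = NA_real_,
               TPF = reader2[[s]][["TPF"]], FPF = reader2[[s]][["FPF"]],
               stringsAsFactors = FALSE)
  }))
  out <- rbind(cls, rdr)
  rownames(out) <- NULL
  out
}

#' Paired one-sample t-test on per-subject performance differences
#'
#' Tests whether the mean of the per-subject difference vector
#' (classifier minus second reader, TPF or FPF) is zero:
#' \eqn{t = \bar d / (s_d / \sqrt n)} with n - 1 degrees of freedom and
#' a two-sided p-value. Zero-variance differences are flagged: a nonzero
#' mean then rejects with p ~ 0, a zero mean fails to reject.
#'
#' @param vec_classifier,vec_reader2 Equal-length numeric vectors of
#'   per-subject fractions, n >= 2.
#' @param alpha Significance level (default 0.05).
#' @return A `paired_ttest` object: `difference_vector`, `mean_diff`,
#'   `t_statistic`, `df`, `p_value`, `alpha`, `reject`,
#'   `degenerate_variance`.
#' @export
paired_difference_ttest <- function(vec_classifier, vec_reader2,
                                    alpha = 0.05) {
  if (length(vec_classifier) != length(vec_reader2))
    stop("vectors must have equal length")
  d <- vec_classifier - vec_reader2
  ok <- is.finite(d)
  d <- d[ok]
  n <- length(d)
  if (n < 2L) stop("need at least 2 paired observations")
  m <- mean(d)
  s <- stats::sd(d)
  degen <- s == 0
  if (degen) {
    tstat <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
  } else {
    tstat <- m / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(tstat), df = n - 1L)
  }
  structure(list(difference_vector = d, mean_diff = m,
                 t_statistic = tstat, df = n - 1L, p_value = p,
                 alpha = alpha, reject = p < alpha,
                 degenerate_variance = degen),
            class = "paired_ttest")
}

#' @export
print.paired_ttest <- function(x, ...) {
  cat(sprintf("Paired one-sample t-test: t = %.4g, df = %d, p = %.4g\n",
              x$t_statistic, x$df, x$p_value))
  cat(sprintf("  mean difference %.4g; H0 (mean = 0) %s at alpha = %g%s\n",
              x$mean_diff, if (x$reject) "rejected" else "not rejected",
              x$alpha,
              if (x$degenerate_variance) " [degenerate variance]" else ""))
  invisible(x)
}

#' Scatter plot of classifier operating points vs. the second reader
#'
#' @param x Data frame from [scatter_table()].
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot_scatter_table <- function(x, ...) {
  cls <- x[x$source == "classifier", ]
  rdr <- x[x$source == "reader2", ]
  graphics::plot(cls$FPF, cls$TPF, pch = 19, col = "firebrick",
                 xlab = "False positive fraction",
                 ylab = "True positive fraction",
                 xlim = range(c(x$FPF, 0), na.rm = TRUE),
                 ylim = c(0, 1), ...)
  graphics::points(rdr$FPF, rdr$TPF, pch = 17, col = "navy")
  graphics::legend("bottomright", legend = c("classifier", "second reader"),
                   pch = c(19, 17), col = c("firebrick", "navy"), bty = "n")
  invisible(x)
}
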