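## Mean log2 value per probe for each requested condition (replicates
## collapsed by arithmetic mean on the log2 scale).
condition_means <- function(x, conditions) {
  validate_expression_matrix(x)
  missing <- setdiff(conditions, x$samples$condition)
  if (length(missing)) {
    stop("condition(s) not present in matrix: ", paste(missing, collapse = ", "))
  }
  out <- vapply(conditions, function(cond) {
    cols <- which(x$samples$condition == cond)
    rowMeans(x$values[, cols, drop = FALSE])
  }, numeric(nrow(x$values)))
  out <- matrix(out, nrow = nrow(x$values),
                dimnames = list(x$probes$probe_id, conditions))
  out
}

#' Remove probes that are lowly expressed in every listed condition
#'
#' A probe is removed iff its mean log2 level (over replicates) is below
#' `threshold` in *every* listed condition; probes above threshold in at
#' least one condition are retained with all their samples. This reproduces
#' the standard treatment of bimodal array intensity distributions, where
#' the low mode is background noise: typical thresholds are log2 = 6
#' (Affymetrix-style data, three dissections) or log2 = 7 (Agilent-style
#' data, three tissues).
#'
#' @param x an `xa_expr` matrix.
#' @param threshold log2 expression threshold.
#' @param conditions character vector of condition labels over which the
#'   "below threshold everywhere" criterion is evaluated.
#' @return The filtered `xa_expr`; the threshold used is recorded in
#'   attribute `"threshold_used"`.
#' @export
filter_low_expression <- function(x, threshold, conditions) {
  if (missing(conditions) || !length(conditions)) {
    stop("parameter error: at least one condition is required")
  }
  cm <- condition_means(x, conditions)
  keep <- rowSums(cm >= threshold) > 0
  out <- expression_matrix(x$values[keep, , drop = FALSE],
                           x$probes[keep, , drop = FALSE],
                           x$samples)
  attr(out, "threshold_used") <- threshold
  out
}

xa_classes <- function(arms) {
  list(x = arms == "X", a = arms %in% AUTOSOME_ARMS)
}

xa_result <- function(fold, p, n_x, n_a, threshold_used = NA_real_) {
  structure(list(fold_a_over_x = fold, p_mw = p, n_x = n_x, n_a = n_a,
                 threshold_used = threshold_used),
            class = "xa_result")
}

#' @export
print.xa_result <- function(x, ...) {
  cat(sprintf("A:X fold = %.3f (n_X = %d, n_A = %d), Mann-Whitney p = %.3g\n",
              x$fold_a_over_x, x$n_x, x$n_a, x$p_mw))
  invisible(x)
}

#' X:autosome fold difference within one condition
#'
#' The central dosage statistic: per-probe values are replicate means of
#' the chosen condition; the fold is `2^(median(A) - median(X))` of the
#' log2 values (equivalently the ratio of geometric "median" intensities),
#' with autosomes excluding the fourth chromosome. A fold of ~1 indicates
#' a dosage-compensated X; ~1.5 matches buffered loss of compensation;
#' ~2 matches raw dose. Significance is a two-sided Mann-Whitney test of X
#' versus autosomal per-probe values (rank-based, hence invariant to any
#' strictly monotone transform of the intensities).
#'
#' @param x a (typically filtered) `xa_expr` matrix.
#' @param condition condition label to analyse.
#' @param linear_medians if `TRUE`, compute the fold as the ratio of
#'   medians of linear-scale intensities instead of `2^` the difference of
#'   log2 medians (the two agree except in pathological distributions).
#' @return An `xa_result` with elements `fold_a_over_x`, `p_mw`, `n_x`,
#'   `n_a`, `threshold_used`.
#' @export
xa_fold_difference <- function(x, condition, linear_medians = FALSE) {
  vals <- condition_means(x, condition)[, 1]
  cls <- xa_classes(x$probes$arm)
  n_x <- sum(cls$x)
  n_a <- sum(cls$a)
  if (n_x < 2 || n_a < 2) {
    stop("insufficient data: need at least 2 probes on X and on the autosomes")
  }
  if (linear_medians) {
    fold <- stats::median(LOG_BASE^vals[cls$a]) / stats::median(LOG_BASE^vals[cls$x])
  } else {
    fold <- LOG_BASE^(stats::median(vals[cls$a]) - stats::median(vals[cls$x]))
  }
  p <- suppressWarnings(
    stats::wilcox.test(vals[cls$x], vals[cls$a], alternative = "two.sided",
                       exact = (n_x <= 50 && n_a <= 50))$p.value
  )
  thr <- attr(x, "threshold_used")
  xa_result(fold, p, n_x, n_a, if (is.null(thr)) NA_real_ else thr)
}

#' X:autosome fold difference from a gene-level RPKM table
#'
#' Genes with RPKM <= 1 are removed (unreliably measured), then the fold
#' is the ratio of the autosomal to the X-linked median RPKM, fourth
#' chromosome excluded. Values below 1 indicate higher X than autosomal
#' expression (the ovary-type pattern).
#'
#' @param table an [rpkm_table()].
#' @param min_rpkm inclusion threshold (genes must exceed it).
#' @return An `xa_result`.
#' @export
xa_fold_rpkm <- function(table, min_rpkm = 1) {
  stopifnot(inherits(table, "rpkm_table"))
  keep <- table$rpkm > min_rpkm
  tab <- table[keep, , drop = FALSE]
  cls <- xa_classes(tab$arm)
  n_x <- sum(cls$x)
  n_a <- sum(cls$a)
  if (n_x < 2 || n_a < 2) {
    stop("insufficient data: fewer than 2 X or autosomal genes pass the RPKM filter")
  }
  fold <- stats::median(tab$rpkm[cls$a]) / stats::median(tab$rpkm[cls$x])
  p <- suppressWarnings(
    stats::wilcox.test(tab$rpkm[cls$x], tab$rpkm[cls$a],
                       alternative = "two.sided",
                       exact = (n_x <= 50 && n_a <= 50))$p.value
  )
  xa_result(fold, p, n_x, n_a, log2(min_rpkm))
}

#' Fold change in the X:A ratio between an impaired and a control state
#'
#' Combining the A:X fold of a compensation-impaired sample with that of
#' its control gives the realised reduction in X-linked expression
#' attributable to the compensation machinery, e.g. a 1.51-fold impaired
#' versus 1.15-fold control A:X difference implies a 1.31-fold reduction.
#'
#' @param fold_impaired A:X fold in the impaired state (e.g. an
#'   `msl2`-knockdown).
#' @param fold_control A:X fold in the matched control.
#' @return The fold reduction in X expression relative to autosomes.
#' @export
dc_impairment_ratio <- function(fold_impaired, fold_control) {
  if (fold_impaired <= 0 || fold_control <= 0) {
    stop("parameter error: folds must be positive")
  }
  fold_impaired / fold_control
}

#' Quantile sweep of the X/autosome composition of an expression
#' distribution
#'
#' Divides the pooled per-probe distribution (X and autosomal probes
#' together) into `n_quantiles` quantiles and, for each cut, reports
#' statistics over probes expressed at or above the cut: X and autosomal
#' counts, the X proportion, a Fisher's exact p contrasting the X/A split
#' above versus below the cut, the difference of medians (A - X) above the
#' cut, and a Mann-Whitney p. A deficit of X-linked probes in the top
#' quantiles relative to the genome-wide X fraction is the signature of a
#' downward-shifted X distribution. Ties at quantile boundaries resolve
#' into the upper set (half-open intervals).
#'
#' @param x an `xa_expr` matrix.
#' @param condition condition label to analyse.
#' @param n_quantiles number of quantiles (>= 2).
#' @return data.frame with one row per cut (`q0`, `q10`, ... for deciles)
#'   and columns `cut`, `threshold`, `n_x`, `n_a`, `prop_x`, `p_fet`,
#'   `median_diff`, `p_mw`.
#' @export
quantile_sweep <- function(x, condition, n_quantiles = 10) {
  if (n_quantiles < 2) stop("parameter error: n_quantiles must be >= 2")
  vals <- condition_means(x, condition)[, 1]
  cls <- xa_classes(x$probes$arm)
  use <- cls$x | cls$a
  v <- vals[use]
  is_x <- cls$x[use]
  probs <- seq(0, 1 - 1 / n_quantiles, by = 1 / n_quantiles)
  cuts <- stats::quantile(v, probs = probs, names = FALSE, type = 7)
  out <- lapply(seq_along(probs), function(i) {
    above <- v >= cuts[i]
    n_x <- sum(is_x & above)
    n_a <- sum(!is_x & above)
    if (any(!above)) {
      tab <- matrix(c(n_x, sum(is_x & !above), n_a, sum(!is_x & !above)),
                    nrow = 2, byrow = TRUE)
      p_fet <- stats::fisher.test(tab)$p.value
    } else {
      p_fet <- 1
    }
    med_diff <- if (n_x >= 1 && n_a >= 1) {
      unname(stats::median(v[!is_x & above]) - stats::median(v[is_x & above]))
    } else NA_real_
    p_mw <- if (n_x >= 1 && n_a >= 1) {
      suppressWarnings(stats::wilcox.test(v[is_x & above], v[!is_x & above],
                                          exact = FALSE)$p.value)
    } else NA_real_
    data.frame(cut = sprintf(">q%d", round(100 * probs[i])),
               threshold = cuts[i], n_x = n_x, n_a = n_a,
               prop_x = n_x / (n_x + n_a), p_fet = p_fet,
               median_diff = med_diff, p_mw = p_mw,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-chromosome-class shift in expression between two conditions
#'
#' Computes per-probe log2 differences `condA - condB` (replicate means)
#' and summarises the median shift for X-linked and autosomal probes
#' (fourth chromosome excluded) plus their difference
#' `delta = median_shift_a - median_shift_x`. When condB lacks X
#' compensation present in condA, delta approaches `log2(attenuation)`.
#'
#' @param x an `xa_expr` matrix.
#' @param condA,condB condition labels.
#' @return list with `median_shift_x`, `median_shift_a`, `delta`.
#' @export
between_group_shift <- function(x, condA, condB) {
  cm <- condition_means(x, c(condA, condB))
  d <- cm[, 1] - cm[, 2]
  cls <- xa_classes(x$probes$arm)
  if (!sum(cls$x) || !sum(cls$a)) {
    stop("insufficient data: empty chromosome class")
  }
  mx <- stats::median(d[cls$x])
  ma <- stats::median(d[cls$a])
  list(median_shift_x = mx, median_shift_a = ma, delta = ma - mx)
}
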