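#' Probe-level two-sample t-tests between two stages
#'
#' Row-wise two-sided t-tests on log2 replicate values, Welch (unequal
#' variance) by default with a pooled-variance switch for sensitivity
#' runs. The log2 fold change is `mean(stage2) - mean(stage1)`, i.e.
#' positive values mean higher expression in the later stage. Probes with
#' zero variance in both stages get `p = 1` (with a warning); with finite
#' replicate noise these arise only in degenerate constructions.
#'
#' @param x an `xa_expr` matrix.
#' @param stage1,stage2 condition labels (earlier, later stage).
#' @param var_equal use the pooled-variance t instead of Welch.
#' @return data.frame with `probe_id`, `arm`, `log2fc`, `t`, `p`.
#' @export
probe_t_tests <- function(x, stage1, stage2, var_equal = FALSE) {
  validate_expression_matrix(x)
  c1 <- which(x$samples$condition == stage1)
  c2 <- which(x$samples$condition == stage2)
  if (length(c1) < 2 || length(c2) < 2) {
    stop("need >= 2 replicates per stage for t-tests (",
         stage1, ": ", length(c1), ", ", stage2, ": ", length(c2), ")")
  }
  m1 <- x$values[, c1, drop = FALSE]
  m2 <- x$values[, c2, drop = FALSE]
  n1 <- length(c1)
  n2 <- length(c2)
  mu1 <- rowMeans(m1)
  mu2 <- rowMeans(m2)
  v1 <- rowSums((m1 - mu1)^2) / (n1 - 1)
  v2 <- rowSums((m2 - mu2)^2) / (n2 - 1)
  lfc <- mu2 - mu1
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- lfc / se
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- se == 0
  if (any(degenerate)) {
    warning(sum(degenerate), " probe(s) with zero variance in both stages; p set to 1")
    tstat[degenerate] <- NA_real_
    p[degenerate] <- 1
  }
  data.frame(probe_id = x$probes$probe_id, arm = x$probes$arm,
             log2fc = lfc, t = tstat, p = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg adjustment with significance flags
#'
#' Step-up q-values controlling the false discovery rate; a test is
#' flagged iff its q-value is at or below `fdr`.
#'
#' @param pvals numeric p-values in \[0, 1\].
#' @param fdr target false discovery rate.
#' @return data.frame with columns `p`, `q`, `significant`.
#' @export
bh_adjust <- function(pvals, fdr = 0.05) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  q <- stats::p.adjust(pvals, method = "BH")
  data.frame(p = pvals, q = q, significant = q <= fdr)
}

TRANSITIONS <- c("early", "late", "net")

#' Classify per-probe expression changes across spermatogenesis stages
#'
#' Runs [probe_t_tests()] for the three stage transitions — early
#' (premeiotic to meiotic), late (meiotic to postmeiotic) and net
#' (premeiotic to postmeiotic, compared directly) — applies the chosen
#' significance scheme with BH correction genome-wide per transition, and
#' assigns each probe a direction: `up` / `down` if significant with
#' positive / negative log2 fold change, `ns` otherwise. The `fold2`
#' scheme ignores p-values and calls a change significant iff
#' `|log2fc| >= 1`.
#'
#' @param x an `xa_expr` with conditions `premeiotic`, `meiotic`,
#'   `postmeiotic`.
#' @param scheme `"fdr05"`, `"fdr01"`, `"fdr005"` or `"fold2"`.
#' @param var_equal passed to [probe_t_tests()].
#' @return An object of class `transition_calls`: a data.frame with
#'   `probe_id`, `arm`, `transition`, `log2fc`, `t`, `p`, `q`,
#'   `direction`.
#' @export
classify_transitions <- function(x, scheme = c("fdr05", "fdr01", "fdr005", "fold2"),
                                 var_equal = FALSE) {
  scheme <- match.arg(scheme)
  stages <- c("premeiotic", "meiotic", "postmeiotic")
  missing <- setdiff(stages, x$samples$condition)
  if (length(missing)) {
    stop("matrix lacks stage(s): ", paste(missing, collapse = ", "))
  }
  pairs <- list(early = c("premeiotic", "meiotic"),
                late = c("meiotic", "postmeiotic"),
                net = c("premeiotic", "postmeiotic"))
  fdr <- switch(scheme, fdr05 = 0.05, fdr01 = 0.01, fdr005 = 0.005,
                fold2 = NA_real_)
  out <- lapply(names(pairs), function(tr) {
    tt <- probe_t_tests(x, pairs[[tr]][1], pairs[[tr]][2], var_equal = var_equal)
    if (scheme == "fold2") {
      sig <- abs(tt$log2fc) >= 1
      q <- rep(NA_real_, nrow(tt))
    } else {
      adj <- bh_adjust(tt$p, fdr)
      sig <- adj$significant
      q <- adj$q
    }
    direction <- ifelse(!sig, "ns", ifelse(tt$log2fc > 0, "up", "down"))
    cbind(tt[c("probe_id", "arm")], transition = tr,
          tt[c("log2fc", "t", "p")], q = q, direction = direction,
          stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, out)
  rownames(calls) <- NULL
  attr(calls, "scheme") <- scheme
  class(calls) <- c("transition_calls", "data.frame")
  calls
}

#' Per-arm counts of significant stage-transition changes
#'
#' Tabulates, for each chromosome arm and transition, the number of
#' expressed probes and the numbers called down and up, plus an aggregate
#' autosome row `A` summing the four major arms (the fourth chromosome is
#' excluded from the aggregate and reported on its own row).
#'
#' @param calls a `transition_calls` object.
#' @return An object of class `arm_summary`: a data.frame with `arm`,
#'   `transition`, `n_expressed`, `n_down`, `n_up`.
#' @export
arm_contingency_summary <- function(calls) {
  stopifnot(inherits(calls, "transition_calls"))
  bad <- setdiff(unique(calls$arm), CHROM_ARMS)
  if (length(bad)) stop("unknown arm(s): ", paste(bad, collapse = ", "))
  arms <- c(CHROM_ARMS, "A")
  trans <- intersect(TRANSITIONS, unique(calls$transition))
  rows <- lapply(trans, function(tr) {
    sub <- calls[calls$transition == tr, ]
    per_arm <- lapply(arms, function(a) {
      sel <- if (a == "A") sub$arm %in% AUTOSOME_ARMS else sub$arm == a
      data.frame(arm = a, transition = tr,
                 n_expressed = sum(sel),
                 n_down = sum(sel & sub$direction == "down"),
                 n_up = sum(sel & sub$direction == "up"),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per_arm)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("arm_summary", "data.frame")
  out
}

#' Render an arm summary with "count (percent)" cells
#'
#' Formats down/up counts as `"741 (38.1%)"` (percent of expressed probes
#' on that arm, one decimal, half-up rounding), one row per arm with the
#' transitions side by side.
#'
#' @param summary an `arm_summary`.
#' @return data.frame of character cells, one row per arm.
#' @export
format_arm_summary <- function(summary) {
  stopifnot(inherits(summary, "arm_summary"))
  arms <- unique(summary$arm)
  trans <- unique(summary$transition)
  out <- data.frame(arm = arms, stringsAsFactors = FALSE)
  first <- summary[summary$transition == trans[1], ]
  out$n_expressed <- formatC(first$n_expressed[match(arms, first$arm)],
                             big.mark = ",", format = "d")
  for (tr in trans) {
    sub <- summary[summary$transition == tr, ]
    i <- match(arms, sub$arm)
    out[[paste0(tr, "_down")]] <- format_count_pct(sub$n_down[i], sub$n_expressed[i])
    out[[paste0(tr, "_up")]] <- format_count_pct(sub$n_up[i], sub$n_expressed[i])
  }
  out
}

#' Fisher's exact test of X versus autosomes for one change direction
#'
#' Two-sided Fisher's exact test on the 2x2 table of X versus aggregate
#' autosomes (fourth chromosome excluded) by called-in-direction versus
#' not; two-sidedness follows the standard convention of summing the
#' probabilities of all tables no more probable than the observed one.
#'
#' @param summary an `arm_summary`.
#' @param transition `"early"`, `"late"` or `"net"`.
#' @param direction `"down"` or `"up"`.
#' @return The two-sided p-value.
#' @export
fisher_x_vs_a <- function(summary, transition, direction = c("down", "up")) {
  stopifnot(inherits(summary, "arm_summary"))
  direction <- match.arg(direction)
  xrow <- summary[summary$arm == "X" & summary$transition == transition, ]
  arow <- summary[summary$arm == "A" & summary$transition == transition, ]
  if (!nrow(xrow) || !nrow(arow)) {
    stop("transition '", transition, "' not present in summary")
  }
  kx <- xrow[[paste0("n_", direction)]]
  ka <- arow[[paste0("n_", direction)]]
  tab <- matrix(c(kx, xrow$n_expressed - kx,
                  ka, arow$n_expressed - ka),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("X", "A"), c(direction, "other")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin in 2x2 table; p undefined, returning 1")
    return(1)
  }
  stats::fisher.test(tab, alternative = "two.sided")$p.value
}

#' Median magnitudes of called changes per arm and transition
#'
#' For each arm (plus the aggregate `A` excluding the fourth chromosome)
#' and transition: the median log2 fold change among down-calls, among
#' up-calls, and among all changed probes (up + down); and for the X
#' versus A contrast, two-sided Mann-Whitney p-values comparing the
#' magnitudes of X versus autosomal calls in each direction.
#'
#' @param calls a `transition_calls` object.
#' @return An object of class `magnitude_summary`: a data.frame with
#'   `arm`, `transition`, `median_down`, `median_up`, `median_changed`
#'   (empty call classes yield `NA`), with attribute `"x_vs_a_p"` holding
#'   the per-(transition, direction) Mann-Whitney p-values.
#' @export
magnitude_summary <- function(calls) {
  stopifnot(inherits(calls, "transition_calls"))
  arms <- c(CHROM_ARMS, "A")
  trans <- intersect(TRANSITIONS, unique(calls$transition))
  med_or_na <- function(v) if (length(v)) stats::median(v) else NA_real_
  rows <- lapply(trans, function(tr) {
    sub <- calls[calls$transition == tr, ]
    per_arm <- lapply(arms, function(a) {
      sel <- if (a == "A") sub$arm %in% AUTOSOME_ARMS else sub$arm == a
      dn <- sub$log2fc[sel & sub$direction == "down"]
      up <- sub$log2fc[sel & sub$direction == "up"]
      data.frame(arm = a, transition = tr,
                 median_down = med_or_na(dn),
                 median_up = med_or_na(up),
                 median_changed = med_or_na(c(dn, up)),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per_arm)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  pvals <- lapply(trans, function(tr) {
    sub <- calls[calls$transition == tr, ]
    vapply(c("down", "up"), function(d) {
      vx <- sub$log2fc[sub$arm == "X" & sub$direction == d]
      va <- sub$log2fc[sub$arm %in% AUTOSOME_ARMS & sub$direction == d]
      if (length(vx) < 2 || length(va) < 2) return(NA_real_)
      suppressWarnings(stats::wilcox.test(vx, va, exact = FALSE)$p.value)
    }, numeric(1))
  })
  names(pvals) <- trans
  attr(out, "x_vs_a_p") <- pvals
  class(out) <- c("magnitude_summary", "data.frame")
  out
}
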