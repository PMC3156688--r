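#' Normalize Ct values against the control-gene mean per dissection and
#' plate
#'
#' For each (dissection, plate), the mean Ct of the control genes is
#' subtracted from every target (and control) Ct on that plate, removing
#' between-plate and between-dissection differences in input RNA amount.
#' By construction the mean normalized Ct of the control genes is zero on
#' every plate, and adding any constant to all Ct values of a plate leaves
#' the normalized values unchanged.
#'
#' @param table a [ct_table()].
#' @return data.frame with columns `gene`, `dissection`, `plate`, `ct`,
#'   `norm_ct` and a logical `is_control`.
#' @export
normalize_ct <- function(table) {
  stopifnot(inherits(table, "ct_table"))
  obs <- table$observations
  key <- interaction(obs$dissection, obs$plate, drop = TRUE)
  is_ctrl <- obs$gene %in% table$control_genes
  ctrl_mean <- tapply(obs$ct[is_ctrl], key[is_ctrl], mean)
  missing <- setdiff(levels(key), names(ctrl_mean))
  if (length(missing)) {
    stop("config error: no control genes on plate(s): ",
         paste(missing, collapse = ", "))
  }
  obs$norm_ct <- obs$ct - as.numeric(ctrl_mean[as.character(key)])
  obs$is_control <- is_ctrl
  obs
}

#' Log2 fold change of one gene between two dissections
#'
#' Ct is inversely related to template abundance (one cycle = one log2
#' unit), so the log2 fold of dissection A over dissection B is
#' `norm_ct(B) - norm_ct(A)`, averaged over plates (per-plate paired
#' differences where both dissections were run on a plate). Positive
#' values mean higher expression in the first-named dissection.
#'
#' @param norm normalized observations from [normalize_ct()].
#' @param gene gene name.
#' @param dissA,dissB dissection codes (`"Ps"`, `"Pn"`, `"M"`).
#' @return Mean log2 fold of A over B.
#' @export
stage_log2fold <- function(norm, gene, dissA, dissB) {
  ga <- norm[norm$gene == gene & norm$dissection == dissA, ]
  gb <- norm[norm$gene == gene & norm$dissection == dissB, ]
  if (!nrow(ga) || !nrow(gb)) {
    stop("missing dissection for gene ", gene, ": need both ", dissA,
         " and ", dissB)
  }
  plates <- intersect(ga$plate, gb$plate)
  if (length(plates)) {
    a <- ga$norm_ct[match(plates, ga$plate)]
    b <- gb$norm_ct[match(plates, gb$plate)]
    mean(b - a)
  } else {
    mean(gb$norm_ct) - mean(ga$norm_ct)
  }
}

#' Sheath-effect percentage
#'
#' The fraction of the apparent premeiotic-to-meiotic expression change
#' attributable to contaminating somatic sheath tissue:
#' `100 * (Ps - Pn) / (Ps - M)` where both arguments are log2 fold
#' changes. Signed; values can exceed 100\% (sheath effect larger than the
#' apparent stage change) or be negative (stage change and sheath effect
#' of opposite sign). The ratio is invariant to a common rescaling of both
#' folds. Undefined when the stage change `ps_m` is zero.
#'
#' @param ps_m log2 fold, premeiotic-with-sheath versus meiotic.
#' @param ps_pn log2 fold, premeiotic-with-sheath versus sheath-removed.
#' @return Percentage (full precision; see [render_percent()] for the
#'   integer display convention), or `NA` if `ps_m` is 0.
#' @export
sheath_effect <- function(ps_m, ps_pn) {
  out <- 100 * ps_pn / ps_m
  out[ps_m == 0] <- NA_real_
  out
}

#' Render a percentage to the nearest integer (half away from zero)
#'
#' @param pct numeric percentage.
#' @return integer-valued numeric.
#' @export
render_percent <- function(pct) round_half_up(pct, 0)

#' Per-gene and pooled sheath-effect table
#'
#' For every non-control gene: the Ps-M and Ps-Pn log2 fold changes
#' (plate-averaged), the sheath-effect percentage, and a two-sided paired
#' t-test of Ps versus Pn across plates. A final `"All genes"` row pools
#' the genes: its folds are the across-gene means of the per-gene folds
#' and its effect is the ratio of those pooled folds (ratio of means, not
#' mean of ratios); its p-value is a paired t-test over all gene-by-plate
#' Ps/Pn pairs.
#'
#' @param table a [ct_table()].
#' @return data.frame with columns `gene`, `ps_m`, `ps_pn`, `effect_pct`,
#'   `effect_pct_rendered`, `p_paired`; the pooled row has
#'   `gene == "All genes"`.
#' @export
sheath_effect_table <- function(table) {
  stopifnot(inherits(table, "ct_table"))
  norm <- normalize_ct(table)
  genes <- setdiff(unique(norm$gene), table$control_genes)
  rows <- lapply(genes, function(g) {
    ps_m <- stage_log2fold(norm, g, "Ps", "M")
    ps_pn <- stage_log2fold(norm, g, "Ps", "Pn")
    tt <- paired_ps_pn_test(norm, g)
    data.frame(gene = g, ps_m = ps_m, ps_pn = ps_pn,
               effect_pct = sheath_effect(ps_m, ps_pn),
               p_paired = tt, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  pooled_ps_m <- mean(out$ps_m)
  pooled_ps_pn <- mean(out$ps_pn)
  pooled <- data.frame(gene = "All genes", ps_m = pooled_ps_m,
                       ps_pn = pooled_ps_pn,
                       effect_pct = sheath_effect(pooled_ps_m, pooled_ps_pn),
                       p_paired = pooled_sheath_tests(table)$pooled_t_p,
                       stringsAsFactors = FALSE)
  out <- rbind(out, pooled)
  out$effect_pct_rendered <- render_percent(out$effect_pct)
  rownames(out) <- NULL
  out[c("gene", "ps_m", "ps_pn", "effect_pct", "effect_pct_rendered",
        "p_paired")]
}

## two-sided paired t of normalized Ct, Ps vs Pn, paired by plate
paired_ps_pn_test <- function(norm, gene) {
  ps <- norm[norm$gene == gene & norm$dissection == "Ps", ]
  pn <- norm[norm$gene == gene & norm$dissection == "Pn", ]
  plates <- intersect(ps$plate, pn$plate)
  if (length(plates) < 2) return(NA_real_)
  a <- ps$norm_ct[match(plates, ps$plate)]
  b <- pn$norm_ct[match(plates, pn$plate)]
  if (stats::sd(a - b) == 0) return(if (all(a == b)) 1 else 0)
  stats::t.test(a, b, paired = TRUE)$p.value
}

#' Significance tests for the pooled sheath effect
#'
#' Three complementary tests of whether sheath-contaminated premeiotic
#' dissections (Ps) show systematically higher expression (lower
#' normalized Ct) than sheath-removed ones (Pn):
#'
#' * per-gene two-sided paired t-tests across plates;
#' * a pooled two-sided paired t over all gene-by-plate pairs;
#' * a two-sided exact binomial sign test on the number of genes whose
#'   plate-averaged Ps expression exceeds Pn (e.g. 12 of 12 concordant
#'   genes give `p = 2 * (1/2)^12 ~ 4.9e-4`).
#'
#' @param table a [ct_table()].
#' @return list with `per_gene_p` (named vector), `pooled_t_p`,
#'   `sign_test_p`, `n_ps_greater`, `n_genes`.
#' @export
pooled_sheath_tests <- function(table) {
  stopifnot(inherits(table, "ct_table"))
  norm <- normalize_ct(table)
  genes <- setdiff(unique(norm$gene), table$control_genes)
  per_gene <- vapply(genes, function(g) paired_ps_pn_test(norm, g), numeric(1))
  diffs <- unlist(lapply(genes, function(g) {
    ps <- norm[norm$gene == g & norm$dissection == "Ps", ]
    pn <- norm[norm$gene == g & norm$dissection == "Pn", ]
    plates <- intersect(ps$plate, pn$plate)
    ps$norm_ct[match(plates, ps$plate)] - pn$norm_ct[match(plates, pn$plate)]
  }))
  pooled_t_p <- if (length(diffs) >= 2 && stats::sd(diffs) > 0) {
    stats::t.test(diffs)$p.value
  } else NA_real_
  ## plate-averaged fold per gene; Ps expression > Pn iff ps_pn fold > 0
  folds <- vapply(genes, function(g) stage_log2fold(norm, g, "Ps", "Pn"),
                  numeric(1))
  n_greater <- sum(folds > 0)
  sign_p <- stats::binom.test(n_greater, length(genes), p = 0.5,
                              alternative = "two.sided")$p.value
  list(per_gene_p = per_gene, pooled_t_p = pooled_t_p,
       sign_test_p = sign_p, n_ps_greater = n_greater,
       n_genes = length(genes))
}
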