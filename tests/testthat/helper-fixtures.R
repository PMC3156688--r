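# Build a small expression matrix from per-arm log2 value lists.
# vals: named list arm -> numeric vector (one value per probe);
# each probe's value is replicated across all samples unless a matrix of
# (probes x samples) is given per arm.
make_expr <- function(vals, conditions = "premeiotic", replicates = 1) {
  samples <- unlist(lapply(conditions, function(cc) paste0(cc, "_", seq_len(replicates))))
  rows <- lapply(names(vals), function(a) {
    v <- vals[[a]]
    if (is.matrix(v)) v else matrix(v, nrow = length(v), ncol = length(samples))
  })
  m <- do.call(rbind, rows)
  colnames(m) <- samples
  arms <- rep(names(vals), vapply(vals, function(v) if (is.matrix(v)) nrow(v) else length(v), 1L))
  probes <- data.frame(probe_id = sprintf("p%04d", seq_len(nrow(m))),
                       arm = arms, stringsAsFactors = FALSE)
  rownames(m) <- probes$probe_id
  expression_matrix(m, probes)
}

# Construct an arm_summary directly from counts (X and aggregate A rows).
make_arm_summary <- function(kx, nx, ka, na, transition = "early",
                             direction = "up") {
  down_x <- if (direction == "down") kx else 0
  up_x <- if (direction == "up") kx else 0
  down_a <- if (direction == "down") ka else 0
  up_a <- if (direction == "up") ka else 0
  out <- data.frame(
    arm = c("X", "A"), transition = transition,
    n_expressed = c(nx, na),
    n_down = c(down_x, down_a), n_up = c(up_x, up_a),
    stringsAsFactors = FALSE)
  class(out) <- c("arm_summary", "data.frame")
  out
}

# Per-probe replicate mean for one condition, computed independently of
# the package's condition-collapsing code path.
condition_mean_for_test <- function(x, cond) {
  cols <- x$samples$condition == cond
  rowMeans(x$values[, cols, drop = FALSE])
}

# Independent two-sided Fisher p by exhaustive hypergeometric enumeration:
# sum the probabilities of all tables with the observed margins whose
# probability does not exceed the observed table's.
fisher_enum_p <- function(a, b, c, d) {
  m <- a + b   # row 1 total
  n <- c + d   # row 2 total
  k <- a + c   # column 1 total
  supp <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(supp, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
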