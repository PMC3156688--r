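test_that("low-expression filtering removes probes below threshold in every condition", {
  vals <- rbind(
    c(5.9, 5.9, 5.9),   # below 6 everywhere -> removed
    c(5.0, 5.0, 6.5),   # above in one condition -> retained
    c(7.0, 7.0, 7.0))   # clearly expressed -> retained
  colnames(vals) <- c("premeiotic_1", "meiotic_1", "postmeiotic_1")
  rownames(vals) <- c("a", "b", "c")
  x <- expression_matrix(vals, data.frame(probe_id = c("a", "b", "c"),
                                          arm = c("X", "2L", "3R")))
  out <- filter_low_expression(x, 6, c("premeiotic", "meiotic", "postmeiotic"))
  expect_setequal(out$probes$probe_id, c("b", "c"))
  expect_equal(attr(out, "threshold_used"), 6)
  expect_error(filter_low_expression(x, 6, character(0)), "condition")
})

test_that("filtering agrees with a brute-force row scan", {
  sim <- simulate_expression(
    stage_design(genes_per_arm = c(X = 150, "2L" = 150, "4" = 20)),
    regulation_params("no_dc_buffered"), seed = 4)
  thr <- 8
  conds <- c("premeiotic", "meiotic", "postmeiotic")
  out <- filter_low_expression(sim, thr, conds)
  keep_brute <- vapply(seq_len(nrow(sim$values)), function(i) {
    cm <- vapply(conds, function(cc) condition_mean_for_test(sim, cc)[i], 1)
    any(cm >= thr)
  }, logical(1))
  expect_identical(out$probes$probe_id, sim$probes$probe_id[keep_brute])
})

test_that("X:A fold is the median log2 difference, with a Mann-Whitney p", {
  # X = {1,2,3}, A = {2,3,4} in log2 -> fold 2^(3-2) = 2
  x <- make_expr(list(X = c(1, 2, 3), "2L" = c(2, 3, 4)))
  res <- xa_fold_difference(x, "premeiotic")
  expect_equal(res$fold_a_over_x, 2)
  expect_equal(res$n_x, 3)
  expect_equal(res$n_a, 3)

  # identical distributions: fold 1, p = 1 for identical paired sets
  y <- make_expr(list(X = 1:20 / 2, "3R" = 1:20 / 2))
  resy <- xa_fold_difference(y, "premeiotic")
  expect_equal(resy$fold_a_over_x, 1)
  expect_gt(resy$p_mw, 0.9)

  # arm 4 never counts as autosomal
  z <- make_expr(list(X = c(1, 2, 3), "2L" = c(2, 3, 4), "4" = c(9, 9, 9)))
  resz <- xa_fold_difference(z, "premeiotic")
  expect_equal(resz$n_a, 3)
  expect_equal(resz$fold_a_over_x, 2)

  expect_error(xa_fold_difference(make_expr(list(X = 1, "2L" = c(1, 2))),
                                  "premeiotic"),
               "insufficient")
})

test_that("fold is shift-invariant and p is monotone-transform-invariant", {
  set.seed(6)
  # single replicate so a value transform acts directly on the per-probe
  # values entering the rank test
  sim <- make_expr(list(X = rnorm(120, 8), "2R" = rnorm(130, 8.4)))
  base <- xa_fold_difference(sim, "premeiotic")
  shifted <- sim
  shifted$values <- shifted$values + 3.7
  res <- xa_fold_difference(shifted, "premeiotic")
  expect_equal(res$fold_a_over_x, base$fold_a_over_x, tolerance = 1e-12)

  mono <- sim
  mono$values <- exp(sim$values / 4)   # strictly increasing transform
  expect_equal(xa_fold_difference(mono, "premeiotic")$p_mw, base$p_mw,
               tolerance = 1e-9)
})

test_that("RPKM-based fold applies the >1 filter and preserves direction", {
  tab <- rpkm_table(data.frame(
    gene_id = sprintf("g%d", 1:8),
    arm = c("X", "X", "X", "2L", "2L", "2L", "4", "4"),
    rpkm = c(4, 8, 16, 4, 8, 16, 100, 100)))
  expect_equal(xa_fold_rpkm(tab)$fold_a_over_x, 1)

  low <- rpkm_table(data.frame(gene_id = c("a", "b"), arm = c("X", "2L"),
                               rpkm = c(0.5, 0.9)))
  expect_error(xa_fold_rpkm(low), "insufficient")

  # ovary-type direction: X above autosomes gives fold < 1
  ov <- rpkm_table(data.frame(
    gene_id = sprintf("g%d", 1:6),
    arm = c("X", "X", "X", "3L", "3L", "3L"),
    rpkm = c(10, 11, 12, 8.9, 9.9, 10.7)))
  expect_lt(xa_fold_rpkm(ov)$fold_a_over_x, 1)
})

test_that("quantile sweep partitions probes and flags a shifted X", {
  # identical X and A values: X proportion is exactly one half at every cut
  v <- seq(1, 10, length.out = 200)
  x <- make_expr(list(X = v, "2L" = v))
  sw <- quantile_sweep(x, "premeiotic", n_quantiles = 10)
  expect_equal(nrow(sw), 10)
  expect_equal(sw$prop_x, rep(0.5, 10))
  total <- sum(x$probes$arm %in% c("X", AUTOSOME_ARMS))
  expect_true(all(sw$n_x + sw$n_a <= total))
  expect_equal(sw$n_x[1] + sw$n_a[1], total)  # the q0 cut keeps everything

  # two quantiles on four probes: a two-row partition
  x4 <- make_expr(list(X = c(1, 2), "3R" = c(3, 4)))
  sw4 <- quantile_sweep(x4, "premeiotic", n_quantiles = 2)
  expect_equal(nrow(sw4), 2)
  expect_equal(sw4$n_x[1] + sw4$n_a[1], 4)

  # a knockdown-style downward X shift depletes the top decile of X probes
  sim <- simulate_expression(
    stage_design(stages = "msl2_knockdown", replicates = 2,
                 genes_per_arm = c(X = 1000, "2L" = 1000, "2R" = 1000,
                                   "3L" = 1000, "3R" = 1000)),
    regulation_params("no_dc_buffered", attenuation_a = 1.5, noise_sd = 0.3),
    seed = 9)
  swk <- quantile_sweep(sim, "msl2_knockdown", n_quantiles = 10)
  genome_x_frac <- 1000 / 5000
  expect_lt(swk$prop_x[nrow(swk)], genome_x_frac)
  expect_lt(swk$p_fet[nrow(swk)], 0.05)
})

test_that("between-group shifts report per-class medians and their delta", {
  sim <- simulate_expression(
    stage_design(stages = c("premeiotic", "meiotic"), replicates = 2,
                 genes_per_arm = c(X = 80, "3L" = 80), prop_down = 0,
                 prop_up = 0),
    regulation_params("full_dc", noise_sd = 0), seed = 2)
  same <- between_group_shift(sim, "premeiotic", "premeiotic")
  expect_equal(same$median_shift_x, 0)
  expect_equal(same$delta, 0)

  # shifting all X probes down by 0.4 gives delta exactly 0.4
  shifted <- sim
  is_x <- sim$probes$arm == "X"
  shifted$values[is_x, sim$samples$condition == "meiotic"] <-
    shifted$values[is_x, sim$samples$condition == "meiotic"] - 0.4
  sh <- between_group_shift(shifted, "meiotic", "premeiotic")
  expect_equal(sh$delta, 0.4, tolerance = 1e-12)

  # germline (no DC, a = 1.5) versus DC-compensated soma: delta ~ log2(1.5)
  sim2 <- simulate_expression(
    stage_design(stages = c("male_thorax", "premeiotic"), replicates = 3,
                 genes_per_arm = c(X = 800, "2L" = 800, "3R" = 800),
                 prop_down = 0, prop_up = 0),
    regulation_params("no_dc_buffered", attenuation_a = 1.5, noise_sd = 0.4),
    seed = 31)
  # germline X sits log2(1.5) below its compensated somatic level, so the
  # autosomal-minus-X median shift is +log2(1.5) in the germline-minus-soma
  # direction and -log2(1.5) the other way round
  sh2 <- between_group_shift(sim2, "premeiotic", "male_thorax")
  expect_equal(sh2$delta, log2(1.5), tolerance = 0.1)
  sh3 <- between_group_shift(sim2, "male_thorax", "premeiotic")
  expect_equal(sh3$delta, -log2(1.5), tolerance = 0.1)
})

test_that("impairment ratio combines control and knockdown folds", {
  expect_equal(dc_impairment_ratio(1.5, 1.0), 1.5)
  expect_error(dc_impairment_ratio(-1, 1), "positive")
})
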