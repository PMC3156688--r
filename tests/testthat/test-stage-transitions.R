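make_two_stage <- function(m1, m2, arms = NULL) {
  n <- nrow(m1)
  vals <- cbind(m1, m2)
  colnames(vals) <- c(paste0("premeiotic_", seq_len(ncol(m1))),
                      paste0("meiotic_", seq_len(ncol(m2))))
  if (is.null(arms)) arms <- rep("2L", n)
  probes <- data.frame(probe_id = sprintf("p%03d", seq_len(n)), arm = arms)
  rownames(vals) <- probes$probe_id
  expression_matrix(vals, probes)
}

test_that("probe t-tests match the stated closed forms", {
  # identical replicate vectors: zero fold change, p = 1 (degenerate warning)
  x <- make_two_stage(matrix(5, 2, 3), matrix(5, 2, 3))
  expect_warning(tt <- probe_t_tests(x, "premeiotic", "meiotic"), "zero variance")
  expect_equal(tt$log2fc, c(0, 0))
  expect_equal(tt$p, c(1, 1))

  # stage1 = {1,1,1}, stage2 = {2, 2.1, 1.9}: lfc = 1, strongly significant
  x2 <- make_two_stage(matrix(1, 1, 3), matrix(c(2, 2.1, 1.9), 1, 3))
  tt2 <- probe_t_tests(x2, "premeiotic", "meiotic")
  expect_equal(tt2$log2fc, 1)
  expect_lt(tt2$p, 0.01)

  expect_error(probe_t_tests(make_two_stage(matrix(1, 1, 1), matrix(1, 1, 3)),
                             "premeiotic", "meiotic"),
               "replicates")
})

test_that("probe t-tests agree with stats::t.test row by row", {
  set.seed(10)
  m1 <- matrix(rnorm(50 * 3, 8), 50, 3)
  m2 <- matrix(rnorm(50 * 4, 8.3), 50, 4)
  x <- make_two_stage(m1, m2)
  for (ve in c(FALSE, TRUE)) {
    tt <- probe_t_tests(x, "premeiotic", "meiotic", var_equal = ve)
    oracle <- t(vapply(seq_len(50), function(i) {
      o <- t.test(m2[i, ], m1[i, ], var.equal = ve)
      c(o$statistic, o$p.value)
    }, numeric(2)))
    expect_equal(tt$t, unname(oracle[, 1]), tolerance = 1e-10)
    expect_equal(tt$p, unname(oracle[, 2]), tolerance = 1e-10)
  }
})

test_that("null probes produce approximately uniform p-values", {
  set.seed(77)
  m1 <- matrix(rnorm(1000 * 4, 8), 1000, 4)
  m2 <- matrix(rnorm(1000 * 4, 8), 1000, 4)
  tt <- probe_t_tests(make_two_stage(m1, m2), "premeiotic", "meiotic")
  ks <- suppressWarnings(ks.test(tt$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("BH adjustment reproduces the step-up procedure", {
  one <- bh_adjust(0.04, 0.05)
  expect_equal(one$q, 0.04)
  expect_true(one$significant)

  adj <- bh_adjust(c(0.01, 0.02, 0.03, 0.9), 0.05)
  # hand-computed step-up: q4 = 0.9, q3 = 0.03*4/3 = 0.04, q2 = q1 = 0.04
  expect_equal(adj$q, c(0.04, 0.04, 0.04, 0.9))
  expect_equal(adj$significant, c(TRUE, TRUE, TRUE, FALSE))

  none <- bh_adjust(rep(1, 10), 0.05)
  expect_false(any(none$significant))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

null_three_stage <- function(n, seed, reps = 3) {
  set.seed(seed)
  vals <- matrix(rnorm(n * 3 * reps, 8, 1), n, 3 * reps)
  colnames(vals) <- paste0(rep(c("premeiotic", "meiotic", "postmeiotic"),
                               each = reps), "_", seq_len(reps))
  probes <- data.frame(probe_id = sprintf("p%04d", seq_len(n)),
                       arm = rep(c("X", "2L", "2R", "3L", "3R"),
                                 length.out = n))
  rownames(vals) <- probes$probe_id
  expression_matrix(vals, probes)
}

test_that("transition classification applies schemes consistently", {
  x <- null_three_stage(300, seed = 55)
  # plant an unambiguous up-change in the early transition
  x$values["p0001", x$samples$condition == "meiotic"] <-
    x$values["p0001", x$samples$condition == "premeiotic"] + 1.2

  calls05 <- classify_transitions(x, "fdr05")
  calls005 <- classify_transitions(x, "fdr005")
  fold2 <- classify_transitions(x, "fold2")

  # a probe with log2fc >= 1 is an up-call under the fold2 scheme
  expect_equal(fold2$direction[fold2$probe_id == "p0001" &
                               fold2$transition == "early"], "up")

  # stricter FDR calls are a subset of looser ones
  k05 <- paste(calls05$probe_id, calls05$transition)[calls05$direction != "ns"]
  k005 <- paste(calls005$probe_id, calls005$transition)[calls005$direction != "ns"]
  expect_true(all(k005 %in% k05))

  # partition: every probe is down, up or ns
  s <- arm_contingency_summary(calls05)
  n_ns <- vapply(seq_len(nrow(s)), function(i) {
    sub <- calls05[calls05$transition == s$transition[i], ]
    sel <- if (s$arm[i] == "A") sub$arm %in% AUTOSOME_ARMS else sub$arm == s$arm[i]
    sum(sel & sub$direction == "ns")
  }, numeric(1))
  expect_equal(s$n_down + s$n_up + n_ns, s$n_expressed)
})

test_that("the contingency summary counts match a brute-force tally", {
  x <- simulate_expression(
    stage_design(genes_per_arm = c(X = 200, "2L" = 150, "2R" = 150,
                                   "3L" = 150, "3R" = 150, "4" = 30)),
    regulation_params("no_dc_buffered", noise_sd = 0.5), seed = 12)
  calls <- classify_transitions(x, "fdr05")
  s <- arm_contingency_summary(calls)
  early <- calls[calls$transition == "early", ]
  expect_equal(s$n_down[s$arm == "X" & s$transition == "early"],
               sum(early$arm == "X" & early$direction == "down"))
  # the A row aggregates the four major arms only
  expect_equal(s$n_expressed[s$arm == "A" & s$transition == "early"], 600)
  expect_equal(s$n_down[s$arm == "A" & s$transition == "early"],
               sum(early$arm %in% AUTOSOME_ARMS & early$direction == "down"))
  # all-ns calls give zero counts and 0.0% cells
  ns_calls <- calls
  ns_calls$direction <- "ns"
  s0 <- arm_contingency_summary(ns_calls)
  expect_true(all(s0$n_down == 0 & s0$n_up == 0))
  f0 <- format_arm_summary(s0)
  expect_match(f0$early_down[1], "^0 \\(0\\.0%\\)$")
})

test_that("Fisher X-vs-A equals exhaustive hypergeometric enumeration", {
  for (nx in 1:8) {
    for (na in 1:8) {
      for (kx in 0:nx) {
        for (ka in 0:na) {
          if (kx + ka == 0 || kx + ka == nx + na) next  # zero column margin
          s <- make_arm_summary(kx, nx, ka, na)
          expect_equal(fisher_x_vs_a(s, "early", "up"),
                       fisher_enum_p(kx, nx - kx, ka, na - ka),
                       tolerance = 1e-9,
                       info = sprintf("table %d/%d vs %d/%d", kx, nx, ka, na))
        }
      }
    }
  }
  # proportionally identical rows carry no association
  expect_equal(fisher_x_vs_a(make_arm_summary(2, 4, 4, 8), "early", "up"), 1)
  # zero-count margin: p defined as 1, with a warning
  expect_warning(p0 <- fisher_x_vs_a(make_arm_summary(0, 4, 0, 8), "early", "up"),
                 "margin")
  expect_equal(p0, 1)
})

test_that("magnitude summary reports medians over called probes", {
  x <- null_three_stage(200, seed = 91)
  calls <- classify_transitions(x, "fdr05")
  # plant a single X up-call at +0.84 in the early transition
  i <- which(calls$arm == "X" & calls$transition == "early")[1]
  calls$direction[calls$transition == "early"] <- "ns"
  calls$direction[i] <- "up"
  calls$log2fc[i] <- 0.84
  ms <- magnitude_summary(calls)
  expect_equal(ms$median_up[ms$arm == "X" & ms$transition == "early"], 0.84)
  expect_true(is.na(ms$median_down[ms$arm == "X" & ms$transition == "early"]))

  # symmetric calls +-c have an up+down median of zero
  calls2 <- classify_transitions(x, "fdr05")
  late <- which(calls2$transition == "late" & calls2$arm == "2L")[1:4]
  calls2$direction[calls2$transition == "late"] <- "ns"
  calls2$direction[late] <- c("down", "down", "up", "up")
  calls2$log2fc[late] <- c(-1.3, -0.7, 0.7, 1.3)
  ms2 <- magnitude_summary(calls2)
  expect_equal(ms2$median_changed[ms2$arm == "2L" & ms2$transition == "late"], 0)

  # brute-force median oracle over the flagged subsets
  calls3 <- classify_transitions(
    simulate_expression(stage_design(genes_per_arm = c(X = 150, "3R" = 150)),
                        regulation_params("no_dc_buffered"), seed = 14),
    "fdr05")
  ms3 <- magnitude_summary(calls3)
  for (tr in c("early", "late", "net")) {
    sub <- calls3[calls3$transition == tr, ]
    brute <- median(sub$log2fc[sub$arm == "X" & sub$direction == "down"])
    expect_equal(ms3$median_down[ms3$arm == "X" & ms3$transition == tr],
                 brute)
  }
})
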