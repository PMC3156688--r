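## Run code with a fixed RNG seed, restoring the caller's RNG state.
## Generation is thereby a pure function of its arguments.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Parameters of the X-regulation generative model
#'
#' Encodes the chromosomal regulation regimes contrasted by the analysis:
#'
#' * `full_dc` — the single male X is fully dosage compensated; X and
#'   autosomal output are equal (attenuation treated as 1).
#' * `no_dc_buffered` — no X-specific compensation, but a generic
#'   transcriptional buffering dampens the 2-fold dose difference to an
#'   `attenuation_a`-fold one (default 1.5, the empirically typical value
#'   for one-dose genes).
#' * `no_dc_raw` — no compensation and no buffering; X output follows raw
#'   gene dose (default attenuation 2).
#'
#' On top of the compensation mode, meiotic sex chromosome inactivation
#' (MSCI) is modelled as silencing in a fraction `msci_fraction_phi` of the
#' cells contributing to a meiotic dissection, by `msci_silencing_s`-fold
#' within affected cells; the realised X attenuation in a meiotic sample is
#' therefore `1 / (1 - phi + phi/s)`. Somatic sheath contamination is a
#' linear-scale convex mixture with weight `sheath_fraction_f` of
#' DC-compensated somatic signal into a germline dissection.
#'
#' @param dc_mode one of `"full_dc"`, `"no_dc_buffered"`, `"no_dc_raw"`.
#' @param attenuation_a realised X expression divisor under no-DC modes
#'   (> 0). Defaults: 1 (`full_dc`), 1.5 (`no_dc_buffered`), 2 (`no_dc_raw`).
#' @param msci_fraction_phi fraction of cells with a silenced X in meiotic
#'   samples, in \[0, 1\].
#' @param msci_silencing_s fold silencing within affected cells (>= 1).
#' @param sheath_fraction_f linear-scale mixture weight of somatic signal
#'   in sheath-contaminated dissections, in \[0, 1\].
#' @param noise_sd log2 measurement noise standard deviation (>= 0). The
#'   default 0.25 reflects typical between-replicate-array variability for
#'   expressed probes and, with three replicates per stage, lets the
#'   default stage-shift mixture yield realistic called-change proportions
#'   (roughly a third of probes per direction).
#' @return An object of class `regulation_params`.
#' @export
regulation_params <- function(dc_mode = c("full_dc", "no_dc_buffered", "no_dc_raw"),
                              attenuation_a = NULL,
                              msci_fraction_phi = 0,
                              msci_silencing_s = 1,
                              sheath_fraction_f = 0,
                              noise_sd = 0.25) {
  dc_mode <- match.arg(dc_mode)
  if (is.null(attenuation_a)) {
    attenuation_a <- switch(dc_mode, full_dc = 1, no_dc_buffered = 1.5,
                            no_dc_raw = 2)
  }
  if (!is.numeric(attenuation_a) || attenuation_a <= 0) {
    stop("parameter error: attenuation_a must be > 0")
  }
  if (dc_mode == "full_dc") attenuation_a <- 1
  if (msci_fraction_phi < 0 || msci_fraction_phi > 1) {
    stop("parameter error: msci_fraction_phi must be in [0, 1]")
  }
  if (msci_silencing_s < 1) stop("parameter error: msci_silencing_s must be >= 1")
  if (sheath_fraction_f < 0 || sheath_fraction_f > 1) {
    stop("parameter error: sheath_fraction_f must be in [0, 1]")
  }
  if (noise_sd < 0) stop("parameter error: noise_sd must be >= 0")
  structure(list(dc_mode = dc_mode, attenuation_a = attenuation_a,
                 msci_fraction_phi = msci_fraction_phi,
                 msci_silencing_s = msci_silencing_s,
                 sheath_fraction_f = sheath_fraction_f,
                 noise_sd = noise_sd),
            class = "regulation_params")
}

#' Linear-scale X attenuation in a meiotic sample under partial MSCI
#'
#' With a fraction `phi` of cells silencing the X by `s`-fold, the bulk
#' signal retains a fraction `1 - phi + phi/s` of the uninactivated level.
#'
#' @param phi fraction of affected cells, in \[0, 1\].
#' @param s fold silencing within affected cells (>= 1).
#' @return The retained linear fraction (<= 1).
#' @export
msci_retained_fraction <- function(phi, s) 1 - phi + phi / s

#' Stage-structured simulation design
#'
#' Describes the sampled stages, replication, per-arm gene counts, the
#' two-component (expressed / low "noise" mode) baseline intensity mixture
#' that reproduces the bimodal log2 intensity distributions typical of
#' arrays, and the mixture of per-gene expression shifts between
#' consecutive stages.
#'
#' Gene counts default to a realistic expressed-probe census per arm
#' (about 1.9-3k per major arm, 58 on the dot fourth). Stage-shift mixture
#' defaults (37\% down around -0.9, 31\% up around +0.95) populate
#' transition summaries at realistic proportions and magnitudes.
#'
#' @param stages ordered character vector of sample conditions (see
#'   [SAMPLE_CONDITIONS]); no condition may repeat.
#' @param replicates replicate arrays per stage (>= 2).
#' @param genes_per_arm named integer vector of gene counts per arm.
#' @param prop_down,prop_up proportions of genes drawing a downward /
#'   upward shift at each stage transition (remainder unchanged); must sum
#'   to <= 1.
#' @param effect_mean_down,effect_mean_up,effect_sd log2 means and sd of
#'   the shift components.
#' @param noise_mode_weight fraction of genes in the low-intensity mode.
#' @param expressed_mean,expressed_sd,noise_mode_mean,noise_mode_sd log2
#'   baseline mixture parameters.
#' @return An object of class `stage_design`.
#' @export
stage_design <- function(stages = c("premeiotic", "meiotic", "postmeiotic"),
                         replicates = 3,
                         genes_per_arm = c(X = 1943, "2L" = 2204, "2R" = 2356,
                                           "3L" = 2335, "3R" = 3009, "4" = 58),
                         prop_down = 0.37, prop_up = 0.31,
                         effect_mean_down = -0.9, effect_mean_up = 0.95,
                         effect_sd = 0.4,
                         noise_mode_weight = 0.25,
                         expressed_mean = 10, expressed_sd = 2,
                         noise_mode_mean = 4, noise_mode_sd = 1) {
  bad <- setdiff(stages, SAMPLE_CONDITIONS)
  if (length(bad)) stop("unknown stage condition(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(stages)) stop("stage conditions must be distinct")
  if (replicates < 2) stop("parameter error: replicates must be >= 2")
  bad <- setdiff(names(genes_per_arm), CHROM_ARMS)
  if (length(bad)) stop("unknown arm(s) in genes_per_arm: ", paste(bad, collapse = ", "))
  if (prop_down < 0 || prop_up < 0 || prop_down + prop_up > 1) {
    stop("parameter error: shift proportions must be non-negative and sum to <= 1")
  }
  if (noise_mode_weight < 0 || noise_mode_weight > 1) {
    stop("parameter error: noise_mode_weight must be in [0, 1]")
  }
  structure(list(stages = stages, replicates = as.integer(replicates),
                 genes_per_arm = genes_per_arm,
                 prop_down = prop_down, prop_up = prop_up,
                 effect_mean_down = effect_mean_down,
                 effect_mean_up = effect_mean_up, effect_sd = effect_sd,
                 noise_mode_weight = noise_mode_weight,
                 expressed_mean = expressed_mean, expressed_sd = expressed_sd,
                 noise_mode_mean = noise_mode_mean,
                 noise_mode_sd = noise_mode_sd),
            class = "stage_design")
}

#' Simulate a stage-structured expression matrix under a regulation model
#'
#' Per-gene baseline log2 levels are drawn from the two-component
#' expressed/noise mixture. Baseline draws are made once per gene *slot*
#' and shared across arms (arm k's genes take slots `1..n_k`), so that
#' arms of equal size have identical baseline multisets and chromosomal
#' differences in the output arise only from the regulation model — this
#' makes the generator's closed forms exact at `noise_sd = 0` rather than
#' approximate. Stage shifts and replicate noise are drawn independently
#' per (arm, gene).
#'
#' Deterministic regulation transforms are applied after all random draws,
#' in this order: (1) under a no-DC mode, X-linked genes in male-germline
#' conditions (and `msl2_knockdown`) are reduced by `log2(attenuation_a)`;
#' (2) in `meiotic` samples, X-linked genes are additionally multiplied on
#' the linear scale by the MSCI retained fraction `1 - phi + phi/s`;
#' (3) in `premeiotic_with_sheath` samples, the germline signal is mixed
#' on the linear scale with weight `sheath_fraction_f` of DC-compensated
#' somatic signal (the gene's stage-free baseline); (4) replicate noise
#' `Normal(0, noise_sd)` is added in log2.
#'
#' The random draw order depends only on `design` and `seed`, never on
#' `reg`, so runs at the same seed under different regulation models share
#' baselines, stage shifts, and (at equal `noise_sd`) noise — enabling
#' exact same-seed contrasts between models.
#'
#' @param design a [stage_design()].
#' @param reg a [regulation_params()].
#' @param seed integer seed; identical `(design, reg, seed)` give
#'   bitwise-identical output.
#' @return An `xa_expr` expression matrix.
#' @export
simulate_expression <- function(design, reg, seed) {
  stopifnot(inherits(design, "stage_design"), inherits(reg, "regulation_params"))
  counts <- design$genes_per_arm
  stages <- design$stages
  S <- length(stages)
  R <- design$replicates
  n <- sum(counts)
  arms <- rep(names(counts), counts)
  slot <- unlist(lapply(counts, seq_len), use.names = FALSE)
  nmax <- max(counts)

  with_seed(seed, {
    ## (1) shared baseline slots: mode then level
    in_noise_mode <- stats::runif(nmax) < design$noise_mode_weight
    base_slot <- ifelse(
      in_noise_mode,
      stats::rnorm(nmax, design$noise_mode_mean, design$noise_mode_sd),
      stats::rnorm(nmax, design$expressed_mean, design$expressed_sd)
    )
    g_base <- base_slot[slot]

    ## (2) cumulative per-gene stage shifts
    eff <- matrix(0, n, S)
    if (S > 1) {
      for (k in 2:S) {
        u <- stats::runif(n)
        shift <- numeric(n)
        is_down <- u < design$prop_down
        is_up <- !is_down & u < design$prop_down + design$prop_up
        shift[is_down] <- stats::rnorm(sum(is_down), design$effect_mean_down,
                                       design$effect_sd)
        shift[is_up] <- stats::rnorm(sum(is_up), design$effect_mean_up,
                                     design$effect_sd)
        eff[, k] <- eff[, k - 1] + shift
      }
    }

    ## (3) replicate noise (drawn before deterministic transforms so the
    ## draw sequence is independent of reg apart from noise_sd scaling)
    noise <- array(stats::rnorm(n * S * R, 0, reg$noise_sd), dim = c(n, S, R))

    ## deterministic regulation transforms
    is_x <- arms == "X"
    x_shift <- -log(reg$attenuation_a, base = LOG_BASE)
    msci_shift <- log(msci_retained_fraction(reg$msci_fraction_phi,
                                             reg$msci_silencing_s),
                      base = LOG_BASE)
    clean <- g_base + eff  # n x S
    for (k in seq_len(S)) {
      cond <- stages[k]
      if (cond %in% GERMLINE_X_CONDITIONS) {
        clean[is_x, k] <- clean[is_x, k] + x_shift
      }
      if (cond == "meiotic") {
        clean[is_x, k] <- clean[is_x, k] + msci_shift
      }
      if (cond == "premeiotic_with_sheath" && reg$sheath_fraction_f > 0) {
        f <- reg$sheath_fraction_f
        clean[, k] <- log((1 - f) * LOG_BASE^clean[, k] + f * LOG_BASE^g_base,
                          base = LOG_BASE)
      }
    }

    vals <- matrix(0, n, S * R)
    cn <- character(S * R)
    for (k in seq_len(S)) {
      for (r in seq_len(R)) {
        j <- (k - 1) * R + r
        vals[, j] <- clean[, k] + noise[, k, r]
        cn[j] <- paste0(stages[k], "_", r)
      }
    }
    colnames(vals) <- cn
    probes <- data.frame(
      probe_id = sprintf("P%05d", seq_len(n)),
      arm = arms,
      stringsAsFactors = FALSE
    )
    rownames(vals) <- probes$probe_id
    expression_matrix(vals, probes)
  })
}

#' Mix a germline signal with somatic sheath signal
#'
#' Linear-scale convex mixture `(1 - f) * germline + f * soma`, re-logged.
#' Models the contamination of an apical testis dissection by surrounding
#' DC-compensated sheath tissue.
#'
#' @param germline,soma numeric log2 vectors over the same probes (names,
#'   if present, must match).
#' @param f somatic mixture weight in \[0, 1\].
#' @return log2 vector of the mixed signal.
#' @export
mix_with_sheath <- function(germline, soma, f) {
  if (length(germline) != length(soma)) {
    stop("alignment error: germline and soma differ in length")
  }
  if (!is.null(names(germline)) && !is.null(names(soma)) &&
      !identical(names(germline), names(soma))) {
    stop("alignment error: probe names differ between germline and soma")
  }
  if (f < 0 || f > 1) stop("parameter error: f must be in [0, 1]")
  log((1 - f) * LOG_BASE^germline + f * LOG_BASE^soma, base = LOG_BASE)
}

#' Simulate a qPCR Ct table from linear expression levels
#'
#' The threshold cycle is inversely log-linear in template abundance:
#' `Ct = c0 - log2(expr) + Normal(0, noise_sd_ct)`, drawn independently per
#' plate. Doubling expression lowers Ct by exactly one cycle.
#'
#' @param expr numeric matrix of linear relative expression, genes x
#'   dissections; rownames are gene names, colnames dissection codes
#'   (`"Ps"`, `"Pn"`, `"M"`). Control genes should have constant rows.
#' @param control_genes names of the normalising control genes (must be
#'   rows of `expr`).
#' @param c0 intercept cycle count for unit expression.
#' @param plates number of replicate plates (>= 1).
#' @param noise_sd_ct per-plate Ct measurement noise (cycles).
#' @param seed integer seed.
#' @return A [ct_table()].
#' @export
simulate_ct <- function(expr, control_genes, c0 = 28, plates = 4,
                        noise_sd_ct = 0.1, seed = 1) {
  expr <- as.matrix(expr)
  if (any(!is.finite(expr)) || any(expr <= 0)) {
    stop("parameter error: expression must be positive and finite")
  }
  if (!all(control_genes %in% rownames(expr))) {
    stop("config error: control genes must be rows of expr")
  }
  genes <- rownames(expr)
  diss <- colnames(expr)
  with_seed(seed, {
    obs <- expand.grid(gene = genes, dissection = diss,
                       plate = seq_len(plates),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    mu <- c0 - log(expr[cbind(obs$gene, obs$dissection)], base = LOG_BASE)
    obs$ct <- mu + stats::rnorm(nrow(obs), 0, noise_sd_ct)
    ct_table(obs, control_genes)
  })
}

#' Simulate a full sheath-contamination qPCR experiment
#'
#' Builds per-gene linear expression across the three dissection classes
#' under the contamination mixture model and returns the resulting Ct
#' table. Each target gene has meiotic level `b`, premeiotic germline
#' level `d * b` (`d = germline_fold`, the true premeiotic:meiotic fold),
#' and somatic sheath level `c * d * b` (`c = soma_to_germline`). The
#' sheath-contaminated premeiotic sample measures
#' `(1 - f) * d * b + f * c * d * b`. Control genes are constant across
#' dissections. The implied sheath-effect percentage has the closed form
#' [expected_sheath_effect()].
#'
#' @param n_targets number of target genes.
#' @param f sheath mixture weight in \[0, 1\].
#' @param germline_fold true premeiotic:meiotic linear fold (> 0).
#' @param soma_to_germline somatic level relative to premeiotic germline.
#' @param n_controls number of control genes.
#' @param baseline_sd log2 sd of per-gene baselines.
#' @param c0,plates,noise_sd_ct,seed passed to [simulate_ct()].
#' @return A [ct_table()]; target genes are named `"T01"`, ..., controls
#'   `"C1"`, ....
#' @export
simulate_sheath_experiment <- function(n_targets = 12, f = 0.3,
                                       germline_fold = 2.5,
                                       soma_to_germline = 2,
                                       n_controls = 3, baseline_sd = 0.8,
                                       c0 = 28, plates = 4,
                                       noise_sd_ct = 0.1, seed = 1) {
  targets <- sprintf("T%02d", seq_len(n_targets))
  controls <- paste0("C", seq_len(n_controls))
  with_seed(seed, {
    b <- LOG_BASE^stats::rnorm(n_targets, 0, baseline_sd)
    e_m <- b
    e_p <- germline_fold * b
    e_s <- soma_to_germline * e_p
    ps <- (1 - f) * e_p + f * e_s
    ctrl_lvl <- LOG_BASE^stats::rnorm(n_controls, 0, baseline_sd)
    expr <- rbind(
      cbind(Ps = ps, Pn = e_p, M = e_m),
      cbind(Ps = ctrl_lvl, Pn = ctrl_lvl, M = ctrl_lvl)
    )
    rownames(expr) <- c(targets, controls)
    ## derive the ct-simulation seed from the generator stream so the whole
    ## experiment remains a pure function of (arguments, seed)
    ct_seed <- sample.int(.Machine$integer.max, 1)
    simulate_ct(expr, control_genes = controls, c0 = c0, plates = plates,
                noise_sd_ct = noise_sd_ct, seed = ct_seed)
  })
}

#' Closed-form sheath-effect percentage under the mixture model
#'
#' For sheath weight `f`, somatic:germline ratio `c` and true
#' premeiotic:meiotic fold `d`, the contaminated sample inflates the
#' premeiotic signal by `m = 1 - f + f * c`, so the apparent Ps-Pn fold is
#' `log2(m)` and the apparent Ps-M fold is `log2(d * m)`; the sheath effect
#' is their ratio as a percentage.
#'
#' @param f sheath mixture weight.
#' @param soma_to_germline somatic level relative to germline premeiotic.
#' @param germline_fold true premeiotic:meiotic fold.
#' @return Expected sheath effect in percent.
#' @export
expected_sheath_effect <- function(f, soma_to_germline, germline_fold) {
  m <- 1 - f + f * soma_to_germline
  100 * log2(m) / log2(germline_fold * m)
}

#' Simulate a gene-level RPKM table
#'
#' Log-normal gene expression with X-linked genes divided by a constant
#' attenuation factor; used to exercise the RPKM-based X:A fold analysis.
#' Baselines are drawn per slot and shared across arms, as in
#' [simulate_expression()].
#'
#' @param genes_per_arm named integer vector of gene counts per arm.
#' @param attenuation_a linear X expression divisor (> 0).
#' @param meanlog2,sdlog2 log2 mean and sd of the baseline distribution.
#' @param seed integer seed.
#' @return An [rpkm_table()].
#' @export
simulate_rpkm <- function(genes_per_arm = c(X = 1500, "2L" = 1500, "2R" = 1500,
                                            "3L" = 1500, "3R" = 1500, "4" = 50),
                          attenuation_a = 1, meanlog2 = 5, sdlog2 = 2,
                          seed = 1) {
  if (attenuation_a <= 0) stop("parameter error: attenuation_a must be > 0")
  arms <- rep(names(genes_per_arm), genes_per_arm)
  slot <- unlist(lapply(genes_per_arm, seq_len), use.names = FALSE)
  nmax <- max(genes_per_arm)
  with_seed(seed, {
    base_slot <- LOG_BASE^stats::rnorm(nmax, meanlog2, sdlog2)
    rpkm <- base_slot[slot]
    rpkm[arms == "X"] <- rpkm[arms == "X"] / attenuation_a
    rpkm_table(data.frame(
      gene_id = sprintf("G%05d", seq_along(arms)),
      arm = arms, rpkm = rpkm, stringsAsFactors = FALSE
    ))
  })
}
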