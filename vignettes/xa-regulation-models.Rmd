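---
title: "Models and methods: X versus autosome expression across spermatogenesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: X versus autosome expression across spermatogenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germlineXA)
```

## The scientific question

A male carries one X chromosome against two copies of each autosome. In
somatic cells the dosage compensation complex (DCC/MSL) hypertranscribes
the single X so that X and autosomal output match; in the male germline
the DCC is absent and the compensation status of the X is contested.
Three distinct processes can depress apparent X expression in testis
samples, and they make different quantitative predictions:

1. **Loss of X-specific dosage compensation.** Without compensation the
   raw 2-fold dose difference would give a 2-fold A:X expression ratio;
   generic transcriptional *buffering* (not X-specific) dampens 2-fold
   dose differences to roughly 1.5-fold, so an uncompensated-but-buffered
   X predicts A:X ≈ 1.5 in every germline stage.
2. **Meiotic sex chromosome inactivation (MSCI).** Facultative silencing
   of the X in spermatocytes entering meiosis predicts a *stage-specific*
   drop: an excess of X-linked genes downregulated between premeiotic and
   meiotic samples, over and above any constant A:X offset.
3. **Somatic sheath contamination.** Apical-tip ("premeiotic")
   dissections can carry DCC-positive somatic sheath tissue. Because the
   sheath is compensated, contamination selectively inflates X signal in
   premeiotic samples and can mimic meiotic downregulation.

The package implements the chromosome-level statistics that separate
these signatures, and a generator that can plant each one.

## The X:A statistic

For a probe-level log2 matrix, per-probe values are the arithmetic mean
of the log2 replicate values of the chosen condition, and

\[ \mathrm{fold}_{A:X} = 2^{\,\mathrm{median}(A) - \mathrm{median}(X)} , \]

with the fourth chromosome excluded from the autosome class everywhere
(its tiny, heterochromatic gene complement behaves unlike the major arms;
it is reported on its own row in all per-arm tables). Significance is a
two-sided Mann–Whitney test on the per-probe values, exact for class
sizes up to 50 and a tie-corrected normal approximation above. Because
the fold depends only on a difference of medians it is invariant to any
common additive log2 shift (i.e. to global rescaling of intensities);
because the test is rank-based its p-value is invariant to any strictly
monotone transform. Published analyses sometimes take medians of linear
intensities instead of `2^`-difference-of-log2-medians; the two agree
except in pathological distributions, and `xa_fold_difference()` exposes
a `linear_medians` switch for the alternative.

RNA-seq analyses use the same construction on gene-level RPKM
(`xa_fold_rpkm()`), after dropping genes with RPKM ≤ 1; there the fold is
the ratio of linear medians directly, and values below 1 (ovary-type
samples) indicate higher X than autosomal expression.

### Filtering and the quantile sweep

Array log2 intensity distributions are distinctly bimodal: an expressed
mode and a low "noise" mode of probes not reliably above background.
`filter_low_expression()` removes a probe only when its condition-mean
log2 value is below threshold in **every** listed condition, so a probe
expressed in any stage is kept everywhere. Typical thresholds are 6
(Affymetrix-style three-dissection data) and 7 (Agilent-style
three-tissue data). Because a downward-shifted X loses proportionally
more probes to the filter, the estimated fold depends somewhat on the
threshold; `quantile_sweep()` quantifies this by reporting X/A counts,
the X proportion, Fisher's exact test (above versus below each cut) and
the Mann–Whitney p at every quantile cut of the pooled distribution.
Ties at a boundary resolve into the upper set (half-open intervals).

### Between-condition shifts

`between_group_shift()` compares two conditions per probe
(`condA − condB` of condition means) and reports the median shift per
chromosome class and `delta = median_A − median_X`. The sign convention
follows the convention of published knockdown analyses: when `condA` is
the compensation-impaired (or germline) member, `delta` is positive and
approaches `log2(attenuation)`. `dc_impairment_ratio()` combines the A:X
folds of an impaired and a control sample into the implied fold reduction
of X expression (e.g. 1.51 / 1.15 = 1.31).

## Stage transitions

`classify_transitions()` tests each probe across three stage pairs —
early (premeiotic → meiotic), late (meiotic → postmeiotic) and net
(premeiotic → postmeiotic, compared directly rather than composed) — and
classifies it up/down/ns per transition. Choices that were genuinely
open, and how they were fixed:

* **t-test variant.** Welch (unequal variances) by default; published
  descriptions of probe-level t-tests rarely specify the variant, and
  Welch is the robust default. A pooled-variance switch (`var_equal`)
  supports sensitivity runs; the two agree closely on balanced designs.
* **Zero-variance probes.** A probe with zero variance in both groups has
  no within-group error estimate; it is assigned p = 1 with a warning
  rather than an infinite statistic. With continuous noise these arise
  only in degenerate constructions.
* **Multiplicity.** BH step-up q-values computed genome-wide per
  transition (all arms together), because published per-arm tables report
  one FDR regime across arms, not arm-wise corrections. Schemes `fdr05`,
  `fdr01`, `fdr005` flag q ≤ 0.05/0.01/0.005; scheme `fold2` ignores
  p-values and flags |log2fc| ≥ 1. Stricter FDR call sets are subsets of
  looser ones by construction.
* **Sign convention.** Positive log2fc = higher in the later stage.

`arm_contingency_summary()` tallies expressed/down/up per arm with an
aggregate A row (2L + 2R + 3L + 3R; never chromosome 4), and
`fisher_x_vs_a()` tests X against that aggregate per direction with the
standard two-sided convention (sum of table probabilities ≤ observed),
which the test suite verifies against exhaustive hypergeometric
enumeration. `magnitude_summary()` reports median log2fc among down-,
up- and all changed probes per arm, with Mann–Whitney X-versus-A
comparisons per column.

## The qPCR contamination model

Threshold cycle is inversely log-linear in template abundance: one cycle
= one log2 unit. `normalize_ct()` subtracts the mean control-gene Ct
within each (dissection, plate), which removes per-plate input-amount
constants exactly. Stage folds are per-plate paired differences of
normalized Ct (B − A for the fold of A over B), averaged across plates.
The sheath effect of a gene is

\[ 100 \cdot \frac{\mathrm{Ps} - \mathrm{Pn}}{\mathrm{Ps} - \mathrm{M}} \ \% , \]

the percentage of the apparent premeiotic → meiotic change attributable
to sheath contamination. It is scale-invariant, can exceed 100% or be
negative, and is undefined (NA) at Ps − M = 0. The pooled "All genes"
effect is the ratio of the across-gene *mean* folds (ratio of means, not
mean of per-gene ratios), which keeps genes with small denominators from
dominating. Three significance tests are provided: per-gene paired t
across plates (the plate is the pairing unit, since every dissection runs
on every plate), a pooled paired t over all gene-by-plate pairs, and a
two-sided exact binomial sign test on the number of genes with higher
expression in Ps than Pn.

Display rounding is half-away-from-zero (`round_half_up()`), to the
nearest integer percent for sheath effects and one decimal for
contingency percentages; base R's banker's rounding would render 42.5%
as 42%, where the field's tables print 43%.

## The transgene ANOVA

`fit_factorial_anova()` fits a full-factorial fixed-effects `lm` of
normalized Ct on sex (or stage), insert location and transgene construct,
with sum-to-zero contrasts, and reports Type II sums of squares: each
term tested against the model containing every term that does not contain
it, respecting marginality — the appropriate choice for unbalanced
reporter designs where insert-line counts differ between constructs.
Type I is available for the balanced-design check (the two coincide
there). The test suite verifies the Type II values against an
independent model-comparison oracle (differences of residual sums of
squares between nested fits). Insert line is not modelled as a factor by
default (the fitted models are fixed-effects factorials over the design
factors); `simulate_transgene_design()` records line identity so a
blocking analysis can be run by hand if wanted.

## The generator: what it emulates and what it does not

`simulate_expression()` draws per-gene baselines from a two-component
mixture — expressed mode N(10, 2), noise mode N(4, 1) in log2, noise-mode
weight 0.25 — reproducing the bimodality that motivates intensity
filtering. Baselines are drawn once per gene *slot* and shared across
arms, so arms of equal size have identical baseline multisets: chromosome
differences in the output arise **only** from the regulation model, which
makes the generator's closed forms exact at `noise_sd = 0` instead of
approximate, and makes same-seed runs under different regulation modes
directly comparable (random draw order never depends on the regulation
parameters). The closed forms, all exercised in the tests:

* dose limits: A:X → 1 under `full_dc`, → `attenuation_a` under no-DC
  (1.5 buffered, 2 raw);
* MSCI: meiotic X retains the linear fraction `1 − φ + φ/s` (fraction φ
  of cells silenced s-fold), so the planted meiotic attenuation is
  `1/(1 − φ + φ/s)`;
* contamination: a sheath mixture with weight f of compensated soma
  turns a germline X level of `A/a` into `((1 − f)/a + f) · A`.

Default design parameters were fixed once: gene counts per arm follow a
realistic expressed-probe census (1,943 X; 2,204 2L; 2,356 2R; 2,335 3L;
3,009 3R; 58 chr4 — about 12k probes), three replicates per stage, and a
stage-shift mixture of 37% down (mean −0.9), 31% up (mean +0.95),
sd 0.4 in log2 per transition, approximating the proportions and median
magnitudes seen on real staged-testis arrays. Replicate noise defaults to
sd 0.25 in log2, typical between-replicate-array variability for
expressed probes; at that level the default shift mixture yields roughly
19%/17% down/up calls per transition at FDR 0.05 with three replicates —
the realistic order of magnitude. (At sd 0.5, three replicates have
essentially no power for ±0.9 shifts and the transition tables come back
empty; such runs are useful as null calibrations only.) The MSCI defaults
used in the power demonstrations (φ = 0.3, s = 10) are illustrative —
no quantitative MSCI strength is established for flies — and were chosen
so the planted early-transition signal is unambiguous.

What the generator does **not** emulate: probe-level sequence effects and
cross-hybridization, correlated noise across probes of one array
(array-level batch effects), mixed cell-type composition beyond the
explicit sheath term, count noise of RNA-seq (RPKM tables are generated
directly from a log-normal), and amplification-efficiency differences in
qPCR. Passing tests therefore demonstrate the correctness and calibration
of the statistics under the stated models, not robustness to every
artefact of real arrays.

`simulate_ct()` inverts the ΔCt model (`Ct = c0 − log2(expr) + noise`)
per plate; `simulate_sheath_experiment()` composes baseline, mixture and
Ct steps so the full qPCR pipeline can be checked against
`expected_sheath_effect()`, its closed form.

## Numerical choices and degenerate inputs

* All matrices are log2 (`LOG_BASE = 2`). Replicate *spots* of one probe
  are averaged on the linear scale and re-logged (scanners report linear
  intensity); linear values are clamped at a floor of 1e-8 first, so
  background-subtracted non-positive intensities stay finite. Replicate
  *arrays* are collapsed by arithmetic mean of log2 values.
* Read/write round trips preserve values to at least 6 decimals; arm
  labels outside {X, 2L, 2R, 3L, 3R, 4} and non-numeric cells are
  rejected with row/column context.
* Fisher tests with a zero margin return p = 1 with a warning; X:A folds
  require at least two probes per class; Mann–Whitney on fewer than two
  calls per class is reported as NA.
* All simulation is a pure function of its arguments and a single integer
  seed; the caller's RNG state is restored afterwards.

## Problem sizes used in the shipped checks

The test suite and acceptance checks run at deliberately moderate sizes —
12k-probe matrices with 3 replicates for single-run demonstrations, 20
seeds for fold recovery, 100 runs of 200-probe null matrices for FDR
calibration, 10 seeds for Monte-Carlo mixture recovery, and exhaustive
Fisher enumeration over all 2×2 tables with margins ≤ 8 — sizes at which
the distributional claims being tested are already sharp.

## Known limitations

* The package consumes probe/gene-level tables; platform-specific raw
  file parsing (CEL, raw Agilent scans) and read alignment are out of
  scope by design.
* Percent rendering reproduces table formatting conventions
  (half-up rounding); numeric columns always carry full precision, and
  one published-table cell (−9% where the printed folds give −10.3%)
  is reproduced at full precision rather than forced to its printed
  rounding.
* The pooled sheath-effect p-value construction (paired t over all
  gene-by-plate pairs) is one reasonable pooling of a design whose
  published description does not pin the scheme down; it is documented
  here and computed reproducibly.
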