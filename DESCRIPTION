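Package: germlineXA
Title: X Chromosome Versus Autosome Expression Analysis Across Spermatogenesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chromosome-level analysis of X versus autosome gene expression
    across spermatogenesis stages in Drosophila-style expression data:
    low-expression filtering, X:autosome median fold statistics with
    Mann-Whitney tests, quantile sweeps of expression distributions,
    stage-transition differential-expression classification with
    Benjamini-Hochberg FDR control and per-arm Fisher enrichment tests,
    qPCR delta-Ct analysis of somatic sheath contamination, and factorial
    ANOVA with Type II sums of squares for transgene reporter designs.
    Includes a synthetic-data generator that embodies the chromosomal
    regulation models being contrasted (full dosage compensation, buffered
    and unbuffered loss of compensation, meiotic sex chromosome
    inactivation, and somatic contamination mixtures) so that every
    analysis step is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
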