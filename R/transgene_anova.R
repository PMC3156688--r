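#' Factorial ANOVA with Type II sums of squares
#'
#' Fits a full-factorial fixed-effects linear model of a continuous
#' response (typically normalized Ct) on the supplied factors and returns
#' the ANOVA table. Type II sums of squares test each term against the
#' model containing every term that does not contain it (respecting
#' marginality), computed on a sum-to-zero contrast parameterisation via
#' `car::Anova`; Type I (sequential) is available for the balanced-design
#' sanity check where the two coincide. Terms are ordered main effects,
#' then two-way, then higher interactions. Because Ct is inversely related
#' to abundance the response sign is irrelevant to F and p.
#'
#' @param data data.frame holding the response and factor columns.
#' @param response name of the numeric response column.
#' @param factors character vector of factor column names (crossed fully).
#' @param ss_type `"II"` (default) or `"I"`.
#' @return An object of class `anova_table`: data.frame with `term`,
#'   `sumsq`, `df`, `F`, `p`, ending with a `Residuals` row.
#' @export
fit_factorial_anova <- function(data, response, factors, ss_type = c("II", "I")) {
  ss_type <- match.arg(ss_type)
  stopifnot(is.data.frame(data), response %in% names(data),
            all(factors %in% names(data)))
  if (!is.numeric(data[[response]]) || any(!is.finite(data[[response]]))) {
    stop("response must be finite numeric")
  }
  dat <- data
  for (f in factors) dat[[f]] <- factor(dat[[f]])
  fml <- stats::as.formula(paste(response, "~", paste(factors, collapse = " * ")))
  contr <- stats::setNames(
    replicate(length(factors), stats::contr.sum, simplify = FALSE), factors)
  fit <- stats::lm(fml, data = dat, contrasts = contr)
  if (any(is.na(stats::coef(fit)))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; aliased coefficients: ",
         paste(aliased, collapse = ", "))
  }
  if (stats::df.residual(fit) < 1) {
    stop("no residual degrees of freedom; reduce the model or add replicates")
  }
  if (ss_type == "II") {
    a <- car::Anova(fit, type = "II")
    tab <- data.frame(term = rownames(a), sumsq = a[["Sum Sq"]],
                      df = a[["Df"]], F = a[["F value"]], p = a[["Pr(>F)"]],
                      stringsAsFactors = FALSE)
  } else {
    a <- stats::anova(fit)
    tab <- data.frame(term = rownames(a), sumsq = a[["Sum Sq"]],
                      df = a[["Df"]], F = a[["F value"]], p = a[["Pr(>F)"]],
                      stringsAsFactors = FALSE)
  }
  rownames(tab) <- NULL
  res <- tab$term == "Residuals"
  tab <- rbind(tab[!res, ], tab[res, ])
  rownames(tab) <- NULL
  class(tab) <- c("anova_table", "data.frame")
  tab
}

#' Simulate a transgene reporter qPCR design
#'
#' Generates replicate-level normalized Ct data for a two-transgene
#' reporter experiment: a sex (or stage) factor, an insert-location
#' factor, and a transgene-construct factor, with per-cell effects
#' supplied in log2 (Ct) units. Defaults mimic a realistic insert-line
#' census (8 X-linked + 8 autosomal lines of one construct, 6 + 5 of the
#' other) and are mildly unbalanced, which is what makes Type II sums of
#' squares differ from sequential ones.
#'
#' @param n_per_cell named replicate counts are derived from the line
#'   census: each insert line contributes `reps` measurements.
#' @param lines_per_level named list giving insert-line counts per
#'   (transgene, location) combination.
#' @param reps measurements per insert line.
#' @param sex_effect,location_effect,interaction_effect effect sizes (Ct
#'   units) for the male level, the X level, and the male-by-X cell.
#' @param sd residual standard deviation (Ct units).
#' @param seed integer seed.
#' @return data.frame with `normalized_ct`, `sex`, `location`,
#'   `transgene`, `line`.
#' @export
simulate_transgene_design <- function(lines_per_level = list(
                                        WOL = c(X = 8, autosome = 8),
                                        YLZ = c(X = 6, autosome = 5)),
                                      reps = 3,
                                      sex_effect = -6, location_effect = 2.5,
                                      interaction_effect = 2, sd = 1,
                                      seed = 1) {
  with_seed(seed, {
    rows <- list()
    line_id <- 0
    for (tg in names(lines_per_level)) {
      for (loc in names(lines_per_level[[tg]])) {
        for (l in seq_len(lines_per_level[[tg]][[loc]])) {
          line_id <- line_id + 1
          for (sex in c("male", "female")) {
            mu <- 10 +
              (sex == "male") * sex_effect +
              (loc == "X") * location_effect +
              (sex == "male" && loc == "X") * interaction_effect
            rows[[length(rows) + 1]] <- data.frame(
              normalized_ct = mu + stats::rnorm(reps, 0, sd),
              sex = sex, location = loc, transgene = tg,
              line = sprintf("L%02d", line_id),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    do.call(rbind, rows)
  })
}
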