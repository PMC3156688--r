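#' @keywords internal
"_PACKAGE"

#' Chromosome arms recognised by the package
#'
#' The five major euchromatic arms plus the heterochromatic dot fourth
#' chromosome. Autosomal aggregates (`AUTOSOME_ARMS`) deliberately exclude
#' the fourth chromosome: the dot behaves unlike the major autosomes
#' (heterochromatic, tiny gene count) and is reported on its own row in all
#' per-arm summaries.
#'
#' @format Character vectors.
#' @export
CHROM_ARMS <- c("X", "2L", "2R", "3L", "3R", "4")

#' @rdname CHROM_ARMS
#' @export
AUTOSOME_ARMS <- c("2L", "2R", "3L", "3R")

#' Recognised sample conditions
#'
#' Dissection / tissue classes usable as sample condition labels. The
#' germline subset (plus the DC-impaired `msl2_knockdown` cell class) is
#' where the simulator applies X-specific attenuation; the remaining somatic
#' classes are treated as fully dosage compensated.
#'
#' @format Character vector.
#' @export
SAMPLE_CONDITIONS <- c(
  "male_thorax", "female_thorax",
  "premeiotic", "premeiotic_with_sheath", "meiotic", "postmeiotic",
  "control_cells", "msl2_knockdown",
  "testis", "ovary", "bam_testis", "bam_ovary"
)

## conditions where the single male X (or experimentally uncompensated X)
## is exposed to loss-of-compensation / MSCI effects
GERMLINE_X_CONDITIONS <- c(
  "premeiotic", "premeiotic_with_sheath", "meiotic", "postmeiotic",
  "testis", "bam_testis", "msl2_knockdown"
)

## all matrices are stored as log to this base; one documented constant
LOG_BASE <- 2

## linear intensities are clamped at this floor before re-logging, so that
## background-subtracted values that happen to be <= 0 stay finite
LINEAR_FLOOR <- 1e-8

#' Round half away from zero
#'
#' Base `round()` rounds halves to even; published tables round 42.5\% up
#' to 43\%, so display formatting uses this variant.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up (away from zero).
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Construct an expression matrix object
#'
#' A light container for probe-level log2 intensities: a numeric matrix
#' (probes x samples), a probe annotation data frame and a sample data
#' frame. Sample columns are named `<condition>_<replicate>`.
#'
#' @param values numeric matrix of log2 intensities, rownames = probe ids.
#' @param probes data.frame with columns `probe_id`, `arm` and optionally
#'   `gene_symbol`, `coordinate`.
#' @param samples data.frame with columns `condition`, `replicate`; row
#'   order must match the columns of `values`. If omitted it is parsed from
#'   `colnames(values)`.
#' @return An object of class `xa_expr`.
#' @export
expression_matrix <- function(values, probes, samples = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(samples)) samples <- parse_sample_labels(colnames(values))
  probes <- as.data.frame(probes, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  x <- structure(
    list(values = values, probes = probes, samples = samples),
    class = "xa_expr"
  )
  validate_expression_matrix(x)
  x
}

parse_sample_labels <- function(nms) {
  if (is.null(nms)) stop("sample columns must be named <condition>_<replicate>")
  cond <- sub("_([0-9]+)$", "", nms)
  rep_ <- suppressWarnings(as.integer(sub("^.*_([0-9]+)$", "\\1", nms)))
  if (anyNA(rep_)) {
    stop("cannot parse replicate number from sample name(s): ",
         paste(nms[is.na(rep_)], collapse = ", "))
  }
  data.frame(sample = nms, condition = cond, replicate = rep_,
             stringsAsFactors = FALSE)
}

validate_expression_matrix <- function(x) {
  stopifnot(inherits(x, "xa_expr"))
  p <- x$probes
  if (!all(c("probe_id", "arm") %in% names(p))) {
    stop("probe annotation must contain 'probe_id' and 'arm'")
  }
  bad <- setdiff(unique(p$arm), CHROM_ARMS)
  if (length(bad)) {
    stop("unknown chromosome arm(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(CHROM_ARMS, collapse = ", "), ")")
  }
  if (anyDuplicated(p$probe_id)) {
    stop("duplicate probe_id in annotation; run average_replicate_spots() first")
  }
  if (nrow(p) != nrow(x$values)) {
    stop("annotation rows (", nrow(p), ") != value rows (", nrow(x$values), ")")
  }
  s <- x$samples
  bad_cond <- setdiff(unique(s$condition), SAMPLE_CONDITIONS)
  if (length(bad_cond)) {
    stop("unknown sample condition(s): ", paste(bad_cond, collapse = ", "))
  }
  if (anyDuplicated(s[c("condition", "replicate")])) {
    stop("duplicate (condition, replicate) sample labels")
  }
  if (nrow(s) != ncol(x$values)) {
    stop("sample rows (", nrow(s), ") != value columns (", ncol(x$values), ")")
  }
  invisible(x)
}

#' @export
print.xa_expr <- function(x, ...) {
  cat("Expression matrix (log2):", nrow(x$values), "probes x",
      ncol(x$values), "samples\n")
  cat("Conditions:", paste(unique(x$samples$condition), collapse = ", "), "\n")
  tab <- table(factor(x$probes$arm, levels = CHROM_ARMS))
  cat("Probes per arm:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = " "), "\n")
  invisible(x)
}

#' Read a probe-level expression table
#'
#' Expects a tab-separated file whose first columns are `probe_id`, `arm`
#' (and optionally `gene_symbol`, `coordinate`), followed by one numeric
#' column per sample named `<condition>_<replicate>`.
#'
#' @param path file path.
#' @return An `xa_expr` object.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ann_cols <- intersect(c("probe_id", "arm", "gene_symbol", "coordinate"),
                        names(df))
  if (!all(c("probe_id", "arm") %in% ann_cols)) {
    stop("annotation error: expression table must have 'probe_id' and 'arm' columns")
  }
  sample_cols <- setdiff(names(df), ann_cols)
  if (!length(sample_cols)) stop("no sample columns found")
  vals <- as.matrix(df[sample_cols])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(df[sample_cols], is.numeric, logical(1)))[1]
    badrow <- which(is.na(suppressWarnings(as.numeric(df[[sample_cols[bad]]]))))[1]
    stop("parse error: non-numeric value in column '", sample_cols[bad],
         "', row ", badrow)
  }
  rownames(vals) <- df$probe_id
  expression_matrix(vals, probes = df[ann_cols])
}

#' Write a probe-level expression table
#'
#' Inverse of [read_expression_table()]; values are written with enough
#' digits for round trips to agree to at least 6 decimals.
#'
#' @param x an `xa_expr` object.
#' @param path output file path.
#' @export
write_expression_table <- function(x, path) {
  validate_expression_matrix(x)
  df <- cbind(x$probes, as.data.frame(x$values, check.names = FALSE))
  utils::write.table(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Average replicate spots for probes printed more than once
#'
#' Arrays often carry the same probe at several physical spots. Signal is
#' averaged across those spots on the linear intensity scale (intensities,
#' not their logs, are what the scanner reports), then re-logged. Linear
#' intensities are clamped at a small positive floor so background-subtracted
#' values never produce -Inf.
#'
#' @param x an `xa_expr`-like object that may contain duplicate `probe_id`
#'   rows (constructed internally; [expression_matrix()] itself rejects
#'   duplicates). Pass a list with `values`, `probes`, `samples`.
#' @return An `xa_expr` with one row per probe id.
#' @export
average_replicate_spots <- function(x) {
  vals <- as.matrix(x$values)
  ids <- x$probes$probe_id
  if (!anyDuplicated(ids)) {
    return(expression_matrix(vals, x$probes, x$samples))
  }
  lin <- pmax(LOG_BASE^vals, LINEAR_FLOOR)
  grp <- factor(ids, levels = unique(ids))
  avg <- rowsum(lin, grp) / as.vector(table(grp))
  out <- log(avg, base = LOG_BASE)
  keep <- !duplicated(ids)
  probes <- x$probes[keep, , drop = FALSE]
  rownames(out) <- probes$probe_id
  expression_matrix(out, probes, x$samples)
}

#' Construct a qPCR Ct table
#'
#' @param observations data.frame with columns `gene`, `dissection`
#'   (one of `"Ps"` premeiotic + sheath, `"Pn"` premeiotic sheath removed,
#'   `"M"` meiotic), `plate` (integer), `ct` (well-mean threshold cycle).
#' @param control_genes character vector of normalising control gene names;
#'   every (dissection, plate) must contain all of them.
#' @return An object of class `ct_table`.
#' @export
ct_table <- function(observations, control_genes) {
  obs <- as.data.frame(observations, stringsAsFactors = FALSE)
  need <- c("gene", "dissection", "plate", "ct")
  if (!all(need %in% names(obs))) {
    stop("Ct table needs columns: ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(obs$dissection), c("Ps", "Pn", "M"))
  if (length(bad)) stop("unknown dissection code(s): ", paste(bad, collapse = ", "))
  if (any(!is.finite(obs$ct)) || any(obs$ct <= 0)) {
    stop("parse error: Ct values must be positive finite cycles")
  }
  missing_ctrl <- setdiff(control_genes, unique(obs$gene))
  if (length(missing_ctrl)) {
    stop("config error: control gene(s) absent from table: ",
         paste(missing_ctrl, collapse = ", "))
  }
  for (d in unique(obs$dissection)) {
    for (pl in unique(obs$plate[obs$dissection == d])) {
      here <- obs$gene[obs$dissection == d & obs$plate == pl]
      miss <- setdiff(control_genes, here)
      if (length(miss)) {
        stop("config error: control gene(s) ", paste(miss, collapse = ", "),
             " missing on plate ", pl, " dissection ", d)
      }
    }
  }
  structure(list(observations = obs, control_genes = control_genes),
            class = "ct_table")
}

#' Read / write a qPCR Ct table
#'
#' Tab-separated with columns `gene`, `dissection`, `plate`, `ct`.
#'
#' @param path file path.
#' @param control_genes character vector of control gene names.
#' @return A `ct_table`.
#' @export
read_ct_table <- function(path, control_genes) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  ct_table(df, control_genes)
}

#' @rdname read_ct_table
#' @param x a `ct_table`.
#' @export
write_ct_table <- function(x, path) {
  stopifnot(inherits(x, "ct_table"))
  utils::write.table(format(x$observations, digits = 12, trim = TRUE,
                            scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-level RPKM table
#'
#' Tab-separated with columns `gene_id`, `arm`, `rpkm` (per-gene values,
#' already summed over transcripts of the same gene).
#'
#' @param path file path.
#' @return data.frame of class `rpkm_table`.
#' @export
read_rpkm_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  rpkm_table(df)
}

#' @rdname read_rpkm_table
#' @param df data.frame with columns `gene_id`, `arm`, `rpkm`.
#' @export
rpkm_table <- function(df) {
  need <- c("gene_id", "arm", "rpkm")
  if (!all(need %in% names(df))) {
    stop("RPKM table needs columns: ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(df$arm), CHROM_ARMS)
  if (length(bad)) stop("unknown chromosome arm(s): ", paste(bad, collapse = ", "))
  if (any(!is.finite(df$rpkm)) || any(df$rpkm < 0)) {
    stop("parse error: RPKM values must be non-negative and finite")
  }
  structure(as.data.frame(df, stringsAsFactors = FALSE),
            class = c("rpkm_table", "data.frame"))
}

#' Format a count with its percentage of a total
#'
#' Renders contingency cells as `"741 (38.1%)"`: counts with big-mark
#' commas, percentages to one decimal with half-up rounding.
#'
#' @param count,total integers.
#' @return character vector.
#' @export
format_count_pct <- function(count, total) {
  pct <- round_half_up(100 * count / total, 1)
  sprintf("%s (%.1f%%)", formatC(count, big.mark = ",", format = "d"), pct)
}

#' Write per-arm summary tables to a directory
#'
#' Emits tab-separated renderings of the contingency summary (counts with
#' percentages) and, optionally, the magnitude and sheath-effect tables.
#' Column order is deterministic; parsing the emitted contingency file back
#' recovers the counts exactly.
#'
#' @param arm_summary an `arm_summary` from [arm_contingency_summary()], or NULL.
#' @param magnitude_summary a `magnitude_summary` from [magnitude_summary()], or NULL.
#' @param sheath_table a sheath-effect data.frame from [sheath_effect_table()], or NULL.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_summary_tables <- function(arm_summary = NULL, magnitude_summary = NULL,
                                 sheath_table = NULL, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  if (!is.null(arm_summary)) {
    p <- file.path(out_dir, "arm_contingency.tsv")
    utils::write.table(format_arm_summary(arm_summary), p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(magnitude_summary)) {
    p <- file.path(out_dir, "arm_magnitude.tsv")
    utils::write.table(format(as.data.frame(magnitude_summary), digits = 6),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(sheath_table)) {
    p <- file.path(out_dir, "sheath_effect.tsv")
    utils::write.table(format(as.data.frame(sheath_table), digits = 6),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
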