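# Exon/junction usage: per-sample feature quantifications are divided by
# the gene expression estimate (the mean of the gene's features), rescaled
# by each feature's 95th-percentile ratio (floored at 0.05), and clamped to
# [0, 1]. The result isolates splicing change from expression change.

USAGE_FLOOR <- 0.05

#' Construct a quantification matrix
#'
#' A features-by-samples matrix of non-negative reals (RSEM-style
#' normalized counts). Rows are feature IDs, columns sample IDs; both must
#' be unique and missing values are not permitted.
#'
#' @param values Numeric matrix with rownames (feature IDs) and colnames
#'   (sample IDs).
#' @param kind One of `"exon"`, `"junction"`, `"isoform"`, `"gene"`.
#' @return An object of class `quant_matrix`.
#' @export
quant_matrix <- function(values, kind = c("exon", "junction", "isoform", "gene")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if ((nrow(values) > 0 && is.null(rownames(values))) ||
      (ncol(values) > 0 && is.null(colnames(values)))) {
    stop("values must have feature IDs as rownames and sample IDs as colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate feature IDs")
  if (anyDuplicated(colnames(values))) stop("duplicate sample IDs")
  if (anyNA(values)) stop("missing values not permitted in a quant_matrix")
  if (any(values < 0)) stop("quantification values must be non-negative")
  structure(list(values = values, kind = kind), class = "quant_matrix")
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat(sprintf("quant_matrix (%s): %d features x %d samples\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.quant_matrix <- function(x) dim(x$values)

#' Read a quantification TSV
#'
#' First column is the feature ID, remaining columns one per sample with a
#' header row of sample IDs. Gzip input is accepted. Missing cells are
#' either imputed to 0 (default, with a warning count) or their row is
#' dropped; the choice and the affected counts are recorded in the
#' `load_report` attribute.
#'
#' @param path TSV (optionally gzipped) path.
#' @param kind Feature kind, see [quant_matrix()].
#' @param missing `"zero"` (impute 0) or `"drop"` (drop rows with missing
#'   cells).
#' @return A `quant_matrix` with attribute `load_report`.
#' @export
read_quant_tsv <- function(path, kind = "exon", missing = c("zero", "drop")) {
  missing <- match.arg(missing)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("quantification TSV needs a feature column and >=1 sample")
  ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  n_missing <- sum(is.na(vals))
  dropped <- character()
  if (n_missing > 0) {
    if (missing == "zero") {
      warning(n_missing, " missing value(s) imputed to 0")
      vals[is.na(vals)] <- 0
    } else {
      keep <- rowSums(is.na(vals)) == 0
      dropped <- rownames(vals)[!keep]
      warning(length(dropped), " row(s) with missing values dropped")
      vals <- vals[keep, , drop = FALSE]
    }
  }
  x <- quant_matrix(vals, kind = kind)
  attr(x, "load_report") <- list(
    n_missing = n_missing, policy = missing, dropped_features = dropped)
  x
}

#' Write a quantification or usage matrix as TSV
#'
#' Same dialect as [read_quant_tsv()]: feature IDs in the first column
#' (`feature_id`), one column per sample. For a `usage_matrix` a sidecar
#' JSON file `<path>.q95.json` mapping feature ID to its 95th-percentile
#' scaling constant is written for provenance.
#'
#' @param x A `quant_matrix` or `usage_matrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_quant_tsv <- function(x, path) {
  vals <- x$values
  df <- data.frame(feature_id = rownames(vals), vals,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (inherits(x, "usage_matrix")) {
    q <- as.list(x$q95)
    jsonlite::write_json(q, paste0(path, ".q95.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Gene expression estimate from feature quantifications
#'
#' The per-sample gene expression e_j is the mean over the gene's n
#' annotated exon/junction features of the quantification values x_ij.
#'
#' @param x A `quant_matrix` whose features all belong to one gene.
#' @return Named numeric vector e (length = number of samples).
#' @export
gene_expression <- function(x) {
  stopifnot(inherits(x, "quant_matrix"))
  if (nrow(x$values) == 0) stop("no annotated features")
  colMeans(x$values)
}

#' Per-sample normalized ratio matrix
#'
#' r_ij = x_ij / e_j. Samples with e_j = 0 (no signal across the gene's
#' features) get r_ij = 0 and are flagged in the
#' `zero_expression_samples` attribute rather than producing NaN.
#'
#' @param x A `quant_matrix`.
#' @param e Gene expression vector aligned with `x`'s samples.
#' @return Numeric matrix of ratios with attribute
#'   `zero_expression_samples`.
#' @export
ratio_matrix <- function(x, e) {
  stopifnot(inherits(x, "quant_matrix"), length(e) == ncol(x$values))
  zero <- e == 0
  esafe <- ifelse(zero, 1, e)
  r <- sweep(x$values, 2, esafe, "/")
  r[, zero] <- 0
  attr(r, "zero_expression_samples") <- colnames(x$values)[zero]
  r
}

#' 95th percentile of each feature's ratio across samples
#'
#' Computed with linear interpolation between closest order statistics
#' (quantile type 7). This is the per-feature scaling constant that sets
#' the usage scale's upper bound.
#'
#' @param r Ratio matrix (features x samples).
#' @return Named numeric vector, one value per feature.
#' @export
q95_per_feature <- function(r) {
  stopifnot(is.matrix(r), nrow(r) >= 1, ncol(r) >= 1)
  apply(r, 1, stats::quantile, probs = 0.95, type = 7, names = FALSE)
}

#' Exon/junction usage values
#'
#' Computes the usage matrix y from a quantification matrix x annotated to
#' a single gene:
#'
#'   y_ij = min(x_ij / (e_j * Q95_i), 1)   if Q95_i >  0.05
#'   y_ij = min(x_ij / (e_j * 0.05), 1)    if Q95_i <= 0.05
#'
#' where e_j is the per-sample gene expression ([gene_expression()]) and
#' Q95_i the 95th percentile across samples of the normalized ratio
#' x_ij / e_j ([q95_per_feature()]). The 95% cap diminishes outlier
#' impact; the 0.05 floor keeps features that are small relative to the
#' gene from being blown up. All defined y lie in [0, 1]. Samples with
#' zero gene expression yield y = 0 and are flagged.
#'
#' @param x A `quant_matrix` (exon or junction) annotated to one gene.
#' @return An object of class `usage_matrix` with fields `values` (y),
#'   `q95`, `floor` (0.05), `gene_expr` (e), `kind` and
#'   `zero_expression_samples`.
#' @export
usage <- function(x) {
  stopifnot(inherits(x, "quant_matrix"))
  if (nrow(x$values) < 1 || ncol(x$values) < 1) {
    stop("usage needs >=1 feature and >=1 sample")
  }
  e <- gene_expression(x)
  r <- ratio_matrix(x, e)
  q95 <- q95_per_feature(r)
  denom <- pmax(q95, USAGE_FLOOR)
  flagged <- attr(r, "zero_expression_samples")
  y <- pmin(r / denom, 1)
  attr(y, "zero_expression_samples") <- NULL
  structure(list(
    values = y,
    q95 = stats::setNames(q95, rownames(x$values)),
    floor = USAGE_FLOOR,
    gene_expr = e,
    kind = x$kind,
    zero_expression_samples = flagged
  ), class = "usage_matrix")
}

#' @export
print.usage_matrix <- function(x, ...) {
  cat(sprintf("usage_matrix (%s): %d features x %d samples, y in [%.3f, %.3f]\n",
              x$kind, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  if (length(x$zero_expression_samples)) {
    cat("  zero-expression samples flagged:",
        length(x$zero_expression_samples), "\n")
  }
  invisible(x)
}

#' @export
summary.usage_matrix <- function(object, ...) {
  res <- data.frame(
    feature_id = rownames(object$values),
    q95 = unname(object$q95),
    mean_usage = rowMeans(object$values),
    frac_clamped = rowMeans(object$values == 1),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  res
}

#' @export
as.matrix.usage_matrix <- function(x, ...) x$values

#' @export
dim.usage_matrix <- function(x) dim(x$values)
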