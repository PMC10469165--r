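#' Filter low-quality cells
#'
#' Retains exactly the cells with detected-gene count strictly between
#' `min_genes` and `max_genes`, total UMI strictly above `min_umi`, and
#' mitochondrial fraction strictly below `max_mito` — i.e. cells at the
#' published bounds (<= 200 or >= 6000 genes, <= 1000 UMI, >= 20% mito)
#' are removed. Genes are left untouched. The per-cell QC table is attached
#' as the `"qc"` attribute and retrievable with [qc_report()].
#'
#' @param x A `caf_sample`.
#' @param min_genes,max_genes Exclusive bounds on detected genes.
#' @param min_umi Exclusive lower bound on total UMI.
#' @param max_mito Exclusive upper bound on the mitochondrial UMI fraction.
#' @param mito_genes Character vector of mitochondrial gene ids, or `NULL`
#'   to select by `mito_pattern`.
#' @param mito_pattern Regular expression for mitochondrial gene ids.
#' @return A filtered `caf_sample`.
#' @export
filter_cells <- function(x, min_genes = 200, max_genes = 6000,
                         min_umi = 1000, max_mito = 0.20,
                         mito_genes = NULL, mito_pattern = "^MT-") {
  stopifnot(inherits(x, "caf_sample"))
  if (min_genes <= 0 || max_genes <= 0 || min_umi <= 0) {
    abort("QC thresholds must be positive.")
  }
  counts <- x$counts
  if (is.null(mito_genes)) {
    mito_genes <- grep(mito_pattern, rownames(counts), value = TRUE)
  } else if (!all(mito_genes %in% rownames(counts))) {
    abort("`mito_genes` must be a subset of the gene ids.")
  }
  n_genes <- Matrix::colSums(counts > 0)
  n_umi <- Matrix::colSums(counts)
  mito_frac <- if (length(mito_genes)) {
    Matrix::colSums(counts[mito_genes, , drop = FALSE]) / pmax(n_umi, 1)
  } else {
    rep(0, ncol(counts))
  }
  pass_genes <- n_genes > min_genes & n_genes < max_genes
  pass_umi <- n_umi > min_umi
  pass_mito <- mito_frac < max_mito
  keep <- pass_genes & pass_umi & pass_mito

  reason <- rep("pass", ncol(counts))
  reason[!pass_mito] <- "high_mito"
  reason[!pass_umi] <- "low_umi"
  reason[!pass_genes] <- "gene_count"
  qc <- tibble(
    barcode = colnames(counts), n_genes = as.integer(n_genes),
    n_umi = as.integer(n_umi), mito_frac = as.numeric(mito_frac),
    pass = keep, reason = reason
  )
  if (!any(keep)) warn(sprintf("%s: no cell passed QC", x$sample_id))
  out <- new_caf_sample(counts[, keep, drop = FALSE],
                        x$meta[keep, , drop = FALSE], x$sample_id)
  attr(out, "qc") <- qc
  out
}

#' Per-cell QC report of the last [filter_cells()] call
#'
#' @param x A filtered `caf_sample`.
#' @return Tibble with barcode, detected genes, UMI, mito fraction,
#'   pass/fail and failure reason.
#' @export
qc_report <- function(x) {
  qc <- attr(x, "qc")
  if (is.null(qc)) abort("no QC record: run filter_cells() first.")
  qc
}

#' Library-size log-normalization
#'
#' `value(g, c) = ln(1 + scale_factor * count(g, c) / total(c))` — the
#' standard per-cell library normalization followed by log1p. Zeros map to
#' zeros, so sparsity is preserved.
#'
#' @param x A `caf_sample`.
#' @param scale_factor Positive scale factor (default 10,000, the usual
#'   convention for a ~20k-gene transcriptome), or `NULL` for the median
#'   library size — appropriate when the gene universe is much smaller,
#'   so per-gene means stay on the scale the variable-feature mean window
#'   expects.
#' @return A `caf_norm` object carrying the normalized sparse matrix and
#'   provenance (scale factor, formula).
#' @export
log_normalize <- function(x, scale_factor = 1e4) {
  stopifnot(inherits(x, "caf_sample"))
  totals <- Matrix::colSums(x$counts)
  scale_factor <- scale_factor %||% median(totals)
  stopifnot(scale_factor > 0)
  if (any(totals == 0)) {
    abort("cells with zero total counts cannot be normalized; filter first.")
  }
  m <- as(x$counts, "CsparseMatrix")
  # scale the non-zero entries column-wise, then log1p
  m@x <- log1p(m@x * rep.int(scale_factor / totals, diff(m@p)))
  new_caf_norm(m, x$meta, x$sample_id, scale_factor)
}
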