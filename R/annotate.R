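#' Reference-correlation cell typing
#'
#' Labels each cell with the reference cell type whose profile has the
#' highest Spearman correlation with the cell, computed over the
#' reference-variable genes (top quartile by between-type variance in the
#' reference) shared with the data. Rank-based, so any monotone per-cell
#' transform of expression leaves the labels unchanged.
#'
#' @param nm A `caf_norm`.
#' @param ref Genes x cell-types reference matrix (e.g. from
#'   [simulate_reference_profiles()]).
#' @return Tibble (barcode, classifier_label, classifier_cor). Cells with
#'   zero variance over the shared genes get label `"unassigned"`.
#' @export
classify_reference <- function(nm, ref) {
  stopifnot(inherits(nm, "caf_norm"))
  if (ncol(ref) < 2) abort("need at least two reference cell types.")
  shared <- intersect(rownames(nm$data), rownames(ref))
  if (length(shared) < 50) abort("fewer than 50 genes shared with the reference.")
  ref <- ref[shared, , drop = FALSE]
  btv <- apply(ref, 1, var)
  use <- shared[btv >= quantile(btv, 0.75)]
  x <- norm_values(nm, use)
  rx <- apply(x, 2, rank)
  rr <- apply(log1p(ref[use, , drop = FALSE]), 2, rank)
  cc <- suppressWarnings(cor(rx, rr))  # Pearson of ranks = Spearman
  best <- max.col(replace(cc, is.na(cc), -Inf), ties.method = "first")
  label <- colnames(ref)[best]
  best_cor <- cc[cbind(seq_len(nrow(cc)), best)]
  zero_var <- apply(x, 2, function(v) var(v) == 0)
  label[zero_var] <- "unassigned"
  best_cor[zero_var] <- NA_real_
  tibble(barcode = colnames(x), classifier_label = label,
         classifier_cor = as.numeric(best_cor))
}

#' Apply the two-condition fibroblast rule and CAF/NF assignment
#'
#' A cell is a fibroblast iff the classifier labeled it `Fibroblast` AND it
#' has a non-zero UMI count for at least one fibroblast marker (default
#' DCN, COL3A1, THY1). Fibroblasts from tumor or border tissue become CAF,
#' those from normal tissue NF. Epithelial cells get the matching tissue
#' rule: `Cancer` in tumor/border tissue, `Epithelial` otherwise.
#'
#' @param cells Tibble with at least barcode, tissue and classifier_label
#'   (e.g. the output of [classify_reference()] joined to sample metadata).
#' @param x The `caf_sample` holding raw counts (marker expression is
#'   assessed on counts, matching the positive-cell definition).
#' @param markers Fibroblast marker genes.
#' @return `cells` with `is_fibroblast`, `fib_class` (`CAF`/`NF`/`none`)
#'   and `type_refined` columns added.
#' @export
annotate_fibroblasts <- function(cells, x,
                                 markers = c("DCN", "COL3A1", "THY1")) {
  stopifnot(inherits(x, "caf_sample"))
  missing <- setdiff(markers, rownames(x$counts))
  if (length(missing)) {
    abort(sprintf("fibroblast marker(s) absent from the matrix: %s",
                  paste(missing, collapse = ", ")))
  }
  marker_pos <- Matrix::colSums(x$counts[markers, , drop = FALSE] > 0) > 0
  cells |>
    mutate(
      is_fibroblast = .data$classifier_label == "Fibroblast" &
        as.vector(marker_pos[.data$barcode]),
      fib_class = dplyr::case_when(
        .data$is_fibroblast & .data$tissue %in% c("tumor", "border") ~ "CAF",
        .data$is_fibroblast & .data$tissue == "normal" ~ "NF",
        .default = "none"
      ),
      type_refined = dplyr::case_when(
        .data$fib_class != "none" ~ .data$fib_class,
        .data$classifier_label == "Epithelial" &
          .data$tissue %in% c("tumor", "border") ~ "Cancer",
        .default = .data$classifier_label
      )
    )
}

#' Fraction of cells positive for a gene
#'
#' A cell is positive for a gene when its UMI count is non-zero.
#'
#' @param x A `caf_sample`.
#' @param gene Gene id.
#' @param cells Character vector of barcodes defining the subset.
#' @return Proportion in `[0, 1]`.
#' @export
positive_fraction <- function(x, gene, cells) {
  stopifnot(inherits(x, "caf_sample"))
  if (!gene %in% rownames(x$counts)) abort(sprintf("gene %s not found", gene))
  if (length(cells) == 0) abort("empty cell subset.")
  if (!all(cells %in% colnames(x$counts))) abort("unknown barcodes in subset.")
  mean(x$counts[gene, cells] > 0)
}

#' Positive-cell fractions on CAFs and NFs for all genes
#'
#' @param x A `caf_sample` (or list of them, pooled).
#' @param cells Annotated cell tibble with `barcode` and `fib_class`.
#' @return Tibble (gene, caf_frac, nf_frac).
#' @export
positive_fraction_table <- function(x, cells) {
  samples <- if (inherits(x, "caf_sample")) list(x) else x
  caf_cells <- cells$barcode[cells$fib_class == "CAF"]
  nf_cells <- cells$barcode[cells$fib_class == "NF"]
  if (length(caf_cells) == 0 || length(nf_cells) == 0) {
    abort("need both CAF and NF cells.")
  }
  pos_counts <- function(m, subset) {
    subset <- intersect(subset, colnames(m))
    list(pos = Matrix::rowSums(m[, subset, drop = FALSE] > 0),
         n = length(subset))
  }
  genes <- rownames(samples[[1]]$counts)
  caf_pos <- nf_pos <- setNames(numeric(length(genes)), genes)
  n_caf <- n_nf <- 0
  for (s in samples) {
    stopifnot(identical(rownames(s$counts), genes))
    pc <- pos_counts(s$counts, caf_cells)
    pn <- pos_counts(s$counts, nf_cells)
    caf_pos <- caf_pos + pc$pos
    nf_pos <- nf_pos + pn$pos
    n_caf <- n_caf + pc$n
    n_nf <- n_nf + pn$n
  }
  tibble(gene = genes, caf_frac = as.numeric(caf_pos / n_caf),
         nf_frac = as.numeric(nf_pos / n_nf))
}
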