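#' Per-gene Wilcoxon rank-sum differential expression
#'
#' Two-sided rank-sum test on normalized values between two cell groups,
#' with the average log2 fold change computed on back-transformed means:
#' `log2((mean(expm1 a) + ps) / (mean(expm1 b) + ps))`. Genes detected in
#' fewer than `min_frac` of the cells of both groups are skipped. The exact
#' null distribution is used where `wilcox.test` supports it (small groups,
#' no ties), the tie-corrected normal approximation otherwise.
#'
#' @param nm A `caf_norm`.
#' @param cells_a,cells_b Barcodes of the two groups (>= 3 cells each).
#' @param min_frac Minimum positive fraction required in at least one group.
#' @param pseudocount Added to both means before the fold-change log.
#' @param genes Genes to test (default: all).
#' @return Tibble (gene, p, p_adj, avg_log2fc, pct_a, pct_b); `p_adj` is
#'   Benjamini-Hochberg over the tested genes.
#' @export
wilcoxon_de <- function(nm, cells_a, cells_b, min_frac = 0.1,
                        pseudocount = 1e-9, genes = NULL) {
  stopifnot(inherits(nm, "caf_norm"))
  if (length(cells_a) < 3 || length(cells_b) < 3) {
    abort("both groups need at least 3 cells.")
  }
  a <- norm_values(nm, genes, cells_a)
  b <- norm_values(nm, genes, cells_b)
  pct_a <- rowMeans(a > 0)
  pct_b <- rowMeans(b > 0)
  keep <- pct_a >= min_frac | pct_b >= min_frac
  a <- a[keep, , drop = FALSE]
  b <- b[keep, , drop = FALSE]

  p <- vapply(seq_len(nrow(a)), function(i) {
    va <- a[i, ]
    vb <- b[i, ]
    if (all(va == va[1]) && all(vb == va[1])) return(1)
    suppressWarnings(wilcox.test(va, vb)$p.value)
  }, numeric(1))
  lfc <- log2((rowMeans(expm1(a)) + pseudocount) /
                (rowMeans(expm1(b)) + pseudocount))
  tibble(
    gene = rownames(a), p = p, p_adj = p.adjust(p, "BH"),
    avg_log2fc = as.numeric(lfc),
    pct_a = as.numeric(pct_a[keep]), pct_b = as.numeric(pct_b[keep])
  )
}

#' Robust markers across discovery samples
#'
#' Takes each sample's `top_n` lowest-p genes for one subtype, intersects
#' them, and drops any gene whose average log2 fold-change sign differs
#' between samples. The retained genes report arithmetic-mean p-values and
#' fold changes over samples.
#'
#' @param de_tables Named list (one per sample, >= 2) of [wilcoxon_de()]
#'   outputs for the same subtype-vs-rest contrast.
#' @param top_n Genes taken per sample before intersecting.
#' @return Tibble (gene, mean_p, mean_log2fc, n_samples) sorted by mean p;
#'   sign-inconsistent genes that were removed are recorded in the
#'   `"dropped_inconsistent"` attribute.
#' @export
robust_markers <- function(de_tables, top_n = 75) {
  if (length(de_tables) < 2) abort("need DE tables from at least 2 samples.")
  tops <- map(de_tables, function(d) {
    d |> arrange(.data$p, .data$gene) |> head(top_n)
  })
  shared <- reduce(map(tops, "gene"), intersect)
  if (length(shared) == 0) {
    inform("top gene lists have empty intersection; no robust markers.")
  }
  stats <- map_dfr(de_tables, ~ filter(.x, .data$gene %in% shared),
                   .id = "sample_id") |>
    group_by(.data$gene) |>
    summarise(
      mean_p = mean(.data$p),
      mean_log2fc = mean(.data$avg_log2fc),
      sign_consistent = dplyr::n_distinct(sign(.data$avg_log2fc)) == 1,
      n_samples = n(),
      .groups = "drop"
    )
  dropped <- stats$gene[!stats$sign_consistent]
  out <- stats |>
    filter(.data$sign_consistent) |>
    select(-"sign_consistent") |>
    arrange(.data$mean_p, .data$gene)
  attr(out, "dropped_inconsistent") <- dropped
  out
}
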