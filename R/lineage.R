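#' Ordering genes for trajectory construction
#'
#' Kruskal-Wallis test per gene across the fibroblast groups (CAF subtypes
#' plus NF), Benjamini-Hochberg adjusted; genes with adjusted p below
#' `alpha` are the ordering genes used to build the trajectory.
#'
#' @param nm A `caf_norm`.
#' @param cells Tibble with `barcode` and `group` (subtype labels and
#'   `"NF"`); at least two groups.
#' @param alpha Adjusted-p cutoff.
#' @param genes Candidate genes (default: all).
#' @return Character vector of ordering genes (adjusted-p order).
#' @export
select_ordering_genes <- function(nm, cells, alpha = 0.001, genes = NULL) {
  stopifnot(inherits(nm, "caf_norm"))
  g <- factor(cells$group)
  if (nlevels(g) < 2) abort("need at least two fibroblast groups.")
  x <- norm_values(nm, genes, cells$barcode)
  variable <- apply(x, 1, function(v) any(v != v[1]))
  x <- x[variable, , drop = FALSE]
  p <- vapply(seq_len(nrow(x)), function(i) {
    kruskal.test(x[i, ], g)$p.value
  }, numeric(1))
  p_adj <- p.adjust(p, "BH")
  hits <- rownames(x)[!is.na(p_adj) & p_adj < alpha]
  if (length(hits) < 10) {
    abort(sprintf(
      "only %d gene(s) pass adjusted p < %g; consider relaxing alpha.",
      length(hits), alpha
    ))
  }
  hits[order(p_adj[match(hits, rownames(x))], hits)]
}

#' Fit a simple one-dimensional pseudotime
#'
#' The default trajectory is deliberately lightweight: cells are embedded
#' in a few principal components of the scaled ordering genes, a piecewise
#' linear curve is threaded through the group centroids — ordered as the
#' shortest path that starts at the NF (anchor) centroid and visits every
#' centroid once (enumerated exactly for up to 8 groups, greedy
#' nearest-neighbor beyond that) — and each cell's pseudotime is its arc
#' length along the curve at its nearest projection. The anchoring
#' guarantees NF cells sit at the origin of the axis regardless of
#' component sign flips. Externally computed pseudotime can be supplied to
#' downstream steps instead — the correlation ranking does not depend on
#' the trajectory method.
#'
#' @param nm A `caf_norm`.
#' @param cells Tibble with `barcode` and `group` covering the fibroblasts.
#' @param ordering_genes Genes from [select_ordering_genes()] (>= 10).
#' @param anchor Group anchoring the start of the axis (default `"NF"`).
#' @param n_dims Principal components used for the curve. Two components
#'   cannot separate more than a few distinct expression programs, so the
#'   default keeps 10 (capped by the data).
#' @param clip Z-score clip used when scaling ordering genes.
#' @return Tibble (barcode, pseudotime) with method metadata attached.
#' @export
fit_pseudotime <- function(nm, cells, ordering_genes, anchor = "NF",
                           n_dims = 10, clip = 10) {
  stopifnot(inherits(nm, "caf_norm"))
  if (length(ordering_genes) < 10) abort("need at least 10 ordering genes.")
  if (!anchor %in% cells$group) {
    abort(sprintf("anchor group '%s' absent; supply an anchor subtype.", anchor))
  }
  x <- norm_values(nm, ordering_genes, cells$barcode)
  mu <- rowMeans(x)
  s <- apply(x, 1, sd)
  s[s == 0] <- 1
  z <- pmin(pmax((x - mu) / s, -clip), clip)
  n_dims <- min(n_dims, length(ordering_genes) - 1L, ncol(x) - 1L)
  emb <- prcomp(t(z), center = FALSE, rank. = n_dims)$x

  groups <- split(seq_len(nrow(emb)), cells$group)
  centroids <- do.call(rbind, map(groups, ~ colMeans(emb[.x, , drop = FALSE])))

  path <- centroids[order_centroid_path(centroids,
                                        match(anchor, rownames(centroids))), ,
                    drop = FALSE]

  seg_start <- path[-nrow(path), , drop = FALSE]
  seg_vec <- path[-1, , drop = FALSE] - seg_start
  seg_len <- sqrt(rowSums(seg_vec^2))
  cum_len <- c(0, cumsum(seg_len))

  project <- function(pt) {
    best <- c(Inf, 0)
    for (j in seq_len(nrow(seg_start))) {
      v <- seg_vec[j, ]
      w <- pt - seg_start[j, ]
      tt <- if (seg_len[j] == 0) 0 else
        min(max(sum(w * v) / sum(v * v), 0), 1)
      dd <- sum((w - tt * v)^2)
      if (dd < best[1]) best <- c(dd, cum_len[j] + tt * seg_len[j])
    }
    best[2]
  }
  pt <- apply(emb, 1, project)

  is_anchor <- cells$group == anchor
  if (mean(pt[is_anchor]) > mean(pt[!is_anchor])) pt <- max(pt) - pt
  out <- tibble(barcode = cells$barcode, pseudotime = as.numeric(pt))
  attr(out, "method") <- "principal_curve_lite"
  attr(out, "ordering_genes") <- ordering_genes
  out
}

# (internal)
# Order centroids as the shortest Hamiltonian path anchored at `start`.
# With k - 1 <= 7 free centroids the (k-1)! permutations are enumerated
# exactly; larger problems fall back to the greedy nearest-neighbor chain.
# Exhaustive ordering matters here: between discrete expression states the
# inter-centroid distances are nearly equal, and only the continuous
# differentiation component makes the sorted order the shortest — a local
# greedy choice can take an early wrong turn the global minimum avoids.
order_centroid_path <- function(centroids, start) {
  k <- nrow(centroids)
  rest <- setdiff(seq_len(k), start)
  d <- as.matrix(stats::dist(centroids))
  if (length(rest) <= 7) {
    perms <- perm_all(rest)
    len <- vapply(perms, function(p) {
      sum(d[cbind(c(start, p[-length(p)]), p)])
    }, numeric(1))
    return(c(start, perms[[which.min(len)]]))
  }
  order_idx <- start
  remaining <- rest
  while (length(remaining)) {
    nxt <- remaining[which.min(d[order_idx[length(order_idx)], remaining])]
    order_idx <- c(order_idx, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  order_idx
}

perm_all <- function(v) {
  if (length(v) <= 1) return(list(v))
  unlist(lapply(seq_along(v), function(i) {
    lapply(perm_all(v[-i]), function(p) c(v[i], p))
  }), recursive = FALSE)
}

#' Mean pseudotime-expression correlation across samples
#'
#' Per sample, the Spearman correlation between pseudotime and the
#' normalized expression of every gene measured in all samples; then the
#' arithmetic mean over samples. Genes with zero variance in a sample get
#' correlation 0 there and are flagged.
#'
#' @param nm_list Named list of `caf_norm` objects.
#' @param pt_list Named list of pseudotime tibbles (barcode, pseudotime);
#'   entries that are `NULL` are skipped with a message.
#' @param genes Gene universe (default: intersection across samples).
#' @return Tibble (gene, mean_rho, n_samples, zero_var_flag).
#' @export
pseudotime_gene_correlation <- function(nm_list, pt_list, genes = NULL) {
  use <- names(nm_list)[vapply(names(nm_list),
                               function(s) !is.null(pt_list[[s]]), logical(1))]
  skipped <- setdiff(names(nm_list), use)
  if (length(skipped)) {
    inform(sprintf("skipping sample(s) without pseudotime: %s",
                   paste(skipped, collapse = ", ")))
  }
  if (length(use) == 0) abort("no sample has pseudotime.")
  genes <- genes %||% reduce(map(nm_list[use], ~ rownames(.x$data)), intersect)

  rho <- matrix(NA_real_, length(genes), length(use),
                dimnames = list(genes, use))
  flagged <- setNames(rep(FALSE, length(genes)), genes)
  for (s in use) {
    pt <- pt_list[[s]]
    x <- norm_values(nm_list[[s]], genes, pt$barcode)
    r <- suppressWarnings(cor(t(x), pt$pseudotime, method = "spearman"))[, 1]
    flagged <- flagged | is.na(r)
    r[is.na(r)] <- 0
    rho[, s] <- r
  }
  tibble(
    gene = genes, mean_rho = unname(rowMeans(rho)), n_samples = length(use),
    zero_var_flag = as.logical(flagged)
  )
}

#' Lineage-specific gene selection
#'
#' The published selection logic: keep genes commonly expressed in CAFs
#' (positive fraction at least `caf_min_frac`), rarely expressed in NFs
#' (at most `nf_max_frac`), and rising along pseudotime (mean Spearman
#' correlation at least `rho_min`); rank by mean correlation, descending.
#'
#' @param rho_tbl Output of [pseudotime_gene_correlation()].
#' @param pos_tbl Output of [positive_fraction_table()].
#' @param caf_min_frac,nf_max_frac,rho_min Selection thresholds.
#' @return Tibble (gene, mean_rho, caf_frac, nf_frac), best first.
#' @export
lineage_specific_genes <- function(rho_tbl, pos_tbl, caf_min_frac = 0.25,
                                   nf_max_frac = 0.05, rho_min = 0.3) {
  inner_join(rho_tbl, pos_tbl, by = "gene") |>
    filter(.data$caf_frac >= caf_min_frac,
           .data$nf_frac <= nf_max_frac,
           .data$mean_rho >= rho_min) |>
    arrange(desc(.data$mean_rho), .data$gene) |>
    select("gene", "mean_rho", "caf_frac", "nf_frac")
}

#' Correlation between one gene and marker gene-set scores
#'
#' Spearman correlation between a gene's normalized expression and the
#' per-cell mean normalized expression of each marker set, over a stated
#' cell subset.
#'
#' @param nm A `caf_norm`.
#' @param gene Gene of interest.
#' @param sets Named list of gene-id vectors.
#' @param cells Barcodes of the cell subset to correlate over.
#' @return Tibble (set, rho, n_genes).
#' @export
marker_set_correlation <- function(nm, gene, sets, cells) {
  stopifnot(inherits(nm, "caf_norm"))
  gx <- norm_values(nm, gene, cells)[1, ]
  map_dfr(names(sets), function(nm_set) {
    present <- intersect(sets[[nm_set]], rownames(nm$data))
    if (length(present) == 0) {
      abort(sprintf("gene set '%s' has no gene in the matrix.", nm_set))
    }
    score <- colMeans(norm_values(nm, present, cells))
    tibble(
      set = nm_set,
      rho = suppressWarnings(cor(gx, score, method = "spearman")),
      n_genes = length(present)
    )
  })
}
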