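#' Enrichment score of a gene set in a ranked list
#'
#' The weighted Kolmogorov-Smirnov running-sum statistic of preranked
#' gene-set enrichment: walking down the ranking, hits increment the sum
#' proportionally to `|score|^weight` (normalized over the set) and misses
#' decrement it uniformly; the enrichment score is the signed extremum.
#' When the set spans the whole ranking there are no misses and the score
#' is 0 by convention. If every hit has score 0 the hit increments fall
#' back to equal weights.
#'
#' @param scores Named numeric vector of ranking scores.
#' @param gene_set Character vector of member genes.
#' @param weight Hit-weight exponent (0 = classic KS).
#' @return The enrichment score in `[-1, 1]`.
#' @export
gsea_es <- function(scores, gene_set, weight = 1) {
  ord <- order(-scores, names(scores))
  s <- scores[ord]
  pos <- which(names(s) %in% gene_set)
  if (length(pos) == 0) abort("gene set is disjoint from the ranking.")
  es_at_positions(abs(s)^weight, pos)
}

# (internal)
# Enrichment score from sorted hit positions. Between hits the running
# sum falls linearly, so its extrema lie at a hit (just after the
# increment) or immediately before one; only those candidates are
# evaluated.
es_at_positions <- function(w_all, pos) {
  n <- length(w_all)
  k <- length(pos)
  n_miss <- n - k
  if (n_miss == 0) return(0)
  w <- w_all[pos]
  if (sum(w) == 0) w <- rep(1, k)
  cum_hit <- cumsum(w) / sum(w)
  miss_before <- (pos - seq_len(k)) / n_miss
  after_hit <- cum_hit - miss_before
  before_hit <- c(0, cum_hit[-k]) - miss_before
  # evaluate candidates in walk order so magnitude ties (exact in rational
  # arithmetic, 1e-16 apart in floats) resolve to the earliest extremum,
  # as a full cumulative walk would
  ord <- order(c(pos - 1L, pos))
  cand <- c(before_hit, after_hit)[ord]
  m <- max(abs(cand))
  unname(cand[which(abs(cand) >= m - 1e-12)[1]])
}

#' Preranked gene-set enrichment with permutation normalization
#'
#' Computes the enrichment score of [gsea_es()], then normalizes it
#' against gene-label permutations: random sets of the same size are drawn
#' from the ranking, the normalized enrichment score is the observed score
#' divided by the mean magnitude of same-sign permuted scores, and the
#' nominal p-value is the same-sign permutation tail fraction (add-one
#' corrected).
#'
#' @param scores Named numeric vector of ranking scores.
#' @param gene_set Character vector; at least 3 members must be in the
#'   ranking.
#' @param weight Hit-weight exponent.
#' @param n_perm Number of gene-label permutations.
#' @param seed Integer seed.
#' @param set_id Optional label carried into the result.
#' @return Tibble (set, es, nes, p, n_hits).
#' @export
preranked_gsea <- function(scores, gene_set, weight = 1, n_perm = 999,
                           seed = 0, set_id = NA_character_) {
  stopifnot(all(is.finite(scores)))
  overlap <- intersect(names(scores), gene_set)
  if (length(overlap) == 0) abort("gene set is disjoint from the ranking.")
  if (length(overlap) < 3) abort("need at least 3 set genes in the ranking.")
  es <- gsea_es(scores, overlap, weight)

  set.seed(seed)
  n <- length(scores)
  k <- length(overlap)
  w_all <- abs(scores[order(-scores, names(scores))])^weight
  perm_es <- vapply(seq_len(n_perm), function(b) {
    es_at_positions(w_all, sort(sample.int(n, k)))
  }, numeric(1))

  if (es == 0) {
    nes <- 0
    p <- 1
  } else {
    same <- perm_es[sign(perm_es) == sign(es)]
    nes <- if (length(same)) es / mean(abs(same)) else NA_real_
    p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  }
  tibble(set = set_id, es = es, nes = nes, p = p, n_hits = k)
}

#' Ranking metric for GSEA from a two-group comparison
#'
#' Signed significance from the per-gene Wilcoxon test:
#' `sign(log2FC) * -log10(p)`, sorted descending with deterministic
#' lexicographic tie-breaking.
#'
#' @param nm A `caf_norm`.
#' @param cells_a,cells_b Barcodes of the two groups (e.g. marker-positive
#'   vs marker-negative CAFs).
#' @return Named numeric vector of ranking scores, best first.
#' @export
rank_genes_for_gsea <- function(nm, cells_a, cells_b) {
  de <- wilcoxon_de(nm, cells_a, cells_b, min_frac = 0)
  score <- sign(de$avg_log2fc) * -log10(pmax(de$p, .Machine$double.xmin))
  names(score) <- de$gene
  score[order(-score, names(score))]
}

#' Average enrichment across discovery samples
#'
#' Arithmetic mean of the normalized enrichment score and nominal p-value
#' per gene set over samples, optionally restricted to sets whose name
#' matches a filter (e.g. `"MESEN|FIBRO"`).
#'
#' @param results Tibble of per-sample [preranked_gsea()] rows with a
#'   `sample` column.
#' @param name_filter Optional regular expression on set names.
#' @return Tibble (set, mean_nes, mean_p, n_samples).
#' @export
average_enrichment <- function(results, name_filter = NULL) {
  if (!is.null(name_filter)) {
    results <- filter(results, grepl(name_filter, .data$set))
  }
  results |>
    group_by(.data$set) |>
    summarise(
      mean_nes = mean(.data$nes), mean_p = mean(.data$p),
      n_samples = n(), .groups = "drop"
    ) |>
    arrange(desc(abs(.data$mean_nes)))
}
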