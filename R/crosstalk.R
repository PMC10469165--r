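#' Permutation score for one ligand-receptor pair
#'
#' The interaction score is the product of group means of back-transformed
#' expression: `mean(expm1 ligand | senders) * mean(expm1 receptor |
#' receivers)`. Significance is the permutation tail probability of the
#' score under random relabeling of the pooled sender/receiver membership
#' (`n_perm` permutations, add-one correction), so `p` lies in `(0, 1]`
#' and a pair with a silent ligand or receptor scores 0 with `p = 1`.
#'
#' @param nm A `caf_norm`.
#' @param ligand,receptor Gene ids.
#' @param sender_cells,receiver_cells Barcodes (>= 10 each).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return Tibble (ligand, receptor, score, p).
#' @export
lr_score <- function(nm, ligand, receptor, sender_cells, receiver_cells,
                     n_perm = 999, seed = 0) {
  stopifnot(inherits(nm, "caf_norm"))
  if (length(sender_cells) < 10 || length(receiver_cells) < 10) {
    abort("sender and receiver groups need at least 10 cells.")
  }
  res <- score_pairs_permuted(
    nm, tibble(ligand = ligand, receptor = receptor),
    sender_cells, receiver_cells, n_perm, seed
  )
  res[, c("ligand", "receptor", "score", "p")]
}

# (internal)
# Shared-permutation scoring of many LR pairs for one sender/receiver
# group pair. Pool ordering is canonicalized by barcode so results do not
# depend on cell order.
score_pairs_permuted <- function(nm, pairs, sender_cells, receiver_cells,
                                 n_perm, seed) {
  senders <- sort(sender_cells)
  receivers <- sort(receiver_cells)
  pool <- c(senders, receivers)
  n_s <- length(senders)
  n <- length(pool)

  lig <- expm1(norm_values(nm, unique(pairs$ligand), pool))
  rec <- expm1(norm_values(nm, unique(pairs$receptor), pool))
  lig_mean <- rowMeans(lig[pairs$ligand, seq_len(n_s), drop = FALSE])
  rec_mean <- rowMeans(rec[pairs$receptor, -seq_len(n_s), drop = FALSE])
  obs <- lig_mean * rec_mean

  set.seed(seed)
  perm <- replicate(n_perm, sample.int(n))
  send_ind <- Matrix::sparseMatrix(
    i = as.vector(perm[seq_len(n_s), ]),
    j = rep(seq_len(n_perm), each = n_s),
    x = 1 / n_s, dims = c(n, n_perm)
  )
  recv_ind <- Matrix::sparseMatrix(
    i = as.vector(perm[-seq_len(n_s), ]),
    j = rep(seq_len(n_perm), each = n - n_s),
    x = 1 / (n - n_s), dims = c(n, n_perm)
  )
  perm_lig <- as.matrix(lig[pairs$ligand, , drop = FALSE] %*% send_ind)
  perm_rec <- as.matrix(rec[pairs$receptor, , drop = FALSE] %*% recv_ind)
  p <- (1 + rowSums(perm_lig * perm_rec >= obs)) / (n_perm + 1)

  mutate(pairs, score = as.numeric(obs), p = as.numeric(p))
}

#' Score all ligand-receptor pairs over all group pairs in one sample
#'
#' Every (LR pair, sender group, receiver group) combination with distinct
#' groups of at least `min_cells` cells is a candidate. A combination is
#' only tested when the ligand is detected in at least `min_pct` of the
#' sender cells and the receptor in at least `min_pct` of the receiver
#' cells — the usual expression gate of ligand-receptor tools, which also
#' keeps the number of permutation tests commensurate with the `1 /
#' (n_perm + 1)` p-value floor. Tested combinations are scored with
#' [lr_score()]'s permutation scheme (permutations shared within a group
#' pair), p-values are Benjamini-Hochberg adjusted within the sample, and
#' combinations with `q <= alpha` are returned. The complete tested table
#' is attached as the `"all"` attribute.
#'
#' @param nm A `caf_norm`.
#' @param cells Tibble with `barcode` and `group` (cancer subclusters,
#'   T cells, myeloid cells, endothelial cells, CAF subtypes, ...).
#' @param lr_table Tibble with `ligand` and `receptor` columns.
#' @param alpha BH-adjusted significance cutoff.
#' @param n_perm,seed Permutation settings.
#' @param min_cells Minimum group size scored.
#' @param min_pct Minimum detection fraction of the ligand (in senders)
#'   and receptor (in receivers) for a combination to be tested.
#' @return Tibble (sample, ligand, receptor, sender, receiver, score, p, q)
#'   of significant interactions.
#' @export
sample_interactions <- function(nm, cells, lr_table, alpha = 0.1,
                                n_perm = 999, seed = 0, min_cells = 10,
                                min_pct = 0.1) {
  stopifnot(inherits(nm, "caf_norm"))
  cells <- filter(cells, !is.na(.data$group))
  sizes <- table(cells$group)
  groups <- sort(names(sizes)[sizes >= min_cells])

  present <- lr_table$ligand %in% rownames(nm$data) &
    lr_table$receptor %in% rownames(nm$data)
  if (any(!present)) {
    inform(sprintf("skipping %d LR pair(s) with missing genes", sum(!present)))
  }
  pairs <- distinct(lr_table[present, c("ligand", "receptor")])

  # detection fraction of every ligand/receptor gene in every group
  lr_genes <- unique(c(pairs$ligand, pairs$receptor))
  det <- norm_values(nm, lr_genes, cells$barcode) > 0
  pct <- vapply(groups, function(g) {
    rowMeans(det[, cells$group == g, drop = FALSE])
  }, numeric(length(lr_genes)))
  rownames(pct) <- lr_genes

  combos <- list()
  i <- 0L
  for (snd in groups) {
    for (rcv in groups) {
      if (snd == rcv) next
      i <- i + 1L
      tested <- pairs[pct[pairs$ligand, snd] >= min_pct &
                        pct[pairs$receptor, rcv] >= min_pct, ]
      if (nrow(tested) == 0) next
      res <- score_pairs_permuted(
        nm, tested,
        cells$barcode[cells$group == snd],
        cells$barcode[cells$group == rcv],
        n_perm, seed + i
      )
      combos[[length(combos) + 1L]] <- mutate(res, sender = snd, receiver = rcv)
    }
  }
  all_scored <- bind_rows(combos) |>
    mutate(sample = nm$sample_id, q = p.adjust(.data$p, "BH")) |>
    select("sample", "ligand", "receptor", "sender", "receiver",
           "score", "p", "q")
  out <- filter(all_scored, .data$q <= alpha)
  attr(out, "all") <- all_scored
  out
}

#' Interactions shared by all samples
#'
#' Within each sample, keeps the interactions that touch a CAF group
#' (sender or receiver matching `caf_pattern`), collapses group labels to
#' types with `collapse` (dropping numbered subcluster suffixes), and then
#' intersects the interaction identities (ligand, receptor, sender type,
#' receiver type) across samples.
#'
#' @param int_list List (>= 2) of [sample_interactions()] outputs.
#' @param caf_pattern Regular expression identifying CAF groups.
#' @param collapse Function mapping a group label to its type label.
#' @return Tibble (ligand, receptor, sender, receiver, n_samples) of
#'   interactions present in every sample.
#' @export
common_interactions <- function(int_list, caf_pattern = "^CAF|^ST",
                                collapse = function(g) sub("_[0-9]+$", "", g)) {
  if (length(int_list) < 2) abort("need interaction sets from at least 2 samples.")
  per_sample <- map(int_list, function(d) {
    d |>
      filter(grepl(caf_pattern, .data$sender) |
               grepl(caf_pattern, .data$receiver)) |>
      mutate(sender = collapse(.data$sender),
             receiver = collapse(.data$receiver)) |>
      distinct(.data$ligand, .data$receptor, .data$sender, .data$receiver)
  })
  shared <- reduce(per_sample, function(a, b) {
    inner_join(a, b, by = c("ligand", "receptor", "sender", "receiver"))
  })
  mutate(shared, n_samples = length(int_list))
}

#' Paired comparison of per-sample interaction frequencies
#'
#' Wilcoxon signed-rank test on the paired per-sample interaction counts
#' of two subtypes (exact null where available, i.e. small n without
#' ties). Reports the dominant direction, the two-sided p, and the
#' one-sided p in that direction.
#'
#' @param count_a,count_b Paired per-sample interaction counts.
#' @return Tibble (n, direction, statistic, p_two_sided, p_one_sided).
#' @export
interaction_frequency_compare <- function(count_a, count_b) {
  stopifnot(length(count_a) == length(count_b))
  d <- count_a - count_b
  if (all(d == 0)) {
    return(tibble(n = length(d), direction = "none", statistic = NA_real_,
                  p_two_sided = 1, p_one_sided = 1))
  }
  direction <- if (sum(sign(d)) >= 0) "a_greater" else "b_greater"
  alt <- if (direction == "a_greater") "greater" else "less"
  two <- suppressWarnings(wilcox.test(count_a, count_b, paired = TRUE))
  one <- suppressWarnings(
    wilcox.test(count_a, count_b, paired = TRUE, alternative = alt)
  )
  tibble(
    n = length(d), direction = direction,
    statistic = unname(two$statistic),
    p_two_sided = two$p.value, p_one_sided = one$p.value
  )
}
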