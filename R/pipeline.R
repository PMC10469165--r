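#' @noRd
subset_cells_norm <- function(nm, barcodes) {
  keep <- match(barcodes, colnames(nm$data))
  new_caf_norm(nm$data[, keep, drop = FALSE],
               nm$meta[keep, , drop = FALSE], nm$sample_id, nm$scale_factor)
}

#' Run the discovery workflow end to end
#'
#' Executes the full analysis on a synthetic study (or user-supplied
#' inputs): per-sample QC and log-normalization; reference-correlation
#' typing with the fibroblast marker rule; per-sample CAF subclustering on
#' the intersected variable features; canonical-correlation matching of
#' subclusters into shared subtypes; robust marker discovery for the
#' marker-bearing (lineage) subtype; pseudotime fitting and
#' pseudotime-correlated lineage-gene selection; permutation-scored
#' ligand-receptor cross-talk with cross-sample aggregation and the paired
#' frequency comparison; preranked enrichment of marker-positive vs
#' marker-negative CAFs; and bulk signature scoring with survival
#' analysis.
#'
#' @param cfg A [caf_sim_config()]; defines both the synthetic inputs and
#'   the seed.
#' @param inputs Optional list overriding the simulated inputs: `samples`
#'   (list of `caf_sample`), `reference`, `lr_table`, `gene_sets`, `bulk`
#'   (a `caf_bulk`).
#' @param scale_factor Normalization target passed to [log_normalize()];
#'   the default `NULL` (median library size) keeps per-gene means on the
#'   scale the variable-feature mean window expects for a compact gene
#'   universe.
#' @param resolution Louvain resolution for CAF subclustering.
#' @param k_neighbors Neighborhood size for the SNN graph.
#' @param n_pcs Principal components used for subclustering.
#' @param n_perm Permutations for LR scoring and GSEA.
#' @param lr_alpha BH cutoff for significant interactions.
#' @param top_n Genes per sample entering the robust-marker intersection.
#' @param out_dir Optional directory; stage tables are written as TSV.
#' @return A `caf_pipeline` list with all stage outputs and a one-row
#'   `summary` tibble.
#' @export
run_caf_pipeline <- function(cfg = caf_sim_config(), inputs = NULL,
                             scale_factor = NULL, resolution = 0.6,
                             k_neighbors = 20, n_pcs = 15, n_perm = 999,
                             lr_alpha = 0.1, top_n = 75, out_dir = NULL) {
  stopifnot(inherits(cfg, "caf_sim_config"))
  marker <- cfg$marker_gene_id

  if (is.null(inputs)) {
    sim <- simulate_sc_samples(cfg)
    inputs <- list(
      samples = sim$samples,
      reference = simulate_reference_profiles(cfg),
      lr_table = simulate_lr_database(cfg),
      gene_sets = simulate_gene_sets(cfg),
      bulk = simulate_bulk_cohort(cfg)$cohort
    )
  }

  # --- QC and normalization -------------------------------------------
  filtered <- map(inputs$samples, filter_cells)
  nms <- map(filtered, log_normalize, scale_factor = scale_factor)

  # --- cell typing and fibroblast annotation --------------------------
  cells <- map2(nms, filtered, function(nm, fs) {
    classify_reference(nm, inputs$reference) |>
      left_join(fs$meta, by = "barcode") |>
      mutate(sample = fs$sample_id) |>
      annotate_fibroblasts(fs)
  }) |>
    bind_rows()

  # --- CAF subclustering on intersected variable features -------------
  caf_barcodes <- split(
    cells$barcode[cells$fib_class == "CAF"],
    cells$sample[cells$fib_class == "CAF"]
  )
  caf_nms <- map(names(nms), function(s) subset_cells_norm(nms[[s]], caf_barcodes[[s]]))
  names(caf_nms) <- names(nms)
  var_sets <- map(caf_nms, select_variable_genes, n_top = 1000)
  common_features <- common_variable_features(var_sets)

  clusterings <- map(caf_nms, function(nm) {
    pca <- scale_and_pca(nm, common_features,
                         n_pcs = min(n_pcs, length(common_features)))
    snn_cluster(pca$embedding, k_neighbors = k_neighbors,
                resolution = resolution, seed = cfg$seed)
  })
  cells <- cells |>
    left_join(
      bind_rows(clusterings) |> rename(caf_cluster = "cluster"),
      by = "barcode"
    )

  # --- canonical-correlation subtype matching -------------------------
  profiles <- map(names(caf_nms), function(s) {
    cl <- clusterings[[s]]
    keep <- names(which(table(cl$cluster) >= 3))
    out <- map(keep, function(k) {
      norm_values(caf_nms[[s]], common_features,
                  cl$barcode[cl$cluster == as.integer(k)])
    })
    names(out) <- paste0("c", keep)
    out
  })
  names(profiles) <- names(caf_nms)
  correspondence <- match_clusters(profiles)

  cells <- cells |>
    left_join(
      correspondence$assignment |>
        mutate(caf_cluster = as.integer(sub("^c", "", .data$cluster))) |>
        select("sample", "caf_cluster", "subtype"),
      by = c("sample", "caf_cluster")
    )

  # lineage subtype = the matched subtype with the highest marker
  # positive fraction among CAFs
  marker_pos <- map_dfr(filtered, function(fs) {
    tibble(barcode = colnames(fs$counts),
           marker_pos = as.numeric(fs$counts[marker, ] > 0))
  })
  cells <- left_join(cells, marker_pos, by = "barcode")
  subtype_stats <- cells |>
    filter(.data$fib_class == "CAF", !is.na(.data$subtype)) |>
    group_by(.data$subtype) |>
    summarise(marker_frac = mean(.data$marker_pos), n = n(), .groups = "drop")
  lineage_subtype <- subtype_stats$subtype[which.max(subtype_stats$marker_frac)]

  # --- robust markers of the lineage subtype --------------------------
  de_tables <- map(names(caf_nms), function(s) {
    sc <- filter(cells, .data$sample == s, .data$fib_class == "CAF",
                 !is.na(.data$subtype))
    wilcoxon_de(nms[[s]],
                sc$barcode[sc$subtype == lineage_subtype],
                sc$barcode[sc$subtype != lineage_subtype])
  })
  names(de_tables) <- names(caf_nms)
  markers <- robust_markers(de_tables, top_n = top_n)

  # --- pseudotime and lineage genes -----------------------------------
  fib_cells <- cells |>
    filter(.data$fib_class == "NF" |
             (.data$fib_class == "CAF" & !is.na(.data$subtype))) |>
    mutate(group = ifelse(.data$fib_class == "NF", "NF", .data$subtype))
  pt_list <- map(names(nms), function(s) {
    fc <- filter(fib_cells, .data$sample == s)
    og <- select_ordering_genes(nms[[s]], fc)
    fit_pseudotime(nms[[s]], fc, og)
  })
  names(pt_list) <- names(nms)

  rho <- pseudotime_gene_correlation(
    map(names(nms), function(s) {
      subset_cells_norm(nms[[s]], pt_list[[s]]$barcode)
    }) |> setNames(names(nms)),
    pt_list
  )
  pos_tbl <- positive_fraction_table(filtered, cells)
  lineage_genes <- lineage_specific_genes(rho, pos_tbl)

  # --- ligand-receptor cross-talk -------------------------------------
  comm_cells <- cells |>
    mutate(group = dplyr::case_when(
      .data$fib_class == "CAF" & !is.na(.data$subtype) ~ .data$subtype,
      .data$type_refined %in% c("Cancer", "Endothelial", "T cell", "Myeloid") ~
        .data$type_refined,
      .default = NA_character_
    ))
  interactions <- map(names(nms), function(s) {
    sample_interactions(nms[[s]],
                        filter(comm_cells, .data$sample == s),
                        inputs$lr_table, alpha = lr_alpha,
                        n_perm = n_perm, seed = cfg$seed)
  })
  names(interactions) <- names(nms)
  shared_interactions <- common_interactions(interactions,
                                             caf_pattern = "^ST")
  freq <- map_dfr(names(interactions), function(s) {
    d <- interactions[[s]]
    other <- setdiff(unique(cells$subtype[!is.na(cells$subtype)]),
                     lineage_subtype)
    tibble(
      sample = s,
      incoming_lineage = sum(d$receiver == lineage_subtype),
      incoming_other = sum(d$receiver %in% other) / max(length(other), 1),
      outgoing_lineage = sum(d$sender == lineage_subtype),
      outgoing_other = sum(d$sender %in% other) / max(length(other), 1)
    )
  })
  freq_test <- interaction_frequency_compare(freq$incoming_lineage,
                                             freq$incoming_other)

  # --- enrichment: marker-positive vs marker-negative CAFs ------------
  enrichment <- map_dfr(names(nms), function(s) {
    sc <- filter(cells, .data$sample == s, .data$fib_class == "CAF")
    pos <- sc$barcode[sc$marker_pos > 0]
    neg <- sc$barcode[sc$marker_pos == 0]
    ranking <- rank_genes_for_gsea(nms[[s]], pos, neg)
    map_dfr(names(inputs$gene_sets), function(gs) {
      preranked_gsea(ranking, inputs$gene_sets[[gs]], n_perm = n_perm,
                     seed = cfg$seed, set_id = gs)
    }) |>
      mutate(sample = s)
  })
  enrichment_avg <- average_enrichment(enrichment)

  # --- bulk signature and survival ------------------------------------
  bulk <- inputs$bulk
  score <- signature_score(bulk, markers$gene)
  abundance <- caf_abundance(bulk, intersect(
    c("DCN", "COL3A1", "THY1", "VIM", "LUM", "FBLN1", "PDGFRA"),
    colnames(bulk$expr)
  ))
  abundance_cor <- cor(score$score, abundance$abundance, method = "spearman")
  surv <- survival_by_signature(bulk, score)
  stage_bin <- bin_stage(bulk$clinical$stage)
  stage_cmp <- group_compare(score$score, stage_bin)
  stage_prop <- subtype_proportion_by_stage(cells, lineage_subtype)

  top_gene <- if (nrow(lineage_genes)) lineage_genes$gene[1] else NA_character_
  summary <- tibble(
    lineage_subtype = lineage_subtype,
    lineage_name = paste0(top_gene, "+"),
    top_lineage_gene = top_gene,
    marker_rank = match(marker, lineage_genes$gene),
    n_robust_markers = nrow(markers),
    n_common_interactions = nrow(shared_interactions),
    freq_p_one_sided = freq_test$p_one_sided,
    logrank_p = surv$logrank$p,
    cox_score_hr = surv$cox_continuous$hr[surv$cox_continuous$term == "score"],
    abundance_cor = abundance_cor
  )

  out <- structure(
    list(
      config = cfg, cells = cells, qc = map(filtered, qc_report),
      common_features = common_features, correspondence = correspondence,
      subtype_stats = subtype_stats, lineage_subtype = lineage_subtype,
      markers = markers, de_tables = de_tables, pseudotime = pt_list,
      rho = rho,
      positive_fractions = pos_tbl, lineage_genes = lineage_genes,
      interactions = interactions, common_interactions = shared_interactions,
      interaction_frequency = freq, freq_test = freq_test,
      enrichment = enrichment, enrichment_avg = enrichment_avg,
      signature_score = score, abundance = abundance,
      survival = surv, stage_compare = stage_cmp,
      stage_proportions = stage_prop, summary = summary
    ),
    class = "caf_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

#' @exportS3Method base::print
print.caf_pipeline <- function(x, ...) {
  cat("<caf_pipeline>\n")
  cat(sprintf("  lineage subtype: %s (%s), marker rank %s\n",
              x$lineage_subtype, x$summary$lineage_name,
              x$summary$marker_rank))
  cat(sprintf("  robust markers: %d; lineage genes: %d; common interactions: %d\n",
              nrow(x$markers), nrow(x$lineage_genes),
              nrow(x$common_interactions)))
  cat(sprintf("  paired frequency p = %.3g; log-rank p = %.3g; Cox HR = %.2f\n",
              x$summary$freq_p_one_sided, x$summary$logrank_p,
              x$summary$cox_score_hr))
  invisible(x)
}

#' @noRd
write_pipeline_outputs <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(d, name) readr::write_tsv(d, file.path(out_dir, name))
  w(x$cells, "cells.tsv")
  w(x$correspondence$assignment, "correspondence.tsv")
  w(x$markers, "robust_markers.tsv")
  w(bind_rows(x$pseudotime, .id = "sample"), "pseudotime.tsv")
  w(x$lineage_genes, "lineage_genes.tsv")
  w(bind_rows(x$interactions), "interactions.tsv")
  w(x$common_interactions, "common_interactions.tsv")
  w(x$enrichment_avg, "enrichment.tsv")
  w(inner_join(x$signature_score, x$abundance, by = "sample"), "bulk_scores.tsv")
  w(tidy(x$survival), "cox.tsv")
  w(x$summary, "summary.tsv")
  cfg_lines <- utils::capture.output(utils::str(unclass(x$config)))
  writeLines(cfg_lines, file.path(out_dir, "config.txt"))
  invisible(out_dir)
}

#' Heatmap of the cluster-to-subtype correspondence
#'
#' @param object A `caf_correspondence` from [match_clusters()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.caf_correspondence <- function(object, ...) {
  d <- object$assignment
  ggplot2::ggplot(d, ggplot2::aes(.data$sample, .data$cluster,
                                  fill = .data$subtype)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$cc1), "", sprintf("%.2f", .data$cc1))
    ), size = 3) +
    ggplot2::labs(x = "Sample", y = "CAF subcluster", fill = "Subtype",
                  title = "Cross-sample subtype correspondence") +
    ggplot2::theme_minimal()
}
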