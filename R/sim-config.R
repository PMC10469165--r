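#' Configuration for the synthetic multi-sample study
#'
#' Builds the configuration object consumed by all `simulate_*()` generators.
#' The defaults define the study conditions the package is exercised under:
#' three discovery samples sharing six CAF subtypes, one of which (the
#' "lineage" subtype) sits at the end of a planted differentiation axis,
#' carries an exclusive marker gene and an elevated collagen/ECM program,
#' receives planted ligand-receptor signals from endothelial cells, and is
#' enriched in high-stage samples.
#'
#' @param n_samples Number of discovery samples.
#' @param n_genes Total genes per sample (shared universe).
#' @param cells_per_sample Cells generated per sample.
#' @param cell_type_fractions Named proportions over the five generated cell
#'   types (`Fibroblast`, `Epithelial`, `Endothelial`, `T cell`, `Myeloid`);
#'   must sum to 1.
#' @param n_caf_subtypes Number of shared CAF subtypes.
#' @param lineage_subtype_index Which subtype carries the marker and the
#'   terminal differentiation program (1-based).
#' @param marker_gene_id Identifier used for the exclusive marker gene.
#' @param program_sizes Integer vector, genes per CAF-subtype program.
#' @param program_effect Mean log2 elevation of subtype/cell-type program
#'   genes in their home population.
#' @param axis_effect Slope `a` of the pseudotime link: axis and lineage
#'   program means are multiplied by `(1 + a * t)` with `t` in `[0, 1]`.
#' @param lineage_elevation,marker_elevation Fold elevation (at `t = 1`) of
#'   the lineage program and marker gene in lineage-subtype cells over their
#'   low ambient baseline.
#' @param nb_dispersion Negative-binomial overdispersion; counts are drawn
#'   with `size = 1 / nb_dispersion`.
#' @param mito_gene_count Number of mitochondrial genes (prefix `MT-`).
#' @param qc_violation_fractions Named proportions of planted low-quality
#'   cells per QC rule: `low_gene`, `low_umi`, `high_mito`.
#' @param lr_pairs_planted Data frame with columns `ligand`, `receptor`,
#'   `sender`, `receiver`, or `NULL` for the default three
#'   endothelial-to-lineage pairs.
#' @param decoy_factor Decoy LR pairs generated per planted pair.
#' @param lineage_fraction Named proportions (`low`, `high`) of CAFs
#'   belonging to the lineage subtype, by sample stage bin.
#' @param stages Character vector of per-sample stage labels, recycled to
#'   `n_samples`; labels follow the clinical convention (`Stage 1..4`,
#'   `LOW`, `HIGH`).
#' @param library_size,library_sd Log-normal per-cell library size
#'   (median and log-sd); each sample also draws a depth factor.
#' @param bulk_n Bulk cohort size (at least 20).
#' @param hazard_beta Log-hazard per unit of the true bulk signature.
#' @param censor_rate Expected censoring proportion, in `[0, 1)`.
#' @param seed Integer seed; every generator derives its randomness from it.
#'
#' @return A list of class `caf_sim_config`.
#' @export
caf_sim_config <- function(n_samples = 3,
                           n_genes = 2000,
                           cells_per_sample = 1000,
                           cell_type_fractions = c(
                             "Fibroblast" = 0.40, "Epithelial" = 0.25,
                             "Endothelial" = 0.10, "T cell" = 0.15,
                             "Myeloid" = 0.10
                           ),
                           n_caf_subtypes = 6,
                           lineage_subtype_index = 6,
                           marker_gene_id = "GJB2",
                           program_sizes = rep(30L, n_caf_subtypes),
                           program_effect = 2.5,
                           axis_effect = 2,
                           lineage_elevation = 450,
                           marker_elevation = 8000,
                           nb_dispersion = 0.5,
                           mito_gene_count = 13,
                           qc_violation_fractions = c(
                             low_gene = 0.02, low_umi = 0.02, high_mito = 0.02
                           ),
                           lr_pairs_planted = NULL,
                           decoy_factor = 5,
                           lineage_fraction = c(low = 0.25, high = 0.40),
                           stages = c("Stage 2", "HIGH", "Stage 4"),
                           library_size = 2500,
                           library_sd = 0.25,
                           bulk_n = 500,
                           hazard_beta = 1,
                           censor_rate = 0.3,
                           seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples),
    n_genes = as.integer(n_genes),
    cells_per_sample = as.integer(cells_per_sample),
    cell_type_fractions = cell_type_fractions,
    n_caf_subtypes = as.integer(n_caf_subtypes),
    lineage_subtype_index = as.integer(lineage_subtype_index),
    marker_gene_id = marker_gene_id,
    program_sizes = as.integer(program_sizes),
    program_effect = program_effect,
    axis_effect = axis_effect,
    lineage_elevation = lineage_elevation,
    marker_elevation = marker_elevation,
    nb_dispersion = nb_dispersion,
    mito_gene_count = as.integer(mito_gene_count),
    qc_violation_fractions = qc_violation_fractions,
    lr_pairs_planted = lr_pairs_planted,
    decoy_factor = as.integer(decoy_factor),
    lineage_fraction = lineage_fraction,
    stages = rep_len(stages, n_samples),
    library_size = library_size,
    library_sd = library_sd,
    bulk_n = as.integer(bulk_n),
    hazard_beta = hazard_beta,
    censor_rate = censor_rate,
    seed = as.integer(seed)
  )
  class(cfg) <- "caf_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (abs(sum(cfg$cell_type_fractions) - 1) > 1e-8) {
    abort("`cell_type_fractions` must sum to 1.")
  }
  if (any(cfg$cell_type_fractions < 0) || any(cfg$cell_type_fractions > 1)) {
    abort("`cell_type_fractions` must lie in [0, 1].")
  }
  if (cfg$lineage_subtype_index < 1 ||
      cfg$lineage_subtype_index > cfg$n_caf_subtypes) {
    abort("`lineage_subtype_index` must index one of the CAF subtypes.")
  }
  if (length(cfg$program_sizes) != cfg$n_caf_subtypes) {
    abort("`program_sizes` must have one entry per CAF subtype.")
  }
  if (any(cfg$qc_violation_fractions < 0) ||
      any(cfg$qc_violation_fractions > 1)) {
    abort("`qc_violation_fractions` must lie in [0, 1].")
  }
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1) {
    abort("`censor_rate` must lie in [0, 1).")
  }
  # fixed per-cell-type programs: 4 non-fibroblast programs of 30 genes,
  # the fibroblast-common panel (20), the pseudotime axis program (60)
  demand <- cfg$mito_gene_count + 20L + 4L * 30L + sum(cfg$program_sizes) +
    1L + 60L
  if (cfg$n_genes < demand) {
    abort(sprintf(
      "`n_genes` (%d) is smaller than the %d genes required by the configured programs.",
      cfg$n_genes, demand
    ))
  }
  invisible(cfg)
}

#' @exportS3Method base::print
print.caf_sim_config <- function(x, ...) {
  cat("<caf_sim_config>\n")
  cat(sprintf(
    "  %d samples x %d cells, %d genes; %d CAF subtypes (lineage = %d, marker = %s)\n",
    x$n_samples, x$cells_per_sample, x$n_genes, x$n_caf_subtypes,
    x$lineage_subtype_index, x$marker_gene_id
  ))
  cat(sprintf(
    "  bulk n = %d, hazard beta = %.2f, censor rate = %.2f, seed = %d\n",
    x$bulk_n, x$hazard_beta, x$censor_rate, x$seed
  ))
  invisible(x)
}
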