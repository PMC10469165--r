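# (internal)
# Deterministic gene layout shared by every generator for one config.
# All gene-level structure (names, ambient baselines, program membership)
# depends only on the config, so single-cell, reference, LR and bulk
# generators agree on the planted truth.
gene_architecture <- function(cfg) {
  n <- cfg$n_genes
  ids <- character(n)
  next_i <- 1L
  take <- function(k) {
    idx <- seq.int(next_i, next_i + k - 1L)
    next_i <<- next_i + k
    idx
  }
  name_block <- function(idx, flavor, prefix) {
    out <- c(flavor, sprintf("%s%02d", prefix, seq_len(length(idx) - length(flavor))))
    out[seq_along(idx)]
  }

  mito <- take(cfg$mito_gene_count)
  ids[mito] <- sprintf("MT-%d", seq_along(mito))

  fib_common <- take(20L)
  ids[fib_common] <- name_block(
    fib_common, c("DCN", "COL3A1", "THY1", "VIM", "LUM", "FBLN1", "PDGFRA"),
    "FIB"
  )

  epithelial <- take(30L)
  ids[epithelial] <- name_block(epithelial, c("EPCAM", "KRT8", "KRT18"), "EPI")

  ligands <- c("DLL4", "PDGFB", "CXCL12")
  endothelial <- take(30L)
  ids[endothelial] <- name_block(
    endothelial, c("PECAM1", "VWF", "CDH5", ligands), "END"
  )

  tcell <- take(30L)
  ids[tcell] <- name_block(tcell, c("CD3D", "CD3E", "TRAC"), "TCL")

  myeloid <- take(30L)
  ids[myeloid] <- name_block(myeloid, c("CD68", "LYZ", "AIF1"), "MYE")

  receptors <- c("NOTCH3", "PDGFRB", "CXCR4")
  subtype_programs <- vector("list", cfg$n_caf_subtypes)
  for (k in seq_len(cfg$n_caf_subtypes)) {
    idx <- take(cfg$program_sizes[k])
    if (k == cfg$lineage_subtype_index) {
      ids[idx] <- name_block(
        idx,
        c("COL10A1", "COL11A1", "COL1A1", "COL5A1", "COL8A1", "LOXL2", receptors),
        "ECM"
      )
    } else {
      ids[idx] <- sprintf("CAF%d_%02d", k, seq_along(idx))
    }
    subtype_programs[[k]] <- idx
  }
  names(subtype_programs) <- paste0("CAF", seq_len(cfg$n_caf_subtypes))

  marker <- take(1L)
  ids[marker] <- cfg$marker_gene_id

  axis <- take(60L)
  ids[axis] <- sprintf("AX%02d", seq_along(axis))

  background <- seq.int(next_i, n)
  ids[background] <- sprintf("G%04d", seq_along(background))

  # ambient baselines (relative expression units); background is drawn once,
  # seeded, and reused identically by every generator
  set.seed(cfg$seed)
  base <- rgamma(n, shape = 0.6, scale = 1.5)
  base[mito] <- 4
  base[fib_common] <- 1.2
  base[epithelial] <- 1
  base[endothelial] <- 1
  base[tcell] <- 1
  base[myeloid] <- 1
  for (k in seq_len(cfg$n_caf_subtypes)) base[subtype_programs[[k]]] <- 1
  lineage <- subtype_programs[[cfg$lineage_subtype_index]]
  base[lineage] <- 0.01
  base[marker] <- 0.002
  base[axis] <- 0.8

  list(
    gene_ids = ids, base = base,
    mito = mito, fib_common = fib_common,
    type_programs = list(
      Epithelial = epithelial, Endothelial = endothelial,
      "T cell" = tcell, Myeloid = myeloid
    ),
    subtype_programs = subtype_programs,
    lineage = lineage, marker = marker, axis = axis,
    background = background,
    ligand_ids = ligands, receptor_ids = receptors
  )
}

# (internal)
# Pseudotime interval for a subtype along the planted axis: non-lineage
# subtypes tile [0.15, 0.85] in index order, the lineage subtype occupies
# the terminal [0.85, 1].
subtype_time_window <- function(k, cfg) {
  if (k == cfg$lineage_subtype_index) {
    return(c(0.85, 1))
  }
  others <- setdiff(seq_len(cfg$n_caf_subtypes), cfg$lineage_subtype_index)
  j <- match(k, others)
  lo <- 0.15 + 0.7 * (j - 1) / length(others)
  c(lo, lo + 0.7 / length(others))
}

#' Generate the multi-sample single-cell study
#'
#' Draws `n_samples` UMI count matrices over a shared gene universe. Every
#' sample contains fibroblasts (normal-tissue NFs plus tumor/border CAFs
#' split into the configured subtypes), epithelial/cancer cells,
#' endothelial cells, T cells and myeloid cells. Subtype gene programs are
#' shared across samples while library depth is sample-specific. Fibroblasts
#' carry a planted pseudotime `t`; axis-program and lineage-program means
#' scale as `(1 + a t)`, the lineage subtype exclusively expresses the
#' marker gene, and a configurable fraction of cells is overwritten with
#' planted QC violations (low detected genes, low UMI, high mitochondrial
#' fraction), flagged in the ground truth.
#'
#' @param cfg A [caf_sim_config()].
#' @return A list with `samples` (list of `caf_sample` objects) and `truth`
#'   (list with per-cell truth tibble and planted gene/pair lists).
#' @export
simulate_sc_samples <- function(cfg = caf_sim_config()) {
  stopifnot(inherits(cfg, "caf_sim_config"))
  arch <- gene_architecture(cfg)
  set.seed(cfg$seed + 1L)

  type_names <- names(cfg$cell_type_fractions)
  lineage_label <- paste0("CAF", cfg$lineage_subtype_index)
  samples <- vector("list", cfg$n_samples)
  truth_cells <- vector("list", cfg$n_samples)

  for (s in seq_len(cfg$n_samples)) {
    sample_id <- paste0("D", s)
    n_cells <- cfg$cells_per_sample
    depth <- rlnorm(1, 0, 0.15)
    stage <- cfg$stages[s]
    stage_bin <- bin_stage(stage)

    type <- sample(type_names, n_cells, replace = TRUE,
                   prob = cfg$cell_type_fractions)
    tissue <- character(n_cells)
    fib <- type == "Fibroblast"
    tissue[fib] <- sample(c("normal", "tumor", "border"), sum(fib),
                          replace = TRUE, prob = c(0.35, 0.55, 0.10))
    epi <- type == "Epithelial"
    tissue[epi] <- sample(c("tumor", "normal"), sum(epi),
                          replace = TRUE, prob = c(0.8, 0.2))
    other <- !fib & !epi
    tissue[other] <- sample(c("tumor", "normal"), sum(other),
                            replace = TRUE, prob = c(0.9, 0.1))

    # CAF subtype assignment: lineage share depends on the sample's stage bin
    subtype <- rep(NA_character_, n_cells)
    caf <- fib & tissue != "normal"
    lin_frac <- unname(cfg$lineage_fraction[stage_bin])
    probs <- rep((1 - lin_frac) / (cfg$n_caf_subtypes - 1), cfg$n_caf_subtypes)
    probs[cfg$lineage_subtype_index] <- lin_frac
    subtype[caf] <- sample(names(arch$subtype_programs), sum(caf),
                           replace = TRUE, prob = probs)

    # planted pseudotime on all fibroblasts
    t_true <- rep(NA_real_, n_cells)
    nf <- fib & tissue == "normal"
    t_true[nf] <- runif(sum(nf), 0, 0.15)
    for (k in seq_len(cfg$n_caf_subtypes)) {
      idx <- which(subtype == names(arch$subtype_programs)[k])
      w <- subtype_time_window(k, cfg)
      t_true[idx] <- runif(length(idx), w[1], w[2])
    }

    # expected relative expression, then NB counts
    M <- matrix(arch$base, nrow = cfg$n_genes, ncol = n_cells)
    fib_idx <- which(fib)
    M[arch$fib_common, fib_idx] <- M[arch$fib_common, fib_idx] * 2^1.5
    M[arch$axis, fib_idx] <- arch$base[arch$axis] %o%
      (1 + cfg$axis_effect * t_true[fib_idx])
    for (tp in names(arch$type_programs)) {
      cols <- which(type == tp)
      rows <- arch$type_programs[[tp]]
      M[rows, cols] <- M[rows, cols] * 2^cfg$program_effect
    }
    # each subtype expresses its own identity program; the continuous
    # differentiation signal lives in the axis program (all fibroblasts)
    # and in the lineage program's (1 + a t) scaling, so the planted axis
    # is recoverable while subtypes remain discrete, matchable states
    for (k in seq_len(cfg$n_caf_subtypes)) {
      rows <- arch$subtype_programs[[k]]
      cols <- which(subtype == names(arch$subtype_programs)[k])
      if (k == cfg$lineage_subtype_index) {
        scale_t <- cfg$lineage_elevation *
          (1 + cfg$axis_effect * t_true[cols]) / (1 + cfg$axis_effect)
        M[rows, cols] <- arch$base[rows] %o% scale_t
        M[arch$marker, cols] <- arch$base[arch$marker] * cfg$marker_elevation *
          (1 + cfg$axis_effect * t_true[cols]) / (1 + cfg$axis_effect)
      } else {
        M[rows, cols] <- M[rows, cols] * 2^cfg$program_effect
      }
    }

    lib <- rlnorm(n_cells, log(cfg$library_size), cfg$library_sd) * depth
    mu <- sweep(M, 2, lib / colSums(M), `*`)
    counts <- matrix(
      rnbinom(length(mu), size = 1 / cfg$nb_dispersion, mu = mu),
      nrow = cfg$n_genes
    )

    # planted QC violations overwrite whole cells (non-overlapping rules)
    qc_flag <- rep("none", n_cells)
    n_viol <- round(cfg$qc_violation_fractions * n_cells)
    viol_cells <- sample(n_cells, sum(n_viol))
    split_idx <- split(
      viol_cells,
      rep(names(n_viol), n_viol)
    )
    non_mito <- setdiff(seq_len(cfg$n_genes), arch$mito)
    for (i in split_idx$low_gene) {
      v <- numeric(cfg$n_genes)
      picked <- sample(non_mito, 120)
      v[picked] <- rmultinom(1, 2500, rep(1, 120))
      counts[, i] <- v
      qc_flag[i] <- "low_gene"
    }
    for (i in split_idx$low_umi) {
      pr <- arch$base
      pr[arch$mito] <- pr[arch$mito] * 0.8
      counts[, i] <- rmultinom(1, 600, pr)
      qc_flag[i] <- "low_umi"
    }
    for (i in split_idx$high_mito) {
      pr <- arch$base
      pr[arch$mito] <- pr[arch$mito] * sum(pr[non_mito]) * 0.4 /
        (0.6 * sum(pr[arch$mito]))
      counts[, i] <- rmultinom(1, 3000, pr)
      qc_flag[i] <- "high_mito"
    }

    barcodes <- sprintf("%s_C%04d", sample_id, seq_len(n_cells))
    dimnames(counts) <- list(arch$gene_ids, barcodes)
    meta <- tibble(
      barcode = barcodes, tissue = tissue, stage = stage
    )
    samples[[s]] <- new_caf_sample(
      as(as(counts, "CsparseMatrix"), "generalMatrix"), meta, sample_id
    )
    truth_cells[[s]] <- tibble(
      barcode = barcodes, sample = sample_id,
      true_type = type, tissue = tissue,
      true_subtype = subtype, true_t = t_true,
      qc_violation = qc_flag
    )
  }
  names(samples) <- map_chr(samples, "sample_id")

  truth <- list(
    cells = bind_rows(truth_cells),
    marker_gene = cfg$marker_gene_id,
    program_genes = arch$gene_ids[arch$lineage],
    axis_genes = arch$gene_ids[arch$axis],
    subtype_programs = map(arch$subtype_programs, ~ arch$gene_ids[.x]),
    signature_genes = c(cfg$marker_gene_id, arch$gene_ids[arch$lineage]),
    lineage_label = lineage_label,
    lr_pairs = planted_lr_pairs(cfg, arch)
  )
  list(samples = samples, truth = truth)
}

# (internal)
planted_lr_pairs <- function(cfg, arch) {
  if (!is.null(cfg$lr_pairs_planted)) {
    return(as_tibble(cfg$lr_pairs_planted))
  }
  tibble(
    ligand = arch$ligand_ids,
    receptor = arch$receptor_ids,
    sender = "Endothelial",
    receiver = paste0("CAF", cfg$lineage_subtype_index)
  )
}

#' Reference expression profiles per cell type
#'
#' Returns the expected relative expression (scaled to counts per 10k) of
#' each generated cell type, computed directly from the generating program
#' means — the stand-in for an external annotation reference.
#'
#' @param cfg A [caf_sim_config()].
#' @return A genes x cell-types matrix.
#' @export
simulate_reference_profiles <- function(cfg = caf_sim_config()) {
  stopifnot(inherits(cfg, "caf_sim_config"))
  arch <- gene_architecture(cfg)
  types <- names(cfg$cell_type_fractions)
  prof <- matrix(arch$base, nrow = cfg$n_genes, ncol = length(types),
                 dimnames = list(arch$gene_ids, types))
  fib <- which(types == "Fibroblast")
  prof[arch$fib_common, fib] <- prof[arch$fib_common, fib] * 2^1.5
  # fibroblast profile at the population-average axis position and a modest
  # average subtype-program load
  prof[arch$axis, fib] <- prof[arch$axis, fib] * (1 + cfg$axis_effect * 0.5)
  for (k in seq_len(cfg$n_caf_subtypes)) {
    rows <- arch$subtype_programs[[k]]
    if (k == cfg$lineage_subtype_index) {
      prof[rows, fib] <- prof[rows, fib] * (1 + cfg$lineage_elevation * 0.15)
      prof[arch$marker, fib] <- prof[arch$marker, fib] *
        (1 + cfg$marker_elevation * 0.15)
    } else {
      prof[rows, fib] <- prof[rows, fib] * (1 + (2^cfg$program_effect - 1) * 0.15)
    }
  }
  for (tp in names(arch$type_programs)) {
    col <- which(types == tp)
    prof[arch$type_programs[[tp]], col] <-
      prof[arch$type_programs[[tp]], col] * 2^cfg$program_effect
  }
  sweep(prof, 2, 1e4 / colSums(prof), `*`)
}

#' Ligand-receptor pair table with decoys
#'
#' The planted endothelial-to-lineage pairs plus `decoy_factor` times as
#' many decoy pairs built from background genes expressed at ambient level
#' in every cell type.
#'
#' @param cfg A [caf_sim_config()].
#' @return A tibble with columns `ligand`, `receptor`, `planted`.
#' @export
simulate_lr_database <- function(cfg = caf_sim_config()) {
  stopifnot(inherits(cfg, "caf_sim_config"))
  arch <- gene_architecture(cfg)
  planted <- planted_lr_pairs(cfg, arch)
  set.seed(cfg$seed + 3L)
  n_decoy <- cfg$decoy_factor * nrow(planted)
  # disjoint ligand/receptor draws from the background pool: unique rows and
  # no self-pairs by construction
  perm <- sample(arch$gene_ids[arch$background], 2L * n_decoy)
  decoy <- tibble(
    ligand = perm[seq_len(n_decoy)],
    receptor = perm[n_decoy + seq_len(n_decoy)]
  )
  bind_rows(
    mutate(planted[, c("ligand", "receptor")], planted = TRUE),
    mutate(decoy, planted = FALSE)
  )
}

#' Gene-set collection for enrichment analysis
#'
#' A small GMT-style collection: the planted collagen/ECM program, a
#' mesenchyme set overlapping the axis program, the fibroblast-common
#' panel, and random background sets.
#'
#' @param cfg A [caf_sim_config()].
#' @return Named list of gene-id vectors.
#' @export
simulate_gene_sets <- function(cfg = caf_sim_config()) {
  stopifnot(inherits(cfg, "caf_sim_config"))
  arch <- gene_architecture(cfg)
  set.seed(cfg$seed + 4L)
  pool <- arch$gene_ids[arch$background]
  sets <- list(
    HALLMARK_ECM_REMODELING = c(cfg$marker_gene_id,
                                arch$gene_ids[arch$lineage]),
    GOBP_MESENCHYME_DEVELOPMENT = c(arch$gene_ids[arch$axis][1:20],
                                    arch$gene_ids[arch$lineage][1:10]),
    GOBP_FIBROBLAST_ACTIVATION = arch$gene_ids[arch$fib_common],
    GOBP_T_CELL_ACTIVATION = arch$gene_ids[arch$type_programs[["T cell"]]]
  )
  for (i in 1:4) {
    sets[[sprintf("RANDOM_SET_%d", i)]] <- sample(pool, 25)
  }
  sets
}
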