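# shared fixtures; expensive objects are built once per test run

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

# compact study for unit tests (two samples keep DE/clustering fast)
small_cfg <- function(seed = 7, ...) {
  caf_sim_config(n_samples = 2, cells_per_sample = 500, bulk_n = 120,
                 stages = c("Stage 2", "HIGH"), seed = seed, ...)
}

small_sim <- function() cached("small_sim", simulate_sc_samples(small_cfg()))

# per-sample normalized data + truth-labeled cell table for the small study
small_prep <- function() {
  cached("small_prep", {
    sim <- small_sim()
    tr <- sim$truth$cells
    filtered <- lapply(sim$samples, filter_cells)
    nms <- lapply(filtered, log_normalize, scale_factor = NULL)
    cells <- do.call(rbind, lapply(filtered, function(fs) {
      idx <- match(colnames(fs$counts), tr$barcode)
      tibble::tibble(
        barcode = colnames(fs$counts), sample = fs$sample_id,
        tissue = tr$tissue[idx], stage = fs$meta$stage,
        true_type = tr$true_type[idx], true_subtype = tr$true_subtype[idx],
        true_t = tr$true_t[idx],
        group = ifelse(tr$true_type[idx] != "Fibroblast", tr$true_type[idx],
                       ifelse(tr$tissue[idx] == "normal", "NF",
                              tr$true_subtype[idx]))
      )
    }))
    list(sim = sim, filtered = filtered, nms = nms, cells = cells,
         truth = sim$truth)
  })
}

# full default pipeline run, reused by several acceptance checks
default_pipeline <- function() {
  cached("default_pipeline",
         suppressMessages(run_caf_pipeline(caf_sim_config())))
}

default_sim <- function() {
  cached("default_sim", suppressMessages(simulate_sc_samples(caf_sim_config())))
}

# build a caf_norm directly from a matrix of normalized values
mk_norm <- function(values, sample_id = "T1") {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("c%03d", seq_len(ncol(values)))
  }
  m <- methods::as(Matrix::Matrix(values, sparse = TRUE), "CsparseMatrix")
  caflineage:::new_caf_norm(m, tibble::tibble(barcode = colnames(values)),
                            sample_id, 1e4)
}

# build a caf_sample from a dense count matrix
mk_sample <- function(counts, tissue = "tumor", stage = "Stage 2",
                      sample_id = "T1") {
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("c%03d", seq_len(ncol(counts)))
  }
  meta <- tibble::tibble(
    barcode = colnames(counts),
    tissue = rep_len(tissue, ncol(counts)),
    stage = rep_len(stage, ncol(counts))
  )
  caflineage:::new_caf_sample(
    methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
    meta, sample_id
  )
}

# dense generalized-eigenvalue CCA oracle: sqrt of eigenvalues of
# Sxx^-1 Sxy Syy^-1 Syx (independent of the package's whitened-SVD route)
cca_oracle <- function(x, y) {
  xc <- scale(x, center = TRUE, scale = FALSE)
  yc <- scale(y, center = TRUE, scale = FALSE)
  n <- nrow(x)
  sxx <- crossprod(xc) / (n - 1)
  syy <- crossprod(yc) / (n - 1)
  sxy <- crossprod(xc, yc) / (n - 1)
  m <- solve(sxx) %*% sxy %*% solve(syy) %*% t(sxy)
  ev <- sort(Re(eigen(m, only.values = TRUE)$values), decreasing = TRUE)
  sqrt(pmax(pmin(ev, 1), 0))
}

# brute-force GSEA running-sum oracle: full O(N) cumulative walk
gsea_oracle <- function(scores, gene_set, weight = 1) {
  ord <- order(-scores, names(scores))
  s <- scores[ord]
  hit <- names(s) %in% gene_set
  n_miss <- sum(!hit)
  if (n_miss == 0) return(0)
  w <- abs(s)^weight
  w[!hit] <- 0
  if (sum(w) == 0) w <- as.numeric(hit)
  inc <- ifelse(hit, w / sum(w), -1 / n_miss)
  running <- cumsum(inc)
  m <- max(abs(running))
  running[which(abs(running) >= m - 1e-12)[1]]
}
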