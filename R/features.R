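#' Select highly variable genes
#'
#' Computes, per gene, the mean of the back-transformed (expm1) normalized
#' values and its dispersion (variance/mean), then standardizes the
#' dispersion within `n_bins` equal-frequency bins of the log1p mean. Genes
#' with log1p mean strictly inside `(min_mean, max_mean)` and standardized
#' dispersion above `min_dispersion` are kept, truncated to the `n_top`
#' highest-dispersion genes.
#'
#' @param nm A `caf_norm`.
#' @param min_mean,max_mean Exclusive bounds on the log1p mean.
#' @param min_dispersion Lower bound on the standardized dispersion.
#' @param n_top Maximum number of genes returned.
#' @param n_bins Equal-frequency mean bins for dispersion standardization.
#' @return Tibble (gene, mean, dispersion, dispersion_z), ordered by
#'   decreasing standardized dispersion.
#' @export
select_variable_genes <- function(nm, min_mean = 0.0125, max_mean = 3,
                                  min_dispersion = 0.5, n_top = 1000,
                                  n_bins = 20) {
  stopifnot(inherits(nm, "caf_norm"), n_top >= 1)
  e <- as(nm$data, "CsparseMatrix")
  e@x <- expm1(e@x)
  n <- ncol(e)
  mu <- Matrix::rowMeans(e)
  v <- (Matrix::rowSums(e^2) - n * mu^2) / (n - 1)
  disp <- ifelse(mu > 0, v / mu, NA_real_)
  mean_log <- log1p(mu)

  tbl <- tibble(gene = rownames(e), mean = mean_log, dispersion = disp) |>
    filter(!is.na(.data$dispersion)) |>
    mutate(bin = dplyr::ntile(.data$mean, n_bins)) |>
    group_by(.data$bin) |>
    mutate(dispersion_z = {
      s <- sd(.data$dispersion)
      if (is.na(s) || s == 0) 0 else (.data$dispersion - mean(.data$dispersion)) / s
    }) |>
    ungroup() |>
    select(-"bin")

  out <- tbl |>
    filter(.data$mean > min_mean, .data$mean < max_mean,
           .data$dispersion_z > min_dispersion) |>
    arrange(desc(.data$dispersion_z)) |>
    head(n_top)
  if (nrow(out) == 0) abort("no gene passed the variable-feature cutoffs.")
  out
}

#' Intersect variable features across samples
#'
#' Exact set intersection of per-sample variable-gene lists, ordered by the
#' mean within-list rank (ties broken lexicographically).
#'
#' @param sets List (length >= 2) of variable-feature tibbles from
#'   [select_variable_genes()] or plain character vectors.
#' @return Character vector of shared genes.
#' @export
common_variable_features <- function(sets) {
  if (length(sets) < 2) abort("need at least two variable-feature sets.")
  lists <- map(sets, function(s) if (is.character(s)) s else s$gene)
  shared <- reduce(lists, intersect)
  if (length(shared) == 0) abort("variable-feature sets have empty intersection.")
  mean_rank <- map(lists, ~ match(shared, .x)) |>
    (\(r) Reduce(`+`, r) / length(r))()
  shared[order(mean_rank, shared)]
}

#' Scale selected genes and run PCA
#'
#' Z-scales each selected gene across cells (clipping at `clip` standard
#' deviations; constant genes become zero rows) and computes principal
#' components of the scaled cell profiles.
#'
#' @param nm A `caf_norm`.
#' @param features Genes to use (subset of the matrix rows).
#' @param n_pcs Number of components (at most `length(features)`).
#' @param clip Absolute z-score clip.
#' @return List with `embedding` (cells x n_pcs, rownames = barcodes),
#'   `variance` (per-component explained variance, non-increasing) and
#'   `rotation`.
#' @export
scale_and_pca <- function(nm, features, n_pcs = 20, clip = 10) {
  stopifnot(inherits(nm, "caf_norm"))
  if (n_pcs > length(features)) {
    abort("`n_pcs` cannot exceed the number of features.")
  }
  x <- norm_values(nm, features)
  mu <- rowMeans(x)
  s <- apply(x, 1, sd)
  const <- s == 0
  if (any(const)) {
    inform(sprintf("%d constant gene(s) scaled to zero", sum(const)))
    s[const] <- 1
  }
  z <- (x - mu) / s
  z[const, ] <- 0
  z[z > clip] <- clip
  z[z < -clip] <- -clip
  n_pcs <- min(n_pcs, ncol(x) - 1L)
  p <- prcomp(t(z), center = FALSE, scale. = FALSE, rank. = n_pcs)
  list(
    embedding = p$x,
    variance = p$sdev[seq_len(n_pcs)]^2,
    rotation = p$rotation
  )
}

#' Locate the elbow of a scree curve
#'
#' Index of the point with maximum perpendicular distance from the chord
#' joining the first and last scree values — the usual heuristic for
#' choosing the number of principal components.
#'
#' @param variance Non-increasing numeric vector of explained variances.
#' @return Integer index of the elbow.
#' @export
find_elbow <- function(variance) {
  n <- length(variance)
  if (n < 3) return(n)
  x <- seq_len(n)
  dx <- n - 1
  dy <- variance[n] - variance[1]
  d <- abs(dy * (x - 1) - dx * (variance - variance[1])) / sqrt(dx^2 + dy^2)
  which.max(d)
}

#' Shared-nearest-neighbor graph clustering
#'
#' Builds a k-nearest-neighbor graph on the embedding, reweights edges by
#' the Jaccard overlap of neighborhoods (pruning below `prune`), and
#' partitions the graph by Louvain modularity optimization at the given
#' resolution. Deterministic for a fixed seed.
#'
#' @param embedding Cells x dims matrix with barcode rownames.
#' @param k_neighbors Neighborhood size (self included).
#' @param resolution Louvain resolution parameter.
#' @param seed Integer seed.
#' @param prune Minimum Jaccard overlap retained as an edge.
#' @return Tibble (barcode, cluster) with the parameters attached as the
#'   `"params"` attribute.
#' @export
snn_cluster <- function(embedding, k_neighbors = 20, resolution = 0.8,
                        seed = 0, prune = 1 / 15) {
  n <- nrow(embedding)
  if (n < 10) abort("need at least 10 cells to cluster.")
  if (k_neighbors >= n) abort("`k_neighbors` must be smaller than the number of cells.")
  d <- as.matrix(stats::dist(embedding))
  nn <- apply(d, 1, function(row) order(row)[seq_len(k_neighbors)])
  adj <- Matrix::sparseMatrix(
    i = rep(seq_len(n), each = k_neighbors), j = as.vector(nn), x = 1,
    dims = c(n, n)
  )
  shared <- Matrix::tcrossprod(adj)
  jac <- shared
  jac@x <- jac@x / (2 * k_neighbors - jac@x)
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  out <- tibble(
    barcode = rownames(embedding),
    cluster = as.integer(igraph::membership(comm))
  )
  attr(out, "params") <- list(k_neighbors = k_neighbors,
                              resolution = resolution, seed = seed)
  out
}
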