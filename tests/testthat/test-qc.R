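# construct a small count matrix with known per-cell QC profiles
qc_fixture <- function() {
  n_genes <- 300
  genes <- c(sprintf("MT-%d", 1:5), sprintf("g%03d", 1:(n_genes - 5)))
  mk_cell <- function(n_detected, total, mito_frac = 0.02) {
    v <- numeric(n_genes)
    mito_umi <- round(total * mito_frac)
    v[1:5] <- c(mito_umi, 0, 0, 0, 0)
    body <- total - mito_umi
    picked <- 5 + seq_len(n_detected - 1)
    v[picked] <- c(rep(1, n_detected - 2), body - (n_detected - 2))
    v
  }
  cells <- cbind(
    exactly200 = mk_cell(200, 2000),    # 200 genes -> removed (bound exclusive)
    just201 = mk_cell(201, 2000),       # retained
    low_umi = mk_cell(250, 1000),       # 1000 UMI -> removed
    umi1001 = mk_cell(250, 1001),       # retained
    high_mito = mk_cell(250, 2000, 0.20), # 20% mito -> removed
    mito19 = mk_cell(250, 2000, 0.19),  # retained
    healthy = mk_cell(260, 3000)
  )
  rownames(cells) <- genes
  mk_sample(cells)
}

test_that("filter_cells applies the published exclusive bounds exactly", {
  f <- filter_cells(qc_fixture())
  expect_setequal(colnames(f$counts),
                  c("just201", "umi1001", "mito19", "healthy"))
  qc <- qc_report(f)
  expect_equal(qc$reason[qc$barcode == "exactly200"], "gene_count")
  expect_equal(qc$reason[qc$barcode == "low_umi"], "low_umi")
  expect_equal(qc$reason[qc$barcode == "high_mito"], "high_mito")
  expect_equal(qc$n_genes[qc$barcode == "exactly200"], 200L)
})

test_that("filter_cells is idempotent and preserves genes", {
  once <- filter_cells(qc_fixture())
  twice <- filter_cells(once)
  expect_identical(as.matrix(once$counts), as.matrix(twice$counts))
  expect_identical(rownames(once$counts), rownames(qc_fixture()$counts))
})

test_that("a planted-violation fixture retains exactly the clean cells", {
  cfg <- caf_sim_config(
    cells_per_sample = 100, n_samples = 1,
    qc_violation_fractions = c(low_gene = 0.04, low_umi = 0.03,
                               high_mito = 0.03),
    library_size = 4000, seed = 42
  )
  sim <- simulate_sc_samples(cfg)
  f <- filter_cells(sim$samples[[1]])
  expect_equal(ncol(f$counts), 90L)
  tr <- sim$truth$cells
  expect_setequal(colnames(f$counts), tr$barcode[tr$qc_violation == "none"])
})

test_that("log-normalization matches its closed form and is scale invariant", {
  counts <- matrix(0, nrow = 3, ncol = 2)
  counts[, 1] <- c(5, 9995, 0)
  counts[, 2] <- c(10, 19990, 0)   # cell 2 = cell 1 with doubled counts
  s <- mk_sample(counts)
  nm <- log_normalize(s, scale_factor = 1e4)
  expect_equal(nm$data[1, 1], log(6), tolerance = 1e-12)
  expect_equal(nm$data[3, 1], 0)
  expect_equal(as.numeric(nm$data[, 1]), as.numeric(nm$data[, 2]),
               tolerance = 1e-12)
})

test_that("log-normalization commutes with cell subsetting and rejects empty cells", {
  s <- small_sim()$samples[[1]]
  s <- filter_cells(s)
  keep <- colnames(s$counts)[1:50]
  sub_first <- caflineage:::new_caf_sample(
    s$counts[, keep], s$meta[match(keep, s$meta$barcode), ], s$sample_id
  )
  a <- log_normalize(sub_first)$data
  b <- log_normalize(s)$data[, keep]
  expect_equal(as.matrix(a), as.matrix(b), tolerance = 1e-12)

  bad <- mk_sample(matrix(c(1, 0, 0, 0), nrow = 2))
  expect_error(log_normalize(bad), "zero total")
})

test_that("variable-gene selection honors mean window, dispersion cutoff and n_top", {
  set.seed(1)
  n_cells <- 200
  base <- matrix(rpois(80 * n_cells, 2), nrow = 80,
                 dimnames = list(sprintf("g%03d", 1:80), NULL))
  # three high-dispersion genes: bimodal on/off expression
  for (i in 1:3) base[i, ] <- rpois(n_cells, ifelse(runif(n_cells) < 0.2, 40, 0.2))
  # a gene too weak for the mean window
  base[4, ] <- rbinom(n_cells, 1, 0.005)
  # a gene far above the mean window
  base[5, ] <- rpois(n_cells, 600)
  s <- mk_sample(base)
  nm <- log_normalize(s, scale_factor = NULL)

  vg <- select_variable_genes(nm, n_top = 10, n_bins = 5)
  expect_true(all(rownames(base)[1:3] %in% vg$gene))
  expect_false(rownames(base)[4] %in% vg$gene)  # mean below 0.0125
  expect_false(rownames(base)[5] %in% vg$gene)  # mean above 3
  expect_true(all(diff(vg$dispersion_z) <= 0))

  top2 <- select_variable_genes(nm, n_top = 2, n_bins = 5)
  expect_equal(nrow(top2), 2)
  expect_identical(top2$gene, vg$gene[1:2])
  expect_error(select_variable_genes(nm, min_dispersion = 1e6, n_bins = 5), "no gene")
})

test_that("common variable features intersect exactly with rank-based ordering", {
  expect_identical(
    common_variable_features(list(c("A", "B", "C"), c("B", "C", "D"),
                                  c("C", "B", "E"))),
    c("B", "C")
  )
  expect_identical(common_variable_features(list(c("A", "B"), c("A", "B"))),
                   c("A", "B"))
  expect_error(common_variable_features(list(c("A"), c("B"))), "empty")
  expect_error(common_variable_features(list(c("A"))), "two")
  # invariant to argument order as a set
  s1 <- common_variable_features(list(c("A", "B", "C"), c("C", "B", "A")))
  s2 <- common_variable_features(list(c("C", "B", "A"), c("A", "B", "C")))
  expect_setequal(s1, s2)
})

test_that("scaled PCA reflects data rank, preserves separation, ignores gene order", {
  set.seed(2)
  # two blobs separated along a known direction
  blob <- cbind(matrix(rnorm(30 * 50), 30), matrix(rnorm(30 * 50, 3), 30))
  rownames(blob) <- sprintf("g%03d", 1:30)
  nm <- mk_norm(abs(blob))
  p <- scale_and_pca(nm, rownames(blob), n_pcs = 10)
  expect_true(all(diff(p$variance) <= 1e-8))
  grp <- rep(c(1, 2), each = 50)
  d_emb <- sqrt(sum((colMeans(p$embedding[grp == 1, ]) -
                       colMeans(p$embedding[grp == 2, ]))^2))
  expect_gt(d_emb, 5)

  perm <- sample(rownames(blob))
  p2 <- scale_and_pca(nm, perm, n_pcs = 10)
  expect_equal(abs(cor(p$embedding[, 1], p2$embedding[, 1])), 1,
               tolerance = 1e-6)
  expect_error(scale_and_pca(nm, rownames(blob)[1:5], n_pcs = 10), "n_pcs")
})

test_that("the scree elbow helper finds a planted kink", {
  scree <- c(10, 8, 6, 1.2, 1.1, 1.0, 0.9, 0.85)
  expect_equal(find_elbow(scree), 4)
  expect_equal(find_elbow(c(5, 1)), 2)
})

test_that("SNN clustering separates blobs, is deterministic, handles edge cases", {
  set.seed(3)
  emb <- rbind(matrix(rnorm(200 * 2), ncol = 2),
               matrix(rnorm(200 * 2, mean = 20), ncol = 2))
  rownames(emb) <- sprintf("c%03d", 1:400)
  cl <- snn_cluster(emb, k_neighbors = 20, resolution = 0.2, seed = 1)
  expect_equal(length(unique(cl$cluster)), 2)
  expect_equal(length(unique(cl$cluster[1:200])), 1)

  cl2 <- snn_cluster(emb, k_neighbors = 20, resolution = 0.2, seed = 1)
  expect_identical(cl$cluster, cl2$cluster)

  same <- matrix(1, nrow = 30, ncol = 2,
                 dimnames = list(sprintf("c%d", 1:30), NULL))
  expect_equal(length(unique(snn_cluster(same, k_neighbors = 5)$cluster)), 1)
  expect_error(snn_cluster(emb[1:5, ], k_neighbors = 2), "at least 10")
  expect_error(snn_cluster(emb[1:20, ], k_neighbors = 25), "smaller")
})
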