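test_that("ordering-gene selection keeps group-differential genes and obeys alpha", {
  set.seed(20)
  n_per <- 40
  groups <- rep(c("NF", "CAF1", "CAF2"), each = n_per)
  n <- length(groups)
  vals <- matrix(abs(rnorm(30 * n, 1, 0.2)), nrow = 30,
                 dimnames = list(sprintf("g%03d", 1:30),
                                 sprintf("c%03d", seq_len(n))))
  shift <- stats::setNames(c(0, 1.5, 3), c("NF", "CAF1", "CAF2"))
  for (i in 1:12) vals[i, ] <- vals[i, ] + shift[groups]
  nm <- mk_norm(vals)
  cells <- tibble::tibble(barcode = colnames(vals), group = groups)

  og <- select_ordering_genes(nm, cells, alpha = 0.001)
  expect_true(all(rownames(vals)[1:12] %in% og))
  expect_false(rownames(vals)[20] %in% og)

  all_genes <- select_ordering_genes(nm, cells, alpha = 1)
  expect_equal(sort(all_genes), sort(rownames(vals)))
  expect_error(select_ordering_genes(nm, cells, alpha = 1e-300),
               "relaxing alpha")
  expect_error(
    select_ordering_genes(nm, dplyr::mutate(cells, group = "NF")),
    "two"
  )
})

test_that("pseudotime recovers a noisy planted 1-D gradient", {
  set.seed(21)
  n <- 240
  t_true <- runif(n)
  group <- cut(t_true, c(0, 0.2, 0.5, 0.8, 1),
               labels = c("NF", "A", "B", "C"))
  vals <- matrix(0, nrow = 40, ncol = n,
                 dimnames = list(sprintf("g%03d", 1:40),
                                 sprintf("c%03d", seq_len(n))))
  for (i in 1:40) vals[i, ] <- i / 10 * t_true + rnorm(n, sd = 0.15)
  nm <- mk_norm(abs(vals) + 0.01)
  cells <- tibble::tibble(barcode = colnames(nm$data),
                          group = as.character(group))
  pt <- fit_pseudotime(nm, cells, rownames(vals))
  expect_gte(cor(pt$pseudotime, t_true, method = "spearman"), 0.9)
  # anchored: NF cells sit at the low end
  expect_lt(mean(pt$pseudotime[cells$group == "NF"]),
            mean(pt$pseudotime[cells$group != "NF"]))
})

test_that("duplicated cells share pseudotime and gene order cannot flip it", {
  set.seed(22)
  n <- 80
  t_true <- seq(0, 1, length.out = n)
  vals <- matrix(rep(t_true, each = 20), nrow = 20) +
    matrix(rnorm(20 * n, sd = 0.05), nrow = 20)
  vals <- cbind(vals, vals[, 1:5])  # duplicates of the first five cells
  dimnames(vals) <- list(sprintf("g%03d", 1:20),
                         sprintf("c%03d", seq_len(ncol(vals))))
  grp <- c(ifelse(t_true < 0.3, "NF", "CAF"), rep("NF", 5))
  nm <- mk_norm(abs(vals))
  cells <- tibble::tibble(barcode = colnames(vals), group = grp)
  pt <- fit_pseudotime(nm, cells, rownames(vals))
  expect_equal(pt$pseudotime[n + 1:5], pt$pseudotime[1:5], tolerance = 1e-9)

  perm <- sample(rownames(vals))
  pt2 <- fit_pseudotime(nm, cells, perm)
  expect_gt(abs(cor(pt$pseudotime, pt2$pseudotime, method = "spearman")), 0.99)

  expect_error(fit_pseudotime(nm, cells, rownames(vals)[1:5]), "10 ordering")
  expect_error(
    fit_pseudotime(nm, dplyr::mutate(cells, group = "CAF"), rownames(vals)),
    "anchor"
  )
})

test_that("pseudotime-expression correlation averages per-sample Spearman values", {
  t1 <- seq(0.01, 1, length.out = 50)
  # sample 1: gene rises with pseudotime; sample 2: gene falls
  nm1 <- mk_norm(rbind(g1 = t1, g2 = rep(1, 50)))
  nm2 <- mk_norm(rbind(g1 = rev(t1), g2 = rep(1, 50)))
  pt <- tibble::tibble(barcode = colnames(nm1$data), pseudotime = t1)
  out <- pseudotime_gene_correlation(list(a = nm1, b = nm2),
                                     list(a = pt, b = pt))
  expect_equal(out$mean_rho[out$gene == "g1"], 0, tolerance = 1e-12)
  expect_equal(out$mean_rho[out$gene == "g2"], 0)
  expect_true(out$zero_var_flag[out$gene == "g2"])

  single <- pseudotime_gene_correlation(list(a = nm1), list(a = pt))
  expect_equal(single$mean_rho[single$gene == "g1"], 1)

  # invariant to strictly monotone transforms of pseudotime
  pt3 <- dplyr::mutate(pt, pseudotime = pseudotime^3)
  tr <- pseudotime_gene_correlation(list(a = nm1), list(a = pt3))
  expect_equal(single$mean_rho, tr$mean_rho, tolerance = 1e-12)

  expect_message(
    pseudotime_gene_correlation(list(a = nm1, b = nm2), list(a = pt)),
    "skipping"
  )
})

test_that("lineage gene selection filters on both fractions and correlation", {
  rho <- tibble::tibble(
    gene = c("marker", "vim_like", "anti", "border"),
    mean_rho = c(0.7, 0.8, -0.5, 0.31),
    n_samples = 3, zero_var_flag = FALSE
  )
  pos <- tibble::tibble(
    gene = c("marker", "vim_like", "anti", "border"),
    caf_frac = c(0.85, 0.99, 0.9, 0.25),
    nf_frac = c(0.005, 0.95, 0.01, 0.05)
  )
  out <- lineage_specific_genes(rho, pos,
                                caf_min_frac = 0.25, nf_max_frac = 0.05,
                                rho_min = 0.3)
  expect_identical(out$gene, c("marker", "border"))
  expect_equal(out$gene[1], "marker")

  # tightening any threshold never adds genes
  for (i in 1:20) {
    set.seed(i)
    r <- tibble::tibble(gene = sprintf("g%02d", 1:30),
                        mean_rho = runif(30, -1, 1))
    p <- tibble::tibble(gene = r$gene, caf_frac = runif(30),
                        nf_frac = runif(30))
    loose <- lineage_specific_genes(r, p, 0.2, 0.1, 0.1)$gene
    tight <- lineage_specific_genes(r, p, 0.3, 0.05, 0.3)$gene
    expect_true(all(tight %in% loose))
  }
})

test_that("marker-set correlations behave at the identities and under independence", {
  set.seed(23)
  n <- 2000
  g <- abs(rnorm(n))
  indep <- matrix(abs(rnorm(3 * n)), nrow = 3)
  vals <- rbind(target = g, indep)
  rownames(vals) <- c("target", "i1", "i2", "i3")
  nm <- mk_norm(vals)
  cells <- colnames(vals)
  out <- marker_set_correlation(nm, "target",
                                list(self = "target", noise = c("i1", "i2", "i3")),
                                cells)
  expect_equal(out$rho[out$set == "self"], 1)
  expect_lt(abs(out$rho[out$set == "noise"]), 0.1)
  expect_error(
    marker_set_correlation(nm, "target", list(gone = c("zz1", "zz2")), cells),
    "gone"
  )
})

test_that("planted co-expression links the marker to the collagen program", {
  prep <- small_prep()
  caf <- prep$cells$barcode[grepl("^CAF", prep$cells$group) &
                              prep$cells$sample == "D1"]
  out <- marker_set_correlation(
    prep$nms[[1]], prep$truth$marker_gene,
    list(collagen = setdiff(prep$truth$program_genes, prep$truth$marker_gene)),
    caf
  )
  expect_gt(out$rho[out$set == "collagen"], 0.3)
})
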