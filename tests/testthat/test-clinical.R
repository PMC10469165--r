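mk_bulk <- function(expr, clinical = NULL) {
  if (is.null(rownames(expr))) rownames(expr) <- sprintf("s%02d", seq_len(nrow(expr)))
  if (is.null(clinical)) {
    clinical <- tibble::tibble(
      sample = rownames(expr),
      time = seq_len(nrow(expr)) * 100, event = 1L,
      stage = "Stage 2", age = 60, sex = "F", cancer_type = "PAAD"
    )
  }
  structure(list(expr = expr, clinical = clinical), class = "caf_bulk")
}

test_that("the signature score equals the hand-computed z-mean on a toy matrix", {
  expr <- matrix(c(1, 2, 3,
                   10, 20, 30,
                   5, 5, 7), nrow = 3,
                 dimnames = list(c("s1", "s2", "s3"), c("gA", "gB", "gC")))
  b <- mk_bulk(expr)
  got <- signature_score(b, c("gA", "gB"))
  z <- scale(log1p(expr[, c("gA", "gB")]))
  expect_equal(got$score, as.numeric(rowMeans(z)), tolerance = 1e-12)

  # adding non-signature genes to the cohort changes nothing
  b2 <- mk_bulk(cbind(expr, gD = c(9, 1, 4)))
  expect_equal(signature_score(b2, c("gA", "gB"))$score, got$score)

  # constant genes are dropped from scoring
  b3 <- mk_bulk(cbind(expr, gK = c(2, 2, 2)))
  expect_message(s3 <- signature_score(b3, c("gA", "gB", "gK")), "constant")
  expect_equal(s3$score, got$score, tolerance = 1e-12)

  expect_error(signature_score(b, c("gA", "zz1", "zz2")), "missing")
})

test_that("one uniformly elevated sample takes the strictly top score", {
  set.seed(50)
  expr <- matrix(rlnorm(20 * 10), nrow = 20,
                 dimnames = list(NULL, sprintf("g%02d", 1:10)))
  expr[7, 1:5] <- expr[7, 1:5] * 50
  b <- mk_bulk(expr)
  sc <- signature_score(b, sprintf("g%02d", 1:5))
  expect_equal(which.max(sc$score), 7L)
})

test_that("panel abundance tracks planted CAF content and ignores noise panels", {
  cfg <- caf_sim_config(bulk_n = 500, seed = 3)
  b <- simulate_bulk_cohort(cfg)
  panel <- intersect(c("DCN", "COL3A1", "THY1", "VIM", "LUM"),
                     colnames(b$cohort$expr))
  ab <- caf_abundance(b$cohort, panel)
  expect_gte(cor(ab$abundance, b$truth$caf_fraction, method = "spearman"), 0.8)

  noise_panel <- grep("^G[0-9]{4}$", colnames(b$cohort$expr), value = TRUE)[1:10]
  ab0 <- caf_abundance(b$cohort, noise_panel)
  expect_lt(abs(cor(ab0$abundance, b$truth$caf_fraction,
                    method = "spearman")), 0.1)

  # a single-gene panel ranks samples exactly like the single-gene signature
  sc1 <- signature_score(b$cohort, panel[1])
  ab1 <- caf_abundance(b$cohort, panel[1])
  expect_equal(cor(sc1$score, ab1$abundance, method = "spearman"), 1)
  expect_error(caf_abundance(b$cohort, character(0)), "empty")
  expect_error(caf_abundance(b$cohort, "NOPE"), "NOPE")
})

test_that("stage labels collapse to the published low/high bins", {
  expect_equal(bin_stage(c("Stage 1", "Stage 2", "LOW")), rep("low", 3))
  expect_equal(bin_stage(c("Stage 3", "Stage 4", "HIGH")), rep("high", 3))
  expect_error(bin_stage("Stage X"), "accepted")
})

test_that("lineage proportions by stage are exact arithmetic", {
  cells <- tibble::tibble(
    fib_class = c(rep("CAF", 150), rep("NF", 10)),
    subtype = c(rep("ST3", 30), rep("ST1", 90), rep("ST3", 10), rep("ST2", 20),
                rep(NA, 10)),
    stage = c(rep("Stage 4", 120), rep("Stage 1", 30), rep("Stage 1", 10))
  )
  out <- subtype_proportion_by_stage(cells, "ST3")
  expect_equal(out$proportion[out$stage_bin == "high"], 30 / 120)
  expect_equal(out$n_caf[out$stage_bin == "low"], 30)
  expect_equal(sum(out$n_caf), 150)

  all_lineage <- dplyr::mutate(cells, subtype = "ST3")
  expect_true(all(subtype_proportion_by_stage(all_lineage, "ST3")$proportion == 1))
  expect_error(subtype_proportion_by_stage(dplyr::filter(cells, fib_class == "NF") |>
                                             dplyr::mutate(stage = NA), "ST3"),
               "no CAF")
})

test_that("the log-rank statistic matches the hand computation and its invariances", {
  time <- c(1, 2, 3, 4, 5, 6)
  event <- rep(1, 6)
  group <- rep(c("A", "B"), each = 3)

  # hand computation: hypergeometric observed-minus-expected at each event time
  o_minus_e <- 0
  v <- 0
  for (tt in sort(time)) {
    at_risk <- time >= tt
    d <- sum(time == tt)
    n <- sum(at_risk)
    n_a <- sum(at_risk & group == "A")
    o_a <- sum(time == tt & group == "A")
    e_a <- d * n_a / n
    o_minus_e <- o_minus_e + (o_a - e_a)
    if (n > 1) v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  hand <- o_minus_e^2 / v

  got <- logrank_test(time, event, group)
  expect_equal(got$statistic, hand, tolerance = 1e-10)
  expect_equal(got$p, pchisq(hand, 1, lower.tail = FALSE))

  # identical data in both groups: statistic 0, p 1
  same <- logrank_test(c(1, 2, 3, 1, 2, 3), rep(1, 6), group)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)

  # invariant to positive time rescaling
  scaled <- logrank_test(time * 365.25, event, group)
  expect_equal(scaled$statistic, got$statistic, tolerance = 1e-10)

  expect_error(logrank_test(time, event, rep("A", 6)), "two")
  expect_error(logrank_test(time, rep(0, 6), group), "event")
})

test_that("the Cox score test at beta = 0 equals the log-rank statistic", {
  time <- c(1, 2, 3, 4, 5, 6)
  event <- rep(1, 6)
  group <- rep(c(1, 0), each = 3)
  fit <- attr(cox_ph(time, event, data.frame(g = group)), "fit")
  sctest <- summary(fit)$sctest[["test"]]
  lr <- logrank_test(time, event, group)$statistic
  expect_equal(sctest, lr, tolerance = 1e-8)
})

test_that("a binary no-ties Cox fit matches the 1-D partial-likelihood oracle", {
  set.seed(51)
  n <- 60
  x <- rbinom(n, 1, 0.5)
  time <- rexp(n, rate = 0.01 * exp(0.8 * x))
  event <- rep(1, n)

  # direct Breslow partial log-likelihood, maximized by golden search
  pll <- function(beta) {
    ord <- order(time)
    xs <- x[ord]
    risk <- exp(beta * xs)
    sum(beta * xs - log(rev(cumsum(rev(risk)))))
  }
  oracle <- stats::optimize(pll, c(-5, 5), maximum = TRUE, tol = 1e-10)$maximum

  fit <- cox_ph(time, event, data.frame(x = x))
  expect_equal(fit$estimate, oracle, tolerance = 1e-6)
  expect_equal(fit$hr, exp(fit$estimate))

  expect_error(cox_ph(time, event, data.frame(k = rep(1, n))), "constant")
  expect_error(cox_ph(time[1:6], event[1:6],
                      data.frame(a = rnorm(6), b = rnorm(6))), "few events")
})

test_that("signature survival analysis detects a planted hazard and splits evenly", {
  cfg <- caf_sim_config(bulk_n = 500, hazard_beta = 1, seed = 9)
  b <- simulate_bulk_cohort(cfg)
  sim <- simulate_sc_samples(small_cfg())
  sc <- signature_score(b$cohort, sim$truth$signature_genes)
  sv <- survival_by_signature(b$cohort, sc)

  expect_lt(sv$logrank$p, 0.05)
  expect_equal(sort(as.integer(table(sv$data$score_group))),
               c(floor(500 / 2), ceiling(500 / 2)))
  expect_gt(sv$cox_continuous$estimate[sv$cox_continuous$term == "score"], 0)

  td <- tidy(sv)
  expect_true(all(c("term", "estimate", "hr", "model") %in% names(td)))
  gl <- glance(sv)
  expect_equal(gl$n, 500)
  expect_lt(gl$cox_score_p, 0.05)
  expect_s3_class(autoplot(sv), "ggplot")
})

test_that("group comparison is exact on small samples and guards degeneracy", {
  out <- group_compare(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(out$p, 0.1)

  same <- group_compare(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$p, 1)

  tt <- group_compare(c(1, 2, 3, 7, 8, 9), rep(c("a", "b"), each = 3),
                      method = "t")
  expect_lt(tt$p, 0.05)
  expect_error(group_compare(c(1, 1, 1, 2, 3, 4), rep(c("a", "b"), each = 3),
                             method = "t"), "variance")
  expect_error(group_compare(1:4, c("a", "a", "a", "a")), "two groups")
})

test_that("high-stage cohorts carry higher signature scores by construction", {
  cfg <- caf_sim_config(bulk_n = 500, seed = 12)
  b <- simulate_bulk_cohort(cfg)
  sim <- simulate_sc_samples(small_cfg())
  sc <- signature_score(b$cohort, sim$truth$signature_genes)
  bins <- bin_stage(b$cohort$clinical$stage)
  cmp <- group_compare(sc$score, bins)
  expect_lt(cmp$p, 0.05)
  expect_gt(mean(sc$score[bins == "high"]), mean(sc$score[bins == "low"]))
})
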