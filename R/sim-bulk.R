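#' Generate a bulk expression cohort with planted survival structure
#'
#' Each sample draws a latent signature value `s ~ N(0, 1)` (correlated
#' with a latent CAF-content fraction) and a log-normal expression profile
#' in which the planted signature genes (the lineage subtype's marker and
#' program genes) shift with `s`, the fibroblast panel genes shift with the
#' CAF fraction, and the axis genes shift weakly with both. Survival times
#' are exponential with hazard proportional to `exp(hazard_beta * s)`;
#' censoring is independent with per-subject probability `censor_rate`;
#' the probability of a high-stage label increases with `s`.
#'
#' @param cfg A [caf_sim_config()] (`bulk_n >= 20`).
#' @return List with `cohort` (a `caf_bulk`: `expr` samples x genes matrix,
#'   `clinical` tibble) and `truth` (sample, true_signature, caf_fraction).
#' @export
simulate_bulk_cohort <- function(cfg = caf_sim_config()) {
  stopifnot(inherits(cfg, "caf_sim_config"))
  if (cfg$bulk_n < 20) abort("`bulk_n` must be at least 20.")
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1) {
    abort("`censor_rate` must lie in [0, 1).")
  }
  arch <- gene_architecture(cfg)
  set.seed(cfg$seed + 2L)
  n <- cfg$bulk_n

  caf_fraction <- runif(n, 0.1, 0.6)
  zf <- as.numeric(scale(caf_fraction))
  s <- 0.5 * zf + sqrt(0.75) * rnorm(n)

  sig_genes <- c(cfg$marker_gene_id, arch$gene_ids[arch$lineage])
  panel_genes <- arch$gene_ids[arch$fib_common]
  axis_genes <- arch$gene_ids[arch$axis]
  program_genes <- unlist(arch$subtype_programs[-cfg$lineage_subtype_index],
                          use.names = FALSE)
  program_genes <- arch$gene_ids[program_genes]
  set.seed(cfg$seed + 5L)
  bg_genes <- sample(arch$gene_ids[arch$background],
                     min(250L, length(arch$background)))
  genes <- c(sig_genes, panel_genes, axis_genes, program_genes, bg_genes)

  mu_g <- runif(length(genes), log(2), log(200))
  effect <- matrix(0, n, length(genes), dimnames = list(NULL, genes))
  effect[, sig_genes] <- 0.8 * s
  effect[, panel_genes] <- 2 * caf_fraction
  effect[, axis_genes] <- outer(0.4 * s + 0.5 * caf_fraction,
                                rep(1, length(axis_genes)))
  effect[, program_genes] <- outer(0.3 * s + 0.5 * caf_fraction,
                                   rep(1, length(program_genes)))
  log_expr <- matrix(mu_g, n, length(genes), byrow = TRUE) + effect +
    matrix(rnorm(n * length(genes), 0, 0.4), n)
  expr <- exp(log_expr)
  sample_ids <- sprintf("B%04d", seq_len(n))
  rownames(expr) <- sample_ids

  lambda <- exp(cfg$hazard_beta * s) / 1500
  t_event <- rexp(n, rate = lambda)
  if (cfg$censor_rate > 0) {
    t_cens <- rexp(n, rate = lambda * cfg$censor_rate / (1 - cfg$censor_rate))
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  } else {
    time <- t_event
    event <- rep(1L, n)
  }

  high <- rbinom(n, 1, plogis(0.9 * s - 0.2)) == 1
  stage <- ifelse(high,
                  sample(c("Stage 3", "Stage 4", "HIGH"), n, replace = TRUE),
                  sample(c("Stage 1", "Stage 2", "LOW"), n, replace = TRUE))
  clinical <- tibble(
    sample = sample_ids,
    time = pmax(time, 1e-3), event = event, stage = stage,
    age = pmin(pmax(round(rnorm(n, 62, 10)), 30), 90),
    sex = sample(c("F", "M"), n, replace = TRUE),
    cancer_type = sample(c("PAAD", "COAD", "STAD"), n, replace = TRUE)
  )
  cohort <- structure(list(expr = expr, clinical = clinical),
                      class = "caf_bulk")
  truth <- tibble(sample = sample_ids, true_signature = s,
                  caf_fraction = caf_fraction)
  list(cohort = cohort, truth = truth)
}

#' @exportS3Method base::print
print.caf_bulk <- function(x, ...) {
  cat(sprintf("<caf_bulk> %d samples x %d genes, %d events / %d\n",
              nrow(x$expr), ncol(x$expr), sum(x$clinical$event),
              nrow(x$clinical)))
  invisible(x)
}
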