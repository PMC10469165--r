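#' Bulk signature score
#'
#' Per-sample mean, over the signature genes, of the z-scored log(1 +
#' expression). Genes that are constant across the cohort are dropped from
#' scoring with a message; at least half the signature genes must be
#' present in the cohort.
#'
#' @param cohort A `caf_bulk`.
#' @param signature_genes Character vector of gene ids.
#' @return Tibble (sample, score).
#' @export
signature_score <- function(cohort, signature_genes) {
  stopifnot(inherits(cohort, "caf_bulk"))
  present <- intersect(signature_genes, colnames(cohort$expr))
  if (length(present) < length(signature_genes) / 2) {
    abort(sprintf(
      "fewer than half the signature genes are present; missing: %s",
      paste(head(setdiff(signature_genes, present), 10), collapse = ", ")
    ))
  }
  x <- log1p(cohort$expr[, present, drop = FALSE])
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    inform(sprintf("dropping %d constant signature gene(s)", sum(sds == 0)))
    x <- x[, sds > 0, drop = FALSE]
    if (ncol(x) == 0) abort("all signature genes are constant.")
  }
  z <- scale(x)
  tibble(sample = rownames(cohort$expr), score = as.numeric(rowMeans(z)))
}

#' Marker-panel CAF abundance
#'
#' Population-abundance score in the MCPcounter style: the per-sample mean
#' log2(1 + expression) of a configurable CAF marker panel.
#'
#' @param cohort A `caf_bulk`.
#' @param panel Character vector of panel gene ids.
#' @return Tibble (sample, abundance).
#' @export
caf_abundance <- function(cohort, panel) {
  stopifnot(inherits(cohort, "caf_bulk"))
  if (length(panel) == 0) abort("marker panel is empty.")
  missing <- setdiff(panel, colnames(cohort$expr))
  if (length(missing)) {
    abort(sprintf("panel gene(s) absent: %s", paste(missing, collapse = ", ")))
  }
  tibble(
    sample = rownames(cohort$expr),
    abundance = rowMeans(log2(1 + cohort$expr[, panel, drop = FALSE]))
  )
}

#' Collapse stage labels into low/high bins
#'
#' `Stage 1`, `Stage 2` and `LOW` map to `"low"`; `Stage 3`, `Stage 4` and
#' `HIGH` map to `"high"`.
#'
#' @param stage Character vector of stage labels.
#' @return Character vector of `"low"`/`"high"`.
#' @export
bin_stage <- function(stage) {
  low <- c("Stage 1", "Stage 2", "LOW")
  high <- c("Stage 3", "Stage 4", "HIGH")
  bad <- setdiff(unique(stage), c(low, high))
  if (length(bad)) {
    abort(sprintf(
      "unrecognized stage label(s): %s (accepted: %s)",
      paste(bad, collapse = ", "), paste(c(low, high), collapse = ", ")
    ))
  }
  ifelse(stage %in% high, "high", "low")
}

#' Lineage-subtype share of CAFs per stage bin
#'
#' @param cells Annotated cell tibble with `fib_class`, `subtype`, `stage`.
#' @param lineage_subtype Label of the lineage subtype.
#' @return Tibble (stage_bin, n_caf, n_lineage, proportion); a bin with no
#'   CAFs reports `NA` proportion.
#' @export
subtype_proportion_by_stage <- function(cells, lineage_subtype) {
  caf <- filter(cells, .data$fib_class == "CAF", !is.na(.data$stage))
  if (nrow(caf) == 0) abort("no CAF cells with stage metadata.")
  caf |>
    mutate(stage_bin = bin_stage(.data$stage)) |>
    group_by(.data$stage_bin) |>
    summarise(
      n_caf = n(),
      n_lineage = sum(.data$subtype == lineage_subtype, na.rm = TRUE),
      .groups = "drop"
    ) |>
    mutate(proportion = ifelse(.data$n_caf > 0,
                               .data$n_lineage / .data$n_caf, NA_real_))
}

#' Log-rank test between two survival groups
#'
#' @param time Survival times (> 0).
#' @param event Event indicators (0/1).
#' @param group Two-level grouping.
#' @return Tibble (statistic, df, p); chi-square with 1 df.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2) {
    abort("log-rank comparison requires exactly two non-empty groups.")
  }
  if (sum(event) < 1) abort("need at least one event.")
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  tibble(
    statistic = sd_fit$chisq, df = 1,
    p = pchisq(sd_fit$chisq, df = 1, lower.tail = FALSE)
  )
}

#' Multivariate Cox proportional-hazards fit
#'
#' Partial-likelihood fit with Efron tie handling and Wald p-values,
#' through the standard survival machinery. Constant covariates are
#' rejected; non-convergence is an error.
#'
#' @param time,event Survival outcome.
#' @param covariates Data frame of covariates (numeric or factor).
#' @return Tibble (term, estimate, se, hr, p); the fitted model is
#'   attached as the `"fit"` attribute.
#' @export
cox_ph <- function(time, event, covariates) {
  covariates <- as.data.frame(covariates)
  n_levels <- vapply(covariates, function(v) length(unique(v)), integer(1))
  if (any(n_levels < 2)) {
    abort(sprintf("constant covariate(s): %s",
                  paste(names(covariates)[n_levels < 2], collapse = ", ")))
  }
  if (sum(event) < ncol(covariates) + 5) {
    abort("too few events for the number of covariates.")
  }
  names(covariates) <- make.names(names(covariates))
  dat <- cbind(data.frame(.time = time, .event = event), covariates)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(names(covariates), collapse = " + ")
  ))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron",
                    control = survival::coxph.control(eps = 1e-9, iter.max = 50)),
    warning = function(w) {
      if (grepl("did not converge|Ran out of iterations",
                conditionMessage(w))) {
        abort(sprintf("Cox fit failed: %s", conditionMessage(w)))
      }
      # separation ("coefficient may be infinite") is surfaced, not fatal:
      # the partial likelihood still yields valid score statistics
      inform(sprintf("Cox fit: %s", conditionMessage(w)))
      invokeRestart("muffleWarning")
    }
  )
  sm <- summary(fit)$coefficients
  out <- tibble(
    term = rownames(sm), estimate = sm[, "coef"],
    se = sm[, "se(coef)"], hr = sm[, "exp(coef)"],
    p = sm[, "Pr(>|z|)"]
  )
  attr(out, "fit") <- fit
  out
}

#' Survival analysis of a bulk signature score
#'
#' Dichotomizes the cohort by the score (median split by default) for
#' Kaplan-Meier curves and a log-rank test, and fits Cox models on both
#' the continuous score and the dichotomy, adjusted for stage (as the
#' low/high bin), age and sex.
#'
#' @param cohort A `caf_bulk`.
#' @param score Output of [signature_score()] (or any tibble with `sample`
#'   and `score`).
#' @param split `"median"`, `"tertile-extremes"` or `"continuous"` (no
#'   dichotomy; log-rank is skipped).
#' @param adjusters Clinical columns used as Cox adjusters.
#' @return A `caf_survival` object; see [tidy.caf_survival()],
#'   [glance.caf_survival()], [autoplot.caf_survival()].
#' @export
survival_by_signature <- function(cohort, score, split = "median",
                                  adjusters = c("stage", "age", "sex")) {
  stopifnot(inherits(cohort, "caf_bulk"))
  split <- match.arg(split, c("median", "tertile-extremes", "continuous"))
  dat <- inner_join(cohort$clinical, score, by = "sample")
  for (a in adjusters) {
    if (mean(is.na(dat[[a]])) > 0.2) {
      abort(sprintf("adjuster '%s' missing for more than 20%% of samples.", a))
    }
  }
  if ("stage" %in% names(dat)) dat$stage_bin <- bin_stage(dat$stage)
  adj <- sub("^stage$", "stage_bin", adjusters)

  if (split == "median") {
    dat$score_group <- ifelse(dat$score > median(dat$score), "high", "low")
  } else if (split == "tertile-extremes") {
    qs <- quantile(dat$score, c(1 / 3, 2 / 3))
    dat$score_group <- dplyr::case_when(
      dat$score <= qs[1] ~ "low", dat$score > qs[2] ~ "high",
      .default = NA_character_
    )
  } else {
    dat$score_group <- NA_character_
  }

  grp <- filter(dat, !is.na(.data$score_group))
  logrank <- if (split == "continuous") NULL else
    logrank_test(grp$time, grp$event, grp$score_group)
  km <- if (split == "continuous") NULL else
    survival::survfit(survival::Surv(time, event) ~ score_group, data = grp)

  cox_cont <- cox_ph(dat$time, dat$event,
                     dat[, c("score", adj), drop = FALSE])
  cox_binary <- if (split == "continuous") NULL else
    cox_ph(grp$time, grp$event,
           cbind(score_high = as.integer(grp$score_group == "high"),
                 grp[, adj, drop = FALSE]))

  structure(
    list(data = dat, split = split, logrank = logrank, km = km,
         cox_continuous = cox_cont, cox_binary = cox_binary),
    class = "caf_survival"
  )
}

#' @exportS3Method base::print
print.caf_survival <- function(x, ...) {
  cat(sprintf("<caf_survival> n = %d, split = %s\n", nrow(x$data), x$split))
  if (!is.null(x$logrank)) {
    cat(sprintf("  log-rank: chi-sq %.2f, p = %.3g\n",
                x$logrank$statistic, x$logrank$p))
  }
  cat("  adjusted Cox (continuous score):\n")
  print(x$cox_continuous)
  invisible(x)
}

#' @rdname survival_by_signature
#' @param x A `caf_survival` object.
#' @param ... Unused.
#' @export
tidy.caf_survival <- function(x, ...) {
  bind_rows(
    mutate(x$cox_continuous, model = "continuous"),
    if (!is.null(x$cox_binary)) mutate(x$cox_binary, model = "dichotomized")
  )
}

#' @rdname survival_by_signature
#' @export
glance.caf_survival <- function(x, ...) {
  tibble(
    n = nrow(x$data), events = sum(x$data$event), split = x$split,
    logrank_p = if (is.null(x$logrank)) NA_real_ else x$logrank$p,
    cox_score_p = x$cox_continuous$p[x$cox_continuous$term == "score"]
  )
}

#' @rdname survival_by_signature
#' @param object A `caf_survival` object.
#' @export
autoplot.caf_survival <- function(object, ...) {
  if (is.null(object$km)) abort("no KM fit for a continuous split.")
  km <- object$km
  groups <- sub("^score_group=", "", rep(names(km$strata),
                                         times = km$strata))
  d <- tibble(time = km$time, surv = km$surv, group = groups) |>
    group_by(.data$group) |>
    dplyr::group_modify(~ bind_rows(tibble(time = 0, surv = 1), .x)) |>
    ungroup()
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$surv,
                                  color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Time (days)", y = "Survival probability",
                  color = "Signature", title = "Survival by signature score") +
    ggplot2::theme_minimal()
}

#' Two-group comparison of a continuous variable
#'
#' Two-sided Mann-Whitney U (exact for combined n <= 20 without ties,
#' normal approximation with tie correction otherwise) or t-test.
#'
#' @param values Numeric vector.
#' @param group Two-level grouping aligned with `values`.
#' @param method `"mann-whitney"` or `"t"`.
#' @return Tibble (method, statistic, p).
#' @export
group_compare <- function(values, group, method = c("mann-whitney", "t")) {
  method <- match.arg(method)
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2) abort("need exactly two groups.")
  split_vals <- split(values, droplevels(group))
  if (any(lengths(split_vals) < 2)) abort("both groups need at least 2 values.")
  if (method == "t") {
    if (any(vapply(split_vals, sd, numeric(1)) == 0)) {
      abort("zero variance within a group; t-test undefined.")
    }
    ht <- t.test(split_vals[[1]], split_vals[[2]])
  } else {
    exact <- length(values) <= 20 && !any(duplicated(values))
    ht <- suppressWarnings(
      wilcox.test(split_vals[[1]], split_vals[[2]], exact = exact)
    )
  }
  tibble(method = method, statistic = unname(ht$statistic), p = ht$p.value)
}
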