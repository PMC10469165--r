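#' Canonical correlations between two expression views
#'
#' Computes the correlations of successive canonical variate pairs between
#' two matrices sharing their observation (row) dimension, via SVD of the
#' whitened cross-covariance. A ridge `epsilon` is added to each
#' within-view covariance so rank-deficient views (more variables than
#' observations) remain solvable; with `epsilon = 0` a rank-deficient view
#' is an error. For cluster matching the observations are the common
#' variable features and the variables are the cells of each cluster.
#'
#' @param x,y Numeric matrices with equal `nrow` (shared observations).
#' @param n_components Number of correlations returned; defaults to
#'   `min(ncol(x), ncol(y), nrow(x) - 1)`.
#' @param epsilon Ridge added to each within-view covariance.
#' @return Non-increasing numeric vector of correlations in `[0, 1]`.
#' @export
canonical_correlations <- function(x, y, n_components = NULL, epsilon = 0) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (nrow(x) != nrow(y)) abort("views must share the observation dimension.")
  n <- nrow(x)
  if (n < 3) abort("need at least 3 shared observations.")
  k_max <- min(ncol(x), ncol(y), n - 1L)
  n_components <- min(n_components %||% k_max, k_max)

  xc <- scale(x, center = TRUE, scale = FALSE)
  yc <- scale(y, center = TRUE, scale = FALSE)
  sxx <- crossprod(xc) / (n - 1) + diag(epsilon, ncol(x))
  syy <- crossprod(yc) / (n - 1) + diag(epsilon, ncol(y))
  sxy <- crossprod(xc, yc) / (n - 1)

  inv_sqrt <- function(s, view) {
    e <- eigen(s, symmetric = TRUE)
    tol <- max(e$values) * 1e-10
    if (any(e$values < tol)) {
      abort(sprintf(
        "%s within-view covariance is rank deficient; use epsilon > 0.", view
      ))
    }
    e$vectors %*% (t(e$vectors) / sqrt(e$values))
  }
  m <- inv_sqrt(sxx, "first") %*% sxy %*% inv_sqrt(syy, "second")
  d <- svd(m, nu = 0, nv = 0)$d
  pmin(pmax(d[seq_len(n_components)], 0), 1)
}

#' Harmonize per-sample CAF clusters into shared subtypes
#'
#' Runs canonical correlation analysis on every cross-sample pair of
#' cluster profiles (rows = common variable features, columns = cells) and
#' assembles subtypes greedily: pairs are visited by descending first
#' canonical correlation, ties resolved by comparing deeper canonical
#' correlations until a difference appears, and a pair is merged unless the
#' merge would place two clusters of the same sample in one subtype.
#' Residual unmatched clusters become singleton subtypes.
#'
#' @param profiles Named list (one entry per sample) of named lists of
#'   feature x cell matrices, all sharing identically ordered feature rows.
#' @param n_components Canonical depth computed per pair (also the maximum
#'   tie-break depth).
#' @param epsilon Ridge passed to [canonical_correlations()].
#' @param tie_tol Correlations closer than this are treated as tied.
#' @return A `caf_correspondence`: list with `assignment` (sample, cluster,
#'   subtype, cc1, cc2, tie_depth) and `pairs` (the full audit trail of
#'   pairwise canonical correlation vectors with accept/reject flags).
#' @export
match_clusters <- function(profiles, n_components = 5, epsilon = 1e-3,
                           tie_tol = 1e-9) {
  if (length(profiles) < 2) abort("need clusters from at least 2 samples.")
  samples <- names(profiles)
  stopifnot(!is.null(samples), all(map_int(profiles, length) >= 1))

  units <- map_dfr(samples, function(s) {
    tibble(sample = s, cluster = names(profiles[[s]]))
  }) |>
    mutate(id = row_number())

  pair_rows <- list()
  for (a in seq_along(samples)) {
    for (b in seq_along(samples)) {
      if (b <= a) next
      for (ca in names(profiles[[a]])) {
        for (cb in names(profiles[[b]])) {
          cc <- canonical_correlations(
            profiles[[a]][[ca]], profiles[[b]][[cb]],
            n_components = n_components, epsilon = epsilon
          )
          cc <- c(cc, rep(0, n_components - length(cc)))
          pair_rows[[length(pair_rows) + 1L]] <- tibble(
            sample_a = samples[a], cluster_a = ca,
            sample_b = samples[b], cluster_b = cb,
            cc1 = cc[1], cc2 = cc[2], cc = list(cc)
          )
        }
      }
    }
  }
  pairs <- bind_rows(pair_rows)

  # lexicographic order on tie-quantized correlation vectors
  q <- do.call(rbind, map(pairs$cc, ~ round(.x / tie_tol)))
  ord <- do.call(order, c(as.data.frame(-q),
                          list(pairs$sample_a, pairs$cluster_a,
                               pairs$sample_b, pairs$cluster_b)))
  pairs <- pairs[ord, ]
  q <- q[ord, , drop = FALSE]

  uid <- function(s, cl) units$id[units$sample == s & units$cluster == cl]
  parent <- units$id
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  group_samples <- map(units$id, ~ units$sample[.x])

  accepted <- logical(nrow(pairs))
  tie_depth <- integer(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ia <- uid(pairs$sample_a[i], pairs$cluster_a[i])
    ib <- uid(pairs$sample_b[i], pairs$cluster_b[i])
    ra <- find(ia)
    rb <- find(ib)
    if (ra == rb) next
    if (length(intersect(group_samples[[ra]], group_samples[[rb]])) > 0) next
    # tie depth: how deep the comparison had to go against the next
    # still-competing pair involving either cluster
    depth <- 1L
    if (i < nrow(pairs)) {
      for (j in seq.int(i + 1L, nrow(pairs))) {
        shares <- (pairs$sample_a[j] == pairs$sample_a[i] &
                     pairs$cluster_a[j] == pairs$cluster_a[i]) ||
          (pairs$sample_b[j] == pairs$sample_b[i] &
             pairs$cluster_b[j] == pairs$cluster_b[i])
        if (shares) {
          diff_at <- which(q[i, ] != q[j, ])
          depth <- if (length(diff_at)) diff_at[1] else n_components
          break
        }
      }
    }
    accepted[i] <- TRUE
    tie_depth[i] <- depth
    parent[ra] <- rb
    group_samples[[rb]] <- c(group_samples[[rb]], group_samples[[ra]])
  }
  pairs$accepted <- accepted
  pairs$tie_depth <- ifelse(accepted, tie_depth, NA_integer_)

  roots <- map_int(units$id, find)
  root_order <- unique(roots[order(units$sample, units$cluster)])
  subtype <- paste0("ST", match(roots, root_order))
  singletons <- names(which(table(roots) == 1))
  if (length(singletons)) {
    inform(sprintf("%d unmatched cluster(s) assigned singleton subtypes",
                   length(singletons)))
  }

  joined <- map_dfr(seq_len(nrow(units)), function(i) {
    hit <- pairs |>
      filter(.data$accepted,
             (.data$sample_a == units$sample[i] & .data$cluster_a == units$cluster[i]) |
               (.data$sample_b == units$sample[i] & .data$cluster_b == units$cluster[i])) |>
      dplyr::slice_max(.data$cc1, n = 1, with_ties = FALSE)
    tibble(
      sample = units$sample[i], cluster = units$cluster[i],
      subtype = subtype[i],
      cc1 = if (nrow(hit)) hit$cc1 else NA_real_,
      cc2 = if (nrow(hit)) hit$cc2 else NA_real_,
      tie_depth = if (nrow(hit)) hit$tie_depth else NA_integer_
    )
  })

  structure(
    list(assignment = joined,
         pairs = select(pairs, -"cc") |>
           mutate(cc_trail = map_chr(pairs$cc, ~ paste(signif(.x, 6), collapse = ","))),
         epsilon = epsilon, n_components = n_components),
    class = "caf_correspondence"
  )
}

#' @exportS3Method base::print
print.caf_correspondence <- function(x, ...) {
  cat(sprintf("<caf_correspondence> %d clusters -> %d subtypes (ridge %g)\n",
              nrow(x$assignment), length(unique(x$assignment$subtype)),
              x$epsilon))
  print(x$assignment, n = 20)
  invisible(x)
}
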