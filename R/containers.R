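# (internal)
new_caf_sample <- function(counts, meta, sample_id) {
  stopifnot(
    is(counts, "sparseMatrix") || is.matrix(counts),
    !anyDuplicated(rownames(counts)), !anyDuplicated(colnames(counts)),
    identical(colnames(counts), meta$barcode)
  )
  if (any(counts < 0)) abort("UMI counts must be non-negative.")
  structure(
    list(counts = counts, meta = as_tibble(meta), sample_id = sample_id),
    class = "caf_sample"
  )
}

#' @exportS3Method base::print
print.caf_sample <- function(x, ...) {
  cat(sprintf(
    "<caf_sample %s> %d genes x %d cells (%s)\n",
    x$sample_id, nrow(x$counts), ncol(x$counts),
    paste(sprintf("%s: %d", names(table(x$meta$tissue)),
                  as.integer(table(x$meta$tissue))), collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.caf_sample <- function(x) dim(x$counts)

# (internal)
new_caf_norm <- function(data, meta, sample_id, scale_factor) {
  structure(
    list(data = data, meta = as_tibble(meta), sample_id = sample_id,
         scale_factor = scale_factor,
         formula = "ln(1 + scale_factor * count / cell_total)"),
    class = "caf_norm"
  )
}

#' @exportS3Method base::print
print.caf_norm <- function(x, ...) {
  cat(sprintf(
    "<caf_norm %s> %d genes x %d cells, scale factor %g\n",
    x$sample_id, nrow(x$data), ncol(x$data), x$scale_factor
  ))
  invisible(x)
}

#' @export
dim.caf_norm <- function(x) dim(x$data)

# (internal)
# Extract a genes x cells dense submatrix of normalized values.
norm_values <- function(nm, genes = NULL, cells = NULL) {
  m <- nm$data
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing)) {
      abort(sprintf("genes not present: %s",
                    paste(head(missing, 5), collapse = ", ")))
    }
    m <- m[genes, , drop = FALSE]
  }
  if (!is.null(cells)) m <- m[, cells, drop = FALSE]
  as.matrix(m)
}
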