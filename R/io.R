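#' Write a sample in 10x triplet format
#'
#' Writes `matrix.mtx`, `features.tsv`, `barcodes.tsv` and a `cells.tsv`
#' metadata table (barcode, sample, tissue, stage) under `dir`.
#'
#' @param x A `caf_sample`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sample_10x <- function(x, dir) {
  stopifnot(inherits(x, "caf_sample"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(as(x$counts, "CsparseMatrix"), file.path(dir, "matrix.mtx"))
  readr::write_tsv(tibble(gene_id = rownames(x$counts)),
                   file.path(dir, "features.tsv"), col_names = FALSE)
  readr::write_tsv(tibble(barcode = colnames(x$counts)),
                   file.path(dir, "barcodes.tsv"), col_names = FALSE)
  readr::write_tsv(
    mutate(x$meta, sample = x$sample_id, .after = "barcode"),
    file.path(dir, "cells.tsv")
  )
  invisible(dir)
}

#' Read a sample from 10x triplet format
#'
#' Expects the files written by [write_sample_10x()]. If `cells.tsv` is
#' absent, tissue defaults to `"tumor"` and stage to `NA`.
#'
#' @param dir Directory holding `matrix.mtx`, `features.tsv`, `barcodes.tsv`.
#' @param sample_id Sample identifier; defaults to the directory name.
#' @return A `caf_sample`.
#' @export
read_sample_10x <- function(dir, sample_id = basename(dir)) {
  mtx <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx)) abort(sprintf("no matrix.mtx under %s", dir))
  counts <- tryCatch(
    as(Matrix::readMM(mtx), "CsparseMatrix"),
    error = function(e) abort(sprintf("failed to parse %s: %s", mtx, conditionMessage(e)))
  )
  genes <- readr::read_tsv(file.path(dir, "features.tsv"),
                           col_names = FALSE, show_col_types = FALSE)[[1]]
  barcodes <- readr::read_tsv(file.path(dir, "barcodes.tsv"),
                              col_names = FALSE, show_col_types = FALSE)[[1]]
  if (nrow(counts) != length(genes) || ncol(counts) != length(barcodes)) {
    abort(sprintf("%s: dimensions do not match features/barcodes files", mtx))
  }
  dimnames(counts) <- list(genes, barcodes)
  cells_path <- file.path(dir, "cells.tsv")
  meta <- if (file.exists(cells_path)) {
    readr::read_tsv(cells_path, show_col_types = FALSE) |>
      select(-dplyr::any_of("sample"))
  } else {
    tibble(barcode = barcodes, tissue = "tumor", stage = NA_character_)
  }
  new_caf_sample(counts, meta[match(barcodes, meta$barcode), ], sample_id)
}

#' Read a GMT gene-set file
#'
#' Standard tab format: set name, description, then member genes.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- map(parts, ~ .x[-(1:2)])
  names(sets) <- map_chr(parts, 1)
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field written for every set.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "synthetic") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
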