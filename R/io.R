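#' Assemble an atlas bundle
#'
#' An atlas bundle holds one dataset of a multi-organ atlas: a sparse
#' genes-by-cells UMI count matrix plus per-gene and per-cell annotation.
#'
#' @param counts A genes x cells sparse (or dense) matrix of nonnegative
#'   integer UMI counts with gene ids as rownames and barcodes as colnames.
#' @param genes Optional data.frame with columns `gene_id`, `organelle`
#'   ("nuclear", "mitochondrial" or "chloroplast") and optionally
#'   `probe_count` and `is_tf`. Defaults are derived from the matrix
#'   rownames with all genes nuclear.
#' @param cells Optional data.frame with a `barcode` column (one row per
#'   matrix column) carrying QC covariates and `cluster`/`subcluster`
#'   labels when known.
#' @param dataset_label Character scalar identifying the dataset (e.g. the
#'   developmental time point or tissue).
#' @param cfg [pipeline_config()] supplying the organelle gene-id prefix
#'   rules used when `genes` lacks an `organelle` column.
#' @return An object of class `atlas_bundle`.
#' @export
atlas_bundle <- function(counts, genes = NULL, cells = NULL, dataset_label,
                         cfg = pipeline_config()) {
  if (!inherits(counts, "CsparseMatrix"))
    counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                      "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0) || any(counts@x != round(counts@x)))
    stopf("count matrix must contain nonnegative integers")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("count matrix must carry gene ids as rownames and barcodes as colnames")
  if (missing(dataset_label) || !is.character(dataset_label) ||
      length(dataset_label) != 1 || !nzchar(dataset_label))
    stopf("dataset_label must be a nonempty string")
  if (is.null(genes)) {
    genes <- data.frame(gene_id = rownames(counts), stringsAsFactors = FALSE)
  }
  need_cols(genes, "gene_id", "genes annotation")
  if (!"organelle" %in% names(genes))
    genes$organelle <- organelle_from_prefix(genes$gene_id, cfg)
  if (!all(genes$organelle %in% c("nuclear", "mitochondrial", "chloroplast")))
    stopf("organelle must be one of nuclear/mitochondrial/chloroplast")
  if (!"probe_count" %in% names(genes)) genes$probe_count <- NA_real_
  if (any(!is.na(genes$probe_count) & genes$probe_count < 0))
    stopf("probe_count must be nonnegative when present")
  if (is.null(cells)) {
    cells <- data.frame(barcode = colnames(counts), stringsAsFactors = FALSE)
  }
  need_cols(cells, "barcode", "cell metadata")
  if (!"dataset_label" %in% names(cells)) cells$dataset_label <- dataset_label
  if (nrow(genes) != nrow(counts))
    stopf("gene annotation rows (%d) do not match matrix rows (%d)",
          nrow(genes), nrow(counts))
  if (nrow(cells) != ncol(counts))
    stopf("cell metadata rows (%d) do not match matrix columns (%d)",
          nrow(cells), ncol(counts))
  if (anyDuplicated(genes$gene_id))
    stopf("duplicated gene ids: %s",
          paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  if (anyDuplicated(cells$barcode))
    stopf("duplicated barcodes within dataset '%s': %s", dataset_label,
          paste(unique(cells$barcode[duplicated(cells$barcode)]), collapse = ", "))
  if (!identical(genes$gene_id, rownames(counts)))
    stopf("gene annotation order does not match matrix rownames")
  if (!identical(cells$barcode, colnames(counts)))
    stopf("cell metadata order does not match matrix colnames")
  rownames(genes) <- NULL
  rownames(cells) <- NULL
  structure(list(counts = counts, genes = genes, cells = cells,
                 dataset_label = dataset_label),
            class = "atlas_bundle")
}

#' @export
print.atlas_bundle <- function(x, ...) {
  cat(sprintf("atlas_bundle '%s': %d genes x %d cells, %s UMI total\n",
              x$dataset_label, nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

organelle_from_prefix <- function(gene_id, cfg = pipeline_config()) {
  out <- rep("nuclear", length(gene_id))
  out[startsWith(gene_id, cfg$mito_prefix)] <- "mitochondrial"
  out[startsWith(gene_id, cfg$chloro_prefix)] <- "chloroplast"
  out
}

#' Read a 10x-style sparse count triplet into an atlas bundle
#'
#' Reads a MatrixMarket sparse matrix together with tab-separated
#' `features` and `barcodes` tables (header line required; features need a
#' `gene_id` column and may carry `organelle`, `probe_count` and `is_tf`;
#' barcodes need a `barcode` column). Matrix entries must be nonnegative
#' integers and dimensions must match the two tables.
#'
#' @param matrix_path Path to the `.mtx` file (genes x cells).
#' @param features_path Path to the features TSV.
#' @param barcodes_path Path to the barcodes TSV.
#' @param dataset_label Dataset identifier stored on the bundle.
#' @param cfg [pipeline_config()] for organelle prefix rules.
#' @return An [atlas_bundle()].
#' @export
read_counts <- function(matrix_path, features_path, barcodes_path,
                        dataset_label, cfg = pipeline_config()) {
  m <- Matrix::readMM(matrix_path)
  m <- methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
  if (any(m@x < 0) || any(m@x != round(m@x)))
    stopf("matrix '%s' contains negative or non-integer entries", matrix_path)
  genes <- utils::read.delim(features_path, stringsAsFactors = FALSE,
                             fileEncoding = "UTF-8")
  need_cols(genes, "gene_id", sprintf("features file '%s'", features_path))
  cells <- utils::read.delim(barcodes_path, stringsAsFactors = FALSE,
                             fileEncoding = "UTF-8")
  need_cols(cells, "barcode", sprintf("barcodes file '%s'", barcodes_path))
  if (nrow(genes) != nrow(m))
    stopf("matrix header says %d rows but features file has %d records",
          nrow(m), nrow(genes))
  if (nrow(cells) != ncol(m))
    stopf("matrix header says %d columns but barcodes file has %d records",
          ncol(m), nrow(cells))
  if ("probe_count" %in% names(genes))
    genes$probe_count <- suppressWarnings(as.numeric(genes$probe_count))
  rownames(m) <- genes$gene_id
  colnames(m) <- cells$barcode
  atlas_bundle(m, genes = genes, cells = cells,
               dataset_label = dataset_label, cfg = cfg)
}

#' Write an atlas bundle as MatrixMarket + TSV tables
#'
#' Inverse of [read_counts()]: writes `matrix.mtx`, `features.tsv`,
#' `barcodes.tsv` and the full cell metadata as `cells.tsv` into `dir`.
#' All tables are tab-separated UTF-8 with a header line; absent
#' probe counts are written as empty strings.
#'
#' @param bundle An [atlas_bundle()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_counts <- function(bundle, dir) {
  stopifnot(inherits(bundle, "atlas_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv",
                            "cells.tsv"))
  Matrix::writeMM(bundle$counts, paths[1])
  write_tsv(bundle$genes, paths[2])
  write_tsv(bundle$cells["barcode"], paths[3])
  write_tsv(bundle$cells, paths[4])
  invisible(paths)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
}

#' Load curated cell-type marker sets (GMT)
#'
#' Each line is `cell_type<TAB>description<TAB>gene1<TAB>gene2...`.
#' Duplicate genes within a line are dropped; a line without at least one
#' gene is a format error. Gene ids are taken as-is (no genome check).
#'
#' @param path GMT file path.
#' @return A named list of character vectors (class `curated_markers`),
#'   one element per cell type.
#' @export
load_curated_markers <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stopf("no marker sets in '%s'", path)
  out <- list()
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stopf("marker set line needs a type, description and >=1 gene: '%s'", ln)
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) < 1)
      stopf("marker set '%s' has an empty gene list", fields[1])
    out[[fields[1]]] <- genes
  }
  structure(out, class = "curated_markers")
}

#' Write curated marker sets as GMT
#'
#' @param sets Named list of gene-id character vectors.
#' @param path Output path.
#' @param description Description field written to every line.
#' @return Invisibly, `path`.
#' @export
write_curated_markers <- function(sets, path, description = ".") {
  stopifnot(length(names(sets)) == length(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Default dataset-to-organ map of the atlas study
#'
#' Groups datasets into organs the way the cross-organ specificity
#' analysis defines them: imbibed/germinating seeds (0 and 1.25 days),
#' seedlings (3, 6 and 12 days), rosettes (21 and 30 days), stems, flowers
#' and siliques.
#'
#' @return data.frame with columns `dataset_label`, `organ_group`.
#' @export
default_organ_map <- function() {
  data.frame(
    dataset_label = c("seed_0d", "seed_1.25d", "seedling_3d", "seedling_6d",
                      "seedling_12d", "rosette_21d", "rosette_30d",
                      "stem", "flower", "silique"),
    organ_group = c("seed", "seed", "seedling", "seedling", "seedling",
                    "rosette", "rosette", "stem", "flower", "silique"),
    stringsAsFactors = FALSE
  )
}
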