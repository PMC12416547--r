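#' Aggregate UMI counts into per-group pseudobulk profiles
#'
#' Sums counts over all cells of each group. Group identifiers are
#' namespaced by dataset as `dataset::group` (every dataset has a
#' "cluster 1", so bare labels would collide across datasets); with
#' `grouping = "dataset"` the whole tissue is aggregated into a single row
#' named by the dataset label.
#'
#' @param bundle An [atlas_bundle()].
#' @param grouping One of `"cluster"`, `"subcluster"`, `"dataset"`.
#' @return Base matrix of raw summed counts, groups x genes. Total counts
#'   are conserved: `sum(result) == sum(bundle$counts)`.
#' @export
aggregate_counts <- function(bundle, grouping = c("cluster", "subcluster",
                                                  "dataset")) {
  stopifnot(inherits(bundle, "atlas_bundle"))
  grouping <- match.arg(grouping)
  labels <- if (grouping == "dataset") {
    rep(bundle$dataset_label, ncol(bundle$counts))
  } else {
    if (!grouping %in% names(bundle$cells))
      stopf("cells carry no '%s' labels", grouping)
    bundle$cells[[grouping]]
  }
  bad <- which(is.na(labels))
  if (length(bad) > 0)
    stopf("unlabelled cell(s): %s",
          paste(bundle$cells$barcode[utils::head(bad, 5)], collapse = ", "))
  grp <- factor(labels)
  ind <- Matrix::sparseMatrix(i = seq_along(grp), j = as.integer(grp), x = 1,
                              dims = c(length(grp), nlevels(grp)))
  agg <- Matrix::t(bundle$counts %*% ind)  # groups x genes
  agg <- as.matrix(agg)
  rn <- levels(grp)
  if (grouping != "dataset") rn <- paste(bundle$dataset_label, rn, sep = "::")
  dimnames(agg) <- list(rn, rownames(bundle$counts))
  agg
}

#' Normalize pseudobulk counts to TPM
#'
#' UMI counts carry no gene-length bias, so TPM here is counts scaled to
#' one million per profile (counts-per-million); each nonzero row of the
#' result sums to 1e6. Rows with zero total count become all-zero and are
#' flagged in the `zero_rows` attribute rather than erroring.
#'
#' @param raw Groups x genes matrix of raw counts (from
#'   [aggregate_counts()]; multiple datasets can be `rbind`-ed first).
#' @return Numeric matrix of TPM values with attribute `zero_rows`.
#' @export
to_tpm <- function(raw) {
  if (any(raw < 0)) stopf("pseudobulk counts must be nonnegative")
  totals <- rowSums(raw)
  zero <- totals == 0
  scale <- ifelse(zero, 0, 1e6 / totals)
  tpm <- raw * scale
  attr(tpm, "zero_rows") <- rownames(raw)[zero] %||% which(zero)
  tpm
}

#' Log2-transform a TPM matrix
#'
#' Uses a pseudocount of 1 (`log2(TPM + 1)`) so zero TPM maps to zero;
#' under this convention "log2 TPM higher than five" means TPM > 31.
#'
#' @param tpm TPM matrix from [to_tpm()].
#' @return Matrix of `log2(TPM + 1)` values.
#' @export
log2_tpm <- function(tpm) {
  out <- log2(tpm + 1)
  attr(out, "zero_rows") <- attr(tpm, "zero_rows")
  out
}

#' Correlate pseudobulk profiles
#'
#' Pearson correlation of log2 TPM profiles between every pair of groups.
#' Constant (e.g. all-zero) profiles have no defined correlation; their
#' rows and columns are NA.
#'
#' @param tpm Groups x genes TPM matrix (>= 2 rows).
#' @return Symmetric groups x groups correlation matrix with unit diagonal
#'   for non-constant profiles.
#' @export
correlate_pseudobulk <- function(tpm) {
  if (nrow(tpm) < 2) stopf("need at least two pseudobulk profiles")
  lg <- log2_tpm(tpm)
  sds <- apply(lg, 1, stats::sd)
  cc <- suppressWarnings(stats::cor(t(lg)))
  cc[sds == 0, ] <- NA_real_
  cc[, sds == 0] <- NA_real_
  diag(cc)[sds > 0] <- 1
  cc
}

#' Pseudobulk TPM across several datasets
#'
#' Aggregates each bundle by `grouping` and stacks the rows before TPM
#' normalization, yielding the cross-organ cluster x gene TPM table the
#' specificity rules operate on. All bundles must share the same genes.
#'
#' @param bundles List of [atlas_bundle()] objects.
#' @param grouping Passed to [aggregate_counts()].
#' @return TPM matrix with `dataset::cluster` rows.
#' @export
pseudobulk_tpm <- function(bundles, grouping = "cluster") {
  if (inherits(bundles, "atlas_bundle")) bundles <- list(bundles)
  gsets <- lapply(bundles, function(b) rownames(b$counts))
  if (length(unique(vapply(gsets, paste, "", collapse = "\r"))) != 1)
    stopf("all bundles must share an identical gene set")
  raw <- do.call(rbind, lapply(bundles, aggregate_counts, grouping = grouping))
  to_tpm(raw)
}
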