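#' Filter nuclei on the atlas quality cut-offs
#'
#' A nucleus is kept iff all of: genes detected > 300 and < 7,000, UMI >
#' 400, mitochondrial reads < 5% and chloroplast reads < 15% (thresholds
#' from `cfg`; every inequality strict). Removed records carry the first
#' failing rule, evaluated in the fixed order `min_genes`, `max_genes`,
#' `min_umi`, `pct_mito`, `pct_chloro` so reports are reproducible.
#'
#' @param cells data.frame of cell records with columns `barcode`,
#'   `genes_detected`, `umi_total`, `pct_mito`, `pct_chloro`.
#' @param cfg [pipeline_config()].
#' @return list with `kept` (input rows passing, original order) and
#'   `removed` (failing rows plus a `reason` column); together they
#'   partition the input.
#' @export
filter_nuclei <- function(cells, cfg = pipeline_config()) {
  need_cols(cells, c("barcode", "genes_detected", "umi_total",
                     "pct_mito", "pct_chloro"), "cell table")
  for (f in c("genes_detected", "umi_total", "pct_mito", "pct_chloro")) {
    bad <- which(is.na(cells[[f]]))
    if (length(bad) > 0)
      stopf("missing %s for barcode(s): %s", f,
            paste(cells$barcode[utils::head(bad, 5)], collapse = ", "))
  }
  if (any(cells$pct_mito < 0 | cells$pct_mito > 100) ||
      any(cells$pct_chloro < 0 | cells$pct_chloro > 100))
    stopf("organelle percentages must lie in [0, 100]")
  reason <- rep(NA_character_, nrow(cells))
  rule <- function(fails, code) {
    reason[is.na(reason) & fails] <<- code
  }
  rule(cells$genes_detected <= cfg$min_genes, "min_genes")
  rule(cells$genes_detected >= cfg$max_genes, "max_genes")
  rule(cells$umi_total <= cfg$min_umi, "min_umi")
  rule(cells$pct_mito >= cfg$max_pct_mito, "pct_mito")
  rule(cells$pct_chloro >= cfg$max_pct_chloro, "pct_chloro")
  keep <- is.na(reason)
  removed <- cells[!keep, , drop = FALSE]
  removed$reason <- reason[!keep]
  rownames(removed) <- NULL
  kept <- cells[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, removed = removed)
}

#' Filter spatial spots on the minimum gene/UMI cut-off
#'
#' Spots with fewer than 125 genes detected or fewer than 125 UMI are
#' removed ("fewer than" is strict, so a spot at exactly 125/125 passes).
#'
#' @param spots data.frame with columns `spot_id`, `genes_detected`,
#'   `umi_total` (and usually `x`, `y`).
#' @param cfg [pipeline_config()].
#' @return list with `kept` and `removed` (with `reason`).
#' @export
filter_spots <- function(spots, cfg = pipeline_config()) {
  need_cols(spots, c("spot_id", "genes_detected", "umi_total"), "spot table")
  if (any(spots$genes_detected < 0 | spots$umi_total < 0, na.rm = FALSE))
    stopf("spot counts must be nonnegative")
  reason <- rep(NA_character_, nrow(spots))
  reason[spots$genes_detected < cfg$spot_min_genes] <- "min_genes"
  reason[is.na(reason) & spots$umi_total < cfg$spot_min_umi] <- "min_umi"
  keep <- is.na(reason)
  removed <- spots[!keep, , drop = FALSE]
  removed$reason <- reason[!keep]
  rownames(removed) <- NULL
  kept <- spots[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, removed = removed)
}

#' Summarize a QC filtering run
#'
#' @param kept,removed The two components returned by [filter_nuclei()] or
#'   [filter_spots()].
#' @return list with `n_input`, `n_kept`, `n_removed`, `removed_by_reason`
#'   (named integer vector) and the median UMI and genes detected over
#'   kept cells (NA when nothing was kept — medians are never reported as
#'   zero for an empty kept set).
#' @export
qc_summary <- function(kept, removed) {
  by_reason <- if (nrow(removed) > 0) table(removed$reason) else table(character())
  list(
    n_input = nrow(kept) + nrow(removed),
    n_kept = nrow(kept),
    n_removed = nrow(removed),
    removed_by_reason = stats::setNames(as.integer(by_reason),
                                        names(by_reason)),
    median_umi = if (nrow(kept) > 0) stats::median(kept$umi_total) else NA_real_,
    median_genes = if (nrow(kept) > 0) stats::median(kept$genes_detected)
                   else NA_real_
  )
}

#' Apply nucleus QC to an atlas bundle
#'
#' Convenience wrapper: runs [filter_nuclei()] on the bundle's cell table
#' and subsets the count matrix to the kept cells.
#'
#' @param bundle An [atlas_bundle()].
#' @param cfg [pipeline_config()].
#' @return list with the filtered `bundle`, the `removed` records and the
#'   [qc_summary()].
#' @export
qc_bundle <- function(bundle, cfg = pipeline_config()) {
  stopifnot(inherits(bundle, "atlas_bundle"))
  res <- filter_nuclei(bundle$cells, cfg)
  keep <- bundle$cells$barcode %in% res$kept$barcode
  filtered <- atlas_bundle(bundle$counts[, keep, drop = FALSE],
                           genes = bundle$genes,
                           cells = bundle$cells[keep, , drop = FALSE],
                           dataset_label = bundle$dataset_label, cfg = cfg)
  list(bundle = filtered, removed = res$removed,
       summary = qc_summary(res$kept, res$removed))
}
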