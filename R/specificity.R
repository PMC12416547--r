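organ_of_rows <- function(tpm, organ_map) {
  ds <- sub("::.*$", "", rownames(tpm))
  miss <- setdiff(unique(ds), organ_map$dataset_label)
  if (length(miss) > 0)
    stopf("organ map does not cover dataset(s): %s",
          paste(miss, collapse = ", "))
  organ_map$organ_group[match(ds, organ_map$dataset_label)]
}

#' Classify one marker gene as organ-unique or shared
#'
#' Applies the cross-organ pseudobulk rules to a candidate marker. With
#' `T` the gene's TPM in the target cluster and `c` ranging over every
#' cluster of every other organ: the gene is rejected by rule 1 when `T`
#' is not more than `fold_ratio` (default 4) times higher than some
#' other-organ cluster (equivalently, a survivor must beat
#' `fold_ratio * max(other-organ TPM)`), and by rule 2 when any
#' other-organ cluster has `log2(TPM + 1)` above `log2tpm_cap` (default
#' 5, i.e. TPM above 31). Rule 1 is evaluated first; the gene is unique
#' iff neither fires. Raw TPM is compared in rule 1 and pseudocount-1
#' log2 TPM in rule 2.
#'
#' @param gene Gene id (must be a column of `tpm`).
#' @param target_cluster `dataset::cluster` row of `tpm`.
#' @param tpm Cross-organ pseudobulk TPM matrix ([pseudobulk_tpm()]).
#' @param organ_map data.frame `dataset_label` -> `organ_group` covering
#'   every dataset in `tpm`.
#' @param cfg [pipeline_config()].
#' @return One-row data.frame: `gene_id`, `cluster`, `classification`
#'   (`unique`, `rejected_rule1` or `rejected_rule2`), `offending_cluster`
#'   (NA when unique), `fold_ratio_min` (T over the other-organ maximum),
#'   `max_other_log2tpm`, `degenerate` (TRUE when no other organ exists,
#'   making uniqueness vacuous).
#' @export
classify_marker <- function(gene, target_cluster, tpm, organ_map,
                            cfg = pipeline_config()) {
  if (!gene %in% colnames(tpm)) stopf("gene '%s' absent from pseudobulk", gene)
  if (!target_cluster %in% rownames(tpm))
    stopf("cluster '%s' absent from pseudobulk", target_cluster)
  organs <- organ_of_rows(tpm, organ_map)
  target_organ <- organs[rownames(tpm) == target_cluster][1]
  other <- which(organs != target_organ)
  t_val <- tpm[target_cluster, gene]
  if (length(other) == 0) {
    return(data.frame(gene_id = gene, cluster = target_cluster,
                      classification = "unique",
                      offending_cluster = NA_character_,
                      fold_ratio_min = Inf, max_other_log2tpm = NA_real_,
                      degenerate = TRUE, stringsAsFactors = FALSE))
  }
  vals <- tpm[other, gene]
  i_max <- which.max(vals)
  max_other <- vals[i_max]
  fold_min <- if (max_other == 0) Inf else t_val / max_other
  max_log2 <- log2(max_other + 1)
  if (t_val <= cfg$fold_ratio * max_other) {
    cls <- "rejected_rule1"
    off <- rownames(tpm)[other][i_max]
  } else if (max_log2 > cfg$log2tpm_cap) {
    cls <- "rejected_rule2"
    off <- rownames(tpm)[other][i_max]
  } else {
    cls <- "unique"
    off <- NA_character_
  }
  data.frame(gene_id = gene, cluster = target_cluster, classification = cls,
             offending_cluster = off, fold_ratio_min = unname(fold_min),
             max_other_log2tpm = unname(max_log2), degenerate = FALSE,
             stringsAsFactors = FALSE)
}

#' Classify all stringent markers across organs
#'
#' Runs the two cross-organ rules on every (gene, target cluster) marker
#' record and summarizes how many distinct genes survive as
#' organ-by-cell-type unique markers.
#'
#' @param markers Stringent marker data.frame from
#'   [call_markers()] (`mode = "stringent"`).
#' @param tpm Cross-organ pseudobulk TPM matrix.
#' @param organ_map data.frame `dataset_label` -> `organ_group`.
#' @param cfg [pipeline_config()].
#' @return list with `calls` (one [classify_marker()] row per marker
#'   record) and `summary` (`n_candidates`, `n_unique` — distinct genes —
#'   and `percent_unique`, rounded to one decimal).
#' @export
classify_all <- function(markers, tpm, organ_map, cfg = pipeline_config()) {
  if (nrow(markers) == 0) {
    return(list(calls = data.frame(), summary = list(
      n_candidates = 0L, n_unique = 0L, percent_unique = 0)))
  }
  need_cols(markers, c("gene_id", "cluster"), "marker table")
  organs <- organ_of_rows(tpm, organ_map)
  # per organ, the per-gene maximum TPM over all clusters OUTSIDE it
  organ_levels <- unique(organs)
  max_excl <- lapply(organ_levels, function(og) {
    rows <- which(organs != og)
    if (length(rows) == 0) return(NULL)
    apply(tpm[rows, , drop = FALSE], 2, max)
  })
  names(max_excl) <- organ_levels
  argmax_excl <- lapply(organ_levels, function(og) {
    rows <- which(organs != og)
    if (length(rows) == 0) return(NULL)
    rownames(tpm)[rows][apply(tpm[rows, , drop = FALSE], 2, which.max)]
  })
  names(argmax_excl) <- organ_levels

  target_organ <- organs[match(markers$cluster, rownames(tpm))]
  if (any(is.na(target_organ)))
    stopf("marker cluster(s) absent from pseudobulk: %s",
          paste(unique(markers$cluster[is.na(target_organ)]), collapse = ", "))
  gi <- match(markers$gene_id, colnames(tpm))
  if (any(is.na(gi)))
    stopf("marker gene(s) absent from pseudobulk: %s",
          paste(unique(markers$gene_id[is.na(gi)]), collapse = ", "))

  n <- nrow(markers)
  t_val <- tpm[cbind(match(markers$cluster, rownames(tpm)), gi)]
  max_other <- numeric(n)
  off_cluster <- character(n)
  degenerate <- logical(n)
  for (og in organ_levels) {
    sel <- target_organ == og
    if (!any(sel)) next
    if (is.null(max_excl[[og]])) {
      degenerate[sel] <- TRUE
      max_other[sel] <- NA_real_
      off_cluster[sel] <- NA_character_
    } else {
      max_other[sel] <- max_excl[[og]][gi[sel]]
      off_cluster[sel] <- argmax_excl[[og]][gi[sel]]
    }
  }
  cls <- rep("unique", n)
  off <- rep(NA_character_, n)
  live <- !degenerate
  r1 <- live & t_val <= cfg$fold_ratio * max_other
  r2 <- live & !r1 & log2(max_other + 1) > cfg$log2tpm_cap
  cls[r1] <- "rejected_rule1"
  cls[r2] <- "rejected_rule2"
  off[r1 | r2] <- off_cluster[r1 | r2]
  calls <- data.frame(
    gene_id = markers$gene_id, cluster = markers$cluster,
    classification = cls, offending_cluster = off,
    fold_ratio_min = ifelse(is.na(max_other) | max_other == 0, Inf,
                            t_val / max_other),
    max_other_log2tpm = log2(max_other + 1),
    degenerate = degenerate, stringsAsFactors = FALSE
  )
  n_candidates <- length(unique(markers$gene_id))
  n_unique <- length(unique(calls$gene_id[calls$classification == "unique"]))
  list(calls = calls,
       summary = list(n_candidates = n_candidates, n_unique = n_unique,
                      percent_unique = fraction_percent(n_unique,
                                                        n_candidates, 1)))
}

#' Assign each subcluster an organ identity by majority vote
#'
#' The dataset comprising the plurality of a subcluster's cells becomes
#' its organ identity; exact ties are broken by the lexicographically
#' first dataset label and flagged.
#'
#' @param cells data.frame with `subcluster` and `dataset_label` columns
#'   (cells without a subcluster are an error).
#' @return data.frame `subcluster`, `organ_identity`, `n_cells`,
#'   `n_majority`, `tie`.
#' @export
assign_majority_organ <- function(cells) {
  need_cols(cells, c("subcluster", "dataset_label"), "cell table")
  if (nrow(cells) == 0) stopf("no cells supplied")
  if (any(is.na(cells$subcluster) | !nzchar(cells$subcluster)))
    stopf("cell(s) without a subcluster label")
  out <- lapply(split(cells$dataset_label, cells$subcluster), function(ds) {
    tab <- sort(table(ds), decreasing = TRUE)
    top <- names(tab)[tab == tab[1]]
    data.frame(organ_identity = sort(top)[1], n_cells = length(ds),
               n_majority = as.integer(tab[1]), tie = length(top) > 1,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- data.frame(subcluster = names(out), res, stringsAsFactors = FALSE,
                    row.names = NULL)
  res[order(res$subcluster), , drop = FALSE]
}
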