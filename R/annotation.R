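#' Cell-type enrichment score of one cluster against one curated set
#'
#' The number of a cluster's markers that are curated markers of the
#' candidate cell type, divided by the number of cluster markers.
#'
#' @param cluster_markers Nonempty character vector of a cluster's marker
#'   genes.
#' @param curated Character vector of curated markers for one cell type.
#' @return list with `score` in `[0, 1]` and `n_overlap`.
#' @export
enrichment_score <- function(cluster_markers, curated) {
  cluster_markers <- unique(cluster_markers)
  if (length(cluster_markers) == 0) stopf("cluster has no marker genes")
  n_overlap <- length(intersect(cluster_markers, curated))
  list(score = n_overlap / length(cluster_markers), n_overlap = n_overlap)
}

#' Annotate clusters against curated cell-type marker sets
#'
#' Scores every cluster against every curated set with
#' [enrichment_score()] and keeps the best-scoring cell type (ties broken
#' by larger overlap, then lexicographically, and flagged). A cluster is
#' called annotated when its best score reaches `cfg$min_score` and at
#' least `cfg$min_overlap_genes` curated markers concur. When `universe`
#' is supplied, curated sets are first restricted to genes present in the
#' data so absent genes cannot silently deflate scores; the restricted
#' set sizes are recorded.
#'
#' @param sets Named list of cluster marker gene vectors (see
#'   [marker_sets()]).
#' @param curated Named list of curated marker sets
#'   ([load_curated_markers()]); empty is an error.
#' @param cfg [pipeline_config()].
#' @param universe Optional character vector of genes present in the
#'   dataset.
#' @return data.frame with one row per cluster: `cluster`, `cell_type`,
#'   `score`, `n_overlap`, `n_markers`, `n_curated_used`, `annotated`,
#'   `tie`.
#' @export
annotate_clusters <- function(sets, curated, cfg = pipeline_config(),
                              universe = NULL) {
  if (length(curated) == 0) stopf("no curated marker sets supplied")
  if (length(sets) == 0) stopf("no cluster marker sets supplied")
  if (!is.null(universe))
    curated <- lapply(curated, intersect, y = universe)
  types <- sort(names(curated))
  out <- lapply(names(sets), function(cl) {
    cm <- unique(sets[[cl]])
    scores <- vapply(types, function(tp) {
      es <- enrichment_score(cm, curated[[tp]])
      c(es$score, es$n_overlap)
    }, numeric(2))
    best <- order(-scores[1, ], -scores[2, ], types)[1]
    is_tie <- sum(scores[1, ] == scores[1, best] &
                    scores[2, ] == scores[2, best]) > 1
    data.frame(
      cluster = cl, cell_type = types[best], score = scores[1, best],
      n_overlap = as.integer(scores[2, best]), n_markers = length(cm),
      n_curated_used = length(curated[[types[best]]]),
      annotated = scores[1, best] >= cfg$min_score &&
        scores[2, best] >= cfg$min_overlap_genes,
      tie = is_tie, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Cluster annotation rate
#'
#' Percentage of clusters called annotated, rounded to the nearest
#' integer (138 annotated of 183 clusters gives 75).
#'
#' @param results data.frame from [annotate_clusters()] (nonempty), or
#'   any data.frame with a logical `annotated` column.
#' @return Integer percentage.
#' @export
annotation_rate <- function(results) {
  if (is.null(results) || nrow(results) == 0) stopf("no annotation results")
  need_cols(results, "annotated", "annotation results")
  fraction_percent(sum(results$annotated), nrow(results), 0)
}
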