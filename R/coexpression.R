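detect_set <- function(counts, genes, threshold) {
  miss <- setdiff(genes, rownames(counts))
  if (length(miss) > 0)
    stopf("unknown gene(s): %s", paste(miss, collapse = ", "))
  sub <- counts[genes, , drop = FALSE]
  as.vector(Matrix::colSums(sub >= threshold) > 0)
}

#' Call nuclei co-expressing two marker sets
#'
#' A nucleus is positive when at least one gene of set A and at least one
#' gene of set B are detected (count at or above `threshold`, default 1
#' UMI/transcript). This is the polarity-positive call: set A a polarity
#' regulator panel, set B a spatially validated polar marker.
#'
#' @param counts Genes x cells count matrix with dimnames (single-nucleus
#'   counts or [points_to_counts()] output).
#' @param set_a,set_b Nonempty gene-id vectors present in the matrix.
#' @param threshold Detection threshold in counts.
#' @return data.frame per cell: `cell_id`, `detected_a`, `detected_b`,
#'   `positive`.
#' @export
co_detect <- function(counts, set_a, set_b, threshold = 1) {
  if (length(set_a) == 0 || length(set_b) == 0)
    stopf("both gene sets must be nonempty")
  da <- detect_set(counts, set_a, threshold)
  db <- detect_set(counts, set_b, threshold)
  data.frame(cell_id = colnames(counts), detected_a = da, detected_b = db,
             positive = da & db, stringsAsFactors = FALSE)
}

#' Group cells at the intersection of two patterning axes
#'
#' Given marker sets for the two poles of each of two axes (apical/basal
#' and convex/concave in the apical-hook analysis), assigns each cell to
#' one of the four conjunction groups (e.g. apical&convex) when exactly
#' one pole of each axis is detected. Cells detected for both poles of an
#' axis are ambiguous for that axis and excluded from all four groups;
#' cells missing a pole on either axis are unassigned. The four groups
#' plus ambiguous plus unassigned partition the cells.
#'
#' @param counts Genes x cells count matrix.
#' @param apical,basal,convex,concave Pairwise-disjoint marker gene sets.
#' @param threshold Detection threshold in counts.
#' @return list with `cells` (per-cell axis states and group) and
#'   `groups` (group sizes, including `ambiguous` and `unassigned`).
#' @export
axis_groups <- function(counts, apical, basal, convex, concave,
                        threshold = 1) {
  sets <- list(apical = apical, basal = basal, convex = convex,
               concave = concave)
  all_genes <- unlist(sets)
  if (anyDuplicated(all_genes))
    stopf("marker sets overlap on gene(s): %s",
          paste(unique(all_genes[duplicated(all_genes)]), collapse = ", "))
  det <- lapply(sets, function(g) detect_set(counts, g, threshold))
  axis_state <- function(pos, neg, pos_lab, neg_lab) {
    out <- rep("none", length(pos))
    out[pos & !neg] <- pos_lab
    out[neg & !pos] <- neg_lab
    out[pos & neg] <- "ambiguous"
    out
  }
  ax1 <- axis_state(det$apical, det$basal, "apical", "basal")
  ax2 <- axis_state(det$convex, det$concave, "convex", "concave")
  group <- rep("unassigned", length(ax1))
  group[ax1 == "ambiguous" | ax2 == "ambiguous"] <- "ambiguous"
  ok <- ax1 %in% c("apical", "basal") & ax2 %in% c("convex", "concave")
  group[ok] <- paste(ax1[ok], ax2[ok], sep = "&")
  cells <- data.frame(cell_id = colnames(counts), axis1 = ax1, axis2 = ax2,
                      group = group, stringsAsFactors = FALSE)
  lvls <- c("apical&convex", "apical&concave", "basal&convex",
            "basal&concave", "ambiguous", "unassigned")
  sizes <- table(factor(group, levels = lvls))
  list(cells = cells,
       groups = data.frame(group = lvls, size = as.integer(sizes),
                           stringsAsFactors = FALSE))
}
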