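#' Normalize single-cell counts for marker testing
#'
#' Per cell, counts are scaled to a total of 10,000 and log1p-transformed
#' (the scale factor makes values comparable across cells of different
#' depth; the log tames the heavy right tail). Zero-count cells should
#' have been removed by QC and are an error here.
#'
#' @param counts Sparse genes x cells count matrix.
#' @return Sparse matrix of `log1p(count * 1e4 / cell_total)` values.
#' @export
normalize_cells <- function(counts) {
  cs <- Matrix::colSums(counts)
  if (any(cs == 0))
    stopf("zero-count cell(s): %s — run QC first",
          paste(utils::head(colnames(counts)[cs == 0], 5), collapse = ", "))
  norm <- counts %*% Matrix::Diagonal(x = 1e4 / cs)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)
  norm
}

#' Wilcoxon rank-sum marker test for one gene
#'
#' Tests normalized expression of one gene between an in-group and an
#' out-group. The p-value is the two-sided Wilcoxon rank-sum test: exact
#' enumeration over all group assignments when the number of combinations
#' is small enough (`choose(n1+n2, n1) <= exact_max`, ties handled through
#' midranks), otherwise the normal approximation with tie and continuity
#' correction. The fold change is
#' `log2((mean(expm1(in)) + 1) / (mean(expm1(out)) + 1))`, finite even for
#' silent groups; detection fractions are computed on the same values
#' (`> 0` iff the raw count was nonzero).
#'
#' @param x_in,x_out Normalized expression values of the two groups.
#' @param exact_max Combination-count bound for the exact path.
#' @return list with `p_value`, `avg_log2FC`, `pct_in`, `pct_out`. With
#'   fewer than 3 in-group cells the p-value is NA with a warning.
#' @export
test_marker <- function(x_in, x_out, exact_max = 1e5) {
  if (length(x_in) == 0 || length(x_out) == 0)
    stopf("both groups must be nonempty")
  res <- list(
    avg_log2FC = log2((mean(expm1(x_in)) + 1) / (mean(expm1(x_out)) + 1)),
    pct_in = mean(x_in > 0),
    pct_out = mean(x_out > 0)
  )
  if (length(x_in) < 3) {
    warnf("fewer than 3 in-group cells; p-value not reported")
    res$p_value <- NA_real_
    return(res[c("p_value", "avg_log2FC", "pct_in", "pct_out")])
  }
  n1 <- length(x_in)
  n2 <- length(x_out)
  r <- rank(c(x_in, x_out))
  w_obs <- sum(r[seq_len(n1)])
  if (choose(n1 + n2, n1) <= exact_max) {
    res$p_value <- exact_ranksum_p(r, n1, w_obs)
  } else {
    ties <- table(r)
    tie_corr <- sum(ties^3 - ties)
    res$p_value <- approx_ranksum_p_vec(w_obs, n1, n2, tie_corr, n1 + n2)
  }
  res[c("p_value", "avg_log2FC", "pct_in", "pct_out")]
}

# exact two-sided rank-sum p by enumeration of all C(n, n1) assignments
exact_ranksum_p <- function(r, n1, w_obs) {
  n <- length(r)
  e <- n1 * (n + 1) / 2
  combs <- utils::combn(n, n1)
  w <- colSums(matrix(r[combs], nrow = n1))
  mean(abs(w - e) >= abs(w_obs - e) - 1e-9)
}

#' Detect cluster markers across a dataset
#'
#' One-vs-rest Wilcoxon marker detection within a dataset (comparisons
#' never cross datasets). A gene enters testing when its detection
#' fraction reaches `min_pct` in at least one of the two groups; it is
#' reported when `avg_log2FC > logfc_min`, and in stringent mode
#' additionally when `p_adj < padj_max` and `avg_log2FC > log2fc_min`.
#' Multiple-testing adjustment is Bonferroni over all genes of the dataset
#' (or Benjamini-Hochberg via `cfg$padj_method = "BH"`).
#'
#' @param bundle An [atlas_bundle()] (or list of bundles, concatenating
#'   the per-dataset results).
#' @param grouping `"cluster"` or `"subcluster"`.
#' @param mode `"standard"` (logfc 0.25) or `"stringent"` (adjusted P <
#'   0.0005, log2 fold change > 2).
#' @param cfg [pipeline_config()].
#' @return data.frame of marker records: `gene_id`, `cluster`
#'   (`dataset::label`), `avg_log2FC`, `pct_in`, `pct_out`, `p_value`,
#'   `p_adj`, ordered by cluster then p-value.
#' @export
call_markers <- function(bundle, grouping = "cluster",
                         mode = c("standard", "stringent"),
                         cfg = pipeline_config()) {
  mode <- match.arg(mode)
  if (!inherits(bundle, "atlas_bundle") && is.list(bundle)) {
    out <- lapply(bundle, call_markers, grouping = grouping, mode = mode,
                  cfg = cfg)
    return(do.call(rbind, c(out, list(make.row.names = FALSE))))
  }
  stopifnot(inherits(bundle, "atlas_bundle"))
  if (!grouping %in% names(bundle$cells) ||
      all(is.na(bundle$cells[[grouping]])))
    stopf("cells carry no '%s' labels", grouping)
  labels <- bundle$cells[[grouping]]
  if (any(is.na(labels))) stopf("unlabelled cells present")
  counts <- bundle$counts
  norm <- normalize_cells(counts)
  n_cells <- ncol(counts)
  n_genes <- nrow(counts)
  grp <- factor(labels)
  ind <- Matrix::sparseMatrix(i = seq_len(n_cells), j = as.integer(grp),
                              x = 1, dims = c(n_cells, nlevels(grp)))
  sizes <- Matrix::colSums(ind)
  if (any(sizes < 3))
    warnf("cluster(s) with fewer than 3 cells: %s",
          paste(levels(grp)[sizes < 3], collapse = ", "))

  rs <- row_rank_stats(as.matrix(norm))
  rank_sums <- rs$ranks %*% as.matrix(ind)      # genes x clusters

  expd <- norm
  expd@x <- expm1(expd@x)
  sum_exp <- as.matrix(expd %*% ind)            # group sums of de-logged values
  tot_exp <- Matrix::rowSums(expd)
  bin <- counts
  bin@x <- rep(1, length(bin@x))
  det <- as.matrix(bin %*% ind)                 # group detection counts
  tot_det <- Matrix::rowSums(bin)

  out <- list()
  for (j in seq_len(nlevels(grp))) {
    n1 <- sizes[j]
    n2 <- n_cells - n1
    if (n1 < 3 || n2 < 1) next
    pct_in <- det[, j] / n1
    pct_out <- (tot_det - det[, j]) / n2
    mean_in <- sum_exp[, j] / n1
    mean_out <- (tot_exp - sum_exp[, j]) / n2
    lfc <- log2((mean_in + 1) / (mean_out + 1))
    gate <- pmax(pct_in, pct_out) >= cfg$min_pct
    p <- approx_ranksum_p_vec(rank_sums[, j], n1, n2, rs$tie, n_cells)
    p_adj <- if (identical(cfg$padj_method, "BH")) {
      stats::p.adjust(p, method = "BH", n = n_genes)
    } else {
      pmin(1, p * n_genes)
    }
    keep <- gate & lfc > cfg$logfc_min
    if (mode == "stringent")
      keep <- keep & p_adj < cfg$padj_max & lfc > cfg$log2fc_min
    keep[is.na(keep)] <- FALSE
    if (!any(keep)) next
    df <- data.frame(
      gene_id = rownames(counts)[keep],
      cluster = paste(bundle$dataset_label, levels(grp)[j], sep = "::"),
      avg_log2FC = lfc[keep],
      pct_in = pct_in[keep],
      pct_out = pct_out[keep],
      p_value = p[keep],
      p_adj = p_adj[keep],
      stringsAsFactors = FALSE
    )
    out[[length(out) + 1]] <- df[order(df$p_value, df$gene_id), ]
  }
  if (length(out) == 0)
    return(data.frame(gene_id = character(), cluster = character(),
                      avg_log2FC = numeric(), pct_in = numeric(),
                      pct_out = numeric(), p_value = numeric(),
                      p_adj = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# vectorized normal-approximation p over genes for one cluster
approx_ranksum_p_vec <- function(w1, n1, n2, tie_corr, n) {
  u <- w1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_corr / (n * (n - 1)))
  z <- u - mu
  z <- (z - sign(z) * 0.5) / sqrt(pmax(sigma2, 0))
  p <- 2 * pmin(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE))
  p[sigma2 <= 0] <- 1
  pmin(p, 1)
}

#' Marker sets as a named list, per cluster
#'
#' @param markers Marker data.frame from [call_markers()].
#' @return Named list of gene-id vectors, one per `dataset::cluster`.
#' @export
marker_sets <- function(markers) {
  need_cols(markers, c("gene_id", "cluster"), "marker table")
  split(markers$gene_id, markers$cluster)
}

#' Quantify exclusive overlaps between marker sets
#'
#' UpSet-style quantification: for every combination of sets, the number
#' of genes belonging to exactly that combination (exclusive
#' intersections). Combinations of two or more sets with fewer than
#' `min_overlap` shared genes are omitted from the report; per-set
#' exclusive counts are always reported.
#'
#' @param sets Named list (>= 2) of gene-id vectors; duplicate names are
#'   an error.
#' @param min_overlap Reporting floor for multi-set combinations
#'   (default 10).
#' @return data.frame with `combination` (set names joined by `&`),
#'   `degree` and `n_genes`, ordered by degree then combination.
#' @export
overlap_markers <- function(sets, min_overlap = 10) {
  if (length(sets) < 2) stopf("need at least two marker sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stopf("marker sets must be named")
  if (anyDuplicated(names(sets)))
    stopf("duplicate set name(s): %s",
          paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  genes <- unique(unlist(sets))
  member <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
  if (length(genes) == 1) member <- matrix(member, nrow = 1,
                                           dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1, function(m) paste(names(sets)[m], collapse = "&"))
  counts <- table(pattern)
  degree <- lengths(strsplit(names(counts), "&", fixed = TRUE))
  df <- data.frame(combination = names(counts), degree = as.integer(degree),
                   n_genes = as.integer(counts), stringsAsFactors = FALSE)
  # always report every set's exclusive count, even when zero
  missing_single <- setdiff(names(sets), df$combination[df$degree == 1])
  if (length(missing_single) > 0)
    df <- rbind(df, data.frame(combination = missing_single, degree = 1L,
                               n_genes = 0L, stringsAsFactors = FALSE))
  df <- df[df$degree == 1 | df$n_genes >= min_overlap, , drop = FALSE]
  df <- df[order(df$degree, df$combination), , drop = FALSE]
  rownames(df) <- NULL
  df
}
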