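# Shared fixture builders; everything is generated in code, seeded.

# tiny bundle from a dense matrix given as genes x cells
make_bundle <- function(mat, clusters = NULL, dataset = "testset") {
  m <- Matrix::Matrix(mat, sparse = TRUE)
  if (is.null(rownames(m))) rownames(m) <- paste0("G", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("cell", seq_len(ncol(m)))
  cells <- data.frame(barcode = colnames(m), dataset_label = dataset,
                      stringsAsFactors = FALSE)
  if (!is.null(clusters)) cells$cluster <- clusters
  atlas_bundle(m, cells = cells, dataset_label = dataset)
}

# random NB bundle with cluster labels
rand_bundle <- function(seed, n_genes = 40, n_cells = 30, n_clusters = 3,
                        mu = 2, dataset = "testset") {
  plantatlas:::with_seed(seed, {
    m <- matrix(rnbinom(n_genes * n_cells, mu = mu, size = 2),
                nrow = n_genes,
                dimnames = list(sprintf("AT1G%05d", seq_len(n_genes) * 10),
                                sprintf("%s_c%03d", dataset,
                                        seq_len(n_cells))))
    m[, 1] <- pmax(m[, 1], 1)  # no all-zero cells
    make_bundle(m, clusters = paste0("c", rep_len(seq_len(n_clusters),
                                                  n_cells)),
                dataset = dataset)
  })
}

# small synthetic atlas config for fast tests
small_atlas_cfg <- function(seed, ...) {
  args <- utils::modifyList(list(
    organs = list(seedling = "seedling_3d", stem = "stem",
                  silique = "silique"),
    clusters_per_dataset = 3, cells_per_cluster = 50, n_genes = 400,
    n_universal = 2, n_organ_shared = 3, n_unique = 2,
    n_mito = 5, n_chloro = 8, seed = seed), list(...))
  do.call(synthetic_atlas_config, args)
}

# exhaustive search: best achievable cluster coverage over all candidate
# subsets within the size and budget constraints
optimal_coverage <- function(cand, k, budget) {
  n <- nrow(cand)
  best <- 0
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) == 0 || length(idx) > k) next
    if (anyDuplicated(cand$gene_id[idx])) next
    if (sum(cand$tpm[idx]) >= budget) next
    best <- max(best, length(unique(cand$cluster[idx])))
  }
  best
}

# independent two-sided rank-sum p by explicit permutation enumeration:
# enumerates every assignment of the pooled values to the in-group and
# counts assignments at least as extreme in |W - E[W]|
perm_ranksum_p <- function(x_in, x_out) {
  n1 <- length(x_in)
  vals <- c(x_in, x_out)
  r <- rank(vals)
  e <- n1 * (length(vals) + 1) / 2
  obs <- abs(sum(r[seq_len(n1)]) - e)
  combs <- utils::combn(length(vals), n1)
  extreme <- 0
  for (j in seq_len(ncol(combs)))
    if (abs(sum(r[combs[, j]]) - e) >= obs - 1e-9) extreme <- extreme + 1
  extreme / ncol(combs)
}
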