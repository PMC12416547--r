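test_that("cell normalization matches the scale-10k log1p formula and is depth-invariant", {
  m <- matrix(c(1, 0, 0, 3, 1, 0), nrow = 3,
              dimnames = list(paste0("g", 1:3), c("c1", "c2")))
  norm <- normalize_cells(Matrix::Matrix(m, sparse = TRUE))
  expect_equal(norm["g1", "c1"], log1p(1e4))
  # per-entry formula oracle
  dense <- plantatlas:::with_seed(3, matrix(rpois(50, 3) + 1, nrow = 5))
  dimnames(dense) <- list(paste0("g", 1:5), paste0("c", 1:10))
  got <- as.matrix(normalize_cells(Matrix::Matrix(dense, sparse = TRUE)))
  want <- log1p(sweep(dense, 2, colSums(dense), "/") * 1e4)
  expect_equal(got, want, ignore_attr = TRUE)
  # doubling a cell's counts leaves its normalized vector unchanged
  doubled <- dense
  doubled[, 1] <- doubled[, 1] * 2
  got2 <- as.matrix(normalize_cells(Matrix::Matrix(doubled, sparse = TRUE)))
  expect_equal(got2[, 1], got[, 1])
  zc <- m
  zc[, 2] <- 0
  expect_error(normalize_cells(Matrix::Matrix(zc, sparse = TRUE)),
               "zero-count")
})

test_that("the marker test reproduces exact rank-sum enumeration p-values", {
  r <- test_marker(c(5, 6, 7), c(0, 0, 0))
  expect_equal(r$p_value, 0.1)  # 2 / choose(6, 3)
  expect_equal(r$pct_in, 1)
  expect_equal(r$pct_out, 0)
  # independent permutation oracle across random tied configurations
  for (seed in 1:10) {
    vals <- plantatlas:::with_seed(seed, {
      n1 <- sample(3:8, 1)
      n2 <- sample(3:8, 1)
      list(x_in = log1p(rnbinom(n1, mu = 3, size = 2)),
           x_out = log1p(rnbinom(n2, mu = 1, size = 2)))
    })
    got <- test_marker(vals$x_in, vals$x_out)$p_value
    want <- perm_ranksum_p(vals$x_in, vals$x_out)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("the large-sample approximation tracks stats::wilcox.test", {
  for (seed in 1:5) {
    vals <- plantatlas:::with_seed(seed, {
      list(x_in = rnorm(60, 0.3), x_out = rnorm(80))
    })
    got <- test_marker(vals$x_in, vals$x_out)$p_value
    want <- suppressWarnings(
      stats::wilcox.test(vals$x_in, vals$x_out, exact = FALSE,
                         correct = TRUE)$p.value)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("marker statistics are symmetric and degenerate cases behave", {
  x <- log1p(c(2, 3, 4, 1))
  y <- log1p(c(0, 1, 5))
  a <- test_marker(x, y)
  b <- test_marker(y, x)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$avg_log2FC, -b$avg_log2FC)
  same <- test_marker(x, x)
  expect_equal(same$avg_log2FC, 0)
  expect_warning(small <- test_marker(c(1, 2), y), "fewer than 3")
  expect_true(is.na(small$p_value))
  expect_error(test_marker(numeric(), y), "nonempty")
})

test_that("under the null the rank test holds its size", {
  frac <- plantatlas:::with_seed(42, {
    hits <- 0
    n_genes <- 2000
    for (g in seq_len(n_genes)) {
      x <- log1p(rnbinom(100, mu = 1, size = 2))
      y <- log1p(rnbinom(100, mu = 1, size = 2))
      p <- test_marker(x, y)$p_value
      if (p < 0.05) hits <- hits + 1
    }
    hits / n_genes
  })
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("planted universal markers are called in every dataset at fold 8", {
  for (seed in 1:5) {
    cfg <- small_atlas_cfg(seed, cells_per_cluster = 200, n_genes = 500,
                           fold_universal = 8)
    atlas <- generate_atlas(cfg)
    markers <- call_markers(atlas$bundles, mode = "standard")
    truth <- atlas$truth$genes
    uni <- truth[truth$class == "universal_celltype", ]
    for (i in seq_len(nrow(uni))) {
      hits <- markers[markers$gene_id == uni$gene_id[i], ]
      got_cluster <- sub("^.*::", "", hits$cluster)
      got_ds <- sub("::.*$", "", hits$cluster)
      expect_true(all(got_cluster == uni$target_celltype[i]))
      expect_setequal(got_ds, names(atlas$bundles))
    }
  }
})

test_that("marker gates and modes enforce min.pct and the stringent thresholds", {
  cfg <- small_atlas_cfg(13, cells_per_cluster = 100)
  atlas <- generate_atlas(cfg)
  std <- call_markers(atlas$bundles[[1]], mode = "standard")
  expect_true(all(pmax(std$pct_in, std$pct_out) >= 0.1))
  expect_true(all(std$avg_log2FC > 0.25))
  expect_true(all(std$p_adj >= std$p_value))
  str <- call_markers(atlas$bundles[[1]], mode = "stringent")
  expect_true(all(str$avg_log2FC > 2))
  expect_true(all(str$p_adj < 0.0005))
  expect_true(all(str$gene_id %in% std$gene_id))
  expect_error(call_markers(atlas$bundles[[1]], grouping = "subcluster"),
               "subcluster")
})

test_that("marker calls are invariant to cell and gene order", {
  rb_cfg <- small_atlas_cfg(17, cells_per_cluster = 50, n_genes = 300)
  b <- generate_atlas(rb_cfg)$bundles[[1]]
  res1 <- call_markers(b, mode = "standard")
  perm <- plantatlas:::with_seed(1, sample(ncol(b$counts)))
  gperm <- plantatlas:::with_seed(2, sample(nrow(b$counts)))
  b2 <- atlas_bundle(b$counts[gperm, perm], genes = b$genes[gperm, ],
                     cells = b$cells[perm, ], dataset_label = b$dataset_label)
  res2 <- call_markers(b2, mode = "standard")
  key <- function(df) df[order(df$cluster, df$gene_id),
                         c("gene_id", "cluster", "avg_log2FC", "p_value")]
  expect_equal(key(res1), key(res2), ignore_attr = TRUE)
})

test_that("marker-set overlaps are exclusive-intersection counts with a reporting floor", {
  g <- function(n, off = 0) paste0("g", seq_len(n) + off)
  rep12 <- overlap_markers(list(A = g(12), B = g(12)))
  expect_equal(rep12$n_genes[rep12$combination == "A&B"], 12)
  expect_equal(rep12$n_genes[rep12$combination %in% c("A", "B")], c(0L, 0L))
  nine <- overlap_markers(list(A = g(29), B = c(g(9), g(30, off = 100))))
  expect_false("A&B" %in% nine$combination)
  expect_equal(nine$n_genes[nine$combination == "A"], 20)
  # brute-force membership-pattern oracle on random sets
  sets <- plantatlas:::with_seed(8, {
    lapply(setNames(1:3, c("s1", "s2", "s3")),
           function(i) sample(paste0("g", 1:40), 25))
  })
  rep3 <- overlap_markers(sets, min_overlap = 1)
  univ <- unique(unlist(sets))
  combos <- unlist(lapply(1:3, function(k)
    combn(names(sets), k, paste, collapse = "&")), use.names = FALSE)
  for (cmb in combos) {
    members <- strsplit(cmb, "&")[[1]]
    inside <- Reduce(intersect, sets[members])
    outside <- unique(unlist(sets[setdiff(names(sets), members)]))
    want <- length(setdiff(inside, outside))
    got <- rep3$n_genes[rep3$combination == cmb]
    if (length(got) == 0) got <- 0L
    if (length(members) == 1 || want >= 1)
      expect_equal(got, want, info = cmb)
  }
  expect_error(overlap_markers(list(A = g(3), A = g(4))), "duplicate")
  expect_error(overlap_markers(list(A = g(3))), "at least two")
})
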