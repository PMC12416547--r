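toy_tpm <- function(target, others) {
  # one target cluster in organ "stem", others in organ "flower"
  rows <- c("stem::c1", paste0("flower::c", seq_along(others)))
  m <- matrix(c(target, others), ncol = 1,
              dimnames = list(rows, "AT1G00010"))
  m
}

toy_map <- data.frame(dataset_label = c("stem", "flower"),
                      organ_group = c("stem", "flower"))

test_that("the fourfold and log2-TPM rules classify as printed", {
  u <- classify_marker("AT1G00010", "stem::c1", toy_tpm(1000, c(10, 5)),
                       toy_map)
  expect_equal(u$classification, "unique")
  expect_true(u$fold_ratio_min > 4)
  r1 <- classify_marker("AT1G00010", "stem::c1", toy_tpm(100, c(30, 1)),
                        toy_map)
  expect_equal(r1$classification, "rejected_rule1")  # 100 <= 4 * 30
  expect_equal(r1$offending_cluster, "flower::c1")
  r2 <- classify_marker("AT1G00010", "stem::c1", toy_tpm(10000, c(40, 1)),
                        toy_map)
  expect_equal(r2$classification, "rejected_rule2")  # log2(41) = 5.36 > 5
  # boundary: exactly fourfold fails rule 1 ("more than fourfold" required)
  r3 <- classify_marker("AT1G00010", "stem::c1", toy_tpm(120, c(30, 1)),
                        toy_map)
  expect_equal(r3$classification, "rejected_rule1")
  # other-organ TPM of exactly 31 sits on the log2 cap and passes rule 2
  r4 <- classify_marker("AT1G00010", "stem::c1", toy_tpm(1000, c(31, 1)),
                        toy_map)
  expect_equal(r4$classification, "unique")
  expect_error(classify_marker("nope", "stem::c1", toy_tpm(1, 1), toy_map),
               "absent")
})

test_that("a single-organ pseudobulk is vacuously unique and flagged degenerate", {
  tpm <- matrix(c(50, 10), ncol = 1,
                dimnames = list(c("stem::c1", "stem::c2"), "AT1G00010"))
  res <- classify_marker("AT1G00010", "stem::c1", tpm,
                         data.frame(dataset_label = "stem",
                                    organ_group = "stem"))
  expect_equal(res$classification, "unique")
  expect_true(res$degenerate)
})

test_that("raising target expression never converts unique to rejected", {
  others <- c(8, 20, 2)
  last <- "rejected_rule1"
  for (t_val in c(10, 50, 81, 200, 1e4)) {
    cls <- classify_marker("AT1G00010", "stem::c1",
                           toy_tpm(t_val, others), toy_map)$classification
    if (last == "unique") expect_equal(cls, "unique")
    last <- cls
  }
})

test_that("vectorized classification agrees with the single-gene path and counts genes", {
  atlas <- generate_atlas(small_atlas_cfg(5, cells_per_cluster = 100))
  markers <- call_markers(atlas$bundles, mode = "stringent")
  tpm <- pseudobulk_tpm(atlas$bundles)
  res <- classify_all(markers, tpm, atlas$organ_map)
  expect_equal(nrow(res$calls), nrow(markers))
  pick <- plantatlas:::with_seed(1, sample(nrow(markers),
                                           min(25, nrow(markers))))
  for (i in pick) {
    single <- classify_marker(markers$gene_id[i], markers$cluster[i], tpm,
                              atlas$organ_map)
    expect_equal(res$calls$classification[i], single$classification)
    expect_equal(res$calls$fold_ratio_min[i], single$fold_ratio_min)
  }
  # summary counts distinct genes, not (gene, cluster) pairs
  expect_equal(res$summary$n_candidates, length(unique(markers$gene_id)))
  expect_equal(res$summary$percent_unique,
               round(100 * res$summary$n_unique /
                       res$summary$n_candidates, 1))
  # relaxing both rules can only grow the survivor set
  relaxed <- classify_all(markers, tpm, atlas$organ_map,
                          pipeline_config(fold_ratio = 1,
                                          log2tpm_cap = Inf))
  def_unique <- res$calls$gene_id[res$calls$classification == "unique"]
  rel_unique <- relaxed$calls$gene_id[relaxed$calls$classification == "unique"]
  expect_true(all(def_unique %in% rel_unique))
})

test_that("empty marker lists summarize to zeros without error", {
  res <- classify_all(data.frame(), matrix(0, 1, 1), toy_map)
  expect_equal(res$summary$n_candidates, 0)
  expect_equal(res$summary$percent_unique, 0)
})

test_that("subcluster organ identity is the plurality dataset with flagged ties", {
  cells <- data.frame(
    subcluster = rep("s1", 100),
    dataset_label = rep(c("silique", "flower"), c(60, 40)))
  res <- assign_majority_organ(cells)
  expect_equal(res$organ_identity, "silique")
  expect_false(res$tie)
  tie <- assign_majority_organ(data.frame(
    subcluster = "s1", dataset_label = rep(c("stem", "flower"), 50)))
  expect_equal(tie$organ_identity, "flower")  # lexicographic first
  expect_true(tie$tie)
  # counting oracle on random labels
  rnd <- plantatlas:::with_seed(31, data.frame(
    subcluster = sample(paste0("s", 1:6), 500, TRUE),
    dataset_label = sample(c("seed_0d", "stem", "silique"), 500, TRUE)))
  res2 <- assign_majority_organ(rnd)
  for (i in seq_len(nrow(res2))) {
    tab <- table(rnd$dataset_label[rnd$subcluster == res2$subcluster[i]])
    expect_equal(unname(tab[res2$organ_identity[i]]), max(tab),
                 ignore_attr = TRUE)
  }
  expect_error(assign_majority_organ(rnd[0, ]), "no cells")
  rnd$subcluster[3] <- NA
  expect_error(assign_majority_organ(rnd), "without a subcluster")
})
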