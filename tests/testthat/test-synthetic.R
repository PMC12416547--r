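test_that("the atlas generator is deterministic given its seed", {
  cfg <- small_atlas_cfg(7)
  a1 <- generate_atlas(cfg)
  a2 <- generate_atlas(cfg)
  expect_identical(serialize(a1, NULL), serialize(a2, NULL))
  a3 <- generate_atlas(small_atlas_cfg(8))
  expect_false(identical(a1$bundles[[1]]$counts, a3$bundles[[1]]$counts))
})

test_that("infeasible generator configurations are rejected", {
  expect_error(small_atlas_cfg(1, n_genes = 40), "infeasible")
  expect_error(small_atlas_cfg(1, cells_per_cluster = 5), "cells_per_cluster")
  expect_error(small_atlas_cfg(1, fold_unique = 0.5), "fold-changes")
})

test_that("planted unique markers exceed the fourfold margin over other organs", {
  # empirical mean ratio target cluster vs best other-organ cluster, fold 16
  ratios <- c()
  for (seed in 1:20) {
    cfg <- small_atlas_cfg(seed, cells_per_cluster = 200, n_genes = 300,
                           n_universal = 1, n_organ_shared = 1, n_unique = 2)
    atlas <- generate_atlas(cfg)
    truth <- atlas$truth$genes
    uniq <- truth[truth$class == "organ_celltype_unique", ]
    means <- lapply(atlas$bundles, function(b) {
      grp <- b$cells$cluster
      vapply(split(seq_along(grp), grp), function(ix)
        Matrix::rowMeans(b$counts[, ix, drop = FALSE]),
        numeric(nrow(b$counts)))
    })
    organ_of <- setNames(atlas$organ_map$organ_group,
                         atlas$organ_map$dataset_label)
    for (i in seq_len(nrow(uniq))) {
      ds_target <- atlas$organ_map$dataset_label[
        atlas$organ_map$organ_group == uniq$target_organ[i]][1]
      g <- uniq$gene_id[i]
      target_mean <- means[[ds_target]][g, uniq$target_celltype[i]]
      other <- unlist(lapply(names(means), function(ds) {
        if (organ_of[[ds]] == uniq$target_organ[i]) return(NULL)
        means[[ds]][g, ]
      }))
      ratios <- c(ratios, target_mean / max(max(other), 1e-12))
    }
  }
  expect_gte(mean(ratios > 4), 0.99)
})

test_that("an atlas without planted markers yields zero unique calls downstream", {
  cfg <- small_atlas_cfg(3, n_universal = 0, n_organ_shared = 0, n_unique = 0)
  atlas <- generate_atlas(cfg)
  markers <- call_markers(atlas$bundles, mode = "stringent")
  res <- classify_all(markers, pseudobulk_tpm(atlas$bundles), atlas$organ_map)
  expect_equal(res$summary$n_unique, 0)
})

test_that("the QC population plants exactly the labelled failures, with boundary cells", {
  pop <- generate_qc_population(100, c(min_genes = 0.1, max_genes = 0.05,
                                       min_umi = 0.05, pct_mito = 0.05,
                                       pct_chloro = 0.05), seed = 11)
  res <- filter_nuclei(pop)
  expect_setequal(res$removed$barcode, pop$barcode[!is.na(pop$planted_fail)])
  merged <- merge(res$removed, pop[c("barcode", "planted_fail")])
  expect_equal(merged$reason, merged$planted_fail)
  # boundary cells at the printed thresholds are planted and must fail
  expect_true(any(res$removed$genes_detected == 300 &
                    res$removed$reason == "min_genes"))
  expect_true(any(res$removed$genes_detected == 7000 &
                    res$removed$reason == "max_genes"))
  expect_true(any(res$removed$umi_total == 400 &
                    res$removed$reason == "min_umi"))
  clean <- generate_qc_population(50, seed = 2)
  expect_equal(nrow(filter_nuclei(clean)$removed), 0)
  expect_error(generate_qc_population(0), "positive")
  expect_error(generate_qc_population(10, c(doublets = 0.5)), "unknown")
})

test_that("spatial point counts follow the planted Poisson intensities", {
  dom <- list(list(name = "A", xlim = c(0, 10), ylim = c(0, 5),
                   n_cells = 10, intensity = c(TT4 = 50)))
  hits <- vapply(1:100, function(s) {
    nrow(generate_spatial_points(dom, seed = s))
  }, 0)
  within_ci <- abs(hits - 50) <= 4 * sqrt(50)
  expect_gte(sum(within_ci), 95)
  expect_error(generate_spatial_points(list()), "nonempty")
})

test_that("domain-restricted genes stay in their domain and co-planted genes co-detect", {
  doms <- list(
    list(name = "A", xlim = c(0, 1), ylim = c(0, 1), n_cells = 40,
         intensity = c(g1 = 120, g2 = 80)),
    list(name = "B", xlim = c(2, 3), ylim = c(0, 1), n_cells = 40,
         intensity = c(g3 = 100))
  )
  pts <- generate_spatial_points(doms, seed = 5)
  expect_true(all(pts$domain[pts$gene %in% c("g1", "g2")] == "A"))
  expect_true(all(pts$domain[pts$gene == "g3"] == "B"))
  # co-detection bookkeeping: empirical rate near independent expectation
  rates <- vapply(1:10, function(s) {
    p <- generate_spatial_points(doms[1], seed = s)
    counts <- points_to_counts(p)
    cd <- co_detect(counts, "g1", "g2")
    mean(cd$positive) * ncol(counts) / 40  # over all 40 domain cells
  }, 0)
  expected <- (1 - exp(-120 / 40)) * (1 - exp(-80 / 40))
  expect_lt(abs(mean(rates) - expected), 0.1)
})
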