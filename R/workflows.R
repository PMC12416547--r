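#' End-to-end budgeted panel design on a synthetic atlas
#'
#' Reproducible workflow behind the panel-budget benchmarks: generates a
#' seeded synthetic multi-organ atlas, applies nucleus QC, detects
#' cluster markers for the target dataset, computes its whole-tissue
#' pseudobulk TPM, assigns every gene a random probe count (uniform on
#' `probe_range`), filters candidates (probes > 25, tissue TPM < 1,000)
#' and selects a budgeted panel. With `tf_quota`, candidates are split
#' into a cluster-marker pool and a transcription-factor pool (the
#' generator's TF flags) with the TF pool holding `tf_quota` slots.
#'
#' @param seed Seed driving the atlas, probe counts and everything else.
#' @param n_genes Genes in the synthetic atlas. The per-gene baseline
#'   mean is scaled as `3000 / n_genes` so the simulated library size
#'   stays at the atlas design point (~3,000 UMI per nucleus) regardless
#'   of gene count.
#' @param panel_size,budget Panel dimensions (140/11,000 for the silique
#'   design point; 1,000/15,000 for the large design).
#' @param target_dataset Dataset whose markers and tissue TPM feed the
#'   design.
#' @param tf_quota Optional transcription-factor slot count.
#' @param probe_range Integer range probe counts are drawn from.
#' @return list with `panel`, `total_tpm`, `n_selected`, `n_candidates`
#'   and the `validation` report.
#' @export
run_panel_experiment <- function(seed, n_genes = 3000, panel_size = 140,
                                 budget = 11000,
                                 target_dataset = "silique",
                                 tf_quota = NULL,
                                 probe_range = c(10, 60)) {
  cfg <- synthetic_atlas_config(n_genes = n_genes,
                                baseline_mean = 3000 / n_genes,
                                seed = seed)
  atlas <- generate_atlas(cfg)
  if (!target_dataset %in% names(atlas$bundles))
    stopf("dataset '%s' not in the synthetic atlas", target_dataset)
  bundle <- qc_bundle(atlas$bundles[[target_dataset]])$bundle
  markers <- call_markers(bundle, mode = "standard")
  tissue <- pseudobulk_tpm(bundle, grouping = "dataset")
  tissue_tpm <- stats::setNames(as.numeric(tissue[1, ]), colnames(tissue))
  probe_counts <- with_seed(seed + 500000L, {
    stats::setNames(sample(probe_range[1]:probe_range[2],
                           nrow(bundle$counts), replace = TRUE),
                    rownames(bundle$counts))
  })
  if (!is.null(tf_quota)) {
    is_tf <- stats::setNames(atlas$truth$genes$is_tf, atlas$truth$genes$gene_id)
    markers$pool <- ifelse(is_tf[markers$gene_id], "tf", "cluster")
    spec <- panel_spec(panel_size, budget,
                       quotas = c(cluster = panel_size - tf_quota,
                                  tf = tf_quota))
  } else {
    spec <- panel_spec(panel_size, budget)
  }
  candidates <- filter_candidates(markers, tissue_tpm, probe_counts)
  panel <- suppressWarnings(select_panel(candidates, spec))
  list(panel = panel, total_tpm = panel$total_tpm,
       n_selected = nrow(panel$genes), n_candidates = nrow(candidates),
       validation = suppressWarnings(validate_panel(panel, spec)))
}

#' Planted unique-marker recovery benchmark
#'
#' Runs the full marker-to-specificity pipeline on one seeded synthetic
#' atlas (QC, stringent marker detection per dataset, cross-organ
#' pseudobulk TPM, uniqueness classification) and scores the recovered
#' organ-by-cell-type unique genes against the generator's ground truth.
#'
#' @param seed Atlas seed.
#' @param cfg Optional [synthetic_atlas_config()]; defaults to the study
#'   design point (3 organs, 5 clusters, 200 cells/cluster, 3,000 genes,
#'   unique-marker fold 16) with `seed`.
#' @return list with `precision`, `recall`, `n_planted`, `n_recovered`,
#'   the classification `summary` and the recovered gene ids.
#' @export
run_recovery_benchmark <- function(seed, cfg = NULL) {
  if (is.null(cfg)) cfg <- synthetic_atlas_config(seed = seed)
  atlas <- generate_atlas(cfg)
  bundles <- lapply(atlas$bundles, function(b) qc_bundle(b)$bundle)
  markers <- call_markers(bundles, mode = "stringent")
  tpm <- pseudobulk_tpm(bundles, grouping = "cluster")
  res <- classify_all(markers, tpm, atlas$organ_map)
  recovered <- unique(res$calls$gene_id[res$calls$classification == "unique"])
  planted <- atlas$truth$genes$gene_id[
    atlas$truth$genes$class == "organ_celltype_unique"]
  tp <- length(intersect(recovered, planted))
  list(
    precision = if (length(recovered) == 0) NA_real_ else tp / length(recovered),
    recall = if (length(planted) == 0) NA_real_ else tp / length(planted),
    n_planted = length(planted), n_recovered = length(recovered),
    summary = res$summary, recovered = recovered
  )
}
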