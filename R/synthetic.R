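#' Configuration for the synthetic multi-organ atlas generator
#'
#' Defines a multi-organ single-nucleus atlas with clustered
#' negative-binomial UMI counts, organelle-flagged genes and three planted
#' marker classes with known ground truth: universal cell-type markers
#' (elevated in one cell type across all organs), organ-shared markers
#' (elevated in every cell type of one organ) and organ-by-cell-type
#' unique markers (elevated in one cell type of one organ only). Cluster
#' `k` of every dataset represents the same cell type, so cross-organ
#' structure is meaningful.
#'
#' Planted marker genes carry a per-gene reference level drawn from
#' `marker_base_range * baseline_mean`; in their target cells the mean is
#' `fold` times that reference, and everywhere else it is suppressed to
#' `marker_off_scale` times the reference, emulating the near-silent
#' off-target behaviour of genuine cell-type markers. All other genes get
#' a lognormal baseline (mean `baseline_mean`) shared by every cell.
#' Library-size heterogeneity is multiplicative lognormal per cell.
#'
#' @param organs Named list mapping organ group to the character vector of
#'   its dataset labels.
#' @param clusters_per_dataset Number of cell types per dataset.
#' @param cells_per_cluster Cells per cluster (>= 20).
#' @param n_genes Total genes including organelle genes.
#' @param baseline_mean Mean NB expression per gene per cell.
#' @param baseline_sdlog Lognormal sdlog of per-gene baselines.
#' @param dispersion NB dispersion phi (variance = mu + phi mu^2).
#' @param libsize_sigma sdlog of the per-cell library-size factor.
#' @param n_universal Universal markers planted per cell type.
#' @param n_organ_shared Organ-shared markers planted per organ.
#' @param n_unique Unique markers planted per (organ, cell type).
#' @param fold_universal,fold_shared,fold_unique Elevation folds (> 1).
#' @param marker_off_scale Off-target suppression of planted markers.
#' @param marker_base_range Range (fraction of `baseline_mean`) of planted
#'   marker reference levels.
#' @param n_mito,n_chloro Mitochondrial/chloroplast gene counts.
#' @param organelle_scale Expression scale of organelle genes relative to
#'   `baseline_mean`.
#' @param tf_fraction Fraction of genes flagged as transcription factors
#'   (consumed by two-pool imaging-panel designs).
#' @param seed RNG seed; the whole generator is deterministic given it.
#' @return A `synthetic_atlas_config` object.
#' @export
synthetic_atlas_config <- function(organs = list(seedling = "seedling_3d",
                                                 stem = "stem",
                                                 silique = "silique"),
                                   clusters_per_dataset = 5,
                                   cells_per_cluster = 200,
                                   n_genes = 3000,
                                   baseline_mean = 1.0,
                                   baseline_sdlog = 1.0,
                                   dispersion = 0.5,
                                   libsize_sigma = 0.3,
                                   n_universal = 4,
                                   n_organ_shared = 10,
                                   n_unique = 6,
                                   fold_universal = 8,
                                   fold_shared = 8,
                                   fold_unique = 16,
                                   marker_off_scale = 1 / 32,
                                   marker_base_range = c(0.1, 0.8),
                                   n_mito = 20,
                                   n_chloro = 30,
                                   organelle_scale = 1.0,
                                   tf_fraction = 0.1,
                                   seed = 1) {
  stopifnot(is.list(organs), length(organs) >= 1,
            !is.null(names(organs)), all(nzchar(names(organs))))
  if (cells_per_cluster < 20)
    stopf("cells_per_cluster must be >= 20")
  if (any(c(fold_universal, fold_shared, fold_unique) <= 1))
    stopf("marker fold-changes must be > 1")
  cfg <- structure(as.list(environment()), class = "synthetic_atlas_config")
  n_datasets <- length(unlist(organs))
  n_organs <- length(organs)
  k <- clusters_per_dataset
  planted <- n_universal * k + n_organ_shared * n_organs +
    n_unique * n_organs * k
  if (planted + n_mito + n_chloro >= n_genes)
    stopf("infeasible config: %d planted + %d organelle genes but only %d genes",
          planted, n_mito + n_chloro, n_genes)
  cfg
}

#' Generate a synthetic multi-organ atlas with ground truth
#'
#' Draws one [atlas_bundle()] per dataset defined in `cfg` plus a ground
#' truth object recording every planted marker's class and target and
#' every cell's true cluster and organ. Deterministic given `cfg$seed`.
#'
#' @param cfg A [synthetic_atlas_config()].
#' @return A list with elements `bundles` (named list of atlas bundles),
#'   `truth` (list with `genes` and `cells` data.frames) and `organ_map`
#'   (data.frame `dataset_label`, `organ_group`).
#' @export
generate_atlas <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_atlas_config"))
  with_seed(cfg$seed, generate_atlas_impl(cfg))
}

generate_atlas_impl <- function(cfg) {
  k <- cfg$clusters_per_dataset
  organs <- cfg$organs
  datasets <- unlist(organs, use.names = FALSE)
  organ_of <- rep(names(organs), lengths(organs))
  names(organ_of) <- datasets
  celltypes <- paste0("c", seq_len(k))

  n_nuclear <- cfg$n_genes - cfg$n_mito - cfg$n_chloro
  gene_id <- c(
    sprintf("AT%dG%05d", (seq_len(n_nuclear) - 1) %% 5 + 1,
            seq_len(n_nuclear) * 10),
    sprintf("ATMG%05d", seq_len(cfg$n_mito) * 10),
    sprintf("ATCG%05d", seq_len(cfg$n_chloro) * 10)
  )
  organelle <- c(rep("nuclear", n_nuclear),
                 rep("mitochondrial", cfg$n_mito),
                 rep("chloroplast", cfg$n_chloro))

  # per-gene baselines: lognormal with mean baseline_mean
  meanlog <- log(cfg$baseline_mean) - cfg$baseline_sdlog^2 / 2
  base_mu <- stats::rlnorm(cfg$n_genes, meanlog, cfg$baseline_sdlog)
  base_mu[organelle != "nuclear"] <-
    stats::rlnorm(cfg$n_mito + cfg$n_chloro, meanlog, cfg$baseline_sdlog) *
    cfg$organelle_scale

  # plant marker classes on disjoint nuclear genes
  gene_class <- rep("background", cfg$n_genes)
  gene_class[organelle != "nuclear"] <- "organelle"
  target_organ <- rep(NA_character_, cfg$n_genes)
  target_celltype <- rep(NA_character_, cfg$n_genes)
  n_planted <- cfg$n_universal * k + cfg$n_organ_shared * length(organs) +
    cfg$n_unique * length(organs) * k
  planted_idx <- sample(seq_len(n_nuclear), n_planted)
  pool <- planted_idx
  take <- function(n) {
    out <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    out
  }
  for (ct in celltypes) {
    idx <- take(cfg$n_universal)
    gene_class[idx] <- "universal_celltype"
    target_celltype[idx] <- ct
  }
  for (og in names(organs)) {
    idx <- take(cfg$n_organ_shared)
    gene_class[idx] <- "organ_shared"
    target_organ[idx] <- og
  }
  for (og in names(organs)) {
    for (ct in celltypes) {
      idx <- take(cfg$n_unique)
      gene_class[idx] <- "organ_celltype_unique"
      target_organ[idx] <- og
      target_celltype[idx] <- ct
    }
  }
  is_marker <- gene_class %in%
    c("universal_celltype", "organ_shared", "organ_celltype_unique")
  base_mu[is_marker] <- stats::runif(sum(is_marker),
                                     cfg$marker_base_range[1],
                                     cfg$marker_base_range[2]) *
    cfg$baseline_mean

  is_tf <- rep(FALSE, cfg$n_genes)
  n_tf <- round(cfg$tf_fraction * cfg$n_genes)
  if (n_tf > 0) is_tf[sample(seq_len(cfg$n_genes), n_tf)] <- TRUE

  fold_of <- c(universal_celltype = cfg$fold_universal,
               organ_shared = cfg$fold_shared,
               organ_celltype_unique = cfg$fold_unique)

  bundles <- list()
  cell_truth <- list()
  for (ds in datasets) {
    n_cells <- k * cfg$cells_per_cluster
    cluster <- rep(celltypes, each = cfg$cells_per_cluster)
    mu <- matrix(base_mu, nrow = cfg$n_genes, ncol = n_cells)
    # marker rows: off-target suppression, then target elevation
    mu[is_marker, ] <- mu[is_marker, ] * cfg$marker_off_scale
    for (g in which(is_marker)) {
      cls <- gene_class[g]
      in_organ <- is.na(target_organ[g]) || organ_of[[ds]] == target_organ[g]
      if (!in_organ) next
      target_cells <- if (cls == "organ_shared") rep(TRUE, n_cells)
                      else cluster == target_celltype[g]
      mu[g, target_cells] <- base_mu[g] * fold_of[[cls]]
    }
    libf <- exp(stats::rnorm(n_cells, 0, cfg$libsize_sigma))
    mu <- sweep(mu, 2, libf, `*`)
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / cfg$dispersion),
                     nrow = cfg$n_genes)
    barcodes <- sprintf("%s_cell%04d", ds, seq_len(n_cells))
    dimnames(counts) <- list(gene_id, barcodes)
    csum <- colSums(counts)
    cells <- data.frame(
      barcode = barcodes,
      dataset_label = ds,
      genes_detected = colSums(counts > 0),
      umi_total = csum,
      pct_mito = 100 * colSums(counts[organelle == "mitochondrial", ,
                                      drop = FALSE]) / pmax(csum, 1),
      pct_chloro = 100 * colSums(counts[organelle == "chloroplast", ,
                                        drop = FALSE]) / pmax(csum, 1),
      cluster = cluster,
      subcluster = NA_character_,
      stringsAsFactors = FALSE
    )
    genes <- data.frame(gene_id = gene_id, organelle = organelle,
                        probe_count = NA_real_, is_tf = is_tf,
                        stringsAsFactors = FALSE)
    bundles[[ds]] <- atlas_bundle(counts, genes = genes, cells = cells,
                                  dataset_label = ds)
    cell_truth[[ds]] <- data.frame(barcode = barcodes, dataset_label = ds,
                                   cluster = cluster,
                                   organ_group = organ_of[[ds]],
                                   stringsAsFactors = FALSE)
  }

  truth <- list(
    genes = data.frame(gene_id = gene_id, class = gene_class,
                       target_organ = target_organ,
                       target_celltype = target_celltype,
                       base_mu = base_mu, is_tf = is_tf,
                       stringsAsFactors = FALSE),
    cells = do.call(rbind, c(cell_truth, list(make.row.names = FALSE)))
  )
  organ_map <- data.frame(dataset_label = datasets,
                          organ_group = unname(organ_of),
                          stringsAsFactors = FALSE)
  list(bundles = bundles, truth = truth, organ_map = organ_map)
}

#' Generate a QC test population with planted pass/fail labels
#'
#' Emits nuclei on both sides of every QC threshold. Cells planted to fail
#' a given rule violate exactly that rule (all other covariates are well
#' inside the pass region), and the first planted failure of each reason
#' sits exactly on the threshold boundary (genes = 300 or 7,000, UMI =
#' 400, 5% mitochondrial, 15% chloroplast), which the strict inequalities
#' must reject.
#'
#' @param n Number of cells (> 0).
#' @param contamination Named fractions in `[0,1]` per failure reason
#'   (`min_genes`, `max_genes`, `min_umi`, `pct_mito`, `pct_chloro`);
#'   missing names default to 0.
#' @param seed RNG seed.
#' @param cfg [pipeline_config()] giving thresholds.
#' @return data.frame of cell records plus a `planted_fail` column (the
#'   reason, or NA for planted passes).
#' @export
generate_qc_population <- function(n, contamination = NULL, seed = 1,
                                   cfg = pipeline_config()) {
  if (length(n) != 1 || n <= 0) stopf("n must be a positive count")
  reasons <- c("min_genes", "max_genes", "min_umi", "pct_mito", "pct_chloro")
  frac <- stats::setNames(rep(0, 5), reasons)
  if (!is.null(contamination)) {
    unknown <- setdiff(names(contamination), reasons)
    if (length(unknown) > 0)
      stopf("unknown contamination reason(s): %s",
            paste(unknown, collapse = ", "))
    if (any(contamination < 0 | contamination > 1))
      stopf("contamination fractions must be in [0,1]")
    frac[names(contamination)] <- contamination
  }
  if (sum(frac) > 1) stopf("contamination fractions sum to more than 1")
  n_fail <- floor(frac * n)
  with_seed(seed, {
    planted <- c(rep(reasons, times = n_fail),
                 rep(NA_character_, n - sum(n_fail)))
    g_lo <- cfg$min_genes
    g_hi <- cfg$max_genes
    u_lo <- cfg$min_umi
    draw_pass <- function(m) {
      genes <- sample((g_lo + 1):(g_hi - 1), m, replace = TRUE)
      data.frame(genes_detected = genes,
                 umi_total = pmax(genes, u_lo + 1) + sample(100:3000, m, TRUE),
                 pct_mito = stats::runif(m, 0, cfg$max_pct_mito * 0.98),
                 pct_chloro = stats::runif(m, 0, cfg$max_pct_chloro * 0.98))
    }
    df <- draw_pass(length(planted))
    fix <- function(reason, fun) {
      idx <- which(planted == reason)
      if (length(idx) > 0) df[idx, ] <<- fun(df[idx, , drop = FALSE])
    }
    fix("min_genes", function(d) {
      d$genes_detected <- sample(0:g_lo, nrow(d), TRUE)
      d$genes_detected[1] <- g_lo
      d
    })
    fix("max_genes", function(d) {
      d$genes_detected <- sample(g_hi:(g_hi + 3000), nrow(d), TRUE)
      d$genes_detected[1] <- g_hi
      d$umi_total <- d$genes_detected + sample(0:3000, nrow(d), TRUE)
      d
    })
    fix("min_umi", function(d) {
      d$umi_total <- sample((g_lo + 1):u_lo, nrow(d), TRUE)
      d$umi_total[1] <- u_lo
      d$genes_detected <- g_lo + 1 +
        floor(stats::runif(nrow(d)) * (d$umi_total - g_lo - 1))
      d
    })
    fix("pct_mito", function(d) {
      d$pct_mito <- stats::runif(nrow(d), cfg$max_pct_mito, 50)
      d$pct_mito[1] <- cfg$max_pct_mito
      d
    })
    fix("pct_chloro", function(d) {
      d$pct_chloro <- stats::runif(nrow(d), cfg$max_pct_chloro, 60)
      d$pct_chloro[1] <- cfg$max_pct_chloro
      d
    })
    ord <- sample.int(length(planted))
    df <- df[ord, , drop = FALSE]
    planted <- planted[ord]
    data.frame(barcode = sprintf("qc_cell%05d", seq_along(planted)),
               dataset_label = "qc_sim",
               df,
               cluster = NA_character_, subcluster = NA_character_,
               planted_fail = planted,
               stringsAsFactors = FALSE, row.names = NULL)
  })
}

#' Generate spatial transcript points from per-domain Poisson processes
#'
#' Each domain is a rectangle holding `n_cells` abstract cells; for every
#' gene with intensity lambda (expected total transcripts in the domain),
#' per-cell transcript counts are Poisson(lambda / n_cells) and each
#' transcript gets a uniform position inside the domain. Genes absent from
#' a domain's intensity vector produce no points there, and two genes
#' listed for the same domain are co-planted in the same cells.
#'
#' @param domains List of domain definitions, each a list with `name`,
#'   `xlim`, `ylim`, optional `n_cells` (default 25) and `intensity` (a
#'   named numeric vector of expected total transcript counts per gene).
#' @param seed RNG seed.
#' @return data.frame with columns `x`, `y`, `gene`, `cell_id`, `domain`.
#' @export
generate_spatial_points <- function(domains, seed = 1) {
  if (!is.list(domains) || length(domains) == 0)
    stopf("domains must be a nonempty list")
  with_seed(seed, {
    rows <- list()
    for (d in domains) {
      stopifnot(!is.null(d$name), length(d$xlim) == 2, length(d$ylim) == 2,
                !is.null(d$intensity), !is.null(names(d$intensity)))
      n_cells <- d$n_cells %||% 25
      for (g in names(d$intensity)) {
        lam <- d$intensity[[g]]
        if (lam < 0) stopf("negative intensity for gene '%s'", g)
        per_cell <- stats::rpois(n_cells, lam / n_cells)
        tot <- sum(per_cell)
        if (tot == 0) next
        rows[[length(rows) + 1]] <- data.frame(
          x = stats::runif(tot, d$xlim[1], d$xlim[2]),
          y = stats::runif(tot, d$ylim[1], d$ylim[2]),
          gene = g,
          cell_id = rep(sprintf("%s_cell%03d", d$name, seq_len(n_cells)),
                        times = per_cell),
          domain = d$name,
          stringsAsFactors = FALSE
        )
      }
    }
    if (length(rows) == 0)
      return(data.frame(x = numeric(), y = numeric(), gene = character(),
                        cell_id = character(), domain = character(),
                        stringsAsFactors = FALSE))
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}

#' Tabulate spatial transcript points into a gene-by-cell count matrix
#'
#' @param points data.frame as produced by [generate_spatial_points()]
#'   (or any segmented transcript table with `gene` and `cell_id`).
#' @return Sparse genes x cells integer count matrix.
#' @export
points_to_counts <- function(points) {
  need_cols(points, c("gene", "cell_id"), "point table")
  genes <- sort(unique(points$gene))
  cells <- sort(unique(points$cell_id))
  m <- Matrix::sparseMatrix(
    i = match(points$gene, genes),
    j = match(points$cell_id, cells),
    x = 1,
    dims = c(length(genes), length(cells)),
    dimnames = list(genes, cells)
  )
  methods::as(m, "CsparseMatrix")
}
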