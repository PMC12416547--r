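#' Pipeline configuration with atlas-study defaults
#'
#' Collects every numeric threshold the pipeline uses, defaulting to the
#' published atlas values: nuclei are kept when >300 and <7,000 genes are
#' detected, >400 UMI, <5% mitochondrial and <15% chloroplast reads;
#' spatial spots with fewer than 125 genes or 125 UMI are removed; cluster
#' markers use a log2 fold-change threshold of 0.25 with min.pct 0.1, and
#' the stringent marker set adds adjusted P < 0.0005 and log2 fold change
#' > 2; cross-organ uniqueness requires the target cluster to be more than
#' fourfold above every other-organ cluster and every other-organ cluster
#' to stay at or below log2 TPM 5; imaging-panel candidates need more than
#' 25 probes and tissue TPM below 1,000.
#'
#' @param ... Named overrides of any default listed below.
#' @return A `pipeline_config` object (named list).
#' @section Fields:
#' \describe{
#'   \item{min_genes, max_genes, min_umi}{nucleus QC bounds (strict
#'     inequalities: 300, 7000, 400).}
#'   \item{max_pct_mito, max_pct_chloro}{organelle read percentage caps
#'     (5, 15).}
#'   \item{spot_min_genes, spot_min_umi}{spatial spot minima (125, 125;
#'     "fewer than" is strict, so equality passes).}
#'   \item{logfc_min, min_pct}{standard marker thresholds (0.25, 0.1).}
#'   \item{padj_max, log2fc_min}{stringent marker thresholds (0.0005, 2).}
#'   \item{padj_method}{"bonferroni" (default) or "BH".}
#'   \item{fold_ratio, log2tpm_cap}{cross-organ uniqueness rules (4, 5).}
#'   \item{probe_min, tpm_cap}{panel candidate filter (25, 1000).}
#'   \item{panel_size, tpm_budget}{default panel dimensions (140, 11000).}
#'   \item{min_score, min_overlap_genes}{annotation confidence gates
#'     (0.02, 3).}
#'   \item{min_overlap}{marker-set overlap reporting floor (10).}
#'   \item{detect_threshold}{counts needed to call a gene detected in
#'     co-expression analysis (1).}
#'   \item{mito_prefix, chloro_prefix}{gene-id prefixes flagging organelle
#'     genes ("ATM", "ATC").}
#'   \item{seed}{default RNG seed (1).}
#' }
#' @examples
#' cfg <- pipeline_config(min_umi = 500)
#' cfg$min_umi
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    min_genes = 300,
    max_genes = 7000,
    min_umi = 400,
    max_pct_mito = 5,
    max_pct_chloro = 15,
    spot_min_genes = 125,
    spot_min_umi = 125,
    logfc_min = 0.25,
    min_pct = 0.1,
    padj_max = 0.0005,
    log2fc_min = 2,
    padj_method = "bonferroni",
    fold_ratio = 4,
    log2tpm_cap = 5,
    probe_min = 25,
    tpm_cap = 1000,
    panel_size = 140,
    tpm_budget = 11000,
    min_score = 0.02,
    min_overlap_genes = 3,
    min_overlap = 10,
    detect_threshold = 1,
    mito_prefix = "ATM",
    chloro_prefix = "ATC",
    seed = 1
  )
  over <- list(...)
  if (length(over) > 0) {
    if (is.null(names(over)) || any(names(over) == ""))
      stopf("pipeline_config() overrides must be named")
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown) > 0)
      stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
    for (k in names(over)) {
      v <- over[[k]]
      if (is.numeric(cfg[[k]])) {
        if (!is.numeric(v) || length(v) != 1 || is.na(v))
          stopf("configuration key '%s' must be a single number", k)
        v <- as.numeric(v)
      }
      cfg[[k]] <- v
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config with", length(x), "settings\n")
  for (k in names(x)) cat(sprintf("  %-18s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Read a pipeline configuration from a flat key-value file
#'
#' Lines are `key: value` or `key = value` (or tab-separated); blank lines
#' and `#` comments are ignored. Keys not present in the file keep their
#' defaults; unknown keys are an error naming the key.
#'
#' @param path File path.
#' @return A [pipeline_config()] object.
#' @export
load_config <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(pipeline_config())
  parts <- regmatches(lines, regexec("^([^:=\t]+)[:=\t][[:space:]]*(.*)$", lines))
  bad <- vapply(parts, length, 1L) != 3L
  if (any(bad))
    stopf("cannot parse configuration line(s): %s",
          paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(parts, `[`, "", 2))
  vals <- trimws(vapply(parts, `[`, "", 3))
  defaults <- pipeline_config()
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown) > 0)
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  over <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (is.numeric(defaults[[k]])) {
      v <- suppressWarnings(as.numeric(vals[i]))
      if (is.na(v))
        stopf("configuration key '%s' must be numeric, got '%s'", k, vals[i])
      over[[k]] <- v
    } else {
      over[[k]] <- vals[i]
    }
  }
  do.call(pipeline_config, over)
}
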