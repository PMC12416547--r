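#' Imaging-panel design specification
#'
#' @param size Maximum number of genes in the panel (K >= 1).
#' @param budget Total pseudobulk TPM the panel must stay strictly below
#'   (imaging panels saturate optically when the summed expression of
#'   their targets is too high).
#' @param quotas Optional named integer vector splitting `size` between
#'   candidate pools (e.g. `c(cluster = 600, tf = 400)` for a design of
#'   600 cluster/subcluster markers plus 400 transcription factors);
#'   candidates must then carry a matching `pool` column. Pools are
#'   filled in the order given, sharing the one budget.
#' @return A `panel_spec` object.
#' @export
panel_spec <- function(size, budget, quotas = NULL) {
  stopifnot(length(size) == 1, size >= 1, length(budget) == 1, budget > 0)
  if (!is.null(quotas)) {
    if (is.null(names(quotas)) || any(!nzchar(names(quotas))))
      stopf("quotas must be named by pool")
    if (sum(quotas) != size)
      stopf("pool quotas (%d) must sum to the panel size (%d)",
            sum(quotas), size)
  }
  structure(list(size = as.integer(size), budget = as.numeric(budget),
                 quotas = quotas), class = "panel_spec")
}

#' Filter imaging-panel candidate genes
#'
#' A marker gene is an eligible panel candidate iff more than
#' `cfg$probe_min` (default 25) specific probes can be designed for it
#' and its whole-tissue pseudobulk TPM is below `cfg$tpm_cap` (default
#' 1,000); both inequalities strict. Genes lacking a probe count are
#' excluded with a warning.
#'
#' @param markers Marker data.frame (`gene_id`, `cluster`, `avg_log2FC`).
#' @param tissue_tpm Named numeric vector: whole-tissue pseudobulk TPM per
#'   gene (all cells of the target dataset aggregated).
#' @param probe_counts Named numeric vector: designable probes per gene.
#' @param cfg [pipeline_config()].
#' @return data.frame of candidates: `gene_id`, `cluster`, `avg_log2FC`,
#'   `tpm`, `probe_count` (plus `pool` if present in `markers`).
#' @export
filter_candidates <- function(markers, tissue_tpm, probe_counts,
                              cfg = pipeline_config()) {
  need_cols(markers, c("gene_id", "cluster", "avg_log2FC"), "marker table")
  probes <- probe_counts[markers$gene_id]
  no_probe <- is.na(probes)
  if (any(no_probe))
    warnf("%d marker record(s) lack a probe count and were excluded",
          sum(no_probe))
  tpm <- tissue_tpm[markers$gene_id]
  if (any(is.na(tpm)))
    stopf("gene(s) missing from tissue pseudobulk: %s",
          paste(unique(markers$gene_id[is.na(tpm)]), collapse = ", "))
  keep <- !no_probe & probes > cfg$probe_min & tpm < cfg$tpm_cap
  out <- markers[keep, intersect(c("gene_id", "cluster", "avg_log2FC", "pool"),
                                 names(markers)), drop = FALSE]
  out$tpm <- unname(tpm[keep])
  out$probe_count <- unname(probes[keep])
  rownames(out) <- NULL
  out
}

# rank candidates the way the panel prefers them: specific (high fold
# change) then low abundance, gene id as the deterministic tie-break
rank_candidates <- function(df) {
  df[order(-df$avg_log2FC, df$tpm, df$gene_id), , drop = FALSE]
}

#' Select an imaging panel under an expression budget
#'
#' Greedy coverage-first selection: clusters are visited in ascending
#' order of their cheapest remaining candidate while a budget reservation
#' is held for the cheapest candidate of every cluster still to cover, so
#' the number of clusters represented is maximal for the budget; within
#' that allowance each cluster contributes its best-ranked candidate
#' (descending `avg_log2FC`, then ascending TPM, then gene id — specific,
#' low-abundance genes keep optical crowding down). Remaining slots are
#' then filled round-robin over clusters under the plain budget check.
#' Wholly deterministic. With pool quotas, pools are processed in order
#' and share the one budget.
#'
#' @param candidates data.frame from [filter_candidates()] (`gene_id`,
#'   `cluster`, `avg_log2FC`, `tpm`, optional `pool`). A gene marking
#'   several clusters is selected at most once.
#' @param spec A [panel_spec()].
#' @return A `panel` object: `genes` (selection order), `total_tpm`,
#'   `covered` clusters, `size_limit`, `budget`. Errors when no candidate
#'   fits the budget at all; warns when fewer than `spec$size` genes fit.
#' @export
select_panel <- function(candidates, spec) {
  stopifnot(inherits(spec, "panel_spec"))
  if (nrow(candidates) == 0) stopf("no candidates supplied")
  need_cols(candidates, c("gene_id", "cluster", "avg_log2FC", "tpm"),
            "candidate table")
  if (is.null(spec$quotas)) {
    candidates$pool <- "all"
    quotas <- stats::setNames(spec$size, "all")
  } else {
    need_cols(candidates, "pool", "candidate table (quota design)")
    quotas <- spec$quotas
  }
  if (all(candidates$tpm >= spec$budget))
    stopf("infeasible budget: no candidate fits below %g", spec$budget)

  total <- 0
  used_genes <- character()
  picked <- list()
  for (pool in names(quotas)) {
    cand <- candidates[candidates$pool == pool, , drop = FALSE]
    slots <- quotas[[pool]]
    covered <- character()
    # phase 1: cover as many clusters as the budget allows
    repeat {
      if (slots <= 0) break
      cand_free <- cand[!cand$gene_id %in% used_genes &
                          !cand$cluster %in% covered, , drop = FALSE]
      if (nrow(cand_free) == 0) break
      mins <- vapply(split(cand_free$tpm, cand_free$cluster), min, 0)
      mins <- mins[order(mins, names(mins))]
      plan <- mins[cumsum(mins) < spec$budget - total]
      plan <- utils::head(plan, slots)
      if (length(plan) == 0) break
      cl <- names(plan)[1]
      reserve <- sum(plan[-1])
      allowed <- spec$budget - total - reserve
      opts <- rank_candidates(cand_free[cand_free$cluster == cl &
                                          cand_free$tpm < allowed, ,
                                        drop = FALSE])
      pick <- opts[1, , drop = FALSE]
      picked[[length(picked) + 1]] <- pick
      used_genes <- c(used_genes, pick$gene_id)
      covered <- c(covered, cl)
      total <- total + pick$tpm
      slots <- slots - 1
    }
    # phase 2: fill remaining slots round-robin over clusters
    clusters <- sort(unique(cand$cluster))
    while (slots > 0) {
      added <- FALSE
      for (cl in clusters) {
        if (slots <= 0) break
        opts <- cand[cand$cluster == cl & !cand$gene_id %in% used_genes &
                       cand$tpm < spec$budget - total, , drop = FALSE]
        if (nrow(opts) == 0) next
        pick <- rank_candidates(opts)[1, , drop = FALSE]
        picked[[length(picked) + 1]] <- pick
        used_genes <- c(used_genes, pick$gene_id)
        total <- total + pick$tpm
        slots <- slots - 1
        added <- TRUE
      }
      if (!added) break
    }
    if (slots > 0)
      warnf("pool '%s': only %d of %d slots could be filled within budget %g",
            pool, quotas[[pool]] - slots, quotas[[pool]], spec$budget)
  }
  genes <- do.call(rbind, c(picked, list(make.row.names = FALSE)))
  if (is.null(genes))
    genes <- candidates[0, , drop = FALSE]
  structure(list(genes = genes, total_tpm = sum(genes$tpm),
                 covered = unique(genes$cluster),
                 size_limit = spec$size, budget = spec$budget),
            class = "panel")
}

#' @export
print.panel <- function(x, ...) {
  cat(sprintf("panel: %d/%d genes, %d clusters covered, total TPM %.1f < %g\n",
              nrow(x$genes), x$size_limit, length(x$covered), x$total_tpm,
              x$budget))
  invisible(x)
}

#' Validate a panel against its specification
#'
#' Checks the panel invariants: size within the limit, total TPM strictly
#' below the budget (and consistent with the member sum), members unique
#' and nonnegative.
#'
#' @param panel A `panel` from [select_panel()] (an empty panel passes
#'   vacuously with a warning).
#' @param spec The [panel_spec()] it was built for.
#' @return list with `pass`, `margin` (budget minus total TPM) and a
#'   `checks` data.frame.
#' @export
validate_panel <- function(panel, spec) {
  stopifnot(inherits(spec, "panel_spec"))
  n <- nrow(panel$genes)
  if (n == 0) warnf("empty panel: validation passes vacuously")
  checks <- data.frame(
    check = c("size_within_limit", "total_below_budget", "total_consistent",
              "genes_unique", "tpm_nonnegative"),
    pass = c(n <= spec$size,
             panel$total_tpm < spec$budget,
             isTRUE(all.equal(panel$total_tpm, sum(panel$genes$tpm))),
             !anyDuplicated(panel$genes$gene_id),
             n == 0 || all(panel$genes$tpm >= 0)),
    stringsAsFactors = FALSE
  )
  list(pass = all(checks$pass), margin = spec$budget - panel$total_tpm,
       checks = checks)
}
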