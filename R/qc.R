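#' Cell-level QC thresholds
#'
#' Defaults follow the study design for the two assay modes. Multiome cells
#' are removed when ATAC reads >= `atac_max` or <= `atac_min`, RNA reads >=
#' `rna_max`, mononucleosomal/nucleosome-free ratio >= `mono_nfr_ratio_max`,
#' TSS enrichment <= `tss_min`, or mitochondrial fraction >= `mito_frac_max`.
#' scRNA cells are removed when expressing fewer than `min_genes` genes or
#' more than `mito_frac_max_scrna` mitochondrial counts.
#'
#' @param atac_max,atac_min,rna_max,mono_nfr_ratio_max,tss_min,mito_frac_max
#'   Multiome thresholds.
#' @param min_genes,mito_frac_max_scrna scRNA thresholds.
#' @return A `cell_qc_thresholds` list.
#' @export
cell_qc_thresholds <- function(atac_max = 100000, atac_min = 1000,
                               rna_max = 50000, mono_nfr_ratio_max = 2,
                               tss_min = 1, mito_frac_max = 0.25,
                               min_genes = 200, mito_frac_max_scrna = 0.15) {
  th <- list(atac_max = atac_max, atac_min = atac_min, rna_max = rna_max,
             mono_nfr_ratio_max = mono_nfr_ratio_max, tss_min = tss_min,
             mito_frac_max = mito_frac_max, min_genes = min_genes,
             mito_frac_max_scrna = mito_frac_max_scrna)
  if (any(unlist(th) <= 0)) stop("all QC thresholds must be positive")
  structure(th, class = "cell_qc_thresholds")
}

#' Filter cells on QC metrics
#'
#' Applies the removal rules for the chosen mode disjunctively: a cell is
#' removed if any rule fires. Rules are applied globally (not per sample).
#'
#' @param metrics data.frame of per-cell metrics. Multiome mode requires
#'   `atac_reads`, `rna_reads`, `mono_nfr_ratio`, `tss_score`, `mito_frac`;
#'   scRNA mode requires `n_genes`, `mito_frac`. A `cell_id` column is used
#'   when present, else row order.
#' @param thresholds A [cell_qc_thresholds()] object.
#' @param mode `"multiome"` or `"scrna"`.
#' @return List with `retained` (cell ids), `removed` (cell ids),
#'   `removed_per_rule` (named counts; a cell failing several rules counts in
#'   each), and `n_input`.
#' @export
qc_filter_cells <- function(metrics, thresholds = cell_qc_thresholds(),
                            mode = c("multiome", "scrna")) {
  mode <- match.arg(mode)
  ids <- metrics$cell_id %||% rownames(metrics) %||% as.character(seq_len(nrow(metrics)))
  need <- switch(mode,
    multiome = c("atac_reads", "rna_reads", "mono_nfr_ratio", "tss_score", "mito_frac"),
    scrna = c("n_genes", "mito_frac"))
  missing <- setdiff(need, names(metrics))
  if (length(missing))
    stop("missing QC metric column(s): ", paste(missing, collapse = ", "))
  th <- thresholds
  rules <- if (mode == "multiome") list(
    atac_high = metrics$atac_reads >= th$atac_max,
    atac_low = metrics$atac_reads <= th$atac_min,
    rna_high = metrics$rna_reads >= th$rna_max,
    mono_nfr_high = metrics$mono_nfr_ratio >= th$mono_nfr_ratio_max,
    tss_low = metrics$tss_score <= th$tss_min,
    mito_high = metrics$mito_frac >= th$mito_frac_max
  ) else list(
    few_genes = metrics$n_genes < th$min_genes,
    mito_high = metrics$mito_frac > th$mito_frac_max_scrna
  )
  fail <- Reduce(`|`, rules)
  list(
    retained = ids[!fail],
    removed = ids[fail],
    removed_per_rule = vapply(rules, sum, integer(1)),
    n_input = nrow(metrics)
  )
}
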