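#' Construct an eRegulon
#'
#' A TF together with its predicted target regions and target genes
#' (TF-region-gene triplet). Classification (`activator` / `repressor` /
#' `dropped`) is assigned by [filter_eregulons()].
#'
#' @param tf TF gene symbol.
#' @param target_regions Character vector of region ids.
#' @param target_genes Character vector of gene symbols.
#' @return An `eregulon` list.
#' @export
eregulon <- function(tf, target_regions, target_genes = character(0)) {
  structure(list(tf = tf, target_regions = target_regions,
                 target_genes = target_genes, class = NA_character_,
                 r = NA_real_),
            class = "eregulon")
}

#' Rank features for one cell
#'
#' Strict ordering by decreasing value; ties broken by feature id so the
#' ranking is always a permutation.
#'
#' @param values Named numeric vector of feature values.
#' @return Character vector of feature ids, best first.
#' @export
rank_features <- function(values) {
  names(values)[order(-values, names(values), method = "radix")]
}

#' Ranking-AUC enrichment of a feature set
#'
#' Area under the recovery curve at the top `top_frac` of the ranking:
#' `y(x)` counts set members among the top `x` ranks for `x = 1..X`,
#' `X = ceiling(top_frac * n)`, and
#' `AUC = sum(y) / (X * min(|set|, X))`, so a fully recovered small set at
#' the very top scores 1.
#'
#' @param ranking Character vector of all feature ids, best first.
#' @param feature_set Non-empty character vector of set members.
#' @param top_frac Fraction of the ranking examined (default 0.05).
#' @return AUC score in `[0, 1]`.
#' @export
auc_enrichment <- function(ranking, feature_set, top_frac = 0.05) {
  if (length(feature_set) == 0) stop("feature_set must be non-empty")
  if (top_frac <= 0 || top_frac > 1) stop("top_frac must be in (0, 1]")
  n <- length(ranking)
  X <- ceiling(top_frac * n)
  y <- cumsum(ranking[seq_len(X)] %in% feature_set)
  sum(y) / (X * min(length(feature_set), X))
}

#' Per-cell AUC scores for a list of regulons
#'
#' @param mat Features x cells value matrix (e.g. accessibility or
#'   expression); per cell, features are ranked by decreasing value.
#' @param regulons Named list of feature-id character vectors, or a list of
#'   [eregulon()] objects (their `target_regions` are used).
#' @param top_frac Fraction of the ranking examined (default 0.05).
#' @return Cells x regulons score matrix.
#' @export
regulon_scores <- function(mat, regulons, top_frac = 0.05) {
  sets <- lapply(regulons, function(r) if (is(r, "eregulon")) r$target_regions else r)
  names(sets) <- names(sets) %||%
    vapply(regulons, function(r) if (is(r, "eregulon")) r$tf else NA_character_,
           character(1))
  out <- matrix(NA_real_, nrow = ncol(mat), ncol = length(sets),
                dimnames = list(colnames(mat), names(sets)))
  for (ci in seq_len(ncol(mat))) {
    v <- setNames(as.numeric(mat[, ci]), rownames(mat))
    ranking <- rank_features(v)
    out[ci, ] <- vapply(sets, function(s) auc_enrichment(ranking, s, top_frac),
                        numeric(1))
  }
  out
}

#' Build pseudo-bulks by stratified sampling
#'
#' Draws `n_draws` pseudo-bulks of `size` cells (without replacement within
#' a draw) from every cell-type x condition stratum, and averages the
#' supplied per-cell profiles over each pseudo-bulk to denoise downstream
#' correlations. Strata with fewer than `size` cells are skipped with a
#' warning.
#'
#' @param meta data.frame with `cell_id`, `cell_type`, `condition`.
#' @param profiles Named list of features x cells matrices to average
#'   (columns matching `meta$cell_id`).
#' @param size Cells per pseudo-bulk (default 5).
#' @param n_draws Pseudo-bulks per stratum (default 50).
#' @param seed Seed.
#' @return A `pseudobulks` object: `meta` (one row per pseudo-bulk),
#'   `members` (list of cell-id vectors), and one averaged matrix per
#'   profile under `averaged`.
#' @export
make_pseudobulks <- function(meta, profiles = list(), size = 5, n_draws = 50,
                             seed = 1L) {
  if (size < 1) stop("size must be >= 1")
  stopifnot(all(c("cell_id", "cell_type", "condition") %in% names(meta)))
  set.seed(sub_seed(seed, "pseudobulk"))
  strata <- split(meta$cell_id,
                  list(meta$cell_type, meta$condition), drop = TRUE)
  members <- list(); pb_meta <- list()
  for (s in names(strata)) {
    ids <- strata[[s]]
    if (length(ids) < size) {
      warning("stratum ", s, " has fewer than ", size, " cells; skipped")
      next
    }
    parts <- strsplit(s, "\\.")[[1]]
    for (d in seq_len(n_draws)) {
      members[[length(members) + 1L]] <- sort(sample(ids, size))
      pb_meta[[length(pb_meta) + 1L]] <- data.frame(
        pb_id = sprintf("pb_%s_%03d", s, d),
        cell_type = parts[1], condition = parts[2],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(members)) stop("no stratum had enough cells for pseudo-bulking")
  pb_meta <- do.call(rbind, pb_meta)
  averaged <- lapply(profiles, function(m) {
    out <- vapply(members, function(ids) Matrix::rowMeans(m[, ids, drop = FALSE]),
                  numeric(nrow(m)))
    dimnames(out) <- list(rownames(m), pb_meta$pb_id)
    out
  })
  structure(list(meta = pb_meta, members = members, averaged = averaged,
                 size = size),
            class = "pseudobulks")
}

#' Filter and classify eRegulons by pseudo-bulk correlation
#'
#' Pearson correlation between the TF's averaged expression and the
#' regulon's recomputed region-enrichment score across pseudo-bulks;
#' `r > cutoff` retains the regulon as activator, `r < -cutoff` as
#' repressor, anything else is dropped. TFs with zero expression variance
#' across pseudo-bulks are dropped with a reason.
#'
#' @param eregulons List of [eregulon()] objects.
#' @param pseudobulks A [make_pseudobulks()] object whose `averaged` list
#'   contains `expression` (genes x pseudobulks) and `accessibility`
#'   (regions x pseudobulks).
#' @param cutoff Absolute correlation cutoff (default 0.5).
#' @param top_frac AUC ranking fraction for rescoring (default 0.05).
#' @return The eregulons with `class` and `r` filled, plus a summary
#'   data.frame attached as attribute `"summary"`.
#' @export
filter_eregulons <- function(eregulons, pseudobulks, cutoff = 0.5,
                             top_frac = 0.05) {
  expr <- pseudobulks$averaged$expression
  acc <- pseudobulks$averaged$accessibility
  if (is.null(expr) || is.null(acc))
    stop("pseudobulks must carry averaged 'expression' and 'accessibility'")
  if (ncol(expr) < 3) stop("need >= 3 pseudobulks for correlation")
  scores <- regulon_scores(acc, eregulons, top_frac = top_frac)
  rows <- lapply(seq_along(eregulons), function(i) {
    er <- eregulons[[i]]
    if (!er$tf %in% rownames(expr))
      return(data.frame(tf = er$tf, r = NA, class = "dropped",
                        reason = "tf_not_expressed"))
    tf_expr <- expr[er$tf, ]
    if (sd(tf_expr) == 0)
      return(data.frame(tf = er$tf, r = NA, class = "dropped",
                        reason = "zero_variance"))
    if (sd(scores[, i]) == 0)
      return(data.frame(tf = er$tf, r = NA, class = "dropped",
                        reason = "zero_variance_score"))
    r <- cor(tf_expr, scores[, i])
    cls <- if (is.na(r)) "dropped" else if (r > cutoff) "activator"
           else if (r < -cutoff) "repressor" else "dropped"
    data.frame(tf = er$tf, r = r, class = cls,
               reason = if (cls == "dropped") "low_correlation" else "",
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)
  for (i in seq_along(eregulons)) {
    eregulons[[i]]$class <- summary$class[i]
    eregulons[[i]]$r <- summary$r[i]
  }
  attr(eregulons, "summary") <- summary
  eregulons
}

#' Regulon specificity score (RSS)
#'
#' One minus the Jensen-Shannon distance (base-2, so in `[0, 1]`) between a
#' regulon's normalized enrichment distribution over cells and a cell
#' label's indicator distribution. RSS is 1 exactly when the enrichment mass
#' coincides with the label's cells.
#'
#' @param enrichment Cells x regulons non-negative score matrix.
#' @param cell_labels Per-cell labels.
#' @return Regulons x labels matrix of RSS values in `[0, 1]`.
#' @export
regulon_specificity_score <- function(enrichment, cell_labels) {
  enrichment <- as.matrix(enrichment)
  if (any(enrichment < 0)) stop("enrichment must be non-negative")
  totals <- colSums(enrichment)
  if (any(totals == 0))
    stop("all-zero regulon(s): ",
         paste(colnames(enrichment)[totals == 0], collapse = ", "))
  labels <- sort(unique(as.character(cell_labels)))
  js_distance <- function(p, q) {
    m <- (p + q) / 2
    kl <- function(a, b) { i <- a > 0; sum(a[i] * log2(a[i] / b[i])) }
    sqrt(pmin(1, pmax(0, 0.5 * kl(p, m) + 0.5 * kl(q, m))))
  }
  out <- matrix(NA_real_, nrow = ncol(enrichment), ncol = length(labels),
                dimnames = list(colnames(enrichment), labels))
  for (lab in labels) {
    q <- as.numeric(cell_labels == lab)
    q <- q / sum(q)
    for (j in seq_len(ncol(enrichment))) {
      p <- enrichment[, j] / totals[j]
      out[j, lab] <- 1 - js_distance(p, q)
    }
  }
  out
}
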