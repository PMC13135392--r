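#' Bin peaks on GC content and mean accessibility
#'
#' Quantile bins on a GC x mean-accessibility grid; background peaks are
#' drawn within the bin of the peak they replace, which controls for the two
#' main technical covariates of accessibility counts.
#'
#' @param gc Per-peak GC fraction.
#' @param mean_acc Per-peak mean accessibility.
#' @param n_bins Bins per covariate (default 10).
#' @return Integer bin id per peak.
#' @export
peak_background_bins <- function(gc, mean_acc, n_bins = 10) {
  qbin <- function(v) {
    br <- unique(quantile(v, probs = seq(0, 1, length.out = n_bins + 1)))
    if (length(br) < 2) return(rep(1L, length(v)))
    as.integer(cut(v, breaks = br, include.lowest = TRUE))
  }
  g <- qbin(gc); a <- qbin(mean_acc)
  as.integer(factor(paste(g, a)))
}

# Draw one background mapping: each peak replaced by a random peak from its
# bin (possibly itself).
sample_background_mapping <- function(bins) {
  by_bin <- split(seq_along(bins), bins)
  out <- integer(length(bins))
  for (members in by_bin) {
    out[members] <- members[sample.int(length(members), length(members),
                                       replace = TRUE)]
  }
  out
}

# Deviation of observed motif counts from the depth-proportional expectation.
# `map` substitutes background peaks while keeping the original matrix's
# cell totals and peak fractions (the published definition of the
# bias-corrected deviation).
raw_deviations <- function(counts, membership,
                           map = seq_len(ncol(counts)),
                           totals = Matrix::rowSums(counts),
                           f = Matrix::colSums(counts) / sum(counts)) {
  obs <- as.matrix(counts[, map, drop = FALSE] %*% membership)
  expected <- totals %o% as.numeric(Matrix::crossprod(membership, f[map]))
  (obs - expected) / expected
}

#' Per-cell motif deviation z-scores
#'
#' For each cell and motif, the raw deviation is
#' `(observed - expected) / expected`, where the expected motif count is the
#' cell's total times the motif peaks' share of all counts. The deviation is
#' standardized against `n_background` background peak sets matched per peak
#' within GC x mean-accessibility quantile bins:
#' `z = (raw - mean_bg) / sd_bg`.
#'
#' @param counts Cells x peaks count matrix (dense or sparse).
#' @param annotations Peaks x motifs logical/0-1 membership matrix.
#' @param gc,mean_acc Per-peak covariates; `mean_acc` defaults to the column
#'   means of `counts`.
#' @param n_background Background sets (default 50).
#' @param n_bins Quantile bins per covariate (default 10).
#' @param seed Seed for background sampling.
#' @param background_sets Optional list of explicit background mappings
#'   (integer vectors, `bg[p]` = replacement peak for peak `p`); overrides
#'   sampling. Used for exact oracle comparisons.
#' @return A `deviation_result`: `z` (cells x motifs), `raw`, `bg_mean`,
#'   `bg_sd`, `bins`.
#' @export
compute_deviation_zscores <- function(counts, annotations, gc = NULL,
                                      mean_acc = NULL, n_background = 50,
                                      n_bins = 10, seed = 1L,
                                      background_sets = NULL) {
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  membership <- Matrix::Matrix(annotations * 1, sparse = TRUE)
  if (nrow(membership) != ncol(counts))
    stop("annotation rows must match the number of peaks")
  motif_sizes <- Matrix::colSums(membership)
  if (any(motif_sizes == 0))
    stop("motif(s) with zero member peaks: ",
         paste(colnames(membership)[motif_sizes == 0], collapse = ", "))
  mean_acc <- mean_acc %||% Matrix::colMeans(counts)
  gc <- gc %||% rep(0.5, ncol(counts))
  bins <- peak_background_bins(gc, mean_acc, n_bins = n_bins)

  totals <- Matrix::rowSums(counts)
  f <- Matrix::colSums(counts) / sum(counts)
  raw <- raw_deviations(counts, membership, totals = totals, f = f)
  if (is.null(background_sets)) {
    set.seed(sub_seed(seed, "deviation_background"))
    background_sets <- replicate(n_background, sample_background_mapping(bins),
                                 simplify = FALSE)
  }
  bg_sum <- 0; bg_sumsq <- 0
  for (bg in background_sets) {
    dev_b <- raw_deviations(counts, membership, map = bg,
                            totals = totals, f = f)
    bg_sum <- bg_sum + dev_b
    bg_sumsq <- bg_sumsq + dev_b^2
  }
  nB <- length(background_sets)
  bg_mean <- bg_sum / nB
  bg_var <- pmax(0, bg_sumsq / nB - bg_mean^2) * nB / max(1, nB - 1)
  bg_sd <- sqrt(bg_var)
  z <- (raw - bg_mean) / bg_sd
  if (any(bg_sd == 0)) {
    warning("zero background SD for some cell/motif pairs; z set to 0")
    z[bg_sd == 0] <- 0
  }
  dimnames(z) <- list(rownames(counts), colnames(membership))
  structure(list(z = z, raw = raw, bg_mean = bg_mean, bg_sd = bg_sd,
                 bins = bins, n_background = nB),
            class = "deviation_result")
}

#' Rank motifs by differential deviation between two groups
#'
#' Two-sided Wilcoxon rank-sum test on each motif's per-cell z-scores (exact
#' when both groups have <= 10 cells, normal approximation with tie and
#' continuity correction otherwise), Bonferroni adjusted; motifs ranked by
#' adjusted p, ties broken by absolute effect (difference of group mean z).
#'
#' @param dev A [compute_deviation_zscores()] result or a cells x motifs
#'   z-score matrix.
#' @param groups Two-level factor/character of cell group labels.
#' @return data.frame ranked: `motif`, `effect`, `p`, `p_adj`, `rank`.
#' @export
rank_differential_motifs <- function(dev, groups) {
  z <- if (is(dev, "deviation_result")) dev$z else as.matrix(dev)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups are required")
  if (any(table(groups) < 2)) stop("each group needs >= 2 cells")
  g1 <- groups == levels(groups)[1]
  exact <- sum(g1) <= 10 && sum(!g1) <= 10
  res <- t(apply(z, 2, function(v) {
    p <- suppressWarnings(wilcox.test(v[g1], v[!g1], exact = exact,
                                      correct = TRUE)$p.value)
    if (is.na(p)) p <- 1  # fully tied motif
    c(effect = mean(v[g1]) - mean(v[!g1]), p = p)
  }))
  out <- data.frame(motif = colnames(z), effect = res[, "effect"],
                    p = res[, "p"],
                    p_adj = pmin(1, res[, "p"] * ncol(z)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_adj, -abs(out$effect)), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
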