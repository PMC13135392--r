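#' Link regulatory regions to genes by distance
#'
#' Each peak is linked to the nearest gene start within `max_dist` bases
#' (nearest-gene priority); peaks with no gene in range are unlinked.
#'
#' @param peaks `GRanges` with a `name` column (peak ids).
#' @param genes `GRanges` gene annotation with `name`s; the strand-aware
#'   start is used as the anchoring coordinate.
#' @param max_dist Maximum linking distance (default 1e5).
#' @return data.frame with `peak`, `gene`, `distance`.
#' @export
link_regions_to_genes <- function(peaks, genes, max_dist = 1e5) {
  tss <- GenomicRanges::resize(genes, width = 1, fix = "start")
  hits <- GenomicRanges::distanceToNearest(peaks, tss, ignore.strand = TRUE)
  keep <- S4Vectors::mcols(hits)$distance <= max_dist
  qh <- S4Vectors::queryHits(hits)[keep]
  sh <- S4Vectors::subjectHits(hits)[keep]
  peak_ids <- peaks$name %||% sprintf("peak_%d", seq_along(peaks))
  gene_ids <- genes$name %||% names(genes)
  data.frame(peak = peak_ids[qh], gene = gene_ids[sh],
             distance = S4Vectors::mcols(hits)$distance[keep],
             stringsAsFactors = FALSE)
}

#' Build a candidate TF-to-gene base GRN from motif hits
#'
#' A TF gains a candidate edge to a gene when the TF's motif scores at least
#' `min_motif_score` in a peak linked to that gene; self-edges are excluded.
#'
#' @param motif_hits data.frame with `peak`, `tf`, `score`.
#' @param region_gene_links data.frame with `peak`, `gene` (from
#'   [link_regions_to_genes()]).
#' @param min_motif_score Motif score cutoff; hits below it are filtered
#'   out (default 10, inclusive at the boundary).
#' @return data.frame of unique candidate edges `tf`, `target`.
#' @export
build_base_grn <- function(motif_hits, region_gene_links,
                           min_motif_score = 10) {
  hits <- motif_hits[motif_hits$score >= min_motif_score, , drop = FALSE]
  merged <- merge(hits, region_gene_links, by = "peak")
  edges <- unique(merged[, c("tf", "gene")])
  names(edges) <- c("tf", "target")
  edges <- edges[edges$tf != edges$target, , drop = FALSE]
  if (nrow(edges) == 0) stop("no candidate edges after motif-score filtering")
  edges <- edges[order(edges$tf, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Select the most variable genes
#'
#' Genes ranked by variance of log-normalized expression; ties broken by
#' gene name for determinism.
#'
#' @param counts Genes x cells count matrix (raw counts; log-normalized
#'   internally), or an already log-normalized matrix with
#'   `normalized = TRUE`.
#' @param n Number of genes to keep (default 3000; all genes when fewer).
#' @param normalized Set when `counts` is already log-normalized.
#' @return Character vector of selected gene names.
#' @export
select_variable_genes <- function(counts, n = 3000, normalized = FALSE) {
  x <- if (normalized) as.matrix(counts) else log_normalize(counts)
  v <- apply(x, 1, var)
  ord <- order(-v, rownames(x), method = "radix")
  rownames(x)[head(ord, min(n, nrow(x)))]
}

# Bayesian ridge fit of one target on its candidate regulators.
# Returns posterior mean coefficients and two-sided Gaussian tail p at 0.
ridge_edge_fit <- function(X, y, lambda) {
  n <- nrow(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  XtX <- crossprod(Xc)
  A <- XtX + diag(lambda, ncol(Xc))
  Ainv <- solve(A)
  beta <- as.numeric(Ainv %*% crossprod(Xc, yc))
  resid <- yc - Xc %*% beta
  eig <- eigen(XtX, symmetric = TRUE, only.values = TRUE)$values
  p_eff <- sum(eig / (eig + lambda))
  sigma2 <- sum(resid^2) / max(1, n - p_eff)
  post_sd <- sqrt(pmax(.Machine$double.eps, sigma2 * diag(Ainv)))
  p <- 2 * pnorm(-abs(beta) / post_sd)
  list(beta = beta, p = p)
}

#' Fit a condition GRN by Bayesian ridge regression
#'
#' For every target gene in the candidate adjacency, its (log-normalized)
#' expression is regressed on its candidate regulators' expression under a
#' Gaussian ridge prior; edge strength is the posterior mean coefficient and
#' the edge p-value is the two-sided tail probability of 0 under the
#' Gaussian posterior. Edges are filtered at `p < p_cutoff` and the top
#' `max_edges` by absolute strength are retained.
#'
#' @param expr Genes x cells log-normalized expression for one condition.
#' @param base_grn data.frame of candidate edges (`tf`, `target`).
#' @param condition Label attached to the model.
#' @param lambda Ridge prior precision (> 0; default 1).
#' @param p_cutoff Edge p-value cutoff (default 0.001).
#' @param max_edges Edges retained per GRN (default 2000).
#' @return A `grn_model`: `edges` (`tf`, `target`, `weight`, `p`),
#'   `condition`, `genes`.
#' @export
fit_grn <- function(expr, base_grn, condition = "condition", lambda = 1,
                    p_cutoff = 0.001, max_edges = 2000) {
  if (lambda <= 0) stop("ridge prior scale must be > 0")
  expr <- as.matrix(expr)
  genes <- rownames(expr)
  cand <- base_grn[base_grn$tf %in% genes & base_grn$target %in% genes, ]
  if (nrow(cand) == 0) stop("no candidate edges among the expressed genes")
  out <- list()
  for (target in unique(cand$target)) {
    regs <- cand$tf[cand$target == target]
    fit <- ridge_edge_fit(t(expr[regs, , drop = FALSE]), expr[target, ], lambda)
    out[[target]] <- data.frame(tf = regs, target = target,
                                weight = fit$beta, p = fit$p,
                                stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, out)
  edges <- edges[edges$p < p_cutoff, , drop = FALSE]
  edges <- edges[order(-abs(edges$weight), edges$tf, edges$target), , drop = FALSE]
  edges <- head(edges, max_edges)
  rownames(edges) <- NULL
  structure(list(edges = edges, condition = condition, genes = genes),
            class = "grn_model")
}

#' @export
print.grn_model <- function(x, ...) {
  cat(sprintf("grn_model [%s]: %d edges over %d genes (%d TFs)\n",
              x$condition, nrow(x$edges), length(x$genes),
              length(unique(x$edges$tf))))
  invisible(x)
}

# BFS distances from a TF over the directed edge list; Inf = unreachable.
grn_reach_distance <- function(edges, genes, tf) {
  dist <- setNames(rep(Inf, length(genes)), genes)
  dist[tf] <- 0
  frontier <- tf
  step <- 0
  while (length(frontier)) {
    step <- step + 1
    nxt <- unique(edges$target[edges$tf %in% frontier])
    nxt <- nxt[is.infinite(dist[nxt])]
    dist[nxt] <- step
    frontier <- nxt
  }
  dist
}

#' Simulate an in-silico TF perturbation on a fitted GRN
#'
#' Knockout sets the TF's expression to 0; overexpression sets it to
#' `oe_factor` times its maximum observed expression. The initial
#' delta-expression (perturbed minus observed) at the TF is propagated
#' `n_propagation` steps through the signed weight matrix: each step adds
#' the next-order increment `W^s delta0`, reaching genes within `s` edges of
#' the TF, while the TF's own delta stays clamped to its perturbed value
#' (it receives no incoming updates). Genes unreachable from the TF keep
#' delta 0.
#'
#' @param grn A [fit_grn()] model.
#' @param expr Genes x cells log-normalized expression.
#' @param tf TF to perturb (must be in the GRN's gene universe).
#' @param mode `"ko"` or `"oe"`.
#' @param oe_factor Overexpression multiplier (default 1.5).
#' @param n_propagation Propagation steps (default 3).
#' @return A `perturbation_result`: `delta` (genes x cells), `tf`, `mode`,
#'   `target_value`.
#' @export
simulate_perturbation <- function(grn, expr, tf, mode = c("ko", "oe"),
                                  oe_factor = 1.5, n_propagation = 3) {
  mode <- match.arg(mode)
  expr <- as.matrix(expr)
  genes <- rownames(expr)
  if (!tf %in% genes || !tf %in% grn$genes)
    stop("TF ", tf, " absent from the GRN gene universe")
  edges <- grn$edges
  W <- Matrix::sparseMatrix(
    i = match(edges$target, genes), j = match(edges$tf, genes),
    x = edges$weight, dims = c(length(genes), length(genes)),
    dimnames = list(genes, genes))
  target_value <- switch(mode, ko = 0, oe = oe_factor * max(expr[tf, ]))
  delta0 <- target_value - expr[tf, ]
  delta <- matrix(0, nrow = length(genes), ncol = ncol(expr),
                  dimnames = dimnames(expr))
  delta[tf, ] <- delta0
  # propagate increments wave by wave; the TF is clamped to its perturbed
  # value (no incoming updates), so each step adds the next-order effect
  incr <- delta
  for (s in seq_len(n_propagation)) {
    incr <- as.matrix(W %*% incr)
    incr[tf, ] <- 0
    delta <- delta + incr
  }
  dist <- grn_reach_distance(edges, genes, tf)
  delta[is.infinite(dist), ] <- 0
  delta[tf, ] <- delta0
  structure(list(delta = delta, tf = tf, mode = mode,
                 target_value = target_value),
            class = "perturbation_result")
}

#' Score perturbation-induced shifts toward a condition
#'
#' The per-cell transition score is the cosine similarity between the cell's
#' delta-expression vector and the direction from the cell to the target
#' condition's centroid in expression space; zero deltas score 0. A 2D shift
#' vector on a principal-component embedding is attached for visualization.
#'
#' @param result A [simulate_perturbation()] result.
#' @param expr Genes x cells log-normalized expression.
#' @param labels Per-cell condition labels.
#' @param target_condition The condition whose centroid cells should move
#'   toward.
#' @param embedding Optional cells x 2 coordinates; defaults to the first
#'   two principal components computed internally.
#' @return List with `scores` (per cell), `embedding`, `shift2d`
#'   (cells x 2), `centroid`.
#' @export
transition_vectors <- function(result, expr, labels, target_condition,
                               embedding = NULL) {
  expr <- as.matrix(expr)
  if (!target_condition %in% labels)
    stop("target_condition absent from labels")
  centroid <- rowMeans(expr[, labels == target_condition, drop = FALSE])
  delta <- result$delta
  scores <- vapply(seq_len(ncol(expr)), function(i) {
    cosine_similarity(delta[, i], centroid - expr[, i])
  }, numeric(1))
  names(scores) <- colnames(expr)
  if (is.null(embedding)) {
    pca <- prcomp(t(expr), rank. = 2)
    embedding <- pca$x[, 1:2, drop = FALSE]
    shift2d <- t(crossprod(pca$rotation[, 1:2, drop = FALSE], delta))
  } else {
    # project deltas through the least-squares map expression -> embedding
    fit <- qr(cbind(1, t(expr)))
    coef <- qr.coef(fit, embedding)
    coef[is.na(coef)] <- 0
    shift2d <- t(delta) %*% coef[-1, , drop = FALSE]
  }
  list(scores = scores, embedding = embedding, shift2d = shift2d,
       centroid = centroid)
}
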