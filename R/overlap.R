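#' Wilcoxon differential expression between two groups
#'
#' Per-gene two-sided rank-sum test on log-normalized expression (exact when
#' both groups have <= 10 cells, normal approximation with tie and
#' continuity correction otherwise) with Bonferroni adjustment over tested
#' genes. The fold change is
#' `log2((mu1 + pseudocount) / (mu2 + pseudocount))` on the de-logged group
#' means. Genes expressed in zero cells are excluded and counted.
#'
#' @param expr Genes x cells log-normalized expression.
#' @param groups Two-level factor of cell labels; group 1 is the first
#'   level (fold changes are group1 over group2).
#' @param pseudocount Pseudocount on the de-logged means (default 1).
#' @return A data.frame of class `de_result`: `gene`, `mean_1`, `mean_2`,
#'   `log2fc`, `p`, `p_adj`; excluded-gene count in attribute
#'   `"n_excluded"`.
#' @export
wilcoxon_de <- function(expr, groups, pseudocount = 1) {
  expr <- as.matrix(expr)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups are required")
  if (any(table(groups) < 2)) stop("each group needs >= 2 cells")
  expressed <- rowSums(expr > 0) > 0
  n_excluded <- sum(!expressed)
  expr <- expr[expressed, , drop = FALSE]
  g1 <- groups == levels(groups)[1]
  exact <- sum(g1) <= 10 && sum(!g1) <= 10
  res <- t(apply(expr, 1, function(v) {
    mu1 <- mean(expm1(v[g1])); mu2 <- mean(expm1(v[!g1]))
    p <- suppressWarnings(wilcox.test(v[g1], v[!g1], exact = exact,
                                      correct = TRUE)$p.value)
    if (is.na(p)) p <- 1  # fully tied gene: no evidence either way
    c(mu1, mu2, p)
  }))
  out <- data.frame(gene = rownames(expr), mean_1 = res[, 1],
                    mean_2 = res[, 2],
                    log2fc = log2((res[, 1] + pseudocount) /
                                  (res[, 2] + pseudocount)),
                    p = res[, 3],
                    p_adj = pmin(1, res[, 3] * nrow(expr)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("de_result", "data.frame")
  out
}

#' Likelihood-ratio differential accessibility
#'
#' Regions are binarized (accessible when count > 0) and each region is
#' tested with a likelihood-ratio comparison of the logistic models
#' `accessible ~ group + covariate` vs `accessible ~ covariate`, Bonferroni
#' adjusted. Regions accessible in all or no cells get p = 1 and are
#' flagged.
#'
#' @param acc Regions x cells count (or binary) matrix.
#' @param groups Two-level factor of cell labels.
#' @param covariate Per-cell latent variable (e.g. total peak counts).
#' @return data.frame: `region`, `p`, `p_adj`, `degenerate` flag.
#' @export
lr_differential_accessibility <- function(acc, groups, covariate) {
  acc <- as.matrix(acc) > 0
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups are required")
  res <- apply(acc, 1, function(y) {
    if (all(y) || !any(y)) return(c(1, TRUE))
    full <- glm(y ~ groups + covariate, family = binomial())
    red <- glm(y ~ covariate, family = binomial())
    stat <- max(0, red$deviance - full$deviance)
    c(pchisq(stat, df = 1, lower.tail = FALSE), FALSE)
  })
  out <- data.frame(region = rownames(acc), p = res[1, ],
                    p_adj = pmin(1, res[1, ] * nrow(acc)),
                    degenerate = as.logical(res[2, ]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Threshold a DE table into a gene set
#'
#' `up`: `log2fc > lfc_min` and `p_adj < p_adj_max` (strict inequalities);
#' `down`: `log2fc < -lfc_min` and `p_adj < p_adj_max`.
#'
#' @param result A [wilcoxon_de()] table.
#' @param p_adj_max Adjusted-p cutoff (default 0.05).
#' @param lfc_min Absolute log2 fold-change cutoff (0.1 / 0.25 / 0.32 in the
#'   comparisons modeled here).
#' @param direction `"up"` or `"down"`.
#' @return Character vector of gene symbols.
#' @export
threshold_de <- function(result, p_adj_max = 0.05, lfc_min = 0.25,
                         direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(p_adj_max > 0, lfc_min > 0)
  keep <- result$p_adj < p_adj_max &
    (if (direction == "up") result$log2fc > lfc_min
     else result$log2fc < -lfc_min)
  result$gene[keep]
}

#' Map gene symbols across namespaces
#'
#' Table lookup first; with the case-rule fallback on, unmapped symbols are
#' converted by casing (mouse Title-case to human UPPER-case or back).
#' Symbols that still fail to map are reported, never silently dropped.
#'
#' @param genes Character vector of symbols to map.
#' @param table data.frame whose first two columns are source and target
#'   symbols (unique per source).
#' @param fallback_case `"upper"`, `"title"`, or `"none"`.
#' @return List with `mapped` (named character: source -> target) and
#'   `unmapped`.
#' @export
map_orthologs <- function(genes, table = NULL,
                          fallback_case = c("upper", "title", "none")) {
  fallback_case <- match.arg(fallback_case)
  mapped <- setNames(rep(NA_character_, length(genes)), genes)
  if (!is.null(table) && nrow(table)) {
    src <- as.character(table[[1]]); dst <- as.character(table[[2]])
    conflict <- tapply(dst, src, function(v) length(unique(v)) > 1)
    if (any(conflict))
      stop("conflicting ortholog rows for: ",
           paste(names(conflict)[conflict], collapse = ", "))
    hit <- match(genes, src)
    mapped[!is.na(hit)] <- dst[hit[!is.na(hit)]]
  }
  todo <- is.na(mapped)
  if (fallback_case == "upper") mapped[todo] <- toupper(genes[todo])
  if (fallback_case == "title") mapped[todo] <- to_title_symbol(genes[todo])
  unmapped <- genes[is.na(mapped)]
  list(mapped = mapped[!is.na(mapped)], unmapped = unmapped)
}

#' Hypergeometric overlap of two gene sets
#'
#' Upper-tail probability `P(X >= k)` of the observed intersection size
#' under a hypergeometric draw from the universe, computed in log space so
#' extreme tails stay finite.
#'
#' @param set_a,set_b Character vectors, subsets of `universe`.
#' @param universe Character vector of all eligible genes.
#' @return An `overlap_result` list: sizes, `k`, `p`, `log10_p`, `method`.
#' @export
hypergeometric_overlap <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  bad <- c(setdiff(set_a, universe), setdiff(set_b, universe))
  if (length(bad))
    stop("set members outside the universe: ",
         paste(unique(bad), collapse = ", "))
  N <- length(universe); K <- length(set_a); n <- length(set_b)
  k <- length(intersect(set_a, set_b))
  log_p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  structure(list(n_a = K, n_b = n, n_universe = N, k = k,
                 p = exp(log_p), log10_p = log_p / log(10),
                 method = "hypergeometric"),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap_result [%s]: k = %d (|A| = %d, |B| = %s, N = %d), p = %.3g\n",
              x$method, x$k, x$n_a,
              if (is.null(x$sizes)) as.character(x$n_b)
              else paste(x$sizes, collapse = ","),
              x$n_universe, x$p))
  invisible(x)
}

#' Monte-Carlo multi-set overlap test
#'
#' Null draws resample `m` random subsets of the observed sizes uniformly
#' without replacement from the universe; the statistic is the size of the
#' m-way intersection and the p-value uses the add-one estimator
#' `(#{null >= observed} + 1) / (B + 1)`.
#'
#' @param sets List of >= 2 character vectors, subsets of `universe`.
#' @param universe Character vector of all eligible genes.
#' @param B Null iterations (default 1e5).
#' @param seed Seed.
#' @return An `overlap_result` with `sizes`, `k`, `p`, `B`.
#' @export
monte_carlo_multiset_overlap <- function(sets, universe, B = 1e5, seed = 1L) {
  if (length(sets) < 2) stop("need at least two sets")
  if (B < 1) stop("B must be >= 1")
  sets <- lapply(sets, unique)
  universe <- unique(universe)
  bad <- unique(unlist(lapply(sets, setdiff, universe)))
  if (length(bad))
    stop("set members outside the universe: ", paste(bad, collapse = ", "))
  sizes <- lengths(sets)
  if (any(sizes > length(universe))) stop("set size exceeds the universe")
  k <- length(Reduce(intersect, sets))
  N <- length(universe)
  set.seed(sub_seed(seed, "monte_carlo_overlap"))
  m <- length(sets)
  exceed <- 0L
  for (b in seq_len(B)) {
    tallies <- integer(N)
    for (j in seq_len(m)) {
      idx <- sample.int(N, sizes[j])
      tallies[idx] <- tallies[idx] + 1L
    }
    if (sum(tallies == m) >= k) exceed <- exceed + 1L
  }
  structure(list(sizes = as.integer(sizes), n_a = sizes[1],
                 n_universe = N, k = k,
                 p = (exceed + 1) / (B + 1), B = as.integer(B),
                 method = "monte_carlo"),
            class = "overlap_result")
}

#' Hypergeometric set enrichment against user-supplied annotations
#'
#' One [hypergeometric_overlap()] per annotation set, Bonferroni-adjusted
#' over annotations.
#'
#' @param query Character vector, subset of `universe`.
#' @param annotations Named list of character vectors (each a subset of
#'   `universe`).
#' @param universe Character vector of all eligible genes.
#' @return data.frame sorted by p: `annotation`, `k`, `size`, `p`, `p_adj`.
#' @export
set_enrichment <- function(query, annotations, universe) {
  rows <- lapply(names(annotations), function(a) {
    ov <- hypergeometric_overlap(query, annotations[[a]], universe)
    data.frame(annotation = a, k = ov$k, size = ov$n_b, p = ov$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p * length(annotations))
  out <- out[order(out$p, out$annotation), ]
  rownames(out) <- NULL
  out
}
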