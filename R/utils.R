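#' @importFrom methods as is
#' @importFrom stats kmeans rnorm runif rpois rnbinom rgamma prcomp
#'   wilcox.test glm pchisq phyper pnorm p.adjust quantile var sd cor
#'   binomial setNames
#' @importFrom utils head read.table write.table
NULL

# Deterministic sub-seed for a named stream, derived from the run seed.
# Keeps results < 2^31 so they are valid R integer seeds.
sub_seed <- function(seed, label) {
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes)) %% 104729L
  as.integer((abs(as.integer(seed)) %% 1000003L) * 2011L + h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Log-normalize a count matrix
#'
#' Library-size normalization to `scale_factor` counts per cell followed by
#' `log1p`, the convention used throughout the single-cell analyses here
#' (genes or regions in rows, cells in columns).
#'
#' @param counts Non-negative count matrix, features x cells.
#' @param scale_factor Target library size (default 1e4).
#' @return Matrix of the same shape with log-normalized values.
#' @export
log_normalize <- function(counts, scale_factor = 1e4) {
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) stop("cells with zero total counts cannot be normalized")
  out <- t(t(as.matrix(counts)) / totals) * scale_factor
  log1p(out)
}

cosine_similarity <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(0)
  sum(x * y) / (nx * ny)
}

# Kahn topological sort on an edge data.frame (from, to). Returns node order
# or NULL when the graph has a cycle.
topological_order <- function(from, to) {
  nodes <- union(from, to)
  indeg <- setNames(integer(length(nodes)), nodes)
  tab <- table(to)
  indeg[names(tab)] <- as.integer(tab)
  out <- split(to, factor(from, levels = nodes))
  queue <- nodes[indeg == 0L]
  order <- character(0)
  while (length(queue)) {
    n <- queue[[1]]; queue <- queue[-1]
    order <- c(order, n)
    for (m in out[[n]]) {
      indeg[[m]] <- indeg[[m]] - 1L
      if (indeg[[m]] == 0L) queue <- c(queue, m)
    }
  }
  if (length(order) < length(nodes)) NULL else order
}

# Title-case a symbol the way murine gene symbols are written (Fosl2).
to_title_symbol <- function(x) {
  paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
}
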