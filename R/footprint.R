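#' Scan a genome for motif instances
#'
#' Scans both strands and reports each hit once with its strand; a
#' palindromic hit matching both strands at the same position is reported on
#' '+'. Modes: exact consensus match (IUPAC-aware), consensus match with up
#' to `m` mismatches, or PWM scanning at a log2-odds threshold against the
#' background base composition.
#'
#' @param genome A `DNAStringSet`.
#' @param motif A [motif_model()].
#' @param mode `"consensus_exact"`, `"consensus_mismatch"` or `"pwm"`.
#' @param max_mismatch Mismatches allowed in `consensus_mismatch` mode.
#' @param min_score Log2-odds threshold for `pwm` mode (default the motif's
#'   `min_score`).
#' @param within Optional `GRanges`; only hits overlapping it are kept.
#' @param background Background base frequencies for the PWM (A,C,G,T).
#' @return `GRanges` of motif-length hits with `motif` column and strand.
#' @export
scan_motif_instances <- function(genome, motif,
                                 mode = c("consensus_exact",
                                          "consensus_mismatch", "pwm"),
                                 max_mismatch = 1, min_score = NULL,
                                 within = NULL, background = NULL) {
  mode <- match.arg(mode)
  letters <- strsplit(motif$consensus, "")[[1]]
  if (!all(letters %in% names(IUPAC_CODES)))
    stop("unknown IUPAC letter in consensus: ",
         paste(setdiff(letters, names(IUPAC_CODES)), collapse = ""))
  len <- motif_length(motif)
  hits <- list()
  add_hits <- function(chrom, starts, strand) {
    if (!length(starts)) return()
    hits[[length(hits) + 1L]] <<- GenomicRanges::GRanges(
      chrom, IRanges::IRanges(starts, width = len), strand = strand)
  }
  if (mode %in% c("consensus_exact", "consensus_mismatch")) {
    mm <- if (mode == "consensus_exact") 0L else as.integer(max_mismatch)
    fwd <- Biostrings::DNAString(motif$consensus)
    rev <- Biostrings::reverseComplement(fwd)
    for (chrom in names(genome)) {
      add_hits(chrom, Biostrings::start(
        Biostrings::matchPattern(fwd, genome[[chrom]], max.mismatch = mm,
                                 fixed = FALSE)), "+")
      add_hits(chrom, Biostrings::start(
        Biostrings::matchPattern(rev, genome[[chrom]], max.mismatch = mm,
                                 fixed = FALSE)), "-")
    }
  } else {
    pwm <- pwm_from_pfm(motif$pfm, background = background)
    thr <- min_score %||% motif$min_score
    for (chrom in names(genome)) {
      fh <- Biostrings::matchPWM(pwm, genome[[chrom]], min.score = thr)
      add_hits(chrom, Biostrings::start(fh), "+")
      rh <- Biostrings::matchPWM(Biostrings::reverseComplement(pwm),
                                 genome[[chrom]], min.score = thr)
      add_hits(chrom, Biostrings::start(rh), "-")
    }
  }
  if (!length(hits)) {
    out <- GenomicRanges::GRanges()
    out$motif <- character(0)
    return(out)
  }
  out <- suppressWarnings(do.call(c, hits))
  # one report per location: palindromic double hits keep '+'
  key <- paste(GenomicRanges::seqnames(out), GenomicRanges::start(out))
  out <- out[order(key, as.character(GenomicRanges::strand(out)))]
  out <- out[!duplicated(paste(GenomicRanges::seqnames(out),
                               GenomicRanges::start(out)))]
  out$motif <- motif$name
  if (!is.null(within) && length(within))
    out <- out[S4Vectors::queryHits(GenomicRanges::findOverlaps(out, within,
                                                                ignore.strand = TRUE))]
  GenomicRanges::sort(unique(out), ignore.strand = TRUE)
}

#' Extract centered multi-condition contribution profiles
#'
#' For each seqlet, per-base contribution over the motif span plus `flank`
#' bases on each side is extracted from every condition's track. Seqlets
#' whose window runs off a chromosome are dropped and counted. With
#' `orient_by_strand`, minus-strand seqlet windows are reversed so profiles
#' align in motif orientation.
#'
#' @param tracks Named list of contribution tracks (`RleList`), one per
#'   condition.
#' @param seqlets `GRanges` of motif instances (equal widths).
#' @param flank Flank size in bases (default 30).
#' @param orient_by_strand Reverse minus-strand windows (default TRUE).
#' @return A `seqlet_profiles` object: `matrix` (rows = seqlets, columns =
#'   condition blocks of width `2*flank + motif length`), `conditions`,
#'   `block_width`, `flank`, `motif_length`, `seqlets` (retained), and
#'   `n_dropped`.
#' @export
extract_profiles <- function(tracks, seqlets, flank = 30,
                             orient_by_strand = TRUE) {
  stopifnot(is.list(tracks), !is.null(names(tracks)))
  if (length(seqlets) == 0) stop("zero usable seqlets")
  widths <- GenomicRanges::width(seqlets)
  if (length(unique(widths)) != 1) stop("seqlets must have equal width")
  motif_len <- widths[1]
  block <- 2L * flank + motif_len
  lens <- track_chrom_lengths(tracks[[1]])
  ws <- GenomicRanges::start(seqlets) - flank
  we <- GenomicRanges::end(seqlets) + flank
  chrom <- as.character(GenomicRanges::seqnames(seqlets))
  ok <- ws >= 1 & we <= lens[chrom] & chrom %in% names(lens)
  n_dropped <- sum(!ok)
  seqlets <- seqlets[ok]; ws <- ws[ok]; we <- we[ok]; chrom <- chrom[ok]
  if (length(seqlets) == 0) stop("zero usable seqlets after edge filtering")
  rev_row <- orient_by_strand & as.character(GenomicRanges::strand(seqlets)) == "-"
  mats <- lapply(names(tracks), function(cond) {
    m <- matrix(NA_real_, nrow = length(seqlets), ncol = block)
    for (i in seq_along(seqlets)) {
      v <- track_window(tracks[[cond]], chrom[i], ws[i], we[i])
      if (rev_row[i]) v <- base::rev(v)
      m[i, ] <- v
    }
    colnames(m) <- sprintf("%s:%+d", cond, seq(-flank, flank + motif_len - 1))
    m
  })
  mat <- do.call(cbind, mats)
  rownames(mat) <- sprintf("seqlet_%d", seq_along(seqlets))
  structure(list(matrix = mat, conditions = names(tracks),
                 block_width = block, flank = flank,
                 motif_length = motif_len, seqlets = seqlets,
                 n_dropped = n_dropped),
            class = "seqlet_profiles")
}

#' @export
print.seqlet_profiles <- function(x, ...) {
  cat(sprintf("seqlet_profiles: %d seqlets x %d conditions (%d columns each), %d dropped at edges\n",
              nrow(x$matrix), length(x$conditions), x$block_width, x$n_dropped))
  invisible(x)
}

# k-means++ seeding (Arthur & Vassilvitskii): spread initial centers.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, nrow = k, ncol = ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1) + 1) {
    if (all(d2 <= 0)) idx <- sample.int(n, 1)
    else idx <- sample.int(n, 1, prob = d2 / sum(d2))
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2))
  }
  centers
}

#' Cluster seqlet profiles with seeded k-means
#'
#' Euclidean k-means on the concatenated condition blocks with k-means++
#' initialization, best of `n_init` restarts by within-cluster sum of
#' squares. Clusters are relabeled in decreasing size order, so cluster 1 is
#' always the largest.
#'
#' @param profiles A [extract_profiles()] result.
#' @param k Number of clusters (>= 2, <= rows).
#' @param seed Seed making the restarts deterministic.
#' @param n_init Number of restarts.
#' @return A `cluster_result`: `k`, `assignment`, `centroids`, `sizes`,
#'   `inertia`, and `condition_means` (per cluster x condition mean
#'   contribution over the motif span).
#' @export
kmeans_cluster_profiles <- function(profiles, k, seed = 1L, n_init = 10) {
  x <- profiles$matrix
  if (k < 2) stop("k must be >= 2")
  if (k > nrow(x)) stop("k exceeds the number of seqlet profiles")
  set.seed(sub_seed(seed, "kmeans"))
  if (k == nrow(x)) {
    # degenerate case: every profile its own cluster
    best <- list(cluster = seq_len(k), centers = x, tot.withinss = 0)
  } else {
  best <- NULL
  for (i in seq_len(n_init)) {
    centers <- kmeanspp_centers(x, k)
    centers <- centers[!duplicated(centers), , drop = FALSE]
    tries <- 0L
    while (nrow(centers) < k && tries < 100L * k) {
      tries <- tries + 1L
      cand <- x[sample.int(nrow(x), 1), , drop = FALSE]
      if (!duplicated(rbind(centers, cand))[nrow(centers) + 1])
        centers <- rbind(centers, cand)
    }
    if (nrow(centers) < k)
      stop("fewer than k distinct profiles; cannot seed k clusters")
    fit <- suppressWarnings(stats::kmeans(x, centers = centers, iter.max = 100))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  }
  # relabel in decreasing size order (stable on ties)
  sizes <- tabulate(best$cluster, nbins = k)
  relabel <- order(-sizes, seq_len(k))
  new_label <- match(seq_len(k), relabel)
  assignment <- new_label[best$cluster]
  centroids <- best$centers[relabel, , drop = FALSE]
  rownames(centroids) <- seq_len(nrow(centroids))

  span <- motif_span_columns(profiles)
  condition_means <- matrix(NA_real_, nrow = k,
                            ncol = length(profiles$conditions),
                            dimnames = list(seq_len(k), profiles$conditions))
  for (cl in seq_len(k)) {
    rows <- which(assignment == cl)
    for (ci in seq_along(profiles$conditions))
      condition_means[cl, ci] <- mean(x[rows, span[[ci]], drop = FALSE])
  }

  structure(list(k = k, assignment = assignment,
                 centroids = centroids, sizes = tabulate(assignment, k),
                 inertia = best$tot.withinss,
                 condition_means = condition_means),
            class = "cluster_result")
}

# Column indices of the motif span within each condition block.
motif_span_columns <- function(profiles) {
  lapply(seq_along(profiles$conditions), function(ci) {
    offset <- (ci - 1L) * profiles$block_width
    offset + profiles$flank + seq_len(profiles$motif_length)
  })
}

#' Score clusters for condition-differential contribution
#'
#' For each cluster, the statistic is the mean contribution over the motif
#' span in condition A minus condition B, averaged over member seqlets. The
#' permutation null shuffles the condition-block labels within each row
#' (random sign flips of the per-row difference for two conditions), with
#' the add-one estimator `p = (#{|perm| >= |obs|} + 1) / (n_perm + 1)`.
#'
#' @param result A [kmeans_cluster_profiles()] result.
#' @param profiles The matching [extract_profiles()] object.
#' @param contrast Length-2 character, conditions A and B.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Seed.
#' @return data.frame per cluster: `cluster`, `n`, `delta`, `p`.
#' @export
score_differential_clusters <- function(result, profiles,
                                        contrast = NULL, n_perm = 999,
                                        seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  contrast <- contrast %||% base::rev(profiles$conditions[1:2])
  if (!all(contrast %in% profiles$conditions))
    stop("contrast conditions not present in the profile matrix")
  span <- motif_span_columns(profiles)
  ia <- match(contrast[1], profiles$conditions)
  ib <- match(contrast[2], profiles$conditions)
  x <- profiles$matrix
  a <- rowMeans(x[, span[[ia]], drop = FALSE])
  b <- rowMeans(x[, span[[ib]], drop = FALSE])
  d <- a - b
  set.seed(sub_seed(seed, "score_differential"))
  signs <- matrix(sample(c(-1, 1), length(d) * n_perm, replace = TRUE),
                  nrow = length(d))
  out <- lapply(seq_len(result$k), function(cl) {
    rows <- which(result$assignment == cl)
    delta <- mean(d[rows])
    perm <- colMeans(signs[rows, , drop = FALSE] * d[rows])
    p <- (sum(abs(perm) >= abs(delta)) + 1) / (n_perm + 1)
    data.frame(cluster = cl, n = length(rows), delta = delta, p = p)
  })
  do.call(rbind, out)
}
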