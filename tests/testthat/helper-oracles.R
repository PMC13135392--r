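# Independent brute-force oracles, shared across test files. These
# re-derive expected values from first principles and share no code with
# the implementation paths they check.

# Recovery-curve AUC: walk the top ranks, count members.
oracle_auc <- function(ranking, set, top_frac) {
  X <- ceiling(top_frac * length(ranking))
  y <- numeric(X)
  seen <- 0
  for (x in seq_len(X)) {
    if (ranking[x] %in% set) seen <- seen + 1
    y[x] <- seen
  }
  sum(y) / (X * min(length(set), X))
}

# Motif deviation z: explicit loops over cells, motifs and background sets.
oracle_deviation_z <- function(counts, membership, background_sets) {
  counts <- as.matrix(counts)
  totals <- rowSums(counts)
  frac <- colSums(counts) / sum(counts)
  dev_for <- function(peak_ids) {
    sapply(seq_len(ncol(membership)), function(m) {
      members <- which(membership[, m] == 1)
      obs <- rowSums(counts[, peak_ids[members], drop = FALSE])
      expd <- totals * sum(frac[peak_ids[members]])
      (obs - expd) / expd
    })
  }
  raw <- dev_for(seq_len(nrow(membership)))
  bgs <- lapply(background_sets, dev_for)
  bg_mean <- Reduce(`+`, bgs) / length(bgs)
  bg_sd <- sqrt(Reduce(`+`, lapply(bgs, function(b) (b - bg_mean)^2)) /
                (length(bgs) - 1))
  (raw - bg_mean) / bg_sd
}

# Run caller: per-base scan, threshold, min-run filter, gap merge.
oracle_call_runs <- function(values, in_peak, thr, min_run, gap) {
  ok <- abs(values) >= thr & in_peak
  runs <- rle(ok)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  keep <- runs$values & runs$lengths >= min_run
  iv <- cbind(starts[keep], ends[keep])
  if (!nrow(iv)) return(iv)
  merged <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv[i, 1] - merged[nrow(merged), 2] - 1 <= gap)
      merged[nrow(merged), 2] <- iv[i, 2]
    else merged <- rbind(merged, iv[i, ])
  }
  merged
}
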