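# Shared fixture builders. All synthetic, built in code at test time.

toy_track <- function(values, chrom = "chr1") {
  contribution_track(setNames(list(values), chrom))
}

toy_granges <- function(starts, ends, chrom = "chr1", strand = "*", ...) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends),
                               strand = strand)
  mc <- list(...)
  for (nm in names(mc)) S4Vectors::mcols(gr)[[nm]] <- mc[[nm]]
  gr
}

# Per-base membership oracle: the set of (chrom, base) pairs covered.
base_set <- function(gr) {
  if (length(gr) == 0) return(character(0))
  unlist(lapply(seq_along(gr), function(i) {
    paste0(GenomicRanges::seqnames(gr)[i], ":",
           seq(GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i]))
  }))
}

# One-hot style PFM from a consensus of unambiguous bases.
consensus_pfm <- function(consensus, hi = 10, lo = 0) {
  bases <- strsplit(consensus, "")[[1]]
  pfm <- matrix(lo, 4, length(bases), dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(bases)) pfm[bases[j], j] <- hi
  pfm
}

small_sim_config <- function(seed = 1, ...) {
  simulation_config(seed = seed, n_chrom = 2, chrom_length = 12000,
                    n_cells_per_group = 50, depth = 1000, ...)
}
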