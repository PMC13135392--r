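#' Per-base contribution tracks
#'
#' A contribution track stores one signed real value per base of a genome
#' (attribution scores of an accessibility model). Internally it is a named
#' `RleList`, one run-length-encoded numeric vector per chromosome.
#'
#' @param values Named list of numeric vectors (or `Rle`s), one per chromosome.
#' @return A numeric `RleList` of class use throughout the package.
#' @export
contribution_track <- function(values) {
  if (is(values, "RleList")) return(values)
  stopifnot(is.list(values), !is.null(names(values)))
  do.call(IRanges::RleList, lapply(values, S4Vectors::Rle))
}

track_chrom_lengths <- function(track) {
  setNames(lengths(track), names(track))
}

#' Read a bedGraph file into a contribution track
#'
#' bedGraph records are 0-based half-open; bases not covered by any record
#' are zero. Overlapping records within a chromosome are an error.
#'
#' @param path bedGraph file (4 columns: chrom, start, end, value).
#' @param chrom_lengths Optional named lengths; defaults to the maximal end
#'   seen per chromosome.
#' @return An `RleList` with one numeric value per base.
#' @export
read_bedgraph <- function(path, chrom_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) == 0) stop("empty bedGraph: ", path)
  if (!is.numeric(gr$score) || anyNA(gr$score))
    stop("non-numeric value in bedGraph: ", path)
  red <- GenomicRanges::reduce(GenomicRanges::granges(gr))
  if (sum(GenomicRanges::width(red)) < sum(GenomicRanges::width(gr)))
    stop("overlapping bedGraph records in ", path)
  chroms <- as.character(GenomeInfoDb::seqnames(GenomeInfoDb::seqinfo(gr)))
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(split(GenomicRanges::end(gr),
                                  as.character(GenomicRanges::seqnames(gr))),
                            max, numeric(1))
    chrom_lengths <- chrom_lengths[order(match(names(chrom_lengths), chroms))]
  }
  GenomeInfoDb::seqlengths(gr) <- chrom_lengths[GenomeInfoDb::seqlevels(gr)]
  GenomicRanges::coverage(gr, weight = "score")
}

#' Write a contribution track as bedGraph
#'
#' Adjacent equal-valued runs are merged into single records; values are
#' written with 17 significant digits so that write-then-read returns
#' bit-identical doubles.
#'
#' @param track An `RleList` (see [contribution_track()]).
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track)) {
    r <- S4Vectors::Rle(track[[chrom]])
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- c(0, ends[-length(ends)])      # 0-based half-open on disk
    vals <- S4Vectors::runValue(r)
    writeLines(sprintf("%s\t%d\t%d\t%.17g", chrom, starts, ends, vals), con)
  }
  invisible(path)
}

# Subset a track to one window, as a plain numeric vector.
track_window <- function(track, chrom, start, end) {
  as.numeric(S4Vectors::window(track[[chrom]], start = start, end = end))
}

#' Call signal peaks on a contribution track
#'
#' Attribution tracks are real-valued, not count-based, so regions of
#' concentrated contribution are called as maximal runs of at least
#' `min_run` consecutive bases with `|score| >= min_abs_score`, restricted to
#' a prior peak set; runs separated by at most `merge_gap` bases are merged.
#'
#' @param track An `RleList` contribution track.
#' @param peaks `GRanges` to restrict scanning to (the track is intersected
#'   with these regions before calling).
#' @param min_abs_score Absolute-score threshold; default the 95th percentile
#'   of `|score|` within `peaks`.
#' @param min_run Minimum run length in bases (>= 1).
#' @param merge_gap Maximum gap between runs that still get merged.
#' @return A sorted `GRanges` of called regions, contained in `peaks`.
#' @export
call_contribution_peaks <- function(track, peaks, min_abs_score = NULL,
                                    min_run = 5, merge_gap = 10) {
  if (min_run < 1) stop("min_run must be >= 1")
  chroms <- names(track)
  lens <- track_chrom_lengths(track)
  pk <- peaks[as.character(GenomicRanges::seqnames(peaks)) %in% chroms]
  if (is.null(min_abs_score)) {
    vals <- unlist(lapply(seq_along(pk), function(i) {
      abs(track_window(track, as.character(GenomicRanges::seqnames(pk)[i]),
                       GenomicRanges::start(pk)[i],
                       min(GenomicRanges::end(pk)[i],
                           lens[[as.character(GenomicRanges::seqnames(pk)[i])]])))
    }))
    min_abs_score <- as.numeric(quantile(vals, 0.95))
  }
  out <- list()
  for (chrom in chroms) {
    in_pk <- rep(FALSE, lens[[chrom]])
    pkc <- pk[as.character(GenomicRanges::seqnames(pk)) == chrom]
    for (i in seq_along(pkc)) {
      s <- max(1L, GenomicRanges::start(pkc)[i])
      e <- min(lens[[chrom]], GenomicRanges::end(pkc)[i])
      if (s <= e) in_pk[s:e] <- TRUE
    }
    ok <- (abs(as.numeric(track[[chrom]])) >= min_abs_score) & in_pk
    rr <- rle(ok)
    ends <- cumsum(rr$lengths)
    starts <- ends - rr$lengths + 1L
    runs <- IRanges::IRanges(starts[rr$values], ends[rr$values])
    runs <- runs[IRanges::width(runs) >= min_run]
    if (length(runs) == 0) next
    merged <- IRanges::reduce(runs, min.gapwidth = merge_gap + 1L)
    out[[chrom]] <- GenomicRanges::GRanges(chrom, merged)
  }
  if (!length(out)) return(GenomicRanges::GRanges())
  GenomicRanges::sort(do.call(c, unname(out)), ignore.strand = TRUE)
}
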