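#' Read a BED file as a GRanges
#'
#' BED is 0-based half-open on disk; the returned `GRanges` follows the usual
#' 1-based closed Bioconductor convention (conversion happens here, at the
#' format boundary, and nowhere else).
#'
#' @param path BED3/BED6 file.
#' @return A `GRanges`, with `name`/`score` columns when present.
#' @export
read_bed <- function(path) {
  rtracklayer::import(path, format = "BED")
}

#' Write a GRanges as BED6
#'
#' Output is sorted for deterministic bytes; scores default to 0 and names to
#' `region_<i>` when absent.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @export
write_bed <- function(gr, path) {
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  if (is.null(gr$name)) gr$name <- sprintf("region_%d", seq_along(gr))
  if (is.null(gr$score)) gr$score <- 0
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Intersect two interval sets
#'
#' Returns the parts of `a` that overlap any interval of `b` (BEDTools
#' `intersect` semantics on the underlying base sets; adjacent output pieces
#' are merged). Strand is ignored.
#'
#' @param a,b `GRanges` objects.
#' @return A sorted `GRanges` covering exactly the bases in both inputs.
#' @export
intersect_intervals <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) return(GenomicRanges::GRanges())
  out <- suppressWarnings(GenomicRanges::intersect(
    GenomicRanges::granges(a), GenomicRanges::granges(b),
    ignore.strand = TRUE
  ))
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

#' Nearest gene for each region
#'
#' Assigns every region its closest gene by genomic distance (0 when
#' overlapping or book-ended). Distance ties are broken toward the gene with
#' the smaller start coordinate and flagged. Regions on chromosomes absent
#' from the annotation get `NA` gene.
#'
#' @param regions `GRanges` of query regions.
#' @param genes `GRanges` gene annotation with a `name` column (or names).
#' @return data.frame with one row per region: `region`, `gene`,
#'   `distance` (signed: negative when the gene lies upstream of the region),
#'   `tie` flag.
#' @export
assign_nearest_gene <- function(regions, genes) {
  if (length(genes) == 0) stop("gene annotation is empty")
  gene_names <- genes$name %||% names(genes)
  if (is.null(gene_names)) gene_names <- sprintf("gene_%d", seq_along(genes))
  region_names <- regions$name %||% names(regions)
  if (is.null(region_names)) region_names <- sprintf("region_%d", seq_along(regions))

  gchrom <- as.character(GenomicRanges::seqnames(genes))
  rchrom <- as.character(GenomicRanges::seqnames(regions))
  out <- data.frame(region = region_names, gene = NA_character_,
                    distance = NA_integer_, tie = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(regions)) {
    cand <- which(gchrom == rchrom[i])
    if (!length(cand)) next
    d <- suppressWarnings(GenomicRanges::distance(regions[i], genes[cand],
                                                  ignore.strand = TRUE))
    best <- cand[which(d == min(d))]
    tie <- length(best) > 1
    # tie-break toward the smaller gene start
    g <- best[which.min(GenomicRanges::start(genes)[best])]
    dist <- min(d)
    sign <- 0L
    if (dist > 0) {
      sign <- if (GenomicRanges::start(genes)[g] > GenomicRanges::end(regions)[i]) 1L else -1L
    }
    out$gene[i] <- gene_names[g]
    out$distance[i] <- sign * dist
    out$tie[i] <- tie
  }
  out
}
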