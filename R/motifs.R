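IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

iupac_for_bases <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  code <- names(IUPAC_CODES)[match(key, IUPAC_CODES)]
  if (is.na(code)) stop("no IUPAC code for base set: ", key)
  code
}

#' Construct a motif model
#'
#' A motif is a named position frequency matrix (PFM, rows A/C/G/T) with a
#' derived IUPAC consensus and a log-odds score threshold used when scanning
#' in PWM mode.
#'
#' @param name Motif name (e.g. `"FOS::JUN"`).
#' @param pfm 4 x L non-negative matrix with rownames A, C, G, T.
#' @param min_score Log-odds threshold in bits for PWM scanning.
#' @param id Optional accession (e.g. a JASPAR ID).
#' @return An object of class `motif_model`.
#' @export
motif_model <- function(name, pfm, min_score = 10, id = NULL) {
  pfm <- as.matrix(pfm)
  if (nrow(pfm) != 4) stop("PFM must have 4 rows (A, C, G, T)")
  rownames(pfm) <- c("A", "C", "G", "T")
  if (ncol(pfm) < 4) stop("motif length must be >= 4")
  if (any(pfm < 0)) stop("PFM counts must be non-negative")
  if (any(colSums(pfm) <= 0)) stop("every PFM column must have positive total count")
  structure(
    list(name = name, id = id, pfm = pfm,
         consensus = consensus_from_pfm(pfm), min_score = min_score),
    class = "motif_model"
  )
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("motif_model %s%s: %s (length %d, min_score %g)\n",
              x$name, if (!is.null(x$id)) paste0(" [", x$id, "]") else "",
              x$consensus, ncol(x$pfm), x$min_score))
  invisible(x)
}

motif_length <- function(motif) ncol(motif$pfm)

#' Derive the IUPAC consensus of a PFM
#'
#' The consensus letter of each column is the maximum-count base; ties yield
#' the IUPAC ambiguity code covering the tied bases.
#'
#' @param pfm 4 x L matrix with rownames A, C, G, T.
#' @return Consensus string of length L.
#' @export
consensus_from_pfm <- function(pfm) {
  letters <- apply(pfm, 2, function(col) {
    iupac_for_bases(rownames(pfm)[col == max(col)])
  })
  paste(letters, collapse = "")
}

#' Read a JASPAR-format PFM file
#'
#' Parses the JASPAR 2016+ text dialect: a `>ID name` header followed by four
#' rows `A [ 4 19 0 ... ]` in A, C, G, T order.
#'
#' @param path Path to the PFM file.
#' @param min_score Score threshold to attach to each motif.
#' @return A `motif_model`, or a named list of them when the file holds
#'   several records.
#' @export
read_jaspar_pfm <- function(path, min_score = 10) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no JASPAR '>' header found in ", path)
  parse_one <- function(block) {
    hdr <- strsplit(sub("^>\\s*", "", block[1]), "\\s+")[[1]]
    id <- hdr[1]
    name <- if (length(hdr) > 1) paste(hdr[-1], collapse = " ") else hdr[1]
    if (length(block) < 5) stop("JASPAR record ", id, " is missing PFM rows")
    rows <- lapply(block[2:5], function(line) {
      base <- sub("^\\s*([ACGT]).*", "\\1", line)
      nums <- sub("^\\s*[ACGT]\\s*\\[?", "", line)
      nums <- sub("\\]\\s*$", "", nums)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(nums), "\\s+")[[1]]))
      if (anyNA(vals)) stop("non-numeric PFM counts in record ", id)
      list(base = base, vals = vals)
    })
    bases <- vapply(rows, `[[`, character(1), "base")
    if (!identical(bases, c("A", "C", "G", "T")))
      stop("JASPAR record ", id, " rows must be A, C, G, T in order")
    lens <- lengths(lapply(rows, `[[`, "vals"))
    if (length(unique(lens)) != 1)
      stop("ragged PFM columns in record ", id)
    pfm <- do.call(rbind, lapply(rows, `[[`, "vals"))
    motif_model(name = name, pfm = pfm, min_score = min_score, id = id)
  }
  ends <- c(starts[-1] - 1L, length(lines))
  motifs <- lapply(seq_along(starts),
                   function(i) parse_one(lines[starts[i]:ends[i]]))
  if (length(motifs) == 1) return(motifs[[1]])
  setNames(motifs, vapply(motifs, `[[`, character(1), "name"))
}

#' Write motifs in JASPAR PFM format
#'
#' @param motifs A `motif_model` or list of them.
#' @param path Output path.
#' @export
write_jaspar_pfm <- function(motifs, path) {
  if (is(motifs, "motif_model")) motifs <- list(motifs)
  out <- unlist(lapply(motifs, function(m) {
    c(sprintf(">%s %s", m$id %||% m$name, m$name),
      vapply(c("A", "C", "G", "T"), function(b) {
        sprintf("%s [ %s ]", b, paste(format(m$pfm[b, ], trim = TRUE), collapse = " "))
      }, character(1)))
  }))
  writeLines(out, path)
  invisible(path)
}

#' The AP-1 (FOS::JUN) motif used throughout the synthetic analyses
#'
#' Consensus TGAGTCA with a strongly peaked PFM; the canonical binding
#' element of JUN/FOS dimers including FOSL2/FRA-2.
#'
#' @param counts Per-column total count mass (default 100).
#' @return A `motif_model`.
#' @export
ap1_motif <- function(counts = 100) {
  consensus <- "TGAGTCA"
  bases <- strsplit(consensus, "")[[1]]
  pfm <- matrix(1, nrow = 4, ncol = length(bases),
                dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(bases)) pfm[bases[j], j] <- counts - 3
  motif_model("FOS::JUN", pfm, min_score = 10, id = "AP1")
}

# Log2-odds position weight matrix against a background base composition.
pwm_from_pfm <- function(pfm, background = NULL, pseudocount = 0.8) {
  if (is.null(background)) background <- c(A = 0.295, C = 0.205, G = 0.205, T = 0.295)
  background <- background / sum(background)
  freq <- t(t(pfm + pseudocount * background) / (colSums(pfm) + pseudocount))
  log2(freq / background)
}
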