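#' Simulation configuration
#'
#' One seeded configuration fully determines every synthetic output;
#' per-output sub-seeds are derived deterministically from `seed`.
#'
#' @param seed Integer master seed.
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of each chromosome in bases.
#' @param condition_names Condition labels; the first is the reference
#'   ("control"), all later ones are treated as disease-like.
#' @param noise_sd Gaussian noise SD of the contribution tracks.
#' @param contribution_level Planted seqlet contribution level (track units).
#' @param n_cells_per_group Cells simulated per condition.
#' @param depth Mean per-cell sequencing depth (total counts).
#' @param gc Background GC fraction of the genome (default 0.41, human-like).
#' @param nb_dispersion Negative-binomial dispersion of expression counts
#'   (default 0.1, a typical scRNA overdispersion scale).
#' @param planting_margin Bases kept free of planted motifs at chromosome
#'   ends so that flanked profile windows always fit.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L, n_chrom = 2L, chrom_length = 50000L,
                              condition_names = c("control", "disease"),
                              noise_sd = 0.1, contribution_level = 1,
                              n_cells_per_group = 100L, depth = 2000,
                              gc = 0.41, nb_dispersion = 0.1,
                              planting_margin = 100L) {
  cfg <- list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
              chrom_length = as.integer(chrom_length),
              condition_names = condition_names, noise_sd = noise_sd,
              contribution_level = contribution_level,
              n_cells_per_group = as.integer(n_cells_per_group),
              depth = depth, gc = gc, nb_dispersion = nb_dispersion,
              planting_margin = as.integer(planting_margin))
  stopifnot(cfg$n_chrom > 0, cfg$chrom_length > 0, length(condition_names) >= 2,
            cfg$noise_sd > 0, cfg$n_cells_per_group > 0, cfg$depth > 0,
            gc > 0, gc < 1, nb_dispersion > 0)
  structure(cfg, class = "simulation_config")
}

empty_seqlet_truth <- function() {
  GenomicRanges::GRanges(motif = character(0), strand_planted = character(0),
                         sequence = character(0), differential = logical(0),
                         delta = numeric(0))
}

#' Generate a synthetic genome with planted motif instances
#'
#' Background bases are i.i.d. with the configured GC fraction; exactly
#' `n_plant_per_motif` non-overlapping instances of each motif consensus are
#' planted at random positions and strands, and recorded in the truth
#' manifest. Ambiguous IUPAC consensus letters are resolved by sampling an
#' allowed base.
#'
#' @param config A [simulation_config()].
#' @param motifs List of [motif_model()] objects (or a single one).
#' @param n_plant_per_motif Instances to plant per motif.
#' @return List with `genome` (a `DNAStringSet`) and `truth` (a
#'   `planting_truth` list holding the seqlet `GRanges` manifest).
#' @export
generate_genome <- function(config, motifs, n_plant_per_motif = 50) {
  if (is(motifs, "motif_model")) motifs <- list(motifs)
  max_len <- max(vapply(motifs, motif_length, numeric(1)))
  if (config$chrom_length <= 2 * (max_len + config$planting_margin))
    stop("chromosomes too short for planting margin")
  set.seed(sub_seed(config$seed, "genome"))
  chroms <- sprintf("chr%d", seq_len(config$n_chrom))
  p <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
         G = config$gc / 2, T = (1 - config$gc) / 2)
  seqs <- lapply(chroms, function(ch) {
    sample(names(p), config$chrom_length, replace = TRUE, prob = p)
  })
  names(seqs) <- chroms

  occupied <- lapply(chroms, function(ch) logical(config$chrom_length))
  names(occupied) <- chroms
  rec <- list()
  total_requested <- n_plant_per_motif * length(motifs)
  if (total_requested * (max_len + 1) >
      0.5 * config$n_chrom * (config$chrom_length - 2 * config$planting_margin))
    stop("infeasible planting density: too many instances requested")

  for (m in motifs) {
    len <- motif_length(m)
    letters <- strsplit(m$consensus, "")[[1]]
    if (!all(letters %in% names(IUPAC_CODES)))
      stop("unknown IUPAC letter in consensus of ", m$name)
    placed <- 0L
    tries <- 0L
    max_tries <- max(1000L, 200L * n_plant_per_motif)
    while (placed < n_plant_per_motif) {
      tries <- tries + 1L
      if (tries > max_tries)
        stop("infeasible planting density: could not place ", m$name,
             " instance ", placed + 1L)
      ch <- chroms[sample.int(length(chroms), 1)]
      start <- config$planting_margin +
        sample.int(config$chrom_length - 2L * config$planting_margin - len + 1L, 1)
      span <- start:(start + len - 1L)
      if (any(occupied[[ch]][span])) next
      strand <- sample(c("+", "-"), 1)
      inst <- vapply(letters, function(l) {
        allowed <- strsplit(IUPAC_CODES[[l]], "")[[1]]
        if (length(allowed) == 1) allowed else sample(allowed, 1)
      }, character(1))
      planted <- paste(inst, collapse = "")
      if (strand == "-")
        planted <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(planted)))
      seqs[[ch]][span] <- strsplit(planted, "")[[1]]
      occupied[[ch]][span] <- TRUE
      placed <- placed + 1L
      rec[[length(rec) + 1L]] <- data.frame(
        chrom = ch, start = start, end = start + len - 1L, strand = strand,
        motif = m$name, sequence = planted, stringsAsFactors = FALSE)
    }
  }

  genome <- Biostrings::DNAStringSet(vapply(seqs, paste, character(1), collapse = ""))
  names(genome) <- chroms
  seqinfo <- GenomeInfoDb::Seqinfo(chroms, seqlengths = rep(config$chrom_length,
                                                            config$n_chrom))
  if (length(rec)) {
    df <- do.call(rbind, rec)
    seqlets <- GenomicRanges::GRanges(df$chrom,
                                      IRanges::IRanges(df$start, df$end),
                                      strand = df$strand, seqinfo = seqinfo)
    seqlets$motif <- df$motif
    seqlets$sequence <- df$sequence
    seqlets$differential <- FALSE
    seqlets$delta <- 1
    seqlets <- GenomicRanges::sort(seqlets, ignore.strand = TRUE)
  } else {
    seqlets <- GenomicRanges::GRanges(seqinfo = seqinfo)
    seqlets$motif <- character(0); seqlets$sequence <- character(0)
    seqlets$differential <- logical(0); seqlets$delta <- numeric(0)
  }
  truth <- structure(list(seqlets = seqlets, seqinfo = seqinfo,
                          de_genes = NULL, grn = NULL),
                     class = "planting_truth")
  list(genome = genome, truth = truth)
}

#' Generate per-condition contribution tracks with planted differentials
#'
#' Background positions are Normal(0, `noise_sd`); every planted seqlet gets
#' an elevated positive contribution (`contribution_level`) in every
#' condition, and a random `differential_fraction` of seqlets is additionally
#' multiplied by `delta` in the non-reference ("disease") conditions only.
#' The peak set is the planted-seqlet neighborhoods plus decoy intervals.
#'
#' @param truth The `planting_truth` from [generate_genome()].
#' @param config A [simulation_config()].
#' @param differential_fraction Fraction of seqlets made differential.
#' @param delta Multiplicative contribution elevation (> 0) in disease.
#' @param peak_flank Bases of neighborhood around each seqlet in the peak set.
#' @param decoy_ratio Decoy peaks per motif window (default 3, so
#'   motif-bearing peaks are a minority of the peak universe, as in real
#'   peak sets; capped by the available motif-free genome space).
#' @return List with `tracks` (named list of `RleList`, one per condition),
#'   `peaks` (`GRanges` with a `motif` flag), and the updated `truth`.
#' @export
generate_contribution_tracks <- function(truth, config,
                                         differential_fraction = 0.25,
                                         delta = 2, peak_flank = 100L,
                                         decoy_ratio = 3) {
  if (delta <= 0) stop("delta must be > 0")
  if (differential_fraction < 0 || differential_fraction > 1)
    stop("differential_fraction must be in [0, 1]")
  seqlets <- truth$seqlets
  n <- length(seqlets)
  if (n == 0 && differential_fraction > 0)
    stop("no planted seqlets but differential_fraction > 0")
  set.seed(sub_seed(config$seed, "tracks"))
  n_diff <- round(differential_fraction * n)
  diff_idx <- if (n_diff > 0) sort(sample.int(n, n_diff)) else integer(0)
  if (n > 0) {
    seqlets$differential <- seq_len(n) %in% diff_idx
    seqlets$delta <- ifelse(seqlets$differential, delta, 1)
  }
  chroms <- as.character(GenomeInfoDb::seqnames(truth$seqinfo))
  lens <- setNames(GenomeInfoDb::seqlengths(truth$seqinfo), chroms)

  sl_chrom <- as.character(GenomicRanges::seqnames(seqlets))
  sl_start <- GenomicRanges::start(seqlets)
  sl_end <- GenomicRanges::end(seqlets)
  sl_diff <- seqlets$differential
  level_for <- function(chrom, disease) {
    lev <- rep(0, lens[[chrom]])
    for (i in which(sl_chrom == chrom)) {
      val <- config$contribution_level
      if (disease && sl_diff[i]) val <- val * delta
      lev[sl_start[i]:sl_end[i]] <- val
    }
    lev
  }
  tracks <- list()
  for (cond in config$condition_names) {
    disease <- cond != config$condition_names[1]
    vals <- lapply(chroms, function(ch) {
      level_for(ch, disease) + rnorm(lens[[ch]], 0, config$noise_sd)
    })
    names(vals) <- chroms
    tracks[[cond]] <- contribution_track(vals)
  }

  # peaks: seqlet neighborhoods + an equal number of non-overlapping decoys
  if (n > 0) {
    windows <- GenomicRanges::reduce(
      GenomicRanges::resize(GenomicRanges::granges(seqlets),
                            width = GenomicRanges::width(seqlets) + 2L * peak_flank,
                            fix = "center"),
      ignore.strand = TRUE)
    GenomicRanges::start(windows) <- pmax(1L, GenomicRanges::start(windows))
    GenomicRanges::end(windows) <- pmin(lens[as.character(GenomicRanges::seqnames(windows))],
                                        GenomicRanges::end(windows))
  } else {
    windows <- GenomicRanges::GRanges(seqinfo = truth$seqinfo)
  }
  # decoys: as many non-overlapping motif-free intervals as space allows,
  # up to the number of motif windows (fast occupancy-vector placement)
  w <- max(2L * peak_flank + 7L, 50L)
  occ <- lapply(chroms, function(ch) {
    v <- logical(lens[[ch]])
    wc <- windows[as.character(GenomicRanges::seqnames(windows)) == ch]
    for (i in seq_along(wc))
      v[GenomicRanges::start(wc)[i]:GenomicRanges::end(wc)[i]] <- TRUE
    v
  })
  names(occ) <- chroms
  free <- sum(vapply(occ, function(v) sum(!v), numeric(1)))
  n_decoy <- min(max(ceiling(decoy_ratio * n), 10L), floor(free / (2L * w)))
  dec_chrom <- character(0); dec_start <- integer(0)
  tries <- 0L
  while (length(dec_start) < n_decoy && tries < 50L * n_decoy) {
    tries <- tries + 1L
    ch <- sample(chroms, 1)
    start <- sample.int(lens[[ch]] - w, 1)
    span <- start:(start + w - 1L)
    if (any(occ[[ch]][span])) next
    occ[[ch]][span] <- TRUE
    dec_chrom <- c(dec_chrom, ch); dec_start <- c(dec_start, start)
  }
  decoys <- GenomicRanges::GRanges(dec_chrom,
                                   IRanges::IRanges(dec_start, width = w),
                                   seqinfo = truth$seqinfo)
  peaks <- suppressWarnings(c(GenomicRanges::granges(windows),
                              GenomicRanges::granges(decoys)))
  peaks$motif <- c(rep(TRUE, length(windows)), rep(FALSE, length(decoys)))
  peaks <- GenomicRanges::sort(peaks, ignore.strand = TRUE)
  GenomeInfoDb::seqinfo(peaks) <- truth$seqinfo

  truth$seqlets <- seqlets
  list(tracks = tracks, peaks = peaks, truth = truth)
}

#' Generate a cell-by-peak accessibility count matrix
#'
#' Counts are Poisson with per-cell depth and per-peak weights; motif-bearing
#' peaks get their weight multiplied by `group_effect` in the affected
#' (non-reference) group, and weights are renormalized within a group so the
#' expected total equals the drawn depth. Per-peak GC content is computed
#' from the genome when supplied.
#'
#' @param peaks `GRanges` with a logical `motif` column.
#' @param config A [simulation_config()].
#' @param group_effect Multiplier (> 0) on motif-bearing peak weights in the
#'   affected group.
#' @param genome Optional `DNAStringSet` to compute per-peak GC from.
#' @return List with `counts` (sparse cells x peaks), `cells` (data.frame
#'   with `cell_id`, `group`, `depth`) and `peaks` (the input with `gc` and
#'   `mean_acc` columns filled).
#' @export
generate_accessibility_matrix <- function(peaks, config, group_effect = 1.5,
                                          genome = NULL) {
  if (length(peaks) == 0) stop("zero peaks")
  if (config$n_cells_per_group <= 0) stop("zero cells")
  if (group_effect <= 0) stop("group_effect must be > 0")
  groups <- config$condition_names
  if (length(groups) < 2) stop("need >= 2 groups")
  set.seed(sub_seed(config$seed, "accessibility"))

  if (!is.null(genome)) {
    gc <- vapply(seq_along(peaks), function(i) {
      ch <- as.character(GenomicRanges::seqnames(peaks)[i])
      s <- Biostrings::subseq(genome[[ch]], GenomicRanges::start(peaks)[i],
                              GenomicRanges::end(peaks)[i])
      as.numeric(Biostrings::letterFrequency(s, "GC", as.prob = TRUE))
    }, numeric(1))
    peaks$gc <- gc
  } else if (is.null(peaks$gc)) {
    peaks$gc <- runif(length(peaks), 0.3, 0.6)
  }

  base_w <- rgamma(length(peaks), shape = 2, rate = 2) + 0.05
  n_cells <- config$n_cells_per_group * length(groups)
  depths <- round(config$depth * exp(rnorm(n_cells, 0, 0.25)))
  cell_group <- rep(groups, each = config$n_cells_per_group)
  counts <- matrix(0L, nrow = n_cells, ncol = length(peaks))
  for (g in groups) {
    w <- base_w
    if (g != groups[1]) w[peaks$motif] <- w[peaks$motif] * group_effect
    w <- w / sum(w)
    rows <- which(cell_group == g)
    lam <- outer(depths[rows], w)
    counts[rows, ] <- rpois(length(lam), lam)
  }
  peak_ids <- sprintf("peak_%d", seq_along(peaks))
  peaks$name <- peak_ids
  dimnames(counts) <- list(sprintf("cell_%03d", seq_len(n_cells)), peak_ids)
  peaks$mean_acc <- colMeans(counts)
  list(
    counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
    cells = data.frame(cell_id = rownames(counts), group = cell_group,
                       depth = depths, stringsAsFactors = FALSE),
    peaks = peaks
  )
}

#' Build a random planted TF-to-target GRN
#'
#' The first TF is the designated disease driver. Weights are drawn from a
#' mixture of moderate and strong effects of either sign; the planted graph
#' is bipartite TF -> target and therefore acyclic.
#'
#' @param n_tf Number of transcription factors (`TF01` is the driver,
#'   renamed `FOSL2`).
#' @param n_targets Number of target genes.
#' @param targets_per_tf Mean out-degree per TF.
#' @param seed Seed.
#' @return data.frame with columns `tf`, `target`, `weight`.
#' @export
plant_grn <- function(n_tf = 10, n_targets = 200, targets_per_tf = 20,
                      seed = 1L) {
  set.seed(sub_seed(seed, "plant_grn"))
  tfs <- c("FOSL2", sprintf("TF%02d", seq_len(n_tf - 1)))
  targets <- sprintf("TGT%03d", seq_len(n_targets))
  edges <- do.call(rbind, lapply(tfs, function(tf) {
    k <- min(n_targets, max(1L, rpois(1, targets_per_tf)))
    tg <- sample(targets, k)
    w <- sample(c(-1, 1), k, replace = TRUE) * runif(k, 0.2, 1.2)
    data.frame(tf = tf, target = tg, weight = w, stringsAsFactors = FALSE)
  }))
  rownames(edges) <- NULL
  edges
}

#' Generate expression counts driven by a planted GRN
#'
#' Latent log2 expression is propagated through the planted edge weights
#' (linear structural equations in topological order) with Gaussian noise;
#' counts are negative binomial around `2^latent` with a per-cell size
#' factor. The designated driver TF is shifted up by `driver_shift` log2
#' units in the disease group, so each target's planted log2 effect is the
#' summed path weight times the shift. A second "mouse-like" namespace with
#' Title-case symbols is emitted with an ortholog table.
#'
#' @param grn_spec data.frame of planted edges (`tf`, `target`, `weight`).
#' @param config A [simulation_config()].
#' @param driver_tf Driver TF symbol (must appear in `grn_spec$tf`).
#' @param driver_shift Log2 shift of the driver in the disease group.
#' @param expr_noise_sd Intrinsic Gaussian noise SD of target-gene latent
#'   log2 expression.
#' @param tf_latent_sd Cell-to-cell SD of exogenous regulator latent
#'   expression (log2); regulators vary more than their targets' intrinsic
#'   noise, as variable driver genes do in single-cell data.
#' @param n_background_genes Unconnected genes added for realism.
#' @return List with `human` and `mouse` (each `counts` genes x cells plus
#'   `cells` metadata), `de_genes` truth records, `orthologs` table, and the
#'   input `grn`.
#' @export
generate_expression_data <- function(grn_spec, config, driver_tf = "FOSL2",
                                     driver_shift = 1, expr_noise_sd = 0.3,
                                     tf_latent_sd = 1,
                                     n_background_genes = 50) {
  ord <- topological_order(grn_spec$tf, grn_spec$target)
  if (is.null(ord)) stop("planted GRN contains a cycle")
  if (!driver_tf %in% grn_spec$tf) stop("driver_tf not a TF in grn_spec")
  genes <- union(ord, sprintf("BG%03d", seq_len(n_background_genes)))

  # planted total effect of the driver shift on every gene (path propagation)
  effect <- setNames(numeric(length(genes)), genes)
  effect[driver_tf] <- driver_shift
  for (g in ord) {
    inc <- grn_spec[grn_spec$target == g, ]
    if (nrow(inc)) effect[g] <- effect[g] + sum(inc$weight * effect[inc$tf])
  }
  de <- data.frame(gene = names(effect), planted_log2fc = as.numeric(effect),
                   stringsAsFactors = FALSE)
  de <- de[abs(de$planted_log2fc) > 1e-12, ]

  simulate_ns <- function(ns_label, group_names) {
    set.seed(sub_seed(config$seed, paste0("expression_", ns_label)))
    baseline <- setNames(runif(length(genes), 1.5, 4), genes)
    n_cells <- config$n_cells_per_group * 2L
    group <- rep(group_names, each = config$n_cells_per_group)
    latent <- matrix(0, nrow = length(genes), ncol = n_cells,
                     dimnames = list(genes, sprintf("%s_cell_%03d", ns_label,
                                                    seq_len(n_cells))))
    exo <- setdiff(genes, grn_spec$target)
    for (g in exo) {
      mu <- baseline[g] + ifelse(g == driver_tf & group == group_names[2],
                                 driver_shift, 0)
      sd_g <- if (g %in% grn_spec$tf) tf_latent_sd else expr_noise_sd
      latent[g, ] <- mu + rnorm(n_cells, 0, sd_g)
    }
    for (g in intersect(ord, grn_spec$target)) {
      inc <- grn_spec[grn_spec$target == g, ]
      dev <- as.numeric(crossprod(inc$weight,
                                  latent[inc$tf, , drop = FALSE] - baseline[inc$tf]))
      latent[g, ] <- baseline[g] + dev + rnorm(n_cells, 0, expr_noise_sd)
    }
    size_factor <- exp(rnorm(n_cells, 0, 0.1))
    mu <- t(t(2^latent) * size_factor)
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
                     nrow = nrow(mu), dimnames = dimnames(mu))
    list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
         cells = data.frame(cell_id = colnames(counts), group = group,
                            stringsAsFactors = FALSE),
         latent = latent)
  }

  human <- simulate_ns("hs", config$condition_names[1:2])
  mouse <- simulate_ns("mm", c("WT", "TG"))
  mouse_symbols <- to_title_symbol(genes)
  rownames(mouse$counts) <- mouse_symbols
  rownames(mouse$latent) <- mouse_symbols
  orthologs <- data.frame(mouse = mouse_symbols, human = genes,
                          stringsAsFactors = FALSE)
  list(human = human, mouse = mouse, de_genes = de, orthologs = orthologs,
       grn = grn_spec)
}

#' Simulate cells with a planted activator eRegulon and decoys
#'
#' One activator TF whose per-cell latent activity drives a graded subset of
#' regions (loadings spread over `load_range`, so region-enrichment AUC
#' responds smoothly to TF expression rather than saturating), plus decoy
#' TFs with random expression and randomly assigned target regions. Used to
#' exercise pseudo-bulk correlation filtering end to end.
#'
#' @param seed Seed.
#' @param n_cells Cells (split evenly into two conditions).
#' @param n_regions Total accessible regions.
#' @param regulon_size Regions per regulon.
#' @param n_decoys Decoy TFs.
#' @param tf_sd Cell-to-cell SD of the activator's latent activity.
#' @param load_range Range of per-region loadings on the activator.
#' @param noise_sd Region accessibility noise SD.
#' @return List with `expression` (genes x cells), `accessibility`
#'   (regions x cells), `regulons` (list of [eregulon()], activator first),
#'   `meta` (cell metadata), `activator` (TF name).
#' @export
simulate_regulon_truth <- function(seed = 1L, n_cells = 60, n_regions = 300,
                                   regulon_size = 15, n_decoys = 10,
                                   tf_sd = 2, load_range = c(0.3, 1.5),
                                   noise_sd = 1) {
  set.seed(sub_seed(seed, "regulon_truth"))
  t_act <- rnorm(n_cells, 0, tf_sd)
  regions <- sprintf("R%03d", seq_len(n_regions))
  genes <- c("ACT", sprintf("DEC%02d", seq_len(n_decoys)))
  cells <- sprintf("cell_%03d", seq_len(n_cells))
  expression <- matrix(rnorm(length(genes) * n_cells, 2, 0.5),
                       nrow = length(genes),
                       dimnames = list(genes, cells))
  expression["ACT", ] <- 2 + t_act
  accessibility <- matrix(rnorm(n_regions * n_cells, 0, noise_sd),
                          nrow = n_regions,
                          dimnames = list(regions, cells))
  load <- seq(load_range[1], load_range[2], length.out = regulon_size)
  accessibility[seq_len(regulon_size), ] <-
    accessibility[seq_len(regulon_size), ] + outer(load, t_act)
  regulons <- c(
    list(eregulon("ACT", regions[seq_len(regulon_size)])),
    lapply(seq_len(n_decoys), function(i) {
      eregulon(sprintf("DEC%02d", i), sample(regions, regulon_size))
    }))
  meta <- data.frame(cell_id = cells, cell_type = "EC",
                     condition = rep(c("control", "disease"),
                                     length.out = n_cells),
                     stringsAsFactors = FALSE)
  list(expression = expression, accessibility = accessibility,
       regulons = regulons, meta = meta, activator = "ACT")
}

#' Write a genome as FASTA
#' @param genome `DNAStringSet`.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a genome from FASTA
#' @param path FASTA file.
#' @return A `DNAStringSet`.
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write the seqlet truth manifest as BED6
#'
#' Score column is the per-seqlet contribution multiplier `delta`; strand is
#' the planted strand.
#'
#' @param truth A `planting_truth`.
#' @param path Output path.
#' @export
write_truth_bed <- function(truth, path) {
  gr <- truth$seqlets
  gr$name <- sprintf("%s_%d", gr$motif, seq_along(gr))
  gr$score <- gr$delta
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
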