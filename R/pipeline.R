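#' Pipeline configuration
#'
#' One validated configuration drives [run_pipeline()]. Defaults are the
#' printed parameters of the analyses modeled here: profile flank 30 bp,
#' k = 4 profile clusters, AUC at the top 5% of the ranking, 5-cell
#' pseudo-bulks, |r| > 0.5 regulon correlation cutoff, GRN edge p < 0.001
#' and top 2000 edges, overexpression at 1.5x the maximum, DE thresholds
#' p_adj < 0.05 and log2FC > 0.25.
#'
#' @param seed Global seed; per-stage sub-seeds are derived from it.
#' @param outdir Output directory for [run_pipeline()].
#' @param simulate Named list of overrides for [simulation_config()] plus
#'   planting sizes `n_seqlets`, `differential_fraction`, `delta`,
#'   `group_effect`, `n_tf`, `n_targets`.
#' @param flank,k,n_perm Footprint-stage parameters.
#' @param n_background Deviation-stage background sets.
#' @param top_frac,pseudobulk_size,pseudobulk_draws,correlation_cutoff
#'   eRegulon-stage parameters.
#' @param p_cutoff,max_edges,oe_factor,n_propagation GRN-stage parameters.
#' @param p_adj_max,lfc_min DE thresholds.
#' @param mc_iterations Monte-Carlo overlap iterations.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, outdir = tempfile("regshift_run_"),
                            simulate = list(), flank = 30L, k = 4L,
                            n_perm = 999L, n_background = 50L,
                            top_frac = 0.05, pseudobulk_size = 5L,
                            pseudobulk_draws = 20L,
                            correlation_cutoff = 0.5, p_cutoff = 0.001,
                            max_edges = 2000L, oe_factor = 1.5,
                            n_propagation = 3L, p_adj_max = 0.05,
                            lfc_min = 0.25, mc_iterations = 2000L) {
  cfg <- list(seed = as.integer(seed), outdir = outdir, simulate = simulate,
              flank = as.integer(flank), k = as.integer(k),
              n_perm = as.integer(n_perm),
              n_background = as.integer(n_background), top_frac = top_frac,
              pseudobulk_size = as.integer(pseudobulk_size),
              pseudobulk_draws = as.integer(pseudobulk_draws),
              correlation_cutoff = correlation_cutoff, p_cutoff = p_cutoff,
              max_edges = as.integer(max_edges), oe_factor = oe_factor,
              n_propagation = as.integer(n_propagation),
              p_adj_max = p_adj_max, lfc_min = lfc_min,
              mc_iterations = as.integer(mc_iterations))
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  if (cfg$k < 2) stop("config invalid: k must be >= 2")
  if (cfg$flank < 1) stop("config invalid: flank must be >= 1")
  if (cfg$top_frac <= 0 || cfg$top_frac > 1)
    stop("config invalid: top_frac must be in (0, 1]")
  if (cfg$pseudobulk_size < 1) stop("config invalid: pseudobulk_size >= 1")
  if (cfg$p_cutoff <= 0 || cfg$p_cutoff >= 1)
    stop("config invalid: p_cutoff in (0, 1)")
  if (cfg$max_edges < 1) stop("config invalid: max_edges >= 1")
  if (cfg$oe_factor <= 0) stop("config invalid: oe_factor > 0")
  if (cfg$n_perm < 1) stop("config invalid: n_perm >= 1")
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys are [pipeline_config()] arguments; a `simulate` mapping is
#' passed through as the simulation overrides.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic demo pipeline
#'
#' Executes every stage in dependency order on seeded synthetic data:
#' simulate (genome, contribution tracks, accessibility, GRN-driven
#' expression), footprint (scan, profiles, k-means, differential clusters,
#' nearest genes), motif deviation and ranking, eRegulon scoring/filtering
#' and RSS, GRN fitting with in-silico KO/OE and transition scores, and
#' DE/overlap statistics. Every output file is a deterministic function of
#' the configuration; a provenance record (stage, parameters, seed, input
#' digests) accompanies the outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of in-memory stage results plus `outdir` and
#'   the provenance table.
#' @export
run_pipeline <- function(config) {
  validate_pipeline_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  prov <- list()
  note <- function(file, stage, params) {
    prov[[length(prov) + 1L]] <<- list(
      file = file, stage = stage, seed = config$seed, params = params,
      md5 = unname(tools::md5sum(file.path(config$outdir, file))))
  }

  ## --- simulate ------------------------------------------------------------
  sim_args <- config$simulate
  scfg <- do.call(simulation_config, c(
    list(seed = config$seed),
    sim_args[intersect(names(sim_args), names(formals(simulation_config)))]))
  motif <- ap1_motif()
  n_seqlets <- sim_args$n_seqlets %||% 100L
  gen <- generate_genome(scfg, motif, n_plant_per_motif = n_seqlets)
  trk <- generate_contribution_tracks(
    gen$truth, scfg,
    differential_fraction = sim_args$differential_fraction %||% 0.25,
    delta = sim_args$delta %||% 2)
  acc <- generate_accessibility_matrix(trk$peaks, scfg,
                                       group_effect = sim_args$group_effect %||% 1.5,
                                       genome = gen$genome)
  grn_spec <- plant_grn(n_tf = sim_args$n_tf %||% 6,
                        n_targets = sim_args$n_targets %||% 60,
                        seed = config$seed)
  expd <- generate_expression_data(grn_spec, scfg)

  write_genome_fasta(gen$genome, file.path(config$outdir, "genome.fa"))
  write_truth_bed(trk$truth, file.path(config$outdir, "truth_seqlets.bed"))
  for (cond in names(trk$tracks))
    write_bedgraph(trk$tracks[[cond]],
                   file.path(config$outdir, sprintf("contrib_%s.bedGraph", cond)))
  write_bed(trk$peaks, file.path(config$outdir, "peaks.bed"))
  Matrix::writeMM(expd$human$counts, file.path(config$outdir, "expression_hs.mtx"))
  writeLines(rownames(expd$human$counts), file.path(config$outdir, "features_hs.txt"))
  writeLines(colnames(expd$human$counts), file.path(config$outdir, "barcodes_hs.txt"))
  write_tsv(expd$orthologs, file.path(config$outdir, "orthologs.tsv"))
  sim_files <- c("genome.fa", "truth_seqlets.bed",
                 sprintf("contrib_%s.bedGraph", names(trk$tracks)),
                 "peaks.bed", "expression_hs.mtx", "features_hs.txt",
                 "barcodes_hs.txt", "orthologs.tsv")
  for (f in sim_files) note(f, "simulate", scfg[c("seed", "n_chrom", "chrom_length")])

  ## --- footprint -----------------------------------------------------------
  seqlets <- scan_motif_instances(gen$genome, motif, mode = "consensus_exact",
                                  within = trk$peaks)
  profiles <- extract_profiles(trk$tracks, seqlets, flank = config$flank)
  clust <- kmeans_cluster_profiles(profiles, k = config$k, seed = config$seed)
  diff_tab <- score_differential_clusters(clust, profiles,
                                          n_perm = config$n_perm,
                                          seed = config$seed)
  prof_df <- data.frame(seqlet = rownames(profiles$matrix),
                        cluster = clust$assignment,
                        profiles$matrix, check.names = FALSE)
  write_tsv(prof_df, file.path(config$outdir, "seqlet_profiles.tsv"))
  write_tsv(diff_tab, file.path(config$outdir, "cluster_differential.tsv"))
  note("seqlet_profiles.tsv", "footprint",
       list(flank = config$flank, k = config$k))
  note("cluster_differential.tsv", "footprint",
       list(n_perm = config$n_perm))

  ## --- deviation -----------------------------------------------------------
  ov <- GenomicRanges::findOverlaps(trk$peaks, seqlets, ignore.strand = TRUE)
  membership <- matrix(0L, nrow = length(trk$peaks), ncol = 1,
                       dimnames = list(trk$peaks$name, motif$name))
  membership[unique(S4Vectors::queryHits(ov)), 1] <- 1L
  dev <- compute_deviation_zscores(acc$counts, membership, gc = trk$peaks$gc,
                                   n_background = config$n_background,
                                   seed = config$seed)
  ranked <- rank_differential_motifs(dev, acc$cells$group)
  write_tsv(data.frame(cell_id = rownames(dev$z), dev$z, check.names = FALSE),
            file.path(config$outdir, "motif_deviations.tsv"))
  write_tsv(ranked, file.path(config$outdir, "motif_ranking.tsv"))
  note("motif_deviations.tsv", "deviation",
       list(n_background = config$n_background))
  note("motif_ranking.tsv", "deviation", list())

  ## --- eregulon ------------------------------------------------------------
  expr_norm <- log_normalize(expd$human$counts)
  acc_norm <- t(as.matrix(acc$counts))  # regions x cells
  driver_targets <- grn_spec$target[grn_spec$tf == "FOSL2" & grn_spec$weight > 0]
  ers <- list(
    eregulon("FOSL2", target_regions = driver_targets,
             target_genes = driver_targets))
  # regulon scores computed on expression of target genes (region scores in
  # the synthetic demo live in gene space)
  meta <- data.frame(cell_id = expd$human$cells$cell_id,
                     cell_type = "EC", condition = expd$human$cells$group,
                     stringsAsFactors = FALSE)
  pb <- make_pseudobulks(meta,
                         profiles = list(expression = expr_norm,
                                         accessibility = expr_norm),
                         size = config$pseudobulk_size,
                         n_draws = config$pseudobulk_draws,
                         seed = config$seed)
  ers <- filter_eregulons(ers, pb, cutoff = config$correlation_cutoff,
                          top_frac = config$top_frac)
  er_summary <- attr(ers, "summary")
  scores <- regulon_scores(expr_norm, ers, top_frac = config$top_frac)
  rss <- regulon_specificity_score(scores + 1e-9, meta$condition)
  write_tsv(er_summary, file.path(config$outdir, "eregulon_summary.tsv"))
  write_tsv(data.frame(regulon = rownames(rss), rss, check.names = FALSE),
            file.path(config$outdir, "eregulon_rss.tsv"))
  note("eregulon_summary.tsv", "eregulon",
       list(cutoff = config$correlation_cutoff, size = config$pseudobulk_size))
  note("eregulon_rss.tsv", "eregulon", list(top_frac = config$top_frac))

  ## --- grn -----------------------------------------------------------------
  base_grn <- unique(grn_spec[, c("tf", "target")])
  groups <- expd$human$cells$group
  conds <- unique(groups)
  grns <- lapply(conds, function(cond) {
    fit_grn(expr_norm[, groups == cond, drop = FALSE], base_grn,
            condition = cond, p_cutoff = config$p_cutoff,
            max_edges = config$max_edges)
  })
  names(grns) <- conds
  disease <- conds[2]
  ko <- simulate_perturbation(grns[[disease]], expr_norm, tf = "FOSL2",
                              mode = "ko", oe_factor = config$oe_factor,
                              n_propagation = config$n_propagation)
  tv <- transition_vectors(ko, expr_norm, groups, target_condition = conds[1])
  for (cond in conds)
    write_tsv(grns[[cond]]$edges,
              file.path(config$outdir, sprintf("grn_edges_%s.tsv", cond)))
  write_tsv(data.frame(cell_id = names(tv$scores), group = groups,
                       transition_score = tv$scores),
            file.path(config$outdir, "ko_transition_scores.tsv"))
  for (cond in conds)
    note(sprintf("grn_edges_%s.tsv", cond), "grn",
         list(p_cutoff = config$p_cutoff, max_edges = config$max_edges))
  note("ko_transition_scores.tsv", "grn",
       list(mode = "ko", n_propagation = config$n_propagation))

  ## --- overlap -------------------------------------------------------------
  de_hs <- wilcoxon_de(expr_norm, factor(groups, levels = base::rev(conds)))
  up_hs <- threshold_de(de_hs, p_adj_max = config$p_adj_max,
                        lfc_min = config$lfc_min, direction = "up")
  expr_mm <- log_normalize(expd$mouse$counts)
  de_mm <- wilcoxon_de(expr_mm, factor(expd$mouse$cells$group,
                                       levels = c("TG", "WT")))
  up_mm <- threshold_de(de_mm, p_adj_max = config$p_adj_max,
                        lfc_min = config$lfc_min, direction = "up")
  up_mm_hs <- map_orthologs(up_mm, expd$orthologs)$mapped
  universe <- intersect(de_hs$gene, map_orthologs(de_mm$gene,
                                                  expd$orthologs)$mapped)
  ovl <- hypergeometric_overlap(intersect(up_hs, universe),
                                intersect(unname(up_mm_hs), universe),
                                universe)
  mc <- monte_carlo_multiset_overlap(
    list(intersect(up_hs, universe), intersect(unname(up_mm_hs), universe)),
    universe, B = config$mc_iterations, seed = config$seed)
  write_tsv(de_hs, file.path(config$outdir, "de_human.tsv"))
  write_tsv(de_mm, file.path(config$outdir, "de_mouse.tsv"))
  jsonlite::write_json(
    list(hypergeometric = unclass(ovl), monte_carlo = unclass(mc)),
    file.path(config$outdir, "overlap_report.json"),
    auto_unbox = TRUE, digits = NA)
  note("de_human.tsv", "overlap",
       list(p_adj_max = config$p_adj_max, lfc_min = config$lfc_min))
  note("de_mouse.tsv", "overlap",
       list(p_adj_max = config$p_adj_max, lfc_min = config$lfc_min))
  note("overlap_report.json", "overlap", list(B = config$mc_iterations))

  ## --- provenance ----------------------------------------------------------
  jsonlite::write_json(prov, file.path(config$outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(outdir = config$outdir, truth = trk$truth, peaks = trk$peaks,
                 profiles = profiles, clusters = clust,
                 cluster_differential = diff_tab, deviations = dev,
                 motif_ranking = ranked, eregulons = ers, rss = rss,
                 grns = grns, ko = ko, transition = tv, de_human = de_hs,
                 de_mouse = de_mm, overlap = ovl, monte_carlo = mc,
                 provenance = prov))
}

#' Small, fast demo configuration
#'
#' @param outdir Output directory.
#' @param seed Seed.
#' @return A `pipeline_config` sized to run in seconds.
#' @export
demo_pipeline_config <- function(outdir = tempfile("regshift_demo_"),
                                 seed = 1L) {
  pipeline_config(
    seed = seed, outdir = outdir,
    simulate = list(n_chrom = 2L, chrom_length = 20000L,
                    n_cells_per_group = 60L, depth = 1500,
                    n_seqlets = 60L, differential_fraction = 0.25,
                    delta = 2, group_effect = 1.5, n_tf = 5L,
                    n_targets = 40L),
    n_perm = 499L, n_background = 25L, pseudobulk_draws = 15L,
    mc_iterations = 1000L)
}
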