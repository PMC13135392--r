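test_that("contribution peak calling matches the exhaustive run oracle", {
  set.seed(13)
  for (rep in 1:8) {
    v <- rnorm(500, 0, 0.3)
    v[sample(500, 60)] <- rnorm(60, 1.2, 0.2)     # plant signal bases
    trk <- toy_track(v)
    pk <- toy_granges(c(1, 301), c(250, 500))
    in_pk <- rep(FALSE, 500); in_pk[1:250] <- TRUE; in_pk[301:500] <- TRUE
    got <- call_contribution_peaks(trk, pk, min_abs_score = 0.8,
                                   min_run = 3, merge_gap = 5)
    want <- oracle_call_runs(v, in_pk, 0.8, 3, 5)
    expect_equal(unname(cbind(GenomicRanges::start(got),
                              GenomicRanges::end(got))), unname(want))
  }
})

test_that("peak calling handles the trivial cases", {
  trk <- toy_track(rep(0, 100))
  pk <- toy_granges(1, 100)
  expect_length(call_contribution_peaks(trk, pk, min_abs_score = 0.5), 0)
  v <- rep(0, 100); v[21:30] <- 1
  got <- call_contribution_peaks(toy_track(v), pk, min_abs_score = 0.5,
                                 min_run = 5)
  expect_equal(GenomicRanges::start(got), 21)
  expect_equal(GenomicRanges::end(got), 30)
  expect_error(call_contribution_peaks(trk, pk, min_abs_score = 1, min_run = 0),
               "min_run")
})

test_that("consensus scanning reports position and strand correctly", {
  genome <- Biostrings::DNAStringSet(c(chrA = "ATGAGTCAT"))
  hits <- scan_motif_instances(genome, ap1_motif(), mode = "consensus_exact")
  # 0-based start 1 == 1-based start 2, plus strand
  expect_equal(GenomicRanges::start(hits), 2)
  expect_equal(as.character(GenomicRanges::strand(hits)), "+")
  # the reverse complement TGACTCA is reported as a '-' strand hit
  genome2 <- Biostrings::DNAStringSet(c(chrA = "CCTGACTCACC"))
  hits2 <- scan_motif_instances(genome2, ap1_motif(), mode = "consensus_exact")
  expect_equal(as.character(GenomicRanges::strand(hits2)), "-")
  expect_equal(GenomicRanges::start(hits2), 3)
})

test_that("scanning the synthetic genome recovers at least the planted instances", {
  cfg <- small_sim_config(seed = 31)
  g <- generate_genome(cfg, ap1_motif(), 40)
  hits <- scan_motif_instances(g$genome, ap1_motif(), mode = "consensus_exact")
  expect_gte(length(hits), 40)
  expect_true(all(GenomicRanges::countOverlaps(g$truth$seqlets, hits,
                                               type = "equal",
                                               ignore.strand = TRUE) > 0))
})

test_that("profile extraction: geometry, edge drops, constant tracks, strand orientation", {
  lens <- 500
  tr_a <- toy_track(rep(2, lens))
  set.seed(2); tr_b <- toy_track(rnorm(lens))
  seqlets <- toy_granges(c(5, 100, 200), c(11, 106, 206),
                         strand = c("+", "+", "-"))
  expect_warning(pr <- NULL, NA)
  pr <- extract_profiles(list(a = tr_a, b = tr_b), seqlets, flank = 30)
  # 67 columns per condition (2*30 + 7); the seqlet 4 bases from the start is dropped
  expect_equal(pr$block_width, 67)
  expect_equal(ncol(pr$matrix), 134)
  expect_equal(pr$n_dropped, 1)
  expect_equal(nrow(pr$matrix), 2)
  # constant track -> constant block
  expect_true(all(pr$matrix[, 1:67] == 2))
  # '-' strand rows are reversed relative to the genome window
  fwd <- as.numeric(tr_b$chr1[(200 - 30):(206 + 30)])
  expect_equal(unname(pr$matrix[2, 68:134]), rev(fwd))
  expect_error(extract_profiles(list(a = tr_a), seqlets[integer(0)]), "zero")
})

test_that("profile extraction is translation-equivariant", {
  set.seed(6)
  v <- rnorm(300)
  offset <- 50
  t1 <- toy_track(v)
  t2 <- toy_track(c(rnorm(offset), v))
  s1 <- toy_granges(c(101, 150), c(107, 156))
  s2 <- GenomicRanges::shift(s1, offset)
  p1 <- extract_profiles(list(x = t1), s1, flank = 20)
  p2 <- extract_profiles(list(x = t2), s2, flank = 20)
  expect_equal(unname(p1$matrix), unname(p2$matrix))
})

test_that("k-means recovers planted profile archetypes and handles degenerate k", {
  set.seed(77)
  n <- 60
  base <- matrix(rnorm(n * 40, 0, 0.1), n, 40)
  planted <- rep(1:2, c(40, 20))
  base[planted == 1, ] <- base[planted == 1, ] + 1      # high everywhere
  base[planted == 2, 21:40] <- base[planted == 2, 21:40] + 3  # high in B only
  pr <- structure(list(matrix = base, conditions = c("a", "b"),
                       block_width = 20, flank = 5, motif_length = 10,
                       seqlets = NULL, n_dropped = 0),
                  class = "seqlet_profiles")
  cl <- kmeans_cluster_profiles(pr, k = 2, seed = 1)
  expect_equal(sort(cl$sizes), c(20, 40))
  # partition equals the planted partition up to label swap
  tab <- table(cl$assignment, planted)
  expect_equal(sum(apply(tab, 1, max)), n)
  # labels are in decreasing size order
  expect_true(all(diff(cl$sizes) <= 0))
  # k = number of rows: every row its own cluster, inertia 0
  small <- pr; small$matrix <- base[1:8, ] + matrix(rnorm(8 * 40, 0, 1e-6), 8)
  cl8 <- kmeans_cluster_profiles(small, k = 8, seed = 2)
  expect_equal(sort(cl8$sizes), rep(1, 8))
  expect_lt(cl8$inertia, 1e-6)
  expect_error(kmeans_cluster_profiles(pr, k = 1), "k")
  expect_error(kmeans_cluster_profiles(small, k = 9), "k")
})

test_that("duplicating every row doubles cluster sizes and keeps centroids", {
  set.seed(5)
  m <- rbind(matrix(rnorm(20 * 10, 0, 0.05), 20, 10),
             matrix(rnorm(20 * 10, 5, 0.05), 20, 10))
  pr <- structure(list(matrix = m, conditions = "a", block_width = 10,
                       flank = 2, motif_length = 6, seqlets = NULL,
                       n_dropped = 0), class = "seqlet_profiles")
  pr2 <- pr; pr2$matrix <- rbind(m, m)
  c1 <- kmeans_cluster_profiles(pr, k = 2, seed = 3)
  c2 <- kmeans_cluster_profiles(pr2, k = 2, seed = 3)
  expect_equal(sort(c2$sizes), sort(2 * c1$sizes))
  expect_equal(c2$centroids[order(c2$centroids[, 1]), ],
               c1$centroids[order(c1$centroids[, 1]), ], tolerance = 1e-6)
})

test_that("differential cluster scoring finds the planted cluster with floor p", {
  set.seed(9)
  n <- 80; width <- 67
  mat <- matrix(rnorm(n * 2 * width, 0, 0.1), n, 2 * width)
  mat[, 1:width] <- mat[, 1:width] + 1          # both conditions elevated
  mat[, width + 1:width] <- mat[, width + 1:width] + 1
  diff_rows <- 1:20
  mat[diff_rows, width + 1:width] <- mat[diff_rows, width + 1:width] + 1
  pr <- structure(list(matrix = mat, conditions = c("control", "disease"),
                       block_width = width, flank = 30, motif_length = 7,
                       seqlets = NULL, n_dropped = 0),
                  class = "seqlet_profiles")
  cl <- kmeans_cluster_profiles(pr, k = 3, seed = 4)
  tab <- score_differential_clusters(cl, pr, contrast = c("disease", "control"),
                                     n_perm = 999, seed = 1)
  top <- tab$cluster[which.max(tab$delta)]
  expect_setequal(which(cl$assignment == top), diff_rows)
  expect_equal(tab$p[tab$cluster == top], 1 / 1000)
  expect_true(all(tab$p >= 1 / 1000 & tab$p <= 1))
  # identical condition blocks: delta 0, p near 1
  pr0 <- pr; pr0$matrix[, width + 1:width] <- pr0$matrix[, 1:width]
  cl0 <- kmeans_cluster_profiles(pr0, k = 2, seed = 4)
  tab0 <- score_differential_clusters(cl0, pr0, c("disease", "control"),
                                      n_perm = 199, seed = 1)
  expect_true(all(tab0$delta == 0))
  expect_true(all(tab0$p == 1))
  expect_error(score_differential_clusters(cl, pr, n_perm = 0), "n_perm")
})

test_that("nearest-gene assignment matches containment, tie and oracle cases", {
  genes <- toy_granges(c(1000, 2000), c(1500, 2500), name = c("G1", "G2"))
  # containment -> distance 0
  inside <- toy_granges(1100, 1110)
  got <- assign_nearest_gene(inside, genes)
  expect_equal(got$gene, "G1"); expect_equal(got$distance, 0)
  # equidistant region -> smaller-start gene, tie flagged
  mid <- toy_granges(1700, 1800)  # gap 199 to G1 end(1500), 199 to G2 start(2000)
  got2 <- assign_nearest_gene(mid, genes)
  expect_equal(got2$gene, "G1"); expect_true(got2$tie)
  expect_lt(got2$distance, 0)  # nearest gene lies upstream
  # chromosome absent from the annotation
  off <- toy_granges(10, 20, chrom = "chrZ")
  expect_true(is.na(suppressWarnings(assign_nearest_gene(off, genes))$gene))
  # random instances vs all-pairs brute force
  set.seed(15)
  for (rep in 1:5) {
    gs <- sort(sample(1:5000, 6))
    genes_r <- toy_granges(gs, gs + 100, name = sprintf("g%d", 1:6))
    rs <- sample(1:5000, 8)
    regions <- toy_granges(rs, rs + 20)
    got <- assign_nearest_gene(regions, genes_r)
    for (i in seq_along(regions)) {
      d <- vapply(seq_along(genes_r), function(j) {
        # bases strictly between the two intervals (0 when touching/overlapping)
        max(GenomicRanges::start(genes_r)[j] - GenomicRanges::end(regions)[i] - 1,
            GenomicRanges::start(regions)[i] - GenomicRanges::end(genes_r)[j] - 1, 0)
      }, numeric(1))
      best <- which(d == min(d))
      pick <- best[which.min(GenomicRanges::start(genes_r)[best])]
      expect_equal(got$gene[i], sprintf("g%d", pick))
      expect_equal(abs(got$distance[i]), min(d))
    }
  }
})
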