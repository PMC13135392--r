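test_that("base GRN construction applies the motif-score cutoff literally", {
  hits <- data.frame(peak = c("p1", "p1", "p2", "p3"),
                     tf = c("TF1", "TF2", "TF1", "TF3"),
                     score = c(9.5, 10, 12, 20))
  links <- data.frame(peak = c("p1", "p2"), gene = c("G1", "G2"))
  grn <- build_base_grn(hits, links, min_motif_score = 10)
  # score 9.5 filtered out; score 10 kept (boundary inclusive); unlinked p3 dropped
  expect_equal(grn, data.frame(tf = c("TF1", "TF2"), target = c("G2", "G1")))
  expect_error(build_base_grn(hits[1, ], links), "no candidate")
})

test_that("variable-gene selection ranks by log-normalized variance", {
  set.seed(41)
  counts <- matrix(rpois(10 * 50, 5), 10, 50,
                   dimnames = list(sprintf("g%02d", 1:10), NULL))
  counts[3, ] <- 7                           # constant gene
  counts[5, ] <- rpois(50, c(1, 60))         # highly variable gene
  sel <- select_variable_genes(counts, n = 5)
  expect_false("g03" %in% sel)
  expect_true("g05" %in% sel)
  # hand-computed ranking on the same normalization
  ln <- log1p(t(t(counts) / colSums(counts)) * 1e4)
  v <- apply(ln, 1, var)
  want <- names(sort(v, decreasing = TRUE))[1:5]
  expect_setequal(sel, want)
  expect_equal(length(select_variable_genes(counts, n = 99)), 10)
})

test_that("ridge GRN fit recovers a strong linear edge and filters noise edges", {
  set.seed(43)
  n <- 200
  x <- rnorm(n, 0, 1)
  expr <- rbind(TFX = x + 3, GY = 2 * x + 1 + rnorm(n, 0, 0.01),
                GN = rnorm(n, 2, 1))
  colnames(expr) <- sprintf("c%03d", 1:n)
  base <- data.frame(tf = c("TFX", "TFX"), target = c("GY", "GN"))
  fit <- fit_grn(expr, base, condition = "x", p_cutoff = 0.001)
  e <- fit$edges
  expect_true("GY" %in% e$target)
  expect_equal(e$weight[e$target == "GY"], 2, tolerance = 0.02)
  expect_lt(e$p[e$target == "GY"], 1e-10)
  # pure-noise regulator stays out at the 0.001 cutoff in most replicates
  null_hit <- vapply(1:60, function(i) {
    set.seed(1000 + i)
    ex <- rbind(TFX = rnorm(n), GN = rnorm(n))
    colnames(ex) <- sprintf("c%03d", 1:n)
    f <- fit_grn(ex, data.frame(tf = "TFX", target = "GN"))
    nrow(f$edges) > 0
  }, logical(1))
  expect_gte(mean(!null_hit), 0.95)
  expect_error(fit_grn(expr, base, lambda = 0), "prior")
})

test_that("edge retention caps at max_edges with the largest absolute strengths", {
  set.seed(47)
  n_tf <- 60; n_tgt <- 50; n <- 150
  tf_expr <- matrix(rnorm(n_tf * n), n_tf, n,
                    dimnames = list(sprintf("TF%02d", 1:n_tf), sprintf("c%d", 1:n)))
  w <- matrix(runif(n_tgt * n_tf, 0.5, 1.5) * sample(c(-1, 1), n_tgt * n_tf, TRUE),
              n_tgt, n_tf)
  tgt_expr <- w %*% tf_expr + matrix(rnorm(n_tgt * n, 0, 0.01), n_tgt, n)
  rownames(tgt_expr) <- sprintf("G%02d", 1:n_tgt)
  expr <- rbind(tf_expr, tgt_expr)
  base <- expand.grid(tf = rownames(tf_expr), target = rownames(tgt_expr),
                      stringsAsFactors = FALSE)
  fit <- fit_grn(expr, base, p_cutoff = 0.001, max_edges = 2000)
  expect_equal(nrow(fit$edges), 2000)
  expect_true(all(fit$edges$p < 0.001))
  # all retained strengths at least the 2000th order statistic of |weight|
  expect_gte(min(abs(fit$edges$weight)), sort(abs(fit$edges$weight),
                                              decreasing = TRUE)[2000])
})

test_that("perturbation propagates deltas along the GRN as specified", {
  genes <- c("A", "B", "C", "D")
  expr <- matrix(c(4, 1, 2, 5,
                   2, 1, 2, 5), nrow = 4,
                 dimnames = list(genes, c("cell1", "cell2")))
  edges <- data.frame(tf = c("A", "B"), target = c("B", "C"),
                      weight = c(0.5, -2), p = c(0, 0))
  grn <- structure(list(edges = edges, condition = "x", genes = genes),
                   class = "grn_model")
  # chain, one step: delta_B = w * (0 - a0); C not yet reached; D unreachable
  ko1 <- simulate_perturbation(grn, expr, "A", "ko", n_propagation = 1)
  expect_equal(unname(ko1$delta["A", ]), c(-4, -2))
  expect_equal(unname(ko1$delta["B", ]), c(-2, -1))
  expect_equal(unname(ko1$delta["C", ]), c(0, 0))
  # two steps: delta_C = w_BC * delta_B (no double counting of B)
  ko2 <- simulate_perturbation(grn, expr, "A", "ko", n_propagation = 2)
  expect_equal(unname(ko2$delta["B", ]), c(-2, -1))
  expect_equal(unname(ko2$delta["C", ]), c(4, 2))
  expect_equal(unname(ko2$delta["D", ]), c(0, 0))
  # no outgoing edges: delta nonzero only at the TF
  koB <- simulate_perturbation(grn, expr, "C", "ko")
  expect_equal(sum(koB$delta != 0), 2)
  # OE clamps to 1.5 x max observed
  oe <- simulate_perturbation(grn, expr, "A", "oe", n_propagation = 2)
  expect_equal(oe$target_value, 6)
  expect_equal(unname(oe$delta["A", ]), c(2, 4))
  # KO and OE deltas are anti-parallel when OE target > observed everywhere
  cosines <- vapply(1:2, function(i) {
    sum(ko2$delta[, i] * oe$delta[, i]) /
      (sqrt(sum(ko2$delta[, i]^2)) * sqrt(sum(oe$delta[, i]^2)))
  }, numeric(1))
  expect_equal(cosines, c(-1, -1))
  # linearity: delta rows proportional to the initial TF delta across cells
  ratio <- ko2$delta[, 1] / ko2$delta[, 2]
  expect_true(all(abs(ratio[ko2$delta[, 2] != 0] - 2) < 1e-12))
  expect_error(simulate_perturbation(grn, expr, "ZZZ", "ko"), "absent")
})

test_that("transition scores are cosine alignments toward the target centroid", {
  set.seed(51)
  expr <- matrix(rnorm(20 * 10), 20, 10,
                 dimnames = list(sprintf("g%d", 1:20), sprintf("c%d", 1:10)))
  labels <- rep(c("dis", "ctl"), each = 5)
  centroid <- rowMeans(expr[, labels == "ctl"])
  res <- structure(list(delta = centroid - expr, tf = "g1", mode = "ko",
                        target_value = 0), class = "perturbation_result")
  tv <- transition_vectors(res, expr, labels, target_condition = "ctl")
  expect_equal(unname(tv$scores), rep(1, 10))
  # orthogonal delta scores 0
  d <- centroid - expr[, 1]
  orth <- c(-d[2], d[1], rep(0, 18))
  res2 <- structure(list(delta = matrix(orth, 20, 10), tf = "g1",
                         mode = "ko", target_value = 0),
                    class = "perturbation_result")
  expect_equal(unname(transition_vectors(res2, expr, labels, "ctl")$scores[1]), 0)
  # zero delta scores 0
  res3 <- res2; res3$delta[] <- 0
  expect_equal(unname(transition_vectors(res3, expr, labels, "ctl")$scores),
               rep(0, 10))
})

test_that("region-gene linking respects the distance cap and nearest priority", {
  genes <- toy_granges(c(1000, 40000), c(2000, 41000), name = c("G1", "G2"))
  peaks <- toy_granges(c(1500, 3000, 200000), c(1600, 3100, 200100),
                       name = c("p1", "p2", "p3"))
  links <- link_regions_to_genes(peaks, genes, max_dist = 1e5)
  expect_equal(links$gene[links$peak == "p1"], "G1")
  expect_equal(links$gene[links$peak == "p2"], "G1")
  expect_false("p3" %in% links$peak)
})
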