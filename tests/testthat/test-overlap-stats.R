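test_that("Wilcoxon DE: null identity and exact small-sample p", {
  expr <- matrix(rep(c(1, 2, 3), 2), nrow = 1,
                 dimnames = list("g1", sprintf("c%d", 1:6)))
  groups <- factor(rep(c("a", "b"), each = 3))
  null_de <- wilcoxon_de(expr, groups)
  expect_equal(null_de$p, 1)
  expect_equal(null_de$log2fc, 0)
  expr2 <- matrix(1:6, nrow = 1, dimnames = list("g1", sprintf("c%d", 1:6)))
  de2 <- wilcoxon_de(expr2, groups)
  expect_equal(de2$p, 0.1)    # exhaustive: 2 of 20 arrangements as extreme
  # all-zero genes are excluded and counted
  expr3 <- rbind(expr2, g0 = rep(0, 6))
  de3 <- wilcoxon_de(expr3, groups)
  expect_equal(nrow(de3), 1)
  expect_equal(attr(de3, "n_excluded"), 1)
  expect_error(wilcoxon_de(expr2, factor(rep("a", 6))), "two groups")
})

test_that("LR differential accessibility matches a direct likelihood oracle", {
  # balanced design where accessibility is independent of group given covariate
  y_pat <- c(1, 1, 0, 0)
  acc <- matrix(rep(y_pat, 2), nrow = 1, dimnames = list("r1", NULL))
  groups <- rep(c("a", "b"), each = 4)
  covar <- rep(c(2, 1, 2, 1), 2)
  tab <- lr_differential_accessibility(acc, groups, covar)
  expect_equal(tab$p, 1, tolerance = 1e-6)
  # deviance agreement with brute-force ML on an 8-cell fixture
  set.seed(61)
  y <- c(1, 0, 1, 1, 0, 0, 1, 0)
  grp <- rep(c("a", "b"), each = 4)
  cv <- rnorm(8)
  nll <- function(par, X) {
    eta <- X %*% par
    -sum(y * eta - log(1 + exp(eta)))
  }
  Xf <- cbind(1, grp == "b", cv)
  Xr <- cbind(1, cv)
  df <- 2 * (optim(c(0, 0), nll, X = Xr, method = "BFGS")$value -
             optim(c(0, 0, 0), nll, X = Xf, method = "BFGS")$value)
  got <- lr_differential_accessibility(matrix(y, 1, dimnames = list("r", NULL)),
                                       grp, cv)
  expect_equal(qchisq(got$p, 1, lower.tail = FALSE), max(0, df),
               tolerance = 1e-5)
  # degenerate regions are flagged with p = 1
  all1 <- matrix(1, 1, 8, dimnames = list("r", NULL))
  tab1 <- lr_differential_accessibility(all1, grp, cv)
  expect_true(tab1$degenerate); expect_equal(tab1$p, 1)
})

test_that("a planted group-specific region is detected at n = 200 cells/group", {
  set.seed(63)
  n <- 400
  grp <- rep(c("a", "b"), each = 200)
  acc <- rbind(
    planted = rbinom(n, 1, ifelse(grp == "a", 0.7, 0.3)),
    matrix(rbinom(19 * n, 1, 0.5), 19,
           dimnames = list(sprintf("null%02d", 1:19), NULL)))
  covar <- rnorm(n)
  tab <- lr_differential_accessibility(acc, grp, covar)
  expect_lt(tab$p_adj[tab$region == "planted"], 0.05)
})

test_that("DE thresholding applies strict inequalities and direction", {
  res <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                    log2fc = c(0.30, 0.30, -0.5, 0.26),
                    p_adj = c(0.04, 0.05, 0.01, 0.01))
  up <- threshold_de(res, p_adj_max = 0.05, lfc_min = 0.25, direction = "up")
  expect_setequal(up, c("g1", "g4"))     # p_adj exactly 0.05 excluded
  down <- threshold_de(res, lfc_min = 0.25, direction = "down")
  expect_equal(down, "g3")
  # direction-exclusive: no gene in both sets
  expect_length(intersect(up, down), 0)
})

test_that("ortholog mapping uses the table first, then the case rule", {
  tab <- data.frame(mouse = c("Fosl2", "Trp53"), human = c("FOSL2", "TP53"))
  m <- map_orthologs(c("Fosl2", "Trp53", "Jun"), tab, fallback_case = "upper")
  expect_equal(unname(m$mapped), c("FOSL2", "TP53", "JUN"))
  # fallback off: unmapped symbols are reported, not dropped
  m2 <- map_orthologs(c("Fosl2", "Jun"), tab, fallback_case = "none")
  expect_equal(m2$unmapped, "Jun")
  # mapping then reverse-mapping over the covered set is the identity
  fwd <- map_orthologs(tab$mouse, tab, fallback_case = "none")$mapped
  back <- map_orthologs(unname(fwd), tab[, c(2, 1)], fallback_case = "none")$mapped
  expect_equal(unname(back), tab$mouse)
  bad <- rbind(tab, data.frame(mouse = "Fosl2", human = "OTHER"))
  expect_error(map_orthologs("Fosl2", bad), "conflict")
})

test_that("hypergeometric overlap matches exact combinatorics", {
  universe <- sprintf("u%02d", 1:20)
  a <- universe[1:5]; b <- universe[6:10]
  expect_equal(hypergeometric_overlap(a, b, universe)$p, 1)  # k = 0
  full <- hypergeometric_overlap(a, a, universe)
  expect_equal(full$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_error(hypergeometric_overlap(c(a, "zz"), b, universe), "zz")
})

test_that("hypergeometric tail matches exhaustive subset enumeration", {
  set.seed(71)
  for (rep in 1:5) {
    N <- sample(8:14, 1)
    universe <- sprintf("u%02d", 1:N)
    a <- sample(universe, sample(2:5, 1))
    b_size <- sample(2:5, 1)
    b <- sample(universe, b_size)
    k <- length(intersect(a, b))
    subsets <- combn(N, b_size)
    tail <- mean(apply(subsets, 2, function(idx) {
      length(intersect(a, universe[idx])) >= k
    }))
    expect_equal(hypergeometric_overlap(a, b, universe)$p, tail,
                 tolerance = 1e-12)
  }
  # monotone decreasing in k for fixed sizes
  ps <- vapply(0:5, function(k) {
    exp(phyper(k - 1, 5, 15, 5, lower.tail = FALSE, log.p = TRUE))
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("extreme tails stay finite in log space", {
  universe <- sprintf("u%05d", 1:20000)
  a <- universe[1:1000]; b <- universe[1:900]
  ov <- hypergeometric_overlap(a, b, universe)
  expect_true(is.finite(ov$log10_p))
  expect_lt(ov$log10_p, -1000)
})

test_that("Monte-Carlo overlap: trivial cases and hypergeometric agreement", {
  universe <- sprintf("u%03d", 1:200)
  a <- universe[1:30]; b <- universe[31:60]
  mc0 <- monte_carlo_multiset_overlap(list(a, b), universe, B = 200, seed = 1)
  expect_equal(mc0$p, 1)      # observed overlap 0: every null >= 0
  expect_gte(mc0$p, 1 / 201)
  # two-set case agrees with the analytic tail
  a2 <- universe[1:40]; b2 <- universe[c(1:12, 101:128)]
  B <- 20000
  mc <- monte_carlo_multiset_overlap(list(a2, b2), universe, B = B, seed = 2)
  hg <- hypergeometric_overlap(a2, b2, universe)
  se <- sqrt(hg$p * (1 - hg$p) / B)
  expect_lt(abs(mc$p - hg$p), 3 * se + 2 / B)
  expect_error(monte_carlo_multiset_overlap(list(a2), universe), "two sets")
})

test_that("set enrichment orders annotations by overlap significance", {
  universe <- sprintf("g%02d", 1:40)
  query <- universe[1:8]
  ann <- list(self = query, partial = universe[5:16], none = universe[30:40])
  tab <- set_enrichment(query, ann, universe)
  expect_equal(tab$annotation[1], "self")
  expect_equal(tab$p[tab$annotation == "none"], 1)
  expect_equal(tab$p_adj, pmin(1, tab$p * 3))
})
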