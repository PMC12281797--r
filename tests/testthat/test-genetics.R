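test_that("CIN score follows the length-weighted definition", {
  lens <- c(chr1 = 1000)
  whole <- data.frame(sample_id = "s1", chromosome = "chr1",
                      start = 1, end = 1000, log2_ratio = 1)
  expect_equal(cinScore(whole, lens)$chr1, 1)
  halves <- data.frame(sample_id = "s1", chromosome = "chr1",
                       start = c(1, 501), end = c(500, 1000),
                       log2_ratio = c(0.5, -0.5))
  expect_equal(cinScore(halves, lens)$chr1, 0.5)
  ## flat genome scores zero
  none <- cinScore(whole[0, ], lens, samples = "s1")
  expect_equal(none$total, 0)
  expect_error(cinScore(data.frame(sample_id = "s1", chromosome = "chrX",
                                   start = 1, end = 10, log2_ratio = 1),
                        lens), "without length")
})

test_that("CIN is invariant to segment splitting and additive", {
  set.seed(61)
  lens <- hg19ChromLengths()
  seg <- data.frame(sample_id = "s1", chromosome = "chr7",
                    start = 1e6, end = 5e6, log2_ratio = 0.73)
  split <- data.frame(sample_id = "s1", chromosome = "chr7",
                      start = c(1e6, 3e6 + 1), end = c(3e6, 5e6),
                      log2_ratio = 0.73)
  expect_equal(cinScore(seg, lens)$total, cinScore(split, lens)$total,
               tolerance = 1e-12)
  ## additivity over disjoint segment sets
  segB <- data.frame(sample_id = "s1", chromosome = "chr8",
                     start = 2e6, end = 4e6, log2_ratio = -0.4)
  both <- rbind(seg, segB)
  expect_equal(cinScore(both, lens)$total,
               cinScore(seg, lens)$total + cinScore(segB, lens)$total,
               tolerance = 1e-12)
})

test_that("alternative CIN weightings behave as documented", {
  lens <- c(chr1 = 1000)
  seg <- data.frame(sample_id = "s1", chromosome = "chr1",
                    start = c(1, 501), end = c(500, 1000),
                    log2_ratio = c(0.5, 0))
  expect_equal(cinScore(seg, lens, weighting = "count")$chr1, 1)
  expect_equal(cinScore(seg, lens, weighting = "amplitude")$chr1, 0.5)
})

test_that("covariate screen recovers exact monotone association", {
  sc <- data.frame(sample_id = sprintf("s%d", 1:20), score = 1:20)
  cin <- data.frame(sample_id = sprintf("s%d", 1:20),
                    total = (1:20)^2)      # monotone transform
  samp <- data.frame(sample_id = sprintf("s%d", 1:20),
                     bmi = rep(25, 20), age = rnorm(20, 60, 5))
  expect_warning(res <- covariateScreen(sc, samp, cin), "constant")
  expect_equal(res$rho[res$covariate == "CIN"], 1)
  expect_true(is.na(res$rho[res$covariate == "BMI"]))
})

test_that("Spearman screen is invariant under monotone transforms", {
  set.seed(62)
  sc <- data.frame(sample_id = sprintf("s%d", 1:50), score = rnorm(50))
  cin <- data.frame(sample_id = sprintf("s%d", 1:50),
                    total = sc$score + rnorm(50))
  samp <- data.frame(sample_id = sprintf("s%d", 1:50))
  r1 <- covariateScreen(sc, samp, cin)
  cin2 <- cin; cin2$total <- exp(cin2$total)
  r2 <- covariateScreen(sc, samp, cin2)
  expect_equal(r1$rho, r2$rho)
})

test_that("per-chromosome regression recovers exact and planted slopes", {
  set.seed(63)
  ids <- sprintf("s%d", 1:10)
  cin <- data.frame(sample_id = ids, chr1 = 1:10, total = 1:10)
  sc <- data.frame(sample_id = ids, score = 2 * (1:10))
  samp <- data.frame(sample_id = ids, age = c(rep(50, 10)))
  res <- perChromosomeRegression(sc, cin, samp)
  expect_equal(res$slope[res$chromosome == "chr1"], 2)
  expect_lt(res$p_raw[res$chromosome == "chr1"], 1e-10)
  ## noisy recovery
  n <- 100
  x <- runif(n, 0, 2)
  sc2 <- data.frame(sample_id = sprintf("t%d", 1:n),
                    score = 1.5 * x + rnorm(n, 0, 0.5))
  cin2 <- data.frame(sample_id = sc2$sample_id, chr5 = x, total = x)
  samp2 <- data.frame(sample_id = sc2$sample_id, age = rep(70, n))
  res2 <- perChromosomeRegression(sc2, cin2, samp2)
  expect_equal(res2$slope, 1.5, tolerance = 0.2, ignore_attr = TRUE)
})

test_that("age 65 lands in the older subgroup", {
  ids <- sprintf("s%d", 1:12)
  cin <- data.frame(sample_id = ids, chr1 = rnorm(12), total = 0)
  sc <- data.frame(sample_id = ids, score = rnorm(12))
  samp <- data.frame(sample_id = ids, age = c(rep(65, 6), rep(50, 6)))
  res <- perChromosomeRegression(sc, cin, samp)
  expect_setequal(unique(res$age_group), c(">=65", "<65"))
  expect_true(all(res$n == 6))
})

test_that("degenerate predictors are skipped with a note", {
  ids <- sprintf("s%d", 1:8)
  cin <- data.frame(sample_id = ids, chr1 = 1, chr2 = rnorm(8), total = 1)
  sc <- data.frame(sample_id = ids, score = rnorm(8))
  samp <- data.frame(sample_id = ids, age = rep(40, 8))
  res <- perChromosomeRegression(sc, cin, samp)
  expect_equal(res$note[res$chromosome == "chr1"], "degenerate predictor")
  expect_true(is.na(res$slope[res$chromosome == "chr1"]))
})

test_that("mutation binarization collapses events and computes rates", {
  mut <- data.frame(sample_id = c("s1", "s1", "s2", "s3"),
                    gene = c("A", "A", "A", "B"),
                    variant_class = c("Missense_Mutation", "Nonsense_Mutation",
                                      "Missense_Mutation", "Silent"))
  m <- binarizeMutations(mut, c("s1", "s2", "s3", "s4"))
  expect_equal(dim(m), c(4, 1))             # Silent is not non-synonymous
  expect_equal(sum(m[, "A"]), 2)
  expect_equal(unname(attr(m, "mutation_rate")["A"]), 0.5)
})

test_that("exact rank-sum p matches stats::wilcox.test without ties", {
  set.seed(64)
  for (i in 1:30) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- sample(1:1000, n1 + n2)    # no ties
    p1 <- methylLink:::exactRankSumP(x[1:n1], x[-(1:n1)])
    p2 <- wilcox.test(x[1:n1], x[-(1:n1)], exact = TRUE)$p.value
    expect_equal(p1, p2, tolerance = 1e-12)
  }
  ## extreme separation of two 3-groups: p = 2/20
  expect_equal(methylLink:::exactRankSumP(c(10, 11, 12), c(1, 2, 3)), 0.1)
})

test_that("mutation score test filters by rate and reports direction", {
  set.seed(65)
  ids <- sprintf("s%d", 1:100)
  sc <- data.frame(sample_id = ids, score = rnorm(100))
  mut <- matrix(FALSE, 100, 3, dimnames = list(ids, c("rare", "up", "null")))
  mut[1:2, "rare"] <- TRUE                  # 2% < 3% -> excluded
  mut[1:20, "up"] <- TRUE
  sc$score[1:20] <- sc$score[1:20] + 3      # strong planted shift
  mut[21:40, "null"] <- TRUE
  res <- mutationScoreTest(sc, mut, minRate = 0.03)
  expect_false("rare" %in% res$gene)
  expect_lt(res$p_adj[res$gene == "up"], 0.01)
  expect_equal(res$direction[res$gene == "up"], 1)
  expect_gt(res$p_raw[res$gene == "null"], 0.01)
})

test_that("two-hit classification requires both hits", {
  mt <- data.frame(gene = c("A", "B", "TP53"),
                   p_adj = c(0.01, 0.2, 0.001))
  th <- twoHitClassify(mt, diffProbeGenes = c("A", "B"))
  expect_true(th$two_hit[th$gene == "A"])
  expect_false(th$two_hit[th$gene == "B"])      # methylation hit only
  expect_false(th$two_hit[th$gene == "TP53"])   # mutation hit only
  expect_false(any(twoHitClassify(mt, character())$two_hit))
})
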