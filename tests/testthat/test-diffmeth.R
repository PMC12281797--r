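mkPairedM <- function(d, base = NULL) {
  ## build an MValueSet from a probes x pairs difference matrix: pre = base,
  ## post = base + d
  n <- nrow(d); np <- ncol(d)
  if (is.null(base)) base <- matrix(0, n, np)
  m <- cbind(base, base + d)
  rownames(m) <- sprintf("cg%03d", seq_len(n))
  colnames(m) <- c(sprintf("p%02d_pre", seq_len(np)),
                   sprintf("p%02d_post", seq_len(np)))
  samples <- data.frame(
    sample_id = colnames(m),
    subject_id = rep(sprintf("p%02d", seq_len(np)), 2),
    group = rep(c("pre", "post"), each = np))
  MValueSet(m, samples)
}

test_that("unpaired subjects are rejected by name", {
  mm <- mkPairedM(matrix(rnorm(40), 4, 10))
  cd <- as.data.frame(SummarizedExperiment::colData(mm))
  expect_error(
    pairedDMP(mm, subject = replace(cd$subject_id, 1, "p99"),
              group = cd$group, groupLevels = c("pre", "post")),
    "p99")
})

test_that("a constant planted shift is declared significant and hyper", {
  set.seed(31)
  d <- matrix(rnorm(50 * 16, 0, 0.3), 50, 16)
  d[1, ] <- d[1, ] + 1.2          # strong hypermethylation in post
  dr <- pairedDMP(mkPairedM(d), groupLevels = c("pre", "post"))
  expect_true(dr$significant[1])
  expect_equal(dr$direction[1], "hyper")
  expect_gt(dr$logFC[1], 0)
})

test_that("unmoderated mode reproduces the textbook paired t-test", {
  set.seed(32)
  d <- matrix(rnorm(20 * 8), 20, 8)
  dr <- pairedDMP(mkPairedM(d), groupLevels = c("pre", "post"),
                  moderated = FALSE)
  for (i in c(1, 7, 20)) {
    tt <- t.test(d[i, ])
    expect_equal(dr$t_stat[i], unname(tt$statistic))
    expect_equal(dr$p_raw[i], tt$p.value)
  }
})

test_that("moderated statistics agree with the limma eBayes cross-check", {
  set.seed(33)
  d <- matrix(rnorm(200 * 10, 0, runif(200, 0.3, 2)), 200, 10)
  dr <- pairedDMP(mkPairedM(d), groupLevels = c("pre", "post"))
  fit <- limma::eBayes(limma::lmFit(d, matrix(1, 10, 1)))
  expect_equal(attr(dr, "d0"), fit$df.prior, tolerance = 1e-8)
  expect_equal(attr(dr, "s0_sq"), fit$s2.prior, tolerance = 1e-8)
  expect_equal(dr$t_stat, unname(fit$t[, 1]), tolerance = 1e-10)
  expect_equal(dr$p_raw, unname(fit$p.value[, 1]), tolerance = 1e-10)
})

test_that("zero-variance probes stay finite under moderation", {
  set.seed(34)
  d <- matrix(rnorm(30 * 6), 30, 6)
  d[5, ] <- 0.4                   # identical difference in every pair
  dr <- pairedDMP(mkPairedM(d), groupLevels = c("pre", "post"))
  expect_true(all(is.finite(dr$t_stat)))
  expect_true(all(is.finite(dr$p_raw)))
})

test_that("BH adjustment is monotone and alpha only moves the flag", {
  set.seed(35)
  d <- matrix(rnorm(100 * 8, 0, 0.6), 100, 8)
  mm <- mkPairedM(d)
  dr <- pairedDMP(mm, groupLevels = c("pre", "post"))
  ord <- order(dr$p_raw)
  expect_true(all(diff(dr$p_adj[ord]) >= -1e-15))
  expect_true(all(dr$p_adj >= dr$p_raw - 1e-15))
  dr2 <- pairedDMP(mm, groupLevels = c("pre", "post"), alpha = 0.5)
  expect_identical(dr2$p_raw, dr$p_raw)
  expect_identical(dr2$t_stat, dr$t_stat)
})

test_that("jaccard conservation does exact set arithmetic", {
  j <- jaccardConservation(c("p1", "p2", "p3"), c("p2", "p3", "p4"))
  expect_equal(j$jaccard, 0.5)
  expect_equal(jaccardConservation(letters[1:4], letters[1:4])$jaccard, 1)
  expect_equal(jaccardConservation("a", "b")$jaccard, 0)
  expect_warning(je <- jaccardConservation(character(), character()),
                 "empty")
  expect_equal(je$jaccard, 0)
  ## symmetry
  expect_equal(jaccardConservation(c("x", "y"), c("y", "z"))$jaccard,
               jaccardConservation(c("y", "z"), c("x", "y"))$jaccard)
})

test_that("direction-discordant genes drop all their probes", {
  dr <- data.frame(probe_id = c("cg1", "cg2", "cg3", "cg4", "cg5"),
                   direction = c("hyper", "hypo", "hyper", "hyper", "hyper"),
                   significant = c(TRUE, TRUE, TRUE, TRUE, TRUE))
  man <- toyManifest(dr$probe_id,
                     gene = c("G", "G", "H", "H", ""))
  keep <- concordantGeneFilter(dr, man)
  expect_setequal(keep, c("cg3", "cg4", "cg5"))   # G discordant, H fine,
                                                  # cg5 intergenic
  dr$significant[2] <- FALSE                      # no conflict anymore
  expect_setequal(concordantGeneFilter(dr, man),
                  c("cg1", "cg3", "cg4", "cg5"))
})

test_that("category summary marginals match the significant set", {
  set.seed(36)
  sim <- genPairedCohort(simConfig(seed = 36, nProbes = 400, nPairs = 16,
                                   plantedDmpFraction = 0.1))
  dr <- pairedDMP(betaToM(sim$beta), groupLevels = c("pre", "post"))
  tab <- categorySummary(dr, sim$manifest)
  expect_equal(sum(tab), sum(dr$significant))
  ## planted mix is recovered roughly among significant probes
  rel <- sim$manifest$island_relation[
    match(dr$probe_id[dr$significant], sim$manifest$probe_id)]
  expect_equal(unname(tab["opensea", "hyper"] + tab["opensea", "hypo"]),
               sum(rel == "opensea"))
})

test_that("detection power increases with the number of pairs", {
  recallAt <- function(np, seed) {
    sim <- genPairedCohort(simConfig(seed = seed, nProbes = 300,
                                     nPairs = np, noiseSdM = 1.4,
                                     subjectSdM = 0.5,
                                     plantedDmpFraction = 0.1))
    dr <- pairedDMP(betaToM(sim$beta), groupLevels = c("pre", "post"))
    mean(dr$significant[sim$truth$is_dmp])
  }
  r8 <- mean(vapply(1:3, function(s) recallAt(8, 400 + s), numeric(1)))
  r16 <- mean(vapply(1:3, function(s) recallAt(16, 400 + s), numeric(1)))
  expect_gt(r16, r8)
})
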