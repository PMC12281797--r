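## helper: BetaSet whose probes all share one latent profile
chainBeta <- function(n, ns = 10, noise = 0, seed = 71) {
  set.seed(seed)
  base <- runif(ns)
  vals <- t(vapply(seq_len(n), function(i) base + rnorm(ns, 0, noise),
                   numeric(ns)))
  vals <- pmin(pmax(vals, 0), 1)
  rownames(vals) <- sprintf("cg%02d", seq_len(n))
  colnames(vals) <- sprintf("s%d", seq_len(ns))
  BetaSet(vals)
}

test_that("a perfect chain forms one block with rho 1", {
  bs <- chainBeta(6)
  man <- toyManifest(probeIds(bs), position = seq(100, by = 100,
                                                  length.out = 6))
  blk <- findBlocks(bs, man, rhoMin = 0.4, minBlockSize = 5)
  expect_equal(nrow(blk), 1)
  expect_equal(blk$n_probes, 6)
  expect_equal(blk$min_adjacent_rho, 1)
  expect_equal(blk$start, 100)
  expect_equal(blk$end, 600)
})

test_that("an uncorrelated probe breaks the chain", {
  bs <- chainBeta(6)
  v <- betaValues(bs)
  set.seed(72)
  v["cg04", ] <- runif(10)
  bs2 <- BetaSet(v)
  man <- toyManifest(probeIds(bs2), position = seq(100, by = 100,
                                                   length.out = 6))
  blk <- findBlocks(bs2, man, rhoMin = 0.6, minBlockSize = 5)
  expect_equal(nrow(blk), 0)   # fragments of 3 and 2 are both too short
})

test_that("a 1001 bp gap splits an otherwise perfect 10-probe chain", {
  bs <- chainBeta(10)
  pos <- seq(100, by = 100, length.out = 10)
  pos[4:10] <- pos[4:10] + 901          # gap between 3 and 4 becomes 1001
  man <- toyManifest(probeIds(bs), position = pos)
  blk <- findBlocks(bs, man, rhoMin = 0.4, minBlockSize = 5)
  expect_equal(nrow(blk), 1)
  expect_equal(blk$n_probes, 7)         # only the 7-probe fragment survives
  expect_equal(strsplit(blk$probe_ids, ",")[[1]][1], "cg04")
  ## exactly 1000 is still inside
  pos2 <- seq(100, by = 100, length.out = 10)
  pos2[4:10] <- pos2[4:10] + 900
  man2 <- toyManifest(probeIds(bs), position = pos2)
  blk2 <- findBlocks(bs, man2, rhoMin = 0.4, minBlockSize = 5)
  expect_equal(blk2$n_probes, 10)
})

test_that("constant probes break the chain (undefined correlation)", {
  bs <- chainBeta(6)
  v <- betaValues(bs)
  v["cg03", ] <- 0.5
  man <- toyManifest(rownames(v), position = seq(100, by = 100,
                                                 length.out = 6))
  blk <- findBlocks(BetaSet(v), man, rhoMin = 0.4, minBlockSize = 3)
  expect_true(all(!grepl("cg03", blk$probe_ids)))
})

test_that("find_blocks equals the brute-force run enumeration oracle", {
  set.seed(73)
  for (i in 1:40) {
    n <- sample(10:50, 1)
    pos <- sort(sample.int(20000, n))
    nGroups <- max(2, n %/% 6)
    latent <- matrix(runif(nGroups * 8), nGroups, 8)
    grp <- sample(nGroups, n, replace = TRUE)
    vals <- latent[grp, ] + matrix(rnorm(n * 8, 0, 0.35), n, 8)
    vals <- pmin(pmax(vals, 0), 1)
    rownames(vals) <- sprintf("cg%03d", seq_len(n))
    colnames(vals) <- sprintf("s%d", 1:8)
    man <- toyManifest(rownames(vals), position = pos)
    for (rho in c(0.4, 0.6)) {
      got <- findBlocks(BetaSet(vals), man, rhoMin = rho,
                        positionGap = 1000, minBlockSize = 5)
      want <- bruteForceBlocks(vals, pos, rho, 1000, 5)
      expect_equal(nrow(got), length(want))
      if (nrow(got))
        expect_equal(strsplit(got$probe_ids, ","), unname(want))
    }
  }
})

test_that("raising the correlation threshold never grows the blocks", {
  set.seed(74)
  for (i in 1:10) {
    n <- 40
    latent <- runif(10)
    vals <- t(vapply(seq_len(n), function(j)
      latent + rnorm(10, 0, runif(1, 0.05, 0.6)), numeric(10)))
    vals <- pmin(pmax(vals, 0), 1)
    rownames(vals) <- sprintf("cg%03d", seq_len(n))
    colnames(vals) <- sprintf("s%d", 1:10)
    man <- toyManifest(rownames(vals),
                       position = seq(100, by = 300, length.out = n))
    bs <- BetaSet(vals)
    n04 <- sum(findBlocks(bs, man, rhoMin = 0.4)$n_probes)
    n06 <- sum(findBlocks(bs, man, rhoMin = 0.6)$n_probes)
    expect_lte(n06, n04)
  }
})

test_that("blocks are invariant to sample permutation and beta/M scale", {
  set.seed(75)
  sim <- genTumorCohort(simConfig(seed = 75, nProbes = 80,
                                  nTumorSamples = 20, cohorts = "LSCC"))
  amp <- sim$truth$samples$sample_id[sim$truth$samples$amplified]
  bs <- sim$beta[, amp]
  blk <- findBlocks(bs, sim$manifest, rhoMin = 0.4, chromosome = "chr19")
  perm <- sample(length(amp))
  blkPerm <- findBlocks(bs[, perm], sim$manifest, rhoMin = 0.4,
                        chromosome = "chr19")
  expect_equal(blk, blkPerm)
  blkM <- findBlocks(betaToM(bs), sim$manifest, rhoMin = 0.4,
                     chromosome = "chr19")
  expect_equal(blk$probe_ids, blkM$probe_ids)
})

test_that("amplification calls apply the strict all-genes rule", {
  genes <- data.frame(gene = c("G1", "G2"), chromosome = "chr19",
                      start = c(100, 1000), end = c(500, 1500))
  seg <- function(id, r1, r2)
    data.frame(sample_id = id, chromosome = "chr19",
               start = c(1, 900), end = c(600, 1600),
               log2_ratio = c(r1, r2))
  segs <- rbind(seg("amp", 0.5, 0.5), seg("edge", 0.5, 0.2),
                seg("flat", 0, 0))
  calls <- callAmplification(segs, genes)
  expect_true(calls$amplified[calls$sample_id == "amp"])
  expect_false(calls$amplified[calls$sample_id == "edge"])  # 0.2 not > 0.2
  expect_false(calls$amplified[calls$sample_id == "flat"])
})

test_that("gene ratios are overlap-length-weighted segment means", {
  genes <- data.frame(gene = "G1", chromosome = "chr19",
                      start = 100, end = 299)
  segs <- data.frame(sample_id = "s1", chromosome = "chr19",
                     start = c(1, 200), end = c(199, 400),
                     log2_ratio = c(0.3, 0.1))
  calls <- callAmplification(segs, genes)
  expect_equal(calls$ratio_G1, 0.2)         # equal 100 bp overlaps
  expect_false(calls$amplified)             # 0.2 not > 0.2
})

test_that("samples without covering segments are not callable", {
  genes <- data.frame(gene = "G1", chromosome = "chr19",
                      start = 100, end = 200)
  segs <- data.frame(sample_id = "s1", chromosome = "chr19",
                     start = 5000, end = 6000, log2_ratio = 1)
  calls <- callAmplification(segs, genes)
  expect_false(calls$callable)
  expect_false(calls$amplified)
})

test_that("block-set comparison uses reciprocal 50% probe overlap", {
  mk <- function(ids) data.frame(chromosome = "chr19", start = 1, end = 2,
                                 n_probes = length(ids),
                                 min_adjacent_rho = 1,
                                 probe_ids = paste(ids, collapse = ","))
  a <- mk(sprintf("p%02d", 1:10))
  identical_ <- compareBlockSets(a, a)
  expect_equal(identical_$preserved_a, 1)
  disjoint <- compareBlockSets(a, mk(sprintf("q%02d", 1:10)))
  expect_equal(disjoint$preserved_a, 0)
  shifted <- compareBlockSets(a, mk(sprintf("p%02d", 2:11)))
  expect_equal(shifted$preserved_a, 1)      # Jaccard 9/11 > 0.5
})
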