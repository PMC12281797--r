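# Small fixtures built in code, plus independent oracles used across files.

toyBeta <- function(vals, probes = NULL, samples = NULL) {
  m <- as.matrix(vals)
  if (is.null(probes)) probes <- sprintf("cg%02d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(m)))
  dimnames(m) <- list(probes, samples)
  BetaSet(m)
}

toyManifest <- function(probes, chromosome = "chr1",
                        position = seq(1000, by = 500,
                                       length.out = length(probes)),
                        gene = "", gene_region = "body",
                        island_relation = "opensea") {
  data.frame(probe_id = probes, chromosome = chromosome,
             position = position, gene = gene,
             gene_region = gene_region,
             island_relation = island_relation,
             stringsAsFactors = FALSE)
}

# Independent ANOVA oracle for the one-way random-effects ICC: explicit
# double-loop sums of squares, no shared code with iccOneway().
iccOracle <- function(x) {
  n <- nrow(x); k <- ncol(x)
  gm <- mean(x)
  ssb <- 0; ssw <- 0
  for (i in seq_len(n)) {
    mi <- mean(x[i, ])
    ssb <- ssb + k * (mi - gm)^2
    for (j in seq_len(k)) ssw <- ssw + (x[i, j] - mi)^2
  }
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  (msb - msw) / (msb + (k - 1) * msw)
}

# Brute-force oracle for co-methylated blocks: mark every adjacent pair
# that satisfies both constraints, then read off maximal satisfied runs.
bruteForceBlocks <- function(beta, pos, rhoMin, gap, minSize) {
  ord <- order(pos, rownames(beta))
  beta <- beta[ord, , drop = FALSE]; pos <- pos[ord]
  n <- nrow(beta)
  if (n < 2) return(list())
  linked <- logical(n - 1)
  for (i in seq_len(n - 1)) {
    rho <- suppressWarnings(
      cor(beta[i, ], beta[i + 1, ], method = "spearman"))
    linked[i] <- !is.na(rho) && rho >= rhoMin &&
      (pos[i + 1] - pos[i]) <= gap
  }
  runs <- rle(linked)
  blocks <- list()
  idx <- 1
  for (r in seq_along(runs$lengths)) {
    if (runs$values[r]) {
      members <- idx:(idx + runs$lengths[r])   # edges -> vertices
      if (length(members) >= minSize)
        blocks[[length(blocks) + 1]] <- rownames(beta)[members]
    }
    idx <- idx + runs$lengths[r]
  }
  blocks
}
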