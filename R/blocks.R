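#' Find co-methylated probe blocks
#'
#' Scans position-sorted probes chromosome by chromosome and grows a block
#' while two chain conditions hold between consecutive probes: the genomic
#' gap is at most \code{positionGap} bp (inclusive) and the Spearman
#' correlation of their methylation profiles is at least \code{rhoMin}.
#' Either violation closes the block; blocks with at least
#' \code{minBlockSize} probes are emitted, disjoint and in genomic order.
#' A constant probe has undefined correlation and always breaks the chain.
#' \code{allPairs = TRUE} additionally requires every pair inside the block
#' (not just adjacent ones) to reach \code{rhoMin}.
#'
#' @param bs a complete \linkS4class{BetaSet} (>= 3 samples); correlation is
#'   rank-based so beta and M inputs give identical blocks
#' @param manifest probe manifest covering all probes of \code{bs}
#' @param rhoMin adjacent-correlation threshold (0.4 or 0.6 are the usual
#'   settings)
#' @param positionGap maximum intra-block gap in bp (default 1000,
#'   inclusive)
#' @param minBlockSize minimum probes per block (default 5)
#' @param chromosome optional chromosome filter
#' @param allPairs require all within-block pairs to pass (default FALSE)
#' @return data.frame: chromosome, start, end, n_probes, min_adjacent_rho,
#'   probe_ids (comma-joined, in position order)
#' @export
findBlocks <- function(bs, manifest, rhoMin = 0.4, positionGap = 1000,
                       minBlockSize = 5, chromosome = NULL,
                       allPairs = FALSE) {
  b <- if (is(bs, "BetaSet")) betaValues(bs) else mValues(bs)
  if (ncol(b) < 3) stop("findBlocks: need >= 3 samples for correlation")
  ann <- manifest[match(rownames(b), manifest$probe_id), ]
  if (anyNA(ann$probe_id))
    stop("findBlocks: probe absent from manifest: ",
         rownames(b)[which(is.na(ann$probe_id))[1]])
  if (!is.null(chromosome)) {
    keep <- ann$chromosome %in% normalizeChrom(chromosome)
    b <- b[keep, , drop = FALSE]; ann <- ann[keep, , drop = FALSE]
  }
  if (!nrow(b))
    return(data.frame(chromosome = character(), start = numeric(),
                      end = numeric(), n_probes = integer(),
                      min_adjacent_rho = numeric(),
                      probe_ids = character(), stringsAsFactors = FALSE))
  rk <- t(apply(b, 1, rank))        # precomputed ranks; Pearson on ranks
  adjRho <- function(i, j) {
    if (sd(rk[i, ]) == 0 || sd(rk[j, ]) == 0) return(NA_real_)
    cor(rk[i, ], rk[j, ])
  }
  out <- list()
  for (chr in unique(ann$chromosome)) {
    sel <- which(ann$chromosome == chr)
    sel <- sel[order(ann$position[sel], rownames(b)[sel])]
    if (length(sel) < minBlockSize) next
    cur <- sel[1]
    flush <- function(members) {
      if (length(members) < minBlockSize) return()
      rhos <- vapply(seq_len(length(members) - 1), function(t)
        adjRho(members[t], members[t + 1]), numeric(1))
      out[[length(out) + 1]] <<- data.frame(
        chromosome = chr,
        start = ann$position[members[1]],
        end = ann$position[members[length(members)]],
        n_probes = length(members),
        min_adjacent_rho = min(rhos),
        probe_ids = paste(rownames(b)[members], collapse = ","),
        stringsAsFactors = FALSE)
    }
    members <- cur
    for (nxt in sel[-1]) {
      gapOk <- (ann$position[nxt] - ann$position[cur]) <= positionGap
      rho <- adjRho(cur, nxt)
      corOk <- !is.na(rho) && rho >= rhoMin
      if (corOk && allPairs && length(members) > 1) {
        rall <- vapply(members, function(mIdx) adjRho(mIdx, nxt), numeric(1))
        corOk <- all(!is.na(rall) & rall >= rhoMin)
      }
      if (gapOk && corOk) {
        members <- c(members, nxt)
      } else {
        flush(members)
        members <- nxt
      }
      cur <- nxt
    }
    flush(members)
  }
  if (!length(out))
    return(data.frame(chromosome = character(), start = numeric(),
                      end = numeric(), n_probes = integer(),
                      min_adjacent_rho = numeric(),
                      probe_ids = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Call region amplification per sample
#'
#' For each sample, computes a per-gene log2 copy ratio as the
#' overlap-length-weighted mean of the sample's segments intersecting the
#' gene interval, then calls the sample amplified when every region gene's
#' ratio strictly exceeds \code{ratioMin}. A gene with no overlapping
#' segment leaves the sample not callable (reported separately, never
#' called amplified).
#'
#' @param segments segment table
#' @param regionGenes data.frame: gene, chromosome, start, end (1-based
#'   inclusive gene intervals inside the region)
#' @param ratioMin amplification threshold on the log2 copy ratio
#'   (default 0.2, strict \code{>})
#' @return data.frame with sample_id, amplified, callable, and one
#'   \code{ratio_<gene>} column per region gene
#' @export
callAmplification <- function(segments, regionGenes, ratioMin = 0.2) {
  segments$chromosome <- normalizeChrom(segments$chromosome)
  regionGenes$chromosome <- normalizeChrom(regionGenes$chromosome)
  geneGr <- GenomicRanges::GRanges(
    regionGenes$chromosome,
    IRanges::IRanges(regionGenes$start, regionGenes$end))
  samples <- unique(segments$sample_id)
  ratios <- matrix(NA_real_, length(samples), nrow(regionGenes),
                   dimnames = list(samples, regionGenes$gene))
  for (si in seq_along(samples)) {
    seg <- segments[segments$sample_id == samples[si], , drop = FALSE]
    if (!nrow(seg)) next
    segGr <- GenomicRanges::GRanges(
      seg$chromosome, IRanges::IRanges(seg$start, seg$end))
    hits <- GenomicRanges::findOverlaps(geneGr, segGr)
    if (!length(hits)) next
    ov <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(geneGr)[S4Vectors::queryHits(hits)],
      IRanges::ranges(segGr)[S4Vectors::subjectHits(hits)]))
    lr <- seg$log2_ratio[S4Vectors::subjectHits(hits)]
    for (g in unique(S4Vectors::queryHits(hits))) {
      w <- ov[S4Vectors::queryHits(hits) == g]
      v <- lr[S4Vectors::queryHits(hits) == g]
      ratios[si, g] <- sum(v * w) / sum(w)
    }
  }
  callable <- !apply(is.na(ratios), 1, any)
  amplified <- callable & apply(ratios > ratioMin, 1, all)
  out <- data.frame(sample_id = samples, amplified = amplified,
                    callable = callable, row.names = NULL,
                    stringsAsFactors = FALSE)
  colnames(ratios) <- paste0("ratio_", regionGenes$gene)
  cbind(out, as.data.frame(ratios, row.names = NULL))
}

#' Compare two block sets for preservation
#'
#' Pairs each block of one list with the block of the other list maximising
#' the Jaccard index of their probe sets; a block is preserved when that
#' best Jaccard is at least 0.5 (reciprocal >= 50% probe overlap).
#'
#' @param blocksA,blocksB data.frames from [findBlocks()] on the same
#'   coordinate system
#' @return list: n_a, n_b, preserved_a, preserved_b, and a pairing
#'   data.frame (block_a, block_b, jaccard)
#' @export
compareBlockSets <- function(blocksA, blocksB) {
  pa <- strsplit(blocksA$probe_ids, ",")
  pb <- strsplit(blocksB$probe_ids, ",")
  jac <- function(x, y) {
    u <- length(union(x, y))
    if (u == 0) 0 else length(intersect(x, y)) / u
  }
  bestJ <- function(sets, others) {
    vapply(sets, function(s) {
      if (!length(others)) return(0)
      max(vapply(others, jac, numeric(1), x = s))
    }, numeric(1))
  }
  ja <- bestJ(pa, pb)
  jb <- bestJ(pb, pa)
  pairs <- if (length(pa) && length(pb)) {
    data.frame(block_a = seq_along(pa),
               block_b = vapply(pa, function(s)
                 which.max(vapply(pb, jac, numeric(1), x = s)), integer(1)),
               jaccard = ja)
  } else data.frame(block_a = integer(), block_b = integer(),
                    jaccard = numeric())
  list(n_a = length(pa), n_b = length(pb),
       preserved_a = sum(ja >= 0.5), preserved_b = sum(jb >= 0.5),
       pairs = pairs)
}
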