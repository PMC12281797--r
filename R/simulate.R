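## Synthetic-data generators with planted ground truth. Every generator is
## fully determined by cfg$seed; all noise is applied on the logit (M) scale
## so beta values stay inside (0,1) and effects compose additively.

## Approximate hg19 chromosome lengths (bp), autosomes.
HG19_LENGTHS <- c(
  chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
  chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
  chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
  chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
  chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
  chr21 = 48129895, chr22 = 51304566)

#' hg19 autosome lengths
#' @return named numeric vector of chromosome lengths in bp
#' @export
hg19ChromLengths <- function() HG19_LENGTHS

#' Generator configuration
#'
#' Collects every knob of the synthetic-data module with the study-like
#' defaults: 2000 probes, 16 pre/post pairs, 6 tissues x 20 subjects,
#' 2 tumor cohorts x 100 samples, planted differential probes at
#' \eqn{\Delta\beta = 0.15} with a majority hypermethylated before surgery,
#' within-pair M-scale noise 0.5. Unknown names are rejected.
#'
#' @param seed integer master seed; fully determines every output
#' @param ... overrides of the defaults listed in the function definition
#' @return a validated config list of class \code{"simConfig"}
#' @export
simConfig <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    nProbes = 2000,
    chromosomes = names(HG19_LENGTHS),
    islandRelationMix = c(island = 0.25, shore = 0.20, shelf = 0.15,
                          opensea = 0.40),
    ## paired pre/post cohort
    nPairs = 16,
    plantedDmpFraction = 0.05,
    deltaBeta = 0.15,
    dmpDirectionMix = 0.3,      # fraction hyper in post (majority hypo:
                                # hypermethylated before surgery)
    subjectSdM = 1.0,
    noiseSdM = 0.5,
    ## multi-tissue repeated measures
    tissues = c("skeletal muscle", "whole blood", "lung", "colon",
                "kidney", "breast"),
    nSubjects = 20,
    iccSigmaB2 = 1.0,           # per-probe between-subject variance (M^2)
    iccSigmaW2 = 1.0,           # per-probe within-subject variance (M^2)
    tissueOffsetSd = 0,
    ## control/replicate technical pairs
    nReplicatePairs = 3,
    replicateNoiseSd = 0.15,
    ## tumor cohorts
    cohorts = c("LSCC", "LUAD"),
    nTumorSamples = 100,
    cnvSegmentsPerChrom = 1.5,
    cnvAmplitudeSd = 0.3,
    couplingStrength = 0.5,     # score-probe association with instability
    nMutGenes = 40,
    nEffectGenes = 5,
    mutationEffectSize = 1.0,   # M-scale shift of signature probes
    nSignatureProbes = 20,
    amplifiedFraction = 0.5,
    chainLength = 6,
    ageMean = 65, ageSd = 8)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("simConfig: unknown field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  for (f in c("plantedDmpFraction", "dmpDirectionMix", "amplifiedFraction"))
    stopIfNotFraction(cfg[[f]], f)
  structure(cfg, class = "simConfig")
}

## logit-normal bimodal baseline: modes near beta = 0.1 and 0.85
.bimodalBaselineM <- function(n, pLow = 0.5) {
  low <- runif(n) < pLow
  ifelse(low, rnorm(n, logit2(0.10), 0.8), rnorm(n, logit2(0.85), 0.8))
}

#' Generate a probe manifest
#'
#' Probe positions follow a mixture spacing (clustered ~300 bp gaps with
#' occasional >1 kb jumps, exercising the position-gap boundary); probes are
#' grouped into short genes with a fraction left intergenic; island
#' relations follow the configured mix.
#'
#' @param cfg a [simConfig()]
#' @return manifest data.frame
#' @export
genManifest <- function(cfg) {
  set.seed(cfg$seed + 101L)
  n <- cfg$nProbes
  chroms <- sample(cfg$chromosomes, n, replace = TRUE)
  df <- data.frame(probe_id = sprintf("cg%07d", seq_len(n)),
                   chromosome = chroms, stringsAsFactors = FALSE)
  df <- df[order(match(df$chromosome, cfg$chromosomes)), ]
  pos <- numeric(n); i <- 1
  for (chr in unique(df$chromosome)) {
    k <- sum(df$chromosome == chr)
    gaps <- ifelse(runif(k) < 0.85,
                   rgamma(k, shape = 3, scale = 100),   # median ~ 300 bp
                   1000 + rgamma(k, shape = 2, scale = 800))
    pos[i:(i + k - 1)] <- 1e6 + round(cumsum(gaps))
    i <- i + k
  }
  df$position <- pos
  ## genes: runs of 1-5 consecutive probes; ~25% intergenic
  gene <- character(n); region <- character(n)
  gi <- 0; i <- 1
  while (i <= n) {
    run <- sample(1:5, 1)
    idx <- i:min(n, i + run - 1)
    if (runif(1) < 0.25) {
      gene[idx] <- ""
      region[idx] <- "IGR"
    } else {
      gi <- gi + 1
      gene[idx] <- sprintf("GENE%04d", gi)
      region[idx] <- sample(setdiff(GENE_REGIONS, "IGR"), length(idx),
                            replace = TRUE)
    }
    i <- max(idx) + 1
  }
  df$gene <- gene
  df$gene_region <- region
  df$island_relation <- sample(names(cfg$islandRelationMix), n,
                               replace = TRUE, prob = cfg$islandRelationMix)
  rownames(df) <- NULL
  df
}

#' Generate a paired pre/post weight-loss cohort
#'
#' Baseline probe methylation is drawn from a bimodal logit-normal mixture;
#' a configured fraction of probes carries a planted post-minus-pre shift of
#' \code{deltaBeta} on the beta scale (majority hypomethylated after surgery
#' by default, i.e. hypermethylated before). Subject effects and measurement
#' noise act on the M scale. If a baseline sits too close to the boundary
#' for the full shift, the shift is shrunk with a warning.
#'
#' @param cfg a [simConfig()]
#' @param truth optional truth table from a previous call: replicating
#'   cohorts of the same intervention share the planted probe set and
#'   directions while drawing their own subjects and noise
#' @return list: \code{beta} (\linkS4class{BetaSet} with sample sheet in
#'   colData), \code{samples}, \code{manifest}, \code{truth} (per-probe
#'   is_dmp, direction, delta_beta)
#' @export
genPairedCohort <- function(cfg, truth = NULL) {
  manifest <- genManifest(cfg)
  set.seed(cfg$seed + 202L)
  n <- cfg$nProbes; np <- cfg$nPairs
  probeIds <- manifest$probe_id
  baseM <- .bimodalBaselineM(n)
  baseB <- expit2(baseM)

  if (!is.null(truth)) {
    if (nrow(truth) != n)
      stop("genPairedCohort: truth table does not match nProbes")
    isDmp <- truth$is_dmp[match(probeIds, truth$probe_id)]
    dir <- ifelse(truth$direction[match(probeIds, truth$probe_id)] == "hyper",
                  1, -1)
  } else {
  nDmp <- round(cfg$plantedDmpFraction * n)
  isDmp <- logical(n)
  if (nDmp > 0) isDmp[sample.int(n, nDmp)] <- TRUE
  dir <- ifelse(runif(n) < cfg$dmpDirectionMix, 1, -1)  # +1: hyper in post
  }
  delta <- ifelse(isDmp, dir * cfg$deltaBeta, 0)
  postB <- baseB + delta
  margin <- 0.02
  shrunk <- postB < margin | postB > 1 - margin
  if (any(shrunk & isDmp)) {
    warning("genPairedCohort: shrank planted delta for ",
            sum(shrunk & isDmp), " probe(s) near the beta boundary")
    postB <- clamp(postB, margin, 1 - margin)
  }
  preM <- logit2(clamp(baseB, 1e-4, 1 - 1e-4))
  postM <- logit2(clamp(postB, 1e-4, 1 - 1e-4))

  subj <- sprintf("SUBJ%02d", seq_len(np))
  u <- rnorm(np, 0, cfg$subjectSdM)
  mkSamp <- function(meanM) {
    vapply(seq_len(np), function(s)
      meanM + u[s] + rnorm(n, 0, cfg$noiseSdM), numeric(n))
  }
  mPre <- mkSamp(preM); mPost <- mkSamp(postM)
  beta <- expit2(cbind(mPre, mPost))
  ids <- c(paste0(subj, "_pre"), paste0(subj, "_post"))
  dimnames(beta) <- list(probeIds, ids)
  samples <- data.frame(
    sample_id = ids,
    subject_id = rep(subj, 2),
    tissue = "skeletal muscle",
    sex = rep(rep(c("M", "F"), length.out = np), 2),
    group = rep(c("pre", "post"), each = np),
    age = rep(round(rnorm(np, 48, 9)), 2),
    bmi = rep(round(rnorm(np, 42, 5), 1), 2),
    tmb = NA_real_, stringsAsFactors = FALSE)
  truth <- data.frame(probe_id = probeIds, is_dmp = isDmp,
                      direction = ifelse(isDmp,
                                         ifelse(dir > 0, "hyper", "hypo"),
                                         ""),
                      delta_beta = ifelse(isDmp, expit2(postM) - baseB, 0),
                      stringsAsFactors = FALSE)
  list(beta = BetaSet(beta, samples), samples = samples,
       manifest = manifest, truth = truth)
}

#' Generate a multi-tissue repeated-measures cohort
#'
#' Per probe: M-value = baseline + subject effect N(0, sigma_b) + tissue
#' offset + noise N(0, sigma_w), so the planted intraclass correlation is
#' \eqn{\sigma_b^2/(\sigma_b^2+\sigma_w^2)} (recorded in the truth table;
#' exact when tissue offsets are 0, the default).
#'
#' @param cfg a [simConfig()]; \code{iccSigmaB2}/\code{iccSigmaW2} may be
#'   vectors recycled over probes
#' @return list: beta (BetaSet), samples, truth (per-probe true_icc)
#' @export
genMultitissue <- function(cfg) {
  set.seed(cfg$seed + 303L)
  n <- cfg$nProbes; ns <- cfg$nSubjects
  tissues <- cfg$tissues
  if (length(tissues) < 2) stop("genMultitissue: need >= 2 tissues")
  sb2 <- rep_len(cfg$iccSigmaB2, n)
  sw2 <- rep_len(cfg$iccSigmaW2, n)
  probeIds <- sprintf("cg%07d", seq_len(n))
  baseM <- .bimodalBaselineM(n)
  tissOff <- matrix(rnorm(n * length(tissues), 0, cfg$tissueOffsetSd),
                    n, length(tissues))
  subjEff <- matrix(rnorm(n * ns), n, ns) * sqrt(sb2)
  cols <- list(); ids <- character(); meta <- list()
  for (ti in seq_along(tissues)) for (s in seq_len(ns)) {
    m <- baseM + subjEff[, s] + tissOff[, ti] + rnorm(n) * sqrt(sw2)
    cols[[length(cols) + 1]] <- expit2(m)
    ids <- c(ids, sprintf("SUBJ%02d_%s", s, gsub(" ", "", tissues[ti])))
    meta[[length(meta) + 1]] <- data.frame(
      sample_id = ids[length(ids)], subject_id = sprintf("SUBJ%02d", s),
      tissue = tissues[ti],
      sex = if (s %% 2) "M" else "F", group = "gtex",
      age = NA_real_, bmi = NA_real_, tmb = NA_real_,
      stringsAsFactors = FALSE)
  }
  beta <- do.call(cbind, cols)
  dimnames(beta) <- list(probeIds, ids)
  samples <- do.call(rbind, meta)
  truth <- data.frame(probe_id = probeIds,
                      sigma_b2 = sb2, sigma_w2 = sw2,
                      true_icc = sb2 / (sb2 + sw2),
                      stringsAsFactors = FALSE)
  list(beta = BetaSet(beta, samples), samples = samples, truth = truth)
}

#' Generate control/replicate technical pairs
#'
#' Replicates are controls plus logit-scale noise; because the change rate
#' divides by the control value, low-beta probes show inflated rates by
#' construction.
#'
#' @param cfg a [simConfig()]
#' @return list: beta (BetaSet), pairs (control/replicate sample ids)
#' @export
genReplicates <- function(cfg) {
  set.seed(cfg$seed + 404L)
  n <- cfg$nProbes; npair <- cfg$nReplicatePairs
  probeIds <- sprintf("cg%07d", seq_len(n))
  baseM <- .bimodalBaselineM(n)
  ctrl <- vapply(seq_len(npair), function(i)
    expit2(baseM + rnorm(n, 0, 0.2)), numeric(n))
  repl <- if (cfg$replicateNoiseSd == 0) ctrl else
    expit2(logit2(clamp(ctrl, 1e-6, 1 - 1e-6)) +
             matrix(rnorm(n * npair, 0, cfg$replicateNoiseSd),
                    n, npair))
  beta <- cbind(ctrl, repl)
  ids <- c(sprintf("CTRL%02d", seq_len(npair)),
           sprintf("REPL%02d", seq_len(npair)))
  dimnames(beta) <- list(probeIds, ids)
  pairs <- data.frame(control = ids[seq_len(npair)],
                      replicate = ids[npair + seq_len(npair)],
                      stringsAsFactors = FALSE)
  list(beta = BetaSet(beta), pairs = pairs)
}

#' Generate tumor cohorts with CNV, mutations and clinical covariates
#'
#' Per cohort: each sample carries a latent instability level driving both
#' its CNV segment amplitudes (hence the CIN score) and, through
#' \code{couplingStrength}, the methylation of the signature probes — so a
#' score fitted on those probes correlates with CIN by construction.
#' Mutations are Bernoulli per gene; a chosen subset of genes shifts the
#' signature probes in mutated samples. Half the samples (by default) are
#' amplified in a 19q12-13.12-like region (all region genes gained at
#' log2 ratio > 0.2) and carry a planted co-methylated probe chain there.
#' TMB is generated correlated with instability.
#'
#' @param cfg a [simConfig()]
#' @return list: beta, samples, manifest, segments, mutations, regionGenes,
#'   chromLengths, truth (per-sample signal level and amplification,
#'   effect genes, signature and chain probes)
#' @export
genTumorCohort <- function(cfg) {
  manifest <- genManifest(cfg)
  set.seed(cfg$seed + 505L)
  n <- cfg$nProbes
  region <- c(start = 28493000, end = 37754420)   # 19q12-13.12-like
  ## re-home the planted chain + signature context: take chainLength probes,
  ## place them inside the region on chr19 with tight spacing
  chainIdx <- seq_len(cfg$chainLength)
  chainProbes <- sprintf("cgCHAIN%02d", chainIdx)
  chainMan <- data.frame(
    probe_id = chainProbes, chromosome = "chr19",
    position = region["start"] + 500000 + (chainIdx - 1) * 200,
    gene = "CCNE1L", gene_region = "body", island_relation = "opensea",
    stringsAsFactors = FALSE)
  manifest <- rbind(manifest, chainMan)
  regionGenes <- data.frame(
    gene = c("CCNE1L", "URI1L", "ZNF536L"),
    chromosome = "chr19",
    start = region["start"] + c(4e5, 3e6, 6e6),
    end = region["start"] + c(8e5, 3.5e6, 6.6e6),
    stringsAsFactors = FALSE)

  probeIds <- c(manifest$probe_id)
  baseM <- c(.bimodalBaselineM(n), rnorm(cfg$chainLength, 0, 0.3))
  sigProbes <- sample(manifest$probe_id[seq_len(n)], cfg$nSignatureProbes)
  sigIdx <- match(sigProbes, probeIds)
  chainIdxAll <- match(chainProbes, probeIds)

  mutGenes <- sprintf("MUT%03d", seq_len(cfg$nMutGenes))
  effectGenes <- sample(mutGenes, cfg$nEffectGenes)
  mutRate <- setNames(runif(cfg$nMutGenes, 0.04, 0.25), mutGenes)

  allBeta <- list(); allSamples <- list(); allSegs <- list()
  allMuts <- list(); allTruth <- list()
  for (co in cfg$cohorts) {
    ns <- cfg$nTumorSamples
    ids <- sprintf("%s_T%03d", co, seq_len(ns))
    u <- rgamma(ns, shape = 2, scale = 0.5)          # instability level
    amplified <- rep(FALSE, ns)
    amplified[sample.int(ns, round(cfg$amplifiedFraction * ns))] <- TRUE

    ## CNV segments: disjoint random partitions per chromosome
    segs <- list()
    for (s in seq_len(ns)) {
      for (chr in names(HG19_LENGTHS)) {
        nseg <- stats::rpois(1, cfg$cnvSegmentsPerChrom)
        if (chr == "chr19") nseg <- max(nseg, 0)
        if (nseg > 0) {
          len <- HG19_LENGTHS[[chr]]
          lo <- if (chr == "chr19") region["end"] + 1 else 1  # keep the
          ## managed region free on chr19
          if (lo < len - 1e6) {
            bp <- sort(sample.int(len - lo + 1, 2 * nseg) + lo - 1)
            st <- bp[seq(1, 2 * nseg, 2)]; en <- bp[seq(2, 2 * nseg, 2)]
            keep <- en > st
            if (any(keep))
              segs[[length(segs) + 1]] <- data.frame(
                sample_id = ids[s], chromosome = chr,
                start = st[keep], end = en[keep],
                log2_ratio = rnorm(sum(keep), 0, cfg$cnvAmplitudeSd *
                                     (0.3 + u[s])),
                stringsAsFactors = FALSE)
          }
        }
      }
      ## the managed 19q region: one segment spanning all region genes
      segs[[length(segs) + 1]] <- data.frame(
        sample_id = ids[s], chromosome = "chr19",
        start = region[["start"]], end = region[["end"]],
        log2_ratio = if (amplified[s]) runif(1, 0.35, 0.8)
                     else rnorm(1, 0, 0.05),
        stringsAsFactors = FALSE)
    }
    segs <- do.call(rbind, segs)

    ## mutations
    mut <- matrix(runif(ns * cfg$nMutGenes) <
                    matrix(mutRate, ns, cfg$nMutGenes, byrow = TRUE),
                  ns, cfg$nMutGenes, dimnames = list(ids, mutGenes))
    mutDf <- data.frame(sample_id = rep(ids, cfg$nMutGenes)[as.vector(mut)],
                        gene = rep(mutGenes, each = ns)[as.vector(mut)],
                        variant_class = "Missense_Mutation",
                        stringsAsFactors = FALSE)

    ## methylation: signature probes carry the instability coupling and the
    ## mutation effects; chain probes share a latent factor in amplified
    ## samples
    zU <- as.numeric(scale(u))
    effShift <- rowSums(mut[, effectGenes, drop = FALSE]) *
      cfg$mutationEffectSize
    m <- matrix(baseM, length(probeIds), ns) +
      matrix(rnorm(length(probeIds) * ns, 0, 0.4), length(probeIds), ns)
    m[sigIdx, ] <- m[sigIdx, ] +
      rep(cfg$couplingStrength * zU + effShift, each = length(sigIdx))
    lat <- rnorm(ns)
    m[chainIdxAll, ] <- matrix(baseM[chainIdxAll], cfg$chainLength, ns) +
      outer(rep(1.5, cfg$chainLength), ifelse(amplified, lat, 0)) +
      matrix(rnorm(cfg$chainLength * ns, 0,
                   ifelse(rep(amplified, each = cfg$chainLength), 0.2, 1)),
             cfg$chainLength, ns)
    beta <- expit2(m)
    dimnames(beta) <- list(probeIds, ids)

    samples <- data.frame(
      sample_id = ids, subject_id = ids, tissue = "tumor",
      sex = sample(c("M", "F"), ns, replace = TRUE),
      group = "tumor", cohort = co,
      age = round(rnorm(ns, cfg$ageMean, cfg$ageSd)),
      bmi = round(rnorm(ns, 27, 4), 1),
      tmb = round(2 + 3 * u + rnorm(ns, 0, 1.5), 2),
      stringsAsFactors = FALSE)

    allBeta[[co]] <- beta
    allSamples[[co]] <- samples
    allSegs[[co]] <- segs
    allMuts[[co]] <- mutDf
    allTruth[[co]] <- data.frame(sample_id = ids, cohort = co,
                                 true_signal_level = u,
                                 amplified = amplified,
                                 stringsAsFactors = FALSE)
  }
  beta <- do.call(cbind, allBeta)
  samples <- do.call(rbind, allSamples); rownames(samples) <- NULL
  truthSamples <- do.call(rbind, allTruth); rownames(truthSamples) <- NULL
  list(beta = BetaSet(beta, samples),
       samples = samples,
       manifest = manifest,
       segments = do.call(rbind, allSegs),
       mutations = do.call(rbind, allMuts),
       regionGenes = regionGenes,
       chromLengths = HG19_LENGTHS,
       truth = list(samples = truthSamples,
                    effect_genes = effectGenes,
                    signature_probes = sigProbes,
                    chain_probes = chainProbes))
}
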