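#' Chromosome instability score from CNV segments
#'
#' Per chromosome, sums \eqn{|log2\ ratio| \times segment\ length /
#' chromosome\ length} over a sample's segments; the total is the sum across
#' chromosomes. Length weighting makes the score additive over disjoint
#' segment sets and invariant to splitting a segment in two. Alternative
#' weightings: \code{"count"} (number of non-neutral segments) and
#' \code{"amplitude"} (plain sum of |log2 ratio|).
#'
#' @param segments segment table (sample_id, chromosome, start, end,
#'   log2_ratio; 1-based inclusive)
#' @param chromLengths named vector, chromosome -> length in bp
#' @param weighting \code{"length"} (default), \code{"count"} or
#'   \code{"amplitude"}
#' @param samples optional sample ids to report (default: those present);
#'   samples without segments score 0
#' @return data.frame: sample_id, one column per chromosome, and total
#' @export
cinScore <- function(segments, chromLengths,
                     weighting = c("length", "count", "amplitude"),
                     samples = NULL) {
  weighting <- match.arg(weighting)
  segments$chromosome <- normalizeChrom(segments$chromosome)
  names(chromLengths) <- normalizeChrom(names(chromLengths))
  unknown <- setdiff(unique(segments$chromosome), names(chromLengths))
  if (length(unknown))
    stop("cinScore: chromosome(s) without length: ",
         paste(unknown, collapse = ", "))
  if (is.null(samples)) samples <- unique(segments$sample_id)
  chroms <- names(chromLengths)
  contrib <- switch(weighting,
    length = abs(segments$log2_ratio) *
      (segments$end - segments$start + 1) /
      chromLengths[segments$chromosome],
    count = as.numeric(segments$log2_ratio != 0),
    amplitude = abs(segments$log2_ratio))
  mat <- matrix(0, length(samples), length(chroms),
                dimnames = list(samples, chroms))
  agg <- tapply(contrib, list(factor(segments$sample_id, levels = samples),
                              factor(segments$chromosome, levels = chroms)),
                sum)
  agg[is.na(agg)] <- 0
  mat[] <- agg
  out <- data.frame(sample_id = samples, mat, total = rowSums(mat),
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out
}

#' Spearman screen of the score against clinical covariates
#'
#' Spearman rank correlation (tie-corrected) of the methylation score with
#' BMI, age, TMB and the total CIN score, with pairwise deletion of missing
#' covariates and BH adjustment across the screened covariates. A constant
#' vector leaves rho undefined (NA, flagged).
#'
#' @param scores data.frame from [scoreSamples()]
#' @param samples sample sheet (bmi, age, tmb columns used when present)
#' @param cin optional data.frame from [cinScore()]; adds covariate
#'   \code{CIN}
#' @return data.frame: covariate, rho, p_raw, p_adj, n
#' @export
covariateScreen <- function(scores, samples, cin = NULL) {
  covs <- list()
  idx <- match(scores$sample_id, samples$sample_id)
  for (v in c("bmi", "age", "tmb"))
    if (v %in% names(samples)) covs[[toupper(v)]] <- samples[[v]][idx]
  if (!is.null(cin))
    covs[["CIN"]] <- cin$total[match(scores$sample_id, cin$sample_id)]
  if (!length(covs)) stop("covariateScreen: no covariates available")
  res <- lapply(names(covs), function(nm) {
    x <- scores$score; y <- covs[[nm]]
    keep <- !is.na(x) & !is.na(y)
    n <- sum(keep)
    if (n < 3)
      return(data.frame(covariate = nm, rho = NA_real_, p_raw = NA_real_,
                        n = n))
    if (sd(x[keep]) == 0 || sd(y[keep]) == 0) {
      warning("covariateScreen: constant vector for ", nm,
              "; rho undefined")
      return(data.frame(covariate = nm, rho = NA_real_, p_raw = NA_real_,
                        n = n))
    }
    ct <- suppressWarnings(stats::cor.test(x[keep], y[keep],
                                           method = "spearman"))
    data.frame(covariate = nm, rho = unname(ct$estimate),
               p_raw = ct$p.value, n = n)
  })
  out <- do.call(rbind, res)
  out$p_adj <- bhAdjust(out$p_raw)
  out[, c("covariate", "rho", "p_raw", "p_adj", "n")]
}

#' Per-chromosome regression of score on instability, by age subgroup
#'
#' Ordinary least squares of the methylation score on each chromosome's
#' instability value, fitted separately within age subgroups (\code{>= ageCut}
#' = older; the boundary age is assigned to the older subgroup) and, when a
#' cohort column is available, within cohorts. P-values are two-sided from
#' the t distribution and BH-adjusted across chromosomes within each
#' (cohort, subgroup). Degenerate predictors (zero variance) and subgroups
#' with fewer than \code{minN} samples are skipped with a note column.
#'
#' @param scores data.frame from [scoreSamples()]
#' @param cin data.frame from [cinScore()] (per-chromosome columns)
#' @param samples sample sheet with \code{age} (and optionally
#'   \code{cohort})
#' @param ageCut subgroup boundary in years (default 65)
#' @param minN minimum subgroup size (default 5)
#' @return data.frame: cohort, age_group, chromosome, slope, p_raw, p_adj, n
#' @export
perChromosomeRegression <- function(scores, cin, samples, ageCut = 65,
                                    minN = 5) {
  idx <- match(scores$sample_id, samples$sample_id)
  age <- samples$age[idx]
  cohort <- if ("cohort" %in% names(samples)) samples$cohort[idx]
            else rep("all", nrow(scores))
  ageGroup <- ifelse(is.na(age), NA_character_,
                     ifelse(age >= ageCut, paste0(">=", ageCut),
                            paste0("<", ageCut)))
  cmat <- cin[match(scores$sample_id, cin$sample_id), , drop = FALSE]
  chroms <- setdiff(names(cmat), c("sample_id", "total"))
  rows <- list()
  for (co in unique(cohort)) for (ag in unique(na.omit(ageGroup))) {
    sel <- which(cohort == co & !is.na(ageGroup) & ageGroup == ag)
    if (length(sel) < minN) next
    sub <- data.frame(chromosome = chroms, slope = NA_real_,
                      p_raw = NA_real_, n = length(sel),
                      note = "", stringsAsFactors = FALSE)
    for (i in seq_along(chroms)) {
      x <- cmat[sel, chroms[i]]
      y <- scores$score[sel]
      if (sd(x) == 0) { sub$note[i] <- "degenerate predictor"; next }
      fit <- lm(y ~ x)
      sm <- summary(fit)$coefficients
      sub$slope[i] <- sm["x", "Estimate"]
      sub$p_raw[i] <- sm["x", "Pr(>|t|)"]
    }
    sub$p_adj <- bhAdjust(sub$p_raw)
    sub <- cbind(cohort = co, age_group = ag, sub)
    rows[[length(rows) + 1]] <- sub
  }
  if (!length(rows))
    stop("perChromosomeRegression: no (cohort, age-subgroup) with n >= ",
         minN)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Binarize a mutation table
#'
#' Collapses MAF-like events to a samples-by-genes logical matrix: TRUE when
#' the sample carries at least one event of a qualifying (non-synonymous)
#' variant class in the gene. Per-gene mutation rates are column means over
#' the full cohort.
#'
#' @param mutations mutation table (sample_id, gene, variant_class)
#' @param samples character vector of cohort sample ids (defines rows and
#'   the rate denominator)
#' @param nonSynClasses variant classes counted as mutant; default the
#'   MAF-style non-synonymous set
#' @return logical matrix with attribute \code{"mutation_rate"}
#' @export
binarizeMutations <- function(mutations, samples,
                              nonSynClasses = c("Missense_Mutation",
                                "Nonsense_Mutation", "Frame_Shift_Del",
                                "Frame_Shift_Ins", "In_Frame_Del",
                                "In_Frame_Ins", "Splice_Site",
                                "Translation_Start_Site", "Nonstop_Mutation")) {
  mut <- mutations[mutations$variant_class %in% nonSynClasses &
                     mutations$sample_id %in% samples, , drop = FALSE]
  genes <- sort(unique(mut$gene))
  mat <- matrix(FALSE, length(samples), length(genes),
                dimnames = list(samples, genes))
  if (nrow(mut))
    mat[cbind(match(mut$sample_id, samples), match(mut$gene, genes))] <- TRUE
  attr(mat, "mutation_rate") <- colMeans(mat)
  mat
}

## Exact two-sided Mann-Whitney p by full enumeration of rank assignments.
## Handles ties via midranks; feasible for n1 + n2 choose n1 up to ~1e5.
exactRankSumP <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  wObs <- sum(r[seq_len(nx)])
  combs <- combn(nx + ny, nx)
  ws <- colSums(matrix(r[combs], nrow = nx))
  mu <- nx * (nx + ny + 1) / 2
  mean(abs(ws - mu) >= abs(wObs - mu) - 1e-12)
}

#' Mutation effect on the methylation score
#'
#' Per gene, compares scores of mutant vs wild-type samples with a two-sided
#' Wilcoxon rank-sum test: exact by full enumeration when both groups have
#' at most \code{exactMax} samples (ties handled via midranks), otherwise
#' the normal approximation with tie and continuity correction. Only genes
#' with mutation rate strictly above \code{minRate} are tested; genes that
#' are all-mutant or all-wild after the filter are excluded with a note. BH
#' adjustment is across tested genes. Effect direction is the sign of the
#' mutant-minus-wild median score difference.
#'
#' @param scores data.frame from [scoreSamples()]
#' @param mutations logical matrix from [binarizeMutations()] (rows must
#'   cover the scored samples)
#' @param minRate minimum cohort mutation rate (default 0.03, strict
#'   \code{>})
#' @param exactMax group-size bound for the exact test (default 8)
#' @return data.frame: gene, n_mut, n_wt, rate, statistic (rank-sum W),
#'   p_raw, p_adj, direction
#' @export
mutationScoreTest <- function(scores, mutations, minRate = 0.03,
                              exactMax = 8) {
  common <- intersect(scores$sample_id, rownames(mutations))
  if (length(common) < 3) stop("mutationScoreTest: too few scored samples")
  sc <- scores$score[match(common, scores$sample_id)]
  mut <- mutations[common, , drop = FALSE]
  rate <- colMeans(mut)
  genes <- colnames(mut)[rate > minRate & rate < 1]
  rows <- list()
  for (g in genes) {
    xm <- sc[mut[, g]]; xw <- sc[!mut[, g]]
    if (!length(xm) || !length(xw)) next
    if (length(xm) <= exactMax && length(xw) <= exactMax) {
      p <- exactRankSumP(xm, xw)
      W <- sum(rank(c(xm, xw))[seq_along(xm)]) -
        length(xm) * (length(xm) + 1) / 2
    } else {
      wt <- suppressWarnings(wilcox.test(xm, xw, exact = FALSE,
                                         correct = TRUE))
      p <- wt$p.value
      W <- unname(wt$statistic)
    }
    rows[[g]] <- data.frame(
      gene = g, n_mut = length(xm), n_wt = length(xw),
      rate = unname(rate[g]), statistic = W, p_raw = p,
      direction = sign(median(xm) - median(xw)),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(gene = character(), n_mut = integer(),
                      n_wt = integer(), rate = numeric(),
                      statistic = numeric(), p_raw = numeric(),
                      direction = numeric(), p_adj = numeric()))
  out <- do.call(rbind, rows)
  out$p_adj <- bhAdjust(out$p_raw)
  rownames(out) <- NULL
  out[, c("gene", "n_mut", "n_wt", "rate", "statistic", "p_raw", "p_adj",
          "direction")]
}

#' Two-hit classification of genes
#'
#' A gene is a "two-hit" gene when it is both significantly score-associated
#' by mutation (BH-adjusted Wilcoxon p < alpha) and carries a significant
#' differential methylation probe.
#'
#' @param mutResults data.frame from [mutationScoreTest()]
#' @param diffProbeGenes character vector of genes with significant
#'   differential probes
#' @param alpha adjusted significance level (default 0.05)
#' @return data.frame: gene, mutated_significant, methylation_hit, two_hit
#' @export
twoHitClassify <- function(mutResults, diffProbeGenes, alpha = 0.05) {
  ms <- !is.na(mutResults$p_adj) & mutResults$p_adj < alpha
  mh <- mutResults$gene %in% diffProbeGenes
  data.frame(gene = mutResults$gene,
             mutated_significant = ms,
             methylation_hit = mh,
             two_hit = ms & mh,
             stringsAsFactors = FALSE)
}
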