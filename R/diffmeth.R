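#' Paired differential methylation with empirical-Bayes moderation
#'
#' Tests each probe's within-subject M-value difference (group2 minus group1)
#' with a moderated paired t-statistic: per-probe sample variances are shrunk
#' toward a common prior \eqn{(d_0, s_0^2)} estimated by method of moments
#' from the distribution of log sample variances, exactly the scaled-F model
#' underlying empirical-Bayes variance moderation. Shrinkage keeps
#' zero-variance probes finite. P-values are two-sided from the t distribution
#' on \eqn{d_0 + (n-1)} degrees of freedom and BH-adjusted across probes.
#'
#' A probe is declared significant when \code{p_adj < alpha} and
#' \code{|logFC| >= logfcMin}, where logFC is the mean paired M difference.
#' The companion \code{delta_beta} (mean paired difference on the beta scale)
#' is reported but not thresholded.
#'
#' @param mm an \linkS4class{MValueSet}
#' @param subject,group per-sample vectors; taken from \code{colData} columns
#'   \code{subject_id} and \code{group} when omitted
#' @param groupLevels length-2 character giving (group1, group2); differences
#'   are group2 minus group1. Defaults to sorted unique group labels.
#' @param logfcMin minimum |logFC| for significance (default 0.1)
#' @param alpha BH-adjusted significance level (default 0.05)
#' @param moderated if FALSE, use the ordinary paired t (oracle mode)
#' @return data.frame with columns probe_id, delta_beta, logFC, t_stat,
#'   df_total, p_raw, p_adj, direction (hyper/hypo relative to group2),
#'   significant; prior estimates in attributes \code{d0}, \code{s0_sq}.
#' @export
pairedDMP <- function(mm, subject = NULL, group = NULL, groupLevels = NULL,
                      logfcMin = 0.1, alpha = 0.05, moderated = TRUE) {
  cd <- SummarizedExperiment::colData(mm)
  if (is.null(subject)) subject <- cd$subject_id
  if (is.null(group)) group <- cd$group
  if (is.null(subject) || is.null(group))
    stop("pairedDMP: subject and group must be supplied or present in colData")
  subject <- as.character(subject); group <- as.character(group)
  if (is.null(groupLevels)) groupLevels <- sort(unique(group))
  if (length(groupLevels) != 2 || !all(group %in% groupLevels))
    stop("pairedDMP: exactly two group levels required")
  g1 <- groupLevels[1]; g2 <- groupLevels[2]
  for (s in unique(subject)) {
    gs <- group[subject == s]
    if (sum(gs == g1) != 1 || sum(gs == g2) != 1)
      stop("pairedDMP: subject '", s, "' is not paired across '",
           g1, "' and '", g2, "'")
  }
  subjects <- unique(subject)
  n <- length(subjects)
  if (n < 3) stop("pairedDMP: need >= 3 pairs")

  m <- mValues(mm)
  idx1 <- vapply(subjects, function(s) which(subject == s & group == g1),
                 integer(1))
  idx2 <- vapply(subjects, function(s) which(subject == s & group == g2),
                 integer(1))
  d <- m[, idx2, drop = FALSE] - m[, idx1, drop = FALSE]
  dbar <- rowMeans(d)
  s2 <- apply(d, 1, var)
  df <- n - 1

  if (moderated) {
    sq <- squeezeVarMoments(s2, df)
    s2t <- sq$var_post
    dfTotal <- df + sq$d0
  } else {
    sq <- list(d0 = 0, s0_sq = NA_real_)
    s2t <- s2
    dfTotal <- rep(df, length(s2))
  }
  tstat <- dbar / sqrt(s2t / n)
  dfForP <- pmin(dfTotal, 1e6)   # t with huge df ~ normal
  p <- 2 * pt(-abs(tstat), dfForP)
  padj <- bhAdjust(p)

  bdiff <- expit2(m[, idx2, drop = FALSE]) - expit2(m[, idx1, drop = FALSE])
  res <- data.frame(
    probe_id = rownames(m),
    delta_beta = rowMeans(bdiff),
    logFC = dbar,
    t_stat = tstat,
    df_total = dfTotal,
    p_raw = p,
    p_adj = padj,
    direction = ifelse(dbar > 0, "hyper", "hypo"),
    significant = padj < alpha & abs(dbar) >= logfcMin,
    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "d0") <- sq$d0
  attr(res, "s0_sq") <- sq$s0_sq
  attr(res, "n_pairs") <- n
  res
}

## Method-of-moments fit of the scaled-F prior for sample variances.
## With z = log(s^2) and s^2 ~ s0^2 * F(df, d0):
##   E z   = log s0^2 + psi(df/2) - log(df/2) - psi(d0/2) + log(d0/2)
##   Var z = psi'(df/2) + psi'(d0/2)
## Zero variances contribute through the posterior but are excluded from the
## moment fit (their log is -Inf); if fewer than 2 positive variances exist
## the prior collapses to d0 = Inf with s0^2 = mean of the variances.
squeezeVarMoments <- function(s2, df) {
  pos <- s2 > 0 & is.finite(s2)
  if (sum(pos) < 2) {
    s0 <- mean(s2[is.finite(s2)])
    if (!is.finite(s0) || s0 <= 0) s0 <- 1e-8
    return(list(d0 = Inf, s0_sq = s0, var_post = rep(s0, length(s2))))
  }
  z <- log(s2[pos])
  ez <- mean(z); vz <- var(z)
  excess <- vz - trigamma(df / 2)
  if (is.na(excess) || excess <= 0) {
    d0 <- Inf
    s0 <- exp(ez - digamma(df / 2) + log(df / 2))
  } else {
    d0 <- 2 * trigammaInverse(excess)
    s0 <- exp(ez - digamma(df / 2) + log(df / 2) +
                digamma(d0 / 2) - log(d0 / 2))
  }
  varPost <- if (is.finite(d0)) (d0 * s0 + df * s2) / (d0 + df)
             else rep(s0, length(s2))
  list(d0 = d0, s0_sq = s0, var_post = varPost)
}

#' Jaccard conservation of two significant-probe sets
#'
#' @param a,b character vectors of probe identifiers
#' @return list with set sizes, intersection and union counts, and
#'   \code{jaccard} = |A∩B| / |A∪B| (defined as 0, with a warning, when both
#'   sets are empty).
#' @export
jaccardConservation <- function(a, b) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  int <- length(intersect(a, b))
  uni <- length(union(a, b))
  j <- if (uni == 0) {
    warning("jaccardConservation: both sets empty; Jaccard defined as 0")
    0
  } else int / uni
  list(n_a = length(a), n_b = length(b),
       intersection = int, union = uni, jaccard = j)
}

#' Drop genes with direction-discordant significant probes
#'
#' Removes every significant probe whose annotated gene also carries a
#' significant probe of the opposite direction; probes without gene
#' annotation pass through. Multi-gene probes are dropped if any of their
#' genes is discordant.
#'
#' @param diffRes data.frame from [pairedDMP()]
#' @param manifest probe manifest (possibly multiple rows per probe)
#' @return character vector of retained significant probe ids
#' @export
concordantGeneFilter <- function(diffRes, manifest) {
  sig <- diffRes[diffRes$significant, c("probe_id", "direction")]
  if (!nrow(sig)) return(character())
  ann <- manifest[manifest$probe_id %in% sig$probe_id & manifest$gene != "",
                  c("probe_id", "gene")]
  ann <- unique(ann)
  ann$direction <- sig$direction[match(ann$probe_id, sig$probe_id)]
  byGene <- split(ann$direction, ann$gene)
  discordant <- names(byGene)[vapply(byGene, function(d)
    length(unique(d)) > 1, logical(1))]
  dropProbes <- unique(ann$probe_id[ann$gene %in% discordant])
  setdiff(sig$probe_id, dropProbes)
}

#' Significant-probe counts by island relation and direction
#'
#' @param diffRes data.frame from [pairedDMP()]
#' @param manifest probe manifest
#' @return integer matrix, rows island/shore/shelf/opensea, columns
#'   hyper/hypo; marginal total equals the number of significant probes.
#' @export
categorySummary <- function(diffRes, manifest) {
  sig <- diffRes[diffRes$significant, c("probe_id", "direction")]
  rel <- manifest$island_relation[match(sig$probe_id, manifest$probe_id)]
  if (any(is.na(rel)))
    stop("categorySummary: significant probe absent from manifest: ",
         sig$probe_id[which(is.na(rel))[1]])
  tab <- table(factor(rel, levels = ISLAND_RELATIONS),
               factor(sig$direction, levels = c("hyper", "hypo")))
  out <- matrix(as.integer(tab), nrow = length(ISLAND_RELATIONS),
                dimnames = list(ISLAND_RELATIONS, c("hyper", "hypo")))
  out
}
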