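#' One-way random-effects intraclass correlation
#'
#' ICC(1) from the balanced one-way random-effects ANOVA decomposition:
#' \deqn{ICC = (MSB - MSW) / (MSB + (k-1) MSW)}
#' where MSB and MSW are the between- and within-subject mean squares and k
#' the number of measurements per subject. Negative estimates (MSW > MSB)
#' are reported as computed, down to \eqn{-1/(k-1)}.
#'
#' @param x measurements: a subjects-by-k numeric matrix, or a list of
#'   per-subject numeric vectors (balanced: equal lengths)
#' @return list with \code{icc}, \code{msb}, \code{msw}, \code{n_subjects},
#'   \code{k}
#' @examples
#' iccOneway(rbind(c(1, 1), c(2, 2), c(3, 3)))$icc  # 1: perfect agreement
#' @export
iccOneway <- function(x) {
  if (is.list(x)) {
    lens <- lengths(x)
    if (length(unique(lens)) != 1)
      stop("iccOneway: unbalanced groups (k must be equal across subjects)")
    x <- do.call(rbind, x)
  }
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  if (n < 2) stop("iccOneway: need >= 2 subjects")
  if (k < 2) stop("iccOneway: need >= 2 measurements per subject")
  if (anyNA(x)) stop("iccOneway: missing values not allowed")
  mi <- rowMeans(x)
  gm <- mean(x)
  msb <- k * sum((mi - gm)^2) / (n - 1)
  msw <- sum((x - mi)^2) / (n * (k - 1))
  icc <- if (msb + (k - 1) * msw == 0) NA_real_
         else (msb - msw) / (msb + (k - 1) * msw)
  list(icc = icc, msb = msb, msw = msw, n_subjects = n, k = k)
}

#' Cross-tissue probe reliability filter
#'
#' For each candidate probe and each (reference tissue, other tissue) pair,
#' computes the one-way random-effects ICC over subjects measured in both
#' tissues (k = 2 per subject). A probe passes when its ICC exceeds
#' \code{iccMin} in at least \code{minPassFraction} of the evaluated tissue
#' pairs (default: all of them, the strict cross-tissue reading). Tissue
#' pairs with fewer than 2 complete subjects are skipped with a warning.
#'
#' @param bs a complete \linkS4class{BetaSet}, or an
#'   \linkS4class{MValueSet} to evaluate reliability on the M scale
#' @param samples sample sheet with sample_id, subject_id, tissue
#' @param candidateProbes probe ids to evaluate (default: all)
#' @param referenceTissue tissue label every pair is anchored on
#'   (e.g. skeletal muscle)
#' @param iccMin pass threshold, default 0.4 (strict \code{>})
#' @param minPassFraction fraction of tissue pairs a probe must pass in
#' @return list: \code{pass} (character vector of passing probes) and
#'   \code{icc} (probes x tissue-pair matrix of ICC estimates)
#' @export
iccFilter <- function(bs, samples, candidateProbes = NULL, referenceTissue,
                      iccMin = 0.4, minPassFraction = 1) {
  b <- if (is(bs, "MValueSet")) mValues(bs) else betaValues(bs)
  if (is.null(candidateProbes)) candidateProbes <- rownames(b)
  missing <- setdiff(candidateProbes, rownames(b))
  if (length(missing))
    stop("iccFilter: candidate probes absent from matrix: ",
         paste(head(missing, 5), collapse = ", "))
  samples <- samples[match(colnames(b), samples$sample_id), , drop = FALSE]
  if (anyNA(samples$sample_id))
    stop("iccFilter: sample sheet does not cover all matrix samples")
  tissues <- setdiff(unique(samples$tissue), referenceTissue)
  if (!referenceTissue %in% samples$tissue)
    stop("iccFilter: reference tissue '", referenceTissue, "' absent")

  iccMat <- matrix(NA_real_, length(candidateProbes), 0,
                   dimnames = list(candidateProbes, NULL))
  for (tis in tissues) {
    refIdx <- which(samples$tissue == referenceTissue)
    othIdx <- which(samples$tissue == tis)
    refSub <- samples$subject_id[refIdx]
    othSub <- samples$subject_id[othIdx]
    common <- intersect(refSub, othSub)
    if (length(common) < 2) {
      warning("iccFilter: tissue pair ", referenceTissue, "-", tis,
              " has < 2 complete subject pairs; skipped")
      next
    }
    i1 <- refIdx[match(common, refSub)]
    i2 <- othIdx[match(common, othSub)]
    vals <- vapply(candidateProbes, function(p) {
      iccOneway(cbind(b[p, i1], b[p, i2]))$icc
    }, numeric(1))
    iccMat <- cbind(iccMat, vals)
    colnames(iccMat)[ncol(iccMat)] <- paste(referenceTissue, tis, sep = "|")
  }
  if (!ncol(iccMat))
    stop("iccFilter: no evaluable tissue pairs")
  passFrac <- rowMeans(iccMat > iccMin, na.rm = TRUE)
  pass <- candidateProbes[!is.na(passFrac) & passFrac >= minPassFraction]
  list(pass = pass, icc = iccMat)
}

#' Replicate change rate
#'
#' \deqn{change = |\beta_{control} - \beta_{replicate}| / base \times 100}
#' with the base value taken from the control (default) or the replicate.
#' A zero base leaves the rate undefined (\code{NA} with a warning); these
#' are the unstable low-beta cases.
#'
#' @param betaControl,betaReplicate methylation fractions (vectorised)
#' @param baseFrom \code{"control"} or \code{"replicate"}
#' @return change rate in percent, \code{NA} where base = 0
#' @examples
#' changeRate(0.5, 0.4)             # 20
#' changeRate(0.05, 0.12)           # 140: low-beta inflation
#' @export
changeRate <- function(betaControl, betaReplicate,
                       baseFrom = c("control", "replicate")) {
  baseFrom <- match.arg(baseFrom)
  base <- if (baseFrom == "control") betaControl else betaReplicate
  out <- abs(betaControl - betaReplicate) / base * 100
  zero <- !is.na(base) & base == 0
  if (any(zero)) {
    warning("changeRate: base value 0 for ", sum(zero),
            " entr", if (sum(zero) == 1) "y" else "ies",
            "; change rate undefined (NA)")
    out[zero] <- NA_real_
  }
  out
}

#' Rank probes by mean replicate change rate
#'
#' Computes the per-probe change rate for every control/replicate sample
#' pair, averages over pairs, and returns the ranking in decreasing order
#' with ties broken by probe id (lexicographic), so the order is
#' deterministic.
#'
#' @param bs a \linkS4class{BetaSet}
#' @param pairs data.frame with columns \code{control} and \code{replicate}
#'   holding sample ids
#' @param topN number of probes to return (capped at the probe count)
#' @param baseFrom base convention passed to [changeRate()]
#' @return data.frame probe_id, change_rate (percent, mean over pairs),
#'   sorted
#' @export
rankByChangeRate <- function(bs, pairs, topN = 10,
                             baseFrom = c("control", "replicate")) {
  baseFrom <- match.arg(baseFrom)
  b <- betaValues(bs)
  if (!nrow(pairs)) stop("rankByChangeRate: need >= 1 control/replicate pair")
  bad <- setdiff(c(pairs$control, pairs$replicate), colnames(b))
  if (length(bad))
    stop("rankByChangeRate: unknown sample ids: ", paste(bad, collapse = ", "))
  rates <- sapply(seq_len(nrow(pairs)), function(i) {
    changeRate(b[, pairs$control[i]], b[, pairs$replicate[i]],
               baseFrom = baseFrom)
  })
  rates <- matrix(rates, nrow = nrow(b))
  mean_rate <- rowMeans(rates)
  ord <- order(-mean_rate, rownames(b))
  out <- data.frame(probe_id = rownames(b)[ord],
                    change_rate = mean_rate[ord],
                    row.names = NULL, stringsAsFactors = FALSE)
  head(out, min(topN, nrow(out)))
}
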