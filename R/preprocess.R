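#' Sample-level quality control by missingness
#'
#' Drops every sample whose fraction of missing probe values exceeds
#' \code{maxMissingFrac} — strictly "more than", so a sample at exactly the
#' threshold is retained. Errors if nothing survives.
#'
#' @param bs a \linkS4class{BetaSet}
#' @param maxMissingFrac maximum tolerated missing fraction, in (0, 1];
#'   default 0.8
#' @return the filtered BetaSet; attribute \code{"removed_samples"} lists the
#'   dropped sample ids.
#' @export
qcFilterSamples <- function(bs, maxMissingFrac = 0.8) {
  stopIfNotFraction(maxMissingFrac, "maxMissingFrac", open_lo = TRUE)
  b <- betaValues(bs)
  frac <- colMeans(is.na(b))
  drop <- frac > maxMissingFrac
  if (all(drop)) stop("qcFilterSamples: all samples exceed the missingness ",
                      "threshold (", maxMissingFrac, ")")
  out <- bs[, !drop]
  attr(out, "removed_samples") <- colnames(b)[drop]
  out
}

#' Probe-wise k-nearest-neighbour imputation
#'
#' Fills each missing cell with the mean of that sample's values over the k
#' probes nearest to the incomplete probe. Distance is Euclidean over the
#' samples where both probes are observed, scaled to a per-sample basis so
#' probes sharing few samples are not spuriously close. Neighbours must be
#' observed in the target sample. Non-missing entries are untouched; imputed
#' values are clipped to \eqn{[0,1]}.
#'
#' @param bs a \linkS4class{BetaSet}
#' @param k number of neighbours (default 10)
#' @return a complete BetaSet
#' @export
imputeKNN <- function(bs, k = 10) {
  b <- betaValues(bs)
  if (!anyNA(b)) return(bs)
  complete <- !apply(is.na(b), 1, any)
  incomplete <- which(!complete)
  if (sum(complete) < 1)
    stop("imputeKNN: no complete probes available as neighbours")
  kEff <- min(k, sum(complete))
  ref <- b[complete, , drop = FALSE]
  for (i in incomplete) {
    x <- b[i, ]
    obs <- !is.na(x)
    if (!any(obs))
      stop("imputeKNN: probe ", rownames(b)[i],
           " is missing in all samples; no neighbours usable")
    ## mean squared difference over shared observed samples
    d2 <- rowMeans((ref[, obs, drop = FALSE] -
                      matrix(x[obs], nrow(ref), sum(obs), byrow = TRUE))^2)
    ord <- order(d2, rownames(ref))
    nn <- ref[ord[seq_len(kEff)], , drop = FALSE]
    fill <- which(!obs)
    x[fill] <- colMeans(nn[, fill, drop = FALSE])
    b[i, ] <- clamp(x, 0, 1)
  }
  out <- BetaSet(b, as.data.frame(SummarizedExperiment::colData(bs)))
  out
}

#' Beta to M-value transform
#'
#' \eqn{M = \log_2(\beta/(1-\beta))} elementwise, after clamping beta to
#' \eqn{[\epsilon, 1-\epsilon]} so boundary values stay finite. Strictly
#' increasing, hence rank-preserving.
#'
#' @param bs a \linkS4class{BetaSet} (no missing values)
#' @param epsilon clamp width, in (0, 0.01]; default 1e-6
#' @return an \linkS4class{MValueSet}
#' @export
betaToM <- function(bs, epsilon = 1e-6) {
  stopIfNotFraction(epsilon, "epsilon", lo = 0, hi = 0.01, open_lo = TRUE)
  b <- clamp(betaValues(bs), epsilon, 1 - epsilon)
  m <- logit2(b)
  MValueSet(m, as.data.frame(SummarizedExperiment::colData(bs)))
}

#' M-value to beta transform
#'
#' Inverse of [betaToM()]: \eqn{\beta = 2^M/(1+2^M)}, always in (0,1).
#' @param mm an \linkS4class{MValueSet}
#' @return a \linkS4class{BetaSet}
#' @export
mToBeta <- function(mm) {
  b <- expit2(mValues(mm))
  BetaSet(b, as.data.frame(SummarizedExperiment::colData(mm)))
}
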