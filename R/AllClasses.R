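#' @import methods
#' @importFrom stats cor cor.test sd var median setNames p.adjust pt
#'   wilcox.test lm rnorm runif rgamma rpois na.omit
#' @importFrom utils read.delim write.table head combn
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame queryHits subjectHits
#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom IRanges IRanges ranges width pintersect
NULL

## Closed vocabularies shared by the manifest reader and the generators.
GENE_REGIONS <- c("1st Exon", "TSS200", "TSS1500", "body", "UTR", "IGR")
ISLAND_RELATIONS <- c("island", "shore", "shelf", "opensea")

#' BetaSet: probes-by-samples methylation fractions
#'
#' A thin wrapper around \linkS4class{SummarizedExperiment} holding a single
#' assay \code{"beta"} of methylation fractions \eqn{\beta = M/(U+M)} in
#' \eqn{[0,1]}. Missing measurements are stored as \code{NA}; probe and sample
#' identifiers are the dimnames and must be unique. Sample annotation (subject,
#' tissue, group, covariates) travels in \code{colData}.
#'
#' @slot .Data inherits all SummarizedExperiment slots.
#' @seealso [BetaSet()], [betaValues()], [betaToM()]
#' @export
setClass("BetaSet", contains = "SummarizedExperiment")

#' MValueSet: logit2-transformed methylation
#'
#' Same shape as the source \linkS4class{BetaSet}, single assay \code{"M"} with
#' \eqn{M = \log_2(\beta/(1-\beta))}, unbounded reals. Produced by
#' [betaToM()]; inverted by [mToBeta()].
#'
#' @export
setClass("MValueSet", contains = "SummarizedExperiment")

.validBetaSet <- function(object) {
  msg <- character()
  if (!"beta" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'beta' is required")
  else {
    b <- SummarizedExperiment::assay(object, "beta")
    if (!is.numeric(b))
      msg <- c(msg, "beta values must be numeric")
    else if (any(b < 0 | b > 1, na.rm = TRUE))
      msg <- c(msg, "beta values must lie in [0, 1]")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "probe ids (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids (colnames) must be present and unique")
  if (length(msg)) msg else TRUE
}
setValidity("BetaSet", .validBetaSet)

.validMValueSet <- function(object) {
  msg <- character()
  if (!"M" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'M' is required")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "probe ids (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids (colnames) must be present and unique")
  if (length(msg)) msg else TRUE
}
setValidity("MValueSet", .validMValueSet)

#' Construct a BetaSet
#'
#' @param beta numeric matrix of methylation fractions in \eqn{[0,1]} with
#'   probe rownames and sample colnames; \code{NA} marks missing cells.
#' @param sampleData optional \code{data.frame} of per-sample annotation whose
#'   rows match \code{colnames(beta)} (matched by \code{sample_id} column or
#'   rownames).
#' @return a validated \linkS4class{BetaSet}.
#' @examples
#' b <- matrix(c(.1, .9, .5, NA), 2, 2,
#'             dimnames = list(c("cg01", "cg02"), c("s1", "s2")))
#' BetaSet(b)
#' @export
BetaSet <- function(beta, sampleData = NULL) {
  beta <- as.matrix(beta)
  storage.mode(beta) <- "double"
  cd <- if (is.null(sampleData)) {
    S4Vectors::DataFrame(row.names = colnames(beta))
  } else {
    sd <- as.data.frame(sampleData)
    if ("sample_id" %in% names(sd)) {
      idx <- match(colnames(beta), sd$sample_id)
      if (anyNA(idx))
        stop("sampleData lacks rows for samples: ",
             paste(colnames(beta)[is.na(idx)], collapse = ", "))
      sd <- sd[idx, , drop = FALSE]
    }
    rownames(sd) <- colnames(beta)
    S4Vectors::DataFrame(sd)
  }
  new("BetaSet", SummarizedExperiment::SummarizedExperiment(
    assays = list(beta = beta), colData = cd))
}

#' Construct an MValueSet
#' @param m numeric matrix of M-values with probe rownames, sample colnames.
#' @param sampleData optional per-sample annotation (see [BetaSet()]).
#' @return a validated \linkS4class{MValueSet}.
#' @export
MValueSet <- function(m, sampleData = NULL) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  cd <- if (is.null(sampleData)) S4Vectors::DataFrame(row.names = colnames(m))
        else S4Vectors::DataFrame(as.data.frame(sampleData),
                                  row.names = colnames(m))
  new("MValueSet", SummarizedExperiment::SummarizedExperiment(
    assays = list(M = m), colData = cd))
}

#' @describeIn BetaSet extract the beta matrix (with NA mask).
#' @param x a BetaSet
#' @export
betaValues <- function(x) {
  stopifnot(is(x, "BetaSet"))
  SummarizedExperiment::assay(x, "beta")
}

#' Extract the M-value matrix
#' @param x an MValueSet
#' @export
mValues <- function(x) {
  stopifnot(is(x, "MValueSet"))
  SummarizedExperiment::assay(x, "M")
}

#' Probe identifiers of a methylation set
#' @param x a BetaSet or MValueSet
#' @export
probeIds <- function(x) rownames(x)

#' Sample identifiers of a methylation set
#' @param x a BetaSet or MValueSet
#' @export
sampleIds <- function(x) colnames(x)

setMethod("show", "BetaSet", function(object) {
  b <- SummarizedExperiment::assay(object, "beta")
  cat("BetaSet:", nrow(b), "probes x", ncol(b), "samples;",
      sum(is.na(b)), "missing cells\n")
  if (ncol(SummarizedExperiment::colData(object)))
    cat("  colData:", paste(colnames(SummarizedExperiment::colData(object)),
                            collapse = ", "), "\n")
})

setMethod("show", "MValueSet", function(object) {
  m <- SummarizedExperiment::assay(object, "M")
  cat("MValueSet:", nrow(m), "probes x", ncol(m), "samples\n")
})

#' ScoreModel: probe weights defining a methylation enrichment score
#'
#' Linear signature \eqn{Score_i = \sum_j w_j \beta_{ij}} with optional
#' min-max normalisation to the training-score range. Fitted by [fitGelnet()]
#' under an L1 plus graph-Laplacian L2 penalty, or imported directly from a
#' published weight table via [readScoreModel()].
#'
#' @slot probeIds ordered probe identifiers (length k)
#' @slot weights numeric weights w_1..w_k
#' @slot lambda1,lambda2 penalty magnitudes (>= 0)
#' @slot laplacian k x k symmetric PSD penalty matrix
#' @slot scoreShift,scoreScale normalisation constants: normalised score =
#'   (raw - scoreShift) * scoreScale, clipped to \eqn{[0,1]}
#' @slot normalize logical; apply the min-max map when scoring
#' @export
setClass("ScoreModel", representation(
  probeIds = "character", weights = "numeric",
  lambda1 = "numeric", lambda2 = "numeric",
  laplacian = "matrix",
  scoreShift = "numeric", scoreScale = "numeric",
  normalize = "logical"))

.validScoreModel <- function(object) {
  msg <- character()
  k <- length(object@probeIds)
  if (length(object@weights) != k)
    msg <- c(msg, "weights and probeIds lengths differ")
  if (anyDuplicated(object@probeIds))
    msg <- c(msg, "probeIds must be unique")
  if (length(object@laplacian) && !all(dim(object@laplacian) == c(k, k)))
    msg <- c(msg, "laplacian must be k x k")
  if (length(object@laplacian) &&
      max(abs(object@laplacian - t(object@laplacian))) > 1e-8)
    msg <- c(msg, "laplacian must be symmetric")
  if (object@lambda1 < 0 || object@lambda2 < 0)
    msg <- c(msg, "penalties must be >= 0")
  if (length(msg)) msg else TRUE
}
setValidity("ScoreModel", .validScoreModel)

#' Construct a ScoreModel
#' @param probeIds,weights parallel vectors defining the signature
#' @param lambda1,lambda2 penalties recorded with the fit
#' @param laplacian penalty matrix (defaults to zero matrix)
#' @param scoreShift,scoreScale,normalize score normalisation constants
#' @return a validated \linkS4class{ScoreModel}
#' @export
ScoreModel <- function(probeIds, weights, lambda1 = 0, lambda2 = 0,
                       laplacian = NULL, scoreShift = 0, scoreScale = 1,
                       normalize = FALSE) {
  k <- length(probeIds)
  if (is.null(laplacian)) laplacian <- matrix(0, k, k)
  new("ScoreModel", probeIds = as.character(probeIds),
      weights = as.numeric(weights),
      lambda1 = lambda1, lambda2 = lambda2,
      laplacian = as.matrix(laplacian),
      scoreShift = scoreShift, scoreScale = scoreScale,
      normalize = normalize)
}

#' Weights of a ScoreModel, named by probe
#' @param model a ScoreModel
#' @export
probeWeights <- function(model) {
  stopifnot(is(model, "ScoreModel"))
  setNames(model@weights, model@probeIds)
}

setMethod("show", "ScoreModel", function(object) {
  nz <- sum(object@weights != 0)
  cat("ScoreModel:", length(object@probeIds), "probes,", nz, "nonzero weights;",
      "lambda1 =", object@lambda1, "lambda2 =", object@lambda2, "\n")
  if (object@normalize)
    cat("  min-max normalised (shift ", object@scoreShift,
        ", scale ", object@scoreScale, ")\n", sep = "")
})
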