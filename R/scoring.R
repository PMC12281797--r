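#' Build a probe-graph Laplacian penalty
#'
#' Connects probes that share an annotated gene (\code{"by-gene"}) or that lie
#' within \code{maxGap} bp of each other on the same chromosome
#' (\code{"by-distance"}), and returns the combinatorial Laplacian
#' \eqn{L = D - A}. Isolated probes are allowed (zero row/column). Row sums
#' are 0 and L is positive semi-definite by construction.
#'
#' @param manifest probe manifest covering \code{probes}
#' @param probes ordered probe ids defining the matrix rows/columns
#' @param mode \code{"by-gene"} or \code{"by-distance"}
#' @param maxGap adjacency distance in bp for by-distance mode (default 1000)
#' @return k x k Laplacian matrix with \code{probes} as dimnames
#' @export
buildProbeGraph <- function(manifest, probes,
                            mode = c("by-gene", "by-distance"),
                            maxGap = 1000) {
  mode <- match.arg(mode)
  missing <- setdiff(probes, manifest$probe_id)
  if (length(missing))
    stop("buildProbeGraph: probes absent from manifest: ",
         paste(head(missing, 5), collapse = ", "))
  k <- length(probes)
  A <- matrix(0, k, k, dimnames = list(probes, probes))
  if (mode == "by-gene") {
    ann <- manifest[manifest$probe_id %in% probes & manifest$gene != "", ]
    for (g in unique(ann$gene)) {
      mem <- unique(ann$probe_id[ann$gene == g])
      if (length(mem) > 1) {
        ij <- match(mem, probes)
        A[ij, ij] <- 1
      }
    }
  } else {
    ann <- manifest[match(probes, manifest$probe_id), ]
    for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
      if (ann$chromosome[i] == ann$chromosome[j] &&
          abs(ann$position[i] - ann$position[j]) <= maxGap)
        A[i, j] <- A[j, i] <- 1
    }
  }
  diag(A) <- 0
  L <- diag(rowSums(A)) - A
  dimnames(L) <- list(probes, probes)
  L
}

#' Fit probe weights by a generalized elastic net
#'
#' Minimises
#' \deqn{\frac{1}{2\sum v_i}\sum_i v_i (y_i - x_i^\top w)^2
#'   + \lambda_1 \|w\|_1 + \frac{\lambda_2}{2} w^\top L w}
#' by cyclic coordinate descent with soft-thresholding. In
#' \code{"one-class"} mode the response is the all-ones target on the
#' training class, so weights describe the class's methylation signature; in
#' \code{"regression"} mode a per-sample response is supplied. The Laplacian
#' L couples graph-adjacent probes, pulling their weights toward each other
#' ("similar but not same") rather than zero.
#'
#' Convergence: after each sweep the exact KKT (subgradient) violation is
#' evaluated; the fit stops when it falls below \code{kktTol} or when the
#' largest coordinate change falls below \code{tol}, and errors with
#' diagnostics after \code{maxSweeps} sweeps. The objective is
#' non-increasing by construction and its per-sweep trace is attached to
#' the result. The sweep works on the k x k Gram matrix, so its cost is
#' independent of the sample count.
#'
#' @param x training data: a complete \linkS4class{BetaSet}
#'   (probes x samples) or a samples-by-features numeric matrix
#' @param lambda1 L1 penalty (default 0.01)
#' @param lambda2 Laplacian L2 penalty (default 1)
#' @param laplacian k x k penalty matrix; default zero (plain elastic net
#'   without coupling). Must be symmetric PSD.
#' @param mode \code{"one-class"} or \code{"regression"}
#' @param response per-sample numeric response (regression mode)
#' @param sampleWeights optional nonnegative per-sample loss weights (see
#'   [cohortSampleWeights()] for equal-cohort weighting)
#' @param normalize store min-max constants mapping training scores to [0,1]
#' @param tol,kktTol,maxSweeps convergence controls (defaults 1e-10, 1e-9,
#'   1e5)
#' @return a \linkS4class{ScoreModel}; attribute \code{"objective_trace"}
#'   holds the per-sweep objective values.
#' @export
fitGelnet <- function(x, lambda1 = 0.01, lambda2 = 1, laplacian = NULL,
                      mode = c("one-class", "regression"), response = NULL,
                      sampleWeights = NULL, normalize = FALSE,
                      tol = 1e-10, kktTol = 1e-9, maxSweeps = 1e5) {
  mode <- match.arg(mode)
  if (is(x, "BetaSet")) {
    if (anyNA(betaValues(x))) stop("fitGelnet: missing values; impute first")
    X <- t(betaValues(x))
  } else X <- as.matrix(x)
  n <- nrow(X); k <- ncol(X)
  if (k < 1) stop("fitGelnet: need >= 1 feature")
  y <- if (mode == "one-class") rep(1, n) else {
    if (is.null(response) || length(response) != n)
      stop("fitGelnet: regression mode needs a response of length n")
    as.numeric(response)
  }
  v <- if (is.null(sampleWeights)) rep(1, n) else {
    if (length(sampleWeights) != n || any(sampleWeights < 0))
      stop("fitGelnet: sampleWeights must be nonnegative, length n")
    as.numeric(sampleWeights)
  }
  v <- v / sum(v)
  L <- if (is.null(laplacian)) matrix(0, k, k) else as.matrix(laplacian)
  if (!all(dim(L) == k)) stop("fitGelnet: laplacian must be k x k")
  if (max(abs(L - t(L))) > 1e-8) stop("fitGelnet: laplacian not symmetric")
  if (k <= 500) {  # PSD gate; for larger k trust the graph construction
    ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(1, max(abs(ev))))
      stop("fitGelnet: laplacian is not positive semi-definite")
  }

  ## covariance (Gram) form: H = X'VX + lambda2 L, b = X'Vy; the quadratic
  ## part of the objective is 0.5 w'Hw - b'w + const
  Xv <- X * v
  H <- crossprod(X, Xv) + lambda2 * L
  b <- drop(crossprod(Xv, y))
  d <- diag(H)
  w <- numeric(k)
  q <- numeric(k)                  # q = H w, maintained incrementally
  const <- 0.5 * sum(v * y^2)
  objective <- function(w, q)
    const - sum(b * w) + 0.5 * sum(w * q) + lambda1 * sum(abs(w))
  kktViolation <- function(w, q) {
    g <- q - b                     # gradient of the smooth part
    nz <- w != 0
    max(c(0, abs(g[nz] + lambda1 * sign(w[nz])),
          pmax(0, abs(g[!nz]) - lambda1)))
  }
  trace <- objective(w, q)
  converged <- FALSE
  for (sweep in seq_len(maxSweeps)) {
    delta <- 0
    for (j in seq_len(k)) {
      wj <- w[j]
      cj <- b[j] - q[j] + d[j] * wj
      wjNew <- if (d[j] <= 0) 0 else {
        s <- abs(cj) - lambda1
        if (s <= 0) 0 else sign(cj) * s / d[j]
      }
      if (wjNew != wj) {
        q <- q + H[, j] * (wjNew - wj)
        w[j] <- wjNew
        delta <- max(delta, abs(wjNew - wj))
      }
    }
    trace <- c(trace, objective(w, q))
    if (kktViolation(w, q) < kktTol || delta < tol) {
      converged <- TRUE; break
    }
  }
  if (!converged)
    stop("fitGelnet: no convergence after ", maxSweeps,
         " sweeps (last max coordinate change ", signif(delta, 3),
         ", KKT violation ", signif(kktViolation(w, q), 3), ")")

  raw <- drop(X %*% w)
  shift <- 0; scale <- 1
  if (normalize) {
    shift <- min(raw)
    rng <- max(raw) - min(raw)
    scale <- if (rng > 0) 1 / rng else 1
  }
  ids <- colnames(X)
  if (is.null(ids)) ids <- paste0("f", seq_len(k))
  model <- ScoreModel(ids, w, lambda1 = lambda1, lambda2 = lambda2,
                      laplacian = L, scoreShift = shift, scoreScale = scale,
                      normalize = normalize)
  attr(model, "objective_trace") <- trace
  attr(model, "sweeps") <- sweep
  model
}

#' Equal-cohort sample weights
#'
#' Loss weights giving each cohort the same total weight regardless of its
#' size, so no cohort dominates a pooled fit.
#' @param cohort per-sample cohort labels
#' @return numeric weights summing to 1
#' @export
cohortSampleWeights <- function(cohort) {
  cohort <- as.character(cohort)
  tab <- table(cohort)
  w <- 1 / (as.numeric(tab[cohort]) * length(tab))
  w / sum(w)
}

#' Score samples with a fitted model
#'
#' \eqn{Score_i = \sum_j w_j \beta_{ij}}, optionally mapped through the
#' model's stored min-max normalisation (training min to 0, max to 1; new
#' samples clipped to [0,1]).
#'
#' @param model a \linkS4class{ScoreModel}
#' @param bs a \linkS4class{BetaSet} containing every model probe
#' @return data.frame with sample_id and score
#' @export
scoreSamples <- function(model, bs) {
  b <- betaValues(bs)
  missing <- setdiff(model@probeIds, rownames(b))
  if (length(missing))
    stop("scoreSamples: probes absent from data: ",
         paste(head(missing, 10), collapse = ", "))
  sub <- b[model@probeIds, , drop = FALSE]
  if (anyNA(sub)) stop("scoreSamples: NA beta values; impute first")
  raw <- drop(crossprod(sub, model@weights))
  score <- if (model@normalize)
    clamp((raw - model@scoreShift) * model@scoreScale, 0, 1) else raw
  data.frame(sample_id = colnames(b), score = score,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Karush-Kuhn-Tucker check for a fitted model
#'
#' Verifies stationarity of the penalized objective at the fitted weights:
#' for \eqn{w_j \ne 0}, \eqn{|\nabla_j loss + \lambda_2 (Lw)_j +
#' \lambda_1 sign(w_j)| < tol}; for \eqn{w_j = 0} the subgradient condition
#' \eqn{|\nabla_j loss + \lambda_2 (Lw)_j| \le \lambda_1 + tol}.
#'
#' @param model a fitted \linkS4class{ScoreModel}
#' @param x training data as passed to [fitGelnet()]
#' @param response,mode,sampleWeights as in [fitGelnet()]
#' @param tol violation tolerance (default 1e-6)
#' @return list: \code{ok} (logical), \code{violations} (indices),
#'   \code{max_violation}
#' @export
verifyKKT <- function(model, x, mode = c("one-class", "regression"),
                      response = NULL, sampleWeights = NULL, tol = 1e-6) {
  mode <- match.arg(mode)
  X <- if (is(x, "BetaSet")) t(betaValues(x)) else as.matrix(x)
  n <- nrow(X)
  if (mode == "regression" && length(response) != n)
    stop("verifyKKT: regression mode needs a response of length n")
  y <- if (mode == "one-class") rep(1, n) else as.numeric(response)
  v <- if (is.null(sampleWeights)) rep(1, n) else as.numeric(sampleWeights)
  v <- v / sum(v)
  w <- model@weights
  L <- model@laplacian
  g <- -drop(crossprod(X, v * (y - drop(X %*% w)))) +
    model@lambda2 * drop(L %*% w)
  nz <- w != 0
  viol <- numeric(length(w))
  viol[nz] <- abs(g[nz] + model@lambda1 * sign(w[nz]))
  viol[!nz] <- pmax(0, abs(g[!nz]) - model@lambda1)
  bad <- which(viol >= tol)
  list(ok = length(bad) == 0, violations = bad, max_violation = max(viol, 0))
}
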