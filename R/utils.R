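## Internal helpers shared across modules.

## Chromosome labels are normalised to "chr"-prefixed form on ingest so that
## manifests, segment tables and generated data always agree.
normalizeChrom <- function(x) {
  x <- as.character(x)
  ifelse(grepl("^chr", x), x, paste0("chr", x))
}

logit2 <- function(beta) log2(beta / (1 - beta))
expit2 <- function(m) 2^m / (1 + 2^m)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Newton inversion of the trigamma function, used by the empirical-Bayes
## variance prior fit. Monotone decreasing on (0, Inf); standard iteration
## on 1/x converges in a handful of steps.
trigammaInverse <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi)) return(NA_real_)
    if (yi <= 0) return(Inf)
    if (yi > 1e7) return(1 / sqrt(yi))
    if (yi < 1e-6) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, 2L)
      x <- x + dif
      if (abs(dif) / x < 1e-10) break
    }
    x
  }, numeric(1))
}

## Benjamini-Hochberg adjustment; NA p-values stay NA and do not count
## toward the number of tests.
bhAdjust <- function(p) p.adjust(p, method = "BH")

stopIfNotFraction <- function(x, name, lo = 0, hi = 1,
                              open_lo = FALSE, open_hi = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) &&
    (if (open_lo) x > lo else x >= lo) &&
    (if (open_hi) x < hi else x <= hi)
  if (!ok) stop(name, " must be in ", if (open_lo) "(" else "[", lo, ", ",
                hi, if (open_hi) ")" else "]", call. = FALSE)
  invisible(x)
}
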