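## Readers and writers for every tabular artifact the pipeline touches.
## TSV is the default; CSV is accepted (sep inferred from the extension or
## forced via `sep`). Only "NA", "NaN" and the empty string parse as missing.
## Readers validate strictly and never silently drop rows: a malformed row is
## an error, and the number of parsed rows is attached as attribute
## "parse_info".

MISSING_STRINGS <- c("NA", "NaN", "")

.inferSep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

.readTable <- function(path, sep = NULL) {
  read.delim(path, sep = .inferSep(path, sep), header = TRUE,
             check.names = FALSE, colClasses = "character",
             na.strings = NULL, stringsAsFactors = FALSE)
}

.requireColumns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, ": missing required column(s): ", paste(miss, collapse = ", "))
  invisible(df)
}

.asNumericChecked <- function(x, what, column) {
  x[x %in% MISSING_STRINGS] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad))
    stop(what, ": non-numeric value '", x[bad[1]], "' in column '", column,
         "', row ", bad[1])
  out
}

#' Read a beta-value matrix
#'
#' Parses a delimited probes-by-samples table of methylation fractions: first
#' column probe identifiers, header row sample identifiers. Cells equal to
#' \code{"NA"}, \code{"NaN"} or empty parse as missing; any other non-numeric
#' cell, a value outside \eqn{[0,1]}, or a duplicated probe/sample identifier
#' is a format error.
#'
#' @param path file path (TSV default; \code{.csv} switches to comma)
#' @param sep optional explicit field separator
#' @return a \linkS4class{BetaSet}; attribute \code{"parse_info"} records row
#'   counts.
#' @export
readBetaMatrix <- function(path, sep = NULL) {
  df <- .readTable(path, sep)
  if (ncol(df) < 2) stop("beta matrix: need probe id column plus >=1 sample")
  probes <- df[[1]]
  if (anyDuplicated(probes))
    stop("beta matrix: duplicate probe ids: ",
         paste(unique(probes[duplicated(probes)]), collapse = ", "))
  samples <- names(df)[-1]
  if (anyDuplicated(samples))
    stop("beta matrix: duplicate sample ids: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  vals <- vapply(seq_along(samples), function(j) {
    .asNumericChecked(df[[j + 1]], "beta matrix", samples[j])
  }, numeric(nrow(df)))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(probes, samples))
  if (any(vals < 0 | vals > 1, na.rm = TRUE)) {
    bad <- which(vals < 0 | vals > 1, arr.ind = TRUE)[1, ]
    stop("beta matrix: value out of [0,1] at probe ", probes[bad[1]],
         ", sample ", samples[bad[2]])
  }
  bs <- BetaSet(vals)
  attr(bs, "parse_info") <- list(n_rows = nrow(df), n_kept = nrow(df))
  bs
}

#' Write a beta-value matrix
#'
#' Inverse of [readBetaMatrix()]: values survive a round trip bit-exactly.
#' @param bs a BetaSet
#' @param path output path
#' @param sep field separator (default tab)
#' @export
writeBetaMatrix <- function(bs, path, sep = "\t") {
  b <- betaValues(bs)
  out <- data.frame(probe_id = rownames(b), check.names = FALSE)
  for (j in seq_len(ncol(b)))
    out[[colnames(b)[j]]] <- sprintf("%.17g", b[, j])
  out[out == "NA"] <- "NA"
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe manifest
#'
#' Columns \code{probe_id, chromosome, position, gene, gene_region,
#' island_relation}. \code{gene_region} and \code{island_relation} are closed
#' vocabularies (\code{"1st Exon", "TSS200", "TSS1500", "body", "UTR", "IGR"}
#' and \code{"island", "shore", "shelf", "opensea"}); unknown categories are
#' errors listing the allowed values. Chromosomes are normalised to
#' \code{chr}-prefixed form; positions are 1-based. A probe annotated to
#' several genes appears as several rows.
#'
#' @inheritParams readBetaMatrix
#' @return validated \code{data.frame}
#' @export
readManifest <- function(path, sep = NULL) {
  df <- .readTable(path, sep)
  .requireColumns(df, c("probe_id", "chromosome", "position", "gene",
                        "gene_region", "island_relation"), "manifest")
  df$position <- .asNumericChecked(df$position, "manifest", "position")
  df$chromosome <- normalizeChrom(df$chromosome)
  df$gene[df$gene %in% MISSING_STRINGS] <- ""
  badR <- setdiff(unique(df$gene_region), GENE_REGIONS)
  if (length(badR))
    stop("manifest: unknown gene_region '", badR[1], "'; allowed: ",
         paste(GENE_REGIONS, collapse = ", "))
  badI <- setdiff(unique(df$island_relation), ISLAND_RELATIONS)
  if (length(badI))
    stop("manifest: unknown island_relation '", badI[1], "'; allowed: ",
         paste(ISLAND_RELATIONS, collapse = ", "))
  if (any(is.na(df$position) | df$position < 1))
    stop("manifest: positions must be >= 1 (1-based coordinates)")
  attr(df, "parse_info") <- list(n_rows = nrow(df), n_kept = nrow(df))
  df
}

#' @rdname readManifest
#' @param manifest a manifest data.frame
#' @param path output path
#' @export
writeManifest <- function(manifest, path) {
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' Required columns \code{sample_id, subject_id, tissue, sex, group};
#' optional numeric \code{age} (years), \code{bmi} (kg/m2), \code{tmb}
#' (mutations/Mb), missing allowed.
#' @inheritParams readBetaMatrix
#' @return validated \code{data.frame}
#' @export
readSamples <- function(path, sep = NULL) {
  df <- .readTable(path, sep)
  .requireColumns(df, c("sample_id", "subject_id", "tissue", "sex", "group"),
                  "sample sheet")
  if (anyDuplicated(df$sample_id))
    stop("sample sheet: duplicate sample_id")
  for (col in intersect(c("age", "bmi", "tmb"), names(df)))
    df[[col]] <- .asNumericChecked(df[[col]], "sample sheet", col)
  attr(df, "parse_info") <- list(n_rows = nrow(df), n_kept = nrow(df))
  df
}

#' @rdname readSamples
#' @param samples a sample sheet data.frame
#' @param path output path
#' @export
writeSamples <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a CNV segment table
#'
#' Columns \code{sample_id, chromosome, start, end, log2_ratio}; coordinates
#' 1-based inclusive. \code{start > end} is an error, as are overlapping
#' segments of one sample on one chromosome.
#' @inheritParams readBetaMatrix
#' @return validated \code{data.frame}
#' @export
readSegments <- function(path, sep = NULL) {
  df <- .readTable(path, sep)
  .requireColumns(df, c("sample_id", "chromosome", "start", "end",
                        "log2_ratio"), "segment table")
  for (col in c("start", "end", "log2_ratio"))
    df[[col]] <- .asNumericChecked(df[[col]], "segment table", col)
  df$chromosome <- normalizeChrom(df$chromosome)
  if (any(df$start > df$end))
    stop("segment table: start > end at row ",
         which(df$start > df$end)[1])
  validateSegments(df)
  attr(df, "parse_info") <- list(n_rows = nrow(df), n_kept = nrow(df))
  df
}

## Overlap check within (sample, chromosome): after sorting by start,
## each segment must begin after the previous one ends.
validateSegments <- function(df) {
  if (!nrow(df)) return(invisible(df))
  key <- paste(df$sample_id, df$chromosome)
  for (k in unique(key)) {
    sub <- df[key == k, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) > 1 && any(sub$start[-1] <= sub$end[-nrow(sub)]))
      stop("segment table: overlapping segments for ", k)
  }
  invisible(df)
}

#' @rdname readSegments
#' @param segments a segment data.frame
#' @param path output path
#' @export
writeSegments <- function(segments, path) {
  seg <- segments
  seg$log2_ratio <- sprintf("%.17g", seg$log2_ratio)
  write.table(seg, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a mutation table
#'
#' MAF-like: one row per (sample, gene, variant_class) event. Duplicate
#' events collapse only on binarization, not at read time.
#' @inheritParams readBetaMatrix
#' @return validated \code{data.frame}
#' @export
readMutations <- function(path, sep = NULL) {
  df <- .readTable(path, sep)
  .requireColumns(df, c("sample_id", "gene", "variant_class"),
                  "mutation table")
  attr(df, "parse_info") <- list(n_rows = nrow(df), n_kept = nrow(df))
  df
}

#' @rdname readMutations
#' @param mutations a mutation data.frame
#' @param path output path
#' @export
writeMutations <- function(mutations, path) {
  write.table(mutations, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export co-methylated blocks as BED
#'
#' Converts the 1-based inclusive block coordinates to BED's 0-based
#' half-open convention at this boundary only.
#' @param blocks data.frame from [findBlocks()]
#' @param path output path
#' @export
blocksToBed <- function(blocks, path) {
  bed <- data.frame(chrom = blocks$chromosome,
                    chromStart = blocks$start - 1L,
                    chromEnd = blocks$end,
                    name = paste0("block_", seq_len(nrow(blocks))),
                    score = round(1000 * pmin(1, pmax(0,
                      blocks$min_adjacent_rho))),
                    strand = ".")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Serialize a ScoreModel
#'
#' Two-column TSV (probe_id, weight) plus a YAML sidecar carrying penalties
#' and normalisation constants; [readScoreModel()] restores a model that
#' reproduces scores bit-identically. A plain published weight table (no
#' sidecar) also loads, with default constants.
#'
#' @param model a \linkS4class{ScoreModel}
#' @param path TSV path; the sidecar is \code{<path>.yaml}
#' @export
writeScoreModel <- function(model, path) {
  df <- data.frame(probe_id = model@probeIds,
                   weight = sprintf("%.17g", model@weights))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(lambda1 = model@lambda1, lambda2 = model@lambda2,
               score_shift = sprintf("%.17g", model@scoreShift),
               score_scale = sprintf("%.17g", model@scoreScale),
               normalize = model@normalize)
  yaml::write_yaml(side, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname writeScoreModel
#' @param path TSV path written by \code{writeScoreModel} or a plain
#'   (probe_id, weight) table
#' @export
readScoreModel <- function(path) {
  df <- .readTable(path)
  .requireColumns(df, c("probe_id", "weight"), "score model")
  w <- .asNumericChecked(df$weight, "score model", "weight")
  sidecar <- paste0(path, ".yaml")
  if (file.exists(sidecar)) {
    side <- yaml::read_yaml(sidecar)
    ScoreModel(df$probe_id, w,
               lambda1 = as.numeric(side$lambda1),
               lambda2 = as.numeric(side$lambda2),
               scoreShift = as.numeric(side$score_shift),
               scoreScale = as.numeric(side$score_scale),
               normalize = isTRUE(side$normalize))
  } else {
    ScoreModel(df$probe_id, w)
  }
}
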