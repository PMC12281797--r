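#' Pipeline configuration
#'
#' Validated bag of stage parameters for [runPipeline()], all defaulting to
#' the package-wide values. Unknown keys are rejected before any
#' computation. \code{sim} holds overrides forwarded to [simConfig()].
#'
#' @param outdir output directory (created if absent)
#' @param seed master seed; drives the generators and makes reruns
#'   hash-identical
#' @param ... overrides of the defaults listed in the function definition
#' @return config list of class \code{"pipelineConfig"}
#' @export
pipelineConfig <- function(outdir, seed = 1, ...) {
  cfg <- list(outdir = outdir, seed = as.integer(seed),
              maxMissingFrac = 0.8, knnK = 10, epsilon = 1e-6,
              logfcMin = 0.1, alpha = 0.05,
              iccMin = 0.4, minPassFraction = 1,
              topChangeRate = 10,
              lambda1 = 0.01, lambda2 = 1,
              minMutRate = 0.03, ageCut = 65,
              rhoMin = c(0.4, 0.6), positionGap = 1000, minBlockSize = 5,
              stages = c("simulate", "preprocess", "dmp", "conserve",
                         "consistency", "score", "genetics", "blocks"),
              sim = list())
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("pipelineConfig: unknown key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipelineConfig")
}

#' Run the full analysis pipeline on synthetic data
#'
#' Chains every stage in dependency order: simulate (two paired weight-loss
#' cohorts, a multi-tissue reliability cohort, technical replicates, tumor
#' cohorts) -> preprocess -> paired differential probes per cohort ->
#' cross-cohort conservation and gene-direction concordance -> ICC and
#' change-rate reliability filters -> one-class score fit on post-surgery
#' samples -> scoring of tumor samples -> CIN, covariate screen,
#' per-chromosome regression, mutation tests, two-hit classification ->
#' co-methylated blocks at each correlation threshold. Every table is
#' written as TSV under \code{config$outdir} together with the effective
#' config (YAML) and a run log; the same seed reproduces every file
#' byte-identically.
#'
#' @param config a [pipelineConfig()]
#' @return invisibly, a list with the artifact manifest (stage -> file
#'   paths) and key in-memory results
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "pipelineConfig"))
    stop("runPipeline: config must come from pipelineConfig()")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(config$outdir, "run.log")
  logLines <- c(paste("methylLink pipeline, seed", config$seed),
                paste("R", getRversion()))
  note <- function(...) {
    msg <- paste(...)
    message(msg)
    logLines <<- c(logLines, msg)
  }
  outfile <- function(name) file.path(config$outdir, name)
  manifest <- list()
  emit <- function(stage, name, writer) {
    p <- outfile(name); writer(p)
    manifest[[stage]] <<- c(manifest[[stage]], p)
    p
  }
  yaml::write_yaml(unclass(config), outfile("effective_config.yaml"))

  ## --- simulate ------------------------------------------------------
  note("stage simulate")
  simA <- genPairedCohort(do.call(simConfig,
           c(list(seed = config$seed), config$sim)))
  simB <- genPairedCohort(do.call(simConfig,
           c(list(seed = config$seed + 1000L), config$sim)),
           truth = simA$truth)
  mt <- genMultitissue(do.call(simConfig,
           c(list(seed = config$seed + 2000L), config$sim)))
  reps <- genReplicates(do.call(simConfig,
           c(list(seed = config$seed + 3000L), config$sim)))
  tum <- genTumorCohort(do.call(simConfig,
           c(list(seed = config$seed + 4000L), config$sim)))
  emit("simulate", "cohortA_beta.tsv",
       function(p) writeBetaMatrix(simA$beta, p))
  emit("simulate", "cohortA_samples.tsv",
       function(p) writeSamples(simA$samples, p))
  emit("simulate", "manifest.tsv",
       function(p) writeManifest(simA$manifest, p))
  emit("simulate", "tumor_segments.tsv",
       function(p) writeSegments(tum$segments, p))
  emit("simulate", "tumor_mutations.tsv",
       function(p) writeMutations(tum$mutations, p))
  emit("simulate", "truth_dmp_cohortA.tsv", function(p)
    write.table(simA$truth, p, sep = "\t", quote = FALSE,
                row.names = FALSE))

  ## --- preprocess ----------------------------------------------------
  note("stage preprocess")
  prep <- function(sim) {
    bs <- qcFilterSamples(sim$beta, config$maxMissingFrac)
    bs <- imputeKNN(bs, config$knnK)
    betaToM(bs, config$epsilon)
  }
  mmA <- prep(simA); mmB <- prep(simB)

  ## --- differential probes per cohort --------------------------------
  note("stage dmp")
  drA <- pairedDMP(mmA, groupLevels = c("pre", "post"),
                   logfcMin = config$logfcMin, alpha = config$alpha)
  drB <- pairedDMP(mmB, groupLevels = c("pre", "post"),
                   logfcMin = config$logfcMin, alpha = config$alpha)
  emit("dmp", "dmp_cohortA.tsv", function(p)
    write.table(drA, p, sep = "\t", quote = FALSE, row.names = FALSE))
  emit("dmp", "dmp_cohortB.tsv", function(p)
    write.table(drB, p, sep = "\t", quote = FALSE, row.names = FALSE))

  ## --- conservation + concordance ------------------------------------
  note("stage conserve")
  keepA <- concordantGeneFilter(drA, simA$manifest)
  keepB <- concordantGeneFilter(drB, simB$manifest)
  cons <- jaccardConservation(keepA, keepB)
  consensus <- intersect(keepA, keepB)
  note(sprintf("  cohort Jaccard %.3f; consensus probes %d",
               cons$jaccard, length(consensus)))
  catTab <- categorySummary(drA, simA$manifest)
  emit("conserve", "conservation.tsv", function(p)
    write.table(as.data.frame(cons)[, c("n_a", "n_b", "intersection",
                                        "union", "jaccard")],
                p, sep = "\t", quote = FALSE, row.names = FALSE))
  emit("conserve", "category_summary.tsv", function(p)
    write.table(data.frame(island_relation = rownames(catTab), catTab),
                p, sep = "\t", quote = FALSE, row.names = FALSE))

  ## --- reliability ----------------------------------------------------
  note("stage consistency")
  candidates <- if (length(consensus)) consensus else
    head(drA$probe_id[order(drA$p_adj)], 20)
  mtM <- betaToM(mt$beta, config$epsilon)
  iccRes <- iccFilter(mtM, mt$samples, candidates,
                      referenceTissue = "skeletal muscle",
                      iccMin = config$iccMin,
                      minPassFraction = config$minPassFraction)
  note(sprintf("  %d / %d candidate probes pass ICC > %g",
               length(iccRes$pass), length(candidates), config$iccMin))
  emit("consistency", "icc_matrix.tsv", function(p)
    write.table(data.frame(probe_id = rownames(iccRes$icc), iccRes$icc,
                           check.names = FALSE),
                p, sep = "\t", quote = FALSE, row.names = FALSE))
  cr <- rankByChangeRate(reps$beta, reps$pairs, config$topChangeRate)
  emit("consistency", "change_rate_top.tsv", function(p)
    write.table(cr, p, sep = "\t", quote = FALSE, row.names = FALSE))

  ## --- score fit + scoring -------------------------------------------
  note("stage score")
  scoreProbes <- if (length(iccRes$pass) >= 2) iccRes$pass else candidates
  postIds <- simA$samples$sample_id[simA$samples$group == "post"]
  trainBs <- mToBeta(mmA)[scoreProbes, postIds]
  L <- buildProbeGraph(simA$manifest, scoreProbes, mode = "by-gene")
  ## probe beta profiles are strongly correlated through subject effects,
  ## so the fit is verified at the package's KKT tolerance rather than the
  ## tighter toy-problem default
  model <- fitGelnet(trainBs, lambda1 = config$lambda1,
                     lambda2 = config$lambda2, laplacian = L,
                     normalize = TRUE, tol = 1e-8, kktTol = 1e-6)
  emit("score", "score_model.tsv", function(p) writeScoreModel(model, p))
  tumScores <- scoreSamples(model, tum$beta)
  emit("score", "tumor_scores.tsv", function(p)
    write.table(tumScores, p, sep = "\t", quote = FALSE, row.names = FALSE))

  ## --- genetics coupling ---------------------------------------------
  note("stage genetics")
  cin <- cinScore(tum$segments, tum$chromLengths,
                  samples = tum$samples$sample_id)
  emit("genetics", "cin.tsv", function(p)
    write.table(cin, p, sep = "\t", quote = FALSE, row.names = FALSE))
  screens <- list(); mutTests <- list(); twoHits <- list()
  diffGenes <- unique(simA$manifest$gene[
    simA$manifest$probe_id %in% consensus & simA$manifest$gene != ""])
  for (co in unique(tum$samples$cohort)) {
    ids <- tum$samples$sample_id[tum$samples$cohort == co]
    sc <- tumScores[tumScores$sample_id %in% ids, ]
    screens[[co]] <- cbind(cohort = co,
      covariateScreen(sc, tum$samples, cin[cin$sample_id %in% ids, ]))
    mm <- binarizeMutations(tum$mutations, ids)
    mt_ <- mutationScoreTest(sc, mm, minRate = config$minMutRate)
    mutTests[[co]] <- if (nrow(mt_)) cbind(cohort = co, mt_) else NULL
    if (nrow(mt_))
      twoHits[[co]] <- cbind(cohort = co,
                             twoHitClassify(mt_, diffGenes, config$alpha))
  }
  reg <- perChromosomeRegression(tumScores, cin, tum$samples,
                                 ageCut = config$ageCut)
  emit("genetics", "covariate_screen.tsv", function(p)
    write.table(do.call(rbind, screens), p, sep = "\t", quote = FALSE,
                row.names = FALSE))
  emit("genetics", "per_chromosome_regression.tsv", function(p)
    write.table(reg, p, sep = "\t", quote = FALSE, row.names = FALSE))
  emit("genetics", "mutation_tests.tsv", function(p)
    write.table(do.call(rbind, mutTests), p, sep = "\t", quote = FALSE,
                row.names = FALSE))
  emit("genetics", "two_hit.tsv", function(p)
    write.table(do.call(rbind, twoHits), p, sep = "\t", quote = FALSE,
                row.names = FALSE))

  ## --- co-methylated blocks ------------------------------------------
  note("stage blocks")
  ampIds <- tum$truth$samples$sample_id[tum$truth$samples$amplified]
  ampCalls <- callAmplification(tum$segments, tum$regionGenes)
  emit("blocks", "amplification_calls.tsv", function(p)
    write.table(ampCalls, p, sep = "\t", quote = FALSE, row.names = FALSE))
  for (rho in config$rhoMin) {
    blk <- findBlocks(tum$beta[, ampIds], tum$manifest, rhoMin = rho,
                      positionGap = config$positionGap,
                      minBlockSize = config$minBlockSize,
                      chromosome = "chr19")
    nm <- sprintf("blocks_chr19_rho%s.tsv", gsub("\\.", "", rho))
    emit("blocks", nm, function(p)
      write.table(blk, p, sep = "\t", quote = FALSE, row.names = FALSE))
    if (nrow(blk))
      emit("blocks", sub("tsv$", "bed", nm),
           function(p) blocksToBed(blk, p))
  }
  writeLines(logLines, logFile)
  invisible(list(manifest = manifest,
                 conservation = cons,
                 icc_pass = iccRes$pass,
                 model = model,
                 scores = tumScores))
}
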