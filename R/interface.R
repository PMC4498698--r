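## Reproducible simulate -> optimize -> validate -> behaviour runs.  A YAML
## config (all defaults echoed into the output manifest for provenance)
## drives four commands, also exposed through the inst/cli/npairsopt
## Rscript entry point.

defaultConfig <- function() {
  list(seed = 1L,
       tasks = "REC",
       nTest = 4L, nRetest = 2L,
       nScans = 48L, gridShape = c(16L, 16L, 8L), trS = 2,
       model = "GNB",
       strategies = c("CONS", "IND-D"),
       gridPreset = "desk",
       flagOptions = list(),
       detrendOrders = NULL, kValues = NULL,
       fwhmMm = 6,
       behaviourCoupling = 1,
       artifactThreshold = 0.6,
       fdrQ = 0.05,
       plsIter = 100L, nBoot = 1000L)
}

#' Read a run configuration
#'
#' Loads a YAML file (or takes a list) and merges it over the package
#' defaults; unknown keys are rejected.
#'
#' @param config path to a YAML file, a list, or NULL for defaults.
#' @export
readRunConfig <- function(config = NULL) {
  base <- defaultConfig()
  if (is.null(config)) return(base)
  user <- if (is.character(config)) yaml::read_yaml(config) else config
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  base[names(user)] <- user
  base$strategies <- match.arg(base$strategies,
                               c("CONS", "FIX", "IND-P", "IND-R", "IND-D"),
                               several.ok = TRUE)
  if (!all(base$tasks %in% c("REC", "TMT", "SART")))
    stop("invalid task name: ",
         paste(setdiff(base$tasks, c("REC", "TMT", "SART")), collapse = ", "))
  base
}

configGrid <- function(config) {
  if (identical(config$gridPreset, "desk") && is.null(config$detrendOrders))
    return(deskGrid(config$model, flagOptions = config$flagOptions))
  if (identical(config$gridPreset, "full") && is.null(config$detrendOrders))
    return(enumeratePipelines(config$model,
                              flagOptions = config$flagOptions))
  enumeratePipelines(config$model, flagOptions = config$flagOptions,
                     detrendOrders = config$detrendOrders %||% 0:5,
                     kValues = config$kValues %||% 1:10)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

runKeys <- function(cohort) names(cohort@runs)

#' Simulate a synthetic cohort to disk
#'
#' Writes per-run NIfTI/TSV/physio/ground-truth files, the behaviour CSV and
#' a manifest JSON (full configuration, file list and MD5 checksums).
#'
#' @param config config path, list or NULL (see \code{\link{readRunConfig}}).
#' @param outDir output directory.
#' @param seed overrides the config seed when given.
#' @return the manifest, invisibly.
#' @export
cmdSimulate <- function(config = NULL, outDir, seed = NULL) {
  cfg <- readRunConfig(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generateCohort(seed = cfg$seed, nTest = cfg$nTest,
                           nRetest = cfg$nRetest, tasks = cfg$tasks,
                           behaviourCoupling = cfg$behaviourCoupling,
                           nScans = cfg$nScans, gridShape = cfg$gridShape,
                           trS = cfg$trS)
  runDir <- file.path(outDir, "runs")
  for (key in runKeys(cohort)) {
    writeSubjectRun(cohort@runs[[key]], runDir, key)
  }
  write.csv(cohort@behaviour, file.path(outDir, "behaviour.csv"),
            row.names = FALSE)
  files <- sort(list.files(outDir, recursive = TRUE))
  files <- setdiff(files, "manifest.json")
  manifest <- list(config = cfg, runs = runKeys(cohort),
                   nRuns = length(cohort@runs), files = files,
                   md5 = unname(tools::md5sum(file.path(outDir, files))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

loadCohortRuns <- function(outDir) {
  manifest <- jsonlite::read_json(file.path(outDir, "manifest.json"),
                                  simplifyVector = TRUE)
  runs <- lapply(manifest$runs, function(key)
    readSubjectRun(file.path(outDir, "runs"), key))
  names(runs) <- manifest$runs
  list(manifest = manifest, runs = runs)
}

#' Optimize pipelines for every simulated run
#'
#' Evaluates the configured pipeline grid per run, applies motion-artifact
#' rejection, writes the full metrics CSV, and stores the selected
#' pipeline spec (JSON) and optimized rSPM(Z) NIfTI per strategy.
#'
#' @param config config path, list or NULL.
#' @param outDir directory previously populated by \code{\link{cmdSimulate}}.
#' @return per-run selection summary, invisibly.
#' @export
cmdOptimize <- function(config = NULL, outDir) {
  cfg <- readRunConfig(config)
  cc <- loadCohortRuns(outDir)
  grid <- configGrid(cfg)
  optDir <- file.path(outDir, "opt")
  dir.create(optDir, recursive = TRUE, showWarnings = FALSE)
  tables <- list()
  for (key in names(cc$runs)) {
    mt <- evaluateGrid(cc$runs[[key]], grid, fwhmMm = cfg$fwhmMm)
    mt <- rejectArtifactPipelines(mt, cfg$artifactThreshold)
    tables[[key]] <- mt
    writeMetricTable(mt, file.path(optDir, paste0(key, "_metrics.csv")))
  }
  fixSpec <- if ("FIX" %in% cfg$strategies) selectFixed(tables) else NULL
  summary <- list()
  for (key in names(tables)) {
    mt <- tables[[key]]
    for (strat in cfg$strategies) {
      spec <- switch(strat,
        "CONS" = consPipeline(cfg$model,
                              cvaK = if (cfg$model == "CVA") 2L else NULL),
        "FIX" = fixSpec,
        "IND-P" = selectIndividual(mt, "P"),
        "IND-R" = selectIndividual(mt, "R"),
        "IND-D" = selectIndividual(mt, "D"))
      idx <- attr(spec, "index") %||% specRowIndex(mt@grid, spec)
      if (length(idx)) {
        idx <- idx[1L]
        row <- mt@table[idx, ]
        met <- list(P = row$P, R = row$R, gSNR = row$gSNR, D = row$D,
                    edgeScore = row$edgeScore)
        zvec <- mt@zmaps[, idx]
        maskIdx <- mt@maskIdx
        spec <- specFromGrid(mt@grid, idx)
      } else {
        ## spec outside the evaluated grid (e.g. CONS under a restricted
        ## grid): evaluate it directly
        mr <- evaluateSpec(cc$runs[[key]], spec, fwhmMm = cfg$fwhmMm)
        met <- list(P = mr@P, R = mr@R, gSNR = mr@gSNR, D = mr@D,
                    edgeScore = edgeArtifactScore(mr@zmap,
                                                  cc$runs[[key]]@brainMask,
                                                  mr@maskIdx))
        zvec <- mr@zmap
        maskIdx <- mr@maskIdx
      }
      tag <- gsub("-", "", strat)
      jsonlite::write_json(
        c(list(strategy = strat, spec = specToList(spec)), met,
          list(gridSize = gridSize(mt@grid))),
        file.path(optDir, paste0(key, "_", tag, ".json")),
        auto_unbox = TRUE, digits = NA)
      z <- spmToVolume(zvec, maskIdx, mt@dim3)
      RNifti::writeNifti(RNifti::asNifti(z),
                         file.path(optDir, paste0(key, "_", tag,
                                                  "_z.nii.gz")))
      summary[[paste(key, strat)]] <- data.frame(
        run = key, strategy = strat, P = met$P, R = met$R, D = met$D)
    }
  }
  out <- do.call(rbind, summary)
  rownames(out) <- NULL
  write.csv(out, file.path(optDir, "selection_summary.csv"),
            row.names = FALSE)
  invisible(out)
}

loadStrategyMasks <- function(outDir, cfg) {
  cc <- loadCohortRuns(outDir)
  manifest <- cc$manifest
  rows <- list()
  for (key in manifest$runs) {
    run <- cc$runs[[key]]
    for (strat in cfg$strategies) {
      tag <- gsub("-", "", strat)
      zf <- file.path(outDir, "opt", paste0(key, "_", tag, "_z.nii.gz"))
      if (!file.exists(zf)) stop("missing optimized SPM: ", zf)
      z <- array(as.numeric(RNifti::readNifti(zf)), gridShape(run))
      mask <- array(FALSE, gridShape(run))
      nz <- z != 0
      mask[nz] <- fdrMask(z[nz], cfg$fdrQ)
      rows[[paste(key, strat)]] <- data.frame(
        subject = run@subject, session = run@session, run = run@run,
        task = run@task, strategy = strat)
      rows[[paste(key, strat)]]$mask <- list(mask)
      rows[[paste(key, strat)]]$zmap <- list(z)
    }
  }
  do.call(rbind, rows)
}

#' Validate optimized pipelines by activation overlap
#'
#' Thresholds every stored rSPM(Z) at the configured FDR level, computes
#' within-subject (between-session) and between-subject (within-session)
#' Jaccard overlap tables per task and strategy, and a paired Wilcoxon
#' comparison of each strategy against CONS.
#'
#' @param config config path, list or NULL.
#' @param outDir directory holding simulate + optimize outputs.
#' @return summary list, invisibly.
#' @export
cmdValidate <- function(config = NULL, outDir) {
  cfg <- readRunConfig(config)
  spms <- loadStrategyMasks(outDir, cfg)
  valDir <- file.path(outDir, "validate")
  dir.create(valDir, recursive = TRUE, showWarnings = FALSE)
  summary <- list()
  for (task in cfg$tasks) {
    for (strat in cfg$strategies) {
      wo <- withinSubjectOverlap(spms, task, strat)
      bo <- betweenSubjectOverlap(spms, task, strat)
      tag <- gsub("-", "", strat)
      write.csv(wo, file.path(valDir,
                              sprintf("within_%s_%s.csv", task, tag)),
                row.names = FALSE)
      write.csv(bo, file.path(valDir,
                              sprintf("between_%s_%s.csv", task, tag)),
                row.names = FALSE)
      summary[[paste(task, strat)]] <-
        list(task = task, strategy = strat,
             withinRows = nrow(wo), withinMean = mean(wo$jaccard),
             betweenRows = nrow(bo), betweenMean = mean(bo$jaccard))
    }
    if ("CONS" %in% cfg$strategies) {
      for (strat in setdiff(cfg$strategies, "CONS")) {
        bA <- betweenSubjectOverlap(spms, task, strat)
        bC <- betweenSubjectOverlap(spms, task, "CONS")
        if (nrow(bA) == nrow(bC) && nrow(bA) >= 5L) {
          summary[[paste(task, strat, "vsCONS")]] <-
            list(task = task, strategy = strat, comparison = "between-vs-CONS",
                 p = as.numeric(pairedWilcoxon(bA$jaccard, bC$jaccard)))
        }
      }
    }
  }
  jsonlite::write_json(summary, file.path(valDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}

#' Behavioural PLS validation of optimized pipelines
#'
#' Screens behavioural and fMRI outliers, runs split-half behavioural PLS
#' per strategy on the stored rSPM(Z) maps against the behaviour table, and
#' bootstraps the difference of each strategy against CONS.
#'
#' @param config config path, list or NULL.
#' @param outDir directory holding simulate + optimize outputs.
#' @return report list, invisibly.
#' @export
cmdBehaviour <- function(config = NULL, outDir) {
  cfg <- readRunConfig(config)
  behFile <- file.path(outDir, "behaviour.csv")
  if (!file.exists(behFile)) stop("behaviour table absent: ", behFile)
  beh <- read.csv(behFile)
  spms <- loadStrategyMasks(outDir, cfg)
  behDir <- file.path(outDir, "behaviour_pls")
  dir.create(behDir, recursive = TRUE, showWarnings = FALSE)
  set.seed(deriveSeed(cfg$seed, 991L))
  report <- list()
  results <- list()
  for (task in cfg$tasks) {
    for (strat in cfg$strategies) {
      sel <- spms$task == task & spms$strategy == strat
      sub <- spms[sel, , drop = FALSE]
      behT <- beh[beh$task == task, , drop = FALSE]
      key <- paste(sub$subject, sub$session, sub$run)
      bkey <- paste(behT$subject, behT$session, behT$run)
      b <- behT$behaviour[match(key, bkey)]
      M <- do.call(rbind, lapply(sub$zmap, as.numeric))
      bOut <- flagBehaviourOutliers(behT[match(key, bkey), , drop = FALSE])
      fOut <- flagFmriOutliers(M)
      keep <- !bOut & !fOut & !is.na(b)
      pls <- plsSplitHalf(M[keep, , drop = FALSE], b[keep],
                          nIter = cfg$plsIter,
                          stratifyBy = sub$session[keep])
      results[[paste(task, strat)]] <- pls
      report[[paste(task, strat)]] <-
        list(task = task, strategy = strat, nRuns = sum(keep),
             nOutliers = sum(!keep), medianRho = pls@medianRho,
             medianGsnr = pls@medianGsnr)
    }
    if ("CONS" %in% cfg$strategies) {
      for (strat in setdiff(cfg$strategies, "CONS")) {
        bd <- bootstrapDelta(results[[paste(task, strat)]],
                             results[[paste(task, "CONS")]],
                             nBoot = cfg$nBoot)
        report[[paste(task, strat, "vsCONS")]] <-
          c(list(task = task, strategy = strat,
                 comparison = "delta-vs-CONS"), bd)
      }
    }
  }
  jsonlite::write_json(report, file.path(behDir, "pls_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
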