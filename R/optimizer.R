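## Exhaustive pipeline grid: 8 binary steps x detrend orders 0..5 gives
## 2^8 x 6 = 1536 GNB pipelines; CVA adds PCA subspace sizes k = 1..10 for
## 2^8 x 6 x 10 = 15360.  Selection rules: CONS (fixed conservative set),
## FIX (lowest median D-rank across runs), IND-P / IND-R / IND-D (per-run
## argmax P / argmax R / argmin D among artifact-eligible rows).

flagNames <- c("mc", "cens", "ret", "stc", "mpr", "gspc1", "taskReg", "phy")

#' Enumerate the preprocessing pipeline grid
#'
#' Cartesian product of the optimised step options in canonical order: the 8
#' binary flags as a binary counter (mc the most significant bit), then the
#' detrend order, then (CVA) the subspace size k.  Option lists can be
#' restricted for reduced grids; the defaults give the full grid.
#'
#' @param model "GNB" or "CVA".
#' @param flagOptions named list of allowed values per binary step.
#' @param detrendOrders allowed Legendre orders (default 0:5).
#' @param kValues allowed CVA subspace sizes (default 1:10).
#' @return a \linkS4class{PipelineGrid}.
#' @export
enumeratePipelines <- function(model = c("GNB", "CVA"), flagOptions = list(),
                               detrendOrders = 0:5, kValues = 1:10) {
  model <- match.arg(model)
  opts <- lapply(flagNames, function(f)
    if (!is.null(flagOptions[[f]])) flagOptions[[f]] else c(FALSE, TRUE))
  names(opts) <- flagNames
  opts$detrendOrder <- as.integer(detrendOrders)
  if (model == "CVA") opts$cvaK <- as.integer(kValues)
  ## expand.grid varies the first factor fastest; reverse for canonical
  ## order (flags as a counter, then N, then k)
  g <- expand.grid(rev(opts), KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  g <- g[, rev(seq_along(g)), drop = FALSE]
  if (model == "GNB") g$cvaK <- NA_integer_
  g$model <- model
  rownames(g) <- NULL
  new("PipelineGrid", specs = g, model = model)
}

#' Extract one PipelineSpec from a grid row
#' @param grid a \linkS4class{PipelineGrid}.
#' @param i row index.
#' @export
specFromGrid <- function(grid, i) {
  r <- grid@specs[i, ]
  PipelineSpec(mc = r$mc, cens = r$cens, ret = r$ret, stc = r$stc,
               mpr = r$mpr, gspc1 = r$gspc1, taskReg = r$taskReg,
               phy = r$phy, detrendOrder = r$detrendOrder, model = r$model,
               cvaK = r$cvaK)
}

specRowIndex <- function(grid, spec) {
  g <- grid@specs
  hit <- g$mc == spec@mc & g$cens == spec@cens & g$ret == spec@ret &
    g$stc == spec@stc & g$mpr == spec@mpr & g$gspc1 == spec@gspc1 &
    g$taskReg == spec@taskReg & g$phy == spec@phy &
    g$detrendOrder == spec@detrendOrder
  if (grid@model == "CVA") hit <- hit & g$cvaK == spec@cvaK
  which(hit)
}

#' Reduced desk-scale grid
#'
#' Restricts detrend orders to {0, 1, 3, 5} and CVA subspace sizes to
#' {1, 3, 5} for fast exploratory runs; the full grid remains the default
#' contract of \code{\link{enumeratePipelines}}.
#' @inheritParams enumeratePipelines
#' @export
deskGrid <- function(model = c("GNB", "CVA"), flagOptions = list()) {
  enumeratePipelines(model, flagOptions = flagOptions,
                     detrendOrders = c(0L, 1L, 3L, 5L), kValues = c(1L, 3L, 5L))
}

#' The conservative (CONS) pipeline
#'
#' Motion correction, censoring, RETROICOR, slice-timing correction and
#' motion-parameter regression ON with linear detrending; global-signal,
#' task-design and data-driven physiological steps OFF.  For CVA the
#' subspace size is an analysis parameter: it is chosen by best D over
#' \code{kValues} when a run is supplied, or must be given explicitly.
#'
#' @param model "GNB" or "CVA".
#' @param bundle optional raw \linkS4class{SubjectRun} used to pick k (CVA).
#' @param cvaK explicit subspace size (CVA).
#' @param kValues candidate k values when choosing from data.
#' @export
consPipeline <- function(model = c("GNB", "CVA"), bundle = NULL,
                         cvaK = NULL, kValues = 1:10) {
  model <- match.arg(model)
  base <- function(k) PipelineSpec(mc = TRUE, cens = TRUE, ret = TRUE,
                                   stc = TRUE, mpr = TRUE,
                                   detrendOrder = 1L, model = model,
                                   cvaK = if (model == "CVA") k
                                          else NA_integer_)
  if (model == "GNB") return(base(NA_integer_))
  if (!is.null(cvaK)) return(base(as.integer(cvaK)))
  if (is.null(bundle))
    stop("CVA CONS pipeline needs either cvaK or a run to choose it from")
  best <- NULL
  bestD <- Inf
  for (k in kValues) {
    sp <- base(as.integer(k))
    pp <- applyPipeline(bundle, sp)
    mr <- npairsEvaluate(pp$run, sp)
    if (mr@D < bestD) { bestD <- mr@D; best <- sp }
  }
  best
}

#' Evaluate every pipeline of a grid on one run
#'
#' Applies each PipelineSpec (caching the shared image-domain stage and GLM
#' components; cached results equal naive recomputation) and runs the NPAIRS
#' split-half evaluation, producing one row of (P, R, gSNR, D) plus the
#' rSPM(Z) map and its edge-artifact score per pipeline.  The non-neuronal
#' tissue mask is computed once per run so all pipelines share a consistent
#' voxel set.  Per-pipeline failures are recorded as flagged rows.
#'
#' @param bundle a raw \linkS4class{SubjectRun}.
#' @param grid a \linkS4class{PipelineGrid}.
#' @param fwhmMm fixed smoothing kernel (mm).
#' @param cache reuse shared image-stage results (default TRUE).
#' @param posterior GNB posterior mode.
#' @return a \linkS4class{MetricTable}.
#' @export
evaluateGrid <- function(bundle, grid, fwhmMm = 6, cache = TRUE,
                         posterior = "joint") {
  g <- grid@specs
  M <- nrow(g)
  needMotion <- any(g$mc) || any(g$mpr)
  ref <- selectReferenceVolume(bundle)
  mp0 <- if (needMotion)
    motionCorrect(bundle, ref, estimateOnly = TRUE)$motion else NULL
  ## consistent non-neuronal mask: smoothed raw data, no optional steps
  base <- imagePreprocess(bundle, FALSE, FALSE, FALSE, FALSE,
                          fwhmMm = fwhmMm, ref = ref)
  noiseMask <- estimateNoiseMask(base$run)
  maskIdx <- which(bundle@brainMask & !noiseMask)

  imgKey <- paste(g$mc, g$cens, g$ret, g$stc)
  imgCache <- list()
  tab <- data.frame(g, P = NA_real_, R = NA_real_, gSNR = NA_real_,
                    D = NA_real_, edgeScore = NA_real_, eligible = TRUE,
                    failed = FALSE, degenerate = FALSE)
  zmaps <- matrix(NA_real_, length(maskIdx), M)

  for (i in seq_len(M)) {
    key <- imgKey[i]
    if (cache && !is.null(imgCache[[key]])) {
      img <- imgCache[[key]]
    } else {
      img <- imagePreprocess(bundle, g$mc[i], g$cens[i], g$ret[i], g$stc[i],
                             fwhmMm = fwhmMm, motionParams = mp0,
                             needMotion = TRUE, ref = ref)
      if (cache) imgCache[[key]] <- img
    }
    res <- tryCatch({
      spec <- specFromGrid(grid, i)
      st <- glmStage(img$run, spec, img$mp, noiseMask)
      mr <- npairsEvaluate(st$run, spec, posterior = posterior)
      mr
    }, error = function(e) e)
    if (inherits(res, "error")) {
      tab$failed[i] <- TRUE
      tab$eligible[i] <- FALSE
      next
    }
    tab$P[i] <- res@P
    tab$R[i] <- res@R
    tab$gSNR[i] <- res@gSNR
    tab$D[i] <- res@D
    tab$degenerate[i] <- any(res@degenerate)
    zmaps[, i] <- res@zmap
    tab$edgeScore[i] <- edgeArtifactScore(res@zmap, bundle@brainMask,
                                          res@maskIdx)
  }
  new("MetricTable", table = tab, zmaps = zmaps,
      maskIdx = as.integer(maskIdx),
      dim3 = as.integer(gridShape(bundle)), grid = grid)
}

#' Edge-artifact score of a Z map
#'
#' Motion-corrupted SPMs concentrate weight on the brain edge.  The score is
#' mean |Z| on the 1-voxel boundary shell of the brain mask divided by the
#' sum of the shell and interior means: 0.5 means no edge preference, 1
#' means all weight on the shell.
#'
#' @param zmap statistic values over \code{maskIdx}.
#' @param brainMask logical 3D mask.
#' @param maskIdx linear voxel indices of \code{zmap} within the grid.
#' @return score in [0, 1].
#' @export
edgeArtifactScore <- function(zmap, brainMask, maskIdx) {
  interior <- erodeMask(brainMask)
  if (!any(interior)) stop("empty mask interior")
  shell <- brainMask & !interior
  vol <- array(NA_real_, dim(brainMask))
  vol[maskIdx] <- abs(zmap)
  ms <- mean(vol[shell], na.rm = TRUE)
  mi <- mean(vol[interior], na.rm = TRUE)
  if (!is.finite(ms)) ms <- 0
  if (!is.finite(mi)) mi <- 0
  if (ms + mi == 0) return(0.5)
  ms / (ms + mi)
}

#' Flag motion-artifact pipelines as ineligible
#'
#' Rows whose edge-artifact score exceeds \code{threshold} are excluded from
#' IND selection.  Rejection never removes every row: if it would, it is
#' disabled with a warning.
#'
#' @param mt a \linkS4class{MetricTable}.
#' @param threshold edge-score cutoff (default 0.6, from null calibration).
#' @export
rejectArtifactPipelines <- function(mt, threshold = 0.6) {
  ok <- !mt@table$failed
  bad <- ok & !is.na(mt@table$edgeScore) & mt@table$edgeScore > threshold
  if (all(bad | !ok)) {
    warning("artifact rejection would flag every pipeline; disabled")
    return(mt)
  }
  mt@table$eligible <- ok & !bad
  mt
}

#' Individually optimised pipeline (IND)
#'
#' Selects the eligible grid row maximising P (IND-P), maximising R (IND-R)
#' or minimising D (IND-D); ties resolve to canonical grid order.
#'
#' @param mt a \linkS4class{MetricTable}.
#' @param criterion "P", "R" or "D".
#' @return the selected \linkS4class{PipelineSpec} (row index in attribute
#'   \code{"index"}).
#' @export
selectIndividual <- function(mt, criterion = c("D", "P", "R")) {
  criterion <- match.arg(criterion)
  tab <- mt@table
  el <- which(tab$eligible & !tab$failed & is.finite(tab$D))
  if (!length(el)) stop("no eligible pipelines")
  val <- switch(criterion, P = tab$P[el], R = tab$R[el], D = -tab$D[el])
  pick <- el[which.max(val)]
  spec <- specFromGrid(mt@grid, pick)
  attr(spec, "index") <- pick
  spec
}

#' Fixed optimised pipeline (FIX) by median D-rank
#'
#' For M pipelines and S runs: rank the pipelines 1..M within each run by D
#' (rank 1 best), take each pipeline's median rank across runs, and select
#' the pipeline with the lowest median; ties resolve by lower mean rank,
#' then canonical order.  All tables must share one grid.
#'
#' @param mts list of \linkS4class{MetricTable}s over the same grid.
#' @return the selected \linkS4class{PipelineSpec} (row index in attribute
#'   \code{"index"}).
#' @export
selectFixed <- function(mts) {
  if (!length(mts)) stop("no metric tables")
  M <- nrow(mts[[1L]]@table)
  for (mt in mts) {
    if (nrow(mt@table) != M ||
        !identical(mt@grid@specs[flagNames], mts[[1L]]@grid@specs[flagNames]))
      stop("grid mismatch across runs")
  }
  ranks <- vapply(mts, function(mt) {
    d <- mt@table$D
    d[!is.finite(d)] <- Inf
    rank(d, ties.method = "average")
  }, numeric(M))
  ranks <- matrix(ranks, M)
  med <- apply(ranks, 1L, median)
  mn <- rowMeans(ranks)
  pick <- order(med, mn)[1L]
  spec <- specFromGrid(mts[[1L]]@grid, pick)
  attr(spec, "index") <- pick
  spec
}

#' Evaluate a single pipeline spec on one raw run
#'
#' Convenience wrapper: applies the pipeline and runs the NPAIRS split-half
#' evaluation.
#'
#' @param bundle a raw \linkS4class{SubjectRun}.
#' @param spec a \linkS4class{PipelineSpec}.
#' @param fwhmMm fixed smoothing kernel (mm).
#' @return a \linkS4class{MetricResult}.
#' @export
evaluateSpec <- function(bundle, spec, fwhmMm = 6) {
  pp <- applyPipeline(bundle, spec, fwhmMm = fwhmMm)
  npairsEvaluate(pp$run, spec)
}
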