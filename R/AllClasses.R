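setClassUnion("PhysioTraceOrNULL", "NULL")
setClassUnion("GroundTruthOrNULL", "NULL")
setClassUnion("MatrixOrNULL", c("matrix", "NULL"))

#' 4D BOLD time series
#'
#' A 4D intensity grid (x, y, z, t) with its repetition time, voxel sizes and
#' per-slice acquisition offsets.
#'
#' @slot data 4D numeric array (x, y, z, t).
#' @slot trS repetition time in seconds.
#' @slot voxelMm voxel edge lengths in mm (length 3).
#' @slot sliceTimesS per-z-slice acquisition offsets in seconds, each in
#'   \code{[0, trS)}.
#' @exportClass VolumeSeries
setClass("VolumeSeries",
  representation(data = "array", trS = "numeric", voxelMm = "numeric",
                 sliceTimesS = "numeric"))

setValidity("VolumeSeries", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L) return("data must be a 4D array")
  if (d[4L] < 2L) return("at least 2 scans required")
  if (!all(is.finite(object@data))) return("non-finite intensities")
  if (length(object@voxelMm) != 3L || any(object@voxelMm <= 0))
    return("voxelMm must be 3 positive lengths")
  if (length(object@trS) != 1L || object@trS <= 0)
    return("trS must be a positive scalar")
  if (length(object@sliceTimesS) != d[3L])
    return("sliceTimesS length must equal the z extent")
  if (any(object@sliceTimesS < 0 | object@sliceTimesS >= object@trS))
    return("slice times must lie in [0, trS)")
  TRUE
})

#' @param data,trS,voxelMm,sliceTimesS see slots.
#' @rdname VolumeSeries-class
#' @export
VolumeSeries <- function(data, trS, voxelMm = c(3, 3, 5), sliceTimesS = NULL) {
  if (is.null(sliceTimesS)) sliceTimesS <- rep(0, dim(data)[3L])
  new("VolumeSeries", data = data, trS = trS, voxelMm = as.numeric(voxelMm),
      sliceTimesS = as.numeric(sliceTimesS))
}

#' Task design
#'
#' Either a block design (one condition label per scan) or an event-related
#' design (onsets/durations in seconds plus a peristimulus window length in
#' TRs, each time lag within the window forming one prediction class).
#'
#' @slot kind "block" or "event".
#' @slot labels per-scan condition labels (block designs).
#' @slot onsetsS,durationsS,conditions event tables (event designs); onsets in
#'   seconds from the acquisition of scan 1.
#' @slot nClasses number of prediction classes (>= 2).
#' @slot windowTrs peristimulus window length in TRs for event designs.
#' @slot nScans number of scans covered by the design.
#' @exportClass TaskDesign
setClass("TaskDesign",
  representation(kind = "character", labels = "character",
                 onsetsS = "numeric", durationsS = "numeric",
                 conditions = "character", nClasses = "integer",
                 windowTrs = "integer", nScans = "integer"))

setValidity("TaskDesign", function(object) {
  if (!object@kind %in% c("block", "event")) return("kind must be block/event")
  if (object@nClasses < 2L) return("nClasses must be >= 2")
  if (object@kind == "block" && length(object@labels) != object@nScans)
    return("block designs need one label per scan")
  if (object@kind == "event") {
    if (object@windowTrs < 1L) return("windowTrs must be >= 1")
    if (length(object@onsetsS) != length(object@durationsS))
      return("onsets/durations length mismatch")
  }
  TRUE
})

#' Construct a block task design from per-scan condition labels
#' @param labels character vector, one condition per scan.
#' @export
blockDesign <- function(labels) {
  labels <- as.character(labels)
  new("TaskDesign", kind = "block", labels = labels,
      onsetsS = numeric(), durationsS = numeric(), conditions = character(),
      nClasses = length(unique(labels)), windowTrs = 1L,
      nScans = length(labels))
}

#' Construct an event-related task design
#'
#' Scans are class-labelled by peristimulus lag over a `windowTrs`-TR window
#' following each onset (each lag is one class).
#' @param onsetsS,durationsS event onsets and durations in seconds.
#' @param nScans number of scans in the run.
#' @param windowTrs peristimulus window length in TRs (default 9).
#' @param conditions optional condition name per event.
#' @export
eventDesign <- function(onsetsS, durationsS, nScans, windowTrs = 9L,
                        conditions = NULL) {
  if (is.null(conditions)) conditions <- rep("event", length(onsetsS))
  new("TaskDesign", kind = "event", labels = character(),
      onsetsS = as.numeric(onsetsS), durationsS = as.numeric(durationsS),
      conditions = as.character(conditions),
      nClasses = as.integer(windowTrs), windowTrs = as.integer(windowTrs),
      nScans = as.integer(nScans))
}

#' Cardiac and respiratory traces
#' @slot fsHz sampling rate in Hz.
#' @slot cardiac,respiratory sampled series.
#' @exportClass PhysioTrace
setClass("PhysioTrace",
  representation(fsHz = "numeric", cardiac = "numeric",
                 respiratory = "numeric"))
setIs("PhysioTrace", "PhysioTraceOrNULL")

#' @param fsHz,cardiac,respiratory see slots.
#' @rdname PhysioTrace-class
#' @export
PhysioTrace <- function(fsHz, cardiac, respiratory) {
  new("PhysioTrace", fsHz = fsHz, cardiac = as.numeric(cardiac),
      respiratory = as.numeric(respiratory))
}

#' Noise profile for the synthetic generator
#'
#' Amplitudes are expressed in percent of the baseline intensity;
#' \code{motionSdMm} is the per-axis random-walk step scale (mm for
#' translations, degrees for rotations).
#'
#' @slot driftOrder polynomial drift order (>= 0).
#' @slot driftAmp,physioAmp,globalAmp,whiteSd amplitudes, % of baseline.
#' @slot cardiacHz,respHz quasi-periodic noise frequencies.
#' @slot motionSdMm random-walk step scale.
#' @slot nSpikes number of abrupt-displacement volumes.
#' @slot ar1 lag-1 autocorrelation of the white-noise family, in [0, 1).
#' @exportClass NoiseProfile
setClass("NoiseProfile",
  representation(driftOrder = "integer", driftAmp = "numeric",
                 cardiacHz = "numeric", respHz = "numeric",
                 physioAmp = "numeric", motionSdMm = "numeric",
                 nSpikes = "integer", globalAmp = "numeric",
                 whiteSd = "numeric", ar1 = "numeric"))

setValidity("NoiseProfile", function(object) {
  amps <- c(object@driftAmp, object@physioAmp, object@globalAmp,
            object@whiteSd, object@motionSdMm)
  if (any(amps < 0)) return("all amplitudes must be >= 0")
  if (object@ar1 < 0 || object@ar1 >= 1) return("ar1 must be in [0, 1)")
  if (object@driftOrder < 0L) return("driftOrder must be >= 0")
  if (object@nSpikes < 0L) return("nSpikes must be >= 0")
  TRUE
})

#' @param driftOrder,driftAmp,cardiacHz,respHz,physioAmp,motionSdMm,nSpikes,globalAmp,whiteSd,ar1
#'   see slots.
#' @rdname NoiseProfile-class
#' @export
NoiseProfile <- function(driftOrder = 3L, driftAmp = 1.5, cardiacHz = 1.1,
                         respHz = 0.3, physioAmp = 0.8, motionSdMm = 0.05,
                         nSpikes = 0L, globalAmp = 1.0, whiteSd = 2.0,
                         ar1 = 0.2) {
  new("NoiseProfile", driftOrder = as.integer(driftOrder),
      driftAmp = driftAmp, cardiacHz = cardiacHz, respHz = respHz,
      physioAmp = physioAmp, motionSdMm = motionSdMm,
      nSpikes = as.integer(nSpikes), globalAmp = globalAmp,
      whiteSd = whiteSd, ar1 = ar1)
}

#' Ground truth of a synthetic run
#' @slot activeMask logical 3D grid of truly active voxels.
#' @slot amplitude planted percent signal change.
#' @slot trueMotion per-scan 6-vector of planted rigid motion.
#' @slot spikeIndices scan indices carrying planted displacement spikes.
#' @slot noiseTimecourses list of per-family regressors and weight maps.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(activeMask = "array", amplitude = "numeric",
                 trueMotion = "matrix", spikeIndices = "integer",
                 noiseTimecourses = "list"))
setIs("GroundTruth", "GroundTruthOrNULL")

#' One preprocessing pipeline configuration
#'
#' Eight binary step flags plus the Legendre detrending order N (0..5), the
#' analysis model (GNB or CVA) and, for CVA, the PCA subspace size k (1..10).
#'
#' @slot mc,cens,ret,stc,mpr,gspc1,taskReg,phy step flags: motion correction,
#'   volume censoring, RETROICOR, slice-timing correction, motion-parameter
#'   regression, global-signal PC1 regression, task-design regression,
#'   data-driven physiological denoising.
#' @slot detrendOrder Legendre polynomial order, 0..5.
#' @slot model "GNB" or "CVA".
#' @slot cvaK PCA subspace size for CVA (NA for GNB).
#' @exportClass PipelineSpec
setClass("PipelineSpec",
  representation(mc = "logical", cens = "logical", ret = "logical",
                 stc = "logical", mpr = "logical", gspc1 = "logical",
                 taskReg = "logical", phy = "logical",
                 detrendOrder = "integer", model = "character",
                 cvaK = "integer"))

setValidity("PipelineSpec", function(object) {
  if (!object@model %in% c("GNB", "CVA")) return("model must be GNB or CVA")
  if (object@detrendOrder < 0L || object@detrendOrder > 5L)
    return("detrendOrder must be in 0..5")
  if (object@model == "CVA") {
    if (is.na(object@cvaK) || object@cvaK < 1L || object@cvaK > 10L)
      return("cvaK must be in 1..10 for CVA")
  } else if (!is.na(object@cvaK)) {
    return("cvaK must be NA for GNB")
  }
  TRUE
})

#' @param mc,cens,ret,stc,mpr,gspc1,taskReg,phy,detrendOrder,model,cvaK see
#'   slots.
#' @rdname PipelineSpec-class
#' @export
PipelineSpec <- function(mc = FALSE, cens = FALSE, ret = FALSE, stc = FALSE,
                         mpr = FALSE, gspc1 = FALSE, taskReg = FALSE,
                         phy = FALSE, detrendOrder = 0L, model = "GNB",
                         cvaK = NA_integer_) {
  new("PipelineSpec", mc = mc, cens = cens, ret = ret, stc = stc, mpr = mpr,
      gspc1 = gspc1, taskReg = taskReg, phy = phy,
      detrendOrder = as.integer(detrendOrder), model = model,
      cvaK = as.integer(cvaK))
}

#' A single subject run
#'
#' Bundle of the 4D series, its task design, optional physiological traces,
#' optional synthetic ground truth, brain and analysis masks, and identifiers.
#' @exportClass SubjectRun
setClass("SubjectRun",
  representation(vols = "VolumeSeries", design = "TaskDesign",
                 physio = "PhysioTraceOrNULL", truth = "GroundTruthOrNULL",
                 brainMask = "array", analysisMask = "array",
                 subject = "character", session = "character",
                 run = "integer", task = "character"))

setValidity("SubjectRun", function(object) {
  d <- dim(object@vols@data)
  if (!identical(dim(object@brainMask), d[1:3]))
    return("brainMask must match the spatial grid")
  if (!identical(dim(object@analysisMask), d[1:3]))
    return("analysisMask must match the spatial grid")
  if (!object@session %in% c("test", "retest"))
    return("session must be test or retest")
  TRUE
})

#' @param vols,design,physio,truth,brainMask,analysisMask,subject,session,run,task
#'   see slots.
#' @rdname SubjectRun-class
#' @export
SubjectRun <- function(vols, design, physio = NULL, truth = NULL,
                       brainMask, analysisMask = NULL, subject = "s01",
                       session = "test", run = 1L, task = "REC") {
  if (is.null(analysisMask)) analysisMask <- brainMask
  new("SubjectRun", vols = vols, design = design, physio = physio,
      truth = truth, brainMask = brainMask, analysisMask = analysisMask,
      subject = subject, session = session, run = as.integer(run),
      task = task)
}

#' Synthetic cohort
#' @slot runs list of \linkS4class{SubjectRun} bundles.
#' @slot behaviour per-run behaviour table.
#' @slot nTest,nRetest subject counts per session.
#' @slot tasks task names.
#' @exportClass Cohort
setClass("Cohort",
  representation(runs = "list", behaviour = "data.frame", nTest = "integer",
                 nRetest = "integer", tasks = "character"))

setValidity("Cohort", function(object) {
  subj <- vapply(object@runs, function(r) r@subject, character(1L))
  sess <- vapply(object@runs, function(r) r@session, character(1L))
  retest <- unique(subj[sess == "retest"])
  if (!all(retest %in% unique(subj[sess == "test"])))
    return("retest subjects must be a subset of test subjects")
  key <- paste(subj, sess, vapply(object@runs, function(r) r@task,
                                  character(1L)))
  if (any(table(key) != 2L))
    return("each (subject, session, task) must have exactly 2 runs")
  TRUE
})

#' NPAIRS metrics for one pipeline on one run
#'
#' Holds prediction P, reproducibility R, gSNR = 2R/(1-R), the distance
#' D = sqrt((1-P)^2 + (1-R)^2) from ideal performance, and the reproducible
#' Z-scored SPM over the analysis mask.
#' @exportClass MetricResult
setClass("MetricResult",
  representation(P = "numeric", R = "numeric", gSNR = "numeric",
                 D = "numeric", zmap = "numeric", maskIdx = "integer",
                 spec = "PipelineSpec", degenerate = "logical"))

setValidity("MetricResult", function(object) {
  if (object@P < 0 || object@P > 1) return("P must be in [0, 1]")
  if (abs(object@R) > 1 + 1e-12) return("R must be in [-1, 1]")
  if (is.finite(object@D) &&
      abs(object@D - sqrt((1 - object@P)^2 + (1 - object@R)^2)) > 1e-8)
    return("D must equal sqrt((1-P)^2 + (1-R)^2)")
  TRUE
})

#' Pipeline grid
#' @slot specs data.frame, one pipeline per row in canonical order.
#' @slot model "GNB" or "CVA".
#' @exportClass PipelineGrid
setClass("PipelineGrid",
  representation(specs = "data.frame", model = "character"))

#' Per-run metric table over a pipeline grid
#' @slot table data.frame with one row per grid spec (P, R, gSNR, D,
#'   edgeScore, eligible flags).
#' @slot zmaps matrix (analysis-mask voxels x pipelines) of rSPM(Z) maps.
#' @slot maskIdx linear voxel indices of the analysis mask.
#' @slot dim3 spatial grid dimensions.
#' @slot grid the \linkS4class{PipelineGrid} evaluated.
#' @exportClass MetricTable
setClass("MetricTable",
  representation(table = "data.frame", zmaps = "matrix", maskIdx = "integer",
                 dim3 = "integer", grid = "PipelineGrid"))

#' Split-half behavioural PLS result
#' @slot rhoSamples,gsnrSamples per-iteration split-half estimates.
#' @slot zmap behavioural salience Z map (averaged over iterations).
#' @slot medianRho,medianGsnr medians over iterations.
#' @exportClass PLSResult
setClass("PLSResult",
  representation(rhoSamples = "numeric", gsnrSamples = "numeric",
                 zmap = "numeric", medianRho = "numeric",
                 medianGsnr = "numeric"))

## ---- show methods -------------------------------------------------------

setMethod("show", "VolumeSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf("VolumeSeries: %dx%dx%d grid, %d scans, TR %.3g s, voxels %s mm\n",
              d[1L], d[2L], d[3L], d[4L], object@trS,
              paste(object@voxelMm, collapse = "x")))
})

setMethod("show", "PipelineSpec", function(object) {
  flags <- c(mc = object@mc, cens = object@cens, ret = object@ret,
             stc = object@stc, mpr = object@mpr, gspc1 = object@gspc1,
             taskReg = object@taskReg, phy = object@phy)
  on <- names(flags)[flags]
  cat(sprintf("PipelineSpec [%s]: {%s} N=%d%s\n", object@model,
              paste(on, collapse = ","), object@detrendOrder,
              if (object@model == "CVA") sprintf(" k=%d", object@cvaK) else ""))
})

setMethod("show", "MetricResult", function(object) {
  cat(sprintf("MetricResult: P=%.3f R=%.3f gSNR=%.3f D=%.3f (%d voxels)\n",
              object@P, object@R, object@gSNR, object@D,
              length(object@zmap)))
})

setMethod("show", "Cohort", function(object) {
  cat(sprintf("Cohort: %d test / %d retest subjects, tasks %s, %d runs\n",
              object@nTest, object@nRetest,
              paste(object@tasks, collapse = ","), length(object@runs)))
})

setMethod("show", "MetricTable", function(object) {
  cat(sprintf("MetricTable: %d pipelines (%s), %d analysis voxels\n",
              nrow(object@table), object@grid@model, length(object@maskIdx)))
})

setMethod("show", "PLSResult", function(object) {
  cat(sprintf("PLSResult: median rho=%.3f, median gSNR=%.3f over %d iterations\n",
              object@medianRho, object@medianGsnr, length(object@rhoSamples)))
})

## ---- accessors ----------------------------------------------------------

#' @export
setGeneric("volData", function(x) standardGeneric("volData"))
#' @export
setGeneric("nScans", function(x) standardGeneric("nScans"))
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))
#' @export
setGeneric("gridSize", function(x) standardGeneric("gridSize"))
#' @export
setGeneric("metricTable", function(x) standardGeneric("metricTable"))

#' @describeIn VolumeSeries-class the 4D intensity array.
setMethod("volData", "VolumeSeries", function(x) x@data)
setMethod("volData", "SubjectRun", function(x) x@vols@data)
#' @describeIn VolumeSeries-class number of scans.
setMethod("nScans", "VolumeSeries", function(x) dim(x@data)[4L])
setMethod("nScans", "SubjectRun", function(x) dim(x@vols@data)[4L])
#' @describeIn VolumeSeries-class spatial grid dimensions.
setMethod("gridShape", "VolumeSeries", function(x) dim(x@data)[1:3])
setMethod("gridShape", "SubjectRun", function(x) dim(x@vols@data)[1:3])
#' @describeIn PipelineGrid-class total pipeline count M.
setMethod("gridSize", "PipelineGrid", function(x) nrow(x@specs))
#' @describeIn MetricTable-class the per-pipeline metrics data.frame.
setMethod("metricTable", "MetricTable", function(x) x@table)
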