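## File plumbing: NIfTI-1 volumes via RNifti, events as tab-separated
## onset/duration/condition (seconds, onsets from the acquisition of the
## first scan), physio as 2-column (time_s, value) text, ground truth and
## run metadata as JSON sidecars.

#' Write a 4D series as NIfTI-1
#' @param vs a \linkS4class{VolumeSeries}.
#' @param path output file (.nii or .nii.gz).
#' @export
writeVolumeSeries <- function(vs, path) {
  img <- RNifti::asNifti(vs@data)
  RNifti::pixdim(img) <- c(vs@voxelMm, vs@trS)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 4D NIfTI-1 series
#' @param path input file.
#' @param sliceTimesS optional per-slice offsets (default all zero).
#' @export
readVolumeSeries <- function(path, sliceTimesS = NULL) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  d <- array(as.numeric(img), dim(img))
  VolumeSeries(d, trS = if (length(pd) >= 4L) pd[4L] else 1,
               voxelMm = pd[1:3], sliceTimesS = sliceTimesS)
}

#' Write task events as tab-separated onset/duration/condition
#' @param design a \linkS4class{TaskDesign}.
#' @param path output TSV.
#' @param trS repetition time (block designs).
#' @export
writeEvents <- function(design, path, trS = 2) {
  if (design@kind == "event") {
    ev <- data.frame(onset = design@onsetsS, duration = design@durationsS,
                     condition = design@conditions)
  } else {
    r <- rle(design@labels)
    ends <- cumsum(r$lengths)
    starts <- c(1L, head(ends, -1L) + 1L)
    ev <- data.frame(onset = (starts - 1L) * trS,
                     duration = r$lengths * trS, condition = r$values)
  }
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

designToList <- function(design) {
  list(kind = design@kind, nScans = design@nScans,
       nClasses = design@nClasses, windowTrs = design@windowTrs,
       labels = design@labels, onsetsS = design@onsetsS,
       durationsS = design@durationsS, conditions = design@conditions)
}

designFromList <- function(x) {
  if (x$kind == "block") blockDesign(unlist(x$labels))
  else eventDesign(unlist(x$onsetsS), unlist(x$durationsS), x$nScans,
                   windowTrs = x$windowTrs,
                   conditions = unlist(x$conditions))
}

#' Write physiological traces as 2-column text (time_s, value)
#' @param physio a \linkS4class{PhysioTrace}.
#' @param prefix output path prefix; writes _cardiac.txt and _resp.txt.
#' @export
writePhysio <- function(physio, prefix) {
  tg <- (seq_along(physio@cardiac) - 1L) / physio@fsHz
  utils::write.table(data.frame(time_s = tg, value = physio@cardiac),
                     paste0(prefix, "_cardiac.txt"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tg2 <- (seq_along(physio@respiratory) - 1L) / physio@fsHz
  utils::write.table(data.frame(time_s = tg2, value = physio@respiratory),
                     paste0(prefix, "_resp.txt"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(prefix)
}

#' Read physiological traces written by \code{\link{writePhysio}}
#' @param prefix path prefix.
#' @export
readPhysio <- function(prefix) {
  card <- utils::read.table(paste0(prefix, "_cardiac.txt"), header = TRUE)
  resp <- utils::read.table(paste0(prefix, "_resp.txt"), header = TRUE)
  fs <- 1 / diff(card$time_s[1:2])
  PhysioTrace(fsHz = fs, cardiac = card$value, respiratory = resp$value)
}

#' Write a SubjectRun to a directory
#'
#' Produces \code{<prefix>_bold.nii.gz}, \code{<prefix>_events.tsv},
#' physio text files, a ground-truth active mask NIfTI and a JSON sidecar
#' holding identifiers, slice times, design, planted motion and spikes.
#'
#' @param run a \linkS4class{SubjectRun}.
#' @param dir output directory.
#' @param prefix file name prefix.
#' @export
writeSubjectRun <- function(run, dir, prefix) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(suffix) file.path(dir, paste0(prefix, suffix))
  writeVolumeSeries(run@vols, p("_bold.nii.gz"))
  writeEvents(run@design, p("_events.tsv"), run@vols@trS)
  if (!is.null(run@physio)) writePhysio(run@physio, p("_physio"))
  maskImg <- RNifti::asNifti(array(as.integer(run@brainMask),
                                   dim(run@brainMask)))
  RNifti::writeNifti(maskImg, p("_brainmask.nii.gz"))
  side <- list(subject = run@subject, session = run@session, run = run@run,
               task = run@task, trS = run@vols@trS,
               voxelMm = run@vols@voxelMm,
               sliceTimesS = run@vols@sliceTimesS,
               design = designToList(run@design),
               hasPhysio = !is.null(run@physio))
  if (!is.null(run@truth)) {
    tr <- run@truth
    RNifti::writeNifti(RNifti::asNifti(array(as.integer(tr@activeMask),
                                             dim(tr@activeMask))),
                       p("_truthmask.nii.gz"))
    side$truth <- list(amplitude = tr@amplitude,
                       spikeIndices = tr@spikeIndices,
                       trueMotion = tr@trueMotion)
  }
  jsonlite::write_json(side, p("_run.json"), auto_unbox = TRUE, digits = NA)
  invisible(file.path(dir, prefix))
}

#' Read a SubjectRun written by \code{\link{writeSubjectRun}}
#' @param dir directory.
#' @param prefix file name prefix.
#' @export
readSubjectRun <- function(dir, prefix) {
  p <- function(suffix) file.path(dir, paste0(prefix, suffix))
  side <- jsonlite::read_json(p("_run.json"), simplifyVector = TRUE)
  vols <- readVolumeSeries(p("_bold.nii.gz"),
                           sliceTimesS = side$sliceTimesS)
  vols@trS <- side$trS
  design <- designFromList(side$design)
  physio <- if (isTRUE(side$hasPhysio)) readPhysio(p("_physio")) else NULL
  brain <- array(RNifti::readNifti(p("_brainmask.nii.gz")) > 0,
                 dim(vols@data)[1:3])
  truth <- NULL
  if (!is.null(side$truth)) {
    act <- array(RNifti::readNifti(p("_truthmask.nii.gz")) > 0,
                 dim(vols@data)[1:3])
    truth <- new("GroundTruth", activeMask = act,
                 amplitude = side$truth$amplitude,
                 trueMotion = matrix(unlist(side$truth$trueMotion),
                                     ncol = 6L),
                 spikeIndices = as.integer(side$truth$spikeIndices),
                 noiseTimecourses = list())
  }
  SubjectRun(vols = vols, design = design, physio = physio, truth = truth,
             brainMask = brain, subject = side$subject,
             session = side$session, run = side$run, task = side$task)
}

specToList <- function(spec) {
  list(mc = spec@mc, cens = spec@cens, ret = spec@ret, stc = spec@stc,
       mpr = spec@mpr, gspc1 = spec@gspc1, taskReg = spec@taskReg,
       phy = spec@phy, detrendOrder = spec@detrendOrder,
       model = spec@model, cvaK = spec@cvaK)
}

specFromList <- function(x) {
  PipelineSpec(mc = x$mc, cens = x$cens, ret = x$ret, stc = x$stc,
               mpr = x$mpr, gspc1 = x$gspc1, taskReg = x$taskReg,
               phy = x$phy, detrendOrder = x$detrendOrder, model = x$model,
               cvaK = if (is.null(x$cvaK)) NA_integer_ else x$cvaK)
}

#' Write a per-run metrics table as CSV (one row per pipeline)
#' @param mt a \linkS4class{MetricTable}.
#' @param path output CSV.
#' @export
writeMetricTable <- function(mt, path) {
  write.csv(mt@table, path, row.names = FALSE)
  invisible(path)
}
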