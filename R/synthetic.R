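## Synthetic task-fMRI generator.  Every downstream stage of the package is
## exercised on cohorts produced here: the generator plants a known HRF
## signal on a known active mask and composes drift, quasi-periodic
## cardiac/respiratory noise, a global component, AR(1) white noise with
## mild spatial smoothness, and rigid motion with occasional displacement
## spikes -- each with a recoverable ground truth.

#' Default ellipsoidal brain mask for a synthetic grid
#' @param gridShape integer 3-vector.
#' @export
makeBrainMask <- function(gridShape) {
  cx <- (gridShape + 1) / 2
  r <- 0.42 * gridShape
  idx <- expand.grid(x = seq_len(gridShape[1L]), y = seq_len(gridShape[2L]),
                     z = seq_len(gridShape[3L]))
  v <- ((idx$x - cx[1L]) / r[1L])^2 + ((idx$y - cx[2L]) / r[2L])^2 +
    ((idx$z - cx[3L]) / r[3L])^2 <= 1
  array(v, gridShape)
}

## Canonical active-voxel template: three spherical blobs at fixed relative
## positions, shared across synthetic subjects so that group-level overlap is
## meaningful.
defaultActiveMask <- function(gridShape, brainMask, radius = 3) {
  centers <- rbind(c(0.36, 0.40, 0.50), c(0.64, 0.56, 0.42),
                   c(0.50, 0.68, 0.58))
  idx <- expand.grid(x = seq_len(gridShape[1L]), y = seq_len(gridShape[2L]),
                     z = seq_len(gridShape[3L]))
  act <- rep(FALSE, nrow(idx))
  for (i in seq_len(nrow(centers))) {
    cc <- centers[i, ] * gridShape
    act <- act | ((idx$x - cc[1L])^2 + (idx$y - cc[2L])^2 +
                    (idx$z - cc[3L])^2) <= radius^2
  }
  array(act, gridShape) & brainMask
}

#' Generate quasi-periodic cardiac and respiratory traces
#'
#' Cycle lengths are jittered around the nominal rates so that cycle phase is
#' recoverable by peak detection but not strictly periodic.
#'
#' @param heartHz,respHz nominal cardiac and respiratory rates (Hz).
#' @param durationS trace duration in seconds.
#' @param fsHz sampling rate; must exceed twice the cardiac rate.
#' @param seed RNG seed.
#' @return a \linkS4class{PhysioTrace}.
#' @export
generatePhysio <- function(heartHz, respHz, durationS, fsHz = 50, seed = 1L) {
  if (fsHz <= 2 * heartHz)
    stop("sampling rate must exceed twice the cardiac rate (Nyquist)")
  if (durationS <= 0) stop("durationS must be positive")
  set.seed(seed)
  tg <- seq(0, durationS, by = 1 / fsHz)
  cyclePhase <- function(f, jitter) {
    nCyc <- ceiling(durationS * f) + 3L
    lens <- pmax(rnorm(nCyc, 1 / f, jitter / f), 0.5 / f)
    peaks <- c(0, cumsum(lens))
    iv <- findInterval(tg, peaks)
    iv[iv < 1L] <- 1L
    2 * pi * (tg - peaks[iv]) / (peaks[iv + 1L] - peaks[iv])
  }
  phC <- cyclePhase(heartHz, 0.07)
  phR <- cyclePhase(respHz, 0.12)
  cardiac <- cos(phC) + 0.4 * cos(2 * phC) + rnorm(length(tg), 0, 0.02)
  respiratory <- sin(phR + pi / 2) + rnorm(length(tg), 0, 0.02)
  PhysioTrace(fsHz = fsHz, cardiac = cardiac, respiratory = respiratory)
}

## Sample a physio trace at arbitrary times (linear interpolation).
samplePhysio <- function(series, fsHz, times) {
  tg <- (seq_along(series) - 1L) / fsHz
  approx(tg, series, xout = times, rule = 2)$y
}

#' Sample a heterogeneous per-subject noise profile
#'
#' Draws one \linkS4class{NoiseProfile} from ranges chosen to emulate the
#' spread of drift, physiological, motion and thermal noise seen across
#' subjects in task-fMRI cohorts.  Uses the current RNG stream.
#' @export
sampleNoiseProfile <- function() {
  NoiseProfile(
    driftOrder = sample(1:4, 1L),
    driftAmp = runif(1L, 0.5, 2.5),
    cardiacHz = runif(1L, 0.9, 1.3),
    respHz = runif(1L, 0.2, 0.35),
    physioAmp = runif(1L, 0.2, 1.2),
    motionSdMm = runif(1L, 0.01, 0.08),
    nSpikes = sample(0:2, 1L, prob = c(0.5, 0.3, 0.2)),
    globalAmp = runif(1L, 0.2, 1.5),
    whiteSd = runif(1L, 1.5, 2.5),
    ar1 = runif(1L, 0, 0.4))
}

#' Generate one synthetic BOLD run with known ground truth
#'
#' The forward model is: baseline + amplitude x (HRF-convolved design) on the
#' active mask + drift + cardiac/respiratory + global + AR(1) white noise,
#' followed by rigid-body resampling with the planted motion parameters
#' (random walk plus displacement spikes).  Deterministic given \code{seed}.
#'
#' @param seed RNG seed.
#' @param gridShape spatial grid (default 24 x 24 x 12 voxels of 3 x 3 x 5
#'   mm, a desk-scale EPI grid).
#' @param nScans number of scans (>= 8).
#' @param design a \linkS4class{TaskDesign} covering at most \code{nScans}.
#' @param profile a \linkS4class{NoiseProfile}.
#' @param amplitude percent signal change on active voxels.
#' @param trS,voxelMm,baseline acquisition constants.
#' @param brainMask,activeMask optional masks (defaults generated).
#' @param subject,session,run,task identifiers.
#' @return a \linkS4class{SubjectRun} with fully populated ground truth.
#' @export
generateRun <- function(seed, gridShape = c(24L, 24L, 12L), nScans = 96L,
                        design = recDesign(nScans), profile = NoiseProfile(),
                        amplitude = 1, trS = 2, voxelMm = c(3, 3, 5),
                        baseline = 100, brainMask = NULL, activeMask = NULL,
                        subject = "s01", session = "test", run = 1L,
                        task = "REC") {
  if (nScans < 8L) stop("nScans must be >= 8")
  if (design@nScans > nScans)
    stop("configuration error: design longer than nScans")
  if (amplitude < 0) stop("amplitude must be >= 0")
  set.seed(seed)
  gridShape <- as.integer(gridShape)
  if (is.null(brainMask)) brainMask <- makeBrainMask(gridShape)
  if (is.null(activeMask)) activeMask <- defaultActiveMask(gridShape, brainMask)
  activeMask <- activeMask & brainMask
  brainIdx <- which(brainMask)
  nb <- length(brainIdx)
  nz <- gridShape[3L]
  sliceTimes <- (seq_len(nz) - 1L) * trS / nz
  sliceOf <- ((brainIdx - 1L) %/% (gridShape[1L] * gridShape[2L])) + 1L

  ## signal
  reg <- hrfRegressor(design, nScans, trS)
  dataMat <- matrix(baseline, nb, nScans)
  activeInBrain <- which(activeMask[brainIdx])
  if (length(activeInBrain) && any(reg != 0)) {
    dataMat[activeInBrain, ] <- dataMat[activeInBrain, ] +
      (amplitude / 100 * baseline) * rep(reg, each = length(activeInBrain))
  }

  unitSd <- function(x) {
    s <- sd(x)
    if (s > 0) (x - mean(x)) / s else x * 0
  }
  tc <- list()

  ## polynomial drift: one shared unit-SD timecourse, N(0,1) voxel weights
  if (profile@driftOrder >= 1L && profile@driftAmp > 0) {
    L <- legendreBasis(nScans, profile@driftOrder)[, -1L, drop = FALSE]
    driftTc <- unitSd(as.numeric(L %*% rnorm(ncol(L))))
    driftW <- rnorm(nb)
    dataMat <- dataMat + (profile@driftAmp / 100 * baseline) *
      outer(driftW, driftTc)
    tc$drift <- driftTc; tc$driftW <- driftW
  }

  ## cardiac + respiratory quasi-periodic noise, sampled per slice
  physio <- generatePhysio(profile@cardiacHz, profile@respHz,
                           durationS = nScans * trS + 2, fsHz = 50,
                           seed = deriveSeed(seed, 11L))
  if (profile@physioAmp > 0) {
    scanT <- (seq_len(nScans) - 1L) * trS
    C <- vapply(sliceTimes, function(st)
      unitSd(samplePhysio(physio@cardiac, physio@fsHz, scanT + st)),
      numeric(nScans))
    Rm <- vapply(sliceTimes, function(st)
      unitSd(samplePhysio(physio@respiratory, physio@fsHz, scanT + st)),
      numeric(nScans))
    wC <- rnorm(nb); wR <- rnorm(nb)
    a <- profile@physioAmp / 100 * baseline / sqrt(2)
    dataMat <- dataMat + a * (wC * t(C[, sliceOf]) + wR * t(Rm[, sliceOf]))
    tc$cardiac <- C; tc$cardiacW <- wC
    tc$resp <- Rm; tc$respW <- wR
  }

  ## global-signal component: AR(1) timecourse, uniform weight on brain
  if (profile@globalAmp > 0) {
    g <- unitSd(as.numeric(stats::filter(rnorm(nScans), 0.5,
                                         method = "recursive")))
    dataMat <- dataMat + (profile@globalAmp / 100 * baseline) *
      rep(g, each = nb)
    tc$global <- g
  }

  ## AR(1) white noise with mild spatial smoothness, exact per-voxel SD
  if (profile@whiteSd > 0) {
    e <- matrix(rnorm(nb * nScans), nb, nScans)
    if (profile@ar1 > 0) {
      e <- t(apply(e, 1L, function(x)
        stats::filter(x, profile@ar1, method = "recursive")))
    }
    kx <- gaussKernelMatrix(gridShape[1L], 0.6)
    ky <- gaussKernelMatrix(gridShape[2L], 0.6)
    kz <- gaussKernelMatrix(gridShape[3L], 0.6)
    full <- array(0, gridShape)
    for (s in seq_len(nScans)) {
      full[brainIdx] <- e[, s]
      sm <- smoothVolume3D(full, kx, ky, kz)
      e[, s] <- sm[brainIdx]
    }
    sds <- apply(e, 1L, sd)
    sds[sds == 0] <- 1
    e <- e / sds * (profile@whiteSd / 100 * baseline)
    dataMat <- dataMat + e - rowMeans(e)
  }

  ## assemble 4D array
  data4d <- array(0, c(gridShape, nScans))
  vol <- array(0, gridShape)
  for (s in seq_len(nScans)) {
    vol[] <- 0
    vol[brainIdx] <- dataMat[, s]
    data4d[, , , s] <- vol
  }

  ## rigid motion: per-axis random walk plus one-scan displacement spikes
  trueMotion <- matrix(0, nScans, 6L)
  if (profile@motionSdMm > 0) {
    steps <- matrix(rnorm(nScans * 6L, 0, profile@motionSdMm), nScans, 6L)
    steps[, 4:6] <- steps[, 4:6] * 0.5   # rotations walk more slowly (deg)
    trueMotion <- apply(steps, 2L, cumsum)
    trueMotion <- sweep(trueMotion, 2L, trueMotion[1L, ])
  }
  spikeIdx <- integer()
  if (profile@nSpikes > 0L) {
    if (nScans < profile@nSpikes + 4L) stop("too few scans for spikes")
    spikeIdx <- sort(sample(3:(nScans - 2L), profile@nSpikes))
    for (si in spikeIdx) {
      ax <- sample(1:3, 1L)
      trueMotion[si, ax] <- trueMotion[si, ax] +
        sample(c(-1, 1), 1L) * 2.2 * voxelMm[ax]
      ## global intensity offset on the spike scan
      data4d[, , , si] <- data4d[, , , si] + 0.02 * baseline * brainMask
    }
  }
  if (any(trueMotion != 0)) {
    dims <- as.integer(gridShape)
    for (s in seq_len(nScans)) {
      if (any(trueMotion[s, ] != 0)) {
        data4d[, , , s] <- array(.rigidApply(as.numeric(data4d[, , , s]),
                                             dims, trueMotion[s, ],
                                             as.numeric(voxelMm)), gridShape)
      }
    }
  }

  truth <- new("GroundTruth", activeMask = activeMask, amplitude = amplitude,
               trueMotion = trueMotion, spikeIndices = as.integer(spikeIdx),
               noiseTimecourses = c(tc, list(baseline = baseline,
                                             taskRegressor = reg,
                                             brainIdx = brainIdx)))
  vols <- VolumeSeries(data4d, trS = trS, voxelMm = voxelMm,
                       sliceTimesS = sliceTimes)
  SubjectRun(vols = vols, design = design, physio = physio, truth = truth,
             brainMask = brainMask, subject = subject, session = session,
             run = run, task = task)
}

#' Built-in task designs for synthetic runs
#'
#' \code{recDesign}: alternating 24 s control/task blocks (recognition-like);
#' \code{tmtDesign}: alternating 20 s taskA/taskB blocks (trail-making-like);
#' \code{sartDesign}: sparse event-related design analysed in a 9-TR
#' peristimulus window (sustained-attention-like).
#'
#' @param nScans number of scans.
#' @param trS repetition time (s).
#' @rdname taskDesigns
#' @export
recDesign <- function(nScans = 96L, trS = 2) {
  blockLen <- max(2L, round(24 / trS))
  lab <- rep(rep(c("control", "task"), each = blockLen),
             length.out = nScans)
  blockDesign(lab)
}

#' @rdname taskDesigns
#' @export
tmtDesign <- function(nScans = 96L, trS = 2) {
  blockLen <- max(2L, round(20 / trS))
  lab <- rep(rep(c("taskA", "taskB"), each = blockLen), length.out = nScans)
  blockDesign(lab)
}

#' @param windowTrs peristimulus window (TRs).
#' @rdname taskDesigns
#' @export
sartDesign <- function(nScans = 96L, trS = 2, windowTrs = 9L) {
  spacing <- (windowTrs + 1L) * trS
  onsets <- seq(2 * trS, (nScans - windowTrs - 1L) * trS, by = spacing)
  eventDesign(onsetsS = onsets, durationsS = rep(0.25, length(onsets)),
              nScans = nScans, windowTrs = windowTrs)
}

taskDesignFor <- function(task, nScans, trS) {
  switch(task,
         REC = recDesign(nScans, trS),
         TMT = tmtDesign(nScans, trS),
         SART = sartDesign(nScans, trS),
         stop("unknown task: ", task))
}

#' Generate a synthetic cohort with heterogeneous noise profiles
#'
#' Subjects receive individual noise profiles drawn by \code{profileSampler};
#' all test subjects contribute one test session, the first \code{nRetest}
#' also a retest session, with exactly 2 runs per (subject, session, task).
#' Per-run behaviour is linearly coupled to the planted activation amplitude:
#' \code{behaviour = coupling * amplitude + noise}.
#'
#' @param seed RNG seed.
#' @param nTest,nRetest subject counts (retest <= test).
#' @param tasks subset of c("REC", "TMT", "SART").
#' @param profileSampler function() returning a \linkS4class{NoiseProfile}.
#' @param behaviourCoupling slope linking behaviour to amplitude.
#' @param behaviourNoiseSd SD of the behavioural noise term.
#' @param nScans,gridShape,trS,voxelMm,baseline generator constants.
#' @return a \linkS4class{Cohort}.
#' @export
generateCohort <- function(seed, nTest = 27L, nRetest = 20L, tasks = "REC",
                           profileSampler = sampleNoiseProfile,
                           behaviourCoupling = 1, behaviourNoiseSd = 0.35,
                           nScans = 96L, gridShape = c(24L, 24L, 12L),
                           trS = 2, voxelMm = c(3, 3, 5), baseline = 100) {
  if (length(tasks) == 0L) stop("task list must not be empty")
  if (nRetest > nTest) stop("nRetest must be <= nTest")
  set.seed(seed)
  subjects <- sprintf("s%02d", seq_len(nTest))
  profiles <- lapply(subjects, function(s) profileSampler())
  names(profiles) <- subjects
  baseAmp <- setNames(runif(nTest, 0.5, 2), subjects)

  runs <- list()
  beh <- list()
  stream <- 0L
  for (si in seq_len(nTest)) {
    sessions <- if (si <= nRetest) c("test", "retest") else "test"
    for (sess in sessions) {
      for (task in tasks) {
        design <- taskDesignFor(task, nScans, trS)
        for (r in 1:2) {
          stream <- stream + 1L
          amp <- baseAmp[si] * runif(1L, 0.9, 1.1)
          b <- behaviourCoupling * amp + rnorm(1L, 0, behaviourNoiseSd)
          sr <- generateRun(seed = deriveSeed(seed, stream),
                            gridShape = gridShape, nScans = nScans,
                            design = design, profile = profiles[[si]],
                            amplitude = amp, trS = trS, voxelMm = voxelMm,
                            baseline = baseline, subject = subjects[si],
                            session = sess, run = r, task = task)
          key <- sprintf("%s_%s_%s_r%d", subjects[si], sess, task, r)
          runs[[key]] <- sr
          beh[[key]] <- data.frame(
            subject = subjects[si], session = sess, run = r, task = task,
            behaviour = b, trueAmplitude = amp,
            meanRtMs = rnorm(1L, 520, 60),
            accuracy = runif(1L, 0.8, 1),
            rtEasyMs = rnorm(1L, 480, 40),
            rtHardMs = NA_real_, stringsAsFactors = FALSE)
          beh[[key]]$rtHardMs <- beh[[key]]$rtEasyMs + abs(rnorm(1L, 60, 20))
        }
      }
    }
  }
  behaviour <- do.call(rbind, beh)
  rownames(behaviour) <- NULL
  new("Cohort", runs = runs, behaviour = behaviour, nTest = as.integer(nTest),
      nRetest = as.integer(nRetest), tasks = tasks)
}
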