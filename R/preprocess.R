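## Ordered preprocessing operators.  Every operator preserves the grid
## shape, TR and scan count; censoring replaces volumes rather than deleting
## them.  applyPipeline() composes the operators in the fixed step order:
## reference volume, motion correction, censoring, RETROICOR, slice timing,
## smoothing (6 mm), non-neuronal tissue mask, then a joint GLM holding the
## Legendre detrend, motion-PC, global-PC1 and task regressors, and finally
## data-driven physiological denoising.

brainMatrix <- function(bundle) {
  d <- volData(bundle)
  dm <- dim(d)
  idx <- which(bundle@brainMask)
  m <- matrix(d, prod(dm[1:3]), dm[4L])[idx, , drop = FALSE]
  attr(m, "idx") <- idx
  m
}

setBrainMatrix <- function(bundle, m) {
  d <- volData(bundle)
  dm <- dim(d)
  flat <- matrix(d, prod(dm[1:3]), dm[4L])
  flat[attr(m, "idx"), ] <- m
  bundle@vols@data <- array(flat, dm)
  bundle
}

#' Select the minimum-displacement reference volume
#'
#' Returns the scan whose coordinates in the full principal-component space
#' of the 4D series lie closest (Euclidean distance) to the coordinate-wise
#' median across scans; ties resolve to the lowest scan index.
#'
#' @param bundle a \linkS4class{SubjectRun}.
#' @return scan index (1-based).
#' @export
selectReferenceVolume <- function(bundle) {
  X <- t(brainMatrix(bundle))               # scans x voxels
  if (!all(is.finite(X))) stop("non-finite data")
  Xc <- sweep(X, 2L, colMeans(X))
  sv <- svd(Xc, nu = min(dim(Xc)), nv = 0L)
  coords <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  med <- apply(coords, 2L, median)
  dist <- sqrt(rowSums(sweep(coords, 2L, med)^2))
  which.min(dist)                           # which.min takes the first tie
}

#' Rigid-body motion correction
#'
#' Aligns every scan to the reference volume by minimising the sum of squared
#' intensity differences over 6 rigid parameters (trilinear resampling,
#' Nelder-Mead).  Estimated per-scan motion parameters are the negated
#' correcting transforms; the reference scan gets zeros.
#'
#' @param bundle a \linkS4class{SubjectRun}.
#' @param ref reference scan index (default: \code{selectReferenceVolume}).
#' @param estimateOnly if TRUE, estimate parameters without resampling.
#' @param params optional precomputed n x 6 motion parameters; when given,
#'   the correction is applied directly without re-estimation.
#' @return list with elements \code{run} (corrected bundle) and
#'   \code{motion} (n x 6 matrix: translations mm, rotations degrees).
#' @export
motionCorrect <- function(bundle, ref = selectReferenceVolume(bundle),
                          estimateOnly = FALSE, params = NULL) {
  d <- volData(bundle)
  dm <- dim(d)
  n <- dm[4L]
  dims <- as.integer(dm[1:3])
  vox <- as.numeric(bundle@vols@voxelMm)
  refVol <- as.numeric(d[, , , ref])
  mp <- matrix(0, n, 6L)
  colnames(mp) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  out <- d
  warm <- rep(0, 6L)
  for (s in seq_len(n)) {
    if (s == ref) { warm <- rep(0, 6L); next }
    vol <- as.numeric(d[, , , s])
    if (is.null(params)) {
      f <- function(p) .rigidSSD(vol, refVol, dims, p, vox)
      f0 <- f(rep(0, 6L))
      q <- tryCatch({
        fit <- optim(warm, f, method = "Nelder-Mead",
                     control = list(maxit = 400L, reltol = 1e-10))
        if (fit$value <= min(f0, f(warm))) fit$par else rep(0, 6L)
      }, error = function(e) {
        warning("registration failure at scan ", s, "; identity used")
        rep(0, 6L)
      })
    } else {
      q <- -params[s, ]
    }
    warm <- q
    mp[s, ] <- -q
    if (!estimateOnly && any(q != 0)) {
      out[, , , s] <- array(.rigidApply(vol, dims, q, vox), dims)
    }
  }
  if (!estimateOnly) bundle@vols@data <- out
  list(run = bundle, motion = mp)
}

#' Censor outlier volumes
#'
#' Scores each scan by its displacement in full PC space (Euclidean distance
#' between consecutive scans, which principal-axis rotation preserves),
#' combined with framewise displacement from motion parameters when
#' available.  Scans whose robust z-score exceeds \code{zThresh} are replaced
#' by linear interpolation between the nearest unflagged neighbours
#' (boundaries copy the nearest unflagged scan), so the series stays
#' continuous.
#'
#' @param bundle a \linkS4class{SubjectRun}.
#' @param mp optional n x 6 motion-parameter matrix.
#' @param zThresh robust-z flagging threshold (default 4).
#' @return list with \code{run} (censored bundle) and \code{flags} (logical
#'   per scan).
#' @export
censorVolumes <- function(bundle, mp = NULL, zThresh = 4) {
  m <- brainMatrix(bundle)
  n <- ncol(m)
  dif <- sqrt(colSums((m[, -1L, drop = FALSE] - m[, -n, drop = FALSE])^2))
  ## robust z on the frame-to-frame jumps, then per-scan score = the smaller
  ## of the two adjacent z values, so an isolated spike flags only itself
  minAdj <- function(zv) {
    s <- numeric(n)
    s[1L] <- zv[1L]
    s[n] <- zv[n - 1L]
    if (n > 2L) s[2:(n - 1L)] <- pmin(zv[1:(n - 2L)], zv[2:(n - 1L)])
    s
  }
  flags <- minAdj(robustZ(dif)) > zThresh
  if (!is.null(mp)) {
    fd <- framewiseDisplacement(mp)[-1L]
    if (any(fd > 0)) flags <- flags | (minAdj(robustZ(fd)) > zThresh)
  }
  if (mean(flags) > 0.5)
    stop("data-quality error: more than 50% of scans flagged for censoring")
  if (any(flags)) {
    good <- which(!flags)
    for (t in which(flags)) {
      prv <- good[good < t]
      nxt <- good[good > t]
      if (length(prv) && length(nxt)) {
        a <- max(prv); b <- min(nxt)
        w <- (t - a) / (b - a)
        m[, t] <- (1 - w) * m[, a] + w * m[, b]
      } else if (length(prv)) {
        m[, t] <- m[, max(prv)]
      } else {
        m[, t] <- m[, min(nxt)]
      }
    }
    bundle <- setBrainMatrix(bundle, m)
  }
  list(run = bundle, flags = flags)
}

## Peak detection: local maxima separated by at least half the dominant
## period, above the series median.
findPeaks <- function(x, fsHz) {
  n <- length(x)
  xc <- x - mean(x)
  spec <- Mod(fft(xc))[2:floor(n / 2)]
  fdom <- which.max(spec) / (n / fsHz)
  minDist <- max(1L, floor(0.5 * fsHz / fdom))
  cand <- which(diff(sign(diff(x))) == -2) + 1L
  cand <- cand[x[cand] > median(x)]
  if (!length(cand)) return(integer())
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep <- integer()
  for (p in cand) {
    if (!length(keep) || all(abs(keep - p) >= minDist)) keep <- c(keep, p)
  }
  sort(keep)
}

## Phase assignment on the physio-trace time grid.
cardiacPhase <- function(series, fsHz) {
  pk <- findPeaks(series, fsHz)
  if (length(pk) < 3L) return(NULL)
  tg <- (seq_along(series) - 1L) / fsHz
  tp <- (pk - 1L) / fsHz
  iv <- findInterval(tg, tp)
  iv <- pmin(pmax(iv, 1L), length(tp) - 1L)
  2 * pi * (tg - tp[iv]) / (tp[iv + 1L] - tp[iv])
}

## Respiratory phase by histogram equalisation of the signed amplitude.
respiratoryPhase <- function(series) {
  rk <- rank(series) / length(series)
  drv <- c(diff(series), 0)
  pi * rk * sign(drv + (drv == 0))
}

#' RETROICOR physiological correction
#'
#' Assigns cardiac and respiratory cycle phases to each scan (honouring
#' per-slice acquisition times), builds the 2nd-order Fourier expansion
#' (8 regressors: sin/cos of orders 1-2 for both modalities) and removes the
#' voxelwise least-squares fit.  The operation is a projection: applying it
#' twice equals applying it once.
#'
#' @param bundle a \linkS4class{SubjectRun} carrying a physio trace.
#' @return corrected bundle; if no cardiac cycles are detectable the step is
#'   skipped with a warning.
#' @export
retroicorCorrect <- function(bundle) {
  physio <- bundle@physio
  if (is.null(physio)) stop("retroicorCorrect requires physiological traces")
  phC <- cardiacPhase(physio@cardiac, physio@fsHz)
  if (is.null(phC)) {
    warning("no detectable cardiac cycles; RETROICOR skipped")
    return(bundle)
  }
  phR <- respiratoryPhase(physio@respiratory)
  tg <- (seq_along(physio@cardiac) - 1L) / physio@fsHz
  regGrid <- cbind(sin(phC), cos(phC), sin(2 * phC), cos(2 * phC),
                   sin(phR), cos(phR), sin(2 * phR), cos(2 * phR))
  d <- volData(bundle)
  dm <- dim(d)
  n <- dm[4L]
  scanT <- (seq_len(n) - 1L) * bundle@vols@trS
  flat <- matrix(d, prod(dm[1:3]), n)
  brain <- bundle@brainMask
  for (z in seq_len(dm[3L])) {
    idx <- which(brain[, , z]) + (z - 1L) * dm[1L] * dm[2L]
    if (!length(idx)) next
    tz <- scanT + bundle@vols@sliceTimesS[z]
    X <- cbind(1, apply(regGrid, 2L, function(g)
      approx(tg, g, xout = tz, rule = 2)$y))
    Y <- t(flat[idx, , drop = FALSE])
    cf <- qr.coef(qr(X), Y)
    cf[is.na(cf)] <- 0
    Y <- Y - X[, -1L, drop = FALSE] %*% cf[-1L, , drop = FALSE]
    flat[idx, ] <- t(Y)
  }
  bundle@vols@data <- array(flat, dm)
  bundle
}

#' Slice-timing correction by Fourier phase shift
#'
#' Shifts every voxel time course in the frequency domain so that all slices
#' are referenced to slice-time 0.  The DC term (voxel mean) is preserved
#' exactly.
#'
#' @param bundle a \linkS4class{SubjectRun}.
#' @return corrected bundle.
#' @export
sliceTimeCorrect <- function(bundle) {
  d <- volData(bundle)
  dm <- dim(d)
  n <- dm[4L]
  trS <- bundle@vols@trS
  f <- c(0:floor(n / 2), -(ceiling(n / 2) - 1L):-1L)[seq_len(n)] / (n * trS)
  flat <- matrix(d, prod(dm[1:3]), n)
  for (z in seq_len(dm[3L])) {
    st <- bundle@vols@sliceTimesS[z]
    if (st == 0) next
    fac <- exp(-2i * pi * f * st)
    if (n %% 2L == 0L) fac[n / 2 + 1L] <- cos(2 * pi * f[n / 2 + 1L] * st)
    idx <- seq_len(dm[1L] * dm[2L]) + (z - 1L) * dm[1L] * dm[2L]
    Y <- t(flat[idx, , drop = FALSE])
    flat[idx, ] <- t(Re(stats::mvfft(stats::mvfft(Y) * fac,
                                     inverse = TRUE)) / n)
  }
  bundle@vols@data <- array(flat, dm)
  bundle
}

#' Isotropic Gaussian spatial smoothing
#'
#' Convolves each volume with a 3D Gaussian of the stated FWHM in mm;
#' anisotropic voxel sizes are honoured and boundaries are reflective, so
#' total intensity is conserved.
#'
#' @param bundle a \linkS4class{SubjectRun}.
#' @param fwhmMm kernel full width at half maximum in mm (default 6).
#' @return smoothed bundle.
#' @export
spatialSmooth <- function(bundle, fwhmMm = 6) {
  if (fwhmMm < 0) stop("fwhm must be >= 0")
  if (fwhmMm == 0) return(bundle)
  d <- volData(bundle)
  dm <- dim(d)
  sig <- fwhmMm / (2 * sqrt(2 * log(2))) / bundle@vols@voxelMm
  kx <- gaussKernelMatrix(dm[1L], sig[1L])
  ky <- gaussKernelMatrix(dm[2L], sig[2L])
  kz <- gaussKernelMatrix(dm[3L], sig[3L])
  for (s in seq_len(dm[4L])) {
    d[, , , s] <- smoothVolume3D(d[, , , s], kx, ky, kz)
  }
  bundle@vols@data <- d
  bundle
}

#' Estimate the non-neuronal tissue mask
#'
#' Flags vasculature-like voxels whose temporal SD is high relative to their
#' mean intensity (robust z of the log SD/mean ratio above \code{zThresh}),
#' capped at a fraction \code{cap} of brain voxels.  Flagged voxels are
#' excluded from all downstream metric computations.
#'
#' @param bundle a \linkS4class{SubjectRun} (smoothed data expected).
#' @param cap maximum flagged fraction of brain voxels (default 0.05).
#' @param zThresh robust-z threshold (default 3).
#' @return logical 3D mask of flagged voxels.
#' @export
estimateNoiseMask <- function(bundle, cap = 0.05, zThresh = 3) {
  m <- brainMatrix(bundle)
  mu <- rowMeans(m)
  s <- apply(m, 1L, sd)
  ratio <- s / pmax(abs(mu), 1e-12)
  z <- robustZ(log(pmax(ratio, 1e-12)))
  cand <- z > zThresh
  maxN <- floor(cap * nrow(m))
  if (sum(cand) > maxN) {
    cand <- rank(-z, ties.method = "first") <= maxN
  }
  mask <- array(FALSE, gridShape(bundle))
  mask[attr(m, "idx")[cand]] <- TRUE
  mask
}

#' Build the GLM design matrix for the temporal-regression steps
#'
#' Columns: discrete-orthogonal Legendre polynomials of orders
#' \code{0..detrendOrder}; if \code{mpr}, the smallest leading set of
#' motion-parameter PCs whose cumulative variance exceeds 85%; if
#' \code{gspc1}, the PC#1 time course of the data; if \code{taskReg}, the
#' HRF-convolved task regressor.  A \code{"family"} attribute labels each
#' column \code{"nuisance"} or \code{"task"}; rank-deficient columns are
#' dropped with a message.
#'
#' @param spec a \linkS4class{PipelineSpec}.
#' @param mp n x 6 motion parameters (required when \code{spec@mpr}).
#' @param bundle a \linkS4class{SubjectRun}.
#' @param design the task design (defaults to the bundle's).
#' @return design matrix with \code{family} attribute.
#' @export
buildGlmDesign <- function(spec, mp, bundle, design = bundle@design) {
  n <- nScans(bundle)
  X <- legendreBasis(n, spec@detrendOrder)
  fam <- rep("nuisance", ncol(X))
  if (spec@mpr) {
    if (is.null(mp)) stop("motion parameters required for motion regression")
    pcs <- motionPCs(mp)
    if (ncol(pcs)) {
      X <- cbind(X, pcs)
      fam <- c(fam, rep("nuisance", ncol(pcs)))
    }
  }
  if (spec@gspc1) {
    g <- dataPC1(bundle)
    X <- cbind(X, gspc1 = g)
    fam <- c(fam, "nuisance")
  }
  if (spec@taskReg) {
    X <- cbind(X, task = hrfRegressor(design, n, bundle@vols@trS))
    fam <- c(fam, "task")
  }
  qrd <- qr(X)
  if (qrd$rank < ncol(X)) {
    drop <- qrd$pivot[(qrd$rank + 1L):ncol(X)]
    message("dropping ", length(drop), " rank-deficient design column(s): ",
            paste(colnames(X)[drop], collapse = ", "))
    X <- X[, -drop, drop = FALSE]
    fam <- fam[-drop]
  }
  attr(X, "family") <- fam
  X
}

## Leading motion-parameter PCs covering > 85% of motion variance.
motionPCs <- function(mp, varThresh = 0.85) {
  v <- apply(mp, 2L, var)
  if (sum(v) == 0) return(matrix(numeric(), nrow(mp), 0L))
  pr <- prcomp(mp, center = TRUE, scale. = FALSE)
  frac <- pr$sdev^2 / sum(pr$sdev^2)
  k <- which(cumsum(frac) > varThresh)[1L]
  out <- pr$x[, seq_len(k), drop = FALSE]
  out <- sweep(out, 2L, sqrt(colSums(out^2)), "/")
  colnames(out) <- paste0("motion_pc", seq_len(k))
  out
}

## PC#1 time course of the (voxelwise-centred) brain data, unit SD.
dataPC1 <- function(bundle) {
  m <- brainMatrix(bundle)
  mc <- m - rowMeans(m)
  sv <- svd(t(mc), nu = 1L, nv = 0L)
  g <- sv$u[, 1L] * sv$d[1L]
  s <- sd(g)
  if (s > 0) g <- (g - mean(g)) / s
  g
}

#' Remove nuisance variance in a joint GLM
#'
#' Fits the full design (nuisance plus task columns) jointly per voxel and
#' subtracts only the nuisance partial fit; task-column variance is retained
#' in the output, protecting against over-regression of task-coupled signal.
#'
#' @param bundle a \linkS4class{SubjectRun}.
#' @param X design matrix from \code{\link{buildGlmDesign}}.
#' @return denoised bundle.
#' @export
glmDenoise <- function(bundle, X) {
  stopifnot(nrow(X) == nScans(bundle))
  fam <- attr(X, "family")
  nuis <- which(fam == "nuisance")
  if (!length(nuis)) return(bundle)
  m <- brainMatrix(bundle)
  Y <- t(m)
  cf <- qr.coef(qr(X), Y)
  cf[is.na(cf)] <- 0
  Y <- Y - X[, nuis, drop = FALSE] %*% cf[nuis, , drop = FALSE]
  m[] <- t(Y)
  setBrainMatrix(bundle, m)
}

#' Data-driven physiological denoising
#'
#' Regresses the top principal-component time courses of the non-neuronal
#' mask voxels (up to 3 components, each explaining at least 5% of the mask
#' variance) out of all brain voxels.  Serves as the data-driven
#' physiological correction behind the \code{phy} pipeline flag.
#'
#' @param bundle a \linkS4class{SubjectRun}.
#' @param noiseMask logical 3D mask of non-neuronal voxels.
#' @param maxComp,varFracMin component count cap and variance floor.
#' @return denoised bundle (identity with a warning on an empty mask).
#' @export
physDenoiseDataDriven <- function(bundle, noiseMask, maxComp = 3L,
                                  varFracMin = 0.05) {
  idx <- which(noiseMask)
  if (!length(idx)) {
    warning("empty noise mask; physiological denoising skipped")
    return(bundle)
  }
  d <- volData(bundle)
  dm <- dim(d)
  flat <- matrix(d, prod(dm[1:3]), dm[4L])
  Ym <- t(flat[idx, , drop = FALSE])
  Ym <- sweep(Ym, 2L, colMeans(Ym))
  sv <- svd(Ym)
  frac <- sv$d^2 / max(sum(sv$d^2), 1e-300)
  nc <- 0L
  while (nc < min(maxComp, length(frac)) && frac[nc + 1L] >= varFracMin)
    nc <- nc + 1L
  if (nc == 0L) return(bundle)
  S <- sv$u[, seq_len(nc), drop = FALSE] *
    rep(sv$d[seq_len(nc)], each = nrow(Ym))
  X <- cbind(1, S)
  m <- brainMatrix(bundle)
  Y <- t(m)
  cf <- qr.coef(qr(X), Y)
  cf[is.na(cf)] <- 0
  Y <- Y - X[, -1L, drop = FALSE] %*% cf[-1L, , drop = FALSE]
  m[] <- t(Y)
  setBrainMatrix(bundle, m)
}

## Image-domain stage (steps 1-6): reference volume, optional motion
## correction / censoring / RETROICOR / slice timing, fixed smoothing.
imagePreprocess <- function(bundle, mc, cens, ret, stc, fwhmMm = 6,
                            motionParams = NULL, needMotion = FALSE,
                            censorZ = 4, ref = NULL) {
  log <- "ref-volume"
  if (is.null(ref)) ref <- selectReferenceVolume(bundle)
  mp <- motionParams
  if (mc) {
    res <- motionCorrect(bundle, ref, params = motionParams)
    bundle <- res$run
    mp <- res$motion
    log <- c(log, "motion-correct")
  } else if (needMotion && is.null(mp)) {
    mp <- motionCorrect(bundle, ref, estimateOnly = TRUE)$motion
  }
  if (cens) {
    res <- censorVolumes(bundle, mp = mp, zThresh = censorZ)
    bundle <- res$run
    log <- c(log, "censor")
  }
  if (ret) {
    if (is.null(bundle@physio))
      stop("RETROICOR requested but no physiological traces present")
    bundle <- retroicorCorrect(bundle)
    log <- c(log, "retroicor")
  }
  if (stc) {
    bundle <- sliceTimeCorrect(bundle)
    log <- c(log, "slice-time")
  }
  bundle <- spatialSmooth(bundle, fwhmMm)
  log <- c(log, "smooth")
  list(run = bundle, mp = mp, log = log, ref = ref)
}

## GLM + data-driven physio stage (steps 8-12).
glmStage <- function(bundle, spec, mp, noiseMask, log = character()) {
  bundle@analysisMask <- bundle@brainMask & !noiseMask
  X <- buildGlmDesign(spec, mp, bundle)
  bundle <- glmDenoise(bundle, X)
  log <- c(log, paste0("detrend-", spec@detrendOrder))
  if (spec@mpr) log <- c(log, "motion-regress")
  if (spec@gspc1) log <- c(log, "global-pc1")
  if (spec@taskReg) log <- c(log, "task-reg")
  if (spec@phy) {
    bundle <- physDenoiseDataDriven(bundle, noiseMask)
    log <- c(log, "phys-datadriven")
  }
  list(run = bundle, log = log)
}

#' Apply a full preprocessing pipeline to a run
#'
#' Executes the pipeline steps in their fixed order -- reference-volume
#' selection, the optional image-domain steps, 6 mm smoothing, the
#' non-neuronal tissue mask, the joint nuisance GLM and optional data-driven
#' physiological denoising -- applying each optional step iff its flag is set
#' in \code{spec}.
#'
#' @param bundle a raw \linkS4class{SubjectRun}.
#' @param spec a \linkS4class{PipelineSpec}.
#' @param fwhmMm smoothing kernel (fixed step; default 6 mm).
#' @param noiseMask optional precomputed non-neuronal mask (computed from the
#'   smoothed data when NULL).
#' @param motionParams optional precomputed motion parameters.
#' @param censorZ censoring threshold.
#' @return list with \code{run} (preprocessed bundle with its analysis
#'   mask), \code{motion}, \code{noiseMask} and \code{log} (ordered step
#'   record).
#' @export
applyPipeline <- function(bundle, spec, fwhmMm = 6, noiseMask = NULL,
                          motionParams = NULL, censorZ = 4) {
  img <- imagePreprocess(bundle, spec@mc, spec@cens, spec@ret, spec@stc,
                         fwhmMm = fwhmMm, motionParams = motionParams,
                         needMotion = spec@mpr, censorZ = censorZ)
  run <- img$run
  log <- img$log
  if (is.null(noiseMask)) noiseMask <- estimateNoiseMask(run)
  log <- c(log, "noise-mask")
  g <- glmStage(run, spec, img$mp, noiseMask, log)
  list(run = g$run, motion = img$mp, noiseMask = noiseMask, log = g$log)
}
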