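test_that("reference volume selection matches the PC-median oracle", {
  ## identical volumes tie -> lowest index
  r <- smallRun(seed = 2, profile = quietProfile(), amplitude = 0)
  expect_identical(selectReferenceVolume(r), 1L)

  ## random run: brute-force distance to the PC-coordinate-wise median
  r2 <- smallRun(seed = 3, profile = quietProfile(whiteSd = 2))
  X <- t(brainMat(r2))
  Xc <- sweep(X, 2L, colMeans(X))
  pr <- prcomp(Xc, center = FALSE)
  med <- apply(pr$x, 2L, median)
  expected <- which.min(sqrt(rowSums(sweep(pr$x, 2L, med)^2)))
  expect_identical(selectReferenceVolume(r2), expected)

  ## two identical volumes plus a displaced one -> one of the pair
  r3 <- generateRun(seed = 5, gridShape = c(8, 8, 4), nScans = 8,
                    design = blockDesign(rep(c("a", "b"), each = 4)),
                    profile = quietProfile(whiteSd = 1), amplitude = 0)
  d <- volData(r3)[, , , c(1, 1, 2)]
  d[, , , 3] <- d[, , , 3] + 5 * r3@brainMask
  r3@vols@data <- d[, , , c(1, 2, 3, 1, 2, 3, 1, 2)]
  expect_lte(selectReferenceVolume(r3), 2L)
})

test_that("motion correction recovers a planted rigid translation", {
  r <- smallRun(seed = 5, gridShape = c(16L, 16L, 8L), nScans = 12L,
                profile = quietProfile(whiteSd = 1), amplitude = 0)
  ## motion-free run: near-zero parameters
  res0 <- motionCorrect(r, ref = 1L)
  expect_lt(max(abs(res0$motion)), 0.1)
  expect_identical(nrow(res0$motion), 12L)

  ## plant a 1-voxel (3 mm) x-translation on scan 5
  d <- volData(r)
  dims <- as.integer(dim(d)[1:3])
  d[, , , 5] <- array(npairsopt:::.rigidApply(as.numeric(d[, , , 5]), dims,
                                              c(3, 0, 0, 0, 0, 0),
                                              c(3, 3, 5)), dims)
  r@vols@data <- d
  res <- motionCorrect(r, ref = 1L)
  expect_lt(abs(res$motion[5, 1] - 3), 0.5)
  corr <- cor(as.numeric(volData(res$run)[, , , 5]),
              as.numeric(volData(res$run)[, , , 1]))
  expect_gt(corr, 0.99)
})

test_that("censoring flags exactly the planted spike and interpolates it", {
  r <- generateRun(seed = 9, gridShape = c(12, 12, 6), nScans = 40,
                   design = blockDesign(rep(c("a", "b"), each = 10)),
                   profile = quietProfile(whiteSd = 1), amplitude = 0)
  clean <- censorVolumes(r)
  expect_identical(sum(clean$flags), 0L)
  expect_identical(volData(clean$run), volData(r))

  d <- volData(r)
  d[, , , 10] <- d[, , , 10] + 5 * r@brainMask
  r@vols@data <- d
  cv <- censorVolumes(r)
  expect_identical(which(cv$flags), 10L)
  m <- brainMat(r)
  mc <- brainMat(cv$run)
  expect_equal(mc[, 10], (m[, 9] + m[, 11]) / 2, tolerance = 1e-12)

  ## boundary spike copies the nearest unflagged scan
  r2 <- generateRun(seed = 9, gridShape = c(12, 12, 6), nScans = 40,
                    design = blockDesign(rep(c("a", "b"), each = 10)),
                    profile = quietProfile(whiteSd = 1), amplitude = 0)
  d2 <- volData(r2)
  d2[, , , 1] <- d2[, , , 1] + 5 * r2@brainMask
  r2@vols@data <- d2
  cv2 <- censorVolumes(r2)
  expect_identical(which(cv2$flags), 1L)
  m2 <- brainMat(cv2$run)
  expect_equal(m2[, 1], m2[, 2])

  ## more than half the scans flagged aborts
  expect_error(censorVolumes(r, zThresh = -10), "data-quality")
})

test_that("RETROICOR removes phase-locked variance, preserves task signal", {
  pr <- NoiseProfile(driftOrder = 0L, driftAmp = 0, physioAmp = 2,
                     motionSdMm = 0, nSpikes = 0L, globalAmp = 0,
                     whiteSd = 0.2, ar1 = 0)
  r <- smallRun(seed = 11, nScans = 96L, profile = pr, amplitude = 1)
  m0 <- brainMat(r)
  before <- apply(m0, 1L, var)
  rc <- retroicorCorrect(r)
  after <- apply(brainMat(rc), 1L, var)
  ## physio-dominated voxels lose nearly all their variance
  expect_gt(1 - median(after / before), 0.9)
  ## a pure task voxel (orthogonal to physio) passes through unchanged
  reg <- hrfRegressor(r@design, nScans(r), r@vols@trS)
  zMid <- 3L
  vox <- which(r@brainMask[, , zMid], arr.ind = TRUE)[1L, ]
  rTask <- r
  dT <- volData(rTask)
  original <- 100 + 5 * reg
  dT[vox[1L], vox[2L], zMid, ] <- original
  rTask@vols@data <- dT
  corrected <- volData(retroicorCorrect(rTask))[vox[1L], vox[2L], zMid, ]
  expect_gt(cor(corrected, original), 0.95)
  ## pure sinusoid locked to the cardiac trace loses >= 95% of variance
  scanT <- (seq_len(nScans(r)) - 1L) * r@vols@trS
  lockTc <- npairsopt:::samplePhysio(r@physio@cardiac, r@physio@fsHz,
                                     scanT + r@vols@sliceTimesS[zMid])
  d <- volData(r)
  d[vox[1L], vox[2L], zMid, ] <- 10 * lockTc
  r@vols@data <- d
  rc2 <- retroicorCorrect(r)
  v0 <- var(10 * lockTc)
  v1 <- var(volData(rc2)[vox[1L], vox[2L], zMid, ])
  expect_gt(1 - v1 / v0, 0.95)
  ## linearity: zero data maps to zero; projection idempotence
  rz <- r
  rz@vols@data <- volData(r) * 0
  expect_equal(max(abs(volData(retroicorCorrect(rz)))), 0)
  twice <- retroicorCorrect(rc2)
  expect_equal(volData(twice), volData(rc2), tolerance = 1e-6)
})

test_that("slice-timing correction aligns slices to time zero", {
  pr <- quietProfile()
  r <- generateRun(seed = 12, gridShape = c(8, 8, 4), nScans = 64,
                   design = blockDesign(rep(c("a", "b"), each = 32)),
                   profile = pr, amplitude = 0)
  ## all-zero slice times: identity
  r0 <- r
  r0@vols@sliceTimesS <- rep(0, 4)
  expect_equal(volData(sliceTimeCorrect(r0)), volData(r0),
               tolerance = 1e-12)
  ## sinusoid sampled at slice-offset times realigns to phase zero
  tt <- (0:63) * r@vols@trS
  d <- volData(r) * 0
  for (z in 1:4) {
    d[, , z, ] <- rep(sin(2 * pi * (tt + r@vols@sliceTimesS[z]) / 20),
                      each = 64)
  }
  baseMean <- mean(d[4, 4, 2, ])
  r@vols@data <- d
  st <- sliceTimeCorrect(r)
  phaseOf <- function(y) {
    f <- lm(y ~ sin(2 * pi * tt / 20) + cos(2 * pi * tt / 20))
    atan2(coef(f)[3L], coef(f)[2L])
  }
  phases <- vapply(1:4, function(z) phaseOf(volData(st)[4, 4, z, ]),
                   numeric(1L))
  lags <- abs(phases - phases[1L]) / (2 * pi)
  expect_lt(max(lags), 0.01)
  ## the voxelwise mean (DC term) is preserved
  expect_equal(mean(volData(st)[4, 4, 2, ]), baseMean, tolerance = 1e-8)
})

test_that("spatial smoothing has the stated FWHM and conserves intensity", {
  r <- generateRun(seed = 13, gridShape = c(15, 15, 9), nScans = 8,
                   design = blockDesign(rep(c("a", "b"), each = 4)),
                   profile = quietProfile(), amplitude = 0)
  ## constant volumes are unchanged
  rc <- r
  rc@vols@data <- array(3, dim(volData(r)))
  expect_equal(volData(spatialSmooth(rc, 6)), volData(rc),
               tolerance = 1e-12)
  ## impulse response: half maximum at half the FWHM (3 mm = 1 x-voxel)
  d <- volData(r) * 0
  d[8, 8, 5, ] <- 1
  r@vols@data <- d
  sm <- volData(spatialSmooth(r, 6))
  ratio <- sm[9, 8, 5, 1] / sm[8, 8, 5, 1]
  expect_lt(abs(ratio - 0.5), 0.02)
  expect_lt(abs(sum(sm[, , , 1]) - 1), 0.01)
})

test_that("noise mask finds vessel-like voxels, spares activation", {
  set.seed(3)
  r <- generateRun(seed = 21, gridShape = c(16, 16, 8), nScans = 96,
                   design = recDesign(96, 2),
                   profile = quietProfile(whiteSd = 2), amplitude = 1)
  bidx <- which(r@brainMask)
  ves <- sample(setdiff(bidx, which(r@truth@activeMask)), 30)
  d <- volData(r)
  flat <- matrix(d, prod(dim(d)[1:3]), dim(d)[4L])
  flat[ves, ] <- 100 + (flat[ves, ] - 100) * 5
  r@vols@data <- array(flat, dim(d))
  nm <- estimateNoiseMask(r)
  expect_gte(mean(nm[ves]), 0.9)
  expect_lt(mean(nm[r@truth@activeMask]), 0.1)
  ## homogeneous noise stays under the cap
  r0 <- generateRun(seed = 22, gridShape = c(16, 16, 8), nScans = 96,
                    design = recDesign(96, 2),
                    profile = quietProfile(whiteSd = 2), amplitude = 0)
  expect_lte(sum(estimateNoiseMask(r0)) / sum(r0@brainMask), 0.05)
})

test_that("HRF regressor has canonical timing and is linear", {
  expect_identical(hrfRegressor(eventDesign(numeric(), numeric(), 20), 20, 2),
                   numeric(20))
  one <- hrfRegressor(eventDesign(10, 0.5, 40), 40, 2)
  peakT <- (which.max(one) - 1L) * 2
  expect_gte(peakT - 10, 4)
  expect_lte(peakT - 10, 6)
  two <- hrfRegressor(eventDesign(c(10, 50), c(0.5, 0.5), 40), 40, 2)
  other <- hrfRegressor(eventDesign(50, 0.5, 40), 40, 2)
  expect_equal(two * max(abs(one + other)), (one + other),
               tolerance = 1e-10)
})

test_that("GLM design has orthogonal detrend columns and the 85% PC rule", {
  r <- smallRun(seed = 4)
  spec <- PipelineSpec(detrendOrder = 5L)
  X <- buildGlmDesign(spec, NULL, r)
  expect_identical(ncol(X), 6L)
  G <- crossprod(sweep(X, 2L, sqrt(colSums(X^2)), "/"))
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  ## motion PCs: variance fractions (0.6, 0.3, 0.1) -> 2 columns
  set.seed(8)
  Q <- qr.Q(qr(matrix(rnorm(48 * 6), 48, 6)))
  mp <- Q %*% diag(sqrt(c(0.6, 0.3, 0.1, 0, 0, 0) * 47))
  pcs <- npairsopt:::motionPCs(mp)
  expect_identical(ncol(pcs), 2L)
  ## all flags off, order 0: single constant column
  X0 <- buildGlmDesign(PipelineSpec(detrendOrder = 0L), NULL, r)
  expect_identical(ncol(X0), 1L)
  expect_lt(diff(range(X0)), 1e-12)
})

test_that("GLM denoising removes nuisance but retains task variance", {
  r <- smallRun(seed = 6, profile = quietProfile(whiteSd = 0.5),
                amplitude = 1)
  ## a pure order-3 polynomial voxel is annihilated by N >= 3
  n <- nScans(r)
  x <- seq(-1, 1, length.out = n)
  poly3 <- 2 + x - 0.5 * x^2 + 0.3 * x^3
  d <- volData(r)
  idx <- which(r@brainMask, arr.ind = TRUE)[1L, ]
  d[idx[1L], idx[2L], idx[3L], ] <- poly3
  r@vols@data <- d
  X <- buildGlmDesign(PipelineSpec(detrendOrder = 3L), NULL, r)
  out <- glmDenoise(r, X)
  resid <- volData(out)[idx[1L], idx[2L], idx[3L], ]
  expect_lt(sqrt(mean(resid^2)), 1e-8 * sqrt(mean(poly3^2)))

  ## task amplitude is protected when the task regressor is in the model
  reg <- hrfRegressor(r@design, n, r@vols@trS)
  drift <- npairsopt:::legendreBasis(n, 1)[, 2L]
  drift <- drift / sd(drift) * sd(reg) * sign(cor(drift, reg))
  rr <- smallRun(seed = 61, profile = quietProfile(whiteSd = 0.2),
                 amplitude = 1)
  d2 <- volData(rr)
  act <- which(rr@truth@activeMask, arr.ind = TRUE)[1L, ]
  d2[act[1L], act[2L], act[3L], ] <-
    100 + 1 * reg + 2 * drift          # task partially collinear with drift
  rr@vols@data <- d2
  fitAmp <- function(taskReg) {
    spec <- PipelineSpec(detrendOrder = 1L, taskReg = taskReg)
    X <- buildGlmDesign(spec, NULL, rr)
    o <- glmDenoise(rr, X)
    y <- volData(o)[act[1L], act[2L], act[3L], ]
    coef(lm(y ~ reg))[2L]
  }
  ampOn <- fitAmp(TRUE)
  ampOff <- fitAmp(FALSE)
  expect_lt(abs(ampOn - 1), 0.05)
  expect_lt(ampOff, ampOn)

  ## design with only a task column subtracts nothing
  Xt <- cbind(task = reg)
  attr(Xt, "family") <- "task"
  expect_identical(volData(glmDenoise(rr, Xt)), volData(rr))
})

test_that("data-driven physio denoising removes shared mask components", {
  r <- smallRun(seed = 14, profile = quietProfile(whiteSd = 1),
                amplitude = 0)
  n <- nScans(r)
  shared <- sin(2 * pi * seq_len(n) / 7)
  noiseMask <- array(FALSE, gridShape(r))
  bidx <- which(r@brainMask)
  maskVox <- bidx[1:20]
  noiseMask[maskVox] <- TRUE
  d <- volData(r)
  flat <- matrix(d, prod(gridShape(r)), n)
  flat[maskVox, ] <- flat[maskVox, ] + 8 * rep(shared, each = 20)
  leak <- bidx[21:40]
  flat[leak, ] <- flat[leak, ] + 2 * rep(shared, each = 20)
  r@vols@data <- array(flat, dim(d))
  out <- physDenoiseDataDriven(r, noiseMask)
  flatOut <- matrix(volData(out), prod(gridShape(r)), n)
  resCor <- max(abs(apply(flatOut[leak, ], 1L, cor, y = shared)))
  expect_lt(resCor, 0.1)
  expect_identical(dim(volData(out)), dim(volData(r)))
  expect_warning(physDenoiseDataDriven(r, array(FALSE, gridShape(r))),
                 "empty")
})

test_that("applyPipeline follows the fixed step order", {
  r <- smallRun(seed = 16, profile = NoiseProfile(motionSdMm = 0.02,
                                                  nSpikes = 0L))
  allOff <- applyPipeline(r, PipelineSpec(detrendOrder = 0L))
  expect_identical(allOff$log,
                   c("ref-volume", "smooth", "noise-mask", "detrend-0"))
  cons <- applyPipeline(r, consPipeline("GNB"))
  expect_identical(cons$log,
                   c("ref-volume", "motion-correct", "censor", "retroicor",
                     "slice-time", "smooth", "noise-mask", "detrend-1",
                     "motion-regress"))
  ## determinism
  again <- applyPipeline(r, consPipeline("GNB"))
  expect_identical(volData(cons$run), volData(again$run))
  ## RETROICOR without physio errors
  r2 <- r
  r2@physio <- NULL
  expect_error(applyPipeline(r2, PipelineSpec(ret = TRUE)), "physio")
})
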