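## Shared fixtures: all synthetic, generated in code at test time.

## a profile with every noise family switched off
quietProfile <- function(whiteSd = 0, ...) {
  NoiseProfile(driftOrder = 0L, driftAmp = 0, physioAmp = 0, motionSdMm = 0,
               nSpikes = 0L, globalAmp = 0, whiteSd = whiteSd, ar1 = 0, ...)
}

## small 2-class block run
smallRun <- function(seed = 1L, gridShape = c(12L, 12L, 6L), nScans = 48L,
                     profile = quietProfile(whiteSd = 2), amplitude = 1,
                     ...) {
  generateRun(seed = seed, gridShape = gridShape, nScans = nScans,
              design = blockDesign(rep(rep(c("control", "task"),
                                           each = max(2L, min(12L, nScans %/% 4L))),
                                       length.out = nScans)),
              profile = profile, amplitude = amplitude, ...)
}

brainMat <- function(run) npairsopt:::brainMatrix(run)

## balanced 2-class toy matrix with a planted mean shift
toyClassData <- function(seed, n = 40L, V = 20L, shift = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * V), n, V)
  y <- rep(c("a", "b"), each = n / 2)
  X[y == "b", ] <- X[y == "b", ] + shift
  list(X = X, y = y)
}
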