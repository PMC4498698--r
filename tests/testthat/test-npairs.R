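test_that("temporal halves are contiguous with the stated tie rule", {
  d40 <- blockDesign(rep(rep(c("a", "b"), each = 5), 4))
  h <- splitHalfIndices(d40, 40)
  expect_identical(lengths(h), c(20L, 20L))
  expect_identical(h[[1L]], 1:20)
  d41 <- blockDesign(rep(c(rep(c("a", "b"), each = 5)), length.out = 41))
  h41 <- splitHalfIndices(d41, 41)
  expect_identical(lengths(h41), c(21L, 20L))
  ## REC-like 4-block alternation: both halves hold both conditions
  dr <- recDesign(96, 2)
  hr <- splitHalfIndices(dr, 96)
  for (half in hr) {
    expect_setequal(unique(dr@labels[half]), c("control", "task"))
  }
  ## an unbalanced design forces a block-aware split off the midpoint
  dbad <- blockDesign(c(rep("a", 10), rep("b", 10), rep("a", 20)))
  expect_message(hbad <- splitHalfIndices(dbad, 40), "split")
  expect_true(all(c("a", "b") %in% dbad@labels[hbad[[1L]]]))
  expect_true(all(c("a", "b") %in% dbad@labels[hbad[[2L]]]))
  ## a class confined to one end admits no valid split at all
  expect_error(splitHalfIndices(blockDesign(c(rep("b", 4), rep("a", 36))),
                                40),
               "no temporal split")
})

test_that("event designs label scans by peristimulus lag", {
  des <- sartDesign(96, 2, windowTrs = 9L)
  lab <- scanLabels(des, 2)
  expect_identical(sort(unique(lab[!is.na(lab)])),
                   sprintf("lag%02d", 1:9))
  tab <- table(lab)
  expect_true(all(tab >= 4L))
})

test_that("GNB sensitivity map follows the pooled-SD contrast", {
  td <- toyClassData(1, shift = 0)
  f0 <- gnbFit(td$X, td$y)
  expect_lt(mean(abs(f0$map)), 0.5)  # no real contrast
  ## one voxel, means 0 and 1, pooled SD 1 -> sensitivity 1
  set.seed(2)
  e <- rnorm(60, sd = 1)
  e <- (e - mean(e)) / sd(e)
  X <- matrix(c(e, e + 1), ncol = 1)
  y <- rep(c("a", "b"), each = 60)
  f <- gnbFit(X, y)
  expect_equal(unname(f$map), 1, tolerance = 1e-12)
  ## constant voxel stays finite through the variance floor
  Xc <- cbind(X, 1)
  fc <- gnbFit(Xc, y)
  expect_true(all(is.finite(fc$map)))
  expect_error(gnbFit(X[c(1, 61), ], y[c(1, 61)]), "at least 2")
})

test_that("GNB posterior matches the analytic Bayes rule on one voxel", {
  set.seed(8)
  e <- rnorm(20)
  X <- matrix(c(e, e + 1.5), ncol = 1)
  y <- rep(c("a", "b"), each = 20)
  f <- gnbFit(X, y)
  xt <- matrix(c(-0.3, 0.9, 2.2), ncol = 1)
  bayes <- vapply(xt, function(x) {
    l1 <- dnorm(x, f$means[1L], sqrt(f$vars[1L]))
    l2 <- dnorm(x, f$means[2L], sqrt(f$vars[2L]))
    l1 / (l1 + l2)
  }, numeric(1L))
  expect_equal(gnbPredict(f, xt, rep("a", 3)), mean(bayes),
               tolerance = 1e-10)
  ## well-separated classes saturate
  td <- toyClassData(3, shift = 10)
  tr <- c(1:10, 21:30)
  te <- c(11:20, 31:40)
  f2 <- gnbFit(td$X[tr, ], td$y[tr])
  expect_gt(gnbPredict(f2, td$X[te, ], td$y[te]), 0.99)
})

test_that("permuted labels give chance-level prediction", {
  p2 <- vapply(1:100, function(s) {
    set.seed(s)
    X <- matrix(rnorm(40 * 50), 40, 50)
    y1 <- sample(rep(c("a", "b"), 10))
    y2 <- sample(rep(c("a", "b"), 10))
    gnbPredict(gnbFit(X[1:20, ], y1), X[21:40, ], y2)
  }, numeric(1L))
  expect_lt(abs(mean(p2) - 0.5), 0.05)
})

test_that("CVA reduces to Fisher LDA at full rank and PC1 at k = 1", {
  set.seed(7)
  V <- 10
  X <- rbind(matrix(rnorm(20 * V), 20, V),
             matrix(rnorm(20 * V, 0.8), 20, V))
  y <- rep(c("a", "b"), each = 20)
  Xc <- scale(X, scale = FALSE)
  f <- cvaFit(Xc, y, k = V)
  m1 <- colMeans(Xc[y == "a", ])
  m2 <- colMeans(Xc[y == "b", ])
  Sw <- cov(Xc[y == "a", ]) * 19 + cov(Xc[y == "b", ]) * 19
  w <- solve(Sw, m2 - m1)
  w <- w / sqrt(sum(w^2))
  expect_gt(abs(sum(f$map * w)), 0.999)
  expect_equal(sqrt(sum(f$map^2)), 1, tolerance = 1e-12)
  ## k = 1: eigenimage collinear with PC1 loadings, signed by the contrast
  f1 <- cvaFit(Xc, y, k = 1)
  v1 <- svd(Xc, nu = 0, nv = 1)$v[, 1L]
  expect_gt(abs(sum(f1$map * v1)), 0.999)
  expect_gt(sum(f1$map * (m2 - m1)), 0)
  expect_error(cvaFit(Xc, y, k = 39), "exceeds")
})

test_that("CVA prediction is calibrated and matches GNB in the 1-D limit", {
  ## separable structure preserved in test data
  set.seed(9)
  V <- 15
  mk <- function(n) rbind(matrix(rnorm(n * V), n, V),
                          matrix(rnorm(n * V, 1.5), n, V))
  ytr <- rep(c("a", "b"), each = 30)
  f <- cvaFit(scale(mk(30), scale = FALSE), ytr, k = 5)
  expect_gt(cvaPredict(f, scale(mk(30), scale = FALSE), ytr), 0.95)
  ## permuted 9-class labels: chance 1/9
  p9 <- vapply(1:100, function(s) {
    set.seed(s)
    X <- matrix(rnorm(90 * 30), 90, 30)
    y1 <- sample(rep(letters[1:9], 5))
    y2 <- sample(rep(letters[1:9], 5))
    cvaPredict(cvaFit(X[1:45, ], y1, k = 6), X[46:90, ], y2)
  }, numeric(1L))
  expect_lt(abs(mean(p9) - 1 / 9), 0.03)
  ## equal-variance 1-voxel case agrees with GNB
  set.seed(8)
  e <- rnorm(20)
  X <- matrix(c(e, e + 1.5), ncol = 1)
  y <- rep(c("a", "b"), each = 20)
  xt <- matrix(c(-0.3, 0.9, 2.2), ncol = 1)
  pg <- gnbPredict(gnbFit(X, y), xt, rep("a", 3))
  pc <- cvaPredict(cvaFit(X, y, 1), xt, rep("a", 3))
  expect_equal(pg, pc, tolerance = 1e-6)
})

test_that("reproducibility and gSNR follow their closed forms", {
  set.seed(4)
  m <- rnorm(100)
  expect_equal(as.numeric(reproducibility(m, m)), 1)
  expect_equal(as.numeric(reproducibility(m, -m)), -1)
  z <- reproducibility(rep(1, 100), m)
  expect_identical(as.numeric(z), 0)
  expect_true(attr(z, "degenerate"))
  ## common pattern + equal-variance noise: E[R] = 0.5
  s <- rnorm(5000)
  r <- reproducibility(s + rnorm(5000), s + rnorm(5000))
  expect_lt(abs(r - 0.5), 0.1)
  expect_identical(gsnrFromR(0), 0)
  expect_identical(gsnrFromR(0.5), 2)
  expect_identical(gsnrFromR(-0.2), 0)
  expect_true(is.infinite(gsnrFromR(1)))
  expect_equal(gsnrFromR(0.5, form = "sqrt"), sqrt(2))
  ## monotone on [0, 1)
  rs <- seq(0, 0.95, by = 0.05)
  expect_true(all(diff(vapply(rs, gsnrFromR, numeric(1L))) > 0))
})

test_that("rSPM(Z) is symmetric, calibrated under the null and signal-sensitive", {
  set.seed(5)
  m1 <- rnorm(5000)
  m2 <- rnorm(5000)
  expect_equal(as.numeric(rspmZ(m1, m2)), as.numeric(rspmZ(m2, m1)))
  z <- as.numeric(rspmZ(m1, m2))
  expect_lt(abs(mean(z)), 0.1)
  expect_lt(abs(sd(z) - 1), 0.1)
  ## planted common signal raises Z on signal voxels
  sig <- c(rep(2, 500), rep(0, 4500))
  zs <- as.numeric(rspmZ(sig + rnorm(5000), sig + rnorm(5000)))
  expect_gt(mean(zs[1:500]), mean(zs[-(1:500)]))
  ## identical maps degenerate
  zd <- rspmZ(m1, m1)
  expect_true(attr(zd, "degenerate"))
})

test_that("npairsEvaluate combines the two directions and computes D", {
  r <- smallRun(seed = 31, profile = quietProfile(whiteSd = 2),
                amplitude = 2)
  spec <- PipelineSpec(detrendOrder = 0L, gspc1 = FALSE)
  pp <- applyPipeline(r, spec)
  mr <- npairsEvaluate(pp$run, spec)
  expect_equal(mr@D, sqrt((1 - mr@P)^2 + (1 - mr@R)^2), tolerance = 1e-12)
  expect_gte(mr@P, 0)
  expect_lte(mr@P, 1)
  expect_lte(abs(mr@R), 1)
  ## formula arithmetic: P = 0.5, R = 0 -> D = sqrt(1.25)
  expect_equal(sqrt((1 - 0.5)^2 + 1), sqrt(1.25))
  ## direction symmetry: reversing the run in time swaps the halves
  rRev <- r
  rRev@vols@data <- volData(r)[, , , rev(seq_len(nScans(r)))]
  rRev@design <- blockDesign(rev(r@design@labels))
  ppR <- applyPipeline(rRev, spec)
  mrR <- npairsEvaluate(ppR$run, spec)
  expect_equal(mrR@P, mr@P, tolerance = 1e-6)
  expect_equal(mrR@R, mr@R, tolerance = 1e-6)
})

test_that("pure-noise runs sit at chance with near-zero reproducibility", {
  res <- vapply(1:50, function(s) {
    r <- generateRun(seed = 500 + s, gridShape = c(10, 10, 5), nScans = 32,
                     design = blockDesign(rep(rep(c("a", "b"), each = 4),
                                              4)),
                     profile = quietProfile(whiteSd = 2), amplitude = 0)
    spec <- PipelineSpec(detrendOrder = 0L)
    pp <- applyPipeline(r, spec)
    mr <- npairsEvaluate(pp$run, spec)
    c(mr@P, mr@R)
  }, numeric(2L))
  expect_gt(mean(res[1L, ]), 0.45)
  expect_lt(mean(res[1L, ]), 0.55)
  expect_lt(abs(mean(res[2L, ])), 0.1)
})

test_that("planted amplitude increases reproducibility monotonically", {
  medR <- vapply(c(0.5, 1, 2), function(amp) {
    rs <- vapply(1:20, function(s) {
      r <- smallRun(seed = 700 + s, profile = quietProfile(whiteSd = 2),
                    amplitude = amp)
      spec <- PipelineSpec(detrendOrder = 0L)
      pp <- applyPipeline(r, spec)
      npairsEvaluate(pp$run, spec)@R
    }, numeric(1L))
    median(rs)
  }, numeric(1L))
  expect_true(all(diff(medR) > 0))
})
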