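test_that("grid enumeration yields the full pipeline cardinalities", {
  gg <- enumeratePipelines("GNB")
  expect_identical(gridSize(gg), 1536L)
  gc <- enumeratePipelines("CVA")
  expect_identical(gridSize(gc), 15360L)
  ## one option per step collapses to a single pipeline
  g1 <- enumeratePipelines("GNB",
                           flagOptions = as.list(setNames(rep(FALSE, 8),
                                                          npairsopt:::flagNames)),
                           detrendOrders = 0L)
  expect_identical(gridSize(g1), 1L)
  ## canonical order: k varies fastest, then N, then the flag counter
  expect_identical(gc@specs$cvaK[1:10], 1:10)
  expect_identical(gc@specs$detrendOrder[c(1, 11)], c(0L, 1L))
  expect_true(all(!gc@specs$mc[seq_len(gridSize(gc) / 2)]))
})

test_that("the CONS pipeline is the conservative member of the grid", {
  spec <- consPipeline("GNB")
  expect_true(spec@mc && spec@cens && spec@ret && spec@stc && spec@mpr)
  expect_false(spec@gspc1 || spec@taskReg || spec@phy)
  expect_identical(spec@detrendOrder, 1L)
  g <- enumeratePipelines("GNB")
  expect_length(npairsopt:::specRowIndex(g, spec), 1L)
  specC <- consPipeline("CVA", cvaK = 3L)
  expect_identical(specC@cvaK, 3L)
  expect_length(npairsopt:::specRowIndex(enumeratePipelines("CVA"), specC),
                1L)
  expect_error(consPipeline("CVA"), "cvaK")
})

test_that("grid evaluation is cache-consistent and deterministic", {
  r <- smallRun(seed = 55,
                profile = NoiseProfile(driftOrder = 2L, motionSdMm = 0.03),
                amplitude = 1.5)
  grid <- enumeratePipelines("GNB",
    flagOptions = list(mc = c(FALSE, TRUE), cens = FALSE, ret = FALSE,
                       stc = FALSE, mpr = FALSE, gspc1 = c(FALSE, TRUE),
                       taskReg = c(FALSE, TRUE), phy = FALSE),
    detrendOrders = c(0L, 2L))
  expect_identical(gridSize(grid), 16L)
  mtC <- evaluateGrid(r, grid, cache = TRUE)
  mtN <- evaluateGrid(r, grid, cache = FALSE)
  expect_identical(nrow(metricTable(mtC)), 16L)
  expect_equal(metricTable(mtC)$P, metricTable(mtN)$P, tolerance = 1e-12)
  expect_equal(metricTable(mtC)$R, metricTable(mtN)$R, tolerance = 1e-12)
  mt2 <- evaluateGrid(r, grid, cache = TRUE)
  expect_identical(metricTable(mtC)$D, metricTable(mt2)$D)
  expect_false(any(metricTable(mtC)$failed))
})

test_that("edge-artifact scoring isolates rim-weighted maps", {
  mask <- makeBrainMask(c(14, 14, 8))
  interior <- npairsopt:::erodeMask(mask)
  shell <- mask & !interior
  maskIdx <- which(mask)
  zInterior <- numeric(length(maskIdx))
  zInterior[interior[maskIdx]] <- 3
  expect_identical(edgeArtifactScore(zInterior, mask, maskIdx), 0)
  zShell <- numeric(length(maskIdx))
  zShell[shell[maskIdx]] <- 3
  expect_identical(edgeArtifactScore(zShell, mask, maskIdx), 1)
  set.seed(10)
  sc <- vapply(1:200, function(i)
    edgeArtifactScore(rnorm(length(maskIdx)), mask, maskIdx), numeric(1L))
  expect_lt(abs(mean(sc) - 0.5), 0.05)
})

test_that("artifact rejection flags rim maps but never everything", {
  r <- smallRun(seed = 56, amplitude = 1.5)
  grid <- enumeratePipelines("GNB",
    flagOptions = as.list(setNames(rep(FALSE, 8), npairsopt:::flagNames)),
    detrendOrders = c(0L, 1L, 2L))
  mt <- evaluateGrid(r, grid)
  ## all scores moderate: nothing flagged at threshold 1
  mt1 <- rejectArtifactPipelines(mt, threshold = 1)
  expect_true(all(metricTable(mt1)$eligible))
  ## plant a rim-artifact map in one row
  shell <- r@brainMask & !npairsopt:::erodeMask(r@brainMask)
  zrim <- numeric(length(mt@maskIdx))
  zrim[shell[mt@maskIdx]] <- 5
  mt@zmaps[, 2L] <- zrim
  mt@table$edgeScore[2L] <- edgeArtifactScore(zrim, r@brainMask, mt@maskIdx)
  mtR <- rejectArtifactPipelines(mt, threshold = 0.6)
  expect_false(metricTable(mtR)$eligible[2L])
  expect_true(any(metricTable(mtR)$eligible))
  ## rejection refuses to flag every row
  mtAll <- mt
  mtAll@table$edgeScore[] <- 0.9
  expect_warning(mtOut <- rejectArtifactPipelines(mtAll, threshold = 0.6),
                 "disabled")
  expect_true(all(metricTable(mtOut)$eligible[!metricTable(mtOut)$failed]))
})

test_that("IND selection matches a brute-force scan with canonical ties", {
  r <- smallRun(seed = 57, amplitude = 1)
  grid <- enumeratePipelines("GNB",
    flagOptions = list(mc = FALSE, cens = FALSE, ret = FALSE, stc = FALSE,
                       mpr = FALSE, gspc1 = c(FALSE, TRUE),
                       taskReg = c(FALSE, TRUE), phy = FALSE),
    detrendOrders = c(0L, 1L, 3L))
  mt <- evaluateGrid(r, grid)
  tab <- metricTable(mt)
  expect_identical(attr(selectIndividual(mt, "P"), "index"),
                   which.max(tab$P))
  expect_identical(attr(selectIndividual(mt, "R"), "index"),
                   which.max(tab$R))
  expect_identical(attr(selectIndividual(mt, "D"), "index"),
                   which.min(tab$D))
  ## ties resolve to the earlier canonical row
  mt@table$D[] <- 1
  mt@table$P[] <- 0.5
  expect_identical(attr(selectIndividual(mt, "D"), "index"), 1L)
  ## a perfect row is the global D minimum
  mt@table$P[5L] <- 1
  mt@table$R[5L] <- 1
  mt@table$D[5L] <- 0
  expect_identical(attr(selectIndividual(mt, "D"), "index"), 5L)
})

test_that("FIX median-rank selection matches the hand-worked example", {
  r <- smallRun(seed = 58, amplitude = 1)
  grid <- enumeratePipelines("GNB",
    flagOptions = as.list(setNames(rep(FALSE, 8), npairsopt:::flagNames)),
    detrendOrders = c(0L, 1L, 2L))
  mt <- evaluateGrid(r, grid)
  mkTable <- function(dvals) {
    m <- mt
    m@table$D <- dvals
    m
  }
  ## ranks S1:(A=1,B=2,C=3), S2:(A=2,B=1,C=3), S3:(A=1,B=3,C=2)
  tabs <- list(mkTable(c(0.1, 0.2, 0.3)), mkTable(c(0.2, 0.1, 0.3)),
               mkTable(c(0.1, 0.3, 0.2)))
  fx <- selectFixed(tabs)
  expect_identical(attr(fx, "index"), 1L)
  ## single subject: FIX degenerates to IND-D
  expect_identical(attr(selectFixed(list(mt)), "index"),
                   attr(selectIndividual(mt, "D"), "index"))
  ## identical tables across subjects agree with any single one
  expect_identical(attr(selectFixed(list(mt, mt, mt)), "index"),
                   attr(selectFixed(list(mt)), "index"))
  ## brute-force median-rank oracle on random tables
  set.seed(11)
  for (rep in 1:20) {
    ds <- replicate(4, runif(3), simplify = FALSE)
    tabs <- lapply(ds, mkTable)
    ranks <- vapply(ds, rank, numeric(3L))
    med <- apply(ranks, 1L, median)
    mn <- rowMeans(ranks)
    expect_identical(attr(selectFixed(tabs), "index"), order(med, mn)[1L])
  }
})
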