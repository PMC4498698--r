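## Validation 2: behavioural and fMRI outlier screening, split-half
## behavioural PLS, and bootstrap comparison of pipelines.

#' Flag behavioural outlier runs
#'
#' A run is flagged if (a) mean reaction time is below 100 ms, (b) mean
#' accuracy is below 50%, or (c) mean RT is shorter for the more difficult
#' task (learning effects predominating).
#'
#' @param table data.frame with columns \code{meanRtMs} and \code{accuracy};
#'   rule (c) additionally needs \code{rtHardMs} and \code{rtEasyMs}.
#' @return logical flags, one per row.
#' @export
flagBehaviourOutliers <- function(table) {
  need <- c("meanRtMs", "accuracy")
  if (!all(need %in% names(table)))
    stop("missing behaviour columns: ",
         paste(setdiff(need, names(table)), collapse = ", "))
  flags <- table$meanRtMs < 100 | table$accuracy < 0.5
  if (all(c("rtHardMs", "rtEasyMs") %in% names(table))) {
    flags <- flags | (table$rtHardMs < table$rtEasyMs)
  }
  flags
}

#' RV coefficient between two map sets
#'
#' Matrix correlation RV = tr(X'X Y'Y) / sqrt(tr((X'X)^2) tr((Y'Y)^2)) on
#' column-centred data, in [0, 1].
#'
#' @param X,Y matrices (observations x voxels) with equal voxel counts;
#'   vectors are treated as single rows.
#' @export
rvCoefficient <- function(X, Y) {
  if (is.vector(X)) X <- matrix(X, 1L)
  if (is.vector(Y)) Y <- matrix(Y, 1L)
  if (ncol(X) != ncol(Y)) stop("voxel count mismatch")
  ## single maps are centred across voxels (observation centring is
  ## degenerate for one row)
  centre <- function(M) {
    if (nrow(M) == 1L) M - mean(M) else sweep(M, 2L, colMeans(M))
  }
  Xc <- centre(X)
  Yc <- centre(Y)
  ## n x n configuration form of the V x V trace identities
  num <- sum((Xc %*% t(Yc))^2)
  den <- sqrt(sum((Xc %*% t(Xc))^2) * sum((Yc %*% t(Yc))^2))
  if (den == 0) stop("zero matrix in RV coefficient")
  num / den
}

#' Flag multivariate fMRI outlier maps
#'
#' Computes each map's mean RV coefficient with all other maps and flags
#' maps falling below Q1 - 1.5 IQR of that distribution.
#'
#' @param spms matrix (maps x voxels), at least 4 maps.
#' @return logical flags per map.
#' @export
flagFmriOutliers <- function(spms) {
  n <- nrow(spms)
  if (n < 4L) stop("need at least 4 maps")
  ## each map is centred across voxels (single-map RV convention)
  Xc <- spms - rowMeans(spms)
  meanRV <- vapply(seq_len(n), function(i) {
    mean(vapply(setdiff(seq_len(n), i), function(j) {
      num <- sum(Xc[i, ] * Xc[j, ])^2
      den <- sum(Xc[i, ]^2) * sum(Xc[j, ]^2)
      if (den == 0) 0 else num / den
    }, numeric(1L)))
  }, numeric(1L))
  qs <- quantile(meanRV, c(0.25, 0.75), names = FALSE)
  meanRV < qs[1L] - 1.5 * (qs[2L] - qs[1L])
}

#' Split-half behavioural PLS
#'
#' Per resampling iteration, the runs are randomly split into halves
#' (optionally stratified); each half yields a behavioural salience map
#' (centred SPM matrix transposed times the standardised behaviour vector).
#' The half-pair gives gSNR_behav (from the salience-map reproducibility)
#' and a reproducible Z map; rho_behav is the correlation between one
#' half's brain scores -- its maps projected onto the other half's salience
#' -- and its own behaviour, averaged over both directions.  Medians are
#' taken over iterations.
#'
#' @param spms matrix (runs x voxels) of SPMs with outliers removed.
#' @param behaviour behavioural value per run (not constant).
#' @param nIter resampling iterations (default 100).
#' @param stratifyBy optional factor (e.g. session) balanced across halves.
#' @return a \linkS4class{PLSResult}.
#' @export
plsSplitHalf <- function(spms, behaviour, nIter = 100L, stratifyBy = NULL) {
  n <- nrow(spms)
  stopifnot(length(behaviour) == n)
  if (n < 8L) stop("need at least 8 runs")
  if (sd(behaviour) == 0) stop("behaviour vector is constant")
  halfSplit <- function() {
    if (is.null(stratifyBy)) {
      perm <- sample.int(n)
      list(perm[seq_len(floor(n / 2))], perm[(floor(n / 2) + 1L):n])
    } else {
      h1 <- unlist(lapply(split(seq_len(n), stratifyBy), function(ix) {
        ix <- sample(ix)
        ix[seq_len(floor(length(ix) / 2))]
      }), use.names = FALSE)
      list(h1, setdiff(seq_len(n), h1))
    }
  }
  salience <- function(idx) {
    Xc <- sweep(spms[idx, , drop = FALSE], 2L,
                colMeans(spms[idx, , drop = FALSE]))
    b <- behaviour[idx]
    b <- (b - mean(b)) / sd(b)
    as.numeric(t(Xc) %*% b / (length(idx) - 1L))
  }
  brainScoreRho <- function(salOther, idx) {
    Xc <- sweep(spms[idx, , drop = FALSE], 2L,
                colMeans(spms[idx, , drop = FALSE]))
    cor(as.numeric(Xc %*% salOther), behaviour[idx])
  }
  rho <- gsnr <- numeric(nIter)
  zAcc <- numeric(ncol(spms))
  for (it in seq_len(nIter)) {
    hs <- halfSplit()
    s1 <- salience(hs[[1L]])
    s2 <- salience(hs[[2L]])
    r <- as.numeric(reproducibility(s1, s2))
    gsnr[it] <- as.numeric(gsnrFromR(r))
    rho[it] <- mean(c(brainScoreRho(s2, hs[[1L]]),
                      brainScoreRho(s1, hs[[2L]])))
    zAcc <- zAcc + as.numeric(rspmZ(s1, s2))
  }
  new("PLSResult", rhoSamples = rho, gsnrSamples = gsnr,
      zmap = zAcc / nIter, medianRho = median(rho),
      medianGsnr = median(gsnr))
}

#' Bootstrap comparison of two pipelines' PLS estimates
#'
#' Resamples each pipeline's split-half estimates with replacement, takes
#' medians, and forms delta-gSNR = gSNR_A - gSNR_B and delta-rho =
#' rho_A - rho_B per draw; reports the fraction of draws with delta > 0 and
#' the empirical p = 1 - fraction.
#'
#' @param resultA,resultB \linkS4class{PLSResult}s with equal sample counts.
#' @param nBoot bootstrap draws (default 1000).
#' @return list with fractions, empirical p-values and \code{nBoot}.
#' @export
bootstrapDelta <- function(resultA, resultB, nBoot = 1000L) {
  nBoot <- as.integer(nBoot)
  nA <- length(resultA@rhoSamples)
  stopifnot(nA == length(resultB@rhoSamples))
  dG <- dR <- numeric(nBoot)
  for (b in seq_len(nBoot)) {
    ia <- sample.int(nA, replace = TRUE)
    ib <- sample.int(nA, replace = TRUE)
    dG[b] <- median(resultA@gsnrSamples[ia]) - median(resultB@gsnrSamples[ib])
    dR[b] <- median(resultA@rhoSamples[ia]) - median(resultB@rhoSamples[ib])
  }
  list(fracGsnr = mean(dG > 0), fracRho = mean(dR > 0),
       pGsnr = 1 - mean(dG > 0), pRho = 1 - mean(dR > 0), nBoot = nBoot)
}
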