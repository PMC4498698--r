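#' @useDynLib npairsopt, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats cor cov prcomp rnorm runif sd median mad quantile fft
#'   pnorm p.adjust wilcox.test setNames var approx optim sd
#' @importFrom utils write.csv read.csv head
NULL

## Sampled Legendre polynomials, orders 0..order, on a uniform grid over
## [-1, 1].  `orthonormal = TRUE` re-orthogonalises the sampled columns (QR)
## so that the discrete basis is exactly orthogonal on the scan grid; the
## column span (polynomials of degree <= order) is unchanged.
legendreBasis <- function(n, order, orthonormal = TRUE) {
  stopifnot(n >= 2L, order >= 0L)
  x <- seq(-1, 1, length.out = n)
  P <- matrix(0, n, order + 1L)
  P[, 1L] <- 1
  if (order >= 1L) P[, 2L] <- x
  if (order >= 2L) {
    for (k in 1L:(order - 1L)) {
      P[, k + 2L] <- ((2 * k + 1) * x * P[, k + 1L] - k * P[, k]) / (k + 1)
    }
  }
  if (orthonormal) {
    qrd <- qr(P)
    Q <- qr.Q(qrd)[, seq_len(order + 1L), drop = FALSE]
    ## fix signs so each column correlates positively with its raw version
    for (j in seq_len(ncol(Q))) {
      if (sum(Q[, j] * P[, j]) < 0) Q[, j] <- -Q[, j]
    }
    P <- Q
  }
  colnames(P) <- paste0("detrend", 0L:order)
  P
}

## Robust z-scores: (x - median) / (1.4826 * MAD), falling back to the SD
## when the MAD degenerates (more than half the values identical).
robustZ <- function(x) {
  med <- median(x)
  s <- mad(x, center = med)
  if (!is.finite(s) || s <= 0) s <- sd(x)
  if (!is.finite(s) || s <= 0) return(rep(0, length(x)))
  (x - med) / s
}

## 1D Gaussian smoothing matrix (length n) with reflective boundaries and
## row-normalised weights; sigma in voxel units.
gaussKernelMatrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma))
  w <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + seq(-r, r)
    ## reflect indices at the boundaries
    j <- ifelse(j < 1L, 2L - j, j)
    j <- ifelse(j > n, 2L * n - j, j)
    for (m in seq_along(j)) A[i, j[m]] <- A[i, j[m]] + w[m]
  }
  A / rowSums(A)
}

## Separable Gaussian smoothing of one 3D volume; sigmaVox per axis.
smoothVolume3D <- function(vol, kx, ky, kz) {
  d <- dim(vol)
  a <- array(kx %*% matrix(vol, d[1L], d[2L] * d[3L]), d)
  a <- aperm(a, c(2L, 1L, 3L))
  a <- array(ky %*% matrix(a, d[2L], d[1L] * d[3L]), c(d[2L], d[1L], d[3L]))
  a <- aperm(a, c(2L, 1L, 3L))
  a <- aperm(a, c(3L, 1L, 2L))
  a <- array(kz %*% matrix(a, d[3L], d[1L] * d[2L]), c(d[3L], d[1L], d[2L]))
  aperm(a, c(2L, 3L, 1L))
}

## Derive a child RNG seed from a base seed and a stream index, staying
## within 32-bit integer range.
deriveSeed <- function(seed, stream) {
  as.integer((as.double(seed) * 7919 + as.double(stream) * 104729) %%
               2147483646) + 1L
}

## Scatter a masked statistic vector back into a 3D volume (zeros elsewhere).
spmToVolume <- function(values, maskIdx, dim3) {
  vol <- array(0, dim3)
  vol[maskIdx] <- values
  vol
}

## 6-neighbourhood erosion of a 3D logical mask.
erodeMask <- function(mask) {
  d <- dim(mask)
  shift <- function(m, ax, by) {
    out <- array(FALSE, d)
    idx <- lapply(d, seq_len)
    src <- idx
    n <- d[ax]
    keep <- seq_len(n - abs(by))
    if (by > 0) { idx[[ax]] <- keep + by; src[[ax]] <- keep }
    else if (by < 0) { idx[[ax]] <- keep; src[[ax]] <- keep - by }
    out[idx[[1L]], idx[[2L]], idx[[3L]]] <- m[src[[1L]], src[[2L]], src[[3L]]]
    out
  }
  out <- mask
  for (ax in 1:3) {
    out <- out & shift(mask, ax, 1L) & shift(mask, ax, -1L)
  }
  out
}

## Framewise displacement from 6-parameter motion (translations mm,
## rotations deg), rotations converted to arc length on a 50 mm sphere.
framewiseDisplacement <- function(mp) {
  stopifnot(ncol(mp) == 6L)
  d <- abs(diff(mp))
  rot <- d[, 4:6, drop = FALSE] * pi / 180 * 50
  c(0, rowSums(cbind(d[, 1:3, drop = FALSE], rot)))
}
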