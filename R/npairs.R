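## Split-half NPAIRS evaluation: a predictive model (GNB or CVA) is trained
## on each temporal half and tested on the other, yielding prediction P
## (mean posterior probability of the true class), spatial reproducibility R
## (Pearson correlation of the two half-maps), gSNR = 2R/(1-R), the distance
## D = sqrt((1-P)^2 + (1-R)^2) from ideal performance, and a reproducible
## Z-scored SPM built from the signal/noise axes of the half-map pair.

#' Per-scan class labels of a task design
#'
#' Block designs label each scan with its condition; event-related designs
#' label scans by peristimulus lag (1..windowTrs) after each onset, each lag
#' forming one class, with NA outside any window.
#'
#' @param design a \linkS4class{TaskDesign}.
#' @param trS repetition time in seconds (event designs).
#' @return character vector of length \code{nScans} (NA = unlabelled).
#' @export
scanLabels <- function(design, trS = 2) {
  if (design@kind == "block") return(design@labels)
  lab <- rep(NA_character_, design@nScans)
  for (on in design@onsetsS) {
    s0 <- floor(on / trS) + 1L
    for (l in seq_len(design@windowTrs)) {
      s <- s0 + l - 1L
      if (s >= 1L && s <= design@nScans && is.na(lab[s]))
        lab[s] <- sprintf("lag%02d", l)
    }
  }
  lab
}

#' Split a run in time into two halves
#'
#' Returns the contiguous first and second temporal halves (odd scan counts
#' give the extra scan to the first half).  If a class would be absent from
#' either half, the split moves to the nearest class boundary that balances
#' the classes, with a message.
#'
#' @param design a \linkS4class{TaskDesign}.
#' @param nScans total scan count.
#' @param trS repetition time (event designs).
#' @return list of two integer index vectors.
#' @export
splitHalfIndices <- function(design, nScans, trS = 2) {
  lab <- scanLabels(design, trS)
  classes <- sort(unique(lab[!is.na(lab)]))
  covered <- function(cut) {
    h1 <- lab[seq_len(cut - 1L)]
    h2 <- lab[cut:nScans]
    all(classes %in% h1) && all(classes %in% h2)
  }
  cut0 <- ceiling(nScans / 2) + 1L
  if (covered(cut0)) {
    return(list(seq_len(cut0 - 1L), cut0:nScans))
  }
  cand <- setdiff(order(abs(seq_len(nScans + 1L) - cut0)), c(1L, nScans + 1L))
  for (cut in cand) {
    if (covered(cut)) {
      message("class-balanced split moved to scan boundary ", cut)
      return(list(seq_len(cut - 1L), cut:nScans))
    }
  }
  stop("no temporal split places every class in both halves")
}

#' Fit a Gaussian naive Bayes model
#'
#' Estimates per-voxel class means and (floored) variances, plus a
#' sensitivity SPM: for two classes, (mean2 - mean1)/pooled SD; for
#' multi-class, the stacked contrasts of each class mean against the grand
#' mean, with the first contrast reported as the map.
#'
#' @param X scans x voxels training matrix.
#' @param y class labels (one per scan).
#' @return list with class statistics and the sensitivity \code{map}.
#' @export
gnbFit <- function(X, y) {
  y <- as.character(y)
  classes <- sort(unique(y))
  if (any(table(y) < 2L)) stop("each class needs at least 2 scans")
  C <- length(classes)
  V <- ncol(X)
  means <- vars <- matrix(0, C, V)
  nC <- integer(C)
  for (ci in seq_len(C)) {
    sel <- y == classes[ci]
    nC[ci] <- sum(sel)
    means[ci, ] <- colMeans(X[sel, , drop = FALSE])
    vars[ci, ] <- apply(X[sel, , drop = FALSE], 2L, var)
  }
  floorVal <- max(1e-12, 1e-8 * mean(vars))
  vars <- pmax(vars, floorVal)
  pooled <- colSums(vars * (nC - 1L)) / sum(nC - 1L)
  poolSd <- sqrt(pmax(pooled, floorVal))
  if (C == 2L) {
    sens <- (means[2L, ] - means[1L, ]) / poolSd
    map <- sens
  } else {
    grand <- colSums(means * nC) / sum(nC)
    sens <- sweep(means, 2L, grand) / rep(poolSd, each = C)
    map <- sens[1L, ]
  }
  list(classes = classes, means = means, vars = vars, n = nC,
       sensitivity = sens, map = map)
}

#' Predict with a Gaussian naive Bayes model
#'
#' Computes the posterior probability of the true class for every test scan
#' from the joint (summed over voxels) log-likelihood with equal priors,
#' softmax-normalised across classes in the log domain; P is the mean over
#' test scans.  \code{posterior = "voxelwise"} instead averages per-voxel
#' posteriors, avoiding the joint-likelihood saturation of high-dimensional
#' data.
#'
#' @param model output of \code{\link{gnbFit}}.
#' @param X,y test data and labels.
#' @param posterior "joint" (default) or "voxelwise".
#' @return mean posterior probability P in [0, 1].
#' @export
gnbPredict <- function(model, X, y, posterior = c("joint", "voxelwise")) {
  posterior <- match.arg(posterior)
  y <- as.character(y)
  C <- length(model$classes)
  S <- nrow(X)
  trueIdx <- match(y, model$classes)
  if (anyNA(trueIdx)) stop("test labels outside the training classes")
  if (posterior == "joint") {
    ll <- matrix(0, S, C)
    for (ci in seq_len(C)) {
      v <- model$vars[ci, ]
      dev <- sweep(X, 2L, model$means[ci, ])
      ll[, ci] <- -0.5 * sum(log(2 * pi * v)) - dev^2 %*% (1 / (2 * v))
    }
    mx <- apply(ll, 1L, max)
    post <- exp(ll - mx)
    post <- post / rowSums(post)
    mean(post[cbind(seq_len(S), trueIdx)])
  } else {
    V <- ncol(X)
    llv <- vapply(seq_len(C), function(ci) {
      v <- model$vars[ci, ]
      dev <- sweep(X, 2L, model$means[ci, ])
      -0.5 * log(2 * pi * rep(v, each = S)) - dev^2 / (2 * rep(v, each = S))
    }, matrix(0, S, V))                    # S x V x C
    mx <- apply(llv, c(1L, 2L), max)
    num <- exp(llv - array(mx, dim(llv)))
    den <- apply(num, c(1L, 2L), sum)
    postVox <- num / array(den, dim(num))
    post <- apply(postVox, c(1L, 3L), mean)
    mean(post[cbind(seq_len(S), trueIdx)])
  }
}

#' Fit a canonical variates model in a PCA subspace
#'
#' Projects the (centred) training data onto principal components 1..k,
#' derives canonical discriminant directions from the within/between-class
#' scatter (ridge-stabilised), and back-projects the first canonical
#' direction to voxel space as a unit-norm eigenimage, sign-aligned to the
#' class contrast.
#'
#' @param X scans x voxels (centred) training matrix.
#' @param y class labels.
#' @param k PCA subspace size, at most min(scans - classes, voxels).
#' @param ridge relative ridge added to the within-class scatter.
#' @return list with PC loadings, canonical directions, canonical class
#'   means and the \code{map} (eigenimage).
#' @export
cvaFit <- function(X, y, k, ridge = 1e-6) {
  y <- as.character(y)
  classes <- sort(unique(y))
  C <- length(classes)
  n <- nrow(X)
  if (k > min(n - C, ncol(X))) stop("k exceeds min(scans - classes, voxels)")
  sv <- svd(X, nu = 0L, nv = k)
  Vk <- sv$v
  Tm <- X %*% Vk                            # scores, n x k
  grand <- colMeans(Tm)
  W <- matrix(0, k, k)
  B <- matrix(0, k, k)
  mu <- matrix(0, C, k)
  for (ci in seq_len(C)) {
    sel <- y == classes[ci]
    mu[ci, ] <- colMeans(Tm[sel, , drop = FALSE])
    dev <- sweep(Tm[sel, , drop = FALSE], 2L, mu[ci, ])
    W <- W + crossprod(dev)
    B <- B + sum(sel) * tcrossprod(mu[ci, ] - grand)
  }
  Wr <- W + diag(ridge * sum(diag(W)) / k, k)
  ev <- eigen(solve(Wr, B))
  m <- min(k, C - 1L)
  ord <- order(Re(ev$values), decreasing = TRUE)[seq_len(m)]
  A <- Re(ev$vectors[, ord, drop = FALSE])
  ## unit within-class variance along each canonical direction
  for (j in seq_len(m)) {
    s <- sqrt(as.numeric(t(A[, j]) %*% Wr %*% A[, j]) / max(n - C, 1L))
    if (s > 0) A[, j] <- A[, j] / s
  }
  ## sign alignment to the class contrast
  contrastT <- if (C == 2L) mu[2L, ] - mu[1L, ] else mu[1L, ] - grand
  if (sum(A[, 1L] * contrastT) < 0) A[, 1L] <- -A[, 1L]
  eig <- as.numeric(Vk %*% A[, 1L])
  nrm <- sqrt(sum(eig^2))
  if (nrm > 0) eig <- eig / nrm
  muCan <- mu %*% A
  list(classes = classes, Vk = Vk, A = A, classMeans = muCan, map = eig)
}

#' Predict with a canonical variates model
#'
#' Projects test scans into the training canonical space and scores them
#' under a Gaussian class model with shared (identity, by construction)
#' covariance; returns the mean posterior probability of the true class.
#'
#' @param model output of \code{\link{cvaFit}}.
#' @param X,y test data (centred) and labels.
#' @return mean posterior probability P.
#' @export
cvaPredict <- function(model, X, y) {
  y <- as.character(y)
  trueIdx <- match(y, model$classes)
  if (anyNA(trueIdx)) stop("test labels outside the training classes")
  Z <- X %*% model$Vk %*% model$A
  C <- length(model$classes)
  ll <- vapply(seq_len(C), function(ci)
    -0.5 * rowSums(sweep(Z, 2L, model$classMeans[ci, ])^2), numeric(nrow(Z)))
  ll <- matrix(ll, nrow(Z), C)
  mx <- apply(ll, 1L, max)
  post <- exp(ll - mx)
  post <- post / rowSums(post)
  mean(post[cbind(seq_len(nrow(Z)), trueIdx)])
}

#' Spatial reproducibility of two SPMs
#'
#' Pearson correlation over voxels of two half-maps on the same mask.  A
#' zero-variance map yields 0 with a \code{degenerate} attribute.
#' @param m1,m2 numeric voxel vectors.
#' @export
reproducibility <- function(m1, m2) {
  stopifnot(length(m1) == length(m2))
  if (sd(m1) == 0 || sd(m2) == 0) {
    r <- 0
    attr(r, "degenerate") <- TRUE
    return(r)
  }
  cor(m1, m2)
}

#' Global signal-to-noise ratio from reproducibility
#'
#' gSNR = 2R/(1-R), clamped at 0 for negative R; \code{form = "sqrt"} applies
#' the square-root variant sqrt(2R/(1-R)) used elsewhere in the NPAIRS
#' literature.
#'
#' @param R reproducibility in [-1, 1].
#' @param form "printed" (default) or "sqrt".
#' @export
gsnrFromR <- function(R, form = c("printed", "sqrt")) {
  form <- match.arg(form)
  if (R >= 1) {
    g <- Inf
    attr(g, "degenerate") <- TRUE
    return(g)
  }
  if (R < 0) return(0)
  g <- 2 * R / (1 - R)
  if (form == "sqrt") g <- sqrt(g)
  g
}

#' Reproducible Z-scored SPM from a split-half map pair
#'
#' Projects the pair onto the signal axis (m1+m2)/sqrt(2) and the noise axis
#' (m1-m2)/sqrt(2) and scales the signal by the SD of the noise axis over
#' voxels (floored at \code{eps}); symmetric in its arguments.
#'
#' @param m1,m2 half-maps on a common mask.
#' @param eps noise-SD floor.
#' @return Z-valued voxel vector (with a \code{degenerate} attribute when
#'   the noise SD hits the floor).
#' @export
rspmZ <- function(m1, m2, eps = 1e-12) {
  stopifnot(length(m1) == length(m2))
  sig <- (m1 + m2) / sqrt(2)
  noi <- (m1 - m2) / sqrt(2)
  sdn <- sd(noi)
  degen <- !is.finite(sdn) || sdn < eps
  if (degen) sdn <- eps
  z <- sig / sdn
  if (degen) attr(z, "degenerate") <- TRUE
  z
}

#' NPAIRS split-half evaluation of one preprocessed run
#'
#' Splits the run in time, fits the analysis model of \code{spec} on each
#' half and predicts the other (P = mean of the two directions), computes R
#' and the reproducible Z-scored SPM from the two half-maps, and
#' D = sqrt((1-P)^2 + (1-R)^2).  Each half is voxelwise mean-centred before
#' fitting.  Event-related designs label scans by peristimulus lag.
#'
#' @param bundle a preprocessed \linkS4class{SubjectRun} (analysis mask set).
#' @param spec the \linkS4class{PipelineSpec} (model and, for CVA, k).
#' @param posterior GNB posterior mode, see \code{\link{gnbPredict}}.
#' @return a \linkS4class{MetricResult}.
#' @export
npairsEvaluate <- function(bundle, spec, posterior = "joint") {
  d <- volData(bundle)
  dm <- dim(d)
  maskIdx <- which(bundle@analysisMask)
  X <- t(matrix(d, prod(dm[1:3]), dm[4L])[maskIdx, , drop = FALSE])
  lab <- scanLabels(bundle@design, bundle@vols@trS)
  halves <- splitHalfIndices(bundle@design, dm[4L], bundle@vols@trS)
  prep <- lapply(halves, function(idx) {
    keep <- idx[!is.na(lab[idx])]
    Xh <- X[keep, , drop = FALSE]
    Xh <- sweep(Xh, 2L, colMeans(Xh))      # within-split normalisation
    list(X = Xh, y = lab[keep])
  })
  fit <- function(h) {
    if (spec@model == "GNB") gnbFit(h$X, h$y)
    else cvaFit(h$X, h$y, spec@cvaK)
  }
  pred <- function(model, h) {
    if (spec@model == "GNB") gnbPredict(model, h$X, h$y, posterior = posterior)
    else cvaPredict(model, h$X, h$y)
  }
  f1 <- fit(prep[[1L]])
  f2 <- fit(prep[[2L]])
  P <- (pred(f1, prep[[2L]]) + pred(f2, prep[[1L]])) / 2
  R <- reproducibility(f1$map, f2$map)
  z <- rspmZ(f1$map, f2$map)
  g <- gsnrFromR(as.numeric(R))
  degen <- c(repro = isTRUE(attr(R, "degenerate")),
             zmap = isTRUE(attr(z, "degenerate")),
             gsnr = isTRUE(attr(g, "degenerate")))
  new("MetricResult", P = as.numeric(P), R = as.numeric(R),
      gSNR = as.numeric(g),
      D = sqrt((1 - as.numeric(P))^2 + (1 - as.numeric(R))^2),
      zmap = as.numeric(z), maskIdx = as.integer(maskIdx), spec = spec,
      degenerate = degen)
}
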