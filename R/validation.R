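## Validation 1: FDR-thresholded activation masks, Jaccard overlap with
## within-subject (between-session) and between-subject (within-session)
## bookkeeping, paired Wilcoxon comparisons, and reproducible group PC1
## eigenimages.

#' FDR-thresholded activation mask from a Z map
#'
#' Two-tailed p-values from Z, Benjamini-Hochberg step-up at level q.
#'
#' @param zmap Z values.
#' @param q FDR level in (0, 1] (default 0.05).
#' @return logical vector of rejected (active) voxels.
#' @export
fdrMask <- function(zmap, q = 0.05) {
  stopifnot(q > 0, q <= 1)
  p <- 2 * pnorm(-abs(zmap))
  p.adjust(p, method = "BH") <= q
}

#' Jaccard overlap of two activation masks
#'
#' |A intersect B| / |A union B|; two empty masks give 0 with a
#' \code{degenerate} attribute.
#' @param maskA,maskB logical arrays or vectors on the same grid.
#' @export
jaccard <- function(maskA, maskB) {
  if (!identical(dim(maskA), dim(maskB)) || length(maskA) != length(maskB))
    stop("mask shape mismatch")
  u <- sum(maskA | maskB)
  if (u == 0) {
    j <- 0
    attr(j, "degenerate") <- TRUE
    return(j)
  }
  sum(maskA & maskB) / u
}

## `spms` tables used below: data.frame with columns subject, session
## ("test"/"retest"), run, task, strategy and a list-column `mask` of
## logical activation grids (FDR-thresholded SPMs).

#' Within-subject, between-session activation overlap
#'
#' Pairs run-k (test) only with run-k (retest) for every retest subject --
#' never run-1 against run-2, to avoid confounds from non-stationary
#' learning -- and returns one Jaccard value per pair: (2 runs) x (retest
#' subjects) rows.
#'
#' @param spms SPM mask table (see source header).
#' @param task,strategy selection filters.
#' @return data.frame with subject, run and jaccard columns.
#' @export
withinSubjectOverlap <- function(spms, task = NULL, strategy = NULL) {
  s <- filterSpms(spms, task, strategy)
  out <- list()
  for (subj in unique(s$subject)) {
    for (r in sort(unique(s$run[s$subject == subj]))) {
      a <- which(s$subject == subj & s$run == r & s$session == "test")
      b <- which(s$subject == subj & s$run == r & s$session == "retest")
      if (length(a) == 1L && length(b) == 1L) {
        out[[length(out) + 1L]] <- data.frame(
          subject = subj, run = r,
          jaccard = as.numeric(jaccard(s$mask[[a]], s$mask[[b]])))
      }
    }
  }
  if (!length(out)) return(data.frame(subject = character(),
                                      run = integer(), jaccard = numeric()))
  do.call(rbind, out)
}

#' Between-subject, within-session activation overlap
#'
#' For each session and run separately, computes every subject's mean
#' Jaccard overlap with all other subjects, then pools the rows over
#' sessions: 27 test subjects x 2 runs give 54 rows, adding 20 retest
#' subjects x 2 runs gives 94 in the full design.
#'
#' @inheritParams withinSubjectOverlap
#' @return data.frame with subject, session, run and jaccard columns.
#' @export
betweenSubjectOverlap <- function(spms, task = NULL, strategy = NULL) {
  s <- filterSpms(spms, task, strategy)
  out <- list()
  for (sess in unique(s$session)) {
    for (r in sort(unique(s$run[s$session == sess]))) {
      idx <- which(s$session == sess & s$run == r)
      if (length(idx) < 2L) stop("need at least 2 subjects per session/run")
      for (i in idx) {
        js <- vapply(setdiff(idx, i), function(j)
          as.numeric(jaccard(s$mask[[i]], s$mask[[j]])), numeric(1L))
        out[[length(out) + 1L]] <- data.frame(
          subject = s$subject[i], session = sess, run = r,
          jaccard = mean(js))
      }
    }
  }
  do.call(rbind, out)
}

filterSpms <- function(spms, task, strategy) {
  if (!is.null(task)) spms <- spms[spms$task == task, , drop = FALSE]
  if (!is.null(strategy))
    spms <- spms[spms$strategy == strategy, , drop = FALSE]
  spms
}

#' Paired two-sided Wilcoxon signed-rank test
#'
#' Zero differences are dropped; if all differences are zero the p-value is
#' 1 with a \code{degenerate} attribute.
#'
#' @param valuesA,valuesB paired samples of equal length (>= 5).
#' @return two-sided p-value.
#' @export
pairedWilcoxon <- function(valuesA, valuesB) {
  stopifnot(length(valuesA) == length(valuesB), length(valuesA) >= 5L)
  d <- valuesA - valuesB
  keep <- d != 0
  if (!any(keep)) {
    p <- 1
    attr(p, "degenerate") <- TRUE
    return(p)
  }
  suppressWarnings(
    wilcox.test(valuesA[keep], valuesB[keep], paired = TRUE,
                exact = FALSE)$p.value)
}

#' Reproducible group PC1 eigenimage (Z-scored)
#'
#' Repeatedly splits a stack of SPMs into random halves, extracts the first
#' principal-component eigenimage of each half (sign-aligned to positive
#' mean loading), forms the reproducible Z map of each pair, and averages
#' the Z maps over splits.
#'
#' @param spms matrix (maps x voxels), at least 4 maps.
#' @param nSplits number of random half-splits (default 50).
#' @return averaged Z-valued voxel vector.
#' @export
pc1EigenimageZ <- function(spms, nSplits = 50L) {
  n <- nrow(spms)
  if (n < 4L) stop("need at least 4 SPMs")
  ## uncentred first singular vector: the dominant shared pattern of the
  ## stack (centring would subtract exactly the stable map being sought)
  pc1 <- function(M) {
    v <- svd(M, nu = 0L, nv = 1L)$v[, 1L]
    if (mean(v) < 0) v <- -v
    v
  }
  zAcc <- numeric(ncol(spms))
  for (s in seq_len(nSplits)) {
    perm <- sample.int(n)
    h1 <- perm[seq_len(floor(n / 2))]
    h2 <- perm[(floor(n / 2) + 1L):n]
    zAcc <- zAcc + as.numeric(rspmZ(pc1(spms[h1, , drop = FALSE]),
                                    pc1(spms[h2, , drop = FALSE])))
  }
  zAcc / nSplits
}

#' Mean correlation matrix between strategy/model SPMs
#'
#' For each run, the pairwise Pearson correlation matrix between the SPMs of
#' every pipeline-strategy/analysis-model combination, averaged across runs.
#'
#' @param spmsByStrategy named list; each element a (runs x voxels) matrix
#'   with aligned rows.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
spmCorrelationMatrix <- function(spmsByStrategy) {
  k <- length(spmsByStrategy)
  nr <- unique(vapply(spmsByStrategy, nrow, integer(1L)))
  nv <- unique(vapply(spmsByStrategy, ncol, integer(1L)))
  if (length(nr) != 1L || length(nv) != 1L)
    stop("SPM stacks must share runs and mask")
  acc <- matrix(0, k, k)
  for (r in seq_len(nr)) {
    maps <- vapply(spmsByStrategy, function(m) m[r, ], numeric(nv))
    acc <- acc + cor(maps)
  }
  out <- acc / nr
  dimnames(out) <- list(names(spmsByStrategy), names(spmsByStrategy))
  diag(out) <- 1
  (out + t(out)) / 2
}
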