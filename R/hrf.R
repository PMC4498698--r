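#' Canonical haemodynamic response function
#'
#' Double-gamma HRF (response peak near 5 s, undershoot near 15 s, undershoot
#' ratio 1/6), evaluated at times \code{t} in seconds.
#'
#' @param t time points in seconds.
#' @return HRF values, unit peak.
#' @export
canonicalHrf <- function(t) {
  h <- stats::dgamma(t, shape = 6, scale = 1) -
    stats::dgamma(t, shape = 16, scale = 1) / 6
  h[t < 0] <- 0
  h / max(h)
}

## Task boxcar sampled on a fine grid from a TaskDesign: for block designs
## the boxcar is 1 during non-reference condition blocks (the reference is
## the first condition level); for event designs, 1 during each event.
taskBoxcar <- function(design, nScansOut, trS, dt = 0.1) {
  tEnd <- nScansOut * trS
  tg <- seq(0, tEnd - dt, by = dt)
  box <- numeric(length(tg))
  if (design@kind == "block") {
    lv <- sort(unique(design@labels))
    on <- design@labels != lv[1L]
    scanOf <- pmin(floor(tg / trS) + 1L, design@nScans)
    box <- as.numeric(on[scanOf])
  } else {
    for (i in seq_along(design@onsetsS)) {
      sel <- tg >= design@onsetsS[i] &
        tg < design@onsetsS[i] + max(design@durationsS[i], dt)
      box[sel] <- 1
    }
  }
  list(t = tg, box = box, dt = dt)
}

#' HRF-convolved task regressor
#'
#' Convolves the task paradigm (block boxcar or event stick function) with
#' the canonical double-gamma HRF and samples the result at scan acquisition
#' times, normalised to unit peak.
#'
#' @param design a \linkS4class{TaskDesign}.
#' @param nScansOut number of scans to cover.
#' @param trS repetition time in seconds.
#' @return numeric vector of length \code{nScansOut}; all zeros when the
#'   design contains no events.
#' @export
hrfRegressor <- function(design, nScansOut, trS) {
  bc <- taskBoxcar(design, nScansOut, trS)
  if (all(bc$box == 0)) return(numeric(nScansOut))
  ht <- canonicalHrf(seq(0, 32, by = bc$dt))
  conv <- stats::convolve(bc$box, rev(ht), type = "open")[seq_along(bc$t)]
  scanT <- (seq_len(nScansOut) - 1L) * trS
  reg <- approx(bc$t, conv, xout = scanT, rule = 2)$y
  m <- max(abs(reg))
  if (m > 0) reg <- reg / m
  reg
}
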