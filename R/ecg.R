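#' Detect R peaks in an ECG recording
#'
#' Pan-Tompkins-style detector: band-pass 5-15 Hz (zero-phase Butterworth),
#' differentiate, square, moving-window integrate over 150 ms, then an
#' adaptive signal/noise threshold with a 250 ms refractory period. Each
#' detection is snapped to the local maximum of the band-passed waveform,
#' so reported beat times are not biased by the integrator delay.
#'
#' @param ecg an \linkS4class{EcgRecording} of at least 10 s.
#' @param searchWindow half-width of the local-maximum refinement window,
#'   seconds.
#' @return A \linkS4class{BeatSeries} (empty, with a warning, for flatline
#'   input).
#' @export
detectRPeaks <- function(ecg, searchWindow = 0.1) {
  stopifnot(is(ecg, "EcgRecording"))
  x <- ecg@samples
  fs <- ecg@fs
  if (length(x) < 10 * fs)
    stop("detectRPeaks: recording must be at least 10 s long")
  if (all(!is.finite(x)) || sd(x[is.finite(x)]) == 0) {
    warning("detectRPeaks: flatline or all-NaN input; returning empty series")
    return(beatSeries(numeric(0)))
  }
  x[!is.finite(x)] <- 0

  bf <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  xb <- signal::filtfilt(bf, x)
  deriv <- c(0, diff(xb)) * fs
  sq <- deriv^2
  w <- max(1L, round(0.15 * fs))
  integ <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  integ[is.na(integ)] <- 0

  refr <- round(0.25 * fs)
  # candidate peaks: local maxima of the integrated signal
  isPk <- which(diff(sign(diff(integ))) < 0) + 1L
  if (!length(isPk)) {
    warning("detectRPeaks: no candidate peaks found")
    return(beatSeries(numeric(0)))
  }
  # adaptive running estimates of signal and noise peak levels
  spki <- max(integ[seq_len(min(length(integ), 2 * fs))]) * 0.5
  npki <- mean(integ[seq_len(min(length(integ), 2 * fs))]) * 0.5
  det <- integer(0)
  lastDet <- -Inf
  for (i in isPk) {
    thr <- npki + 0.25 * (spki - npki)
    if (integ[i] > thr && (i - lastDet) > refr) {
      det <- c(det, i)
      lastDet <- i
      spki <- 0.125 * integ[i] + 0.875 * spki
    } else {
      npki <- 0.125 * integ[i] + 0.875 * npki
    }
  }
  if (!length(det)) {
    warning("detectRPeaks: no peaks above threshold")
    return(beatSeries(numeric(0)))
  }
  # snap each detection to the band-passed waveform maximum nearby
  half <- as.integer(round(searchWindow * fs))
  peaks <- vapply(det, function(i) {
    lo <- max(1L, i - half)
    hi <- min(length(xb), i + half)
    as.integer(lo + which.max(xb[lo:hi]) - 1L)
  }, integer(1))
  peaks <- sort(unique(peaks))
  # drop refinements collapsing within the refractory period
  if (length(peaks) > 1L)
    peaks <- peaks[c(TRUE, diff(peaks) > refr)]
  beatSeries(ecg@startTime + (peaks - 1L) / fs, artifact = TRUE)
}

#' Clean an RR-interval series
#'
#' Flags RR intervals outside [0.25, 2.0] s or differing by more than 20%
#' from the running median of 5 RRs, and repairs each maximal run of
#' flagged intervals by removing its interior beats and re-inserting beats
#' by linear interpolation between the bounding (untouched) beats, with the
#' inserted count chosen from the local median RR. The operation is
#' idempotent. The number of corrected intervals is reported via
#' \code{message}.
#'
#' @param beats a \linkS4class{BeatSeries} with at least 3 beats.
#' @param maxFracFlagged recordings with more than this fraction of RRs
#'   flagged are rejected as invalid (error of class
#'   \code{invalidRecording}).
#' @return A cleaned \linkS4class{BeatSeries}.
#' @export
cleanRR <- function(beats, maxFracFlagged = 0.2) {
  stopifnot(is(beats, "BeatSeries"))
  bt <- beatTimes(beats)
  if (length(bt) < 3L) stop("cleanRR: need at least 3 beats")
  rr <- diff(bt)
  med <- runningMedian5(rr)
  bad <- rr < 0.25 | rr > 2.0 | abs(rr - med) / med > 0.2
  if (!any(bad)) return(beatSeries(bt))
  if (mean(bad) > maxFracFlagged)
    stop(structure(class = c("invalidRecording", "error", "condition"),
                   list(message = sprintf(
                     "cleanRR: %.0f%% of RR intervals flagged; recording marked invalid",
                     100 * mean(bad)), call = sys.call())))
  # group flagged RRs into maximal runs; RR i spans beats (i, i+1)
  r <- rle(bad)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- rep(TRUE, length(bt))
  inserts <- list()
  for (j in which(r$values)) {
    i0 <- starts[j]          # first flagged RR index
    i1 <- ends[j]            # last flagged RR index
    tA <- bt[i0]             # bounding beats stay untouched
    tB <- bt[i1 + 1L]
    if (i1 > i0) keep[(i0 + 1L):i1] <- FALSE
    m <- max(0L, as.integer(round((tB - tA) / med[i0])) - 1L)
    if (m > 0L)
      inserts[[length(inserts) + 1L]] <- tA + (tB - tA) * seq_len(m) / (m + 1L)
  }
  out <- sort(c(bt[keep], unlist(inserts)))
  message("cleanRR: corrected ", sum(bad), " RR interval(s)")
  beatSeries(out)
}

runningMedian5 <- function(x) {
  n <- length(x)
  if (n < 5L) return(rep(median(x), n))
  m <- stats::runmed(x, 5L, endrule = "median")
  as.numeric(m)
}

#' Evenly sampled instantaneous heart rate from beats
#'
#' Assigns hr = 60/RR to each RR midpoint, interpolates with a cubic
#' spline onto a uniform grid at \code{fsOut}, and holds the edge values
#' constant beyond the first/last midpoint.
#'
#' @param beats a \linkS4class{BeatSeries} with at least 3 beats.
#' @param fsOut output sampling rate, Hz (default 4, standard for HRV
#'   spectral analysis).
#' @param tStart,tEnd grid limits in seconds; default to the first/last RR
#'   midpoint.
#' @param method \code{"cubic"} (default) or \code{"linear"} interpolation.
#' @return An \linkS4class{HrSignal}.
#' @export
instantaneousHR <- function(beats, fsOut = 4, tStart = NULL, tEnd = NULL,
                            method = c("cubic", "linear")) {
  stopifnot(is(beats, "BeatSeries"))
  method <- match.arg(method)
  bt <- beatTimes(beats)
  if (length(bt) < 3L) stop("instantaneousHR: need at least 3 beats")
  rr <- diff(bt)
  mid <- bt[-length(bt)] + rr / 2
  hrv <- 60 / rr
  if (is.null(tStart)) tStart <- mid[1L]
  if (is.null(tEnd)) tEnd <- mid[length(mid)]
  grid <- seq(tStart, tEnd, by = 1 / fsOut)
  if (length(grid) < 2L)
    stop("instantaneousHR: span shorter than one output sample")
  tc <- pmin(pmax(grid, mid[1L]), mid[length(mid)])  # edge-hold
  hr <- if (method == "cubic") spline(mid, hrv, xout = tc, method = "fmm")$y
        else approx(mid, hrv, xout = tc, rule = 2)$y
  hrSignal(grid, hr, fsOut)
}

#' Read an ECG from a two-column CSV (t_s, mV)
#' @param path file path; first column time in seconds (uniform grid),
#'   second column amplitude in mV.
#' @return An \linkS4class{EcgRecording}.
#' @export
readEcgCsv <- function(path) {
  d <- utils::read.csv(path)
  t <- d[[1L]]
  fs <- 1 / median(diff(t))
  ecgRecording(d[[2L]], fs, startTime = t[1L])
}

#' Write / read an HrSignal as CSV (t_s, hr_bpm)
#' @param hr an \linkS4class{HrSignal}.
#' @param path file path.
#' @return \code{readHrSignal} returns an \linkS4class{HrSignal}.
#' @export
writeHrSignal <- function(hr, path) {
  utils::write.csv(data.frame(t_s = hrTime(hr), hr_bpm = hrBpm(hr)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeHrSignal
#' @export
readHrSignal <- function(path) {
  d <- utils::read.csv(path)
  fs <- 1 / median(diff(d$t_s))
  hrSignal(d$t_s, d$hr_bpm, round(fs, 9))
}
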