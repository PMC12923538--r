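#' Exact-frequency spectral power of one block
#'
#' Projects the mean-removed heart-rate segment onto the exact entrainment
#' frequency (a single-frequency discrete Fourier projection, not an
#' FFT-bin estimate):
#' \deqn{P = (2/N^2) |\sum_n x_n e^{-i 2 \pi f_0 t_n}|^2}
#' so a pure sinusoid of amplitude A at \eqn{f_0} returns \eqn{A^2/2}
#' regardless of grid alignment. This realizes the high-frequency-resolution
#' estimate at 0.0625 Hz used to quantify heart-brain coupling per block.
#'
#' @param hr an \linkS4class{HrSignal}.
#' @param window numeric length-2, half-open block window
#'   \code{[start, end)} in seconds.
#' @param f0 analysis frequency, Hz.
#' @return Power in bpm^2; \code{NA} (with invalid semantics) if the window
#'   contains non-finite samples.
#' @examples
#' t <- seq(0, 16 - 0.25, by = 0.25)
#' hr <- hrSignal(t, 70 + 2 * sin(2 * pi * 0.0625 * t), 4)
#' blockPower(hr, c(0, 16))  # 2.0 = A^2/2 with A = 2
#' @export
blockPower <- function(hr, window, f0 = 0.0625) {
  stopifnot(is(hr, "HrSignal"), length(window) == 2L)
  if (f0 <= 0) stop("blockPower: f0 must be positive")
  if (diff(window) < 1 / hr@fsOut)
    stop("blockPower: window shorter than one sample grid step")
  idx <- hr@time >= window[1L] & hr@time < window[2L]
  x <- hr@hr[idx]
  tn <- hr@time[idx]
  if (length(x) < 8L)
    stop("blockPower: window contains fewer than 8 samples")
  if (anyNA(x) || any(!is.finite(x))) return(NA_real_)
  x <- x - mean(x)
  z <- sum(x * exp(-1i * 2 * pi * f0 * tn))
  (2 / length(x)^2) * Mod(z)^2
}

#' Per-block HBC power for one recording
#'
#' Computes the entrainment-frequency power for every block of the
#' schedule, marks the protocol blocks (the rest block at 0 %MSO plus the
#' active ramp) as retained for analysis — the flanking pre/post rest
#' blocks are excluded from modeling to mitigate edge effects but their
#' powers are preserved for baseline correction — and flags blocks with
#' fewer than 2 beats as invalid.
#'
#' @param hr an \linkS4class{HrSignal} covering all block windows.
#' @param schedule a \linkS4class{ProtocolSchedule}.
#' @param meta optional named list (e.g. participant, session, target)
#'   prepended as constant columns.
#' @param beats optional \linkS4class{BeatSeries} used to count beats per
#'   block; without it \code{n_beats} is \code{NA} and no block is
#'   invalidated by beat count.
#' @param f0 analysis frequency, Hz.
#' @return A data.frame with one row per block: \code{block_index},
#'   \code{phase}, \code{intensity_pct_mso}, \code{intensity_pct_mt},
#'   \code{hbc_power}, \code{n_beats}, \code{valid}, \code{retained}.
#' @export
computeSessionHbc <- function(hr, schedule, meta = list(), beats = NULL,
                              f0 = 0.0625) {
  stopifnot(is(hr, "HrSignal"), is(schedule, "ProtocolSchedule"))
  b <- scheduleBlocks(schedule)
  tr <- range(hr@time)
  if (tr[1L] > min(b$onset_s) + 1e-9 ||
      tr[2L] < max(b$onset_s + b$duration_s) - 1 / hr@fsOut - 1e-9)
    stop("computeSessionHbc: HR signal does not cover the schedule (",
         "signal [", tr[1L], ", ", tr[2L], "], schedule [",
         min(b$onset_s), ", ", max(b$onset_s + b$duration_s), "))")
  bt <- if (!is.null(beats)) beatTimes(beats) else NULL
  mt <- intensityPctMt(schedule)
  pw <- numeric(nrow(b))
  nb <- rep(NA_integer_, nrow(b))
  valid <- rep(TRUE, nrow(b))
  for (i in seq_len(nrow(b))) {
    win <- c(b$onset_s[i], b$onset_s[i] + b$duration_s[i])
    pw[i] <- blockPower(hr, win, f0 = f0)
    if (!is.null(bt)) {
      nb[i] <- sum(bt >= win[1L] & bt < win[2L])
      if (nb[i] < 2L) valid[i] <- FALSE
    }
    if (is.na(pw[i])) valid[i] <- FALSE
  }
  if (any(!valid))
    message("computeSessionHbc: ", sum(!valid), " invalid block(s)")
  out <- data.frame(
    block_index = b$index, phase = b$phase,
    intensity_pct_mso = b$intensity_pct_mso, intensity_pct_mt = mt,
    hbc_power = ifelse(valid, pw, NA_real_), n_beats = nb, valid = valid,
    retained = b$phase %in% c("protocol_rest", "active"),
    stringsAsFactors = FALSE)
  if (length(meta)) out <- cbind(as.data.frame(meta, stringsAsFactors = FALSE),
                                 out, row.names = NULL)
  out
}

#' Baseline-correct block powers against the pre-stimulation rest mean
#'
#' Subtracts, within each participant x session x target recording (or the
#' whole table when those columns are absent), the mean power over valid
#' \code{pre_rest} blocks, adding a \code{hbc_power_corrected} column. Raw
#' powers are retained unchanged: downstream Gamma modeling uses the raw
#' (strictly positive) values, the corrected values serve descriptive
#' comparisons.
#'
#' @param rows a data.frame as produced by \code{\link{computeSessionHbc}}.
#' @return \code{rows} with an extra \code{hbc_power_corrected} column.
#' @export
baselineCorrect <- function(rows) {
  stopifnot(is.data.frame(rows), "hbc_power" %in% names(rows))
  keyCols <- intersect(c("participant", "session", "target"), names(rows))
  grp <- if (length(keyCols)) interaction(rows[keyCols], drop = TRUE)
         else factor(rep(1L, nrow(rows)))
  corrected <- rep(NA_real_, nrow(rows))
  for (g in levels(grp)) {
    sel <- grp == g
    ref <- sel & rows$phase == "pre_rest" & rows$valid &
           !is.na(rows$hbc_power)
    if (!any(ref)) {
      warning("baselineCorrect: no valid pre_rest block for group '", g,
              "'; correction skipped")
      next
    }
    corrected[sel] <- rows$hbc_power[sel] - mean(rows$hbc_power[ref])
  }
  rows$hbc_power_corrected <- corrected
  rows
}

#' Assemble the study-level block table
#'
#' Runs beat cleaning, instantaneous-HR derivation and per-block power over
#' every recording of a simulated (or loaded) study and joins the recording
#' metadata, yielding the tidy block table consumed by the modeling, ICC
#' and directionality stages. Rows are ordered by participant, session,
#' target, block.
#'
#' @param study a \code{StudySimulation} (see \code{\link{simulateStudy}}).
#' @param fsOut instantaneous-HR sampling rate, Hz.
#' @param f0 analysis frequency, Hz.
#' @param clean apply \code{\link{cleanRR}} before HR derivation.
#' @return A data.frame (HBC block table) with metadata columns
#'   (participant, session, target, rmt, pain, side_effects_sum) plus the
#'   per-block columns of \code{\link{computeSessionHbc}} and
#'   \code{hbc_power_corrected}.
#' @export
studyHbcTable <- function(study, fsOut = 4, f0 = 0.0625, clean = FALSE) {
  stopifnot(inherits(study, "StudySimulation"))
  rows <- vector("list", length(study$recordings))
  for (i in seq_along(study$recordings)) {
    rec <- study$recordings[[i]]
    key <- names(study$recordings)[i]
    m <- study$meta[study$meta$key == key, , drop = FALSE]
    beats <- rec$beats
    if (clean) beats <- suppressMessages(cleanRR(beats))
    sb <- scheduleBlocks(rec$schedule)
    hr <- instantaneousHR(beats, fsOut = fsOut, tStart = 0,
                          tEnd = max(sb$onset_s + sb$duration_s))
    tab <- computeSessionHbc(hr, rec$schedule,
                             meta = list(participant = m$participant,
                                         session = m$session,
                                         target = m$target,
                                         rmt = m$rmt, pain = m$pain,
                                         side_effects_sum = m$side_effects_sum),
                             beats = beats, f0 = f0)
    rows[[i]] <- tab
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$participant, out$session, out$target, out$block_index), ]
  rownames(out) <- NULL
  baselineCorrect(out)
}

#' Write / read an HBC block table as tidy CSV
#' @param table a block-table data.frame.
#' @param path file path.
#' @return \code{readHbcTable} returns the data.frame.
#' @export
writeHbcTable <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeHbcTable
#' @export
readHbcTable <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
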