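#' Post-train heart-rate change per active block
#'
#' For each active block, compares mean HR over the window
#' \code{[train_end, train_end + window)} against two references:
#' \describe{
#'   \item{\code{delta_bpm_pretrain}}{minus the mean HR over the
#'     \code{window}-long period immediately before train onset.}
#'   \item{\code{delta_bpm_stable}}{minus a stable session baseline: the
#'     mean HR over all rest-phase blocks excluding the first two blocks of
#'     the recording.}
#' }
#' Negative deltas denote deceleration. Blocks whose windows extend past
#' the recording are skipped with a message.
#'
#' @param hr an \linkS4class{HrSignal}.
#' @param schedule a \linkS4class{ProtocolSchedule}.
#' @param window analysis window length, seconds.
#' @param trainDuration train duration within each active block, seconds.
#' @param meta optional named list of constant identifier columns.
#' @return data.frame: (meta columns), block_index, intensity_pct_mt,
#'   delta_bpm_stable, delta_bpm_pretrain.
#' @export
postTrainHrChange <- function(hr, schedule, window = 2, trainDuration = 5,
                              meta = list()) {
  stopifnot(is(hr, "HrSignal"), is(schedule, "ProtocolSchedule"))
  b <- scheduleBlocks(schedule)
  mt <- intensityPctMt(schedule)
  t <- hrTime(hr)
  y <- hrBpm(hr)
  winMean <- function(a, z) {
    sel <- t >= a & t < z
    if (!any(sel)) NA_real_ else mean(y[sel])
  }
  restSel <- b$phase %in% c("pre_rest", "protocol_rest", "post_rest") &
    b$index > 2L
  if (!any(restSel)) stop("postTrainHrChange: no rest blocks for the stable baseline")
  stableSamples <- rep(FALSE, length(t))
  for (i in which(restSel))
    stableSamples <- stableSamples |
      (t >= b$onset_s[i] & t < b$onset_s[i] + b$duration_s[i])
  stable <- mean(y[stableSamples])
  rows <- list()
  for (i in which(b$phase == "active")) {
    trainStart <- b$onset_s[i]
    trainEnd <- trainStart + trainDuration
    if (trainEnd + window > max(t) + 1 / hr@fsOut) {
      message("postTrainHrChange: block ", b$index[i],
              " window extends past recording; skipped")
      next
    }
    post <- winMean(trainEnd, trainEnd + window)
    pre <- winMean(trainStart - window, trainStart)
    rows[[length(rows) + 1L]] <- data.frame(
      block_index = b$index[i], intensity_pct_mt = mt[i],
      delta_bpm_stable = post - stable,
      delta_bpm_pretrain = post - pre, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (length(meta))
    out <- cbind(as.data.frame(meta, stringsAsFactors = FALSE), out,
                 row.names = NULL)
  out
}

#' Post-train HR change over a whole study
#'
#' Applies \code{\link{postTrainHrChange}} to every recording of a
#' simulated study.
#'
#' @param study a \code{StudySimulation}.
#' @param window,trainDuration passed through.
#' @param fsOut instantaneous-HR sampling rate, Hz.
#' @return data.frame of per-block HR-change rows with participant,
#'   session, target identifiers.
#' @export
studyHrChange <- function(study, window = 2, trainDuration = NULL,
                          fsOut = 4) {
  stopifnot(inherits(study, "StudySimulation"))
  if (is.null(trainDuration)) trainDuration <- study$config@trainDuration
  rows <- lapply(names(study$recordings), function(key) {
    rec <- study$recordings[[key]]
    sb <- scheduleBlocks(rec$schedule)
    hr <- instantaneousHR(rec$beats, fsOut = fsOut, tStart = 0,
                          tEnd = max(sb$onset_s + sb$duration_s))
    postTrainHrChange(hr, rec$schedule, window = window,
                      trainDuration = trainDuration,
                      meta = list(participant = rec$participant,
                                  session = rec$session,
                                  target = rec$target))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize HR-change direction per target and intensity
#'
#' Cell means with normal-approximation 95% CIs of the chosen delta, plus
#' a per-target monotonic-trend statistic (Spearman correlation of delta
#' with intensity).
#'
#' @param rows output of \code{\link{postTrainHrChange}} /
#'   \code{\link{studyHrChange}}.
#' @param which \code{"pretrain"} or \code{"stable"} delta.
#' @param level confidence level.
#' @return list with \code{cells}: data.frame (target, intensity_pct_mt,
#'   mean_delta, se, ci_low, ci_high, n) and \code{trend}: data.frame
#'   (target, spearman_rho, n).
#' @export
directionSummary <- function(rows, which = c("pretrain", "stable"),
                             level = 0.95) {
  which <- match.arg(which)
  col <- paste0("delta_bpm_", which)
  stopifnot(col %in% names(rows), "target" %in% names(rows))
  zc <- qnorm(1 - (1 - level) / 2)
  cells <- list()
  for (tg in sort(unique(rows$target))) {
    for (mt in sort(unique(rows$intensity_pct_mt[rows$target == tg]))) {
      d <- rows[[col]][rows$target == tg & rows$intensity_pct_mt == mt]
      d <- d[is.finite(d)]
      if (length(d) < 2L) next
      m <- mean(d)
      se <- sd(d) / sqrt(length(d))
      cells[[length(cells) + 1L]] <- data.frame(
        target = tg, intensity_pct_mt = mt, mean_delta = m, se = se,
        ci_low = m - zc * se, ci_high = m + zc * se, n = length(d),
        stringsAsFactors = FALSE)
    }
  }
  trend <- lapply(sort(unique(rows$target)), function(tg) {
    d <- rows[rows$target == tg & is.finite(rows[[col]]), , drop = FALSE]
    data.frame(target = tg,
               spearman_rho = suppressWarnings(
                 cor(d$intensity_pct_mt, d[[col]], method = "spearman")),
               n = nrow(d), stringsAsFactors = FALSE)
  })
  list(cells = do.call(rbind, cells), trend = do.call(rbind, trend))
}
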