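#' Entrainment frequency of a protocol
#'
#' One stimulation cycle is a train plus its inter-train interval; the
#' protocol entrains heart rate at the reciprocal of that cycle. For the
#' default 5 s + 11 s cycle this is 0.0625 Hz.
#'
#' @param config a \linkS4class{ProtocolConfig}.
#' @return Frequency in Hz.
#' @examples
#' entrainmentFrequency(protocolConfig())          # 0.0625
#' entrainmentFrequency(protocolConfig(9, 11))     # 0.05
#' @export
setGeneric("entrainmentFrequency",
           function(config) standardGeneric("entrainmentFrequency"))

#' @rdname entrainmentFrequency
#' @export
setMethod("entrainmentFrequency", "ProtocolConfig", function(config) {
  if (config@trainDuration <= 0 || config@interTrainInterval <= 0)
    stop("entrainmentFrequency: durations must be positive")
  1 / (config@trainDuration + config@interTrainInterval)
})

#' Build the block schedule for one session
#'
#' Lays out pre-rest blocks, one protocol rest block at 0 %MSO, the active
#' intensity ramp, and post-rest blocks on an abutting half-open time axis.
#' The final active intensity is \code{round(finalIntensityFactor * rmt)}
#' (nearest integer, ties up) and the ramp starts \code{rampSpan} %MSO below
#' it, giving \code{rampSpan/intensityStep + 1} active blocks. With the
#' default configuration and rMT = 40 %MSO the ramp runs 20, 22, ..., 48
#' %MSO (15 trains, 120 \%MT final) and the session has 26 blocks of 16 s.
#'
#' @param config a \linkS4class{ProtocolConfig}.
#' @param rmt resting motor threshold, %MSO; the capped final intensity
#'   \code{finalIntensityFactor * rmt} must not exceed 100 %MSO.
#' @return A \linkS4class{ProtocolSchedule}.
#' @examples
#' sch <- buildSchedule(protocolConfig(), rmt = 40)
#' subset(scheduleBlocks(sch), phase == "active")$intensity_pct_mso
#' @export
buildSchedule <- function(config, rmt) {
  stopifnot(is(config, "ProtocolConfig"))
  validObject(config)
  if (rmt <= 0) stop("buildSchedule: rmt must be positive")
  finalI <- roundHalfUp(config@finalIntensityFactor * rmt)
  if (finalI > 100)
    stop("buildSchedule: final intensity ", finalI,
         " %MSO exceeds stimulator maximum (100 %MSO)")
  nActive <- as.integer(round(config@rampSpan / config@intensityStep)) + 1L
  firstI <- finalI - config@rampSpan
  if (firstI < 0)
    stop("buildSchedule: first active intensity would be negative; rmt too low")
  nProtRest <- config@nProtocolBlocks - nActive
  if (nProtRest != 1L)
    stop("buildSchedule: protocol block count must equal active blocks + 1 rest block (",
         nActive, " + 1 != ", config@nProtocolBlocks, ")")
  phases <- c(rep("pre_rest", config@nPreRestBlocks),
              "protocol_rest",
              rep("active", nActive),
              rep("post_rest", config@nPostRestBlocks))
  intensity <- c(rep(0, config@nPreRestBlocks), 0,
                 seq(firstI, finalI, by = config@intensityStep),
                 rep(0, config@nPostRestBlocks))
  dur <- config@trainDuration + config@interTrainInterval
  n <- length(phases)
  blocks <- data.frame(
    index = seq_len(n),
    onset_s = (seq_len(n) - 1) * dur,
    duration_s = rep(dur, n),
    phase = phases,
    intensity_pct_mso = as.integer(round(intensity)),
    stringsAsFactors = FALSE)
  new("ProtocolSchedule", blocks = blocks, rmt = as.numeric(rmt))
}

# round-half-up (R's round() is round-half-even)
roundHalfUp <- function(x) floor(x + 0.5)

#' Intensity labels in \%MT
#'
#' Converts the stored %MSO intensities to \%MT relative to the session rMT
#' (nearest integer, ties up). The default ramp ends exactly at 120 \%MT.
#'
#' @param schedule a \linkS4class{ProtocolSchedule}.
#' @return Integer vector, one \%MT value per block (0 for rest blocks).
#' @export
intensityPctMt <- function(schedule) {
  stopifnot(is(schedule, "ProtocolSchedule"))
  as.integer(roundHalfUp(100 * schedule@blocks$intensity_pct_mso / schedule@rmt))
}

#' Write / read a schedule as a CSV event table
#'
#' Columns: \code{index}, \code{onset_s}, \code{duration_s}, \code{phase},
#' \code{intensity_pct_mso}; rMT is kept in a header comment line so the
#' round trip is lossless.
#'
#' @param schedule a \linkS4class{ProtocolSchedule}.
#' @param path file path.
#' @return \code{readSchedule} returns a \linkS4class{ProtocolSchedule};
#'   \code{writeSchedule} returns \code{path} invisibly.
#' @export
writeSchedule <- function(schedule, path) {
  stopifnot(is(schedule, "ProtocolSchedule"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rmt_pct_mso=%.10g", schedule@rmt), con)
  utils::write.csv(schedule@blocks, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSchedule
#' @export
readSchedule <- function(path) {
  first <- readLines(path, n = 1L)
  rmt <- as.numeric(sub("^# rmt_pct_mso=", "", first))
  blocks <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  blocks$intensity_pct_mso <- as.integer(blocks$intensity_pct_mso)
  blocks$onset_s <- as.numeric(blocks$onset_s)
  blocks$duration_s <- as.numeric(blocks$duration_s)
  blocks$index <- as.integer(blocks$index)
  new("ProtocolSchedule", blocks = blocks, rmt = rmt)
}
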