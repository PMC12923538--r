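#' @import methods
#' @importFrom stats approx spline median quantile rnorm runif rbinom sd
#'   coef vcov predict AIC logLik pf qf qnorm pnorm qt pt p.adjust
#'   model.matrix as.formula setNames aggregate complete.cases cor
NULL

BLOCK_PHASES <- c("pre_rest", "protocol_rest", "active", "post_rest")

#' Stimulation protocol configuration
#'
#' Timing and intensity-ramp rules of an entrainment rTMS protocol: each
#' block holds one TMS train followed by an inter-train interval, and active
#' intensities ramp up in fixed steps to a final intensity expressed as a
#' multiple of the resting motor threshold (rMT). The defaults encode the
#' NCG-TMS 2.0 protocol: 5 s trains at 10 Hz, 11 s inter-train interval
#' (16 s cycle, 0.0625 Hz entrainment), 2 %MSO steps over a 28 %MSO span
#' ending at 120% rMT, and a 8 / 16 / 2 pre-rest / protocol / post-rest
#' block layout (the 16 protocol blocks are 1 rest block at 0 %MSO plus 15
#' active trains).
#'
#' @slot trainDuration TMS train duration in seconds.
#' @slot interTrainInterval rest interval after each train, seconds.
#' @slot pulseRate within-train pulse rate, Hz.
#' @slot intensityStep intensity increment between active blocks, %MSO.
#' @slot rampSpan total ramp span below the final intensity, %MSO; must be
#'   an integer multiple of \code{intensityStep}.
#' @slot finalIntensityFactor final intensity as a multiple of rMT
#'   (1.2 = 120 \%MT).
#' @slot nPreRestBlocks,nProtocolBlocks,nPostRestBlocks block counts for the
#'   pre-stimulation rest, protocol (rest + active), and post-stimulation
#'   rest phases.
#' @exportClass ProtocolConfig
setClass("ProtocolConfig",
  representation(
    trainDuration = "numeric",
    interTrainInterval = "numeric",
    pulseRate = "numeric",
    intensityStep = "numeric",
    rampSpan = "numeric",
    finalIntensityFactor = "numeric",
    nPreRestBlocks = "integer",
    nProtocolBlocks = "integer",
    nPostRestBlocks = "integer"
  )
)

setValidity("ProtocolConfig", function(object) {
  msg <- character()
  if (object@trainDuration + object@interTrainInterval <= 0)
    msg <- c(msg, "train duration + inter-train interval must be positive")
  if (object@trainDuration < 0 || object@interTrainInterval < 0)
    msg <- c(msg, "durations must be non-negative")
  cnt <- c(object@nPreRestBlocks, object@nProtocolBlocks, object@nPostRestBlocks)
  if (any(cnt < 0L)) msg <- c(msg, "block counts must be >= 0")
  if (object@intensityStep <= 0) msg <- c(msg, "intensityStep must be positive")
  if (object@rampSpan < 0) msg <- c(msg, "rampSpan must be >= 0")
  ratio <- object@rampSpan / object@intensityStep
  if (abs(ratio - round(ratio)) > 1e-9)
    msg <- c(msg, "rampSpan must be an integer multiple of intensityStep")
  if (object@finalIntensityFactor <= 0)
    msg <- c(msg, "finalIntensityFactor must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a protocol configuration
#'
#' @param trainDuration,interTrainInterval block timing in seconds.
#' @param pulseRate pulse rate within trains, Hz.
#' @param intensityStep,rampSpan intensity ramp geometry, %MSO.
#' @param finalIntensityFactor final intensity as multiple of rMT.
#' @param nPreRestBlocks,nProtocolBlocks,nPostRestBlocks phase block counts.
#' @return A \linkS4class{ProtocolConfig}.
#' @examples
#' cfg <- protocolConfig()
#' entrainmentFrequency(cfg)  # 0.0625 Hz
#' @export
protocolConfig <- function(trainDuration = 5, interTrainInterval = 11,
                           pulseRate = 10, intensityStep = 2, rampSpan = 28,
                           finalIntensityFactor = 1.2, nPreRestBlocks = 8L,
                           nProtocolBlocks = 16L, nPostRestBlocks = 2L) {
  new("ProtocolConfig",
      trainDuration = as.numeric(trainDuration),
      interTrainInterval = as.numeric(interTrainInterval),
      pulseRate = as.numeric(pulseRate),
      intensityStep = as.numeric(intensityStep),
      rampSpan = as.numeric(rampSpan),
      finalIntensityFactor = as.numeric(finalIntensityFactor),
      nPreRestBlocks = as.integer(nPreRestBlocks),
      nProtocolBlocks = as.integer(nProtocolBlocks),
      nPostRestBlocks = as.integer(nPostRestBlocks))
}

#' Block schedule of one stimulation session
#'
#' Ordered, abutting blocks on a half-open time axis \code{[onset,
#' onset + duration)} measured in seconds from recording start. Every block
#' carries a phase label (\code{pre_rest}, \code{protocol_rest},
#' \code{active}, \code{post_rest}) and an intensity in %MSO; intensities are
#' stored as the physical %MSO quantity, with \%MT derived on demand from the
#' session rMT.
#'
#' @slot blocks a data.frame with columns \code{index}, \code{onset_s},
#'   \code{duration_s}, \code{phase}, \code{intensity_pct_mso}.
#' @slot rmt resting motor threshold of the session, %MSO.
#' @exportClass ProtocolSchedule
setClass("ProtocolSchedule",
  representation(blocks = "data.frame", rmt = "numeric"))

setValidity("ProtocolSchedule", function(object) {
  b <- object@blocks
  need <- c("index", "onset_s", "duration_s", "phase", "intensity_pct_mso")
  if (!all(need %in% names(b)))
    return(paste("blocks must have columns:", paste(need, collapse = ", ")))
  msg <- character()
  if (nrow(b) == 0L) return("schedule has no blocks")
  if (any(diff(b$onset_s) <= 0)) msg <- c(msg, "onsets must be strictly increasing")
  if (any(abs(b$onset_s[-1L] - (b$onset_s[-nrow(b)] + b$duration_s[-nrow(b)])) > 1e-9))
    msg <- c(msg, "consecutive blocks must abut")
  if (!all(b$phase %in% BLOCK_PHASES))
    msg <- c(msg, paste("phase must be one of:", paste(BLOCK_PHASES, collapse = ", ")))
  pr <- which(b$phase == "protocol_rest")
  if (length(pr) != 1L) {
    msg <- c(msg, "exactly one protocol_rest block required")
  } else {
    if (b$intensity_pct_mso[pr] != 0)
      msg <- c(msg, "protocol_rest block must be at 0 %MSO")
    act <- which(b$phase == "active")
    if (length(act) && (act[1L] != pr + 1L))
      msg <- c(msg, "protocol_rest must immediately precede the active blocks")
    if (length(act) > 1L) {
      st <- diff(b$intensity_pct_mso[act])
      if (any(st <= 0) || any(abs(st - st[1L]) > 1e-9))
        msg <- c(msg, "active intensities must be a strictly increasing arithmetic sequence")
    }
  }
  if (length(msg)) msg else TRUE
})

#' R-peak (beat) time series
#'
#' Strictly increasing beat times in seconds; successive differences are the
#' RR intervals. Physiological RR intervals lie in (0.25, 3.0) s; values
#' outside are permitted only on objects flagged as containing artifacts.
#'
#' @slot beatTimes strictly increasing beat times, seconds.
#' @slot artifact logical; TRUE suspends the physiological RR range check.
#' @exportClass BeatSeries
setClass("BeatSeries",
  representation(beatTimes = "numeric", artifact = "logical"),
  prototype(artifact = FALSE))

setValidity("BeatSeries", function(object) {
  bt <- object@beatTimes
  if (anyNA(bt)) return("beat times must be finite")
  if (length(bt) > 1L) {
    rr <- diff(bt)
    if (any(rr <= 0)) return("beat times must be strictly increasing")
    if (!isTRUE(object@artifact) && (any(rr <= 0.25) || any(rr >= 3.0)))
      return("RR intervals outside (0.25, 3.0) s; construct with artifact = TRUE to allow")
  }
  TRUE
})

#' Construct a BeatSeries
#' @param beatTimes strictly increasing beat times in seconds.
#' @param artifact set TRUE to allow non-physiological RR intervals.
#' @return A \linkS4class{BeatSeries}.
#' @export
beatSeries <- function(beatTimes, artifact = FALSE) {
  new("BeatSeries", beatTimes = as.numeric(beatTimes), artifact = artifact)
}

#' Evenly sampled instantaneous heart-rate signal
#'
#' @slot time uniform time grid, seconds.
#' @slot hr instantaneous heart rate, bpm.
#' @slot fsOut sampling rate of the grid, Hz.
#' @exportClass HrSignal
setClass("HrSignal",
  representation(time = "numeric", hr = "numeric", fsOut = "numeric"))

setValidity("HrSignal", function(object) {
  if (length(object@time) != length(object@hr))
    return("time and hr must have equal length")
  if (length(object@time) > 1L) {
    dt <- diff(object@time)
    if (any(abs(dt - 1 / object@fsOut) > 1e-6))
      return("time grid must be uniform with spacing 1/fsOut")
  }
  TRUE
})

#' Construct an HrSignal
#' @param time uniform time grid, seconds.
#' @param hr heart rate samples, bpm.
#' @param fsOut grid sampling rate, Hz.
#' @return An \linkS4class{HrSignal}.
#' @export
hrSignal <- function(time, hr, fsOut) {
  new("HrSignal", time = as.numeric(time), hr = as.numeric(hr),
      fsOut = as.numeric(fsOut))
}

#' ECG recording
#'
#' @slot fs sampling rate, Hz (>= 100).
#' @slot samples amplitude samples, mV.
#' @slot startTime time of the first sample, seconds.
#' @exportClass EcgRecording
setClass("EcgRecording",
  representation(fs = "numeric", samples = "numeric", startTime = "numeric"),
  prototype(startTime = 0))

setValidity("EcgRecording", function(object) {
  if (object@fs < 100) return("fs must be >= 100 Hz")
  if (anyNA(object@samples) || any(!is.finite(object@samples)))
    return("samples must be finite")
  TRUE
})

#' Construct an EcgRecording
#' @param samples amplitude samples, mV.
#' @param fs sampling rate, Hz.
#' @param startTime time of the first sample, seconds.
#' @return An \linkS4class{EcgRecording}.
#' @export
ecgRecording <- function(samples, fs, startTime = 0) {
  new("EcgRecording", fs = as.numeric(fs), samples = as.numeric(samples),
      startTime = as.numeric(startTime))
}

# ---- generics & accessors ---------------------------------------------------

#' Beat times of a BeatSeries
#' @param object a \linkS4class{BeatSeries}.
#' @return numeric vector of beat times, seconds.
#' @export
setGeneric("beatTimes", function(object) standardGeneric("beatTimes"))

#' @rdname beatTimes
#' @export
setMethod("beatTimes", "BeatSeries", function(object) object@beatTimes)

#' RR intervals of a BeatSeries
#' @param object a \linkS4class{BeatSeries}.
#' @return numeric vector of RR intervals, seconds (length = beats - 1).
#' @export
setGeneric("rrIntervals", function(object) standardGeneric("rrIntervals"))

#' @rdname rrIntervals
#' @export
setMethod("rrIntervals", "BeatSeries", function(object) diff(object@beatTimes))

#' Number of beats
#' @param object a \linkS4class{BeatSeries}.
#' @return integer beat count.
#' @export
setGeneric("nBeats", function(object) standardGeneric("nBeats"))

#' @rdname nBeats
#' @export
setMethod("nBeats", "BeatSeries", function(object) length(object@beatTimes))

#' Block table of a schedule
#' @param object a \linkS4class{ProtocolSchedule}.
#' @return data.frame of blocks (index, onset_s, duration_s, phase,
#'   intensity_pct_mso).
#' @export
setGeneric("scheduleBlocks", function(object) standardGeneric("scheduleBlocks"))

#' @rdname scheduleBlocks
#' @export
setMethod("scheduleBlocks", "ProtocolSchedule", function(object) object@blocks)

#' Time grid / heart rate of an HrSignal
#' @param object an \linkS4class{HrSignal}.
#' @return numeric vector.
#' @export
setGeneric("hrTime", function(object) standardGeneric("hrTime"))

#' @rdname hrTime
#' @export
setMethod("hrTime", "HrSignal", function(object) object@time)

#' @rdname hrTime
#' @export
setGeneric("hrBpm", function(object) standardGeneric("hrBpm"))

#' @rdname hrTime
#' @export
setMethod("hrBpm", "HrSignal", function(object) object@hr)

setMethod("show", "ProtocolConfig", function(object) {
  cycle <- object@trainDuration + object@interTrainInterval
  cat("ProtocolConfig:", object@trainDuration, "s train +",
      object@interTrainInterval, "s rest (", 1 / cycle, "Hz entrainment ),",
      object@pulseRate, "Hz pulses\n")
  cat("  ramp:", object@intensityStep, "%MSO steps over", object@rampSpan,
      "%MSO, final", object@finalIntensityFactor, "x rMT\n")
  cat("  blocks:", object@nPreRestBlocks, "pre-rest /", object@nProtocolBlocks,
      "protocol /", object@nPostRestBlocks, "post-rest\n")
})

setMethod("show", "ProtocolSchedule", function(object) {
  b <- object@blocks
  cat("ProtocolSchedule:", nrow(b), "blocks,",
      sum(b$phase == "active"), "active, rMT", object@rmt, "%MSO\n")
  cat("  span: [", min(b$onset_s), ",", max(b$onset_s + b$duration_s), ") s\n")
})

setMethod("show", "BeatSeries", function(object) {
  n <- length(object@beatTimes)
  cat("BeatSeries:", n, "beats")
  if (n > 1L) {
    rr <- diff(object@beatTimes)
    cat(" over", round(diff(range(object@beatTimes)), 2), "s, mean RR",
        round(mean(rr), 3), "s")
  }
  cat("\n")
})

setMethod("show", "HrSignal", function(object) {
  cat("HrSignal:", length(object@hr), "samples at", object@fsOut,
      "Hz, HR range [", round(min(object@hr), 1), ",",
      round(max(object@hr), 1), "] bpm\n")
})

setMethod("show", "EcgRecording", function(object) {
  cat("EcgRecording:", length(object@samples), "samples at", object@fs,
      "Hz (", round(length(object@samples) / object@fs, 1), "s )\n")
})
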