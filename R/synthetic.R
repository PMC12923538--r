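#' Parameters of the synthetic cardiac-entrainment generator
#'
#' Encodes the effect structure the analysis assumes: a per-participant
#' baseline heart rate with low- and high-frequency HRV, a train-locked HR
#' modulation at the protocol entrainment frequency whose depth follows a
#' logistic dose-response in stimulation intensity (\%MT) and scales with a
#' per-target gain (sham gain is exactly 0), a tonic pain confound, and
#' participant / session-slope / block random effects.
#'
#' Default values describe a healthy-adult cohort: 70 bpm baseline, a
#' maximum modulation depth of 3 bpm reached only at suprathreshold
#' intensities (logistic midpoint 90 \%MT, slope 0.15 per \%MT), HR
#' deceleration during trains (\code{hrDirection = -1}), LF/HF HRV sinusoids
#' at 0.1 / 0.25 Hz, and 19 participants by 3 sessions as in a three-visit
#' repeatability design.
#'
#' @param baselineHr baseline heart rate, bpm (30-200).
#' @param targetGain named numeric vector mapping target label to a
#'   dimensionless modulation gain; must contain \code{sham = 0}.
#' @param depthMax maximum modulation depth at full gain, bpm.
#' @param doseMidpoint logistic dose-response midpoint, \%MT.
#' @param doseSlope logistic slope, per \%MT.
#' @param hrDirection -1 for deceleration during trains, +1 for acceleration.
#' @param hrvAmpLf,hrvAmpHf HRV sinusoid amplitudes, bpm.
#' @param hrvFreqLf,hrvFreqHf HRV sinusoid frequencies, Hz.
#' @param painCoef tonic HR shift per pain point, bpm.
#' @param hrNoiseSd white sample-level HR noise SD, bpm.
#' @param sdParticipant,sdSessionSlope,sdBlock additive random-effect SDs
#'   on the heart-rate level, bpm.
#' @param sdLogAmpParticipant,sdLogAmpSessionSlope SDs of the
#'   per-participant (and per-participant session-slope) log-amplitude
#'   random effects that multiplicatively scale each recording's
#'   entrainment modulation depth; they give participants and sessions
#'   stable multiplicative signatures in the block-level spectral power of
#'   modulated (non-sham) targets — the variance the mixed model's
#'   \code{(1 + session | participant)} structure describes — while sham
#'   recordings retain no stable subject signal.
#' @param nParticipants,nSessions design size.
#' @param seed integer RNG seed for the whole study.
#' @return An object of class \code{SimulationParams} (a validated list).
#' @export
simulationParams <- function(baselineHr = 70,
                             targetGain = c(sham = 0, cm5 = 0.15, F3 = 0.35,
                                            F3_medial = 0.3, F3_anterior = 0.55,
                                            F3_posterior = 0.8, F3_lateral = 1.0),
                             depthMax = 3, doseMidpoint = 90, doseSlope = 0.15,
                             hrDirection = -1,
                             hrvAmpLf = 1.5, hrvAmpHf = 1.0,
                             hrvFreqLf = 0.1, hrvFreqHf = 0.25,
                             painCoef = 0.3, hrNoiseSd = 0.3,
                             sdParticipant = 3, sdSessionSlope = 0.5,
                             sdBlock = 0.5,
                             sdLogAmpParticipant = 0.3,
                             sdLogAmpSessionSlope = 0.15,
                             nParticipants = 19L, nSessions = 3L,
                             seed = 1L) {
  p <- list(baselineHr = baselineHr, targetGain = targetGain,
            depthMax = depthMax, doseMidpoint = doseMidpoint,
            doseSlope = doseSlope, hrDirection = hrDirection,
            hrvAmpLf = hrvAmpLf, hrvAmpHf = hrvAmpHf,
            hrvFreqLf = hrvFreqLf, hrvFreqHf = hrvFreqHf,
            painCoef = painCoef, hrNoiseSd = hrNoiseSd,
            sdParticipant = sdParticipant, sdSessionSlope = sdSessionSlope,
            sdBlock = sdBlock,
            sdLogAmpParticipant = sdLogAmpParticipant,
            sdLogAmpSessionSlope = sdLogAmpSessionSlope,
            nParticipants = as.integer(nParticipants),
            nSessions = as.integer(nSessions), seed = as.integer(seed))
  if (p$depthMax < 0) stop("depthMax must be >= 0")
  if (p$doseMidpoint <= 0) stop("doseMidpoint must be positive")
  if (p$baselineHr < 30 || p$baselineHr > 200)
    stop("baselineHr must lie in [30, 200] bpm")
  if (!("sham" %in% names(p$targetGain)))
    stop("targetGain must contain a 'sham' entry")
  if (p$targetGain[["sham"]] != 0) stop("sham gain must be exactly 0")
  class(p) <- "SimulationParams"
  p
}

# logistic dose-response of modulation depth on intensity (%MT)
doseDepth <- function(params, intensityMt) {
  params$depthMax / (1 + exp(-params$doseSlope * (intensityMt - params$doseMidpoint)))
}

#' Simulate the instantaneous heart-rate profile of one recording
#'
#' rate(t) = baseline + HRV sinusoids + random-effect offsets +
#' hrDirection * gain(target) * depth(intensity) * shape(t), where depth
#' follows the logistic dose-response and shape(t) is a boxcar over each
#' active train with exponential recovery (time constant \code{tauRecovery})
#' during the following rest interval. Rest-phase blocks carry no
#' modulation. The rate is floored at 25 bpm.
#'
#' @param params \code{SimulationParams}.
#' @param schedule a \linkS4class{ProtocolSchedule}.
#' @param target target label; must be a name of \code{params$targetGain}.
#' @param trainDuration train duration within each active block, seconds.
#' @param fsGrid sampling rate of the time grid, Hz.
#' @param pain pain score (0-10) entering as a tonic shift
#'   \code{painCoef * pain}.
#' @param interceptOffset participant/session tonic offset, bpm.
#' @param blockOffsets per-block tonic offsets, bpm (recycled to the number
#'   of blocks).
#' @param phaseLf,phaseHf HRV sinusoid phases, radians.
#' @param noise white noise samples to add (length of the grid) or NULL.
#' @param tauRecovery recovery time constant after each train, seconds.
#' @return An \linkS4class{HrSignal}.
#' @export
simulateHrProfile <- function(params, schedule, target, trainDuration = 5,
                              fsGrid = 4, pain = 0, interceptOffset = 0,
                              blockOffsets = 0, phaseLf = 0, phaseHf = 0,
                              noise = NULL, tauRecovery = 3) {
  stopifnot(inherits(params, "SimulationParams"), is(schedule, "ProtocolSchedule"))
  if (!(target %in% names(params$targetGain)))
    stop("simulateHrProfile: unknown target label '", target, "'")
  b <- scheduleBlocks(schedule)
  tEnd <- max(b$onset_s + b$duration_s)
  t <- seq(0, tEnd, by = 1 / fsGrid)
  rate <- rep(params$baselineHr + interceptOffset + params$painCoef * pain,
              length(t))
  rate <- rate +
    params$hrvAmpLf * sin(2 * pi * params$hrvFreqLf * t + phaseLf) +
    params$hrvAmpHf * sin(2 * pi * params$hrvFreqHf * t + phaseHf)

  blockOffsets <- rep_len(blockOffsets, nrow(b))
  gain <- params$targetGain[[target]]
  mtLabels <- 100 * b$intensity_pct_mso / schedule@rmt
  for (i in seq_len(nrow(b))) {
    inBlock <- t >= b$onset_s[i] & t < b$onset_s[i] + b$duration_s[i]
    rate[inBlock] <- rate[inBlock] + blockOffsets[i]
    if (b$phase[i] != "active") next
    depth <- params$hrDirection * gain * doseDepth(params, mtLabels[i])
    trainEnd <- b$onset_s[i] + trainDuration
    tb <- t[inBlock]
    shape <- ifelse(tb < trainEnd, 1, exp(-(tb - trainEnd) / tauRecovery))
    rate[inBlock] <- rate[inBlock] + depth * shape
  }
  if (!is.null(noise)) rate <- rate + rep_len(noise, length(t))
  rate <- pmax(rate, 25)
  hrSignal(t, rate, fsGrid)
}

#' IPFM beat generation from a sampled rate profile
#'
#' Integral pulse frequency modulation: a beat is emitted each time the
#' running integral of rate/60 crosses an integer. Integration is
#' trapezoidal on the sample grid with linear refinement of each crossing
#' time, so total beat count equals the integral of the rate to within one
#' beat.
#'
#' @param rate an \linkS4class{HrSignal}, or a numeric rate vector (bpm)
#'   with \code{time} supplied.
#' @param time time grid in seconds (ignored when \code{rate} is an
#'   HrSignal).
#' @return A \linkS4class{BeatSeries}.
#' @examples
#' hr <- hrSignal(seq(0, 60, by = 0.25), rep(60, 241), 4)
#' nBeats(ipfmBeats(hr))  # 60 beats, RR exactly 1 s
#' @export
ipfmBeats <- function(rate, time = NULL) {
  if (is(rate, "HrSignal")) {
    time <- hrTime(rate)
    rate <- hrBpm(rate)
  }
  if (is.null(time) || length(time) != length(rate))
    stop("ipfmBeats: time grid must match the rate vector")
  if (any(diff(time) <= 0)) stop("ipfmBeats: time grid must be increasing")
  if (any(rate < 25)) stop("ipfmBeats: rate must be >= 25 bpm everywhere")
  dt <- diff(time)
  # trapezoid cumulative integral of rate/60 (beats elapsed)
  cum <- c(0, cumsum((rate[-length(rate)] + rate[-1L]) / 2 / 60 * dt))
  k <- seq_len(floor(cum[length(cum)]))
  if (!length(k)) return(beatSeries(numeric(0)))
  # cum is strictly increasing (rate > 0): invert by linear interpolation
  bt <- approx(cum, time, xout = k, ties = "ordered")$y
  beatSeries(bt)
}

#' Synthesize an ECG-like waveform from beat times
#'
#' Sums narrow Gaussian QRS templates centered on the beat times, plus
#' optional sinusoidal baseline wander and white noise. Used as a
#' ground-truth harness for the R-peak detector: with wander amplitude
#' below ~0.3 of the QRS amplitude the waveform argmax stays within 10 ms
#' of each true beat.
#'
#' @param beats a \linkS4class{BeatSeries}.
#' @param fs sampling rate, Hz (>= 100).
#' @param qrsWidth QRS template width parameter (Gaussian SD), seconds.
#' @param qrsAmp QRS amplitude, mV.
#' @param wanderAmp,wanderFreq baseline wander amplitude (mV) and
#'   frequency (Hz).
#' @param noiseSd white noise SD, mV (drawn from the current RNG stream).
#' @param pad flat margin appended before the first / after the last
#'   beat, seconds.
#' @return An \linkS4class{EcgRecording} starting at time 0.
#' @export
synthesizeEcg <- function(beats, fs = 250, qrsWidth = 0.01, qrsAmp = 1,
                          wanderAmp = 0, wanderFreq = 0.3, noiseSd = 0,
                          pad = 0.5) {
  stopifnot(is(beats, "BeatSeries"))
  bt <- beatTimes(beats)
  if (!length(bt)) stop("synthesizeEcg: empty BeatSeries")
  if (fs < 100) stop("synthesizeEcg: fs must be >= 100 Hz")
  tEnd <- max(bt) + pad
  n <- floor(tEnd * fs) + 1L
  t <- (seq_len(n) - 1L) / fs
  x <- numeric(n)
  halfSupport <- 6 * qrsWidth
  for (b in bt) {
    i0 <- max(1L, floor((b - halfSupport) * fs) + 1L)
    i1 <- min(n, ceiling((b + halfSupport) * fs) + 1L)
    idx <- i0:i1
    x[idx] <- x[idx] + qrsAmp * exp(-((t[idx] - b)^2) / (2 * qrsWidth^2))
  }
  if (wanderAmp != 0) x <- x + wanderAmp * sin(2 * pi * wanderFreq * t)
  if (noiseSd > 0) x <- x + rnorm(n, sd = noiseSd)
  ecgRecording(x, fs)
}

# deterministic per-recording sub-seed below 2^31
recordingSeed <- function(seed, p, s, t) {
  as.integer((as.double(seed) * 2654435761 + p * 40503 + s * 9973 + t * 733)
             %% 2147483647)
}

#' Simulate a full multi-participant entrainment study
#'
#' Generates one IPFM beat series per participant x session x target cell
#' under the design encoded in \code{params} (random intercepts and session
#' slopes by participant, block-level offsets, HRV with per-recording random
#' phases, white HR noise), together with a metadata table carrying rMT,
#' pain scores (0-10, truncated, increasing with the participant's absolute
#' stimulation intensity in %MSO) and side-effect sum scores (20 items,
#' 0-4 each). Fully reproducible from \code{params$seed}; per-recording
#' RNG substreams are derived deterministically so cells are independent of
#' iteration order.
#'
#' @param params \code{SimulationParams}.
#' @param config a \linkS4class{ProtocolConfig}.
#' @param targets character vector of distinct target labels (subset of
#'   \code{names(params$targetGain)}); must include "sham".
#' @param rmtPerParticipant rMT values (%MSO), recycled to
#'   \code{nParticipants}.
#' @param fsGrid rate-grid sampling rate, Hz.
#' @return A list of class \code{StudySimulation}:
#'   \describe{
#'     \item{recordings}{named list (\code{P<p>_S<s>_<target>}) of lists
#'       with elements \code{beats} (\linkS4class{BeatSeries}),
#'       \code{schedule}, and identifiers.}
#'     \item{meta}{data.frame with participant, session, target, rmt, pain,
#'       side_effects_sum, gain, and the injected depth at the top ramp
#'       intensity (\code{depth_final_bpm}).}
#'     \item{params, config}{the generating settings.}
#'   }
#' @export
simulateStudy <- function(params, config = protocolConfig(),
                          targets = names(params$targetGain),
                          rmtPerParticipant = 40, fsGrid = 4) {
  stopifnot(inherits(params, "SimulationParams"))
  if (anyDuplicated(targets)) stop("simulateStudy: duplicate target labels")
  if (sum(targets == "sham") != 1L)
    stop("simulateStudy: exactly one 'sham' target required")
  if (!all(targets %in% names(params$targetGain)))
    stop("simulateStudy: targets missing from targetGain: ",
         paste(setdiff(targets, names(params$targetGain)), collapse = ", "))
  nP <- params$nParticipants
  nS <- params$nSessions
  rmt <- rep_len(rmtPerParticipant, nP)

  set.seed(params$seed)
  uIntercept <- rnorm(nP, 0, params$sdParticipant)
  uSlope <- rnorm(nP, 0, params$sdSessionSlope)
  uLogAmp <- rnorm(nP, 0, params$sdLogAmpParticipant)
  uLogAmpSlope <- rnorm(nP, 0, params$sdLogAmpSessionSlope)

  recordings <- list()
  meta <- list()
  for (p in seq_len(nP)) {
    schedule <- buildSchedule(config, rmt[p])
    nBlocks <- nrow(scheduleBlocks(schedule))
    finalMso <- max(scheduleBlocks(schedule)$intensity_pct_mso)
    for (s in seq_len(nS)) {
      for (ti in seq_along(targets)) {
        tg <- targets[ti]
        set.seed(recordingSeed(params$seed, p, s, ti))
        pain <- min(10, max(0, round(
          2 + 0.05 * (finalMso - 40) + rnorm(1, 0, 1.5))))
        seItems <- rbinom(20L, 4L, stats::plogis(-3 + 0.03 * finalMso))
        blockOff <- rnorm(nBlocks, 0, params$sdBlock)
        nGrid <- length(seq(0, nBlocks * (config@trainDuration +
                                          config@interTrainInterval),
                            by = 1 / fsGrid))
        # multiplicative modulation-depth signature of this recording
        amp <- exp(uLogAmp[p] + uLogAmpSlope[p] * (s - (nS + 1) / 2))
        recParams <- params
        recParams$depthMax <- params$depthMax * amp
        noise <- if (params$hrNoiseSd > 0)
          rnorm(nGrid, 0, params$hrNoiseSd) else NULL
        hr <- simulateHrProfile(
          recParams, schedule, tg,
          trainDuration = config@trainDuration, fsGrid = fsGrid,
          pain = pain,
          interceptOffset = uIntercept[p] + uSlope[p] * (s - 1),
          blockOffsets = blockOff,
          phaseLf = runif(1, 0, 2 * pi), phaseHf = runif(1, 0, 2 * pi),
          noise = noise)
        key <- sprintf("P%02d_S%d_%s", p, s, tg)
        recordings[[key]] <- list(beats = ipfmBeats(hr), schedule = schedule,
                                  participant = p, session = s, target = tg)
        meta[[key]] <- data.frame(
          key = key, participant = sprintf("P%02d", p), session = s,
          target = tg, rmt = rmt[p], pain = pain,
          side_effects_sum = sum(seItems),
          gain = params$targetGain[[tg]],
          depth_final_bpm = params$targetGain[[tg]] *
            doseDepth(params, 100 * finalMso / rmt[p]),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- list(recordings = recordings,
              meta = do.call(rbind, c(meta, list(make.row.names = FALSE))),
              params = params, config = config)
  class(out) <- "StudySimulation"
  out
}

#' @method print StudySimulation
#' @export
print.StudySimulation <- function(x, ...) {
  cat("StudySimulation:", length(x$recordings), "recordings (",
      x$params$nParticipants, "participants x", x$params$nSessions,
      "sessions x", length(unique(x$meta$target)), "targets ), seed",
      x$params$seed, "\n")
  invisible(x)
}

#' Write a beat series as a single-column CSV of seconds
#' @param beats a \linkS4class{BeatSeries}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
writeBeats <- function(beats, path) {
  utils::write.csv(data.frame(beat_time_s = beatTimes(beats)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeBeats
#' @param artifact passed to \code{\link{beatSeries}}.
#' @export
readBeats <- function(path, artifact = FALSE) {
  beatSeries(utils::read.csv(path)[[1L]], artifact = artifact)
}
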