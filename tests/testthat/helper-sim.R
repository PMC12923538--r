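# Simulation settings used across tests.

# Deterministic generator: no HRV, no noise, no random effects, no pain
# effect; modulation only if depthMax > 0.
quietParams <- function(depthMax = 0, ...) {
  simulationParams(depthMax = depthMax,
                   hrvAmpLf = 0, hrvAmpHf = 0, hrNoiseSd = 0,
                   painCoef = 0, sdParticipant = 0, sdSessionSlope = 0,
                   sdBlock = 0, sdLogAmpParticipant = 0,
                   sdLogAmpSessionSlope = 0, ...)
}

defaultSchedule <- function(rmt = 40) buildSchedule(protocolConfig(), rmt)

# Synthetic block table drawn straight from a Gamma GLM with known fixed
# effects and no random effects (for oracle-equivalence and calibration
# tests that bypass the signal pipeline).
glmBlockTable <- function(nP = 12, targets = c("sham", "tA", "tB"),
                          beta = list(intercept = 0,
                                      target = c(tA = 0.3, tB = 0.6),
                                      mt = 0.01),
                          shape = 4, nSessions = 3, seed = 1,
                          participantSd = 0, sessionSlopeSd = 0,
                          blockSd = 0) {
  set.seed(seed)
  mtVals <- c(0, seq(70, 120, length.out = 15))
  g <- expand.grid(participant = sprintf("P%02d", seq_len(nP)),
                   session = seq_len(nSessions), target = targets,
                   block_index = 9:24, stringsAsFactors = FALSE)
  g$intensity_pct_mt <- mtVals[g$block_index - 8L]
  g$phase <- ifelse(g$block_index == 9L, "protocol_rest", "active")
  g$pain <- round(runif(nrow(g), 0, 6))
  g$side_effects_sum <- rbinom(nrow(g), 20, 0.2)
  g$retained <- TRUE
  g$valid <- TRUE
  eta <- beta$intercept +
    ifelse(g$target == "sham", 0, beta$target[g$target]) +
    beta$mt * (g$intensity_pct_mt - mean(g$intensity_pct_mt))
  if (participantSd > 0) {
    u <- rnorm(nP, 0, participantSd)
    eta <- eta + u[as.integer(factor(g$participant))]
  }
  if (sessionSlopeSd > 0) {
    v <- rnorm(nP, 0, sessionSlopeSd)
    eta <- eta + v[as.integer(factor(g$participant))] *
      (g$session - mean(g$session))
  }
  if (blockSd > 0) {
    w <- rnorm(16, 0, blockSd)
    eta <- eta + w[g$block_index - 8L]
  }
  g$hbc_power <- rgamma(nrow(g), shape = shape, rate = shape / exp(eta))
  g
}
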