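test_that("block power returns A^2/2 for pure sinusoids at f0", {
  t <- seq(0, 16 - 0.25, by = 0.25)
  for (A in c(0.5, 1, 2, 3.7)) {
    for (ph in c(0, 1, 2.5)) {
      hr <- hrSignal(t, 70 + A * sin(2 * pi * 0.0625 * t + ph), 4)
      expect_equal(blockPower(hr, c(0, 16)), A^2 / 2, tolerance = 1e-10)
    }
  }
  # constant signal has zero power after mean removal
  expect_equal(blockPower(hrSignal(t, rep(70, length(t)), 4), c(0, 16)), 0)
})

test_that("block power matches a dense zero-padded FFT oracle on mixtures", {
  t <- seq(0, 16 - 0.25, by = 0.25)
  x <- 70 + 1.4 * sin(2 * pi * 0.0625 * t + 0.3) +
    0.8 * sin(2 * pi * 0.25 * t + 1.1)
  hr <- hrSignal(t, x, 4)
  p <- blockPower(hr, c(0, 16))
  pOracle <- fftPowerOracle(x, fs = 4, f0 = 0.0625)
  expect_lt(abs(p - pOracle) / pOracle, 1e-6)
  # and for an off-grid-phase window not starting at t = 0
  t2 <- seq(32, 48 - 0.25, by = 0.25)
  hr2 <- hrSignal(t2, 70 + 2 * sin(2 * pi * 0.0625 * t2 + 0.7) +
                    sin(2 * pi * 0.1875 * t2), 4)
  p2 <- blockPower(hr2, c(32, 48))
  pOracle2 <- fftPowerOracle(hrBpm(hr2), fs = 4, f0 = 0.0625)
  expect_lt(abs(p2 - pOracle2) / pOracle2, 1e-6)
})

test_that("block power input validation", {
  t <- seq(0, 16 - 0.25, by = 0.25)
  hr <- hrSignal(t, 70 + sin(t), 4)
  expect_error(blockPower(hr, c(0, 0.1)), "shorter")
  expect_error(blockPower(hr, c(0, 1.5)), "fewer than 8")
  hrNa <- hrSignal(t, c(NA, (70 + sin(t))[-1]), 4)
  expect_true(is.na(blockPower(hrNa, c(0, 16))))
})

test_that("session HBC computes 26 rows with 16 retained", {
  sch <- defaultSchedule()
  p <- quietParams(depthMax = 2)
  hr <- simulateHrProfile(p, sch, "F3_lateral")
  tab <- computeSessionHbc(hr, sch)
  expect_equal(nrow(tab), 26)
  expect_equal(sum(tab$retained), 16)
  expect_identical(tab$phase[tab$retained],
                   c("protocol_rest", rep("active", 15)))
  # rest-phase rows are preserved with powers
  expect_true(all(!is.na(tab$hbc_power)))
  # recording/schedule mismatch
  short <- hrSignal(seq(0, 100, 0.25), rep(70, 401), 4)
  expect_error(computeSessionHbc(short, sch), "cover")
})

test_that("a dropout block is invalidated without affecting its neighbors", {
  sch <- defaultSchedule()
  hr <- simulateHrProfile(quietParams(depthMax = 2), sch, "F3_lateral")
  # beats everywhere except block 12 ([176, 192))
  bt <- seq(0.5, 415.5, by = 1)
  bt <- bt[!(bt >= 176 & bt < 192)]
  beats <- beatSeries(bt, artifact = TRUE)
  expect_message(tab <- computeSessionHbc(hr, sch, beats = beats), "invalid")
  expect_false(tab$valid[tab$block_index == 12])
  expect_true(is.na(tab$hbc_power[tab$block_index == 12]))
  expect_true(all(tab$valid[tab$block_index != 12]))
})

test_that("baseline correction subtracts the pre-rest mean", {
  tab <- data.frame(
    participant = "P1", session = 1, target = "F3",
    block_index = 1:6,
    phase = c("pre_rest", "pre_rest", "protocol_rest", "active", "active",
              "post_rest"),
    hbc_power = c(1, 3, 2, 5, 2, 4), valid = TRUE,
    retained = c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE))
  out <- baselineCorrect(tab)
  expect_equal(out$hbc_power_corrected, tab$hbc_power - 2)  # mean(1, 3) = 2
  # rank order within the session is preserved
  expect_identical(order(out$hbc_power_corrected), order(out$hbc_power))
  # no valid pre-rest block -> warning, NA
  tab2 <- tab
  tab2$valid[1:2] <- FALSE
  expect_warning(out2 <- baselineCorrect(tab2), "skipped")
  expect_true(all(is.na(out2$hbc_power_corrected)))
})

test_that("doubling modulation amplitude quadruples block power", {
  pw <- vapply(c(1, 2), function(d) {
    p <- quietParams(depthMax = d, doseMidpoint = 50, doseSlope = 1,
                     nParticipants = 1, nSessions = 1)
    sim <- simulateStudy(p, targets = c("sham", "F3_lateral"))
    tab <- studyHbcTable(sim)
    mean(tab$hbc_power[tab$target == "F3_lateral" &
                       tab$intensity_pct_mt >= 100])
  }, numeric(1))
  expect_equal(pw[2] / pw[1], 4, tolerance = 0.02)
})

test_that("mean retained power orders targets by injected gain", {
  p <- simulationParams(nParticipants = 6, nSessions = 3, seed = 21)
  sim <- simulateStudy(p, targets = c("sham", "F3", "F3_lateral"))
  tab <- studyHbcTable(sim)
  act <- tab[tab$retained & tab$phase == "active", ]
  m <- tapply(act$hbc_power, act$target, mean)
  expect_true(m[["sham"]] < m[["F3"]])
  expect_true(m[["F3"]] < m[["F3_lateral"]])
})

test_that("block table round-trips through CSV", {
  p <- quietParams(depthMax = 2, nParticipants = 1, nSessions = 1)
  sim <- simulateStudy(p, targets = c("sham", "F3"))
  tab <- studyHbcTable(sim)
  f <- withr::local_tempfile(fileext = ".csv")
  writeHbcTable(tab, f)
  back <- readHbcTable(f)
  expect_equal(back$hbc_power, tab$hbc_power, tolerance = 1e-12)
  expect_identical(back$target, tab$target)
  expect_identical(nrow(back), nrow(tab))
})
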