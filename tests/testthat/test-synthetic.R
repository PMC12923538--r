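test_that("hr profile reduces to baseline when all variation is off", {
  sch <- defaultSchedule()
  hr <- simulateHrProfile(quietParams(), sch, "sham")
  expect_true(all(hr@hr == 70))
  # unknown target label
  expect_error(simulateHrProfile(quietParams(), sch, "nope"), "unknown target")
})

test_that("in-train rate approaches baseline - depthMax far above midpoint", {
  p <- quietParams(depthMax = 3, doseMidpoint = 50, doseSlope = 0.5)
  sch <- defaultSchedule()
  hr <- simulateHrProfile(p, sch, "F3_lateral")
  b <- scheduleBlocks(sch)
  top <- b[b$phase == "active", ][15, ]  # 120 %MT >> midpoint
  sel <- hr@time >= top$onset_s & hr@time < top$onset_s + 5
  expect_equal(mean(hr@hr[sel]), 70 - 3, tolerance = 1e-3)
  # rest-phase blocks carry no modulation at all
  pre <- hr@time < b$onset_s[9]
  expect_true(all(hr@hr[pre] == 70))
})

test_that("IPFM emits exact beats for constant rates", {
  t <- seq(0, 60, by = 0.25)
  bs60 <- ipfmBeats(hrSignal(t, rep(60, length(t)), 4))
  expect_equal(nBeats(bs60), 60)
  expect_equal(rrIntervals(bs60), rep(1, 59), tolerance = 1e-12)
  bs120 <- ipfmBeats(hrSignal(t, rep(120, length(t)), 4))
  expect_equal(rrIntervals(bs120), rep(0.5, 119), tolerance = 1e-12)
})

test_that("IPFM beat count matches fine-grid quadrature within one beat", {
  for (seed in 1:20) {
    set.seed(seed)
    a <- runif(1, 55, 90)
    b1 <- runif(1, 0, 8)
    f1 <- runif(1, 0.02, 0.2)
    ph <- runif(1, 0, 2 * pi)
    rateFun <- function(t) a + b1 * sin(2 * pi * f1 * t + ph)
    t <- seq(0, 120, by = 0.25)
    beats <- ipfmBeats(hrSignal(t, rateFun(t), 4))
    expect_lte(abs(nBeats(beats) - beatCountOracle(rateFun, 0, 120)), 1)
  }
})

test_that("synthetic ECG peaks sit on the true beat times", {
  bt <- seq(1, 30, by = 1)
  ecg <- synthesizeEcg(beatSeries(bt), fs = 250)
  x <- ecg@samples
  t <- (seq_along(x) - 1) / 250
  for (b in bt) {
    win <- which(abs(t - b) <= 0.2)
    expect_lt(abs(t[win[which.max(x[win])]] - b), 0.01 + 1 / 250)
  }
  # doubling fs leaves peak times unchanged within one sample
  ecg2 <- synthesizeEcg(beatSeries(bt), fs = 500)
  t2 <- (seq_along(ecg2@samples) - 1) / 500
  for (b in bt[1:5]) {
    w1 <- which(abs(t - b) <= 0.2)
    w2 <- which(abs(t2 - b) <= 0.2)
    p1 <- t[w1[which.max(x[w1])]]
    p2 <- t2[w2[which.max(ecg2@samples[w2])]]
    expect_lt(abs(p1 - p2), 1 / 250)
  }
  expect_error(synthesizeEcg(beatSeries(numeric(0))), "empty")
})

test_that("moderate baseline wander displaces peaks by < 10 ms", {
  bt <- seq(1, 30, by = 0.9)
  ecg <- synthesizeEcg(beatSeries(bt), fs = 250, wanderAmp = 0.25,
                       wanderFreq = 0.3)
  t <- (seq_along(ecg@samples) - 1) / 250
  for (b in bt) {
    win <- which(abs(t - b) <= 0.3)
    expect_lt(abs(t[win[which.max(ecg@samples[win])]] - b), 0.01 + 1 / 250)
  }
})

test_that("study simulation is reproducible and has the full design", {
  p <- simulationParams(nParticipants = 3, nSessions = 2, seed = 11)
  s1 <- simulateStudy(p)
  s2 <- simulateStudy(p)
  expect_identical(lapply(s1$recordings, function(r) beatTimes(r$beats)),
                   lapply(s2$recordings, function(r) beatTimes(r$beats)))
  expect_identical(s1$meta, s2$meta)
  expect_equal(length(s1$recordings), 3 * 2 * 7)
  expect_true(all(s1$meta$pain >= 0 & s1$meta$pain <= 10))
  expect_true(all(s1$meta$side_effects_sum >= 0 &
                  s1$meta$side_effects_sum <= 80))
  # sham carries zero injected depth
  expect_true(all(s1$meta$depth_final_bpm[s1$meta$target == "sham"] == 0))
  expect_error(simulateStudy(p, targets = c("sham", "sham", "F3")),
               "duplicate")
  expect_error(simulateStudy(p, targets = c("F3", "F3_lateral")), "sham")
})

test_that("beat conservation holds across a simulated study", {
  p <- simulationParams(nParticipants = 2, nSessions = 1, seed = 3)
  sim <- simulateStudy(p, targets = c("sham", "F3_lateral"))
  for (rec in sim$recordings) {
    sb <- scheduleBlocks(rec$schedule)
    hr <- instantaneousHR(rec$beats, tStart = 0,
                          tEnd = max(sb$onset_s + sb$duration_s))
    # beats within the covered span approximate the integral of the rate
    span <- range(beatTimes(rec$beats))
    expected <- mean(hrBpm(hr)) / 60 * diff(span)
    expect_lt(abs(nBeats(rec$beats) - expected) / expected, 0.05)
  }
})

test_that("zero modulation with zero noise yields essentially zero power", {
  p <- quietParams(nParticipants = 1, nSessions = 1)
  sim <- simulateStudy(p, targets = c("sham", "F3_lateral"))
  tab <- studyHbcTable(sim)
  expect_true(all(tab$hbc_power < 1e-6))
})

test_that("estimated block power is monotone in injected depth", {
  pw <- vapply(c(0, 1, 2, 4), function(d) {
    p <- quietParams(depthMax = d, nParticipants = 1, nSessions = 1)
    sim <- simulateStudy(p, targets = c("sham", "F3_lateral"))
    tab <- studyHbcTable(sim)
    mean(tab$hbc_power[tab$target == "F3_lateral" & tab$phase == "active" &
                       tab$intensity_pct_mt >= 110])
  }, numeric(1))
  expect_true(all(diff(pw) > 0))
})
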