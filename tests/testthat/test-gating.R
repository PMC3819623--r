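test_that("period estimation reaches sub-half-frame accuracy", {
  sim <- ctrlHeart(nFrames = 120)
  est <- estimatePeriod(sim$video)
  expect_lt(abs(est - 400), (1000 / 30) / 2)
  # faster heart at higher sampling: 300 ms at 60 fps
  fast <- simulateHeartVideo(heartSimParams(periodMs = 300, fps = 60,
                                            nFrames = 180, noiseSigma = 0))
  est60 <- estimatePeriod(fast$video, searchRangeMs = c(150, 800))
  expect_lt(abs(est60 - 300), (1000 / 60) / 2)
})

test_that("a frozen video is rejected as aperiodic", {
  frozen <- array(rep(matrix(runif(96 * 96), 96), 90), c(96, 96, 90))
  v <- VideoSequence(frozen, fps = 30, pixelSizeUm = 2.5)
  expect_error(estimatePeriod(v), "aperiodic")
})

test_that("reference building spans one cycle, anchored at end-diastole", {
  sim <- ctrlHeart(nFrames = 60)
  refs <- buildReference(sim$video, 400, 1, "end-diastole")
  expect_equal(nFrames(refs), 12)  # 400 ms at 30 fps
  expect_equal(refPhases(refs)[1], 0)
  expect_equal(targetPhase(refs), 0)
  # the anchor's true phase is end-diastole within one phase quantum
  anchorIdx <- which(timestampsMs(sim$video) ==
                       timestampsMs(sim$video)[which.max(
                         sim$truth$areaPerFrame[1:12])])[1]
  expect_lte(circAbs(sim$truth$phasePerFrame[anchorIdx], 0),
             2 * pi / nFrames(refs))
  # numeric target phase is stored as given
  r2 <- buildReference(sim$video, 400, 1, pi)
  expect_equal(targetPhase(r2), pi)
})

test_that("end-diastole is unidentifiable on a non-contracting video", {
  sim <- simulateHeartVideo(heartSimParams(nFrames = 40, efTruePct = 0,
                                           noiseSigma = 0))
  expect_error(buildReference(sim$video, 400, 1, "end-diastole"),
               "end-diastole")
})

test_that("phase matching is exact on reference frames and bounded off-grid", {
  sim <- ctrlHeart(nFrames = 90)
  refs <- buildReference(sim$video, 400, 1, "end-diastole")
  pe <- estimatePhase(refs@refFrames[, , 5], refs)
  expect_equal(pe$phase, refPhases(refs)[5], tolerance = 1e-9)
  expect_equal(pe$score, 1, tolerance = 1e-9)
  # every frame of the video recovers its true phase within one quantum
  quantum <- 2 * pi / nFrames(refs)
  anchorPhase <- sim$truth$phasePerFrame[
    which.max(sim$truth$areaPerFrame[1:12])]
  errs <- vapply(20:80, function(i) {
    est <- estimatePhase(frames(sim$video, i), refs)$phase
    circAbs(est, sim$truth$phasePerFrame[i] - anchorPhase)
  }, numeric(1))
  expect_lte(max(errs), quantum)
})

test_that("pure-noise frames score below the trigger confidence floor", {
  sim <- ctrlHeart(nFrames = 40)
  refs <- buildReference(sim$video, 400, 1, "end-diastole")
  set.seed(99)
  confs <- vapply(1:10, function(i)
    estimatePhase(matrix(runif(96 * 96), 96), refs)$confidence, numeric(1))
  expect_lt(max(confs), gateConfig()$confidenceFloor)
})

test_that("phase-rate fitting recovers the angular rate", {
  tt <- seq(0, 700, by = 1000 / 30)
  truePh <- (2 * pi / 400 * tt) %% (2 * pi)
  fit <- unwrapAndFit(truePh, tt)
  expect_equal(fit$slope, 2 * pi / 400, tolerance = 1e-9)
  expect_lt(fit$residual, 1e-9)
  # constant history (pause): slope ~ 0
  fitp <- unwrapAndFit(rep(1.3, 8), tt[1:8])
  expect_equal(fitp$slope, 0, tolerance = 1e-12)
  expect_error(unwrapAndFit(c(0.1, 0.2), c(0, 33)), "insufficient history")
})

test_that("noisy phase fits are unbiased within Monte-Carlo error", {
  tt <- seq(0, 700, by = 1000 / 30)
  trueSlope <- 2 * pi / 400
  set.seed(7)
  slopes <- replicate(120, {
    ph <- (trueSlope * tt + rnorm(length(tt), 0, 0.08)) %% (2 * pi)
    unwrapAndFit(ph, tt)$slope
  })
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lte(abs(mean(slopes) - trueSlope), 3 * se)
})

test_that("trigger prediction solves the phase line exactly", {
  fit <- list(slope = 2 * pi / 400, intercept = 0, residual = 0)
  # at t=0 phase is exactly the target: next crossing one full period on
  ev <- predictTrigger(fit, 0, nowMs = 0, latencyMs = 0)
  expect_equal(ev$fire_time_ms, 400, tolerance = 1e-9)
  expect_equal(ev$predicted_period_ms, 400, tolerance = 1e-12)
  # latency is subtracted exactly, monotonically
  for (lat in c(1, 5, 20)) {
    evl <- predictTrigger(fit, 0, nowMs = 0, latencyMs = lat)
    expect_equal(evl$fire_time_ms, 400 - lat, tolerance = 1e-9)
  }
  # withhold paths
  expect_true(predictTrigger(list(slope = 1e-9, intercept = 0,
                                  residual = 0), 0, 0)$withheld)
  expect_equal(predictTrigger(list(slope = 1e-9, intercept = 0,
                                   residual = 0), 0, 0)$reason,
               "pause/asystole")
  expect_equal(predictTrigger(list(slope = 0.0157, intercept = 0,
                                   residual = 2), 0, 0)$reason, "arrhythmia")
})

test_that("predicted crossings match a 0.01 ms brute-force scan", {
  set.seed(21)
  worst <- 0
  for (r in 1:200) {
    fit <- list(slope = 2 * pi / runif(1, 250, 700),
                intercept = runif(1, -10, 10), residual = 0)
    target <- runif(1, 0, 2 * pi)
    now <- runif(1, 0, 1000)
    ev <- predictTrigger(fit, target, now)
    grid <- seq(now, now + 2 * pi / fit$slope + 1, by = 0.01)
    phase <- (fit$intercept + fit$slope * grid - target) %% (2 * pi)
    hit <- grid[which(diff(phase) < -pi)[1] + 1L]
    worst <- max(worst, abs(ev$fire_time_ms - hit))
  }
  expect_lte(worst, 0.02)
})

test_that("the gating loop fires on true end-diastole crossings", {
  sim <- ctrlHeart(nFrames = 150)
  refs <- buildReference(sim$video, estimatePeriod(sim$video), 1,
                         "end-diastole")
  tr <- gateStream(sim$video, refs, gateConfig(nPulses = 10,
                                               refractoryS = 0.5))
  fired <- tr[!tr$withheld, ]
  expect_gt(nrow(fired), 2)
  cross <- truePhaseCrossings(sim$truth, 0)
  errs <- vapply(fired$fire_time_ms, function(t) min(abs(cross - t)),
                 numeric(1))
  expect_lte(max(errs), 1000 / 30)
  # consecutive fires respect the refractory interval
  expect_true(all(diff(fired$fire_time_ms) >= 500 - 1e-6))
})

test_that("a multi-pulse schedule emits exactly the requested pulses", {
  sim <- ctrlHeart(nFrames = 400)
  refs <- buildReference(sim$video, 400, 1, "end-diastole")
  tr <- gateStream(sim$video, refs, gateConfig(nPulses = 5,
                                               refractoryS = 2))
  fired <- tr[!tr$withheld, ]
  expect_equal(nrow(fired), 5)
  expect_true(all(diff(fired$fire_time_ms) >= 2000 - 1e-6))
})

test_that("no trigger ever falls inside a cardiac pause", {
  for (seed in 1:5) {
    sim <- injuredHeart(noiseSigma = 0.05, seed = seed)
    refs <- buildReference(sim$video, 400, 1, "end-diastole")
    tr <- gateStream(sim$video, refs, gateConfig(nPulses = 50,
                                                 refractoryS = 0.2))
    fired <- tr[!tr$withheld, ]
    tPause <- timestampsMs(sim$video)[90]
    expect_false(any(fired$fire_time_ms > tPause &
                       fired$fire_time_ms < tPause + 2500))
    # the pause is reported as a withheld event
    expect_true(any(tr$withheld & tr$reason == "pause/asystole"))
  }
})

test_that("gating is deterministic for identical inputs", {
  sim <- ctrlHeart(nFrames = 100, noiseSigma = 0.05, seed = 3)
  refs <- buildReference(sim$video, 400, 1, "end-diastole")
  t1 <- gateStream(sim$video, refs, gateConfig(nPulses = 3,
                                               refractoryS = 0.5))
  sim2 <- ctrlHeart(nFrames = 100, noiseSigma = 0.05, seed = 3)
  t2 <- gateStream(sim2$video, refs, gateConfig(nPulses = 3,
                                                refractoryS = 0.5))
  expect_identical(t1, t2)
})

test_that("pulse power follows energy over duration", {
  expect_equal(pulsePower(laserPulseSpec(0.9, 3)), 300)
  expect_equal(pulsePower(1, 1), 1000)
  expect_equal(pulsePower(0.9, 9), 100)
  expect_error(laserPulseSpec(0.9, 0), "durationMs")
  expect_error(pulsePower(0.9, 0), "durationMs")
  expect_error(laserPulseSpec(nPulses = 5, interPulseIntervalS = 0),
               "interPulseIntervalS")
})
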