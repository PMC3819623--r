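test_that("segmentation recovers the rendered area within 2%", {
  sim <- ctrlHeart(nFrames = 24)
  for (i in c(1, 7, 13, 20)) {
    got <- segmentVentricle(frames(sim$video, i), 2.5)$areaUm2
    true <- sim$truth$areaPerFrame[i]
    expect_lte(abs(got - true) / true, 0.02)
  }
})

test_that("segmentation rejects blank frames and keeps the largest blob", {
  expect_error(segmentVentricle(matrix(0.5, 64, 64), 1), "blank frame")
  # two disjoint blobs: only the larger contributes to the area
  f <- matrix(0.1, 64, 64)
  f[10:30, 10:30] <- 0.9   # 441 px
  f[45:50, 45:50] <- 0.9   # 36 px
  seg <- segmentVentricle(f, 1)
  expect_equal(seg$areaUm2, 441)
})

test_that("intensity scaling leaves the functional report unchanged", {
  sim <- ctrlHeart(nFrames = 80)
  r1 <- cardiacReport(sim$video)
  scaled <- VideoSequence(frames(sim$video) * 0.35, fps = 30,
                          pixelSizeUm = 2.5)
  r2 <- cardiacReport(scaled)
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("beat detection finds one boundary per cycle, none in pauses", {
  # 10 cycles at 400 ms, 30 fps -> 120 frames
  sim <- ctrlHeart(nFrames = 121)
  bs <- buildBeatSeries(sim$video)
  expect_gte(nrow(perBeat(bs)), 8)
  expect_lte(nrow(perBeat(bs)), 10)
  # pause video: no boundaries inside the pause
  simp <- injuredHeart()
  bsp <- buildBeatSeries(simp$video, periodMs = 400)
  tb <- timestampsMs(simp$video)[beatBoundaries(bsp)]
  tPause <- timestampsMs(simp$video)[90]
  expect_false(any(tb > tPause + 100 & tb < tPause + 2400))
  # constant-area video cannot yield beats
  flat <- simulateHeartVideo(heartSimParams(nFrames = 60, efTruePct = 0,
                                            noiseSigma = 0))
  expect_error(buildBeatSeries(flat$video), "insufficient beats")
})

test_that("heart rate is 60000 over the mean inter-peak interval", {
  mk <- function(bounds, tMs) new("BeatSeries",
    areaUm2 = rep(1, length(tMs)), timestampsMs = tMs,
    beatBoundaries = as.integer(bounds),
    perBeat = data.frame(Ad_um2 = 1, As_um2 = 1))
  s <- mk(c(1, 501, 1001), 0:1200)
  expect_equal(heartRate(s), 120)
  expect_error(heartRate(mk(1L, 0:10)), "insufficient beats")
})

test_that("heart rate recovers simulated operating points within 1%", {
  for (per in c(400, 512)) {  # 150 bpm control-like, 117.2 bpm post-injury
    sim <- simulateHeartVideo(heartSimParams(periodMs = per, nFrames = 100,
                                             noiseSigma = 0))
    hr <- heartRate(buildBeatSeries(sim$video))
    expect_lte(abs(hr - 60000 / per) / (60000 / per), 0.01)
  }
})

test_that("ejection fraction formula and bounds hold", {
  expect_equal(ejectionFraction(10, 8), 20)
  expect_equal(ejectionFraction(10, 10), 0)
  expect_error(ejectionFraction(10, 11), "exceeds")
  expect_error(ejectionFraction(0, 0), "positive")
  # bounds property over random valid extrema
  set.seed(5)
  Ad <- runif(200, 1, 100)
  As <- Ad * runif(200)
  ef <- ejectionFraction(Ad, As)
  expect_true(all(ef >= 0 & ef <= 100))
})

test_that("the full pipeline recovers EF within one percentage point", {
  sim <- ctrlHeart(nFrames = 100)
  r <- cardiacReport(sim$video)
  expect_lte(abs(r$ef_pct - 20), 1)
})

test_that("diastolic area recovers the control operating point", {
  sim <- ctrlHeart(nFrames = 100)
  bs <- buildBeatSeries(sim$video)
  expect_lte(abs(ventricleDiastolicArea(bs) - 10100) / 10100, 0.02)
  # single-beat series: VDA is that beat's Ad
  one <- new("BeatSeries", areaUm2 = c(1, 2, 1), timestampsMs = c(0, 1, 2),
             beatBoundaries = c(1L, 3L),
             perBeat = data.frame(Ad_um2 = 123, As_um2 = 45))
  expect_equal(ventricleDiastolicArea(one), 123)
})

test_that("area scales with the square of the pixel size", {
  sim <- ctrlHeart(nFrames = 2)
  f <- frames(sim$video, 1)
  a1 <- segmentVentricle(f, 2.5)$areaUm2
  a2 <- segmentVentricle(f, 5)$areaUm2
  expect_equal(a2, 4 * a1)
})
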