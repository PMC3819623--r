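test_that("true phase advances by 2*pi/period per unit time", {
  sim <- ctrlHeart(nFrames = 60)
  dphi <- diff(sim$truth$unwrappedPhase)
  expect_equal(dphi, rep(2 * pi * (1000 / 400) / 30, 59), tolerance = 1e-12)
  # affine in time with slope 2*pi/period
  fit <- lm(sim$truth$unwrappedPhase ~ timestampsMs(sim$video))
  expect_equal(unname(coef(fit)[2]), 2 * pi / 400, tolerance = 1e-12)
})

test_that("EF 0 gives a constant-area, non-contracting video", {
  sim <- simulateHeartVideo(heartSimParams(nFrames = 30, efTruePct = 0,
                                           noiseSigma = 0))
  expect_equal(diff(range(sim$truth$areaPerFrame)), 0)
})

test_that("a pause freezes the phase and suppresses crossings", {
  sim <- injuredHeart()
  tPause <- timestampsMs(sim$video)[90]
  cross <- truePhaseCrossings(sim$truth, 0)
  expect_false(any(cross > tPause & cross < tPause + 2500))
  inPause <- timestampsMs(sim$video) > tPause &
    timestampsMs(sim$video) < tPause + 2500
  expect_equal(diff(range(sim$truth$phasePerFrame[inPause])), 0)
  # frozen frames are identical
  idx <- which(inPause)
  expect_identical(frames(sim$video, idx[1]), frames(sim$video, idx[3]))
  # post-pause rate reflects the bradycardic period
  hr <- sim$truth$hrBpmPiecewise
  expect_equal(hr$bpm, c(150, 0, 100))
})

test_that("identical seed and params give bit-identical outputs", {
  a <- ctrlHeart(nFrames = 20, noiseSigma = 0.05, seed = 42)
  b <- ctrlHeart(nFrames = 20, noiseSigma = 0.05, seed = 42)
  expect_identical(frames(a$video), frames(b$video))
  va <- simulateVesselVideo(vesselSimParams(nFrames = 8, seed = 5))
  vb <- simulateVesselVideo(vesselSimParams(nFrames = 8, seed = 5))
  expect_identical(frames(va$video), frames(vb$video))
  sa <- smallStack(nIn = 20, nOut = 5, seed = 11)
  sb <- smallStack(nIn = 20, nOut = 5, seed = 11)
  expect_identical(channel(sa$scene, "dapi"), channel(sb$scene, "dapi"))
})

test_that("vessel cells move v/fps per frame and truth bookkeeping holds", {
  sim <- simulateVesselVideo(vesselSimParams(velocityUmS = 300, fps = 30,
                                             pixelSizeUm = 1, nCells = 4,
                                             nFrames = 10))
  tr <- sim$trajectories
  expect_equal(nrow(tr), 4 * 10)
  one <- tr[tr$cell == 1, ]
  step <- diff(one$x_px) %% 160  # wrap-aware
  expect_equal(step, rep(10, 9), tolerance = 1e-12)
  # zero velocity: identical noiseless frames
  z <- simulateVesselVideo(vesselSimParams(velocityUmS = 0, nFrames = 5,
                                           noiseSigma = 0))
  expect_identical(frames(z$video, 1), frames(z$video, 5))
})

test_that("stack truth counts are exact by construction", {
  sim <- smallStack(nIn = 40, nOut = 8, phh3Fraction = 0, nTunel = 1)
  expect_equal(sim$truth$vct, 40)
  expect_equal(sim$truth$vcm, 0L)
  expect_equal(sim$truth$tunel, 1)
  # phh3Fraction 1: every in-mask nucleus is mitotic, centres coincide
  sim2 <- smallStack(nIn = 10, nOut = 0, phh3Fraction = 1, nTunel = 0)
  expect_equal(sim2$truth$vcm, 10L)
  expect_equal(sort(sim2$truth$mitoticIdx), 1:10)
  # rendered nuclei match requested counts (ground-truth conservation)
  lab <- cardiogate:::label3D(channel(sim2$scene, "dapi") > 0.5)
  expect_equal(max(lab), 10)
})

test_that("infeasible nucleus packing raises a packing error", {
  expect_error(
    simulateHeartStack(stackSimParams(shapeZYX = c(4, 24, 24),
                                      nNucleiInMask = 500)),
    "packing infeasible")
})

test_that("parameter validation rejects non-physical inputs", {
  expect_error(heartSimParams(periodMs = 0), "periodMs")
  expect_error(heartSimParams(fps = -1), "fps")
  expect_error(heartSimParams(efTruePct = 100), "efTruePct")
  expect_error(heartSimParams(pauseOnsetFrame = 500, nFrames = 100),
               "pauseOnsetFrame")
  expect_error(vesselSimParams(cellRadiusUm = 1000), "field")
  expect_error(stackSimParams(phh3Fraction = 1.5), "phh3Fraction")
})

test_that("TIFF round-trips preserve video and stack content", {
  sim <- ctrlHeart(nFrames = 6)
  tf <- withr::local_tempfile(fileext = ".tif")
  writeVideoTiff(sim$video, tf)
  back <- readVideoTiff(tf, fps = 30, pixelSizeUm = 2.5)
  expect_equal(nFrames(back), 6)
  expect_lt(max(abs(frames(back) - frames(sim$video))), 1 / 65535)

  st <- smallStack(nIn = 10, nOut = 2)
  pre <- file.path(withr::local_tempdir(), "stack")
  files <- writeStackTiff(st$scene, pre)
  sc <- readStackTiff(files, zStepUm = 3, pixelSizeUm = 1.5)
  expect_equal(channelNames(sc), channelNames(st$scene))
  expect_lt(max(abs(channel(sc, "gfp") - channel(st$scene, "gfp"))),
            1 / 65535)
})

test_that("ground-truth sidecar writes CSV and YAML echo", {
  sim <- ctrlHeart(nFrames = 10)
  csv <- withr::local_tempfile(fileext = ".csv")
  writeHeartTruth(sim, csv)
  df <- read.csv(csv)
  expect_equal(nrow(df), 10)
  expect_equal(df$area_um2, sim$truth$areaPerFrame)
  cfg <- yaml::read_yaml(paste0(csv, ".yaml"))
  expect_equal(cfg$periodMs, 400)
})
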