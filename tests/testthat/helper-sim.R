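# Shared fixtures: small, fast synthetic scenes built in code.

# Control-regime heart video: 400 ms period (150 bpm), 30 fps.
ctrlHeart <- function(nFrames = 150, noiseSigma = 0, seed = 1, ...) {
  simulateHeartVideo(heartSimParams(nFrames = nFrames,
                                    noiseSigma = noiseSigma,
                                    seed = seed, ...))
}

# Injured-heart video: 2.5 s pause at frame 90, then bradycardia (600 ms).
injuredHeart <- function(nFrames = 300, noiseSigma = 0, seed = 1,
                         pauseOnsetFrame = 90, pauseDurationMs = 2500,
                         postPausePeriodMs = 600) {
  simulateHeartVideo(heartSimParams(
    nFrames = nFrames, noiseSigma = noiseSigma, seed = seed,
    pauseOnsetFrame = pauseOnsetFrame, pauseDurationMs = pauseDurationMs,
    postPausePeriodMs = postPausePeriodMs))
}

# A small stack that still counts exactly: fewer nuclei, smaller field.
smallStack <- function(nIn = 60, nOut = 12, phh3Fraction = 0.05,
                       nTunel = 5, seed = 1, noiseSigma = 0, ...) {
  simulateHeartStack(stackSimParams(
    shapeZYX = c(16, 80, 80), nNucleiInMask = nIn, nNucleiOutMask = nOut,
    phh3Fraction = phh3Fraction, nTunelPuncta = nTunel, seed = seed,
    noiseSigma = noiseSigma, ...))
}

# Circular absolute difference between two phases.
circAbs <- function(a, b) {
  d <- abs((a - b) %% (2 * pi))
  pmin(d, 2 * pi - d)
}
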