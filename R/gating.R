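# Prospective optical gating: estimate the cardiac phase of incoming video
# frames by image similarity against a one-cycle reference set, fit the
# phase-vs-time line over a sliding window, and predict the next time the
# heart reaches a chosen target phase (end-diastole by default) so a laser
# pulse can be fired at that instant, compensated for system latency.
#
# Similarity metric everywhere: zero-normalized cross-correlation (ZNCC),
# invariant to affine intensity drift of the illumination.

#' Estimate the cardiac period from a video by temporal self-similarity
#'
#' Computes the mean zero-normalized cross-correlation between all frame
#' pairs separated by a candidate lag, picks the lag maximizing this
#' self-similarity within \code{searchRangeMs}, and refines it to sub-frame
#' resolution by quadratic interpolation through the peak and its two
#' neighbours.
#'
#' @param video a \linkS4class{VideoSequence} covering at least two cycles
#' @param searchRangeMs numeric length-2: candidate period range (ms)
#' @param minPeakSimilarity confidence floor: the peak mean ZNCC must
#'   exceed this, and the self-similarity curve must have non-trivial
#'   contrast, otherwise an "aperiodic input" error is thrown (frozen or
#'   paused videos have a flat curve)
#' @return estimated period in ms
#' @export
estimatePeriod <- function(video, searchRangeMs = c(200, 1000),
                           minPeakSimilarity = 0.5) {
  stopifnot(is(video, "VideoSequence"))
  fps <- video@fps
  n <- nFrames(video)
  lagLo <- max(2L, floor(searchRangeMs[1] / 1000 * fps))
  lagHi <- ceiling(searchRangeMs[2] / 1000 * fps)
  if (lagHi + 2 > n - 3)
    lagHi <- n - 5L
  if (lagHi < lagLo + 1)
    stop("video too short to cover the period search range twice")
  Fn <- normalizeFrames(video@frames)
  npair <- 40L  # frame pairs averaged per lag; enough to beat noise
  simAtLag <- function(L) {
    idx <- unique(round(seq(1, n - L, length.out = min(npair, n - L))))
    mean(colSums(Fn[, idx, drop = FALSE] * Fn[, idx + L, drop = FALSE]))
  }
  lags <- lagLo:min(lagHi + 1L, n - 2L)
  S <- vapply(lags, simAtLag, numeric(1))
  if (all(!is.finite(S)) || diff(range(S)) < 0.02)
    stop("aperiodic input: self-similarity curve is flat (frozen or paused video?)")
  best <- firstDominantPeak(S)  # fundamental, not a multiple
  if (S[best] < minPeakSimilarity)
    stop("aperiodic input: no periodicity above the confidence floor")
  # refine with circular-safe neighbours inside the scanned range
  iL <- max(1L, best - 1L); iR <- min(length(S), best + 1L)
  off <- if (iL == best || iR == best) 0 else
    quadPeakOffset(S[iL], S[best], S[iR])
  (lags[best] + off) / fps * 1000
}

#' Build a one-cycle phase reference set
#'
#' Takes the frames of one cardiac cycle starting at \code{anchorFrame} and
#' assigns phases uniformly by time within the cycle, phase 0 at the
#' anchor. When \code{target = "end-diastole"} the anchor is moved to the
#' frame of maximal segmented ventricular area within one period of
#' \code{anchorFrame} (the canonical gating target: the ventricle at its
#' largest diameter), and the stored target phase is 0.
#'
#' @param video a \linkS4class{VideoSequence}
#' @param periodMs the cardiac period (ms), e.g. from
#'   \code{\link{estimatePeriod}}
#' @param anchorFrame 1-based frame starting a stretch of >= one period
#' @param target either \code{"end-diastole"} or a numeric phase in
#'   [0, 2*pi) relative to the anchor
#' @return a \linkS4class{ReferenceSet}
#' @export
buildReference <- function(video, periodMs, anchorFrame = 1L,
                           target = "end-diastole") {
  stopifnot(is(video, "VideoSequence"), periodMs > 0)
  fps <- video@fps
  n <- nFrames(video)
  nRef <- max(3L, round(periodMs / 1000 * fps))
  if (anchorFrame + 2 * nRef - 1 > n && anchorFrame + nRef - 1 > n)
    stop("period longer than the remaining video after anchorFrame")

  targetPhase <- 0
  if (identical(target, "end-diastole")) {
    cyc <- anchorFrame:min(n, anchorFrame + nRef - 1L)
    areas <- vapply(cyc, function(i)
      segmentVentricle(video@frames[, , i], video@pixelSizeUm)$areaUm2,
      numeric(1))
    if (diff(range(areas)) / max(areas) < 0.02)
      stop("no identifiable end-diastole: ventricular area is constant")
    anchorFrame <- cyc[which.max(areas)]
  } else {
    targetPhase <- wrapPhase(as.numeric(target))
  }
  if (anchorFrame + nRef - 1 > n)
    stop("period longer than the remaining video after anchorFrame")
  idx <- anchorFrame:(anchorFrame + nRef - 1L)
  tRel <- (video@timestampsMs[idx] - video@timestampsMs[anchorFrame])
  phases <- wrapPhase(2 * pi * tRel / periodMs)
  new("ReferenceSet", refFrames = video@frames[, , idx, drop = FALSE],
      refPhases = phases, periodMs = periodMs, targetPhase = targetPhase,
      pixelSizeUm = video@pixelSizeUm)
}

#' Estimate the cardiac phase of a single frame
#'
#' Matches the frame against every reference frame by ZNCC, then refines
#' the phase by quadratic interpolation over the circularly indexed
#' similarity-vs-reference-phase curve. Confidence combines the best score
#' with the margin over the best non-neighbouring competitor and is
#' monotone in that margin; a pure-noise frame scores near zero.
#'
#' @param frame a 2-D numeric array matching the reference frame shape
#' @param refs a \linkS4class{ReferenceSet}
#' @param marginScale margin at which confidence saturates
#' @return list with \code{phase} in [0, 2*pi), \code{score} (best ZNCC),
#'   \code{confidence} in [0, 1], and \code{bestIndex}
#' @export
estimatePhase <- function(frame, refs, marginScale = 0.05) {
  stopifnot(is(refs, "ReferenceSet"))
  Rn <- refsNormalized(refs)
  v <- normalizeFrame(frame)
  s <- as.numeric(crossprod(Rn, v))
  k <- length(s)
  best <- which.max(s)
  iL <- if (best == 1) k else best - 1L
  iR <- if (best == k) 1L else best + 1L
  # an exact reference hit needs no sub-frame refinement
  off <- if (s[best] > 1 - 1e-9) 0 else quadPeakOffset(s[iL], s[best], s[iR])
  # phase step to the interpolation side (circular)
  ph <- refs@refPhases
  stepR <- wrapPhase(ph[iR] - ph[best]); if (stepR == 0) stepR <- 2 * pi / k
  stepL <- wrapPhase(ph[best] - ph[iL]); if (stepL == 0) stepL <- 2 * pi / k
  phase <- wrapPhase(ph[best] + ifelse(off >= 0, off * stepR, off * stepL))
  # margin over the best non-adjacent competitor (adjacent phases are
  # legitimately similar); fall back to curve range for tiny ref sets
  excl <- unique(c(best, iL, iR))
  margin <- if (k > 3) s[best] - max(s[-excl]) else diff(range(s))
  conf <- max(0, min(1, s[best])) * max(0, min(1, margin / marginScale))
  list(phase = phase, score = s[best], confidence = conf, bestIndex = best)
}

# Cache the normalized reference matrix on the ReferenceSet instance.
refsNormalized <- local({
  cacheKey <- NULL; cacheVal <- NULL
  function(refs) {
    key <- c(dim(refs@refFrames), refs@periodMs, sum(refs@refFrames[, , 1]))
    if (!identical(key, cacheKey)) {
      cacheVal <<- normalizeFrames(refs@refFrames)
      cacheKey <<- key
    }
    cacheVal
  }
})

#' Unwrap a phase history and fit the phase-vs-time line
#'
#' Circularly unwraps the last \code{window} phase estimates (adding 2*pi
#' at each wrap) and least-squares fits unwrapped phase against time. The
#' slope is the instantaneous angular rate of the heart (rad/ms); its
#' reciprocal scaled by 2*pi is the running period.
#'
#' @param phases numeric phase estimates in [0, 2*pi), oldest first
#' @param timestampsMs matching timestamps (ms)
#' @param window number of most recent estimates to use (default 8)
#' @return list with \code{slope} (rad/ms), \code{intercept} (rad at t=0),
#'   \code{residual} (RMS of fit residuals, rad), \code{n}
#' @export
unwrapAndFit <- function(phases, timestampsMs, window = 8L) {
  n <- length(phases)
  if (n < 3L)
    stop("insufficient history: need at least 3 usable phase estimates")
  use <- max(1L, n - window + 1L):n
  ph <- phases[use]; tt <- timestampsMs[use]
  d <- diff(ph)
  d <- d + 2 * pi * (d < -pi) - 2 * pi * (d > pi)
  unw <- cumsum(c(ph[1], d))
  fit <- lm.fit(cbind(1, tt), unw)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       residual = sqrt(mean(fit$residuals^2)),
       n = length(use))
}

#' Predict the next latency-compensated trigger time for a target phase
#'
#' Solves the fitted phase line for the smallest time strictly after
#' \code{nowMs + latencyMs} at which the predicted phase equals the target
#' (mod 2*pi), then subtracts the system latency so the pulse lands on the
#' crossing. Triggers are withheld (not raised as errors) when the fitted
#' rate is at or below the slope floor (pause/asystole) or the fit residual
#' exceeds tolerance (arrhythmic, unreliable prediction).
#'
#' @param fit result of \code{\link{unwrapAndFit}}
#' @param targetPhase target phase in [0, 2*pi)
#' @param nowMs current time (ms); the fire time is strictly later
#' @param latencyMs trigger-to-laser system latency to compensate (ms)
#' @param slopeFloor minimum angular rate (rad/ms) considered a beating
#'   heart; default corresponds to a 4 s period
#' @param residualTol maximum acceptable fit RMS residual (rad)
#' @return a one-row data.frame (a trigger event): fire_time_ms,
#'   target_phase, predicted_period_ms, confidence, withheld, reason
#' @export
predictTrigger <- function(fit, targetPhase, nowMs, latencyMs = 0,
                           slopeFloor = 2 * pi / 4000, residualTol = 0.5) {
  targetPhase <- wrapPhase(targetPhase)
  withhold <- function(reason) data.frame(
    fire_time_ms = NA_real_, target_phase = targetPhase,
    predicted_period_ms = if (fit$slope > 0) 2 * pi / fit$slope else Inf,
    confidence = 0, withheld = TRUE, reason = reason,
    stringsAsFactors = FALSE)
  if (!is.finite(fit$slope) || fit$slope <= slopeFloor)
    return(withhold("pause/asystole"))
  if (fit$residual > residualTol)
    return(withhold("arrhythmia"))
  tMin <- nowMs + latencyMs
  # smallest t > tMin with intercept + slope*t = target + 2*pi*k
  k <- ceiling((fit$intercept + fit$slope * tMin - targetPhase) / (2 * pi) +
                 1e-12)
  tCross <- (targetPhase + 2 * pi * k - fit$intercept) / fit$slope
  if (tCross <= tMin) tCross <- tCross + 2 * pi / fit$slope
  conf <- max(0, min(1, 1 - fit$residual / residualTol))
  data.frame(fire_time_ms = tCross - latencyMs, target_phase = targetPhase,
             predicted_period_ms = 2 * pi / fit$slope, confidence = conf,
             withheld = FALSE, reason = "", stringsAsFactors = FALSE)
}

#' Gating configuration
#'
#' @param nPulses maximum number of laser pulses to schedule
#' @param refractoryS minimum spacing between fires (s); default 60 s, the
#'   multi-pulse protocol spacing
#' @param latencyMs system latency compensated by the scheduler (ms)
#' @param window sliding window of phase estimates for the rate fit
#' @param confidenceFloor minimum per-frame match confidence for an
#'   estimate to enter the fit
#' @param slopeFloor minimum angular rate (rad/ms) treated as beating
#' @param residualTol maximum fit RMS residual (rad)
#' @return a list of class \code{gateConfig}
#' @export
gateConfig <- function(nPulses = 1L, refractoryS = 60, latencyMs = 0,
                       window = 8L, confidenceFloor = 0.2,
                       slopeFloor = 2 * pi / 4000, residualTol = 0.5) {
  if (nPulses < 1) stop("nPulses must be >= 1")
  if (refractoryS < 0) stop("refractoryS must be non-negative")
  structure(list(nPulses = as.integer(nPulses), refractoryS = refractoryS,
                 latencyMs = latencyMs, window = as.integer(window),
                 confidenceFloor = confidenceFloor, slopeFloor = slopeFloor,
                 residualTol = residualTol), class = "gateConfig")
}

#' Run the prospective gating loop over a video
#'
#' Online loop over frames: estimate the phase of each incoming frame
#' against the reference set, maintain a sliding window of confident
#' estimates, fit the phase line, and schedule a trigger whenever the
#' predicted target-phase crossing falls before the next frame arrives.
#' Fires are spaced by the refractory interval; pauses and low-quality
#' fits produce withheld events rather than fires.
#'
#' @param video a \linkS4class{VideoSequence}
#' @param refs a \linkS4class{ReferenceSet} (its stored target phase is
#'   the gating target)
#' @param config a \code{\link{gateConfig}}
#' @return data.frame of trigger events (fired and withheld), columns
#'   fire_time_ms, target_phase, predicted_period_ms, confidence,
#'   withheld, reason
#' @export
gateStream <- function(video, refs, config = gateConfig()) {
  stopifnot(is(video, "VideoSequence"), is(refs, "ReferenceSet"))
  cfg <- config
  n <- nFrames(video)
  tMs <- video@timestampsMs
  dtMs <- 1000 / video@fps
  Rn <- normalizeFrames(refs@refFrames)
  Vn <- normalizeFrames(video@frames)
  S <- crossprod(Rn, Vn)  # k_ref x n similarity, all frames at once
  ph <- refs@refPhases
  k <- nrow(S)

  events <- list()
  histPh <- numeric(); histT <- numeric()
  nFired <- 0L
  lastFire <- -Inf
  withheldReason <- NULL

  for (i in seq_len(n)) {
    s <- S[, i]
    best <- which.max(s)
    iL <- if (best == 1) k else best - 1L
    iR <- if (best == k) 1L else best + 1L
    off <- if (s[best] > 1 - 1e-9) 0 else quadPeakOffset(s[iL], s[best], s[iR])
    stepR <- wrapPhase(ph[iR] - ph[best]); if (stepR == 0) stepR <- 2 * pi / k
    stepL <- wrapPhase(ph[best] - ph[iL]); if (stepL == 0) stepL <- 2 * pi / k
    phase <- wrapPhase(ph[best] + if (off >= 0) off * stepR else off * stepL)
    excl <- unique(c(best, iL, iR))
    margin <- if (k > 3) s[best] - max(s[-excl]) else diff(range(s))
    conf <- max(0, min(1, s[best])) * max(0, min(1, margin / 0.05))
    if (conf >= cfg$confidenceFloor) {
      histPh <- c(histPh, phase); histT <- c(histT, tMs[i])
      if (length(histPh) > cfg$window) {
        histPh <- tail(histPh, cfg$window); histT <- tail(histT, cfg$window)
      }
    }
    if (nFired >= cfg$nPulses) break
    if (length(histPh) < 3L) next
    fit <- unwrapAndFit(histPh, histT, window = cfg$window)
    ev <- predictTrigger(fit, refs@targetPhase, nowMs = tMs[i],
                         latencyMs = cfg$latencyMs,
                         slopeFloor = cfg$slopeFloor,
                         residualTol = cfg$residualTol)
    if (ev$withheld) {
      # record each withhold reason once per contiguous episode
      if (!identical(withheldReason, ev$reason)) {
        events[[length(events) + 1L]] <- ev
        withheldReason <- ev$reason
      }
      next
    }
    withheldReason <- NULL
    fireAt <- ev$fire_time_ms + cfg$latencyMs  # actual crossing instant
    if (fireAt - lastFire < cfg$refractoryS * 1000) next
    # commit only when the crossing arrives before the next frame update
    # (this is the final, most informed prediction for that crossing); the
    # 10% guard keeps crossings that land a fraction of a ms past the
    # boundary from being missed on both sides of it
    if (fireAt <= tMs[i] + 1.1 * dtMs) {
      events[[length(events) + 1L]] <- ev
      nFired <- nFired + 1L
      lastFire <- fireAt
    }
  }
  if (!length(events))
    return(data.frame(fire_time_ms = numeric(), target_phase = numeric(),
                      predicted_period_ms = numeric(), confidence = numeric(),
                      withheld = logical(), reason = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, events)
}

#' Laser pulse specification
#'
#' @param energyMJ energy per pulse (mJ)
#' @param durationMs pulse duration (ms)
#' @param nPulses number of pulses in the schedule
#' @param interPulseIntervalS spacing between pulses (s); required when
#'   nPulses > 1
#' @return a list of class \code{laserPulseSpec}
#' @export
laserPulseSpec <- function(energyMJ = 0.9, durationMs = 3, nPulses = 1L,
                           interPulseIntervalS = if (nPulses > 1) 60 else 0) {
  if (energyMJ <= 0) stop("energyMJ must be positive")
  if (durationMs <= 0) stop("durationMs must be positive")
  if (nPulses < 1) stop("nPulses must be >= 1")
  if (nPulses > 1 && (is.null(interPulseIntervalS) || interPulseIntervalS <= 0))
    stop("interPulseIntervalS is required when nPulses > 1")
  structure(list(energyMJ = energyMJ, durationMs = durationMs,
                 nPulses = as.integer(nPulses),
                 interPulseIntervalS = interPulseIntervalS),
            class = "laserPulseSpec")
}

#' Average optical power of a laser pulse
#'
#' Power (mW) = energy (mJ) / duration (ms) x 1000. The standard operating
#' point, 0.9 mJ over 3 ms, is 300 mW.
#'
#' @param spec a \code{\link{laserPulseSpec}}, or a plain energy in mJ
#' @param durationMs pulse duration in ms (when \code{spec} is numeric)
#' @return average power in mW
#' @examples
#' pulsePower(laserPulseSpec(0.9, 3))  # 300
#' @export
pulsePower <- function(spec, durationMs = NULL) {
  if (inherits(spec, "laserPulseSpec"))
    return(spec$energyMJ / spec$durationMs * 1000)
  if (is.null(durationMs) || durationMs <= 0)
    stop("durationMs must be positive")
  spec / durationMs * 1000
}
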