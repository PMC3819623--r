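# Synthetic-data module: renders beating-heart videos, caudal-vein videos
# and immunostained confocal z-stacks with exact ground truth, emulating the
# phenomenology of laser injury experiments on 72 hpf zebrafish embryos
# (periodic ventricular contraction, an injury-induced pause followed by
# bradycardia, erythrocyte streaming, DAPI/PHH3/TUNEL-stained hearts).

#' Parameters of the synthetic beating-heart video
#'
#' The defaults are the control operating point used throughout: a 400 ms
#' cardiac period (150 bpm), 30 fps video, a 10.1 x 10^3 um^2 diastolic
#' ventricle and a 20% area-based ejection fraction.
#'
#' @param periodMs cardiac period (ms)
#' @param fps acquisition frame rate (frames/s)
#' @param nFrames number of frames to render
#' @param diastolicAreaUm2 maximal (end-diastolic) projected area (um^2)
#' @param efTruePct true area-based ejection fraction, in (0, 100); 0 is
#'   accepted as the degenerate non-contracting case
#' @param pixelSizeUm micrometres per pixel
#' @param noiseSigma sd of additive Gaussian intensity noise (intensity
#'   units on the [0, 1] range; clipped after addition)
#' @param pauseOnsetFrame optional 1-based frame at which the heart freezes
#'   (laser-injury pause); NULL for none
#' @param pauseDurationMs duration of the frozen pause (ms)
#' @param postPausePeriodMs period after the pause (bradycardia); defaults
#'   to \code{periodMs}
#' @param seed integer RNG seed (only the noise consumes randomness)
#' @param ny,nx frame size in pixels
#' @param shapeAsym amplitude of the sin-phase aspect-ratio modulation that
#'   makes expansion and contraction visually distinct (see vignette)
#' @return a validated parameter list of class \code{heartSimParams}
#' @export
heartSimParams <- function(periodMs = 400, fps = 30, nFrames = 150,
                           diastolicAreaUm2 = 10100, efTruePct = 20,
                           pixelSizeUm = 2.5, noiseSigma = 0.05,
                           pauseOnsetFrame = NULL, pauseDurationMs = 0,
                           postPausePeriodMs = NULL, seed = 1,
                           ny = 96, nx = 96, shapeAsym = 0.15) {
  if (periodMs <= 0) stop("periodMs must be positive")
  if (fps <= 0) stop("fps must be positive")
  if (nFrames < 1) stop("nFrames must be a positive integer")
  if (diastolicAreaUm2 <= 0) stop("diastolicAreaUm2 must be positive")
  if (efTruePct < 0 || efTruePct >= 100)
    stop("efTruePct must lie in [0, 100): systolic area must stay positive")
  if (pixelSizeUm <= 0) stop("pixelSizeUm must be positive")
  if (noiseSigma < 0) stop("noiseSigma must be non-negative")
  if (!is.null(pauseOnsetFrame)) {
    if (pauseOnsetFrame < 1 || pauseOnsetFrame > nFrames)
      stop("pauseOnsetFrame must lie in [1, nFrames]")
    if (pauseDurationMs < 0) stop("pauseDurationMs must be non-negative")
  }
  if (!is.null(postPausePeriodMs) && postPausePeriodMs <= 0)
    stop("postPausePeriodMs must be positive")
  structure(list(
    periodMs = periodMs, fps = fps, nFrames = as.integer(nFrames),
    diastolicAreaUm2 = diastolicAreaUm2, efTruePct = efTruePct,
    pixelSizeUm = pixelSizeUm, noiseSigma = noiseSigma,
    pauseOnsetFrame = if (is.null(pauseOnsetFrame)) NULL
      else as.integer(pauseOnsetFrame),
    pauseDurationMs = pauseDurationMs,
    postPausePeriodMs = postPausePeriodMs %||% periodMs,
    seed = as.integer(seed), ny = as.integer(ny), nx = as.integer(nx),
    shapeAsym = shapeAsym), class = "heartSimParams")
}

# Piecewise-linear unwrapped phase segments for a heart video:
# rows (t0, t1, phi0, omega) with omega in rad/ms; phase 0 at t = 0
# (end-diastole by construction: area is maximal at phase 0).
phaseSegments <- function(p) {
  w1 <- 2 * pi / p$periodMs
  tEnd <- (p$nFrames - 1) / p$fps * 1000 + 1000 / p$fps
  if (is.null(p$pauseOnsetFrame) || p$pauseDurationMs <= 0)
    return(data.frame(t0 = 0, t1 = tEnd, phi0 = 0, omega = w1))
  tp <- (p$pauseOnsetFrame - 1) / p$fps * 1000
  w2 <- 2 * pi / p$postPausePeriodMs
  phiP <- w1 * tp
  data.frame(
    t0 = c(0, tp, tp + p$pauseDurationMs),
    t1 = c(tp, tp + p$pauseDurationMs, max(tEnd, tp + p$pauseDurationMs)),
    phi0 = c(0, phiP, phiP),
    omega = c(w1, 0, w2))
}

unwrappedPhaseAt <- function(segs, tMs) {
  out <- numeric(length(tMs))
  for (i in seq_len(nrow(segs))) {
    sel <- tMs >= segs$t0[i] & (tMs < segs$t1[i] | i == nrow(segs))
    out[sel] <- segs$phi0[i] + segs$omega[i] * (tMs[sel] - segs$t0[i])
  }
  out
}

#' Times at which the simulated heart truly passes a phase
#'
#' Solves the generator's piecewise-linear unwrapped phase for all crossings
#' of \code{target + 2*pi*k} inside the simulated time span. During a pause
#' the phase is frozen, so no crossings occur there.
#'
#' @param truth the ground-truth list returned by
#'   \code{\link{simulateHeartVideo}}
#' @param target target phase in [0, 2*pi); default 0 (end-diastole)
#' @return numeric vector of crossing times (ms), increasing
#' @export
truePhaseCrossings <- function(truth, target = 0) {
  segs <- truth$phaseSegments
  target <- wrapPhase(target)
  out <- numeric()
  for (i in seq_len(nrow(segs))) {
    if (segs$omega[i] <= 0) next
    phiA <- segs$phi0[i]
    phiB <- segs$phi0[i] + segs$omega[i] * (segs$t1[i] - segs$t0[i])
    ks <- seq(ceiling((phiA - target) / (2 * pi)),
              floor((phiB - target) / (2 * pi)))
    if (!length(ks)) next
    tt <- segs$t0[i] + (target + 2 * pi * ks - phiA) / segs$omega[i]
    out <- c(out, tt[tt > segs$t0[i] - 1e-9 & tt <= segs$t1[i] + 1e-9])
  }
  sort(unique(out))
}

# Render one elliptical "ventricle" frame. Area is exact (anti-aliased
# edge); aspect ratio is modulated by shapeAsym*sin(phase) so that phases
# phi and 2*pi - phi (equal area) remain visually distinct.
renderHeartFrame <- function(areaUm2, phase, p, fg = 0.85, bg = 0.12) {
  aspect <- 1.3 * (1 + p$shapeAsym * sin(phase))
  aPx <- sqrt(areaUm2 * aspect / pi) / p$pixelSizeUm
  bPx <- sqrt(areaUm2 / (aspect * pi)) / p$pixelSizeUm
  cy <- (p$ny + 1) / 2; cx <- (p$nx + 1) / 2
  dy <- matrix(seq_len(p$ny) - cy, p$ny, p$nx)
  dx <- matrix(seq_len(p$nx) - cx, p$ny, p$nx, byrow = TRUE)
  s <- sqrt((dx / aPx)^2 + (dy / bPx)^2)
  gradN <- sqrt((dx / aPx^2)^2 + (dy / bPx^2)^2) / pmax(s, 1e-9)
  distPx <- (1 - s) / pmax(gradN, 1e-9)
  cov <- pmin(pmax(distPx + 0.5, 0), 1)
  bg + (fg - bg) * cov
}

#' Simulate a video of a beating (optionally laser-injured) ventricle
#'
#' Renders an ellipse whose projected area oscillates sinusoidally between
#' the diastolic area and the systolic area implied by the true ejection
#' fraction, at the stated cardiac period. If a pause is configured, the
#' image freezes at the pause-onset phase for \code{pauseDurationMs} and
#' then resumes at the (typically longer) post-pause period, emulating the
#' pause-plus-bradycardia response to ventricular laser injury.
#'
#' @param params a \code{\link{heartSimParams}} list
#' @return a list with elements \code{video} (a
#'   \linkS4class{VideoSequence}) and \code{truth}: per-frame true phase in
#'   [0, 2*pi) (\code{phasePerFrame}), unwrapped phase, exact pre-noise
#'   area per frame (um^2, \code{areaPerFrame}), piecewise heart rate
#'   (\code{hrBpmPiecewise}), the phase segments used by
#'   \code{\link{truePhaseCrossings}}, and the generating parameters
#' @examples
#' sim <- simulateHeartVideo(heartSimParams(nFrames = 30, noiseSigma = 0))
#' sim$video
#' @export
simulateHeartVideo <- function(params = heartSimParams()) {
  stopifnot(inherits(params, "heartSimParams"))
  p <- params
  tMs <- (seq_len(p$nFrames) - 1) / p$fps * 1000
  segs <- phaseSegments(p)
  phiU <- unwrappedPhaseAt(segs, tMs)
  phi <- wrapPhase(phiU)
  Ad <- p$diastolicAreaUm2
  As <- Ad * (1 - p$efTruePct / 100)
  area <- As + (Ad - As) * (1 + cos(phi)) / 2

  arr <- array(0, c(p$ny, p$nx, p$nFrames))
  for (i in seq_len(p$nFrames))
    arr[, , i] <- renderHeartFrame(area[i], phi[i], p)
  if (p$noiseSigma > 0) {
    set.seed(p$seed)
    arr <- arr + array(rnorm(length(arr), 0, p$noiseSigma), dim(arr))
    arr <- pmin(pmax(arr, 0), 1)
  }

  hrSeg <- data.frame(
    t0 = segs$t0, t1 = segs$t1,
    bpm = 60000 * segs$omega / (2 * pi))
  list(
    video = VideoSequence(arr, fps = p$fps, pixelSizeUm = p$pixelSizeUm,
                          timestampsMs = tMs),
    truth = list(phasePerFrame = phi, unwrappedPhase = phiU,
                 areaPerFrame = area, hrBpmPiecewise = hrSeg,
                 phaseSegments = segs, params = p))
}

#' Parameters of the synthetic caudal-vein video
#'
#' Defaults follow the control flow regime (~300 um/s erythrocyte velocity
#' at 30 fps) and the measurement protocol of four cells tracked over at
#' least ten frames.
#'
#' @param velocityUmS erythrocyte velocity along the vessel axis (um/s)
#' @param nCells number of rendered cells
#' @param fps frames per second
#' @param nFrames number of frames
#' @param pixelSizeUm micrometres per pixel
#' @param cellRadiusUm cell radius (um)
#' @param seed integer RNG seed
#' @param ny,nx frame size in pixels; cells travel along x and wrap
#' @param noiseSigma additive intensity noise sd
#' @return a validated list of class \code{vesselSimParams}
#' @export
vesselSimParams <- function(velocityUmS = 300, nCells = 4, fps = 30,
                            nFrames = 30, pixelSizeUm = 1,
                            cellRadiusUm = 3, seed = 1,
                            ny = 64, nx = 160, noiseSigma = 0.02) {
  if (velocityUmS < 0) stop("velocityUmS must be non-negative")
  if (nCells < 1) stop("nCells must be a positive integer")
  if (fps <= 0 || nFrames < 1) stop("fps and nFrames must be positive")
  if (pixelSizeUm <= 0 || cellRadiusUm <= 0)
    stop("pixelSizeUm and cellRadiusUm must be positive")
  if (cellRadiusUm / pixelSizeUm * 2 >= min(ny, nx))
    stop("cellRadiusUm must be smaller than the field")
  structure(list(velocityUmS = velocityUmS, nCells = as.integer(nCells),
                 fps = fps, nFrames = as.integer(nFrames),
                 pixelSizeUm = pixelSizeUm, cellRadiusUm = cellRadiusUm,
                 seed = as.integer(seed), ny = as.integer(ny),
                 nx = as.integer(nx), noiseSigma = noiseSigma),
            class = "vesselSimParams")
}

#' Simulate a caudal-vein video of streaming erythrocytes
#'
#' Bright discs translate along the vessel (x) axis at constant velocity,
#' wrapping deterministically at the field edge. Cells occupy distinct
#' y-lanes so trajectories never collide.
#'
#' @param params a \code{\link{vesselSimParams}} list
#' @return list with \code{video} (a \linkS4class{VideoSequence}),
#'   \code{velocityUmS} (the true velocity) and \code{trajectories} (a
#'   data.frame: cell, frame, x_px, y_px — true centres, 1-based pixels)
#' @export
simulateVesselVideo <- function(params = vesselSimParams()) {
  stopifnot(inherits(params, "vesselSimParams"))
  p <- params
  set.seed(p$seed)
  rPx <- p$cellRadiusUm / p$pixelSizeUm
  margin <- ceiling(rPx) + 2
  lanes <- seq(margin, p$ny - margin, length.out = p$nCells)
  x0 <- runif(p$nCells, 1, p$nx)
  dPx <- p$velocityUmS / p$fps / p$pixelSizeUm
  traj <- do.call(rbind, lapply(seq_len(p$nCells), function(c) {
    x <- (x0[c] + (seq_len(p$nFrames) - 1) * dPx - 1) %% p$nx + 1
    data.frame(cell = c, frame = seq_len(p$nFrames), x_px = x,
               y_px = rep(lanes[c], p$nFrames))
  }))
  dy <- matrix(seq_len(p$ny), p$ny, p$nx)
  dx <- matrix(seq_len(p$nx), p$ny, p$nx, byrow = TRUE)
  arr <- array(0.1, c(p$ny, p$nx, p$nFrames))
  for (f in seq_len(p$nFrames)) {
    fr <- arr[, , f]
    sub <- traj[traj$frame == f, ]
    for (c in seq_len(nrow(sub))) {
      # wrap-aware distance along x
      ddx <- abs(dx - sub$x_px[c])
      ddx <- pmin(ddx, p$nx - ddx)
      dist <- sqrt(ddx^2 + (dy - sub$y_px[c])^2)
      cov <- pmin(pmax(rPx - dist + 0.5, 0), 1)
      fr <- pmax(fr, 0.1 + 0.8 * cov)
    }
    arr[, , f] <- fr
  }
  if (p$noiseSigma > 0) {
    arr <- arr + array(rnorm(length(arr), 0, p$noiseSigma), dim(arr))
    arr <- pmin(pmax(arr, 0), 1)
  }
  list(video = VideoSequence(arr, fps = p$fps, pixelSizeUm = p$pixelSizeUm),
       velocityUmS = p$velocityUmS, trajectories = traj)
}

#' Parameters of the synthetic immunostained heart z-stack
#'
#' Defaults emulate an isolated 72 hpf ventricle imaged at 3 um z-steps:
#' 238 DAPI nuclei inside the GFP-positive myocardial mask (the control
#' mean total cardiomyocyte count), a small fraction of them PHH3-positive,
#' plus out-of-mask nuclei and TUNEL puncta.
#'
#' @param shapeZYX integer triple (nz, ny, nx) of the stack
#' @param zStepUm axial spacing (um)
#' @param nNucleiInMask nuclei placed inside the ventricle mask
#' @param nNucleiOutMask nuclei placed outside the mask
#' @param phh3Fraction fraction of in-mask nuclei copied to the PHH3
#'   channel (rounded to a count)
#' @param nTunelPuncta TUNEL puncta rendered inside the heart region
#' @param nucleusRadiusUm nucleus radius (um)
#' @param minSeparationUm minimum centre-to-centre distance between nuclei
#' @param pixelSizeUm lateral pixel size (um)
#' @param noiseSigma additive intensity noise sd
#' @param seed integer RNG seed
#' @return a validated list of class \code{stackSimParams}
#' @export
stackSimParams <- function(shapeZYX = c(24, 128, 128), zStepUm = 3,
                           nNucleiInMask = 238, nNucleiOutMask = 30,
                           phh3Fraction = 0.023, nTunelPuncta = 5,
                           nucleusRadiusUm = 2.5, minSeparationUm = 10.5,
                           pixelSizeUm = 1.5, noiseSigma = 0,
                           seed = 1) {
  if (length(shapeZYX) != 3 || any(shapeZYX < 2))
    stop("shapeZYX must be three integers >= 2")
  if (zStepUm <= 0 || pixelSizeUm <= 0)
    stop("zStepUm and pixelSizeUm must be positive")
  if (nNucleiInMask < 0 || nNucleiOutMask < 0 || nTunelPuncta < 0)
    stop("counts must be non-negative")
  if (phh3Fraction < 0 || phh3Fraction > 1)
    stop("phh3Fraction must lie in [0, 1]")
  if (nucleusRadiusUm <= 0 || minSeparationUm <= 0)
    stop("nucleusRadiusUm and minSeparationUm must be positive")
  structure(list(shapeZYX = as.integer(shapeZYX), zStepUm = zStepUm,
                 nNucleiInMask = as.integer(nNucleiInMask),
                 nNucleiOutMask = as.integer(nNucleiOutMask),
                 phh3Fraction = phh3Fraction,
                 nTunelPuncta = as.integer(nTunelPuncta),
                 nucleusRadiusUm = nucleusRadiusUm,
                 minSeparationUm = minSeparationUm,
                 pixelSizeUm = pixelSizeUm, noiseSigma = noiseSigma,
                 seed = as.integer(seed)), class = "stackSimParams")
}

# Sample n points (um coordinates, rows x/y/z) satisfying `inside` and a
# hard-core minimum separation, by rejection against previously accepted
# points (which may include points from another compartment).
sampleHardcore <- function(n, boundsUm, inside, minSep, existing = NULL,
                           maxAttempts = max(20000L, 2000L * n)) {
  pts <- existing
  out <- matrix(NA_real_, n, 3)
  got <- 0L
  att <- 0L
  while (got < n) {
    att <- att + 1L
    if (att > maxAttempts)
      stop("nucleus packing infeasible: could not place ", n,
           " centres at min separation ", minSep, " um")
    cand <- c(runif(1, boundsUm[1, 1], boundsUm[1, 2]),
              runif(1, boundsUm[2, 1], boundsUm[2, 2]),
              runif(1, boundsUm[3, 1], boundsUm[3, 2]))
    if (!inside(cand)) next
    if (!is.null(pts) && nrow(pts) &&
        min(sqrt(colSums((t(pts) - cand)^2))) < minSep) next
    got <- got + 1L
    out[got, ] <- cand
    pts <- rbind(pts, cand)
  }
  out
}

# Paint a solid sphere (um geometry, anisotropic voxels) into `arr`.
paintSphere <- function(arr, centerUm, radiusUm, pxUm, zUm, value = 1) {
  d <- dim(arr)  # (ny, nx, nz)
  yr <- max(1, floor((centerUm[2] - radiusUm) / pxUm)):
        min(d[1], ceiling((centerUm[2] + radiusUm) / pxUm + 1))
  xr <- max(1, floor((centerUm[1] - radiusUm) / pxUm)):
        min(d[2], ceiling((centerUm[1] + radiusUm) / pxUm + 1))
  zr <- max(1, floor((centerUm[3] - radiusUm) / zUm)):
        min(d[3], ceiling((centerUm[3] + radiusUm) / zUm + 1))
  for (z in zr) {
    dz <- (z - 0.5) * zUm - centerUm[3]
    if (abs(dz) > radiusUm) next
    rSlice <- sqrt(radiusUm^2 - dz^2)
    yy <- (yr - 0.5) * pxUm - centerUm[2]
    xx <- (xr - 0.5) * pxUm - centerUm[1]
    dd <- sqrt(outer(yy^2, xx^2, "+"))
    sl <- arr[yr, xr, z]
    sl[dd <= rSlice] <- pmax(sl[dd <= rSlice], value)
    arr[yr, xr, z] <- sl
  }
  arr
}

#' Simulate a multi-channel confocal z-stack of an isolated heart
#'
#' The GFP channel is a filled ellipsoidal myocardial mask ("ventricle");
#' DAPI nuclei are solid spheres placed by hard-core rejection sampling
#' inside and outside that mask; a rounded fraction of in-mask nuclei is
#' copied into the PHH3 channel; TUNEL puncta are small bright spots inside
#' the heart region. All truth counts are exact by construction.
#'
#' @param params a \code{\link{stackSimParams}} list
#' @return list with \code{scene} (a \linkS4class{ZStackScene} with
#'   channels gfp, dapi, phh3, tunel) and \code{truth}: \code{vct},
#'   \code{vcm}, \code{tunel}, the logical ventricle \code{mask} and the
#'   nucleus centre tables (um coordinates)
#' @export
simulateHeartStack <- function(params = stackSimParams()) {
  stopifnot(inherits(params, "stackSimParams"))
  p <- params
  set.seed(p$seed)
  nz <- p$shapeZYX[1]; ny <- p$shapeZYX[2]; nx <- p$shapeZYX[3]
  px <- p$pixelSizeUm; zs <- p$zStepUm
  fieldUm <- c(nx * px, ny * px, nz * zs)   # x, y, z extents
  ctr <- fieldUm / 2
  semi <- c(0.40 * fieldUm[1], 0.40 * fieldUm[2], 0.42 * fieldUm[3])

  insideEllipsoid <- function(ptUm, shrinkUm = 0) {
    sum(((ptUm - ctr) / (semi - shrinkUm))^2) <= 1
  }

  # voxel-centre mask of the ellipsoid (the ground-truth ventricle mask)
  xs <- (seq_len(nx) - 0.5) * px; ys <- (seq_len(ny) - 0.5) * px
  zsUm <- (seq_len(nz) - 0.5) * zs
  mask <- array(FALSE, c(ny, nx, nz))
  for (z in seq_len(nz)) {
    e <- outer(((ys - ctr[2]) / semi[2])^2, ((xs - ctr[1]) / semi[1])^2, "+") +
      ((zsUm[z] - ctr[3]) / semi[3])^2
    mask[, , z] <- e <= 1
  }

  pad <- p$nucleusRadiusUm + 1
  bounds <- rbind(c(pad, fieldUm[1] - pad),
                  c(pad, fieldUm[2] - pad),
                  c(pad, fieldUm[3] - pad))
  inPts <- if (p$nNucleiInMask > 0)
    sampleHardcore(p$nNucleiInMask, bounds,
                   function(q) insideEllipsoid(q, shrinkUm = p$nucleusRadiusUm),
                   p$minSeparationUm)
  else matrix(numeric(), 0, 3)
  outPts <- if (p$nNucleiOutMask > 0)
    sampleHardcore(p$nNucleiOutMask, bounds,
                   function(q) !insideEllipsoid(q, shrinkUm = -p$minSeparationUm),
                   p$minSeparationUm, existing = inPts)
  else matrix(numeric(), 0, 3)

  gfp <- array(0, c(ny, nx, nz)); gfp[mask] <- 0.8
  dapi <- array(0, c(ny, nx, nz))
  for (i in seq_len(nrow(inPts)))
    dapi <- paintSphere(dapi, inPts[i, ], p$nucleusRadiusUm, px, zs, 0.9)
  for (i in seq_len(nrow(outPts)))
    dapi <- paintSphere(dapi, outPts[i, ], p$nucleusRadiusUm, px, zs, 0.9)

  nMit <- round(p$phh3Fraction * p$nNucleiInMask)
  mitIdx <- if (nMit > 0) sample(seq_len(nrow(inPts)), nMit) else integer()
  phh3 <- array(0, c(ny, nx, nz))
  for (i in mitIdx)
    phh3 <- paintSphere(phh3, inPts[i, ], p$nucleusRadiusUm, px, zs, 0.9)

  # TUNEL puncta: small spots inside the mask, z snapped to slice centres
  # so a punctum always intersects at least one slice; kept clear of each
  # other but allowed to overlap nuclei (apoptotic nuclei in vivo).
  tunel <- array(0, c(ny, nx, nz))
  tunelPts <- matrix(numeric(), 0, 3)
  if (p$nTunelPuncta > 0) {
    tunelPts <- sampleHardcore(p$nTunelPuncta, bounds,
                               function(q) insideEllipsoid(q, shrinkUm = 2),
                               max(4, p$minSeparationUm))
    tunelPts[, 3] <- (round(tunelPts[, 3] / zs - 0.5) + 0.5) * zs
    for (i in seq_len(nrow(tunelPts)))
      tunel <- paintSphere(tunel, tunelPts[i, ], 1.6, px, zs, 0.95)
  }

  chans <- list(gfp = gfp, dapi = dapi, phh3 = phh3, tunel = tunel)
  if (p$noiseSigma > 0)
    chans <- lapply(chans, function(a)
      pmin(pmax(a + array(rnorm(length(a), 0, p$noiseSigma), dim(a)), 0), 1))

  scene <- new("ZStackScene", channels = chans, zStepUm = zs,
               pixelSizeUm = px)
  list(scene = scene,
       truth = list(vct = p$nNucleiInMask, vcm = as.integer(nMit),
                    tunel = p$nTunelPuncta, mask = mask,
                    nucleiInUm = inPts, nucleiOutUm = outPts,
                    mitoticIdx = mitIdx, tunelUm = tunelPts))
}
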