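#' @import methods
#' @importFrom stats lm.fit median sd var aov t.test rnorm runif
#' @importFrom utils head tail write.csv read.csv combn
NULL

#' VideoSequence: an ordered stack of 2-D frames with timing and scale
#'
#' The substrate for gating and functional quantification: frames are stored
#' as a numeric array of dimension (ny, nx, n_frames) with intensities in
#' [0, 1], together with strictly increasing per-frame timestamps (ms), the
#' pixel size (micrometres per pixel) and the nominal acquisition frame rate
#' (frames per second).
#'
#' @slot frames numeric array, dim (ny, nx, n_frames)
#' @slot timestampsMs numeric, one strictly increasing timestamp per frame
#' @slot pixelSizeUm positive scalar, micrometres per pixel
#' @slot fps positive scalar, frames per second
#' @exportClass VideoSequence
setClass("VideoSequence",
  representation(
    frames = "array",
    timestampsMs = "numeric",
    pixelSizeUm = "numeric",
    fps = "numeric"
  )
)

setValidity("VideoSequence", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (length(d) != 3L)
    msg <- c(msg, "frames must be a 3-D array (ny, nx, n_frames)")
  else if (length(object@timestampsMs) != d[3])
    msg <- c(msg, "timestampsMs length must equal the number of frames")
  if (length(object@timestampsMs) > 1L &&
      any(diff(object@timestampsMs) <= 0))
    msg <- c(msg, "timestampsMs must be strictly increasing")
  if (length(object@pixelSizeUm) != 1L || object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be a positive scalar")
  if (length(object@fps) != 1L || object@fps <= 0)
    msg <- c(msg, "fps must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' ReferenceSet: one cardiac cycle of frames with assigned phases
#'
#' A phase-matching dictionary built from a single cardiac cycle. Frame i
#' carries phase \code{refPhases[i]} in [0, 2*pi), assigned uniformly by time
#' within the cycle, with phase 0 at the anchor frame (by convention
#' end-diastole when the anchor is chosen as the maximal-area frame).
#'
#' @slot refFrames numeric array, dim (ny, nx, n_ref)
#' @slot refPhases numeric in [0, 2*pi), strictly increasing, first is 0
#' @slot periodMs positive scalar, cardiac period (ms)
#' @slot targetPhase scalar in [0, 2*pi), the phase triggers aim at
#' @slot pixelSizeUm positive scalar
#' @exportClass ReferenceSet
setClass("ReferenceSet",
  representation(
    refFrames = "array",
    refPhases = "numeric",
    periodMs = "numeric",
    targetPhase = "numeric",
    pixelSizeUm = "numeric"
  )
)

setValidity("ReferenceSet", function(object) {
  msg <- character()
  d <- dim(object@refFrames)
  if (length(d) != 3L)
    msg <- c(msg, "refFrames must be a 3-D array")
  else if (length(object@refPhases) != d[3])
    msg <- c(msg, "refPhases length must equal the number of reference frames")
  ph <- object@refPhases
  if (length(ph)) {
    if (abs(ph[1]) > 1e-12)
      msg <- c(msg, "first reference phase must be 0")
    if (any(diff(ph) <= 0))
      msg <- c(msg, "refPhases must be strictly increasing")
    if (any(ph < 0 | ph >= 2 * pi))
      msg <- c(msg, "refPhases must lie in [0, 2*pi)")
  }
  if (object@periodMs <= 0)
    msg <- c(msg, "periodMs must be positive")
  if (object@targetPhase < 0 || object@targetPhase >= 2 * pi)
    msg <- c(msg, "targetPhase must lie in [0, 2*pi)")
  if (length(msg)) msg else TRUE
})

#' BeatSeries: per-frame ventricular area with beat boundaries
#'
#' @slot areaUm2 numeric, segmented ventricle area per frame (um^2)
#' @slot timestampsMs numeric, per-frame timestamps (ms)
#' @slot beatBoundaries integer, frame indices (1-based) of diastolic maxima
#' @slot perBeat data.frame with columns Ad_um2, As_um2 (one row per beat)
#' @exportClass BeatSeries
setClass("BeatSeries",
  representation(
    areaUm2 = "numeric",
    timestampsMs = "numeric",
    beatBoundaries = "integer",
    perBeat = "data.frame"
  )
)

setValidity("BeatSeries", function(object) {
  msg <- character()
  if (length(object@areaUm2) != length(object@timestampsMs))
    msg <- c(msg, "areaUm2 and timestampsMs must have equal length")
  b <- object@beatBoundaries
  if (length(b) > 1L && any(diff(b) <= 0))
    msg <- c(msg, "beatBoundaries must be strictly increasing")
  pb <- object@perBeat
  if (nrow(pb)) {
    if (!all(c("Ad_um2", "As_um2") %in% names(pb)))
      msg <- c(msg, "perBeat needs columns Ad_um2, As_um2")
    else if (any(pb$As_um2 > pb$Ad_um2 + 1e-9))
      msg <- c(msg, "systolic area cannot exceed diastolic area within a beat")
  }
  if (length(msg)) msg else TRUE
})

#' ZStackScene: a multi-channel confocal z-stack with voxel geometry
#'
#' Channels are named 3-D arrays of identical dimension (ny, nx, nz);
#' canonical names are "gfp" (myocardium), "dapi" (nuclei), and optionally
#' "phh3" (mitosis marker) and "tunel" (apoptosis puncta).
#'
#' @slot channels named list of numeric 3-D arrays, all the same dim
#' @slot zStepUm positive scalar, z spacing (um)
#' @slot pixelSizeUm positive scalar, lateral pixel size (um)
#' @exportClass ZStackScene
setClass("ZStackScene",
  representation(
    channels = "list",
    zStepUm = "numeric",
    pixelSizeUm = "numeric"
  )
)

setValidity("ZStackScene", function(object) {
  msg <- character()
  ch <- object@channels
  if (!length(ch) || is.null(names(ch)) || any(!nzchar(names(ch))))
    msg <- c(msg, "channels must be a non-empty named list")
  dims <- lapply(ch, dim)
  if (length(ch) && any(vapply(dims, length, 1L) != 3L))
    msg <- c(msg, "every channel must be a 3-D array")
  else if (length(ch) > 1L &&
           !all(vapply(dims[-1], identical, TRUE, dims[[1]])))
    msg <- c(msg, "all channels must share one shape")
  if (object@zStepUm <= 0) msg <- c(msg, "zStepUm must be positive")
  if (object@pixelSizeUm <= 0) msg <- c(msg, "pixelSizeUm must be positive")
  if (length(msg)) msg else TRUE
})
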