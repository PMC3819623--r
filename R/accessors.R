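# Accessors, constructors and show methods for the core classes.

#' Construct a VideoSequence
#'
#' @param frames numeric 3-D array (ny, nx, n_frames), intensities in [0, 1]
#' @param fps frames per second
#' @param pixelSizeUm micrometres per pixel
#' @param timestampsMs optional per-frame timestamps (ms); defaults to
#'   regular sampling at \code{fps} starting at 0
#' @return a \linkS4class{VideoSequence}
#' @export
VideoSequence <- function(frames, fps, pixelSizeUm,
                          timestampsMs = NULL) {
  frames <- as.array(frames)
  if (is.null(timestampsMs))
    timestampsMs <- (seq_len(dim(frames)[3]) - 1) * 1000 / fps
  new("VideoSequence", frames = frames, timestampsMs = as.numeric(timestampsMs),
      pixelSizeUm = as.numeric(pixelSizeUm), fps = as.numeric(fps))
}

#' Number of frames in a video or reference set
#' @param x a VideoSequence or ReferenceSet
#' @return integer frame count
#' @export
nFrames <- function(x) {
  if (is(x, "VideoSequence")) return(dim(x@frames)[3])
  if (is(x, "ReferenceSet")) return(dim(x@refFrames)[3])
  stop("nFrames is defined for VideoSequence and ReferenceSet")
}

#' Extract the frame array
#' @param x a VideoSequence
#' @param i optional frame index; if given, the single 2-D frame is returned
#' @return the full (ny, nx, n) array, or one 2-D frame
#' @export
frames <- function(x, i = NULL) {
  stopifnot(is(x, "VideoSequence"))
  if (is.null(i)) x@frames else x@frames[, , i]
}

#' Per-frame timestamps in milliseconds
#' @param x a VideoSequence or BeatSeries
#' @return numeric vector of timestamps (ms)
#' @export
timestampsMs <- function(x) x@timestampsMs

#' Pixel size in micrometres
#' @param x a VideoSequence, ReferenceSet or ZStackScene
#' @return scalar pixel size (um/px)
#' @export
pixelSizeUm <- function(x) x@pixelSizeUm

#' Frame rate in frames per second
#' @param x a VideoSequence
#' @return scalar fps
#' @export
frameRate <- function(x) x@fps

#' Reference phases of a ReferenceSet
#' @param x a ReferenceSet
#' @return numeric phases in [0, 2*pi)
#' @export
refPhases <- function(x) x@refPhases

#' Target phase stored in a ReferenceSet
#' @param x a ReferenceSet
#' @return scalar phase in [0, 2*pi)
#' @export
targetPhase <- function(x) x@targetPhase

#' Cardiac period stored in a ReferenceSet
#' @param x a ReferenceSet
#' @return scalar period (ms)
#' @export
periodMs <- function(x) x@periodMs

#' Per-frame ventricular area of a BeatSeries
#' @param x a BeatSeries
#' @return numeric vector (um^2)
#' @export
areaUm2 <- function(x) x@areaUm2

#' Diastolic-maximum frame indices of a BeatSeries
#' @param x a BeatSeries
#' @return integer vector of 1-based frame indices
#' @export
beatBoundaries <- function(x) x@beatBoundaries

#' Per-beat diastolic/systolic extrema
#' @param x a BeatSeries
#' @return data.frame with columns Ad_um2, As_um2
#' @export
perBeat <- function(x) x@perBeat

#' Named channel array of a ZStackScene
#' @param x a ZStackScene
#' @param name channel name, e.g. "gfp", "dapi", "phh3", "tunel"
#' @return numeric 3-D array
#' @export
channel <- function(x, name) {
  stopifnot(is(x, "ZStackScene"))
  if (!name %in% names(x@channels))
    stop("no channel named '", name, "'")
  x@channels[[name]]
}

#' Channel names of a ZStackScene
#' @param x a ZStackScene
#' @return character vector
#' @export
channelNames <- function(x) names(x@channels)

#' Axial step of a ZStackScene
#' @param x a ZStackScene
#' @return scalar z spacing (um)
#' @export
zStepUm <- function(x) x@zStepUm

setMethod("show", "VideoSequence", function(object) {
  d <- dim(object@frames)
  cat("VideoSequence:", d[3], "frames of", d[1], "x", d[2], "px |",
      format(object@fps), "fps |", format(object@pixelSizeUm), "um/px |",
      sprintf("%.1f ms span\n", diff(range(object@timestampsMs))))
})

setMethod("show", "ReferenceSet", function(object) {
  d <- dim(object@refFrames)
  cat("ReferenceSet:", d[3], "reference frames | period",
      sprintf("%.2f ms", object@periodMs), "| target phase",
      sprintf("%.3f rad\n", object@targetPhase))
})

setMethod("show", "BeatSeries", function(object) {
  cat("BeatSeries:", length(object@areaUm2), "frames |",
      nrow(object@perBeat), "beats |",
      if (length(object@areaUm2))
        sprintf("area %.0f-%.0f um^2\n", min(object@areaUm2),
                max(object@areaUm2)) else "\n")
})

setMethod("show", "ZStackScene", function(object) {
  d <- dim(object@channels[[1]])
  cat("ZStackScene:", paste(names(object@channels), collapse = "/"),
      "|", d[1], "x", d[2], "x", d[3], "voxels | z step",
      format(object@zStepUm), "um |", format(object@pixelSizeUm), "um/px\n")
})
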