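# TIFF / CSV / YAML interchange: multi-page TIFF for videos (one page per
# frame) and z-stacks (one page per slice per channel file), sidecar
# ground-truth CSV and a YAML echo of the generating configuration.

#' Write a video as a multi-page TIFF
#'
#' @param video a \linkS4class{VideoSequence}
#' @param path output .tif path
#' @return \code{path}, invisibly
#' @export
writeVideoTiff <- function(video, path) {
  stopifnot(is(video, "VideoSequence"))
  pages <- lapply(seq_len(nFrames(video)), function(i) video@frames[, , i])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF (or a directory of single-frame TIFFs) as a video
#'
#' @param path a .tif file, or a directory whose *.tif files are frames in
#'   lexicographic order
#' @param fps frame rate to attach (frames/s)
#' @param pixelSizeUm pixel size to attach (um/px)
#' @return a \linkS4class{VideoSequence}
#' @export
readVideoTiff <- function(path, fps, pixelSizeUm) {
  pages <- if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE))
    if (!length(files)) stop("no .tif frames found in ", path)
    lapply(files, function(f) tiff::readTIFF(f))
  } else {
    tiff::readTIFF(path, all = TRUE)
  }
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  arr <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  VideoSequence(arr, fps = fps, pixelSizeUm = pixelSizeUm)
}

#' Write a z-stack scene as per-channel multi-page TIFFs
#'
#' Each channel becomes \code{<prefix>_<channel>.tif} with one page per
#' z-slice.
#'
#' @param scene a \linkS4class{ZStackScene}
#' @param prefix output path prefix
#' @return named character vector of written files, invisibly
#' @export
writeStackTiff <- function(scene, prefix) {
  stopifnot(is(scene, "ZStackScene"))
  files <- vapply(channelNames(scene), function(ch) {
    a <- channel(scene, ch)
    pages <- lapply(seq_len(dim(a)[3]), function(z) a[, , z])
    f <- paste0(prefix, "_", ch, ".tif")
    tiff::writeTIFF(pages, f, bits.per.sample = 16L)
    f
  }, character(1))
  invisible(files)
}

#' Read per-channel multi-page TIFFs as a z-stack scene
#'
#' @param files named character vector: channel name -> .tif path
#' @param zStepUm axial spacing (um)
#' @param pixelSizeUm lateral pixel size (um)
#' @return a \linkS4class{ZStackScene}
#' @export
readStackTiff <- function(files, zStepUm, pixelSizeUm) {
  stopifnot(length(names(files)) == length(files))
  chans <- lapply(files, function(f) {
    pages <- tiff::readTIFF(f, all = TRUE)
    pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1]
                    else p)
    array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  })
  new("ZStackScene", channels = chans, zStepUm = zStepUm,
      pixelSizeUm = pixelSizeUm)
}

#' Write the ground-truth sidecar for a simulated heart video
#'
#' CSV columns: frame, time_ms, phase_rad, area_um2; plus a YAML echo of
#' the generating parameters next to it.
#'
#' @param sim result of \code{\link{simulateHeartVideo}}
#' @param csvPath output CSV path; the YAML echo is written alongside as
#'   \code{<csvPath>.yaml}
#' @return \code{csvPath}, invisibly
#' @export
writeHeartTruth <- function(sim, csvPath) {
  tr <- sim$truth
  df <- data.frame(frame = seq_along(tr$phasePerFrame),
                   time_ms = timestampsMs(sim$video),
                   phase_rad = tr$phasePerFrame,
                   area_um2 = tr$areaPerFrame)
  write.csv(df, csvPath, row.names = FALSE)
  pr <- tr$params
  yaml::write_yaml(pr[!vapply(pr, is.null, TRUE)],
                   paste0(csvPath, ".yaml"))
  invisible(csvPath)
}
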