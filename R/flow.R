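# Caudal-vein blood-flow velocimetry: detect erythrocytes as bright blobs
# per frame, link them across frames by gated nearest-neighbour matching
# (mirroring the manual frame-by-frame procedure), and average per-frame
# displacements of the longest tracks into a mean cell velocity (um/s).

#' Detect erythrocyte centroids in a single frame
#'
#' Bright blobs above an automatic (Otsu) threshold whose pixel area lies
#' within configured bounds; returns their intensity-weighted centroids.
#'
#' @param frame 2-D numeric intensity array
#' @param minAreaPx,maxAreaPx admissible blob area bounds (pixels)
#' @return data.frame with columns x, y (1-based pixel coordinates); empty
#'   when nothing is detected
#' @export
detectCells <- function(frame, minAreaPx = 4, maxAreaPx = 400) {
  frame <- as.matrix(frame)
  empty <- data.frame(x = numeric(), y = numeric())
  if (diff(range(frame)) < 0.05) return(empty)
  thr <- otsuThreshold(frame)
  bw <- frame > thr
  if (!any(bw)) return(empty)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw)))
  counts <- tabulate(as.integer(lab))
  keep <- which(counts >= minAreaPx & counts <= maxAreaPx)
  if (!length(keep)) return(empty)
  idx <- which(array(lab %in% keep, dim(lab)), arr.ind = TRUE)
  l <- lab[cbind(idx[, 1], idx[, 2])]
  w <- frame[cbind(idx[, 1], idx[, 2])]
  sw <- tapply(w, l, sum)
  data.frame(
    x = as.numeric(tapply(w * idx[, 2], l, sum) / sw),
    y = as.numeric(tapply(w * idx[, 1], l, sum) / sw))
}

#' Link per-frame detections into cell tracks
#'
#' Greedy gated nearest-neighbour linking: each track is extended by the
#' closest unclaimed detection in the next frame within \code{maxDispPx};
#' unmatched detections start new tracks, and tracks shorter than
#' \code{minLength} are dropped.
#'
#' @param detections list of data.frames (x, y), one per frame
#' @param maxDispPx gating distance in pixels
#' @param minLength minimum track length (positions) to keep
#' @return list of tracks, each a data.frame (frame, x, y)
#' @export
linkTracks <- function(detections, maxDispPx, minLength = 2L) {
  if (length(detections) < 2L) return(list())
  open <- list()    # active tracks
  done <- list()
  for (f in seq_along(detections)) {
    det <- detections[[f]]
    claimed <- rep(FALSE, nrow(det))
    keepOpen <- logical(length(open))
    for (tr in seq_along(open)) {
      last <- tail(open[[tr]], 1)
      if (nrow(det)) {
        dd <- sqrt((det$x - last$x)^2 + (det$y - last$y)^2)
        dd[claimed] <- Inf
        j <- which.min(dd)
        if (length(j) && is.finite(dd[j]) && dd[j] <= maxDispPx) {
          open[[tr]] <- rbind(open[[tr]],
                              data.frame(frame = f, x = det$x[j], y = det$y[j]))
          claimed[j] <- TRUE
          keepOpen[tr] <- TRUE
          next
        }
      }
      done[[length(done) + 1L]] <- open[[tr]]
    }
    open <- open[keepOpen]
    for (j in which(!claimed))
      open[[length(open) + 1L]] <- data.frame(frame = f, x = det$x[j],
                                              y = det$y[j])
  }
  done <- c(done, open)
  done[vapply(done, nrow, 1L) >= minLength]
}

#' Mean erythrocyte velocity from tracks
#'
#' Selects the \code{nCells} longest tracks, requires each to span at
#' least \code{nFramesReq} positions (the measurement protocol: four cells
#' over ten frames), and returns the mean over those tracks of the mean
#' per-frame displacement x fps x pixel size.
#'
#' @param tracks list of tracks from \code{\link{linkTracks}}
#' @param pixelSizeUm micrometres per pixel
#' @param fps frames per second
#' @param nCells number of tracks to average (default 4)
#' @param nFramesReq minimum positions per selected track (default 10)
#' @return mean velocity in um/s
#' @export
meanVelocity <- function(tracks, pixelSizeUm, fps, nCells = 4L,
                         nFramesReq = 10L) {
  lens <- vapply(tracks, nrow, 1L)
  qual <- tracks[lens >= nFramesReq]
  if (length(qual) < nCells)
    stop("insufficient tracks: need ", nCells, " tracks of >= ",
         nFramesReq, " positions, found ", length(qual))
  qual <- qual[order(vapply(qual, nrow, 1L), decreasing = TRUE)]
  sel <- qual[seq_len(nCells)]
  v <- vapply(sel, function(tr) {
    steps <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
    mean(steps) * fps * pixelSizeUm
  }, numeric(1))
  mean(v)
}

#' Caudal-vein blood-flow velocity from a video
#'
#' Convenience wrapper: detect per frame, link, and average the velocity
#' of the longest tracks.
#'
#' @param video a \linkS4class{VideoSequence}
#' @param expectedDispPx expected per-frame displacement (px) used to set
#'   the linking gate (1.5 x this value); when NULL it is estimated from
#'   the median nearest-detection displacement between consecutive frames
#' @param nCells,nFramesReq selection rule passed to
#'   \code{\link{meanVelocity}}
#' @return mean velocity in um/s
#' @export
caudalVeinFlow <- function(video, expectedDispPx = NULL, nCells = 4L,
                           nFramesReq = 10L) {
  stopifnot(is(video, "VideoSequence"))
  dets <- lapply(seq_len(nFrames(video)), function(i)
    detectCells(video@frames[, , i]))
  if (is.null(expectedDispPx)) {
    d01 <- vapply(seq_len(length(dets) - 1L), function(f) {
      a <- dets[[f]]; b <- dets[[f + 1L]]
      if (!nrow(a) || !nrow(b)) return(NA_real_)
      median(vapply(seq_len(nrow(a)), function(i)
        min(sqrt((b$x - a$x[i])^2 + (b$y - a$y[i])^2)), numeric(1)))
    }, numeric(1))
    expectedDispPx <- max(1, median(d01, na.rm = TRUE))
  }
  tracks <- linkTracks(dets, maxDispPx = 1.5 * expectedDispPx,
                       minLength = 2L)
  meanVelocity(tracks, pixelSizeUm = video@pixelSizeUm, fps = video@fps,
               nCells = nCells, nFramesReq = nFramesReq)
}
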