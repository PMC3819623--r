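# Heart-function quantification from ventricle-area time series: automatic
# ventricle segmentation per frame, beat detection on the area signal, and
# the derived heart rate (bpm), area-based ejection fraction (%) and
# ventricle diastolic area (um^2).

#' Segment the ventricle in a single frame
#'
#' Binary mask = largest connected component above an automatic (Otsu)
#' intensity threshold, holes filled; area = pixel count x pixelSizeUm^2.
#' The threshold adapts to the frame's own intensity range, so multiplying
#' all intensities by a positive constant leaves the mask unchanged.
#'
#' @param frame 2-D numeric intensity array
#' @param pixelSizeUm micrometres per pixel
#' @param minForegroundFrac frames whose foreground fraction after
#'   thresholding is below this are treated as blank (segmentation error)
#' @param frameIndex optional index used in error messages
#' @return list with \code{mask} (logical matrix) and \code{areaUm2}
#' @export
segmentVentricle <- function(frame, pixelSizeUm, minForegroundFrac = 1e-3,
                             frameIndex = NA) {
  frame <- as.matrix(frame)
  rng <- range(frame)
  if (diff(rng) < 1e-3)
    stop("segmentation failed on frame ", frameIndex,
         ": blank frame (no intensity contrast)")
  thr <- otsuThreshold(frame)
  bw <- frame > thr
  if (mean(bw) < minForegroundFrac)
    stop("segmentation failed on frame ", frameIndex, ": empty mask")
  lab <- EBImage::bwlabel(EBImage::Image(bw))
  counts <- tabulate(as.integer(lab))
  biggest <- which.max(counts)
  mask <- EBImage::fillHull(EBImage::Image(lab == biggest))
  mask <- EBImage::imageData(mask) > 0
  list(mask = mask, areaUm2 = sum(mask) * pixelSizeUm^2)
}

#' Build a per-frame area series with detected beats
#'
#' Segments every frame, then finds diastolic maxima by peak detection on
#' the area signal with a minimum peak distance of 0.6 x the estimated
#' cardiac period (preventing double-counting of noisy maxima). Each beat
#' spans consecutive diastolic maxima; within it, Ad is the maximum and As
#' the minimum area.
#'
#' @param video a \linkS4class{VideoSequence} covering >= 2 cycles
#' @param periodMs optional known period (ms); estimated from the area
#'   signal's autocorrelation when NULL
#' @return a \linkS4class{BeatSeries}
#' @export
buildBeatSeries <- function(video, periodMs = NULL) {
  stopifnot(is(video, "VideoSequence"))
  n <- nFrames(video)
  area <- vapply(seq_len(n), function(i)
    segmentVentricle(video@frames[, , i], video@pixelSizeUm,
                     frameIndex = i)$areaUm2, numeric(1))
  tMs <- video@timestampsMs
  fps <- video@fps

  if (diff(range(area)) / max(area) < 0.02)
    stop("insufficient beats: ventricular area is constant")

  if (is.null(periodMs)) periodMs <- areaSignalPeriodMs(area, fps)
  minDist <- max(2L, floor(0.6 * periodMs / 1000 * fps))
  ac <- area - min(area)
  pk <- pracma::findpeaks(ac, minpeakdistance = minDist,
                          minpeakheight = min(ac) + 0.5 * diff(range(ac)),
                          peakpat = "[+]{1,}[0]*[-]{1,}")  # allow plateaus
  if (is.null(pk) || nrow(pk) < 2)
    stop("insufficient beats: fewer than 2 diastolic maxima detected")
  bounds <- sort(as.integer(pk[, 2]))
  # pixel-count areas are quantized, so diastole can be a flat run of tied
  # values; centre each peak on its plateau to avoid edge jitter in HR
  bounds <- vapply(bounds, function(b) {
    l <- b; while (l > 1L && ac[l - 1L] == ac[b]) l <- l - 1L
    r <- b; while (r < length(ac) && ac[r + 1L] == ac[b]) r <- r + 1L
    as.integer(round((l + r) / 2))
  }, integer(1))
  bounds <- unique(bounds)
  # edge beats may be partial: a truncated diastole near the series ends
  # leaves only a jitter micro-peak there, so exclude the guard zone
  guard <- ceiling(0.3 * periodMs / 1000 * fps)
  bounds <- bounds[bounds > guard & bounds <= length(ac) - guard]
  if (length(bounds) < 2)
    stop("insufficient beats: fewer than 2 diastolic maxima detected")

  perBeat <- do.call(rbind, lapply(seq_len(length(bounds) - 1L), function(b) {
    seg <- area[bounds[b]:bounds[b + 1L]]
    data.frame(Ad_um2 = max(seg), As_um2 = min(seg))
  }))
  new("BeatSeries", areaUm2 = area, timestampsMs = tMs,
      beatBoundaries = bounds, perBeat = perBeat)
}

# Period (ms) of a quasi-periodic area signal from its autocorrelation
# peak, refined by quadratic interpolation.
areaSignalPeriodMs <- function(area, fps, searchRangeMs = c(200, 1200)) {
  x <- area - mean(area)
  n <- length(x)
  lagLo <- max(2L, floor(searchRangeMs[1] / 1000 * fps))
  lagHi <- min(n - 3L, ceiling(searchRangeMs[2] / 1000 * fps))
  if (lagHi < lagLo + 1) stop("series too short to estimate a period")
  ac <- vapply(lagLo:lagHi, function(L)
    sum(x[1:(n - L)] * x[(1 + L):n]) / (n - L), numeric(1))
  # the fundamental, not a multiple of it: smallest-lag local peak whose
  # height is within 5% of the global maximum of the autocorrelation
  best <- firstDominantPeak(ac)
  off <- if (best == 1 || best == length(ac)) 0 else
    quadPeakOffset(ac[best - 1], ac[best], ac[best + 1])
  (lagLo + best - 1 + off) / fps * 1000
}

# Index of the smallest-lag local maximum within tolFrac of the global
# maximum of a (self-)similarity curve; guards against locking onto an
# integer multiple of the true period.
firstDominantPeak <- function(s, tolFrac = 0.05) {
  gmax <- max(s)
  tol <- tolFrac * diff(range(s))
  n <- length(s)
  for (i in seq_len(n)) {
    lo <- if (i == 1) -Inf else s[i - 1]
    hi <- if (i == n) -Inf else s[i + 1]
    if (s[i] >= lo && s[i] >= hi && s[i] >= gmax - tol) return(i)
  }
  which.max(s)
}

#' Heart rate from detected beats
#'
#' 60000 / mean inter-peak interval (ms) of the diastolic maxima.
#'
#' @param series a \linkS4class{BeatSeries}
#' @return heart rate in beats per minute
#' @export
heartRate <- function(series) {
  stopifnot(is(series, "BeatSeries"))
  b <- series@beatBoundaries
  if (length(b) < 2)
    stop("insufficient beats: need >= 2 diastolic maxima for a heart rate")
  60000 / mean(diff(series@timestampsMs[b]))
}

#' Area-based ejection fraction
#'
#' EF (\%) = (Ad - As) / Ad x 100, from the diastolic and systolic
#' projected areas.
#'
#' @param AdUm2 diastolic (maximal) area, um^2
#' @param AsUm2 systolic (minimal) area, um^2
#' @return ejection fraction in percent
#' @examples
#' ejectionFraction(10, 8)  # 20
#' @export
ejectionFraction <- function(AdUm2, AsUm2) {
  if (any(AdUm2 <= 0)) stop("diastolic area must be positive")
  if (any(AsUm2 < 0)) stop("systolic area must be non-negative")
  if (any(AsUm2 > AdUm2))
    stop("systolic area exceeds diastolic area")
  (AdUm2 - AsUm2) / AdUm2 * 100
}

#' Mean ventricle diastolic area over beats
#'
#' @param series a \linkS4class{BeatSeries} with >= 1 complete beat
#' @return mean per-beat diastolic area (um^2)
#' @export
ventricleDiastolicArea <- function(series) {
  stopifnot(is(series, "BeatSeries"))
  if (!nrow(series@perBeat))
    stop("no complete beat in series")
  mean(series@perBeat$Ad_um2)
}

#' Full functional report for a heart video
#'
#' Convenience wrapper: builds the beat series and reports heart rate,
#' mean per-beat ejection fraction and ventricle diastolic area.
#'
#' @param video a \linkS4class{VideoSequence}
#' @param periodMs optional known period (ms)
#' @return data.frame with hr_bpm, ef_pct, vda_um2, n_beats
#' @export
cardiacReport <- function(video, periodMs = NULL) {
  series <- buildBeatSeries(video, periodMs = periodMs)
  efs <- ejectionFraction(series@perBeat$Ad_um2, series@perBeat$As_um2)
  data.frame(hr_bpm = heartRate(series),
             ef_pct = mean(efs),
             vda_um2 = ventricleDiastolicArea(series),
             n_beats = nrow(series@perBeat))
}
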