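# 3-D nucleus counting in multi-channel confocal z-stacks of isolated
# hearts: a GFP-derived myocardial mask restricts counting to ventricular
# cardiomyocytes; DAPI components give the total count (VCt), their
# PHH3-positive subset the mitotic count (VCm); TUNEL puncta are counted
# as 3-D spots within the heart region. All labeling is 3-D with
# 26-connectivity, so a nucleus spanning several z-slices counts once.

#' Ventricular myocardium mask from the GFP channel
#'
#' Automatic (Otsu) threshold, morphological closing, then the largest
#' 3-D connected component only — an automatic stand-in for the manual
#' exclusion of the atrium and bulbus arteriosus, which are disconnected
#' from the ventricle in isolated-heart stacks.
#'
#' @param gfp 3-D numeric array (ny, nx, nz)
#' @param closing logical: apply a 3x3x3 closing before labeling
#' @return logical 3-D array
#' @export
ventricleMask <- function(gfp, closing = TRUE) {
  stopifnot(length(dim(gfp)) == 3L)
  if (diff(range(gfp)) < 1e-3)
    stop("empty GFP channel: no myocardial signal to mask")
  bw <- gfp > otsuThreshold(gfp)
  if (!any(bw)) stop("empty ventricle mask after thresholding")
  if (closing) bw <- closing3D(bw)
  lab <- label3D(bw, connectivity = 26)
  counts <- tabulate(lab[lab > 0])
  lab == which.max(counts)
}

#' Count total ventricular cardiomyocyte nuclei (VCt)
#'
#' Thresholds the DAPI channel, restricts it to the myocardial mask,
#' labels 3-D connected components (26-connectivity) and counts those
#' whose volume falls in the admissible nucleus-volume window derived
#' from the configured nucleus radius +/- 50\%. Merged blobs (above the
#' window) are reported via attribute \code{nMerged}.
#'
#' @param dapi 3-D numeric array
#' @param mask logical 3-D ventricle mask
#' @param pixelSizeUm lateral pixel size (um)
#' @param zStepUm axial step (um)
#' @param nucleusRadiusUm nominal nucleus radius (um)
#' @return integer count, with attributes \code{labels} (the label array,
#'   for colocalization) and \code{kept} (label ids counted)
#' @export
countNuclei <- function(dapi, mask, pixelSizeUm, zStepUm,
                        nucleusRadiusUm = 2.5) {
  stopifnot(identical(dim(dapi), dim(mask)))
  thr <- otsuThreshold(dapi)
  bw <- (dapi > thr) & mask
  lab <- label3D(bw, connectivity = 26)
  nLab <- max(lab)
  if (nLab == 0L) {
    out <- 0L
    attr(out, "labels") <- lab; attr(out, "kept") <- integer()
    return(out)
  }
  voxUm3 <- pixelSizeUm^2 * zStepUm
  volUm3 <- tabulate(lab[lab > 0], nbins = nLab) * voxUm3
  vNom <- 4 / 3 * pi * nucleusRadiusUm^3
  win <- vNom * c(0.5, 1.5)^3
  kept <- which(volUm3 >= win[1] & volUm3 <= win[2])
  out <- length(kept)
  attr(out, "labels") <- lab
  attr(out, "kept") <- kept
  attr(out, "nMerged") <- sum(volUm3 > win[2])
  out
}

#' Count mitotic cardiomyocyte nuclei (VCm)
#'
#' A counted DAPI nucleus is mitotic when the mean PHH3 intensity over its
#' voxels exceeds \code{phh3Threshold}. PHH3 signal outside every DAPI
#' component is never counted (colocalization rule), so VCm <= VCt.
#'
#' @param phh3 3-D numeric array
#' @param vct result of \code{\link{countNuclei}} (carries the label
#'   array and the counted label ids)
#' @param phh3Threshold mean-intensity threshold for positivity
#' @return integer mitotic count
#' @export
countMitotic <- function(phh3, vct, phh3Threshold = 0.3) {
  lab <- attr(vct, "labels")
  kept <- attr(vct, "kept")
  if (is.null(lab) || !length(kept)) return(0L)
  stopifnot(identical(dim(phh3), dim(lab)))
  inLab <- lab > 0
  means <- tapply(phh3[inLab], lab[inLab], mean)
  pos <- as.integer(names(means)[means > phh3Threshold])
  length(intersect(pos, kept))
}

#' Count TUNEL puncta in the heart region
#'
#' 3-D spot detection: the TUNEL channel is thresholded inside a dilated
#' heart region, labeled in 3-D, and components passing a minimum voxel
#' size are counted as puncta (each punctum is the neighbourhood of one
#' local intensity maximum in noiseless renders).
#'
#' @param tunel 3-D numeric array
#' @param mask logical ventricle mask; dilated once to admit puncta on
#'   the heart surface
#' @param threshold absolute intensity threshold; NULL for Otsu
#' @param minVoxels minimum component size to count as a punctum
#' @return integer puncta count
#' @export
countTunel <- function(tunel, mask, threshold = NULL, minVoxels = 2L) {
  stopifnot(identical(dim(tunel), dim(mask)))
  region <- shiftReduce(mask, max)  # one-step 26-neighbour dilation
  if (diff(range(tunel)) < 1e-3) return(0L)
  thr <- threshold %||% otsuThreshold(tunel)
  bw <- (tunel > thr) & region
  lab <- label3D(bw, connectivity = 26)
  if (max(lab) == 0L) return(0L)
  sum(tabulate(lab[lab > 0]) >= minVoxels)
}

#' Full count report for a z-stack scene
#'
#' Runs mask construction, VCt, VCm and TUNEL counting on a
#' \linkS4class{ZStackScene} and reports the counts and mask volume.
#'
#' @param scene a \linkS4class{ZStackScene} with channels gfp and dapi
#'   (phh3, tunel optional)
#' @param nucleusRadiusUm nominal nucleus radius (um)
#' @param phh3Threshold PHH3 positivity threshold
#' @return data.frame with vct, vcm, tunel_puncta, mask_volume_um3
#' @export
countStack <- function(scene, nucleusRadiusUm = 2.5, phh3Threshold = 0.3) {
  stopifnot(is(scene, "ZStackScene"))
  mask <- ventricleMask(channel(scene, "gfp"))
  vct <- countNuclei(channel(scene, "dapi"), mask, scene@pixelSizeUm,
                     scene@zStepUm, nucleusRadiusUm)
  vcm <- if ("phh3" %in% channelNames(scene))
    countMitotic(channel(scene, "phh3"), vct, phh3Threshold) else NA_integer_
  tun <- if ("tunel" %in% channelNames(scene))
    countTunel(channel(scene, "tunel"), mask) else NA_integer_
  data.frame(vct = as.integer(vct), vcm = vcm, tunel_puncta = tun,
             mask_volume_um3 = sum(mask) * scene@pixelSizeUm^2 * scene@zStepUm)
}
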