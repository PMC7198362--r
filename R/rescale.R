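# Histogram-mode-anchored linear rescaling of the MP2RAGE UNI image and the
# T1 map, negative-voxel repair, and construction of the contrast-enhanced
# RATIO image.
#
# The calibration anchors the white-matter and CSF histogram modes of each
# modality to fixed reference intensities (Ref1 = 100 bright, Ref2 = 20
# dark). On the UNI image white matter is bright (wm -> Ref1, csf -> Ref2);
# on the T1 map the ordering is inverted (wm -> Ref2, csf -> Ref1). The
# RATIO image UNI_cal / T1map_cal then amplifies gray/white contrast.

#' Parameters of the anchored linear rescaling
#'
#' @param ref1 Target intensity of the bright anchor.
#' @param ref2 Target intensity of the dark anchor.
#' @param tissue_prob_threshold Probability cutoff defining high-confidence
#'   tissue voxels for mode estimation.
#' @param vessel_low_pct Lower exclusion percentile applied to T1-map
#'   intensities before mode estimation (vessels are dark on the T1 map).
#' @param vessel_high_pct Upper exclusion percentile applied to UNI
#'   intensities (vessels are bright on UNI).
#' @param ratio_cap_pct Percentile above which RATIO outliers are replaced by
#'   the mean of their sub-percentile neighbours.
#' @return An object of class `rescale_params`.
#' @export
rescale_params <- function(ref1 = 100, ref2 = 20,
                           tissue_prob_threshold = 0.9,
                           vessel_low_pct = 1, vessel_high_pct = 95,
                           ratio_cap_pct = 99) {
  stopifnot(ref1 > ref2, ref2 > 0,
            tissue_prob_threshold > 0, tissue_prob_threshold < 1,
            vessel_low_pct >= 0, vessel_high_pct <= 100,
            vessel_low_pct < vessel_high_pct,
            ratio_cap_pct > 0, ratio_cap_pct <= 100)
  structure(list(ref1 = ref1, ref2 = ref2,
                 tissue_prob_threshold = tissue_prob_threshold,
                 vessel_low_pct = vessel_low_pct,
                 vessel_high_pct = vessel_high_pct,
                 ratio_cap_pct = ratio_cap_pct),
            class = "rescale_params")
}

#' Histogram mode of a tissue's high-confidence voxels
#'
#' Collects intensities of voxels whose tissue probability exceeds the
#' threshold, excludes presumed vessel voxels (below the `vessel_low_pct`
#' percentile for the T1 map, above the `vessel_high_pct` percentile for
#' UNI), and returns the centre of the fullest of 256 equal-width histogram
#' bins (ties broken toward the lower bin).
#'
#' @param image,tissue_prob Volumes on a common grid.
#' @param params A [rescale_params()].
#' @param tissue `"csf"` or `"wm"` (used in error messages).
#' @param modality `"uni"` or `"t1map"` (selects the vessel exclusion side).
#' @param nbins Number of histogram bins.
#' @return The scalar mode estimate in input intensity units.
#' @export
estimate_tissue_mode <- function(image, tissue_prob, params = rescale_params(),
                                 tissue = c("csf", "wm"),
                                 modality = c("uni", "t1map"),
                                 nbins = 256L) {
  tissue <- match.arg(tissue)
  modality <- match.arg(modality)
  stopifnot(identical(dim(image), dim(tissue_prob)))
  x <- image[tissue_prob > params$tissue_prob_threshold]
  if (length(x) < 100)
    stop(sprintf("estimate_tissue_mode: only %d high-confidence %s voxels (need >= 100); check the tissue probability map",
                 length(x), tissue))
  x <- if (modality == "uni") {
    x[x <= stats::quantile(x, params$vessel_high_pct / 100)]
  } else {
    x[x >= stats::quantile(x, params$vessel_low_pct / 100)]
  }
  histogram_mode(x, nbins)
}

#' @keywords internal
histogram_mode <- function(x, nbins = 256L) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  counts <- tabulate(pmin(findInterval(x, breaks, rightmost.closed = TRUE),
                          nbins), nbins)
  i <- which.max(counts)              # first max = lower bin on ties
  (breaks[i] + breaks[i + 1L]) / 2
}

#' Linear scale factors anchoring tissue modes to the reference intensities
#'
#' Solves `mode * fact - shift` so that for UNI the white-matter mode maps to
#' `ref1` and the CSF mode to `ref2`, and for the T1 map the reverse. Both
#' anchor identities hold exactly by construction.
#'
#' @param wm_mode,csf_mode Histogram modes in input units.
#' @param params A [rescale_params()].
#' @param modality `"uni"` or `"t1map"`.
#' @return An object of class `scale_factors` with `fact`, `shift`,
#'   `wm_mode`, `csf_mode`, `modality`.
#' @examples
#' sf <- compute_scale_factors(3000, 1000, modality = "uni")
#' sf$fact                      # 0.04
#' 3000 * sf$fact - sf$shift    # the bright anchor, 100
#' 1000 * sf$fact - sf$shift    # the dark anchor, 20
#' @export
compute_scale_factors <- function(wm_mode, csf_mode,
                                  params = rescale_params(),
                                  modality = c("uni", "t1map")) {
  modality <- match.arg(modality)
  if (wm_mode == csf_mode)
    stop("compute_scale_factors: wm and csf modes are identical")
  r1 <- params$ref1; r2 <- params$ref2
  if (modality == "uni") {
    if (wm_mode <= csf_mode)
      stop("compute_scale_factors: UNI requires wm_mode > csf_mode; the tissue maps may be swapped")
    fact <- (r1 - r2) / (wm_mode - csf_mode)
    shift <- (csf_mode * r1 - wm_mode * r2) / (wm_mode - csf_mode)
  } else {
    if (csf_mode <= wm_mode)
      stop("compute_scale_factors: T1map requires csf_mode > wm_mode; the tissue maps may be swapped")
    fact <- (r1 - r2) / (csf_mode - wm_mode)
    shift <- (wm_mode * r1 - csf_mode * r2) / (csf_mode - wm_mode)
  }
  structure(list(fact = fact, shift = shift, wm_mode = wm_mode,
                 csf_mode = csf_mode, modality = modality,
                 ref1 = r1, ref2 = r2),
            class = "scale_factors")
}

#' @export
print.scale_factors <- function(x, ...) {
  cat(sprintf("%s scale factors: fact = %.6g, shift = %.6g (wm mode %.6g, csf mode %.6g)\n",
              x$modality, x$fact, x$shift, x$wm_mode, x$csf_mode))
  invisible(x)
}

#' Apply linear rescaling inside a brain mask
#'
#' @param image Input volume.
#' @param sf A [compute_scale_factors()] result.
#' @param brain_mask Binary volume; output is 0 outside it.
#' @return Rescaled volume (negatives not yet repaired).
#' @export
apply_rescale <- function(image, sf, brain_mask) {
  stopifnot(identical(dim(image), dim(brain_mask)))
  out <- (image * sf$fact - sf$shift) * (brain_mask > 0)
  out
}

#' Replace negative voxels by the mean of non-negative face neighbours
#'
#' Single pass over the original values: every masked voxel with a negative
#' value is replaced by the mean of its non-negative 6-connected masked
#' neighbours; a negative voxel with no such neighbour is set to 0.
#'
#' @param image Rescaled volume.
#' @param brain_mask Binary volume.
#' @return Repaired volume.
#' @export
repair_negative_voxels <- function(image, brain_mask) {
  m <- brain_mask > 0
  bad <- m & image < 0
  if (!any(bad)) return(image)
  nb <- neighbour_mean(image, m & image >= 0)
  out <- image
  out[bad] <- ifelse(nb$count[bad] > 0, nb$sum[bad] / nb$count[bad], 0)
  out
}

#' RATIO image with outlier capping
#'
#' Computes UNI_cal / T1map_cal inside the mask (denominator guarded by an
#' epsilon of 1e-6 times the masked T1map median), then replaces masked
#' voxels above the `ratio_cap_pct` percentile by the mean of their
#' 6-connected masked neighbours at or below that percentile; a voxel with no
#' qualifying neighbour is set to the percentile value.
#'
#' @param uni_cal,t1map_cal Repaired (non-negative inside mask) volumes.
#' @param params A [rescale_params()].
#' @param brain_mask Binary volume.
#' @return RATIO volume, 0 outside the mask.
#' @export
compute_ratio <- function(uni_cal, t1map_cal, params = rescale_params(),
                          brain_mask) {
  m <- brain_mask > 0
  med <- stats::median(t1map_cal[m])
  eps <- 1e-6 * max(med, .Machine$double.eps)
  ratio <- uni_cal / pmax(t1map_cal, eps)
  ratio[!m] <- 0
  q <- stats::quantile(ratio[m], params$ratio_cap_pct / 100, names = FALSE)
  over <- m & ratio > q
  if (any(over)) {
    nb <- neighbour_mean(ratio, m & ratio <= q)
    ratio[over] <- ifelse(nb$count[over] > 0,
                          nb$sum[over] / nb$count[over], q)
  }
  ratio
}

#' Mean-intensity contrast between two regions
#'
#' @param image Volume.
#' @param roi_bright,roi_dark Non-empty binary masks.
#' @return `mean(image[roi_bright]) / mean(image[roi_dark])`.
#' @export
compute_contrast <- function(image, roi_bright, roi_dark) {
  stopifnot(any(roi_bright > 0), any(roi_dark > 0))
  dark <- mean(image[roi_dark > 0])
  if (dark <= 0)
    stop("compute_contrast: dark-ROI mean is not positive")
  mean(image[roi_bright > 0]) / dark
}

#' Rescale one subject's UNI and T1 map and build the RATIO image
#'
#' Convenience wrapper running mode estimation, scale-factor computation,
#' rescaling, negative-voxel repair and RATIO construction for a subject with
#' CSF/WM tissue probability maps.
#'
#' @param uni,t1map Input volumes.
#' @param tissue_probs List with `csf` and `wm` probability volumes.
#' @param params A [rescale_params()].
#' @param brain_mask Binary volume; default: any tissue probability positive.
#' @return List with `uni_cal`, `t1map_cal`, `ratio`, `factors` (per
#'   modality), `brain_mask`.
#' @export
rescale_subject <- function(uni, t1map, tissue_probs,
                            params = rescale_params(), brain_mask = NULL) {
  if (is.null(brain_mask)) {
    brain_mask <- (tissue_probs$csf + tissue_probs$gm + tissue_probs$wm) > 0.5
  }
  sf_uni <- compute_scale_factors(
    estimate_tissue_mode(uni, tissue_probs$wm, params, "wm", "uni"),
    estimate_tissue_mode(uni, tissue_probs$csf, params, "csf", "uni"),
    params, "uni")
  sf_t1 <- compute_scale_factors(
    estimate_tissue_mode(t1map, tissue_probs$wm, params, "wm", "t1map"),
    estimate_tissue_mode(t1map, tissue_probs$csf, params, "csf", "t1map"),
    params, "t1map")
  uni_cal <- repair_negative_voxels(apply_rescale(uni, sf_uni, brain_mask),
                                    brain_mask)
  t1map_cal <- repair_negative_voxels(apply_rescale(t1map, sf_t1, brain_mask),
                                      brain_mask)
  ratio <- compute_ratio(uni_cal, t1map_cal, params, brain_mask)
  list(uni_cal = uni_cal, t1map_cal = t1map_cal, ratio = ratio,
       factors = list(uni = sf_uni, t1map = sf_t1),
       brain_mask = brain_mask * 1)
}
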