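# Brainstem channel extraction: crop the calibrated channels to the
# brainstem label, derive the tissue mask that participates in clustering,
# and assemble the z-scored per-voxel feature stack.

#' Extract and crop the brainstem channels
#'
#' Zeroes the three calibrated channels outside the brainstem label and crops
#' them to its bounding box (optionally a caller-supplied box so several
#' subjects share one grid).
#'
#' @param uni_cal,t1map_cal,ratio Calibrated whole-brain volumes.
#' @param bs_label Binary brainstem label on the same grid.
#' @param box Optional bounding box `list(lo =, hi =)` in voxel indices;
#'   default: tight box around `bs_label`.
#' @param pad Padding (voxels) added to a computed box.
#' @return List with cropped `uni`, `t1map`, `ratio`, `label`, and `box`.
#' @export
extract_brainstem <- function(uni_cal, t1map_cal, ratio, bs_label,
                              box = NULL, pad = 2L) {
  stopifnot(identical(dim(uni_cal), dim(bs_label)),
            identical(dim(t1map_cal), dim(bs_label)),
            identical(dim(ratio), dim(bs_label)))
  if (!any(bs_label > 0)) stop("extract_brainstem: empty brainstem label")
  if (is.null(box)) box <- bounding_box(bs_label, pad = pad)
  keep <- bs_label > 0
  list(uni = crop_to_box(uni_cal * keep, box),
       t1map = crop_to_box(t1map_cal * keep, box),
       ratio = crop_to_box(ratio * keep, box),
       label = crop_to_box((bs_label > 0) * 1L, box),
       box = box)
}

#' Brainstem tissue mask for clustering
#'
#' Thresholds the calibrated brainstem UNI: voxels inside the brainstem label
#' with intensity above the threshold participate in clustering. The default
#' threshold of 10 (half the dark anchor Ref2) removes residual near-zero
#' CSF-adjacent voxels while keeping the boundary shell.
#'
#' @param bs_uni Cropped calibrated UNI volume.
#' @param bs_label Cropped brainstem label.
#' @param threshold Intensity threshold.
#' @param min_voxels Minimum admissible mask size (default 300, i.e. 50 per
#'   cluster for k = 6).
#' @return Binary mask array.
#' @export
make_tissue_mask <- function(bs_uni, bs_label, threshold = 10,
                             min_voxels = 300L) {
  mask <- (bs_label > 0) & (bs_uni > threshold)
  if (sum(mask) < min_voxels)
    stop(sprintf("make_tissue_mask: only %d voxels above threshold %g (need >= %d)",
                 sum(mask), threshold, min_voxels))
  array(mask * 1L, dim(bs_uni))
}

#' Assemble the per-voxel channel stack
#'
#' Collects (UNI_cal, T1map_cal, RATIO) at every mask voxel and standardizes
#' each channel to z-scores (population sd, i.e. divide by n).
#'
#' @param channels List with `uni`, `t1map`, `ratio` cropped volumes (any
#'   subset of the three names, in clustering order).
#' @param mask Binary mask on the same grid.
#' @return An object of class `channel_stack`: `coords` (n x 3 voxel
#'   indices), `values` (n x p matrix), `z` (standardized values), `dim`,
#'   `mask`.
#' @export
channel_stack <- function(channels, mask) {
  stopifnot(length(channels) >= 1, all(mask %in% c(0, 1)))
  idx <- which(mask > 0)
  if (length(idx) < 2) stop("channel_stack: mask has fewer than 2 voxels")
  coords <- arrayInd(idx, dim(mask))
  values <- vapply(channels, function(ch) {
    stopifnot(identical(dim(ch), dim(mask)))
    ch[idx]
  }, numeric(length(idx)))
  colnames(values) <- names(channels)
  stack <- structure(list(coords = coords, values = values, z = NULL,
                          dim = dim(mask), mask = mask, index = idx),
                     class = "channel_stack")
  standardize(stack)
}

#' Standardize the channel stack to z-scores
#'
#' @param stack A [channel_stack()].
#' @return The stack with `z` filled; each column has mean 0, population sd 1.
#' @export
standardize <- function(stack) {
  v <- stack$values
  n <- nrow(v)
  mu <- colMeans(v)
  sdev <- sqrt(colMeans(v^2) - mu^2)
  zero <- sdev <= 0 | !is.finite(sdev)
  if (any(zero))
    stop("standardize: zero variance in channel ",
         paste(colnames(v)[zero], collapse = ", "))
  stack$z <- sweep(sweep(v, 2, mu), 2, sdev, "/")
  stack
}

#' @export
print.channel_stack <- function(x, ...) {
  cat("channel_stack:", nrow(x$values), "voxels x", ncol(x$values),
      "channels (", paste(colnames(x$values), collapse = ", "), ")\n")
  invisible(x)
}
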