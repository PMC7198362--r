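# Segmentation quality surface: low-silhouette index, miss-classification
# index with standardized distances, ROI mean intensities, and group
# statistics with multiple-comparison control.

#' Low-silhouette index
#'
#' For every cluster except the partial-volume one, the percentage of its
#' voxels with silhouette strictly above the threshold; the index is the
#' mean of those percentages (empty clusters are dropped from the mean).
#'
#' @param silhouettes Per-voxel silhouette values (NA allowed; NA voxels are
#'   ignored).
#' @param labels Per-voxel cluster labels (same length).
#' @param k Number of clusters.
#' @param excluded_cluster Cluster excluded from the mean (the CSF/tissue
#'   boundary partial-volume cluster, 2 by convention).
#' @param threshold Silhouette threshold (strict inequality).
#' @return List with `index` (percent) and `per_cluster` percents.
#' @export
low_silhouette_index <- function(silhouettes, labels, k = 6L,
                                 excluded_cluster = 2L, threshold = 0.6) {
  keep <- !is.na(silhouettes)
  pct <- vapply(seq_len(k), function(c) {
    i <- keep & labels == c
    if (!any(i)) return(NA_real_)
    100 * mean(silhouettes[i] > threshold)
  }, 0)
  use <- setdiff(seq_len(k), excluded_cluster)
  list(index = mean(pct[use], na.rm = TRUE), per_cluster = pct)
}

#' Miss-classification index
#'
#' Per cluster, the percentage of first-pass voxels falling outside the
#' subject-space prior thresholded at `prior_threshold` (prior < threshold
#' counts as outside); the index is the mean over nonempty clusters. Also
#' returns the mean standardized centroid-distance weight of all
#' miss-classified voxels.
#'
#' @param binary_maps List of first-pass binary cluster volumes.
#' @param priors_subject List of subject-space prior volumes.
#' @param prior_threshold Prior cutoff.
#' @param distance_weights Optional volume of standardized weights.
#' @return List with `index` (percent), `per_cluster` percents,
#'   `mean_std_distance`.
#' @export
missclassification_index <- function(binary_maps, priors_subject,
                                     prior_threshold = 0.3,
                                     distance_weights = NULL) {
  k <- length(binary_maps)
  per <- rep(NA_real_, k)
  wsum <- 0; wn <- 0
  for (c in seq_len(k)) {
    inmap <- binary_maps[[c]] > 0
    n_c <- sum(inmap)
    if (n_c == 0) next
    miss <- inmap & priors_subject[[c]] < prior_threshold
    per[c] <- 100 * sum(miss) / n_c
    if (!is.null(distance_weights) && any(miss)) {
      wsum <- wsum + sum(distance_weights[miss])
      wn <- wn + sum(miss)
    }
  }
  list(index = mean(per, na.rm = TRUE), per_cluster = per,
       mean_std_distance = if (wn > 0) wsum / wn else NA_real_)
}

#' Mean intensities per ROI per image
#'
#' @param images Named list of volumes.
#' @param roi_labels Integer label volume on the same grid (0 = outside).
#' @param rois Optional vector of expected ROI ids; an id absent from the
#'   label volume yields NA (default: the ids present).
#' @return Data frame: one row per ROI label, one column per image; an empty
#'   ROI yields NA.
#' @export
roi_mean_intensities <- function(images, roi_labels, rois = NULL) {
  if (is.null(rois)) rois <- sort(unique(roi_labels[roi_labels > 0]))
  out <- data.frame(roi = rois)
  for (nm in names(images)) {
    stopifnot(identical(dim(images[[nm]]), dim(roi_labels)))
    out[[nm]] <- vapply(rois, function(r) {
      i <- roi_labels == r
      if (!any(i)) NA_real_ else mean(images[[nm]][i])
    }, 0)
  }
  out
}

#' Two-group comparison with a normality gate
#'
#' Shapiro-Wilk at alpha = 0.05 selects the test: if the data look normal a
#' t-test is used, otherwise a Wilcoxon (signed-rank if paired, rank-sum
#' otherwise). For paired comparisons the normality gate is applied to the
#' within-pair differences.
#'
#' @param a,b Per-subject scalars (>= 3 per group).
#' @param paired Paired comparison?
#' @return List with `statistic`, `p`, `test` (name used).
#' @export
group_compare <- function(a, b, paired = FALSE) {
  stopifnot(length(a) >= 3, length(b) >= 3)
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    stop("group_compare: zero variance in both groups")
  if (paired) stopifnot(length(a) == length(b))
  if (paired && stats::sd(a - b) == 0) {
    # constant differences: no test can run; identical pairs are the null
    delta <- (a - b)[1]
    return(list(statistic = 0,
                p = if (delta == 0) 1 else 0,
                test = "degenerate (constant paired differences)"))
  }
  normal <- if (paired) {
    stats::shapiro.test(a - b)$p.value >= 0.05
  } else {
    stats::shapiro.test(a)$p.value >= 0.05 &&
      stats::shapiro.test(b)$p.value >= 0.05
  }
  if (normal) {
    ht <- stats::t.test(a, b, paired = paired)
    test <- if (paired) "paired t-test" else "t-test"
  } else {
    ht <- stats::wilcox.test(a, b, paired = paired, exact = FALSE)
    test <- if (paired) "wilcoxon signed-rank" else "wilcoxon rank-sum"
  }
  list(statistic = unname(ht$statistic), p = ht$p.value, test = test)
}

#' Benjamini-Hochberg selection at a given FDR level
#'
#' @param p Vector of p-values (one family of ROI comparisons).
#' @param q FDR level.
#' @return List with `adjusted` p-values and logical `rejected`.
#' @export
fdr_select <- function(p, q = 0.05) {
  adj <- stats::p.adjust(p, method = "BH")
  list(adjusted = adj, rejected = adj <= q)
}

#' Quality report for one subject's segmentation
#'
#' @param model Matched `cluster_model`.
#' @param stack The [channel_stack()].
#' @param priors_subject Subject-space priors.
#' @param input_combo Label of the channel combination used.
#' @param silhouettes Optional precomputed silhouettes (else computed).
#' @param max_sil_n Silhouette subsampling cap.
#' @param compute_silhouettes If `FALSE`, skip the silhouette pass (the
#'   low-silhouette index is NA); the miss-classification side is unaffected.
#' @return Object of class `quality_report` with `low_silhouette_index`,
#'   `missclassification_index`, `missclass_std_distance`, `per_cluster`
#'   breakdown and `input_combo`.
#' @export
quality_report <- function(model, stack, priors_subject,
                           input_combo = "all3", silhouettes = NULL,
                           max_sil_n = 20000L, compute_silhouettes = TRUE) {
  if (is.null(silhouettes) && compute_silhouettes)
    silhouettes <- silhouette_values(stack, model, max_n = max_sil_n,
                                     seed = model$seed)
  lsi <- if (is.null(silhouettes)) {
    list(index = NA_real_, per_cluster = rep(NA_real_, model$k))
  } else low_silhouette_index(silhouettes, model$labels, model$k)
  maps <- labels_to_binary_maps(model)
  w <- standardize_distances(model)
  w_vol <- array(0, stack$dim)
  w_vol[stack$index] <- w
  mci <- missclassification_index(maps, priors_subject,
                                  distance_weights = w_vol)
  structure(list(low_silhouette_index = lsi$index,
                 missclassification_index = mci$index,
                 missclass_std_distance = mci$mean_std_distance,
                 per_cluster = data.frame(
                   cluster = seq_len(model$k),
                   low_silhouette_pct = lsi$per_cluster,
                   missclassification_pct = mci$per_cluster),
                 input_combo = input_combo),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("quality_report [%s]: low-silhouette %.1f%%, miss-classification %.1f%% (std dist %.4f)\n",
              x$input_combo, x$low_silhouette_index,
              x$missclassification_index, x$missclass_std_distance))
  invisible(x)
}
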