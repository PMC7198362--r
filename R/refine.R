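# Final probabilistic segmentation: consistency-checked reassignment of the
# first-pass labels against the subject-space priors, followed by conversion
# of the binary labels into probabilistic maps weighted by the standardized
# centroid distances.

#' Standardized centroid-distance weights
#'
#' Per cluster, min-max rescales the voxel-to-centroid distances to [0, 1]
#' so the voxel nearest its centroid has weight 1 and the farthest weight 0;
#' if all distances in a cluster are equal every weight is 1.
#'
#' @param model A `cluster_model`.
#' @return Numeric vector of weights, one per stack voxel.
#' @export
standardize_distances <- function(model) {
  w <- numeric(length(model$labels))
  for (c in seq_len(model$k)) {
    i <- model$labels == c
    if (!any(i)) next
    d <- model$distances[i]
    rng <- range(d)
    w[i] <- if (rng[2] > rng[1]) 1 - (d - rng[1]) / (rng[2] - rng[1]) else 1
  }
  w
}

#' Reassign voxels inconsistent with the priors
#'
#' A voxel is consistent when its first-pass label equals the argmax of the
#' subject-space priors (ties toward the lower cluster index). An
#' inconsistent voxel is reassigned to the prior-argmax (alternate) cluster
#' iff the alternate prior is at least `p_high`, or exceeds the original
#' cluster's prior by at least `p_margin`; otherwise it keeps its label.
#'
#' @param labels Integer label volume (0 outside the tissue mask).
#' @param priors_subject List of 6 prior volumes in subject space.
#' @param p_high Absolute-probability reassignment threshold.
#' @param p_margin Probability-margin reassignment threshold.
#' @return List with `labels` (after reassignment) and `reassigned_mask`.
#' @export
reassign_inconsistent <- function(labels, priors_subject,
                                  p_high = 0.75, p_margin = 0.20) {
  k <- length(priors_subject)
  idx <- which(labels > 0)
  P <- vapply(priors_subject, function(p) p[idx], numeric(length(idx)))
  if (length(idx) == 1L) P <- matrix(P, nrow = 1L)
  lab <- labels[idx]
  alt <- max.col(P, ties.method = "first")
  p_alt <- P[cbind(seq_along(idx), alt)]
  p_orig <- P[cbind(seq_along(idx), lab)]
  move <- alt != lab & (p_alt >= p_high | (p_alt - p_orig) >= p_margin)
  out <- labels
  out[idx[move]] <- alt[move]
  re <- array(0L, dim(labels))
  re[idx[move]] <- 1L
  list(labels = out, reassigned_mask = re)
}

#' Final probabilistic maps
#'
#' final_prob_c(v) = [label(v) = c] * prior_c(v) * weight(v): exactly one
#' nonzero channel per masked voxel, never exceeding the warped prior.
#'
#' @param labels Label volume after reassignment.
#' @param priors_subject List of 6 prior volumes in subject space.
#' @param weight_vol Volume of standardized distance weights (0 outside
#'   mask).
#' @return List of 6 probability volumes.
#' @export
finalize_probabilistic <- function(labels, priors_subject, weight_vol) {
  lapply(seq_along(priors_subject), function(c) {
    (labels == c) * priors_subject[[c]] * weight_vol
  })
}

#' Refine a first-pass segmentation into the final probabilistic one
#'
#' Runs distance standardization, prior-consistency reassignment and
#' probabilistic finalization. Weights of reassigned voxels are recomputed
#' from their distance to the new cluster's centroid, standardized within
#' that cluster's distance range.
#'
#' @param model A `cluster_model` (after centroid matching).
#' @param stack The [channel_stack()] the model was fit on.
#' @param priors_subject List of 6 subject-space priors.
#' @param p_high,p_margin Reassignment thresholds.
#' @return Object of class `segmentation_result`: `final_probs` (6 volumes),
#'   `final_labels`, `first_pass_labels`, `reassigned_mask`,
#'   `distance_weights` (volume), `n_reassigned`.
#' @export
refine_segmentation <- function(model, stack, priors_subject,
                                p_high = 0.75, p_margin = 0.20) {
  d <- stack$dim
  lab_vol <- array(0L, d)
  lab_vol[stack$index] <- model$labels
  re <- reassign_inconsistent(lab_vol, priors_subject, p_high, p_margin)

  w <- standardize_distances(model)
  new_lab <- re$labels[stack$index]
  moved <- which(new_lab != model$labels)
  if (length(moved)) {
    # distance of each moved voxel to its new centroid, standardized with
    # the receiving cluster's min-max range
    rngs <- lapply(seq_len(model$k), function(c) {
      dc <- model$distances[model$labels == c]
      if (length(dc)) range(dc) else c(0, 0)
    })
    for (i in moved) {
      c_new <- new_lab[i]
      dist_new <- sqrt(sum((stack$z[i, ] - model$centroids[c_new, ])^2))
      rng <- rngs[[c_new]]
      w[i] <- if (rng[2] > rng[1]) {
        min(1, max(0, 1 - (dist_new - rng[1]) / (rng[2] - rng[1])))
      } else 1
    }
  }
  w_vol <- array(0, d)
  w_vol[stack$index] <- w
  probs <- finalize_probabilistic(re$labels, priors_subject, w_vol)
  structure(list(final_probs = probs, final_labels = re$labels,
                 first_pass_labels = lab_vol,
                 reassigned_mask = re$reassigned_mask,
                 distance_weights = w_vol,
                 n_reassigned = length(moved)),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("segmentation_result:", sum(x$final_labels > 0), "voxels,",
      x$n_reassigned, "reassigned\n")
  invisible(x)
}
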