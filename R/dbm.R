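# Deformation-based morphometry: Jacobian determinant maps of the
# template-building deformations and voxelwise group comparison with
# permutation max-T family-wise error control.

#' Jacobian determinant map of a deformation
#'
#' Determinant of the central-finite-difference spatial gradient of the
#' mapping x -> x + u(x) (one-sided differences at the boundary). The field
#' is the template-to-subject sampling displacement, so values above 1 mean
#' the subject is locally larger than the template.
#'
#' @param field A [deformation_field()].
#' @return Object of class `jacobian_map` with `values` (3-D array) and
#'   `spacing`.
#' @export
jacobian_from_deformation <- function(field) {
  stopifnot(inherits(field, "deformation_field"))
  j <- jac_det_disp(field$displacement)
  nbad <- sum(j <= 0)
  if (nbad > 0)
    stop(sprintf("jacobian_from_deformation: %d voxels with non-positive determinant (folded transform)",
                 nbad))
  structure(list(values = j, spacing = field$spacing),
            class = "jacobian_map")
}

#' Voxelwise two-sample test with permutation max-T FWE control
#'
#' Computes a pooled-variance two-sample t statistic at every voxel of the
#' mask and controls the family-wise error rate by permuting group labels
#' and recording the maximum |t| per permutation; voxels whose observed |t|
#' exceeds the (1 - alpha) quantile of the max-T null are significant.
#'
#' @param jacobians_a,jacobians_b Lists of `jacobian_map` (or plain arrays)
#'   on the template grid; >= 3 subjects per group.
#' @param mask Binary analysis mask (default: all voxels).
#' @param n_permutations Number of random label permutations (< 20 is an
#'   error, < 100 a warning).
#' @param alpha FWE level.
#' @param seed RNG seed for the permutations.
#' @return List with `tmap` (array, NA outside mask), `fwe_threshold`,
#'   `significant_mask`, `n_significant`, `max_t_null`.
#' @export
dbm_group_test <- function(jacobians_a, jacobians_b, mask = NULL,
                           n_permutations = 1000L, alpha = 0.05,
                           seed = 1L) {
  get_vals <- function(j) if (inherits(j, "jacobian_map")) j$values else j
  A <- lapply(jacobians_a, get_vals)
  B <- lapply(jacobians_b, get_vals)
  na <- length(A); nb <- length(B)
  stopifnot(na >= 3, nb >= 3)
  if (n_permutations < 20) stop("dbm_group_test: need >= 20 permutations")
  if (n_permutations < 100)
    warning("dbm_group_test: fewer than 100 permutations; the FWE threshold is coarse")
  d <- dim(A[[1]])
  if (is.null(mask)) mask <- array(TRUE, d)
  idx <- which(mask > 0)
  X <- vapply(c(A, B), function(v) v[idx], numeric(length(idx)))  # vox x n
  n <- na + nb

  tstat <- function(ga) {
    xa <- X[, ga, drop = FALSE]; xb <- X[, -ga, drop = FALSE]
    ma <- rowMeans(xa); mb <- rowMeans(xb)
    va <- rowSums((xa - ma)^2); vb <- rowSums((xb - mb)^2)
    sp2 <- (va + vb) / (n - 2)
    se <- sqrt(sp2 * (1 / ncol(xa) + 1 / ncol(xb)))
    tv <- (ma - mb) / se
    tv[se == 0] <- 0
    tv
  }
  t_obs <- tstat(seq_len(na))
  set.seed(seed)
  max_t <- vapply(seq_len(n_permutations), function(p) {
    max(abs(tstat(sample.int(n, na))))
  }, 0)
  # Westfall-Young order-statistic threshold: the ceil((1-alpha)(B+1))-th
  # smallest max-|t|, the standard (slightly conservative) permutation cut
  thr <- sort(max_t)[min(ceiling((1 - alpha) * (n_permutations + 1)),
                         n_permutations)]
  sig <- abs(t_obs) > thr
  tmap <- array(NA_real_, d)
  tmap[idx] <- t_obs
  sig_mask <- array(0L, d)
  sig_mask[idx[sig]] <- 1L
  list(tmap = tmap, fwe_threshold = thr, significant_mask = sig_mask,
       n_significant = sum(sig), max_t_null = max_t)
}

#' Binary dilation of a mask by n voxels (6-connectivity per step)
#' @param mask Binary array.
#' @param n Number of dilation steps.
#' @return Dilated binary array.
#' @export
dilate_mask <- function(mask, n = 1L) {
  m <- mask > 0
  for (i in seq_len(n)) {
    nb <- neighbour_mean(m * 1, array(TRUE, dim(m)))
    m <- m | nb$sum > 0
  }
  m * 1L
}
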