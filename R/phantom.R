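# Synthetic MP2RAGE-like brainstem phantom.
#
# The phantom emulates the statistical structure the segmentation pipeline
# relies on: a head with high-confidence CSF and white-matter compartments
# (the rescaling anchors), and a stylized brainstem containing six tissue
# classes -- a gray-matter matrix (1), a CSF/tissue boundary shell (2), paired
# white-matter tracts (3), a periaqueductal-like dorsal column (4), and two
# pairs of nuclear blobs (5, 6) -- with opposite intensity orderings on the
# T1-weighted (UNI) and quantitative T1-map channels, smooth multiplicative
# bias, additive (optionally Rician) noise, and small diffeomorphic
# per-subject warps with known ground truth.

# integer codes in the combined class volume
.PH_BG <- 0L; .PH_CSF <- 1L; .PH_GM <- 2L; .PH_WM <- 3L
.PH_BS <- 10L  # brainstem classes are 11..16

#' Default per-tissue channel means for the phantom
#'
#' Rows: gross head tissues (csf, gm, wm) and the six brainstem classes
#' (bs1..bs6); columns: mean intensity on the UNI and T1-map channels in
#' arbitrary scanner units. The six brainstem classes are laid out along the
#' gray/white continuum with opposite orderings on the two channels, as real
#' brainstem tissue types are.
#'
#' @return A data frame with columns `uni` and `t1map`.
#' @export
default_intensity_means <- function() {
  data.frame(
    row.names = c("csf", "gm", "wm", paste0("bs", 1:6)),
    uni   = c(1000, 2300, 3000, 2300, 1600, 3050, 2000, 2550, 2800),
    t1map = c(4000, 1550,  900, 1550, 3000,  900, 1900, 1300, 1100)
  )
}

#' Specify a synthetic brainstem phantom
#'
#' @param grid_shape Integer vector of three voxel counts (all >= 16).
#' @param voxel_size_mm Isotropic voxel spacing in mm.
#' @param intensity_means Data frame as [default_intensity_means()].
#' @param noise_sd Named numeric, additive noise sd per channel
#'   (`uni`, `t1map`) in scanner units.
#' @param bias_amplitude Relative amplitude of the smooth multiplicative bias
#'   field (0 disables it).
#' @param subject_jitter RMS magnitude (mm) of the per-subject smooth random
#'   warp; 0 makes all subjects identical to the template.
#' @param rician If `TRUE` use Rician instead of additive Gaussian noise.
#' @param atrophy Optional `list(label =, scale =)`: volumetrically scale the
#'   given brainstem class (1..6) by `scale` in every generated subject.
#' @param seed Integer RNG seed; identical spec + seed reproduce the cohort
#'   bit-identically.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48L, 56L, 40L),
                         voxel_size_mm = 1,
                         intensity_means = default_intensity_means(),
                         noise_sd = c(uni = 60, t1map = 80),
                         bias_amplitude = 0.05,
                         subject_jitter = 1.5,
                         rician = FALSE,
                         atrophy = NULL,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, voxel_size_mm > 0,
            all(noise_sd >= 0), bias_amplitude >= 0, subject_jitter >= 0)
  if (any(grid_shape < 16L))
    stop("phantom_spec: all grid dimensions must be >= 16")
  m <- intensity_means
  need <- c("csf", "gm", "wm", paste0("bs", 1:6))
  if (!all(need %in% rownames(m)))
    stop("intensity_means must have rows ", paste(need, collapse = ", "))
  if (!(m["csf", "uni"] < m["gm", "uni"] && m["gm", "uni"] < m["wm", "uni"]))
    stop("intensity ordering violated on UNI channel: require csf < gm < wm")
  if (!(m["wm", "t1map"] < m["gm", "t1map"] && m["gm", "t1map"] < m["csf", "t1map"]))
    stop("intensity ordering violated on T1map channel: require wm < gm < csf")
  bs <- paste0("bs", 1:6)
  if (any(m[bs, "uni"] <= m["csf", "uni"]))
    stop("intensity ordering violated on UNI channel: brainstem classes must exceed csf")
  if (any(m[bs, "t1map"] >= m["csf", "t1map"]))
    stop("intensity ordering violated on T1map channel: brainstem classes must be below csf")
  if (!is.null(atrophy)) {
    stopifnot(is.list(atrophy), atrophy$label %in% 1:6,
              atrophy$scale > 0, atrophy$scale <= 1)
  }
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 intensity_means = m, noise_sd = noise_sd,
                 bias_amplitude = bias_amplitude,
                 subject_jitter = subject_jitter, rician = rician,
                 atrophy = atrophy, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("phantom_spec:", paste(x$grid_shape, collapse = "x"),
      "grid,", x$voxel_size_mm, "mm voxels\n")
  cat("  noise sd:", paste(names(x$noise_sd), x$noise_sd, collapse = ", "),
      "| bias:", x$bias_amplitude, "| jitter:", x$subject_jitter, "mm\n")
  if (!is.null(x$atrophy))
    cat("  atrophy: class", x$atrophy$label, "scale", x$atrophy$scale, "\n")
  invisible(x)
}

#' Template class geometry of the phantom
#'
#' Builds the undeformed template: a combined class volume (0 background,
#' 1 csf, 2 gm, 3 wm, 11..16 brainstem classes 1..6), the head mask and the
#' brainstem ground-truth labels.
#'
#' @param spec A [phantom_spec()].
#' @return List with `classes`, `head`, `truth_labels`.
#' @export
phantom_template <- function(spec) {
  d <- spec$grid_shape
  g <- grid_coords(d)
  cx <- (d[1] + 1) / 2
  cy <- (d[2] + 1) / 2
  cz <- (d[3] + 1) / 2
  sx <- d[1] / 2.4; sy <- d[2] / 2.2; sz <- d[3] / 2.3
  rho_head <- sqrt(((g$x - cx) / sx)^2 + ((g$y - cy) / sy)^2 +
                     ((g$z - cz) / sz)^2)
  head <- rho_head <= 1

  cls <- rep(.PH_BG, prod(d))
  cls[head & rho_head > 0.90] <- .PH_CSF            # outer CSF rim
  cls[head & rho_head <= 0.90] <- .PH_GM            # gray-matter matrix
  # white-matter bulk, upper/anterior
  wx <- d[1] * 0.30; wy <- d[2] * 0.26; wz <- d[3] * 0.24
  wcy <- cy - d[2] * 0.08; wcz <- cz + d[3] * 0.12
  in_wm <- (((g$x - cx) / wx)^2 + ((g$y - wcy) / wy)^2 +
              ((g$z - wcz) / wz)^2) <= 1
  cls[head & in_wm] <- .PH_WM
  # ventricle CSF blob inside the white matter
  in_vent <- (((g$x - cx) / (d[1] * 0.10))^2 +
                ((g$y - wcy) / (d[2] * 0.08))^2 +
                ((g$z - wcz) / (d[3] * 0.09))^2) <= 1
  cls[in_vent] <- .PH_CSF

  # stylized brainstem: tapered elliptical cylinder, posterior/inferior
  z0 <- round(d[3] * 0.22); z1 <- round(d[3] * 0.80)
  bcy <- cy + d[2] * 0.10
  zf <- pmin(pmax((g$z - z0) / (z1 - z0), 0), 1)      # 0 bottom .. 1 top
  rx <- (9 - 3 * zf) * d[1] / 48
  ry <- (8 - 2.5 * zf) * d[2] / 56
  u <- (g$x - cx); w <- (g$y - bcy)
  rho_bs <- sqrt((u / rx)^2 + (w / ry)^2)
  in_bs <- rho_bs <= 1 & g$z >= z0 & g$z <= z1

  truth <- rep(0L, prod(d))
  truth[in_bs] <- 1L                                   # gm matrix (class 1)
  # boundary shell (class 2): within ~1.3 voxels of the lateral surface or
  # the end caps
  shell <- in_bs & (rho_bs >= 1 - 1.3 / pmin(rx, ry) |
                      g$z <= z0 + 1 | g$z >= z1 - 1)
  core <- in_bs & !shell
  # class 3: paired ventral tracts
  t3 <- core & ((sqrt((u - 0.45 * rx)^2 + (w + 0.40 * ry)^2) <= 1.9) |
                  (sqrt((u + 0.45 * rx)^2 + (w + 0.40 * ry)^2) <= 1.9))
  # class 4: dorsal periaqueductal-like column
  t4 <- core & !t3 & (sqrt(u^2 + (w - 0.45 * ry)^2) <= 1.7)
  # class 5: two nuclear blobs, inferior-left and superior-right
  zlen <- z1 - z0
  t5 <- core & !t3 & !t4 &
    ((sqrt((g$x - (cx - 3))^2 + (g$y - bcy)^2 +
             (g$z - (z0 + 0.25 * zlen))^2) <= 3.2) |
       (sqrt((g$x - (cx + 3))^2 + (g$y - bcy)^2 +
               (g$z - (z0 + 0.72 * zlen))^2) <= 3.2))
  # class 6: two blobs on the opposite diagonal
  t6 <- core & !t3 & !t4 & !t5 &
    ((sqrt((g$x - (cx + 3))^2 + (g$y - (bcy + 1))^2 +
             (g$z - (z0 + 0.28 * zlen))^2) <= 2.9) |
       (sqrt((g$x - (cx - 3))^2 + (g$y - (bcy + 1))^2 +
               (g$z - (z0 + 0.70 * zlen))^2) <= 2.9))
  truth[shell] <- 2L
  truth[t3] <- 3L; truth[t4] <- 4L; truth[t5] <- 5L; truth[t6] <- 6L

  cls[truth > 0] <- .PH_BS + truth[truth > 0]
  list(classes = array(cls, d), head = array(head, d),
       truth_labels = array(truth, d))
}

# class id -> channel mean lookup (vector indexed by id + 1)
.mean_lut <- function(m, channel) {
  lut <- numeric(17)
  lut[.PH_CSF + 1] <- m["csf", channel]
  lut[.PH_GM + 1] <- m["gm", channel]
  lut[.PH_WM + 1] <- m["wm", channel]
  lut[.PH_BS + (1:6) + 1] <- m[paste0("bs", 1:6), channel]
  lut
}

# smooth random velocity field with given RMS displacement (voxels)
.random_velocity <- function(d, rms_vox, smooth_sigma = 4) {
  v <- array(0, c(d, 3))
  for (c in 1:3) v[, , , c] <- gauss_smooth3(array(stats::rnorm(prod(d)), d),
                                             smooth_sigma)
  m <- sqrt(mean(v[, , , 1]^2 + v[, , , 2]^2 + v[, , , 3]^2))
  if (m > 0) v <- v * (rms_vox / m)
  v
}

# 6-connected components of a binary volume (queue-based flood fill over the
# foreground voxels only)
.connected_components <- function(mask) {
  d <- dim(mask)
  lin <- which(mask)
  comp <- integer(length(mask))
  nxt <- 0L
  strides <- c(1L, d[1], d[1] * d[2])
  coord <- arrayInd(lin, d)
  inside <- logical(length(mask)); inside[lin] <- TRUE
  for (start in lin) {
    if (comp[start] > 0L) next
    nxt <- nxt + 1L
    queue <- start
    comp[start] <- nxt
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ci <- arrayInd(cur, d)
      for (ax in 1:3) for (s in c(-1L, 1L)) {
        if (ci[ax] + s < 1L || ci[ax] + s > d[ax]) next
        nb <- cur + s * strides[ax]
        if (inside[nb] && comp[nb] == 0L) {
          comp[nb] <- nxt
          queue <- c(queue, nb)
        }
      }
    }
  }
  list(labels = array(comp, d), n = nxt)
}

# velocity implementing volumetric scaling of one class region; each
# connected component is contracted radially about its own centroid so the
# deformation stays local to the component
.atrophy_velocity <- function(truth, label, scale, d) {
  cc <- .connected_components(truth == label)
  if (cc$n == 0L) stop("atrophy: class ", label, " has no voxels")
  g <- grid_coords(d)
  a <- -log(scale) / 3          # per-axis log expansion of the lookup map
  num <- matrix(0, prod(d), 3)
  wsum <- numeric(prod(d))
  for (k in seq_len(cc$n)) {
    idx <- which(cc$labels == k, arr.ind = TRUE)
    ctr <- colMeans(idx)
    dx <- g$x - ctr[1]; dy <- g$y - ctr[2]; dz <- g$z - ctr[3]
    r <- sqrt(dx^2 + dy^2 + dz^2)
    r0 <- max(sqrt(rowSums(sweep(idx, 2, ctr)^2))) + 1
    wgt <- ifelse(r <= r0, 1,
                  ifelse(r >= 1.6 * r0, 0,
                         0.5 * (1 + cos(pi * (r - r0) / (0.6 * r0)))))
    num[, 1] <- num[, 1] + a * dx * wgt
    num[, 2] <- num[, 2] + a * dy * wgt
    num[, 3] <- num[, 3] + a * dz * wgt
    wsum <- wsum + wgt
  }
  # where tapers overlap, renormalize so the combined map stays a pure
  # per-axis log-scale `a` contraction (never a compounded one)
  scl <- 1 / pmax(1, wsum)
  v <- array(0, c(d, 3))
  for (c in 1:3) v[, , , c] <- array(num[, c] * scl, d)
  v
}

#' Generate a cohort of phantom subjects
#'
#' Each subject is the template geometry deformed by a small smooth invertible
#' warp, rendered into UNI and T1-map channels with per-tissue means, smooth
#' multiplicative bias and noise. Ground-truth labels, gross tissue
#' probability maps and the applied deformation are returned per subject.
#'
#' @param spec A [phantom_spec()].
#' @param n_subjects Number of subjects (>= 1).
#' @return List of `phantom_subject` objects, each with elements `uni`,
#'   `t1map`, `tissue_probs` (list csf/gm/wm), `brainstem_mask`,
#'   `truth_labels`, `truth_warp` (a [deformation_field()] or `NULL`),
#'   `spacing`, `id`.
#' @examples
#' spec <- phantom_spec(grid_shape = c(32, 36, 28), subject_jitter = 0)
#' cohort <- generate_cohort(spec, 2)
#' table(cohort[[1]]$truth_labels[cohort[[1]]$brainstem_mask > 0])
#' @export
generate_cohort <- function(spec, n_subjects) {
  stopifnot(inherits(spec, "phantom_spec"), n_subjects >= 1)
  tmpl <- phantom_template(spec)
  d <- spec$grid_shape
  lut_uni <- .mean_lut(spec$intensity_means, "uni")
  lut_t1 <- .mean_lut(spec$intensity_means, "t1map")
  jitter_vox <- spec$subject_jitter / spec$voxel_size_mm
  v_atroph <- if (!is.null(spec$atrophy)) {
    .atrophy_velocity(tmpl$truth_labels, spec$atrophy$label,
                      spec$atrophy$scale, d)
  } else NULL

  set.seed(spec$seed)
  lapply(seq_len(n_subjects), function(s) {
    warp <- NULL
    if (jitter_vox > 0 || !is.null(v_atroph)) {
      v <- if (jitter_vox > 0) .random_velocity(d, jitter_vox) else
        array(0, c(d, 3))
      if (!is.null(v_atroph)) v <- v + v_atroph
      warp <- deformation_field(exp_svf(v), exp_svf(-v), spec$voxel_size_mm)
      classes <- warp_scalar(tmpl$classes, warp$displacement, "nearest")
      truth <- warp_scalar(tmpl$truth_labels, warp$displacement, "nearest")
    } else {
      classes <- tmpl$classes
      truth <- tmpl$truth_labels
    }
    storage.mode(truth) <- "integer"
    uni <- array(lut_uni[classes + 1], d)
    t1m <- array(lut_t1[classes + 1], d)
    head <- classes > 0
    if (spec$bias_amplitude > 0) {
      for (ch in c("uni", "t1map")) {
        f <- gauss_smooth3(array(stats::rnorm(prod(d)), d), 8)
        f <- f / max(abs(f[head]))
        b <- 1 + spec$bias_amplitude * f
        if (ch == "uni") uni <- uni * b else t1m <- t1m * b
      }
    }
    add_noise <- function(img, sd) {
      if (sd <= 0) return(img)
      if (spec$rician) {
        n1 <- array(stats::rnorm(prod(d), sd = sd), d)
        n2 <- array(stats::rnorm(prod(d), sd = sd), d)
        out <- sqrt((img + n1)^2 + n2^2)
      } else {
        out <- img + array(stats::rnorm(prod(d), sd = sd), d)
      }
      out[!head] <- 0
      out
    }
    uni <- add_noise(uni, spec$noise_sd[["uni"]])
    t1m <- add_noise(t1m, spec$noise_sd[["t1map"]])
    uni[!head] <- 0; t1m[!head] <- 0

    pv <- classes == (.PH_BS + 2L)                    # boundary shell
    p_csf <- (classes == .PH_CSF) * 1 + pv * 0.5
    p_gm <- (classes %in% c(.PH_GM, .PH_BS + c(1L, 4L, 6L))) * 1 + pv * 0.5
    p_wm <- (classes %in% c(.PH_WM, .PH_BS + c(3L, 5L))) * 1
    structure(list(
      uni = uni, t1map = t1m,
      tissue_probs = list(csf = array(p_csf, d), gm = array(p_gm, d),
                          wm = array(p_wm, d)),
      brainstem_mask = array((truth > 0) * 1L, d),
      truth_labels = truth,
      truth_warp = warp,
      spacing = spec$voxel_size_mm,
      id = sprintf("sub-%02d", s)
    ), class = "phantom_subject")
  })
}

#' Write a phantom cohort as NIfTI volumes plus a JSON sidecar
#'
#' @param cohort Output of [generate_cohort()].
#' @param spec The [phantom_spec()] used.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the sidecar path.
#' @export
write_cohort <- function(cohort, spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- lapply(cohort, function(sub) {
    base <- file.path(dir, sub$id)
    paths <- list(
      uni = paste0(base, "_uni.nii.gz"),
      t1map = paste0(base, "_t1map.nii.gz"),
      csf = paste0(base, "_prob-csf.nii.gz"),
      gm = paste0(base, "_prob-gm.nii.gz"),
      wm = paste0(base, "_prob-wm.nii.gz"),
      brainstem = paste0(base, "_mask-brainstem.nii.gz"),
      truth = paste0(base, "_truth.nii.gz")
    )
    wv <- function(x, p) RNifti::writeNifti(
      RNifti::asNifti(x, pixdim = rep(sub$spacing, 3)), p)
    wv(sub$uni, paths$uni); wv(sub$t1map, paths$t1map)
    wv(sub$tissue_probs$csf, paths$csf)
    wv(sub$tissue_probs$gm, paths$gm)
    wv(sub$tissue_probs$wm, paths$wm)
    wv(sub$brainstem_mask, paths$brainstem)
    wv(sub$truth_labels, paths$truth)
    paths
  })
  names(files) <- vapply(cohort, `[[`, "", "id")
  sidecar <- file.path(dir, "cohort.json")
  jsonlite::write_json(list(
    spec = list(grid_shape = spec$grid_shape,
                voxel_size_mm = spec$voxel_size_mm,
                noise_sd = as.list(spec$noise_sd),
                bias_amplitude = spec$bias_amplitude,
                subject_jitter = spec$subject_jitter,
                rician = spec$rician, seed = spec$seed),
    subjects = files), sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(sidecar)
}
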