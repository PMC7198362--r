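# Probabilistic group priors by iterative multi-channel diffeomorphic
# template construction.
#
# Each subject's six binary cluster maps are registered jointly (sum of
# per-channel squared differences) to an evolving group average with a
# stationary-velocity-field registration: demons-style update forces,
# Gaussian fluid/elastic regularization, and a scaling-and-squaring
# exponential so every transform is invertible by construction (the inverse
# is the exponential of the negated velocity). The final channel averages
# are the priors; the per-subject transforms are kept so priors can be
# projected back into each subject's space.

#' An invertible deformation between a subject and the template grid
#'
#' @param displacement 4-D array (nx, ny, nz, 3), the template-to-subject
#'   sampling displacement in voxel units: warping a subject image onto the
#'   template grid samples it at x + displacement(x).
#' @param inverse_displacement The inverse map's displacement (subject grid
#'   to template sampling).
#' @param spacing Isotropic voxel spacing in mm.
#' @return Object of class `deformation_field`.
#' @export
deformation_field <- function(displacement, inverse_displacement, spacing = 1) {
  stopifnot(length(dim(displacement)) == 4, dim(displacement)[4] == 3,
            identical(dim(displacement), dim(inverse_displacement)))
  structure(list(displacement = displacement,
                 inverse_displacement = inverse_displacement,
                 spacing = spacing),
            class = "deformation_field")
}

#' Registration / template-building parameters
#'
#' @param n_reg_iter Demons iterations per subject per outer template
#'   iteration.
#' @param sigma_update Gaussian sigma (voxels) smoothing each update field
#'   (fluid-like regularization).
#' @param sigma_velocity Gaussian sigma (voxels) smoothing the accumulated
#'   velocity (elastic-like regularization).
#' @param force_k Demons normalization constant; bounds the per-iteration
#'   step to about sqrt(force_k)/2 voxels.
#' @param n_outer Outer template-building iterations.
#' @return List of parameters.
#' @export
priors_params <- function(n_reg_iter = 12L, sigma_update = 1.0,
                          sigma_velocity = 1.2, force_k = 1.0,
                          n_outer = 3L) {
  list(n_reg_iter = n_reg_iter, sigma_update = sigma_update,
       sigma_velocity = sigma_velocity, force_k = force_k,
       n_outer = n_outer)
}

# multi-channel SSD cost of warped moving vs fixed
.ssd_cost <- function(moving, fixed, disp) {
  sum(vapply(seq_along(fixed), function(c) {
    sum((fixed[[c]] - warp_scalar(moving[[c]], disp))^2)
  }, 0))
}

#' Multi-channel stationary-velocity-field registration (demons)
#'
#' Estimates a smooth invertible deformation aligning the moving channels to
#' the fixed channels by minimizing the summed squared difference with
#' demons forces and Gaussian regularization. If an iteration increases the
#' cost the step is halved once before that update is rejected.
#'
#' @param moving,fixed Lists of volumes (same grids, same length).
#' @param params [priors_params()].
#' @param v_init Optional initial velocity (warm start).
#' @return List with `velocity`, `field` (a [deformation_field()]),
#'   `cost_trace`.
#' @keywords internal
register_svf <- function(moving, fixed, params = priors_params(),
                         v_init = NULL) {
  d <- dim(fixed[[1]])
  v <- if (is.null(v_init)) array(0, c(d, 3)) else v_init
  step <- 1
  disp <- exp_svf(v)
  cost <- .ssd_cost(moving, fixed, disp)
  trace <- cost
  for (it in seq_len(params$n_reg_iter)) {
    upd_num <- array(0, c(d, 3))
    upd_den <- array(0, d)
    diff2 <- array(0, d)
    warped <- lapply(moving, function(m) warp_scalar(m, disp))
    for (c in seq_along(fixed)) {
      delta <- fixed[[c]] - warped[[c]]
      g <- grad3(warped[[c]])
      upd_num[, , , 1] <- upd_num[, , , 1] + delta * g[[1]]
      upd_num[, , , 2] <- upd_num[, , , 2] + delta * g[[2]]
      upd_num[, , , 3] <- upd_num[, , , 3] + delta * g[[3]]
      upd_den <- upd_den + g[[1]]^2 + g[[2]]^2 + g[[3]]^2
      diff2 <- diff2 + delta^2
    }
    den <- upd_den + diff2 / params$force_k
    den[den < 1e-9] <- 1e-9
    u <- upd_num / as.vector(den)
    for (c in 1:3) u[, , , c] <- gauss_smooth3(u[, , , c],
                                               params$sigma_update)
    accepted <- FALSE
    for (attempt in 1:2) {
      v_new <- v + step * u
      for (c in 1:3) v_new[, , , c] <- gauss_smooth3(v_new[, , , c],
                                                     params$sigma_velocity)
      disp_new <- exp_svf(v_new)
      cost_new <- .ssd_cost(moving, fixed, disp_new)
      if (!is.finite(cost_new))
        stop("register_svf: non-finite registration cost")
      if (cost_new <= cost) {
        v <- v_new; disp <- disp_new; cost <- cost_new
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    trace <- c(trace, cost)
    if (!accepted) break
  }
  jmin <- min(jac_det_disp(disp))
  if (jmin <= 0)
    stop(sprintf("register_svf: folded transform (min Jacobian %.3g)", jmin))
  list(velocity = v,
       field = deformation_field(disp, exp_svf(-v)),
       cost_trace = trace)
}

#' Build probabilistic group priors by iterative template construction
#'
#' Alternates (1) voxelwise averaging of the warped per-subject cluster maps
#' into the current template and (2) joint multi-channel registration of
#' each subject to that template, for `n_outer` iterations. An implicit
#' background channel (1 - sum of maps) stabilizes boundary registration.
#'
#' @param binary_maps_per_subject List (subjects) of lists (6 channels) of
#'   volumes on one common grid.
#' @param params [priors_params()].
#' @param spacing Voxel spacing in mm.
#' @return Object of class `prior_set`: `priors` (list of 6 volumes in
#'   [0, 1]), `transforms` (list of [deformation_field()] per subject),
#'   `velocities`, `n_subjects`, `metrics` (per-iteration mean cost and
#'   generalized Dice of warped maps against the template argmax; the
#'   iteration-0 row is the pre-registration baseline).
#' @export
build_group_template <- function(binary_maps_per_subject,
                                 params = priors_params(), spacing = 1) {
  n_sub <- length(binary_maps_per_subject)
  stopifnot(n_sub >= 2)
  k <- length(binary_maps_per_subject[[1]])
  d <- dim(binary_maps_per_subject[[1]][[1]])
  with_bg <- lapply(binary_maps_per_subject, function(maps) {
    bg <- 1 - Reduce(`+`, maps)
    c(maps, list(bg))
  })
  template <- lapply(seq_len(k + 1L), function(c) {
    Reduce(`+`, lapply(with_bg, `[[`, c)) / n_sub
  })
  velocities <- rep(list(array(0, c(d, 3))), n_sub)
  fields <- vector("list", n_sub)
  # iteration-0 baseline: unregistered maps against the initial average
  metrics <- data.frame(
    iteration = 0L,
    mean_cost = mean(vapply(with_bg, function(m) {
      sum(vapply(seq_along(m), function(c) sum((template[[c]] - m[[c]])^2),
                 0))
    }, 0)),
    overlap = .template_overlap(with_bg, template, k))
  warped_all <- with_bg
  for (outer in seq_len(params$n_outer)) {
    costs <- numeric(n_sub)
    for (s in seq_len(n_sub)) {
      reg <- register_svf(with_bg[[s]], template, params,
                          v_init = velocities[[s]])
      velocities[[s]] <- reg$velocity
      fields[[s]] <- reg$field
      fields[[s]]$spacing <- spacing
      costs[s] <- utils::tail(reg$cost_trace, 1)
      warped_all[[s]] <- lapply(with_bg[[s]], function(m)
        warp_scalar(m, reg$field$displacement))
    }
    template <- lapply(seq_len(k + 1L), function(c) {
      Reduce(`+`, lapply(warped_all, `[[`, c)) / n_sub
    })
    metrics <- rbind(metrics, data.frame(
      iteration = outer, mean_cost = mean(costs),
      overlap = .template_overlap(warped_all, template, k)))
  }
  priors <- lapply(template[seq_len(k)], function(p) {
    p[p < 0] <- 0; p[p > 1] <- 1; p
  })
  structure(list(priors = priors, transforms = fields,
                 velocities = velocities, n_subjects = n_sub,
                 metrics = metrics, spacing = spacing),
            class = "prior_set")
}

# generalized Dice of the warped subject maps against the template argmax.
# Both sides are discretized by argmax over all channels (incl. background)
# so interpolation softness does not masquerade as misalignment; scored on
# the k tissue channels.
.template_overlap <- function(warped_all, template, k) {
  arg <- .argmax_maps(template)
  num <- 0; den <- 0
  for (s in seq_along(warped_all)) {
    sub_arg <- .argmax_maps(warped_all[[s]])
    for (c in seq_len(k)) {
      w <- sub_arg == c
      t_c <- arg == c
      num <- num + 2 * sum(w & t_c)
      den <- den + sum(w) + sum(t_c)
    }
  }
  num / den
}

#' @keywords internal
.argmax_maps <- function(maps) {
  arg <- array(1L, dim(maps[[1]]))
  best <- maps[[1]]
  for (c in seq_along(maps)[-1]) {
    upd <- maps[[c]] > best
    arg[upd] <- c
    best[upd] <- maps[[c]][upd]
  }
  arg
}

#' @export
print.prior_set <- function(x, ...) {
  cat("prior_set:", length(x$priors), "priors from", x$n_subjects,
      "subjects;", nrow(x$metrics), "template iterations\n")
  invisible(x)
}

#' Project the group priors into a subject's space
#'
#' Resamples each prior through the subject's inverse deformation with
#' trilinear interpolation; values clipped to [0, 1].
#'
#' @param prior_set A [build_group_template()] result.
#' @param subject_id Subject index (1-based) into the prior set.
#' @return List of 6 prior volumes in subject space.
#' @export
warp_priors_to_subject <- function(prior_set, subject_id) {
  if (!(subject_id %in% seq_len(prior_set$n_subjects)))
    stop("warp_priors_to_subject: unknown subject ", subject_id)
  f <- prior_set$transforms[[subject_id]]
  lapply(prior_set$priors, function(p) {
    out <- warp_scalar(p, f$inverse_displacement)
    out[out < 0] <- 0; out[out > 1] <- 1
    out
  })
}
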