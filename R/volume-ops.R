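# Low-level 3-D array operations shared by the phantom generator, the
# diffeomorphic registration and the morphometry code. Volumes are plain 3-D
# numeric arrays; displacement fields are 4-D arrays dim c(nx, ny, nz, 3) in
# voxel units (grid spacing is carried separately and assumed isotropic).

#' @keywords internal
shift_arr <- function(a, axis, by) {
  if (by == 0L) return(a)
  d <- dim(a)
  idx <- pmin(pmax(seq_len(d[axis]) + by, 1L), d[axis])
  switch(axis,
         a[idx, , , drop = FALSE],
         a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

#' Separable Gaussian smoothing of a 3-D array
#'
#' Edge-replicated separable convolution; `sigma` is in voxels and may be 0
#' (identity).
#' @keywords internal
gauss_smooth3 <- function(a, sigma) {
  if (sigma <= 0) return(a)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  w <- stats::dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  for (axis in 1:3) {
    out <- array(0, dim(a))
    for (k in seq_along(w)) out <- out + w[k] * shift_arr(a, axis, k - r - 1L)
    a <- out
  }
  a
}

# cached voxel-coordinate columns for a given grid
.grid_cache <- new.env(parent = emptyenv())

#' @keywords internal
grid_coords <- function(d) {
  key <- paste(d, collapse = "x")
  g <- .grid_cache[[key]]
  if (is.null(g)) {
    g <- list(
      x = rep.int(seq_len(d[1]), d[2] * d[3]),
      y = rep.int(rep(seq_len(d[2]), each = d[1]), d[3]),
      z = rep(seq_len(d[3]), each = d[1] * d[2])
    )
    .grid_cache[[key]] <- g
  }
  g
}

#' Trilinear interpolation of a 3-D array at fractional voxel coordinates
#'
#' Coordinates are 1-based; samples outside the grid are clamped to the edge.
#' @keywords internal
interp3 <- function(vol, xi, yi, zi, method = c("linear", "nearest")) {
  method <- match.arg(method)
  d <- dim(vol)
  xi <- pmin(pmax(xi, 1), d[1])
  yi <- pmin(pmax(yi, 1), d[2])
  zi <- pmin(pmax(zi, 1), d[3])
  if (method == "nearest") {
    return(vol[cbind(round(xi), round(yi), round(zi))])
  }
  x0 <- pmin(floor(xi), d[1] - 1L); fx <- xi - x0
  y0 <- pmin(floor(yi), d[2] - 1L); fy <- yi - y0
  z0 <- pmin(floor(zi), d[3] - 1L); fz <- zi - z0
  n12 <- d[1] * d[2]
  i000 <- x0 + (y0 - 1) * d[1] + (z0 - 1) * n12
  v000 <- vol[i000];          v100 <- vol[i000 + 1]
  v010 <- vol[i000 + d[1]];   v110 <- vol[i000 + d[1] + 1]
  i001 <- i000 + n12
  v001 <- vol[i001];          v101 <- vol[i001 + 1]
  v011 <- vol[i001 + d[1]];   v111 <- vol[i001 + d[1] + 1]
  c00 <- v000 + fx * (v100 - v000)
  c10 <- v010 + fx * (v110 - v010)
  c01 <- v001 + fx * (v101 - v001)
  c11 <- v011 + fx * (v111 - v011)
  c0 <- c00 + fy * (c10 - c00)
  c1 <- c01 + fy * (c11 - c01)
  c0 + fz * (c1 - c0)
}

#' Warp a scalar volume through a displacement field
#'
#' Samples `vol` at x + u(x); the result lives on the grid of `disp`.
#' @keywords internal
warp_scalar <- function(vol, disp, method = c("linear", "nearest")) {
  d <- dim(disp)[1:3]
  g <- grid_coords(d)
  out <- interp3(vol,
                 g$x + as.vector(disp[, , , 1]),
                 g$y + as.vector(disp[, , , 2]),
                 g$z + as.vector(disp[, , , 3]),
                 method = match.arg(method))
  array(out, d)
}

#' Compose two displacement fields: (u o v)(x) = v(x) + u(x + v(x))
#' @keywords internal
compose_disp <- function(u, v) {
  d <- dim(v)[1:3]
  g <- grid_coords(d)
  xs <- g$x + as.vector(v[, , , 1])
  ys <- g$y + as.vector(v[, , , 2])
  zs <- g$z + as.vector(v[, , , 3])
  w <- v
  for (c in 1:3) {
    w[, , , c] <- v[, , , c] + array(interp3(u[, , , c], xs, ys, zs), d)
  }
  w
}

#' Exponentiate a stationary velocity field by scaling and squaring
#'
#' Returns the displacement of the diffeomorphism exp(v); guarantees
#' invertibility for smooth small-magnitude fields (the inverse is exp(-v)).
#' @keywords internal
exp_svf <- function(v) {
  mx <- sqrt(max(v[, , , 1]^2 + v[, , , 2]^2 + v[, , , 3]^2))
  if (mx == 0) return(v)
  n <- max(0L, as.integer(ceiling(log2(mx / 0.4))))
  u <- v / 2^n
  if (n > 0) for (i in seq_len(n)) u <- compose_disp(u, u)
  u
}

#' Central-difference gradient of a 3-D array (one-sided at the boundary)
#' @keywords internal
grad3 <- function(a) {
  d <- dim(a)
  g <- vector("list", 3)
  for (axis in 1:3) {
    gi <- (shift_arr(a, axis, 1L) - shift_arr(a, axis, -1L)) / 2
    # edge-replication halves the one-sided difference; restore it
    if (d[axis] >= 2) {
      idx_lo <- slice_idx(d, axis, 1L)
      idx_hi <- slice_idx(d, axis, d[axis])
      gi[idx_lo] <- 2 * gi[idx_lo]
      gi[idx_hi] <- 2 * gi[idx_hi]
    }
    g[[axis]] <- gi
  }
  g
}

#' @keywords internal
slice_idx <- function(d, axis, i) {
  switch(axis,
         cbind(i, rep(seq_len(d[2]), times = d[3]),
               rep(seq_len(d[3]), each = d[2])),
         cbind(rep(seq_len(d[1]), times = d[3]), i,
               rep(seq_len(d[3]), each = d[1])),
         cbind(rep(seq_len(d[1]), times = d[2]),
               rep(seq_len(d[2]), each = d[1]), i))
}

#' Jacobian determinant of the mapping x -> x + u(x)
#' @keywords internal
jac_det_disp <- function(disp) {
  gx <- grad3(disp[, , , 1])
  gy <- grad3(disp[, , , 2])
  gz <- grad3(disp[, , , 3])
  a11 <- 1 + gx[[1]]; a12 <- gx[[2]]; a13 <- gx[[3]]
  a21 <- gy[[1]]; a22 <- 1 + gy[[2]]; a23 <- gy[[3]]
  a31 <- gz[[1]]; a32 <- gz[[2]]; a33 <- 1 + gz[[3]]
  a11 * (a22 * a33 - a23 * a32) -
    a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
}

#' Mean values of the six 6-connected neighbours satisfying a predicate
#'
#' For every voxel returns (sum, count) of face-neighbour values that are
#' finite and pass `keep` (a logical array); used by the negative-voxel and
#' ratio-cap repairs.
#' @keywords internal
neighbour_mean <- function(vol, keep) {
  s <- array(0, dim(vol))
  n <- array(0, dim(vol))
  for (axis in 1:3) for (by in c(-1L, 1L)) {
    v <- shift_arr(vol, axis, by)
    k <- shift_arr(keep * 1, axis, by)
    # edge replication would let a voxel count itself at the boundary;
    # zero out the replicated slice
    d <- dim(vol)
    edge <- slice_idx(d, axis, if (by == 1L) d[axis] else 1L)
    k[edge] <- 0
    s <- s + v * k
    n <- n + k
  }
  list(sum = s, count = n)
}

#' @keywords internal
bounding_box <- function(mask, pad = 0L) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("bounding_box: mask is empty")
  d <- dim(mask)
  lo <- pmax(apply(idx, 2, min) - pad, 1L)
  hi <- pmin(apply(idx, 2, max) + pad, d)
  list(lo = as.integer(lo), hi = as.integer(hi))
}

#' @keywords internal
crop_to_box <- function(vol, box) {
  vol[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2], box$lo[3]:box$hi[3],
      drop = FALSE]
}
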