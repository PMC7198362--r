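# First-pass 6-class k-means segmentation of the z-scored brainstem channel
# stack, cross-subject centroid matching, and silhouette computation.

# squared Euclidean distances between rows of X (n x p) and C (k x p)
.dist2 <- function(X, C) {
  d2 <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * X %*% t(C)
  d2[d2 < 0] <- 0
  d2
}

# k-means++ seeding
.kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  i <- sample.int(n, 1L)
  centers[1, ] <- X[i, ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    p <- d2 / sum(d2)
    if (!all(is.finite(p)) || sum(d2) == 0) {
      i <- sample.int(n, 1L)
    } else {
      i <- sample.int(n, 1L, prob = p)
    }
    centers[j, ] <- X[i, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
  }
  centers
}

# one Lloyd run; returns labels, centers, inertia and the per-iteration
# inertia trace, or NULL if a cluster emptied
.lloyd_once <- function(X, k, max_iter) {
  centers <- .kmeanspp_init(X, k)
  trace <- numeric(0)
  labels <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- .dist2(X, centers)
    new_labels <- max.col(-d2)
    inertia <- sum(d2[cbind(seq_len(nrow(X)), new_labels)])
    trace <- c(trace, inertia)
    counts <- tabulate(new_labels, k)
    if (any(counts == 0L)) return(NULL)
    if (!is.null(labels) && all(new_labels == labels)) break
    labels <- new_labels
    for (j in seq_len(k)) centers[j, ] <- colMeans(X[labels == j, , drop = FALSE])
  }
  d2 <- .dist2(X, centers)
  labels <- max.col(-d2)
  list(labels = labels, centers = centers,
       inertia = sum(d2[cbind(seq_len(nrow(X)), labels)]),
       trace = trace,
       dist = sqrt(d2[cbind(seq_len(nrow(X)), labels)]))
}

#' First-pass k-means clustering of the channel stack
#'
#' Lloyd's algorithm with squared Euclidean distance on the z-scored
#' channels, k-means++ seeding, `replicates` random restarts, and the
#' best-inertia model returned. A replicate whose clustering empties a
#' cluster is re-seeded (up to 10 attempts). Deterministic given `seed`.
#'
#' @param stack A [channel_stack()].
#' @param k Number of clusters.
#' @param max_iter Maximum Lloyd iterations per replicate.
#' @param replicates Number of random restarts.
#' @param seed Integer RNG seed.
#' @return An object of class `cluster_model`: `k`, `centroids` (k x p),
#'   `labels`, `distances` (plain Euclidean to own centroid), `inertia`,
#'   `replicate_inertias`, `inertia_trace` (best replicate), `seed`.
#' @export
kmeans_firstpass <- function(stack, k = 6L, max_iter = 1000L,
                             replicates = 100L, seed = 1L) {
  X <- stack$z
  stopifnot(!is.null(X), nrow(X) >= 50 * k)
  set.seed(seed)
  best <- NULL
  rep_inertias <- numeric(replicates)
  for (r in seq_len(replicates)) {
    fit <- NULL
    for (try in 1:10) {
      fit <- .lloyd_once(X, k, max_iter)
      if (!is.null(fit)) break
    }
    if (is.null(fit))
      stop("kmeans_firstpass: could not find ", k,
           " nonempty clusters after reseeding")
    rep_inertias[r] <- fit$inertia
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  structure(list(k = as.integer(k), centroids = best$centers,
                 labels = best$labels, distances = best$dist,
                 inertia = best$inertia,
                 replicate_inertias = rep_inertias,
                 inertia_trace = best$trace, seed = as.integer(seed),
                 stack_dim = stack$dim, stack_index = stack$index),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("cluster_model: k =", x$k, ",", length(x$labels), "voxels, inertia",
      format(x$inertia, digits = 6), "\n")
  invisible(x)
}

#' @keywords internal
all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1L)
  out <- do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- seq_len(k)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), k - 1L))
  }))
  dimnames(out) <- NULL
  out
}

#' Optimal permutation matching of two centroid sets
#'
#' Exhaustive search over the k! one-to-one assignments minimizing the total
#' Euclidean distance between matched centroids (k is at most 8; the method
#' fixes k = 6, i.e. 720 candidates).
#'
#' @param subject,reference Objects of class `cluster_model` with equal `k`.
#' @return The subject model relabeled so its cluster c matches reference
#'   cluster c; the applied permutation is in `$permutation` (new label =
#'   permutation[old label]).
#' @export
match_centroids <- function(subject, reference) {
  stopifnot(subject$k == reference$k)
  k <- subject$k
  if (k > 8L) stop("match_centroids: exhaustive matching limited to k <= 8")
  cost <- sqrt(.dist2(subject$centroids, reference$centroids))
  perms <- all_permutations(k)
  tot <- apply(perms, 1, function(p) sum(cost[cbind(seq_len(k), p)]))
  p <- perms[which.min(tot), ]          # subject cluster i -> reference p[i]
  inv <- order(p)
  out <- subject
  out$labels <- p[subject$labels]
  out$centroids <- subject$centroids[inv, , drop = FALSE]
  out$permutation <- p
  out
}

#' Binary image-space maps of the clusters
#'
#' @param model A `cluster_model`.
#' @param dim Grid dimensions (default: the stack grid recorded in the
#'   model).
#' @return List of `model$k` binary arrays partitioning the tissue mask.
#' @export
labels_to_binary_maps <- function(model, dim = model$stack_dim) {
  lapply(seq_len(model$k), function(c) {
    m <- array(0, dim)
    m[model$stack_index[model$labels == c]] <- 1
    m
  })
}

#' Per-voxel silhouette values
#'
#' Classical silhouette s = (b - a) / max(a, b) with mean intra-cluster
#' distance a and minimal mean other-cluster distance b, Euclidean in z-score
#' space, computed blockwise. Above `max_n` voxels a seeded subsample of
#' `max_n` is evaluated (other voxels get `NA`); singleton-cluster voxels get
#' s = 0.
#'
#' @param stack A [channel_stack()].
#' @param model A `cluster_model` on that stack.
#' @param max_n Exact-computation cap.
#' @param seed Seed for the subsample.
#' @return Numeric vector of silhouettes (NA where subsampled away).
#' @export
silhouette_values <- function(stack, model, max_n = 20000L, seed = 1L) {
  X <- stack$z
  lab <- model$labels
  k <- model$k
  if (k < 2L) stop("silhouette_values: need k >= 2")
  n <- nrow(X)
  s <- rep(NA_real_, n)
  idx <- seq_len(n)
  if (n > max_n) {
    set.seed(seed)
    idx <- sort(sample.int(n, max_n))
  }
  counts <- tabulate(lab, k)
  onehot <- matrix(0, n, k)
  onehot[cbind(seq_len(n), lab)] <- 1
  block <- 512L
  for (start in seq(1L, length(idx), by = block)) {
    ii <- idx[start:min(start + block - 1L, length(idx))]
    D <- sqrt(.dist2(X[ii, , drop = FALSE], X))      # |ii| x n
    S <- D %*% onehot                                # row sums per cluster
    li <- lab[ii]
    res <- numeric(length(ii))
    for (j in seq_along(ii)) {
      c0 <- li[j]
      if (counts[c0] <= 1L) { res[j] <- 0; next }
      a <- S[j, c0] / (counts[c0] - 1L)
      b <- min(S[j, -c0] / counts[-c0])
      res[j] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
    }
    s[ii] <- res
  }
  s
}
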