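# Probabilistic refinement: distance weights, reassignment rules, final maps.

test_that("distance standardization is per-cluster min-max with anchors", {
  model <- structure(list(k = 2L,
                          labels = c(1L, 1L, 1L, 2L, 2L),
                          distances = c(0, 5, 10, 3, 3),
                          centroids = matrix(0, 2, 3)),
                     class = "cluster_model")
  w <- standardize_distances(model)
  expect_equal(w[1:3], c(1, 0.5, 0))
  expect_equal(w[4:5], c(1, 1))         # all-equal cluster: weights 1
  # the nearest voxel of each cluster always has weight 1
  for (c in 1:2) expect_equal(max(w[model$labels == c]), 1)
})

test_that("reassignment follows the printed probability rules exactly", {
  d <- c(2, 2, 1)
  mk_priors <- function(p_by_cluster) {
    lapply(1:6, function(c) array(p_by_cluster[c], d))
  }
  labels <- array(3L, d)

  # (a) alternate prior 0.80 >= 0.75: reassign
  p <- rep(0, 6); p[5] <- 0.80; p[3] <- 0.10
  out <- reassign_inconsistent(labels, mk_priors(p))
  expect_true(all(out$labels == 5))
  expect_true(all(out$reassigned_mask == 1))

  # (b) margin 0.50 - 0.25 = 0.25 >= 0.20: reassign
  p <- rep(0, 6); p[5] <- 0.50; p[3] <- 0.25
  out <- reassign_inconsistent(labels, mk_priors(p))
  expect_true(all(out$labels == 5))

  # neither rule: margin 0.10, alternate 0.50 < 0.75: keep
  p <- rep(0, 6); p[5] <- 0.50; p[3] <- 0.40
  out <- reassign_inconsistent(labels, mk_priors(p))
  expect_true(all(out$labels == 3))
  expect_true(all(out$reassigned_mask == 0))

  # consistent voxel: label equals the prior argmax, never flagged
  p <- rep(0, 6); p[3] <- 0.90
  out <- reassign_inconsistent(labels, mk_priors(p))
  expect_true(all(out$labels == 3))
  expect_true(all(out$reassigned_mask == 0))

  # boundary: margin exactly 0.20 reassigns, alternate exactly 0.75 reassigns
  p <- rep(0, 6); p[5] <- 0.45; p[3] <- 0.25
  expect_true(all(reassign_inconsistent(labels, mk_priors(p))$labels == 5))
  p <- rep(0, 6); p[5] <- 0.75; p[3] <- 0.70
  expect_true(all(reassign_inconsistent(labels, mk_priors(p))$labels == 5))
})

test_that("raising the thresholds only shrinks the reassigned set", {
  set.seed(41)
  d <- c(8, 8, 6)
  labels <- array(sample(0:6, prod(d), replace = TRUE), d)
  priors <- lapply(1:6, function(c) array(runif(prod(d)), d))
  norm <- Reduce(`+`, priors)
  priors <- lapply(priors, function(p) p / norm)
  prev <- NULL
  for (th in list(c(0.5, 0.1), c(0.75, 0.2), c(0.9, 0.4))) {
    cur <- reassign_inconsistent(labels, priors, th[1], th[2])$reassigned_mask
    if (!is.null(prev)) expect_true(all(cur <= prev))
    prev <- cur
  }
})

test_that("final probabilities are the label-gated prior-weight product", {
  d <- c(2, 2, 1)
  labels <- array(c(1L, 2L, 0L, 1L), d)
  priors <- lapply(1:6, function(c) array(0.6, d))
  w <- array(0.5, d); w[labels == 0] <- 0
  probs <- finalize_probabilistic(labels, priors, w)
  expect_equal(probs[[1]][1, 1, 1], 0.3)           # 0.6 * 0.5
  expect_equal(probs[[2]][2, 1, 1], 0.3)
  expect_equal(probs[[1]][2, 1, 1], 0)             # other channel zero
  expect_true(all(Reduce(`+`, lapply(probs, function(p) p > 0))[labels == 0]
                  == 0))
  # exactly one nonzero channel per labeled voxel
  nonzero <- Reduce(`+`, lapply(probs, function(p) (p > 0) * 1))
  expect_true(all(nonzero[labels > 0] == 1))
  # never exceeds the prior
  for (c in 1:6) expect_true(all(probs[[c]] <= priors[[c]] + 1e-12))
})

test_that("perfect priors on a noise-free subject change nothing", {
  fx <- fx_quiet_subject()
  stack <- fx$stack
  model <- kmeans_firstpass(stack, replicates = 5, seed = 5)
  truth <- bstemseg:::crop_to_box(fx$sub$truth_labels, fx$bs$box)
  # relabel the model to the truth numbering via best-Dice permutation
  lab_vol <- array(0L, stack$dim)
  lab_vol[stack$index] <- model$labels
  perm <- dice_scores(lab_vol, truth, box = NULL)$permutation
  model$labels <- match(model$labels, perm)
  model$centroids <- model$centroids[perm, ]
  priors <- lapply(1:6, function(c) (truth == c) * 1)
  seg <- refine_segmentation(model, stack, priors)
  expect_equal(seg$n_reassigned, 0)
  expect_true(all(seg$final_labels == truth))
  amax <- bstemseg:::.argmax_maps(seg$final_probs)
  expect_true(all(amax[truth > 0] == truth[truth > 0]))
})
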