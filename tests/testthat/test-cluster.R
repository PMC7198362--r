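# First-pass k-means, centroid matching, binary maps, silhouettes.

test_that("k-means recovers well-separated blobs exactly and deterministically", {
  bd <- blob_data(n_per = 100, sep = 10, sd = 1)
  st <- stack_from_matrix(bd$X)
  m1 <- kmeans_firstpass(st, k = 6, replicates = 5, seed = 31)
  m2 <- kmeans_firstpass(st, k = 6, replicates = 5, seed = 31)
  expect_identical(m1$labels, m2$labels)
  expect_identical(m1$centroids, m2$centroids)
  # perfect recovery up to permutation
  tab <- table(m1$labels, bd$labels)
  expect_equal(sum(apply(tab, 1, max)), length(bd$labels))
  # chosen replicate minimizes inertia
  expect_equal(m1$inertia, min(m1$replicate_inertias))
  # inertia never increases along the Lloyd trace
  expect_true(all(diff(m1$inertia_trace) <= 1e-9))
})

test_that("k = 1 degenerates to the channel means", {
  set.seed(32)
  X <- matrix(rnorm(300), 100, 3)
  st <- stack_from_matrix(X)
  m <- kmeans_firstpass(st, k = 1, replicates = 2, seed = 1)
  expect_true(all(m$labels == 1))
  expect_equal(as.vector(m$centroids), unname(colMeans(st$z)),
               tolerance = 1e-12)
})

test_that("our k-means matches the stats::kmeans oracle on a fixture", {
  bd <- blob_data(n_per = 60, sep = 8, sd = 1, seed = 33)
  st <- stack_from_matrix(bd$X)
  ours <- kmeans_firstpass(st, k = 6, replicates = 10, seed = 33)
  ref <- stats::kmeans(st$z, centers = 6, nstart = 10, iter.max = 100)
  expect_lt(abs(ours$inertia - ref$tot.withinss) / ref$tot.withinss, 1e-6)
  # identical partitions up to label permutation
  expect_equal(length(unique(paste(ours$labels, ref$cluster))), 6)
})

test_that("centroid matching undoes a known permutation optimally", {
  bd <- blob_data(n_per = 50, sep = 10, seed = 34)
  st <- stack_from_matrix(bd$X)
  ref <- kmeans_firstpass(st, k = 6, replicates = 3, seed = 34)
  expect_identical(match_centroids(ref, ref)$labels, ref$labels)

  pi <- c(3, 1, 4, 6, 2, 5)
  subj <- ref
  subj$centroids <- ref$centroids[pi, ]          # subject cluster i = ref pi[i]
  subj$labels <- match(ref$labels, pi)
  matched <- match_centroids(subj, ref)
  expect_identical(matched$labels, ref$labels)
  expect_equal(matched$centroids, ref$centroids, tolerance = 1e-12)

  # small centroid noise (well below inter-centroid gaps) keeps the matching
  subj2 <- subj
  set.seed(35)
  subj2$centroids <- subj$centroids + matrix(rnorm(18, sd = 0.01), 6, 3)
  expect_identical(match_centroids(subj2, ref)$labels, ref$labels)

  # exhaustive optimality: no permutation has lower total distance
  cost <- sqrt(bstemseg:::.dist2(subj$centroids, ref$centroids))
  perms <- bstemseg:::all_permutations(6)
  tots <- apply(perms, 1, function(p) sum(cost[cbind(1:6, p)]))
  chosen <- sum(cost[cbind(1:6, matched$permutation)])
  expect_equal(chosen, min(tots))
})

test_that("binary maps partition the tissue mask", {
  fx <- fx_noisy_subject()
  maps <- labels_to_binary_maps(fx$model)
  total <- Reduce(`+`, maps)
  expect_true(all(total == fx$mask))
  counts <- vapply(maps, sum, 0)
  expect_equal(unname(counts), unname(tabulate(fx$model$labels, 6)))
  one_label <- fx$model
  one_label$labels <- rep(3L, length(one_label$labels))
  maps3 <- labels_to_binary_maps(one_label)
  expect_true(all(maps3[[3]] == fx$mask))
  expect_equal(sum(maps3[[1]]) + sum(maps3[[2]]), 0)
})

test_that("silhouettes match the O(n^2) oracle and detect structure", {
  # widely separated blobs: intra-cluster distances (~sqrt(6)) are tiny
  # against the inter-blob separation, so silhouettes approach 1
  bd <- blob_data(n_per = 50, sep = 80, seed = 36)
  st <- stack_from_matrix(bd$X)
  model <- kmeans_firstpass(st, k = 6, replicates = 3, seed = 36)
  s <- silhouette_values(st, model)
  expect_true(all(s >= -1 & s <= 1))
  expect_true(all(s > 0.9))             # maximal separation

  # direct per-point oracle
  D <- as.matrix(dist(st$z))
  oracle <- vapply(seq_along(model$labels), function(i) {
    own <- model$labels == model$labels[i]
    a <- sum(D[i, own]) / (sum(own) - 1)
    b <- min(vapply(setdiff(1:6, model$labels[i]), function(c)
      mean(D[i, model$labels == c]), 0))
    (b - a) / max(a, b)
  }, 0)
  expect_equal(s, oracle, tolerance = 1e-10)

  # one blob split arbitrarily into two labels: mean silhouette near 0
  set.seed(37)
  X1 <- matrix(rnorm(600), 200, 3)
  st1 <- stack_from_matrix(X1)
  split_model <- structure(list(k = 2L, labels = rep(1:2, 100),
                                centroids = matrix(0, 2, 3),
                                distances = numeric(200), seed = 1L),
                           class = "cluster_model")
  s_split <- silhouette_values(st1, split_model)
  expect_lt(mean(s_split), 0.05)

  # subsampling above the cap leaves unsampled voxels NA
  s_sub <- silhouette_values(st, model, max_n = 120L, seed = 2)
  expect_equal(sum(!is.na(s_sub)), 120)
})
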