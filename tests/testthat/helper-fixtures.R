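# Shared fixtures, computed lazily and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- fn()
  .fixture_cache[[name]]
}

# a channel_stack built directly from a feature matrix (one voxel per row)
stack_from_matrix <- function(X) {
  n <- nrow(X)
  d <- c(n, 1L, 1L)
  structure(list(coords = cbind(seq_len(n), 1L, 1L),
                 values = X, z = scale_pop(X), dim = d,
                 mask = array(1L, d), index = seq_len(n)),
            class = "channel_stack")
}

scale_pop <- function(X) {
  mu <- colMeans(X)
  sdev <- sqrt(colMeans(X^2) - mu^2)
  sweep(sweep(X, 2, mu), 2, sdev, "/")
}

# six well-separated Gaussian blobs in 3-D feature space
blob_data <- function(n_per = 100L, sep = 10, sd = 1, seed = 42L) {
  set.seed(seed)
  centers <- sep * matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1,
                            1, 1, 0, 1, 0, 1), 6, 3, byrow = TRUE)
  X <- do.call(rbind, lapply(1:6, function(c) {
    matrix(stats::rnorm(n_per * 3, sd = sd), n_per, 3) +
      rep(centers[c, ], each = n_per)
  }))
  list(X = X, labels = rep(1:6, each = n_per), centers = centers)
}

# small quiet phantom spec used by several module tests
small_spec <- function(...) {
  args <- utils::modifyList(list(grid_shape = c(40L, 48L, 32L), seed = 5L),
                            list(...))
  do.call(phantom_spec, args)
}

quiet_spec <- function(...) {
  small_spec(noise_sd = c(uni = 0, t1map = 0), bias_amplitude = 0,
             subject_jitter = 0, ...)
}

# one noise-free subject with its calibrated channels and stack
fx_quiet_subject <- function() {
  fixture("quiet_subject", function() {
    spec <- quiet_spec()
    sub <- generate_cohort(spec, 1)[[1]]
    cal <- rescale_subject(sub$uni, sub$t1map, sub$tissue_probs)
    bs <- extract_brainstem(cal$uni_cal, cal$t1map_cal, cal$ratio,
                            sub$brainstem_mask)
    mask <- make_tissue_mask(bs$uni, bs$label)
    stack <- channel_stack(list(uni = bs$uni, t1map = bs$t1map,
                                ratio = bs$ratio), mask)
    list(spec = spec, sub = sub, cal = cal, bs = bs, mask = mask,
         stack = stack)
  })
}

# one moderately noisy subject, same geometry
fx_noisy_subject <- function() {
  fixture("noisy_subject", function() {
    spec <- small_spec(subject_jitter = 0)
    sub <- generate_cohort(spec, 1)[[1]]
    cal <- rescale_subject(sub$uni, sub$t1map, sub$tissue_probs)
    bs <- extract_brainstem(cal$uni_cal, cal$t1map_cal, cal$ratio,
                            sub$brainstem_mask)
    mask <- make_tissue_mask(bs$uni, bs$label)
    stack <- channel_stack(list(uni = bs$uni, t1map = bs$t1map,
                                ratio = bs$ratio), mask)
    model <- kmeans_firstpass(stack, k = 6, replicates = 5, seed = 5)
    list(spec = spec, sub = sub, cal = cal, bs = bs, mask = mask,
         stack = stack, model = model)
  })
}

# configured small pipeline run shared by orchestration and determinism tests
pipeline_cfg <- function(out = NULL, n = 3L) {
  cfg <- default_config()
  cfg$seed <- 17L
  cfg$phantom$n_subjects <- n
  cfg$phantom$grid_shape <- c(40L, 48L, 32L)
  cfg$phantom$subject_jitter <- 1.0
  cfg$cluster$replicates <- 5L
  cfg$priors$n_outer <- 2L
  cfg$priors$n_reg_iter <- 8L
  cfg$evaluate$max_sil_n <- 3000L
  cfg$output_dir <- out
  cfg
}

fx_pipeline_run <- function() {
  fixture("pipeline_run", function() {
    out <- file.path(tempdir(), "bstemseg-run1")
    list(out = out, run = run_pipeline(pipeline_cfg(out)))
  })
}

# moderate-noise 8-subject study cohort and its three-channel run
fx_study_cohort <- function() {
  fixture("study_cohort", function() generate_cohort(phantom_spec(seed = 7L), 8L))
}

fx_study_all3 <- function() {
  fixture("study_all3", function() {
    segment_cohort(fx_study_cohort(), replicates = 10L, seed = 7L,
                   compute_silhouettes = FALSE)
  })
}

# a smooth random stationary velocity field
random_svf <- function(d, rms = 1.0, seed = 1L) {
  set.seed(seed)
  v <- array(0, c(d, 3))
  for (c in 1:3) v[, , , c] <- bstemseg:::gauss_smooth3(
    array(stats::rnorm(prod(d)), d), 3)
  m <- sqrt(mean(v[, , , 1]^2 + v[, , , 2]^2 + v[, , , 3]^2))
  v * (rms / m)
}
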