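# Diffeomorphic template building and prior projection.

# small two-blob "cluster maps" fixture on a compact grid
two_channel_maps <- function(d = c(20, 20, 14), shift = 0L) {
  m1 <- array(0, d); m2 <- array(0, d)
  m1[(6:9) + shift, 8:12, 5:9] <- 1
  m2[(12:15) + shift, 8:12, 5:9] <- 1
  list(m1, m2)
}

test_that("identical subjects are a fixed point: identity transforms, binary priors", {
  maps <- two_channel_maps()
  ps <- build_group_template(list(maps, maps, maps),
                             priors_params(n_outer = 2))
  for (f in ps$transforms) {
    rms <- sqrt(mean(f$displacement^2) * 3)
    expect_lt(rms, 0.1)
  }
  for (c in 1:2) expect_equal(ps$priors[[c]], maps[[c]], tolerance = 1e-6)
})

test_that("registration sharpens the priors of translated subjects", {
  maps_a <- two_channel_maps()
  maps_b <- two_channel_maps(shift = 2L)
  # unregistered voxelwise average; sharpness = mass-weighted mean
  # max-probability (threshold-free: mass is conserved under warping, so a
  # plain whole-grid mean cannot discriminate)
  sharpness <- function(p1, p2) {
    mx <- pmax(p1, p2)
    sum(mx^2) / sum(mx)
  }
  naive <- lapply(1:2, function(c) (maps_a[[c]] + maps_b[[c]]) / 2)
  naive_sharp <- sharpness(naive[[1]], naive[[2]])
  ps <- build_group_template(list(maps_a, maps_b),
                             priors_params(n_outer = 3, n_reg_iter = 20))
  reg_sharp <- sharpness(ps$priors[[1]], ps$priors[[2]])
  expect_gt(reg_sharp, naive_sharp)
  # invertibility of every accepted transform
  for (f in ps$transforms)
    expect_gt(min(bstemseg:::jac_det_disp(f$displacement)), 0)
  # cost non-increasing over outer iterations (1% slack for resampling)
  cost <- ps$metrics$mean_cost
  expect_true(all(diff(cost) <= 0.01 * cost[-length(cost)]))
})

test_that("jittered phantom maps: overlap rises and mass is conserved", {
  spec <- small_spec(noise_sd = c(uni = 0, t1map = 0), bias_amplitude = 0,
                     subject_jitter = 1.2, seed = 19)
  coh <- generate_cohort(spec, 4)
  box <- bstemseg:::bounding_box(phantom_template(spec)$truth_labels > 0,
                                 pad = 3L)
  maps <- lapply(coh, function(sub) {
    tl <- bstemseg:::crop_to_box(sub$truth_labels, box)
    lapply(1:6, function(c) (tl == c) * 1)
  })
  ps <- build_group_template(maps, priors_params())
  ov <- ps$metrics$overlap                      # row 1 = before registration
  expect_true(all(diff(ov) > 0))
  cost <- ps$metrics$mean_cost
  expect_true(all(diff(cost) <= 0.01 * cost[-length(cost)]))
  # prior mass within 5% of the mean per-subject labeled volume
  prior_mass <- sum(Reduce(`+`, ps$priors))
  subj_mass <- mean(vapply(maps, function(m) sum(Reduce(`+`, m)), 0))
  expect_lt(abs(prior_mass - subj_mass) / subj_mass, 0.05)
  # every prior in [0, 1], total at most 1 (+ tolerance)
  for (p in ps$priors) expect_true(all(p >= 0 & p <= 1))
  expect_lt(max(Reduce(`+`, ps$priors)), 1 + 1e-3)
})

test_that("projecting priors back to a subject respects range and round-trips", {
  maps <- two_channel_maps()
  ps <- build_group_template(list(maps, maps), priors_params(n_outer = 1))
  pri <- warp_priors_to_subject(ps, 1)      # identity-ish transform
  for (c in 1:2) expect_equal(pri[[c]], ps$priors[[c]], tolerance = 1e-6)
  expect_error(warp_priors_to_subject(ps, 99), "unknown subject")

  # round trip through a genuine warp: smooth volume, forward then inverse
  d <- c(20, 20, 14)
  v <- random_svf(d, rms = 0.8, seed = 20)
  fwd <- bstemseg:::exp_svf(v); inv <- bstemseg:::exp_svf(-v)
  set.seed(21)
  p <- bstemseg:::gauss_smooth3(array(runif(prod(d)), d), 2.5)
  rt <- bstemseg:::warp_scalar(bstemseg:::warp_scalar(p, fwd), inv)
  interior <- array(FALSE, d); interior[4:17, 4:17, 3:12] <- TRUE
  expect_lt(sqrt(mean((rt - p)[interior]^2)), 0.02)
  # clipping contract
  for (c in 1:2) expect_true(all(pri[[c]] >= 0 & pri[[c]] <= 1))
})
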