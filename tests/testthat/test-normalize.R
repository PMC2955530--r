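test_that("maximum intensity projection equals the per-pixel maximum", {
  # identity on a single plane
  plane <- matrix(rnorm(64), 8, 8)
  expect_identical(max_intensity_project(array(plane, c(8, 8, 1))), plane)

  # constant planes collapse to the largest constant
  stack <- array(0, c(6, 6, 3))
  for (z in 1:3) stack[, , z] <- c(3, 1, 2)[z]
  expect_true(all(max_intensity_project(stack) == 3))

  # random stack against an exhaustive loop oracle
  set.seed(7)
  stack <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  oracle <- matrix(0, 8, 8)
  for (y in 1:8) for (x in 1:8) oracle[y, x] <- max(stack[y, x, ])
  expect_equal(max_intensity_project(stack), oracle)

  expect_error(max_intensity_project(list()), "empty")
})

test_that("EM segmentation recovers a well-separated mixture", {
  set.seed(11)
  x <- c(rnorm(5000, 0, 1), rnorm(5000, 10, 1))
  img <- matrix(sample(x), 100, 100)
  cm <- segment_cell(img)
  expect_lt(abs(cm$mixture$mean[1] - 0), 0.1)
  expect_lt(abs(cm$mixture$mean[2] - 10), 0.1)
  expect_equal(sum(cm$mask), cm$area)
  # hard assignment agrees with the known component of almost all samples
  expect_gt(cm$area / length(img), 0.45)
  expect_lt(cm$area / length(img), 0.55)
})

test_that("EM segmentation cross-checks against mclust", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  set.seed(3)
  img <- matrix(c(rnorm(3000, 5, 1), rnorm(2000, 12, 1.5)), 50, 100)
  cm <- segment_cell(img)
  mc <- mclust::Mclust(as.numeric(img), G = 2, modelNames = "V",
                       verbose = FALSE)
  expect_equal(sort(cm$mixture$mean), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.05)
})

test_that("segmentation rejects degenerate input and is affine invariant", {
  expect_error(segment_cell(matrix(5, 10, 10)), "degenerate")

  set.seed(4)
  img <- matrix(c(rnorm(2000, 0, 1), rnorm(2000, 8, 1)), 40, 100)
  m1 <- segment_cell(img)$mask
  m2 <- segment_cell(3.7 * img + 120)$mask
  expect_identical(m1, m2)
})

test_that("segmentation of the synthetic cell recovers the ellipse area", {
  sim <- generate_sequence(sim_config(n_frames = 20), seed = 3)
  mean_img <- apply(sim$sequence$frames, c(1, 2), mean)
  cm <- segment_cell(mean_img)
  expect_lt(abs(cm$area - sum(sim$cell)) / sum(sim$cell), 0.05)
})

test_that("noise parameters are recovered from a static sequence", {
  cfg <- sim_config(n_frames = 50, n_event_spots = 0, n_movers = 0)
  sim <- generate_sequence(cfg, seed = 11)
  np <- estimate_noise_params(sim$sequence)
  expect_lt(abs(np$gain - 0.1) / 0.1, 0.10)
})

test_that("noise estimation handles gain-free and degenerate sequences", {
  # static intensity ramp + constant Gaussian noise: flat mean-variance line
  set.seed(2)
  ramp <- matrix(seq(0, 1000, length.out = 128), 128, 128)
  fr <- array(0, dim = c(128, 128, 20))
  for (t in 1:20) fr[, , t] <- ramp + rnorm(128 * 128, 0, 5)
  np <- estimate_noise_params(fr)
  expect_lte(np$gain, 0.01 * 5)
  expect_lt(abs(np$dark_sd - 5) / 5, 0.05)

  # noiseless constant sequence
  npc <- suppressWarnings(estimate_noise_params(array(7, c(64, 64, 5))))
  expect_equal(npc$gain, 0)
  expect_equal(npc$dark_sd, 0)

  # too few blocks
  expect_error(estimate_noise_params(array(rnorm(8 * 8 * 3), c(8, 8, 3))),
               "blocks")
})

test_that("generalized Anscombe transform matches its closed form", {
  np <- noise_params(gain = 1, dark_mean = 0, dark_sd = 0)
  expect_equal(generalized_anscombe(1, np), 2 * sqrt(1 + 3 / 8),
               tolerance = 1e-12)
  # strictly increasing above the clamp point
  z <- seq(0.1, 100, length.out = 50)
  expect_true(all(diff(generalized_anscombe(z, np)) > 0))
  # gain 0 is refused
  expect_error(generalized_anscombe(1, noise_params(0, 0, 1)), "gain")
})

test_that("stabilized Poisson-Gaussian noise has unit variance across fluxes", {
  np <- noise_params(gain = 0.1, dark_mean = 2000, dark_sd = 3.6)
  set.seed(21)
  for (lambda in c(100, 2500, 10000)) {
    z <- 0.1 * rpois(256^2, lambda) + rnorm(256^2, 2000, 3.6)
    v <- var(generalized_anscombe(z, np))
    expect_gt(v, 0.9)
    expect_lt(v, 1.1)
  }
})

test_that("Gauss-Newton recovers exact and noisy exponential decays", {
  tt <- 0:119
  y <- 10 * exp(-tt / 30) + 2
  fr <- array(rep(y, each = 64), c(8, 8, 120))
  mask <- matrix(FALSE, 8, 8)
  mask[3:6, 3:6] <- TRUE
  bm <- fit_bleaching(spot_sequence(fr, 1, "WF"), mask)
  expect_equal(bm$amplitude, 10, tolerance = 1e-6)
  expect_equal(bm$offset, 2, tolerance = 1e-6)
  expect_equal(bm$tau, 30, tolerance = 1e-6)

  set.seed(9)
  for (t in 1:120) fr[, , t] <- y[t] + rnorm(64, 0, 0.05)
  bm2 <- fit_bleaching(spot_sequence(fr, 1, "WF"), mask)
  expect_lt(abs(bm2$tau - 30) / 30, 0.05)

  # constant series warns and flags, never throws
  frc <- array(5, c(8, 8, 10))
  expect_warning(bmc <- fit_bleaching(spot_sequence(frc, 1, "WF"), mask),
                 "no-bleach|negligible")
  expect_true(bmc$no_bleach)
  expect_equal(bmc$amplitude, 0)
})

test_that("Gauss-Newton agrees with an independent nonlinear fitter", {
  skip_if_not_installed("minpack.lm")
  set.seed(14)
  tt <- 0:59
  y <- 7 * exp(-tt / 22) + 1.5 + rnorm(60, 0, 0.03)
  fr <- array(rep(y, each = 16), c(4, 4, 60))
  mask <- matrix(c(TRUE, TRUE, FALSE, FALSE), 4, 4)
  bm <- fit_bleaching(spot_sequence(fr, 1, "WF"), mask)
  ref <- minpack.lm::nlsLM(y ~ A * exp(-tt / tau) + B,
                           start = list(A = 5, B = 1, tau = 30))
  expect_equal(bm$tau, coef(ref)[["tau"]], tolerance = 1e-4)
  expect_equal(bm$amplitude, coef(ref)[["A"]], tolerance = 1e-4)
})

test_that("bleaching correction has unit gain at t = 0 and the B = 0 limit", {
  bm <- bleach_model(amplitude = 4, offset = 1, tau = 25)
  fr <- array(1, c(6, 6, 10))
  out <- correct_bleaching(spot_sequence(fr, 1, "WF"), bm)
  infl <- attr(out, "variance_inflation")
  expect_equal(infl[1], 1)
  expect_equal(out$frames[1, 1, 1], 1)

  # B = 0: c(t) = exp(t / (2 tau)), variance inflation exp(t / tau)
  bm0 <- bleach_model(amplitude = 4, offset = 0, tau = 25)
  out0 <- correct_bleaching(spot_sequence(fr, 1, "WF"), bm0)
  tt <- 0:9
  expect_equal(attr(out0, "variance_inflation"), exp(tt / 25),
               tolerance = 1e-12)
  # correction multiplies frame-wise variance by exactly c(t)^2
  set.seed(5)
  frn <- array(rnorm(6 * 6 * 10), c(6, 6, 10))
  outn <- correct_bleaching(spot_sequence(frn, 1, "WF"), bm0)
  for (t in c(1, 5, 10)) {
    expect_equal(var(as.numeric(outn$frames[, , t])),
                 var(as.numeric(frn[, , t])) * exp((t - 1) / 25),
                 tolerance = 1e-10)
  }
})

test_that("the full pipeline makes bleached wide-field sequences stationary", {
  cfg <- sim_config(n_frames = 60, height = 128, width = 128,
                    n_event_spots = 0, n_movers = 0, bleach_tau = 40)
  sim <- generate_sequence(cfg, seed = 21)
  norm <- normalize_pipeline(sim$sequence)
  expect_equal(norm$modality, "WF")
  expect_false(norm$bleach$no_bleach)
  expect_lt(abs(norm$bleach$tau - 40) / 40, 0.1)
  m <- norm$mask$mask
  means <- vapply(1:60, function(t) mean(norm$sequence$frames[, , t][m]),
                  numeric(1))
  expect_lt((max(means) - min(means)) / mean(means), 0.02)
})

test_that("pipeline short-circuits when there is nothing to correct", {
  cfg <- sim_config(n_frames = 30, height = 128, width = 128,
                    n_event_spots = 0, n_movers = 0)
  sim <- generate_sequence(cfg, seed = 22)

  # TIRF: no bleach model at all
  tirf <- normalize_pipeline(sim$sequence)
  expect_null(tirf$bleach)
  expect_true(all(tirf$variance_inflation == 1))

  # WF without injected bleaching: output identical to stabilize-only
  wf <- sim$sequence
  wf$modality <- "WF"
  norm <- normalize_pipeline(wf)
  expect_true(norm$bleach$no_bleach)
  stab <- generalized_anscombe(wf, norm$noise)
  expect_lt(max(abs(norm$sequence$frames - stab$frames)), 1e-6)
})
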