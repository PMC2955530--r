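test_that("robust sigma estimates the frame noise level", {
  set.seed(1)
  a <- matrix(rnorm(256^2), 256, 256)
  b <- matrix(rnorm(256^2), 256, 256)
  s <- robust_sigma(a, b)
  expect_gt(s, 0.97)
  expect_lt(s, 1.03)

  expect_equal(robust_sigma(a, a), 0)

  # 1% bright outliers barely move the MAD
  b2 <- b
  idx <- sample(length(b2), length(b2) %/% 100)
  b2[idx] <- b2[idx] + 50
  expect_lt(abs(robust_sigma(a, b2) - 1), 0.05)
})

test_that("the bidirectional distance set has exactly 2 W^2 - 1 members", {
  fr <- unit_noise_seq(32, 32, 2, seed = 2)
  for (w in c(1L, 3L, 5L)) {
    cfg <- patch_config(patch_size = 3, search_size = w)
    ds <- patch_distance_set(fr, 16, 16, 1, cfg)
    expect_length(ds, 2L * w^2 - 1L)
  }
  # the search window of Figure-4 size gives 17 samples
  expect_length(
    patch_distance_set(fr, 16, 16, 1, patch_config(search_size = 3)), 17L)
})

test_that("identical frames always contain a perfect match", {
  cfg <- patch_config(patch_size = 3, search_size = 3)
  # spatially constant pair: every comparison is exact, all distances 0
  frc <- array(5, c(24, 24, 2))
  expect_true(all(patch_distance_set(frc, 12, 12, 1, cfg) == 0))

  # identical noisy frames: the aligned comparison is exact, so the
  # minimum distance is 0 at every site
  fr <- unit_noise_seq(24, 24, 2, seed = 3)
  fr[, , 2] <- fr[, , 1]
  ds <- patch_distance_set(fr, 12, 12, 1, cfg)
  expect_equal(min(ds), 0)
  mm <- min_distance_map(fr, cfg)
  expect_true(all(mm$d_min[[1]][mm$valid] == 0))
})

test_that("detection is symmetric under time reversal of the pair", {
  fr <- unit_noise_seq(24, 24, 2, seed = 4)
  rev <- fr[, , 2:1]
  cfg <- patch_config(patch_size = 3, search_size = 3)
  for (site in list(c(10, 10), c(12, 15))) {
    d_fwd <- patch_distance_set(fr, site[1], site[2], 1, cfg, sigma = 1)
    d_rev <- patch_distance_set(rev, site[1], site[2], 1, cfg, sigma = 1)
    expect_equal(sort(d_fwd), sort(d_rev), tolerance = 1e-12)
  }
})

test_that("the vectorized minimum map equals exhaustive per-site enumeration", {
  fr <- unit_noise_seq(16, 16, 3, seed = 5)
  for (pw in c(3L, 5L)) {
    cfg <- patch_config(patch_size = pw, search_size = 3)
    mm <- min_distance_map(fr, cfg)
    mar <- (pw - 1L) %/% 2L + 1L
    for (tp in 1:2) {
      s <- mm$sigma[tp]
      for (x in (1 + mar):(16 - mar)) {
        for (y in (1 + mar):(16 - mar)) {
          brute <- min(patch_distance_set(fr, x, y, tp, cfg, sigma = s))
          expect_equal(mm$d_min[[tp]][y, x], brute, tolerance = 1e-9)
        }
      }
    }
  }
})

test_that("sites outside the valid region are refused", {
  fr <- unit_noise_seq(20, 20, 2, seed = 6)
  cfg <- patch_config(patch_size = 5, search_size = 3)
  expect_error(patch_distance_set(fr, 3, 10, 1, cfg), "valid region")
  expect_error(patch_distance_set(fr, 10, 18, 1, cfg), "valid region")
})

test_that("null patch distances follow the chi-square law", {
  # independent sites: one distance per site on a coarse grid, via a 1x1
  # search window (the set then contains exactly the aligned comparison)
  set.seed(8)
  fr <- array(rnorm(240 * 240 * 2), c(240, 240, 2))
  cfg <- patch_config(patch_size = 3, search_size = 1)
  mm <- min_distance_map(fr, cfg, sigma = c(1))
  grid <- seq(4, 236, by = 8)
  d <- mm$d_min[[1]][grid, grid]
  expect_equal(mean(d), 9, tolerance = 0.1)
  expect_gt(ks.test(as.numeric(d), pchisq, df = 9)$p.value, 0.01)
})

test_that("fitted null p-values are approximately uniform", {
  set.seed(9)
  fr <- array(rnorm(200 * 200 * 2), c(200, 200, 2))
  cfg <- patch_config(patch_size = 3, search_size = 3)
  mm <- min_distance_map(fr, cfg)
  f <- fit_gev(mm$d_min[[1]][mm$valid])
  grid <- seq(4, 196, by = 7)
  p <- gev_pvalue(mm$d_min[[1]][grid, grid], f)
  expect_gt(ks.test(as.numeric(p), "punif")$p.value, 0.01)
})

test_that("the Monte-Carlo white-noise null is deterministic and calibrated", {
  cfg <- patch_config(patch_size = 3, search_size = 3)
  g1 <- monte_carlo_null_gev(cfg, seed = 7)
  g2 <- monte_carlo_null_gev(cfg, seed = 7)
  expect_identical(g1, g2)

  # fresh null sample: the fitted 0.999 quantile is exceeded at close to
  # the nominal rate, and the location sits near the theoretical
  # exp(-1) ~ 37th percentile of the minima
  set.seed(10)
  fr <- array(rnorm(200 * 200 * 3), c(200, 200, 3))
  mm <- min_distance_map(fr, cfg)
  d <- unlist(lapply(mm$d_min, function(m) m[mm$valid]))
  exceed <- mean(d > qgev(0.999, g1$loc, g1$scale, g1$shape))
  expect_gte(exceed, 0.0005)
  expect_lte(exceed, 0.002)
  loc_pct <- mean(d <= g1$loc)
  expect_gt(loc_pct, 0.25)
  expect_lt(loc_pct, 0.50)
})

test_that("Sidak control matches its closed form and the FDR set contains it", {
  expect_equal(control_fwer_sidak(0.02, alpha = 0.05, n_tests = 1)$threshold,
               0.05)
  expect_equal(control_fwer_sidak(0.02, alpha = 0.05, n_tests = 2)$threshold,
               0.0253206, tolerance = 1e-5)
  expect_error(control_fwer_sidak(numeric(0), 0.05), "no tests")

  # detections under FDR are a superset of Sidak FWER detections
  set.seed(12)
  for (rep in 1:50) {
    p <- runif(500)^2  # some small p-values
    fwer <- control_fwer_sidak(p, 0.05)$significant
    fdr <- control_fdr_bh(p, 0.05)$significant
    expect_true(all(fdr[fwer] | sum(fwer) <= 1))
  }
})

test_that("BH and BY step-up match brute-force enumeration", {
  # harmonic divisor
  n <- 3
  expect_equal(sum(1 / seq_len(n)), 11 / 6)

  brute_stepup <- function(p, alpha, cn) {
    n <- length(p)
    o <- order(p)
    k_max <- 0
    for (k in seq_len(n)) {
      if (p[o[k]] <= k * alpha / (n * cn)) k_max <- k
    }
    rej <- rep(FALSE, n)
    if (k_max > 0) rej[o[seq_len(k_max)]] <- TRUE
    rej
  }
  p0 <- c(0.001, 0.011, 0.02, 0.04, 0.9)
  expect_equal(control_fdr_bh(p0, 0.05)$significant,
               brute_stepup(p0, 0.05, 1))
  set.seed(13)
  for (rep in 1:100) {
    p <- round(runif(sample(3:10, 1)), 3)
    for (dep in c(FALSE, TRUE)) {
      cn <- if (dep) sum(1 / seq_along(p)) else 1
      expect_equal(control_fdr_bh(p, 0.05, dependent = dep)$significant,
                   brute_stepup(p, 0.05, cn))
    }
  }
  # single small p-value is rejected
  expect_true(control_fdr_bh(0.01, 0.05)$significant)
})

test_that("Sidak control holds its family-wise error level on null maps", {
  set.seed(14)
  n_runs <- 200
  n_tests <- 1e4
  fwe <- 0
  thr <- 1 - (1 - 0.05)^(1 / n_tests)
  for (r in seq_len(n_runs)) {
    if (min(runif(n_tests)) <= thr) fwe <- fwe + 1
  }
  rate <- fwe / n_runs
  expect_lte(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / n_runs))
})

test_that("pure-noise sequences yield no detections at FWER level", {
  clean <- 0
  for (run in 1:10) {
    fr <- unit_noise_seq(80, 80, 5, seed = 100 + run)
    det <- detect(fr, patch_config(control = "fwer", alpha = 0.05),
                  seed = run)
    if (count_significant(det) == 0) clean <- clean + 1
  }
  expect_gte(clean, 9)
})

test_that("a high-SNR appearing spot is detected at its birth pair", {
  fr <- unit_noise_seq(64, 64, 4, seed = 5)
  fr <- inject_spot(fr, 32, 32, amp = 12, frames = 3:4)
  det <- detect(fr, patch_config(control = "fwer"), seed = 1)
  sig <- which(det$pairs[[2]]$significant, arr.ind = TRUE)
  expect_gt(nrow(sig), 0)
  expect_true(any(sqrt((sig[, 1] - 32)^2 + (sig[, 2] - 32)^2) <= 2))
  # no detections on the pair where the spot is present in both frames
  expect_equal(sum(det$pairs[[3]]$significant, na.rm = TRUE), 0)

  # determinism: identical seeds give identical results
  det2 <- detect(fr, patch_config(control = "fwer"), seed = 1)
  expect_identical(det, det2)
})

test_that("the cell mask restricts the tested sites", {
  fr <- unit_noise_seq(48, 48, 3, seed = 20)
  mask <- matrix(FALSE, 48, 48)
  mask[10:30, 10:30] <- TRUE
  det <- detect(fr, patch_config(), mask = mask, seed = 1)
  expect_lt(sum(det$tested), sum(mask) + 4 * 48 * 2)
  expect_true(all(is.na(det$pairs[[1]]$p[40:48, 40:48])))
})
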