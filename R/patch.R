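#' Detection configuration for the patch (SSD) method
#'
#' @param patch_size odd patch side in pixels (default 5: wide enough to
#'   cover the core of a diffraction-limited spot, small enough that the
#'   chi-square degrees-of-freedom cost of extra pixels does not drown the
#'   spot's signal).
#' @param search_size odd search window side in pixels (default 3, giving a
#'   bidirectional distance set of 2 * 3^2 - 1 = 17 members).
#' @param frame_interval temporal interval (frames) between the two compared
#'   frames (default 1).
#' @param control multiple-testing control: `"fwer"` (Bonferroni-Sidak) or
#'   `"fdr"` (Benjamini-Hochberg step-up).
#' @param alpha significance level of the chosen control (default 0.05).
#' @param gev_refresh number of frame pairs between GEV null re-fits
#'   (default 10); intermediate pairs reuse the last fit.
#' @param presel_quantile prior GEV quantile above which minima are
#'   discarded before refitting (default 0.999).
#' @param fdr_dependent apply the dependence divisor (Benjamini-Yekutieli)
#'   in the FDR control (default FALSE: the plain Benjamini-Hochberg
#'   step-up, which rejects at least the Sidak FWER set; the Yekutieli
#'   divisor is available for strict dependence-robust guarantees but is
#'   more conservative than the FWER control at these test counts).
#' @return an object of class `patch_config`.
#' @export
patch_config <- function(patch_size = 5L, search_size = 3L,
                         frame_interval = 1L, control = c("fwer", "fdr"),
                         alpha = 0.05, gev_refresh = 10L,
                         presel_quantile = 0.999, fdr_dependent = FALSE) {
  control <- match.arg(control)
  stopifnot(is_odd(patch_size), patch_size >= 1L,
            is_odd(search_size), search_size >= 1L,
            frame_interval >= 1L, alpha > 0, alpha < 1,
            presel_quantile > 0.9, presel_quantile < 1, gev_refresh >= 1L)
  structure(
    list(patch_size = as.integer(patch_size),
         search_size = as.integer(search_size),
         frame_interval = as.integer(frame_interval), control = control,
         alpha = alpha, gev_refresh = as.integer(gev_refresh),
         presel_quantile = presel_quantile, fdr_dependent = fdr_dependent),
    class = "patch_config"
  )
}

# Margin inside which sites are excluded: patch half-width + search radius.
valid_margin <- function(cfg) {
  (cfg$patch_size - 1L) %/% 2L + (cfg$search_size - 1L) %/% 2L
}

#' Robust noise standard deviation from a frame pair
#'
#' `1.4826 * MAD(frame_b - frame_a) / sqrt(2)`: the median absolute
#' deviation of the temporal difference is insensitive to the sparse moving
#' or appearing structures, and the `sqrt(2)` removes the doubling of the
#' variance in a difference of two independent frames. Identical frames
#' give 0 (callers must guard the division).
#'
#' @param frame_a,frame_b two frames of identical shape.
#' @return the estimated per-frame noise standard deviation.
#' @export
robust_sigma <- function(frame_a, frame_b) {
  stopifnot(identical(dim(frame_a), dim(frame_b)))
  d <- as.numeric(frame_b) - as.numeric(frame_a)
  1.4826 * stats::median(abs(d - stats::median(d))) / sqrt(2)
}

#' Bidirectional patch distance set at one site
#'
#' Normalized SSD between the patch centred at `(x, y)` in frame `t` and
#' every patch of the search window centred at `(x, y)` in frame
#' `t + frame_interval`:
#' \deqn{d(x, x') = \sum_{u} [f(x+u, t) - f(x'+u, t+\Delta)]^2 / (2 \hat\sigma^2).}
#' To make detection symmetric in time, the distances from the patch at
#' `(x, y)` in frame `t + frame_interval` back to the search window in frame
#' `t` are added, with the zero-displacement comparison counted once, giving
#' exactly `2 * search_size^2 - 1` members. After variance stabilization
#' each member follows a chi-square distribution with `patch_size^2` degrees
#' of freedom under the no-change hypothesis.
#'
#' @param seq a (normalized) `spot_sequence` or H x W x T array.
#' @param x,y site coordinates (column, row; 1-based).
#' @param t index of the first frame of the pair.
#' @param cfg a `patch_config`.
#' @param sigma noise standard deviation; estimated with [robust_sigma()]
#'   from the frame pair when `NULL`.
#' @return numeric vector of `2 * search_size^2 - 1` distances. Forward
#'   (t -> t+interval) displacements come first in row-major order, then the
#'   backward displacements excluding the duplicate centre.
#' @export
patch_distance_set <- function(seq, x, y, t, cfg = patch_config(),
                               sigma = NULL) {
  fr <- as_frames(seq)
  h <- dim(fr)[1L]
  w <- dim(fr)[2L]
  mar <- valid_margin(cfg)
  if (x <= mar || x > w - mar || y <= mar || y > h - mar) {
    stop("site outside the valid region (patch + search window must fit)")
  }
  t2 <- t + cfg$frame_interval
  stopifnot(t >= 1L, t2 <= dim(fr)[3L])
  a <- fr[, , t]
  b <- fr[, , t2]
  if (is.null(sigma)) sigma <- robust_sigma(a, b)
  if (sigma == 0 && !identical(a, b)) {
    sigma <- sqrt(mean((b - a)^2) / 2)
  }
  q <- (cfg$patch_size - 1L) %/% 2L
  r <- (cfg$search_size - 1L) %/% 2L
  pa <- a[(y - q):(y + q), (x - q):(x + q)]
  pb <- b[(y - q):(y + q), (x - q):(x + q)]
  denom <- 2 * sigma^2
  if (denom == 0) denom <- 1  # identical frames: every SSD is exactly 0
  vals <- numeric(0L)
  # forward: patch at (x, y, t) vs search window at t + interval
  for (dy in -r:r) {
    for (dx in -r:r) {
      cand <- b[(y + dy - q):(y + dy + q), (x + dx - q):(x + dx + q)]
      vals <- c(vals, sum((pa - cand)^2) / denom)
    }
  }
  # backward: patch at (x, y, t + interval) vs search window at t,
  # skipping the zero displacement already counted
  for (dy in -r:r) {
    for (dx in -r:r) {
      if (dy == 0L && dx == 0L) next
      cand <- a[(y + dy - q):(y + dy + q), (x + dx - q):(x + dx + q)]
      vals <- c(vals, sum((pb - cand)^2) / denom)
    }
  }
  vals
}

# Vectorized per-offset SSD maps for one frame pair. Returns the forward
# SSD map for each displacement o as a full H x W matrix (garbage outside
# the box-filterable area, which callers must not read).
ssd_offset_maps <- function(a, b, q, r, denom) {
  h <- nrow(a)
  w <- ncol(a)
  offs <- expand.grid(dx = -r:r, dy = -r:r)  # row-major in (dy, dx)
  maps <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    dy <- offs$dy[k]
    dx <- offs$dx[k]
    e <- matrix(0, h, w)
    ys <- max(1L, 1L - dy):min(h, h - dy)
    xs <- max(1L, 1L - dx):min(w, w - dx)
    diffm <- a[ys, xs, drop = FALSE] - b[ys + dy, xs + dx, drop = FALSE]
    e[ys, xs] <- diffm * diffm
    maps[[k]] <- box_sum(e, q) / denom
  }
  list(maps = maps, offsets = offs)
}

#' Minimum patch distance map for every frame pair
#'
#' Computes, at every valid site of every frame pair `(t, t + interval)`,
#' the minimum of the bidirectional distance set: if even the best match in
#' the search window is poor, no pattern was matched and a sudden event is
#' likely. Identical frames give a map of zeros (the 0/0 normalization is
#' taken as 0).
#'
#' @inheritParams patch_distance_set
#' @param sigma optional numeric vector of per-pair noise standard
#'   deviations; estimated per pair when `NULL`.
#' @return an object of class `min_distance_map`: list with `d_min` (list
#'   of H x W matrices, NA outside the valid region), `sigma` (per pair),
#'   `valid` (logical matrix of the valid region), `cfg`.
#' @export
min_distance_map <- function(seq, cfg = patch_config(), sigma = NULL) {
  fr <- as_frames(seq)
  h <- dim(fr)[1L]
  w <- dim(fr)[2L]
  nt <- dim(fr)[3L]
  delta <- cfg$frame_interval
  stopifnot(nt >= delta + 1L)
  q <- (cfg$patch_size - 1L) %/% 2L
  r <- (cfg$search_size - 1L) %/% 2L
  mar <- q + r
  stopifnot(h > 2L * mar, w > 2L * mar)
  valid <- matrix(FALSE, h, w)
  valid[(1L + mar):(h - mar), (1L + mar):(w - mar)] <- TRUE

  n_pairs <- nt - delta
  d_min <- vector("list", n_pairs)
  sig <- numeric(n_pairs)
  for (tp in seq_len(n_pairs)) {
    a <- fr[, , tp]
    b <- fr[, , tp + delta]
    s <- if (is.null(sigma)) robust_sigma(a, b) else sigma[tp]
    if (s == 0 && !identical(a, b)) {
      # zero MAD but non-identical frames (sparse change on a noiseless
      # background): fall back to an RMS-based scale to keep distances finite
      s <- sqrt(mean((b - a)^2) / 2)
    }
    sig[tp] <- s
    if (s == 0) {
      dm <- matrix(0, h, w)
    } else {
      om <- ssd_offset_maps(a, b, q, r, denom = 2 * sig[tp]^2)
      dm <- om$maps[[(length(om$maps) + 1L) %/% 2L]]  # zero offset
      for (k in seq_along(om$maps)) {
        dy <- om$offsets$dy[k]
        dx <- om$offsets$dx[k]
        if (!(dy == 0L && dx == 0L)) {
          # forward displacement o
          dm <- pmin(dm, om$maps[[k]], na.rm = FALSE)
          # backward displacement o = shifted forward map of -o
          k_neg <- which(om$offsets$dy == -dy & om$offsets$dx == -dx)
          dm <- pmin(dm, shift_mat(om$maps[[k_neg]], dy, dx))
        }
      }
    }
    dm[!valid] <- NA_real_
    d_min[[tp]] <- dm
  }
  structure(
    list(d_min = d_min, sigma = sig, valid = valid, cfg = cfg),
    class = "min_distance_map"
  )
}

#' Monte-Carlo white-noise GEV null
#'
#' Simulates a unit-variance Gaussian white-noise sequence (the behaviour
#' of a stabilized sequence with no structure), computes its minimum
#' distance map, and fits the GEV to the pooled minima. This provides the
#' initialization null used for the first frame pair of a real sequence;
#' later pairs warm-start from the previously fitted parameters.
#'
#' @param cfg a `patch_config`.
#' @param n_frames number of white-noise frames to simulate (default 6).
#' @param seed integer seed; the result is bit-identical for equal seeds.
#' @param frame_size side of the simulated square frames (default 64).
#' @return a `gev_params` object.
#' @export
monte_carlo_null_gev <- function(cfg = patch_config(), n_frames = 6L,
                                 seed = 1L, frame_size = 64L) {
  stopifnot(n_frames >= 2L)
  with_seed(seed, {
    fr <- array(stats::rnorm(frame_size^2 * n_frames),
                dim = c(frame_size, frame_size, n_frames))
    mm <- min_distance_map(fr, cfg)
    minima <- unlist(lapply(mm$d_min, function(m) m[mm$valid]))
    fit_gev(minima)
  })
}

#' Patch-based event detection
#'
#' The full per-pair detection pass: robust noise estimation, minimum
#' distance map, GEV calibration (Monte-Carlo white-noise initialization,
#' refreshed every `gev_refresh` pairs with warm-started outlier
#' preselection), upper-tail p-values, and the configured multiple-testing
#' control over the tested sites of each pair.
#'
#' @param x a `normalized_sequence` (output of [normalize_pipeline()]), a
#'   stabilized `spot_sequence`, or an H x W x T array.
#' @param cfg a `patch_config`.
#' @param mask optional logical H x W matrix restricting tested sites (the
#'   cell mask of a `normalized_sequence` is used automatically); it is
#'   dilated by the search radius before use.
#' @param seed integer seed for the Monte-Carlo initialization (recorded in
#'   the result).
#' @return an object of class `detection_result`: `pairs` (list per frame
#'   pair with `p` map, `significant` map, `threshold`, `n_tests`, `gev`),
#'   `sigma`, `cfg`, `method = "ssd"`, `seed`, `tested` (logical map of
#'   tested sites).
#' @export
detect <- function(x, cfg = patch_config(), mask = NULL, seed = 1L) {
  if (inherits(x, "normalized_sequence")) {
    if (is.null(mask)) mask <- x$mask$mask
    seq <- x$sequence
  } else {
    seq <- x
  }
  fr <- as_frames(seq)
  mm <- min_distance_map(seq, cfg)
  tested <- mm$valid
  if (!is.null(mask)) {
    m <- if (inherits(mask, "cell_mask")) mask$mask else mask
    tested <- tested & dilate_mask(m, (cfg$search_size - 1L) %/% 2L)
  }
  n_tests <- sum(tested)
  if (n_tests == 0L) stop("no tested sites: empty mask or frame too small")

  gev <- monte_carlo_null_gev(cfg, seed = seed)
  pairs <- vector("list", length(mm$d_min))
  for (tp in seq_along(mm$d_min)) {
    dm <- mm$d_min[[tp]]
    if ((tp - 1L) %% cfg$gev_refresh == 0L) {
      samples <- dm[tested]
      refit <- tryCatch(
        fit_gev(samples, prior = gev,
                presel_quantile = cfg$presel_quantile, shape_min = 0),
        error = function(e) NULL
      )
      if (!is.null(refit)) gev <- refit
    }
    p <- matrix(NA_real_, nrow(dm), ncol(dm))
    p[tested] <- gev_pvalue(dm[tested], gev)
    ctrl <- if (cfg$control == "fwer") {
      control_fwer_sidak(p, cfg$alpha, n_tests)
    } else {
      control_fdr_bh(p, cfg$alpha, dependent = cfg$fdr_dependent)
    }
    pairs[[tp]] <- list(p = p, significant = ctrl$significant,
                        threshold = ctrl$threshold, n_tests = n_tests,
                        gev = gev, d_min = dm)
  }
  structure(
    list(pairs = pairs, sigma = mm$sigma, cfg = cfg, method = "ssd",
         seed = seed, tested = tested),
    class = "detection_result"
  )
}

#' @export
print.detection_result <- function(x, ...) {
  ns <- vapply(x$pairs, function(pr) sum(pr$significant, na.rm = TRUE),
               numeric(1L))
  cat(sprintf(
    "detection_result (%s, %s control, alpha %.3g): %d frame pairs, %d significant sites\n",
    x$method, toupper(x$cfg$control), x$cfg$alpha, length(x$pairs), sum(ns)))
  invisible(x)
}
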