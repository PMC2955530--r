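#' Sensor noise parameters
#'
#' The affine Poisson-Gaussian sensor model: the measured intensity is
#' `z = gain * N + eps`, with `N ~ Poisson(lambda)` the photo-electron count
#' and `eps ~ Normal(dark_mean, dark_sd^2)` the dark current plus readout
#' noise. Under this model `Var(z) = gain * (E[z] - dark_mean) + dark_sd^2`,
#' which is the line the estimator fits.
#'
#' @param gain camera gain (intensity units per photo-electron), >= 0.
#' @param dark_mean dark signal mean (intensity units).
#' @param dark_sd dark signal standard deviation (intensity units), >= 0.
#' @return an object of class `noise_params`.
#' @export
noise_params <- function(gain, dark_mean, dark_sd) {
  stopifnot(gain >= 0, dark_sd >= 0, is.finite(dark_mean))
  structure(
    list(gain = gain, dark_mean = dark_mean, dark_sd = dark_sd,
         intercept = dark_sd^2 - gain * dark_mean),
    class = "noise_params"
  )
}

#' @export
print.noise_params <- function(x, ...) {
  cat(sprintf("noise_params: gain %.4g, dark mean %.5g, dark sd %.4g\n",
              x$gain, x$dark_mean, x$dark_sd))
  invisible(x)
}

#' Estimate sensor noise parameters from a sequence
#'
#' A mean-variance regression over local blocks: temporal pseudo-residuals
#' of successive frame pairs, `(z[t+1] - z[t]) / sqrt(2)`, isolate the noise
#' (their per-block variance estimates `Var(z)` wherever the signal is
#' locally static), while the per-block mean of `(z[t] + z[t+1]) / 2`
#' estimates `E[z]`. A robust line fit of block variance against block mean
#' (`MASS::rlm`, least squares as fallback) yields the slope `gain` and the
#' intercept `dark_sd^2 - gain * dark_mean`. Blocks containing moving or
#' blinking structures enter as outliers the robust fit ignores.
#'
#' The dark mean is not identifiable from the mean-variance line alone. If
#' `dark_mean_hint` is supplied it is used directly; otherwise the mode of
#' the lowest-decile block means is taken (a proxy that is only exact when
#' truly dark regions exist; the generalized Anscombe transform depends only
#' on the slope and intercept, so a biased dark mean does not affect
#' stabilization).
#'
#' @param seq a `spot_sequence` or H x W x T array (T >= 2).
#' @param dark_mean_hint optional externally calibrated dark mean.
#' @param block block side in pixels (default 8).
#' @param max_pairs at most this many frame pairs are pooled (default 20).
#' @return a `noise_params` object with extra fields `n_blocks` and
#'   `estimated = TRUE`.
#' @export
estimate_noise_params <- function(seq, dark_mean_hint = NULL, block = 8L,
                                  max_pairs = 20L) {
  fr <- as_frames(seq)
  stopifnot(length(dim(fr)) == 3L, dim(fr)[3L] >= 2L)
  h <- dim(fr)[1L] %/% block * block
  w <- dim(fr)[2L] %/% block * block
  nt <- dim(fr)[3L]
  pairs <- seq_len(min(nt - 1L, max_pairs))

  bm <- NULL
  bv <- NULL
  for (t in pairs) {
    a <- fr[seq_len(h), seq_len(w), t]
    b <- fr[seq_len(h), seq_len(w), t + 1L]
    d <- (b - a) / sqrt(2)
    m <- (a + b) / 2
    # fold into (block x block) cells: rows = blocks, cols = in-block pixels
    grp <- outer((seq_len(h) - 1L) %/% block,
                 ((seq_len(w) - 1L) %/% block) * (h %/% block), "+") + 1L
    bm <- c(bm, tapply(as.numeric(m), as.numeric(grp), mean))
    bv <- c(bv, tapply(as.numeric(d), as.numeric(grp), stats::var))
  }
  keep <- is.finite(bm) & is.finite(bv)
  bm <- bm[keep]
  bv <- bv[keep]
  if (length(bm) < 10L) stop("fewer than 10 blocks: cannot fit noise model")

  fit <- tryCatch(
    MASS::rlm(bv ~ bm, maxit = 100L),
    error = function(e) stats::lm(bv ~ bm)
  )
  g <- unname(stats::coef(fit)[2L])
  ic <- unname(stats::coef(fit)[1L])
  if (!is.finite(g)) {  # e.g. static noiseless sequence: all block means equal
    g <- 0
    ic <- mean(bv)
  }
  if (g < 0) {
    warning("negative fitted gain clamped to 0 (no detectable shot noise)")
    g <- 0
  }
  m0 <- if (!is.null(dark_mean_hint)) {
    dark_mean_hint
  } else {
    low <- bm[bm <= stats::quantile(bm, 0.1)]
    if (length(low) >= 3L && stats::sd(low) > 0) {
      dd <- stats::density(low)
      dd$x[which.max(dd$y)]
    } else {
      min(bm)
    }
  }
  s2 <- max(ic + g * m0, 0)
  out <- noise_params(g, m0, sqrt(s2))
  out$intercept <- ic  # keep the fitted intercept exactly
  out$n_blocks <- length(bm)
  out$estimated <- TRUE
  out
}

#' Generalized Anscombe transform
#'
#' Variance-stabilizing transform for the affine Poisson-Gaussian sensor
#' model:
#' \deqn{t(z) = \frac{2}{g}\sqrt{g z + \tfrac{3}{8} g^2 + \sigma_{dc}^2 - g m},}
#' after which the noise variance is approximately 1 everywhere in the
#' sequence (exactly 1 in the large-photon-count limit). The square-root
#' argument is clamped at 0 below its root so rare dark-noise pixels map to
#' 0 rather than NaN. The transform is strictly increasing above the clamp
#' point.
#'
#' @param seq a `spot_sequence`, array, or matrix of intensities.
#' @param params a `noise_params` object with `gain > 0` (for a pure
#'   Gaussian sensor use plain standardization instead).
#' @return object of the same type with transformed intensities.
#' @export
generalized_anscombe <- function(seq, params) {
  stopifnot(inherits(params, "noise_params"))
  if (params$gain <= 0) stop("gain required: generalized Anscombe transform undefined for gain 0")
  g <- params$gain
  transform <- function(z) {
    2 / g * sqrt(pmax(g * z + 0.375 * g^2 + params$intercept, 0))
  }
  if (inherits(seq, "spot_sequence")) {
    out <- seq
    out$frames <- transform(seq$frames)
    attr(out, "stabilized") <- TRUE
    out
  } else {
    transform(seq)
  }
}

# Plain standardization for gain-0 (pure Gaussian) sensors.
standardize_gaussian <- function(seq, params) {
  stopifnot(params$dark_sd > 0)
  out <- seq
  out$frames <- (seq$frames - params$dark_mean) / params$dark_sd
  attr(out, "stabilized") <- TRUE
  out
}
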