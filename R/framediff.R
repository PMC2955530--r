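#' Configuration for the frame-difference baseline
#'
#' The comparison baseline thresholds the pixel-wise difference of two
#' frames under a Logistic null. The Logistic's heavier-than-Gaussian tail,
#' plus a deliberate inflation of the noise scale, desensitizes the test to
#' residual motion; it is the limit of the patch approach as patch and
#' search window shrink to one pixel (with a different null family).
#'
#' @param frame_interval temporal interval in frames (default 1).
#' @param control `"fwer"` or `"fdr"`.
#' @param alpha significance level (default 0.05).
#' @param inflation multiplier `k >= 1` on the robust noise scale
#'   (default 1.5); `k = 1` gives a calibrated (slightly conservative)
#'   test, larger values trade sensitivity for robustness to motion.
#' @param fdr_dependent apply the Benjamini-Yekutieli divisor in FDR mode.
#' @return an object of class `fd_config`.
#' @export
fd_config <- function(frame_interval = 1L, control = c("fwer", "fdr"),
                      alpha = 0.05, inflation = 1.5, fdr_dependent = FALSE) {
  control <- match.arg(control)
  stopifnot(frame_interval >= 1L, alpha > 0, alpha < 1, inflation >= 1)
  structure(
    list(frame_interval = as.integer(frame_interval), control = control,
         alpha = alpha, inflation = inflation,
         fdr_dependent = fdr_dependent),
    class = "fd_config"
  )
}

#' Frame-difference p-value maps
#'
#' For each pair `(t, t + interval)` the difference
#' `d = f(., t+interval) - f(., t)` is tested against a Logistic null with
#' location 0 and scale `s = k * sigma * sqrt(2) * sqrt(3) / pi`, i.e. the
#' Logistic whose standard deviation matches the inflated difference
#' standard deviation `k * sigma * sqrt(2)`. The two-sided p-value is
#' `2 * min(F(d), 1 - F(d))`.
#'
#' @param seq a normalized `spot_sequence` or H x W x T array.
#' @param cfg an `fd_config`.
#' @return list with `p` (list of H x W p-value maps per pair), `diff`
#'   (list of difference maps), `sigma` (per-pair robust noise sd).
#' @export
framediff_pvalues <- function(seq, cfg = fd_config()) {
  fr <- as_frames(seq)
  nt <- dim(fr)[3L]
  delta <- cfg$frame_interval
  stopifnot(nt >= delta + 1L)
  n_pairs <- nt - delta
  p <- vector("list", n_pairs)
  dmaps <- vector("list", n_pairs)
  sig <- numeric(n_pairs)
  for (tp in seq_len(n_pairs)) {
    a <- fr[, , tp]
    b <- fr[, , tp + delta]
    s <- robust_sigma(a, b)
    if (s == 0) {
      if (identical(a, b)) {
        # d = 0 everywhere: the two-sided p-value is 1 under any scale
        p[[tp]] <- matrix(1, nrow(a), ncol(a))
        dmaps[[tp]] <- a - a
        next
      }
      stop("zero noise estimate from a non-identical frame pair")
    }
    sig[tp] <- s
    scale <- cfg$inflation * s * sqrt(2) * sqrt(3) / pi
    d <- b - a
    cdf <- stats::plogis(d, location = 0, scale = scale)
    p[[tp]] <- 2 * pmin(cdf, 1 - cdf)
    dmaps[[tp]] <- d
  }
  list(p = p, diff = dmaps, sigma = sig)
}

#' Frame-difference event detection
#'
#' Applies the same multiple-testing controls as the patch method to the
#' Logistic frame-difference p-values.
#'
#' @param x a `normalized_sequence`, stabilized `spot_sequence`, or array.
#' @param cfg an `fd_config`.
#' @param mask optional logical matrix restricting tested sites.
#' @return a `detection_result` with `method = "fd"`; each pair also keeps
#'   the difference map (used for polarity classification).
#' @export
framediff_detect <- function(x, cfg = fd_config(), mask = NULL) {
  if (inherits(x, "normalized_sequence")) {
    if (is.null(mask)) mask <- x$mask$mask
    seq <- x$sequence
  } else {
    seq <- x
  }
  pv <- framediff_pvalues(seq, cfg)
  fr <- as_frames(seq)
  tested <- matrix(TRUE, dim(fr)[1L], dim(fr)[2L])
  if (!is.null(mask)) {
    m <- if (inherits(mask, "cell_mask")) mask$mask else mask
    tested <- tested & m
  }
  n_tests <- sum(tested)
  if (n_tests == 0L) stop("no tested sites: empty mask")
  pairs <- vector("list", length(pv$p))
  for (tp in seq_along(pv$p)) {
    p <- pv$p[[tp]]
    p[!tested] <- NA_real_
    ctrl <- if (cfg$control == "fwer") {
      control_fwer_sidak(p, cfg$alpha, n_tests)
    } else {
      control_fdr_bh(p, cfg$alpha, dependent = cfg$fdr_dependent)
    }
    pairs[[tp]] <- list(p = p, significant = ctrl$significant,
                        threshold = ctrl$threshold, n_tests = n_tests,
                        diff = pv$diff[[tp]])
  }
  structure(
    list(pairs = pairs, sigma = pv$sigma, cfg = cfg, method = "fd",
         tested = tested),
    class = "detection_result"
  )
}
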