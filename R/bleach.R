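#' Photobleaching decay model
#'
#' Exponential decay of the mean in-cell intensity under illumination,
#' `fbar(t) = A * exp(-t / tau) + B`, with `t` in seconds from the first
#' frame. The offset `B` is not forced to zero: auto-fluorescence keeps the
#' in-cell mean above the fully bleached level in practice.
#'
#' @param amplitude decay amplitude `A` >= 0.
#' @param offset asymptotic level `B` >= 0.
#' @param tau decay time constant in seconds, > 0 (may be `Inf` when no
#'   bleaching is detectable).
#' @param rss residual sum of squares of the fit.
#' @param f_out mean background (outside-mask) intensity, for diagnostics.
#' @param no_bleach flag set when the series shows no measurable decay.
#' @return an object of class `bleach_model`.
#' @export
bleach_model <- function(amplitude, offset, tau, rss = NA_real_,
                         f_out = NA_real_, no_bleach = FALSE) {
  stopifnot(tau > 0)
  structure(
    list(amplitude = amplitude, offset = offset, tau = tau, rss = rss,
         f_out = f_out, no_bleach = no_bleach),
    class = "bleach_model"
  )
}

#' @export
print.bleach_model <- function(x, ...) {
  if (x$no_bleach) {
    cat(sprintf("bleach_model: no measurable decay (level %.4g)\n", x$offset))
  } else {
    cat(sprintf("bleach_model: A = %.4g, B = %.4g, tau = %.4g s (rss %.3g)\n",
                x$amplitude, x$offset, x$tau, x$rss))
  }
  invisible(x)
}

# Gauss-Newton fit of y ~ A exp(-t/tau) + B with step halving.
gauss_newton_exp <- function(tt, y, init, max_iter, tol) {
  par <- init  # c(A, B, tau)
  res <- y - (par[1L] * exp(-tt / par[3L]) + par[2L])
  rss <- sum(res^2)
  for (it in seq_len(max_iter)) {
    e <- exp(-tt / par[3L])
    jac <- cbind(e, 1, par[1L] * tt * e / par[3L]^2)
    step <- tryCatch(qr.solve(jac, res), error = function(e2) NULL)
    if (is.null(step) || !all(is.finite(step))) {
      stop(sprintf(
        "bleaching fit failed (singular Jacobian) at A=%.4g B=%.4g tau=%.4g",
        par[1L], par[2L], par[3L]))
    }
    lambda <- 1
    repeat {
      cand <- par + lambda * step
      if (cand[3L] > 0) {
        res_c <- y - (cand[1L] * exp(-tt / cand[3L]) + cand[2L])
        rss_c <- sum(res_c^2)
        if (rss_c <= rss) break
      }
      lambda <- lambda / 2
      if (lambda < 1e-12) {  # cannot improve: treat as converged
        return(list(par = par, rss = rss, iterations = it, converged = TRUE))
      }
    }
    converged <- (rss - rss_c) <= tol * (rss + tol)
    par <- cand
    res <- res_c
    rss <- rss_c
    if (converged) {
      return(list(par = par, rss = rss, iterations = it, converged = TRUE))
    }
  }
  list(par = par, rss = rss, iterations = max_iter, converged = FALSE)
}

#' Fit the photobleaching decay
#'
#' Computes the per-frame mean intensity inside the cell mask and fits
#' `A * exp(-t / tau) + B` by Gauss-Newton iterations with step halving,
#' initialized at `B = min(fbar)`, `A = fbar(0) - B`,
#' `tau = T * frame_period / 2`. A constant series returns a no-bleach
#' model (`A = 0`) with a warning rather than an error.
#'
#' `mean_scale = "squared"` fits the model to the squared mean series: the
#' generalized Anscombe transform is a square root, so the squared
#' stabilized mean is affine in the raw intensity and follows the same
#' exponential decay (same `tau`) as the raw signal. [normalize_pipeline()]
#' uses this so that the square-root correction factor of
#' [correct_bleaching()] makes the stabilized mean stationary.
#'
#' @param seq a `spot_sequence` (wide-field; T >= 4).
#' @param mask a `cell_mask` or logical H x W matrix.
#' @param max_iter maximum Gauss-Newton iterations (default 100).
#' @param tol relative residual-sum-of-squares change for convergence
#'   (default 1e-12).
#' @param mean_scale fit the mean series as-is (`"linear"`) or squared
#'   (`"squared"`).
#' @return a `bleach_model`.
#' @export
fit_bleaching <- function(seq, mask, max_iter = 100L, tol = 1e-12,
                          mean_scale = c("linear", "squared")) {
  mean_scale <- match.arg(mean_scale)
  fr <- as_frames(seq)
  stopifnot(length(dim(fr)) == 3L)
  nt <- dim(fr)[3L]
  if (nt < 4L) stop("at least 4 frames required to fit the decay")
  m <- if (inherits(mask, "cell_mask")) mask$mask else mask
  stopifnot(is.logical(m), any(m), !all(m))
  period <- if (inherits(seq, "spot_sequence")) seq$frame_period else 1

  y <- vapply(seq_len(nt), function(t) mean(fr[, , t][m]), numeric(1L))
  f_out <- mean(vapply(seq_len(nt), function(t) mean(fr[, , t][!m]),
                       numeric(1L)))
  if (mean_scale == "squared") y <- y^2
  tt <- (seq_len(nt) - 1L) * period

  b0 <- min(y)
  a0 <- y[1L] - b0
  if (diff(range(y)) <= 1e-8 * max(abs(y), 1) || a0 <= 0) {
    warning("no measurable bleaching decay; returning no-bleach model")
    return(bleach_model(0, mean(y), Inf, rss = sum((y - mean(y))^2),
                        f_out = f_out, no_bleach = TRUE))
  }
  fit <- gauss_newton_exp(tt, y, c(a0, b0, nt * period / 2), max_iter, tol)
  fit$par <- unname(fit$par)
  if (!fit$converged) {
    stop(sprintf(
      "bleaching fit did not converge in %d iterations (last A=%.4g B=%.4g tau=%.4g)",
      max_iter, fit$par[1L], fit$par[2L], fit$par[3L]))
  }
  if (fit$par[3L] <= 0) stop("fitted bleaching time constant is not positive")
  if (fit$par[1L] <= 1e-3 * (fit$par[1L] + fit$par[2L])) {
    # total fractional decay below 0.1%: indistinguishable from no bleaching
    warning("fitted decay amplitude is negligible; returning no-bleach model")
    return(bleach_model(0, mean(y), Inf, rss = fit$rss, f_out = f_out,
                        no_bleach = TRUE))
  }
  bleach_model(fit$par[1L], fit$par[2L], fit$par[3L], rss = fit$rss,
               f_out = f_out)
}

#' Correct a stabilized sequence for photobleaching
#'
#' Multiplies frame `t` by
#' \deqn{c(t) = \sqrt{\frac{A + B}{A e^{-t/\tau} + B}},}
#' which makes the stabilized in-cell mean constant over time when
#' `(A, B, tau)` describe the raw-intensity decay (see [fit_bleaching()]).
#' `c(0) = 1` always; with `B = 0`, `c(t) = exp(t / (2 tau))`. The noise
#' variance of frame `t` is multiplied by `c(t)^2`; this variance inflation
#' profile is recorded in the `"variance_inflation"` attribute of the
#' result so downstream tests can renormalize per frame.
#'
#' @param stab a stabilized `spot_sequence`.
#' @param model a `bleach_model`.
#' @return the corrected `spot_sequence`, with attribute
#'   `"variance_inflation"` (numeric vector of `c(t)^2` per frame).
#' @export
correct_bleaching <- function(stab, model) {
  stopifnot(inherits(stab, "spot_sequence"), inherits(model, "bleach_model"))
  nt <- n_frames(stab)
  tt <- (seq_len(nt) - 1L) * stab$frame_period
  ct <- if (model$no_bleach || model$amplitude == 0) {
    rep(1, nt)
  } else {
    sqrt((model$amplitude + model$offset) /
           (model$amplitude * exp(-tt / model$tau) + model$offset))
  }
  out <- stab
  for (t in seq_len(nt)) out$frames[, , t] <- stab$frames[, , t] * ct[t]
  attr(out, "stabilized") <- attr(stab, "stabilized")
  attr(out, "variance_inflation") <- ct^2
  out
}
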