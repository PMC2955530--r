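#' Generalized extreme value distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the three-parameter generalized extreme value (GEV) distribution in
#' its standard max-form,
#' \deqn{G(x) = \exp\{-[1 + \xi (x - \mu)/\sigma]^{-1/\xi}\},}
#' with the Gumbel limit \eqn{G(x) = \exp\{-e^{-(x-\mu)/\sigma}\}} used when
#' \eqn{|\xi|} is below 1e-8. The GEV is the Fisher-Tippett limit law for
#' extrema and serves here as the null distribution of the minimum patch
#' distance.
#'
#' @param x,q vector of quantiles.
#' @param p vector of probabilities.
#' @param n number of draws.
#' @param loc location parameter \eqn{\mu}.
#' @param scale width parameter \eqn{\sigma > 0}.
#' @param shape shape parameter \eqn{\xi}.
#' @return `dgev` the density, `pgev` the CDF, `qgev` quantiles, `rgev`
#'   random deviates.
#' @name gev
NULL

GUMBEL_EPS <- 1e-8

#' @rdname gev
#' @export
dgev <- function(x, loc, scale, shape) {
  stopifnot(scale > 0)
  z <- (x - loc) / scale
  if (abs(shape) < GUMBEL_EPS) {
    return(exp(-z - exp(-z)) / scale)
  }
  s <- 1 + shape * z
  d <- numeric(length(z))
  d[is.na(s)] <- NA_real_
  ok <- !is.na(s) & s > 0
  d[ok] <- s[ok]^(-1 / shape - 1) * exp(-s[ok]^(-1 / shape)) / scale
  d
}

#' @rdname gev
#' @export
pgev <- function(q, loc, scale, shape) {
  stopifnot(scale > 0)
  z <- (q - loc) / scale
  if (abs(shape) < GUMBEL_EPS) {
    return(exp(-exp(-z)))
  }
  s <- 1 + shape * z
  out <- numeric(length(z))
  out[is.na(s)] <- NA_real_
  ok <- !is.na(s) & s > 0
  out[ok] <- exp(-s[ok]^(-1 / shape))
  # below support for shape > 0 -> 0; above support for shape < 0 -> 1
  out[!is.na(s) & s <= 0] <- if (shape > 0) 0 else 1
  out
}

#' @rdname gev
#' @export
qgev <- function(p, loc, scale, shape) {
  stopifnot(scale > 0, all(p >= 0 & p <= 1))
  if (abs(shape) < GUMBEL_EPS) {
    return(loc - scale * log(-log(p)))
  }
  loc + scale * ((-log(p))^(-shape) - 1) / shape
}

#' @rdname gev
#' @export
rgev <- function(n, loc, scale, shape) {
  qgev(stats::runif(n), loc, scale, shape)
}

#' Construct a GEV parameter triple
#'
#' @param loc location \eqn{\mu}.
#' @param scale width \eqn{\sigma > 0}.
#' @param shape shape \eqn{\xi}.
#' @param n_samples,n_retained bookkeeping of the fit (sample size before and
#'   after outlier preselection).
#' @param method label of the estimator that produced the triple.
#' @return an object of class `gev_params`.
#' @export
gev_params <- function(loc, scale, shape, n_samples = NA_integer_,
                       n_retained = NA_integer_, method = "manual") {
  stopifnot(is.finite(loc), is.finite(scale), scale > 0, is.finite(shape))
  structure(
    list(loc = loc, scale = scale, shape = shape,
         n_samples = as.integer(n_samples),
         n_retained = as.integer(n_retained), method = method),
    class = "gev_params"
  )
}

#' @export
print.gev_params <- function(x, ...) {
  cat(sprintf("GEV(loc = %.4g, scale = %.4g, shape = %.4g) [%s",
              x$loc, x$scale, x$shape, x$method))
  if (!is.na(x$n_retained)) {
    cat(sprintf(", %d/%d samples retained", x$n_retained, x$n_samples))
  }
  cat("]\n")
  invisible(x)
}

# First three sample L-moments via unbiased probability-weighted moments
# (direct order-statistic weighting).
sample_lmoments <- function(x) {
  x <- sort(x)
  n <- length(x)
  stopifnot(n >= 3L)
  i <- seq_len(n)
  b0 <- mean(x)
  b1 <- sum((i - 1) / (n - 1) * x) / n
  b2 <- sum((i - 1) * (i - 2) / ((n - 1) * (n - 2)) * x) / n
  l1 <- b0
  l2 <- 2 * b1 - b0
  l3 <- 6 * b2 - 6 * b1 + b0
  c(l1 = l1, l2 = l2, t3 = l3 / l2)
}

# Hosking's L-moment estimator for the GEV. Hosking parametrizes with
# k = -shape; the rational approximation for k is accurate for |t3| < 0.5.
gev_fit_lmom <- function(x) {
  lm <- sample_lmoments(x)
  if (!is.finite(lm["t3"]) || lm["l2"] <= 0) {
    stop("degenerate sample: L-moment estimation impossible")
  }
  cc <- 2 / (3 + lm[["t3"]]) - log(2) / log(3)
  k <- 7.8590 * cc + 2.9554 * cc^2
  if (abs(k) < GUMBEL_EPS) {
    scale <- lm[["l2"]] / log(2)
    loc <- lm[["l1"]] - 0.5772156649015329 * scale
    shape <- 0
  } else {
    scale <- lm[["l2"]] * k / ((1 - 2^(-k)) * gamma(1 + k))
    loc <- lm[["l1"]] - scale * (1 - gamma(1 + k)) / k
    shape <- -k
  }
  if (!is.finite(scale) || scale <= 0) {
    stop("degenerate sample: L-moment estimation impossible")
  }
  gev_params(loc, scale, shape, n_samples = length(x),
             n_retained = length(x), method = "lmom")
}

gev_negloglik <- function(par, x) {
  loc <- par[1L]
  scale <- exp(par[2L])
  shape <- par[3L]
  z <- (x - loc) / scale
  if (abs(shape) < GUMBEL_EPS) {
    return(length(x) * log(scale) + sum(z + exp(-z)))
  }
  s <- 1 + shape * z
  if (any(s <= 0)) return(.Machine$double.xmax / 2)
  length(x) * log(scale) + (1 / shape + 1) * sum(log(s)) + sum(s^(-1 / shape))
}

#' Fit a GEV null to minimum patch distances
#'
#' Mixed L-moments / maximum-likelihood estimator with robust outlier
#' preselection. When a prior GEV is supplied, samples above its
#' `presel_quantile` quantile are discarded before fitting, so that true
#' events (unusually large minimum distances) do not contaminate the null
#' estimate. L-moment estimates initialize a maximum-likelihood refinement;
#' if the likelihood optimization fails, the L-moment estimate is returned
#' with a warning.
#'
#' @param minima numeric vector of observed minimum distances.
#' @param prior optional `gev_params` used for preselection (typically the
#'   Monte-Carlo white-noise null for the first frame pair, the previous fit
#'   afterwards).
#' @param presel_quantile probability of the prior quantile above which
#'   samples are discarded (default 0.999).
#' @param shape_min optional lower bound on the shape parameter. The
#'   detection null uses `shape_min = 0` (Gumbel floor): the upper tail of
#'   the minimum of a set of correlated chi-square distances decays
#'   exponentially, and an unconstrained fit can return a Weibull-type
#'   (negative-shape) law whose finite upper endpoint truncates exactly the
#'   tail the per-test thresholds extrapolate into.
#' @return a `gev_params` object.
#' @export
fit_gev <- function(minima, prior = NULL, presel_quantile = 0.999,
                    shape_min = NULL) {
  stopifnot(is.numeric(minima), presel_quantile > 0.9, presel_quantile < 1)
  x <- minima[is.finite(minima)]
  n0 <- length(x)
  if (!is.null(prior)) {
    stopifnot(inherits(prior, "gev_params"))
    cut <- qgev(presel_quantile, prior$loc, prior$scale, prior$shape)
    x <- x[x <= cut]
  }
  if (length(x) < 100L) {
    stop("insufficient null sample: fewer than 100 retained minima")
  }
  if (stats::sd(x) == 0) stop("degenerate sample: constant minima")
  init <- gev_fit_lmom(x)
  fit <- tryCatch(
    stats::optim(c(init$loc, log(init$scale), init$shape), gev_negloglik,
                 x = x, method = "Nelder-Mead",
                 control = list(maxit = 2000L, reltol = 1e-10)),
    error = function(e) NULL
  )
  if (is.null(fit) || fit$convergence != 0 || !all(is.finite(fit$par))) {
    warning("GEV maximum-likelihood refinement failed; using L-moment estimate")
    init$n_samples <- n0
    if (!is.null(shape_min) && init$shape < shape_min) {
      init$shape <- shape_min
    }
    return(init)
  }
  par <- c(fit$par[1L], exp(fit$par[2L]), fit$par[3L])
  if (!is.null(shape_min) && par[3L] < shape_min) {
    # profile out location and scale with the shape held at the bound
    fix <- tryCatch(
      stats::optim(c(par[1L], log(par[2L])), function(th) {
        gev_negloglik(c(th[1L], th[2L], shape_min), x)
      }, method = "Nelder-Mead", control = list(maxit = 2000L, reltol = 1e-10)),
      error = function(e) NULL
    )
    if (!is.null(fix) && all(is.finite(fix$par))) {
      par <- c(fix$par[1L], exp(fix$par[2L]), shape_min)
    } else {
      par[3L] <- shape_min
    }
  }
  gev_params(par[1L], par[2L], par[3L],
             n_samples = n0, n_retained = length(x), method = "lmom+ml")
}

#' Upper-tail p-value under a GEV null
#'
#' An event corresponds to an unusually poor best match, i.e. a minimum
#' distance in the upper tail of the null, so `p = 1 - G(d_min)`. The
#' Gumbel limit is used for |shape| < 1e-8; values outside the GEV support
#' map to p = 0 (above, shape < 0) or p = 1 (below, shape > 0). p is
#' non-increasing in `d_min`.
#'
#' @param d_min numeric vector (or matrix) of minimum distances.
#' @param params a `gev_params` object.
#' @return p-values with the shape of `d_min`, clamped to \[0, 1\].
#' @export
gev_pvalue <- function(d_min, params) {
  stopifnot(inherits(params, "gev_params"))
  p <- 1 - pgev(as.numeric(d_min), params$loc, params$scale, params$shape)
  p <- pmin(pmax(p, 0), 1)
  if (is.matrix(d_min)) p <- matrix(p, nrow(d_min), ncol(d_min))
  p[is.na(d_min)] <- NA_real_
  p
}
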