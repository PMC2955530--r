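#' Segment the cell from the background
#'
#' Models the intensity histogram as a mixture of two Gaussian components
#' (background and cell) fitted by Expectation-Maximization, then assigns
#' each pixel to the component with the higher posterior probability. The
#' cell is the component with the larger mean. Because the EM is initialized
#' from the 25th/75th intensity percentiles with equal weights and
#' scale-proportional spreads, the hard assignment is invariant to affine
#' rescaling of the image.
#'
#' For time-lapse data, segment a temporal summary image (see
#' [normalize_pipeline()], which uses the temporal mean to suppress noise).
#'
#' @param image H x W numeric matrix.
#' @param max_iter maximum EM iterations (default 500).
#' @param tol relative log-likelihood change below which EM stops
#'   (default 1e-8).
#' @return an object of class `cell_mask`: `mask` (H x W logical, TRUE =
#'   cell), `mixture` (data frame of mean, sd, weight per component),
#'   `area` (cell pixel count), `loglik`, `iterations`.
#' @export
segment_cell <- function(image, max_iter = 500L, tol = 1e-8) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  x <- as.numeric(image)
  rng <- diff(range(x))
  if (rng == 0) stop("degenerate mixture: constant image")

  mu <- unname(stats::quantile(x, c(0.25, 0.75)))
  if (mu[1L] == mu[2L]) mu <- mu + c(-0.25, 0.25) * rng
  sd2 <- rep(stats::sd(x) / 2, 2L)
  w <- c(0.5, 0.5)
  ll_old <- -Inf
  it <- 0L
  repeat {
    it <- it + 1L
    d1 <- w[1L] * stats::dnorm(x, mu[1L], sd2[1L])
    d2 <- w[2L] * stats::dnorm(x, mu[2L], sd2[2L])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r2 <- d2 / tot
    ll <- sum(log(tot))
    if (is.finite(ll_old) &&
        abs(ll - ll_old) <= tol * (abs(ll_old) + tol)) break
    if (it >= max_iter) break
    ll_old <- ll
    n2 <- sum(r2)
    n1 <- length(x) - n2
    if (n1 < 2 || n2 < 2) stop("degenerate mixture: empty component")
    mu[1L] <- sum((1 - r2) * x) / n1
    mu[2L] <- sum(r2 * x) / n2
    v1 <- sum((1 - r2) * (x - mu[1L])^2) / n1
    v2 <- sum(r2 * (x - mu[2L])^2) / n2
    if (v1 <= (1e-12 * rng)^2 || v2 <= (1e-12 * rng)^2) {
      stop("degenerate mixture: component variance collapsed")
    }
    sd2 <- sqrt(c(v1, v2))
    w <- c(n1, n2) / length(x)
  }

  # cell = component with the higher mean
  cell_cmp <- which.max(mu)
  post_cell <- if (cell_cmp == 2L) r2 else 1 - r2
  mask <- matrix(post_cell > 0.5, nrow(image), ncol(image))
  area <- sum(mask)
  if (area == 0L || area == length(x)) {
    stop("degenerate mixture: segmentation assigned a single class")
  }
  ord <- order(mu)
  structure(
    list(mask = mask,
         mixture = data.frame(component = c("background", "cell"),
                              mean = mu[ord], sd = sd2[ord],
                              weight = w[ord]),
         area = area, loglik = ll, iterations = it),
    class = "cell_mask"
  )
}

#' @export
print.cell_mask <- function(x, ...) {
  cat(sprintf("cell_mask: %d px cell area (%.1f%% of image)\n", x$area,
              100 * x$area / length(x$mask)))
  print(x$mixture, row.names = FALSE)
  invisible(x)
}
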