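# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library calls never perturb user RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      stats::runif(1L)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Summed-area-table box filter: out[y, x] = sum of m over the (2q+1)^2 square
# centred at (y, x). Positions closer than q to the border are NA.
box_sum <- function(m, q) {
  h <- nrow(m)
  w <- ncol(m)
  stopifnot(q >= 0L, h > 2L * q, w > 2L * q)
  if (q == 0L) return(m)
  s <- matrix(0, h + 1L, w + 1L)
  s[-1L, -1L] <- t(apply(apply(m, 2L, cumsum), 1L, cumsum))
  out <- matrix(NA_real_, h, w)
  i <- (1L + q):(h - q)
  j <- (1L + q):(w - q)
  out[i, j] <- s[i + q + 1L, j + q + 1L] - s[i - q, j + q + 1L] -
    s[i + q + 1L, j - q] + s[i - q, j - q]
  out
}

# out[y, x] = m[y + dy, x + dx]; cells whose source falls outside get `fill`.
shift_mat <- function(m, dy, dx, fill = NA_real_) {
  h <- nrow(m)
  w <- ncol(m)
  out <- matrix(fill, h, w)
  ys <- max(1L, 1L - dy):min(h, h - dy)
  xs <- max(1L, 1L - dx):min(w, w - dx)
  if (length(ys) > 0L && length(xs) > 0L) {
    out[ys, xs] <- m[ys + dy, xs + dx]
  }
  out
}

# Binary dilation of a logical matrix with a (2r+1)^2 square structuring
# element, used to grow the cell mask by the search radius.
dilate_mask <- function(mask, r) {
  if (r <= 0L) return(mask)
  out <- mask
  for (dy in -r:r) {
    for (dx in -r:r) {
      if (dy == 0L && dx == 0L) next
      out <- out | shift_mat(mask, dy, dx, fill = FALSE)
    }
  }
  out
}

is_odd <- function(x) x %% 2L == 1L
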