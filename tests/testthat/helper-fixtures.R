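# Shared fixture builders; everything is generated in code at test time.

# Unit-variance Gaussian white-noise sequence, the idealized output of a
# perfectly stabilized acquisition.
unit_noise_seq <- function(h = 64L, w = 64L, nt = 4L, seed = 1L) {
  set.seed(seed)
  array(stats::rnorm(h * w * nt), dim = c(h, w, nt))
}

# Add a Gaussian spot of peak `amp` at integer centre (x0, y0) to the given
# frames of an array.
inject_spot <- function(fr, x0, y0, amp, frames, sigma = 1.5) {
  rad <- ceiling(3 * sigma)
  for (t in frames) {
    for (dy in -rad:rad) {
      for (dx in -rad:rad) {
        y <- y0 + dy
        x <- x0 + dx
        if (y >= 1 && y <= dim(fr)[1L] && x >= 1 && x <= dim(fr)[2L]) {
          fr[y, x, t] <- fr[y, x, t] + amp * exp(-(dy^2 + dx^2) / (2 * sigma^2))
        }
      }
    }
  }
  fr
}

# Small benchmark configuration used throughout the detection tests: the
# generator's default conditions scaled to a quarter of the field of view
# with area-proportional spot and mover counts.
scaled_sim_config <- function(spot_intensity = 120, n_event_spots = 25L,
                              n_movers = 5L, n_frames = 40L) {
  sim_config(n_frames = n_frames, height = 128L, width = 128L,
             n_event_spots = n_event_spots, spot_intensity = spot_intensity,
             n_movers = n_movers)
}

count_significant <- function(det) {
  sum(vapply(det$pairs, function(p) sum(p$significant, na.rm = TRUE),
             numeric(1L)))
}

surviving_clusters <- function(cl) {
  cl$clusters[!cl$clusters$discarded, , drop = FALSE]
}
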