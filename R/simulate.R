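#' Configuration of the synthetic benchmark generator
#'
#' The generator emulates a fluorescence acquisition of a single cell: a
#' flat background at 2500 measured intensity levels, an elliptic cell at
#' 2600 levels, 100 Gaussian event spots (half suddenly appearing, half
#' suddenly vanishing), dummy spots moving as a Gaussian random walk, and
#' an affine Poisson-Gaussian sensor with gain 0.1 and dark signal
#' N(2000, 3.6^2). All intensities are specified on the measured (gray
#' level) scale and converted to photon flux via
#' `lambda = (level - dark_mean) / gain`, so the expected measured image
#' reproduces the specified levels with variance
#' `gain * (level - dark_mean) + dark_sd^2`. Spot intensity (added to the
#' local level at the spot peak) is the signal-to-noise axis, swept from 20
#' to 200 in the benchmark.
#'
#' @param n_frames frames per sequence (default 100).
#' @param height,width frame size in pixels (default 256 x 256).
#' @param background background level in measured intensity units
#'   (default 2500).
#' @param cell_level in-cell level in measured intensity units
#'   (default 2600).
#' @param ellipse_center,ellipse_axes cell ellipse centre and semi-axes in
#'   pixels (defaults: image centre, semi-axes 100 x 70 at 256 x 256,
#'   scaled proportionally otherwise).
#' @param n_event_spots number of ground-truth event spots (default 100).
#' @param spot_intensity peak intensity a spot adds, measured units
#'   (default 100; the benchmark sweeps 20..200).
#' @param spot_sigma Gaussian spot width in pixels (default 1.5, a
#'   diffraction-limited spot).
#' @param n_movers number of moving dummy spots (default 20).
#' @param mover_step_sd random-walk step standard deviation in px/frame
#'   (default 1; comparable to the search radius, so the patch matcher
#'   can usually track a mover while occasional larger steps escape it).
#' @param gain,dark_mean,dark_sd sensor parameters (defaults 0.1, 2000,
#'   3.6).
#' @param frame_period seconds per frame (default 1).
#' @param min_separation minimum distance between event spots in pixels
#'   (default 6, so ground-truth events are unambiguous at the matching
#'   tolerance).
#' @param bleach_tau optional bleaching time constant in seconds; `NULL`
#'   (default) disables bleaching, matching the benchmark conditions.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_frames = 100L, height = 256L, width = 256L,
                       background = 2500, cell_level = 2600,
                       ellipse_center = NULL, ellipse_axes = NULL,
                       n_event_spots = 100L, spot_intensity = 100,
                       spot_sigma = 1.5, n_movers = 20L, mover_step_sd = 1,
                       gain = 0.1, dark_mean = 2000, dark_sd = 3.6,
                       frame_period = 1, min_separation = 6,
                       bleach_tau = NULL) {
  if (is.null(ellipse_center)) ellipse_center <- c((width + 1) / 2, (height + 1) / 2)
  if (is.null(ellipse_axes)) {
    ellipse_axes <- c(100, 70) * min(width, height) / 256
  }
  stopifnot(n_frames >= 2L, height >= 32L, width >= 32L,
            background > dark_mean, cell_level > dark_mean,
            n_event_spots >= 0L, spot_intensity > 0,
            spot_sigma > 0, n_movers >= 0L, mover_step_sd >= 0, gain > 0,
            dark_sd >= 0, frame_period > 0, min_separation >= 0)
  structure(
    list(n_frames = as.integer(n_frames), height = as.integer(height),
         width = as.integer(width), background = background,
         cell_level = cell_level, ellipse_center = ellipse_center,
         ellipse_axes = ellipse_axes,
         n_event_spots = as.integer(n_event_spots),
         spot_intensity = spot_intensity, spot_sigma = spot_sigma,
         n_movers = as.integer(n_movers), mover_step_sd = mover_step_sd,
         gain = gain, dark_mean = dark_mean, dark_sd = dark_sd,
         frame_period = frame_period, min_separation = min_separation,
         bleach_tau = bleach_tau),
    class = "sim_config"
  )
}

# Rasterize the cell ellipse.
ellipse_mask <- function(cfg) {
  x <- matrix(seq_len(cfg$width), cfg$height, cfg$width, byrow = TRUE)
  y <- matrix(seq_len(cfg$height), cfg$height, cfg$width)
  ((x - cfg$ellipse_center[1L]) / cfg$ellipse_axes[1L])^2 +
    ((y - cfg$ellipse_center[2L]) / cfg$ellipse_axes[2L])^2 <= 1
}

# Draw positions uniformly inside the ellipse, at least min_sep apart.
draw_spot_positions <- function(cfg, n, min_sep, max_tries = 2000L) {
  pos <- matrix(NA_real_, n, 2L)
  a <- cfg$ellipse_axes[1L]
  b <- cfg$ellipse_axes[2L]
  cx <- cfg$ellipse_center[1L]
  cy <- cfg$ellipse_center[2L]
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      x <- stats::runif(1L, cx - a, cx + a)
      y <- stats::runif(1L, cy - b, cy + b)
      if (((x - cx) / a)^2 + ((y - cy) / b)^2 > 1) next
      if (i > 1L) {
        d <- sqrt((pos[seq_len(i - 1L), 1L] - x)^2 +
                    (pos[seq_len(i - 1L), 2L] - y)^2)
        if (min(d, na.rm = TRUE) < min_sep) next
      }
      pos[i, ] <- c(x, y)
      ok <- TRUE
      break
    }
    if (!ok) stop("could not place a spot inside the ellipse after retries")
  }
  pos
}

# Add a Gaussian spot of peak amplitude `amp` at (x0, y0) to flux frame `f`.
add_spot <- function(f, x0, y0, amp, sigma) {
  rad <- ceiling(3 * sigma)
  xs <- max(1L, round(x0) - rad):min(ncol(f), round(x0) + rad)
  ys <- max(1L, round(y0) - rad):min(nrow(f), round(y0) + rad)
  g <- amp * exp(-(outer((ys - y0)^2, (xs - x0)^2, "+")) / (2 * sigma^2))
  f[ys, xs] <- f[ys, xs] + g
  f
}

#' Generate a synthetic benchmark sequence with ground truth
#'
#' Builds the photon-flux movie (background + cell ellipse + event spots
#' present only between their birth and death frames + random-walk movers),
#' then applies the sensor model per pixel and frame:
#' `z = gain * Poisson(flux) + Normal(dark_mean, dark_sd^2)`. Half the
#' event spots appear (birth uniform in the central frame range, persisting
#' to the end), half vanish (present from the start, death uniform).
#' Reproducible: equal seeds give bit-identical sequences.
#'
#' @param cfg a `sim_config`.
#' @param seed integer seed.
#' @return an object of class `sim_sequence`: `sequence` (a
#'   `spot_sequence`), `truth` (data frame with one row per event spot:
#'   `x`, `y`, `kind` ("appear"/"vanish"), `birth`, `death`, `pair` = the
#'   frame-pair index on which the event happens), `movers` (list of
#'   trajectories), `cfg`, `seed`, `cell` (ground-truth ellipse mask).
#' @export
generate_sequence <- function(cfg = sim_config(), seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(seed, {
    cell <- ellipse_mask(cfg)
    base <- matrix(cfg$background, cfg$height, cfg$width)
    base[cell] <- cfg$cell_level

    n_ev <- cfg$n_event_spots
    pos <- if (n_ev > 0L) {
      draw_spot_positions(cfg, n_ev, cfg$min_separation)
    } else {
      matrix(numeric(0L), 0L, 2L)
    }
    n_app <- n_ev %/% 2L
    kind <- rep(c("appear", "vanish"), c(n_app, n_ev - n_app))
    lo <- 6L
    hi <- max(cfg$n_frames - 5L, lo + 1L)
    birth <- integer(n_ev)
    death <- integer(n_ev)
    change <- if (n_ev > 0L) sample(lo:hi, n_ev, replace = TRUE) else integer(0L)
    for (i in seq_len(n_ev)) {
      if (kind[i] == "appear") {
        birth[i] <- change[i]            # first frame present
        death[i] <- cfg$n_frames + 1L    # persists to the end
      } else {
        birth[i] <- 1L
        death[i] <- change[i]            # first frame absent
      }
    }
    truth <- data.frame(
      spot = seq_len(n_ev), x = pos[, 1L], y = pos[, 2L], kind = kind,
      birth = birth, death = death,
      pair = change - 1L  # event visible on pair (change - 1, change)
    )

    movers <- vector("list", cfg$n_movers)
    if (cfg$n_movers > 0L) {
      mpos <- draw_spot_positions(cfg, cfg$n_movers, 0)
      for (j in seq_len(cfg$n_movers)) {
        steps_x <- stats::rnorm(cfg$n_frames - 1L, 0, cfg$mover_step_sd)
        steps_y <- stats::rnorm(cfg$n_frames - 1L, 0, cfg$mover_step_sd)
        tx <- pmin(pmax(cumsum(c(mpos[j, 1L], steps_x)), 1), cfg$width)
        ty <- pmin(pmax(cumsum(c(mpos[j, 2L], steps_y)), 1), cfg$height)
        movers[[j]] <- cbind(x = tx, y = ty)
      }
    }

    decay <- if (is.null(cfg$bleach_tau)) {
      rep(1, cfg$n_frames)
    } else {
      exp(-(seq_len(cfg$n_frames) - 1L) * cfg$frame_period / cfg$bleach_tau)
    }

    frames <- array(0, dim = c(cfg$height, cfg$width, cfg$n_frames))
    for (t in seq_len(cfg$n_frames)) {
      # expected measured image in gray levels
      level <- matrix(cfg$background, cfg$height, cfg$width)
      # bleaching (when enabled) fades the cell excess over background
      level[cell] <- cfg$background +
        (cfg$cell_level - cfg$background) * decay[t]
      for (i in seq_len(n_ev)) {
        if (t >= truth$birth[i] && t < truth$death[i]) {
          level <- add_spot(level, truth$x[i], truth$y[i],
                            cfg$spot_intensity * decay[t], cfg$spot_sigma)
        }
      }
      for (j in seq_len(cfg$n_movers)) {
        # movers are rendered on the pixel lattice so that a whole-pixel
        # displacement inside the search window can be matched exactly
        level <- add_spot(level, round(movers[[j]][t, 1L]),
                          round(movers[[j]][t, 2L]),
                          cfg$spot_intensity * decay[t], cfg$spot_sigma)
      }
      flux <- (level - cfg$dark_mean) / cfg$gain
      frames[, , t] <- cfg$gain * stats::rpois(length(flux), flux) +
        stats::rnorm(length(flux), cfg$dark_mean, cfg$dark_sd)
    }
    modality <- if (is.null(cfg$bleach_tau)) "TIRF" else "WF"
    structure(
      list(sequence = spot_sequence(frames, cfg$frame_period, modality),
           truth = truth, movers = movers, cfg = cfg, seed = seed,
           cell = cell),
      class = "sim_sequence"
    )
  })
}

#' @export
print.sim_sequence <- function(x, ...) {
  cat(sprintf(
    "sim_sequence (seed %d): %d event spots (%d appear / %d vanish), %d movers\n",
    x$seed, nrow(x$truth), sum(x$truth$kind == "appear"),
    sum(x$truth$kind == "vanish"), length(x$movers)))
  print(x$sequence)
  invisible(x)
}

#' Score detections against the generator ground truth
#'
#' Greedy one-to-one matching: candidate detection/truth pairs within the
#' spatial and temporal tolerances are matched in order of ascending
#' spatial distance; each detection and each truth event is used at most
#' once. Matched detections are true positives, unmatched detections false
#' alarms, unmatched truth events misses.
#'
#' @param detections data frame with `x`, `y`, `pair` columns (e.g. the
#'   surviving clusters of [meanshift_cluster()]).
#' @param truth truth data frame of a `sim_sequence` (or the object itself).
#' @param tol_xy spatial matching tolerance in pixels (default 3).
#' @param tol_t temporal tolerance in frame pairs (default 1).
#' @return list with `tp`, `fa`, `fn` counts and `matches` (data frame of
#'   matched detection/truth row indices and their distance).
#' @export
match_detections <- function(detections, truth, tol_xy = 3, tol_t = 1) {
  if (inherits(truth, "sim_sequence")) truth <- truth$truth
  nd <- nrow(detections)
  nt <- nrow(truth)
  if (nd == 0L) {
    return(list(tp = 0L, fa = 0L, fn = nt,
                matches = data.frame(detection = integer(0L),
                                     truth = integer(0L),
                                     dist = numeric(0L))))
  }
  cand <- NULL
  for (i in seq_len(nd)) {
    dt <- abs(detections$pair[i] - truth$pair)
    dxy <- sqrt((detections$x[i] - truth$x)^2 +
                  (detections$y[i] - truth$y)^2)
    j <- which(dt <= tol_t & dxy <= tol_xy)
    if (length(j) > 0L) {
      cand <- rbind(cand, data.frame(detection = i, truth = j,
                                     dist = dxy[j]))
    }
  }
  matches <- data.frame(detection = integer(0L), truth = integer(0L),
                        dist = numeric(0L))
  if (!is.null(cand)) {
    cand <- cand[order(cand$dist), , drop = FALSE]
    used_d <- logical(nd)
    used_t <- logical(nt)
    for (k in seq_len(nrow(cand))) {
      i <- cand$detection[k]
      j <- cand$truth[k]
      if (!used_d[i] && !used_t[j]) {
        used_d[i] <- TRUE
        used_t[j] <- TRUE
        matches <- rbind(matches, cand[k, ])
      }
    }
  }
  tp <- nrow(matches)
  list(tp = tp, fa = nd - tp, fn = nt - tp, matches = matches)
}

# One full pipeline pass on a simulated sequence; the p-value maps are
# computed once per method and both controls are applied to them, so the
# expensive patch matching is not repeated.
score_sim_sequence <- function(sim, method = c("ssd", "fd"),
                               controls = c("fwer", "fdr"), alpha = 0.05,
                               patch_cfg = patch_config(alpha = alpha),
                               fd_cfg = fd_config(alpha = alpha),
                               seed = 1L, h_s = 3, h_t = 1, norm = NULL) {
  method <- match.arg(method)
  if (is.null(norm)) norm <- normalize_pipeline(sim$sequence)
  det0 <- if (method == "ssd") {
    cfg <- patch_cfg
    cfg$control <- controls[1L]
    detect(norm, cfg, seed = seed)
  } else {
    cfg <- fd_cfg
    cfg$control <- controls[1L]
    framediff_detect(norm, cfg)
  }
  out <- list()
  for (ctrl in controls) {
    det <- reapply_control(det0, ctrl, alpha)
    ev <- extract_events(det, norm)
    # the FD baseline shares pre-processing and statistical control with the
    # patch method but not its motion-artifact post-processing
    cl <- meanshift_cluster(ev, h_s = h_s, h_t = h_t,
                            motion_filter = method == "ssd")
    keep <- cl$clusters[!cl$clusters$discarded, , drop = FALSE]
    sc <- match_detections(keep, sim$truth)
    out[[ctrl]] <- list(score = sc, n_clusters = nrow(keep),
                        rate = event_rate(cl, n_frames(sim$sequence)))
  }
  out
}

#' Re-apply a multiple-testing control to stored p-value maps
#'
#' Detection results keep the per-pair p-value maps, so a different control
#' (or level) can be applied without recomputing the distance maps.
#'
#' @param det a `detection_result`.
#' @param control `"fwer"` or `"fdr"`.
#' @param alpha significance level.
#' @param fdr_dependent Benjamini-Yekutieli divisor in FDR mode; defaults
#'   to the value in the result's configuration.
#' @return a `detection_result` with updated significance maps.
#' @export
reapply_control <- function(det, control = c("fwer", "fdr"), alpha = 0.05,
                            fdr_dependent = NULL) {
  control <- match.arg(control)
  if (is.null(fdr_dependent)) {
    fdr_dependent <- isTRUE(det$cfg$fdr_dependent)
  }
  n_tests <- sum(det$tested)
  for (tp in seq_along(det$pairs)) {
    p <- det$pairs[[tp]]$p
    ctrl <- if (control == "fwer") {
      control_fwer_sidak(p, alpha, n_tests)
    } else {
      control_fdr_bh(p, alpha, dependent = fdr_dependent)
    }
    det$pairs[[tp]]$significant <- ctrl$significant
    det$pairs[[tp]]$threshold <- ctrl$threshold
  }
  det$cfg$control <- control
  det$cfg$alpha <- alpha
  det
}

#' Benchmark sweep over spot intensities
#'
#' Runs the full pipeline (normalization, detection, clustering, scoring)
#' over a grid of spot intensities for the patch (SSD) and frame-difference
#' (FD) methods under FWER and FDR control, on `n_seq` independently seeded
#' sequences per intensity, and aggregates mean true-positive and
#' false-alarm counts. The reported SNR column is the peak spot amplitude
#' over the measured noise standard deviation at the spot peak,
#' `a / sqrt(gain * (background + a - dark_mean) + dark_sd^2)`.
#'
#' @param intensities numeric vector of spot intensities (the benchmark
#'   sweeps 20 to 200).
#' @param cfg base `sim_config`; its `spot_intensity` is overridden.
#' @param n_seq sequences per intensity (default 3).
#' @param methods subset of `c("ssd", "fd")`.
#' @param controls subset of `c("fwer", "fdr")`.
#' @param alpha significance level for both controls (default 0.05).
#' @param patch_cfg,fd_cfg detection configurations (their `control` and
#'   `alpha` fields are overridden per sweep cell).
#' @param base_seed integer; sequence s at intensity index i uses seed
#'   `base_seed + 1000 * i + s`, and the detection Monte-Carlo uses
#'   `base_seed`.
#' @return data frame with one row per (intensity, method, control,
#'   replicate): `intensity`, `snr`, `method`, `control`, `seed`, `tp`,
#'   `fa`, `fn`.
#' @export
snr_sweep <- function(intensities = seq(20, 200, by = 20),
                      cfg = sim_config(), n_seq = 3L,
                      methods = c("ssd", "fd"),
                      controls = c("fwer", "fdr"), alpha = 0.05,
                      patch_cfg = patch_config(alpha = alpha),
                      fd_cfg = fd_config(alpha = alpha),
                      base_seed = 1L) {
  stopifnot(length(intensities) >= 1L)
  rows <- list()
  for (i in seq_along(intensities)) {
    a <- intensities[i]
    snr <- a /
      sqrt(cfg$gain * (cfg$background + a - cfg$dark_mean) + cfg$dark_sd^2)
    for (s in seq_len(n_seq)) {
      ccfg <- cfg
      ccfg$spot_intensity <- a
      sim <- generate_sequence(ccfg, seed = base_seed + 1000L * i + s)
      norm <- normalize_pipeline(sim$sequence)
      for (method in methods) {
        res <- score_sim_sequence(sim, method, controls, alpha,
                                  patch_cfg = patch_cfg, fd_cfg = fd_cfg,
                                  seed = base_seed, norm = norm)
        for (ctrl in controls) {
          rows[[length(rows) + 1L]] <- data.frame(
            intensity = a, snr = snr, method = method, control = ctrl,
            seed = sim$seed, tp = res[[ctrl]]$score$tp,
            fa = res[[ctrl]]$score$fa, fn = res[[ctrl]]$score$fn)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate a sweep table to per-condition means
#'
#' @param sweep output of [snr_sweep()].
#' @return data frame of mean `tp` and `fa` per (intensity, method,
#'   control).
#' @export
summarize_sweep <- function(sweep) {
  agg <- stats::aggregate(cbind(tp, fa) ~ intensity + snr + method + control,
                          data = sweep, FUN = mean)
  agg[order(agg$method, agg$control, agg$intensity), ]
}
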