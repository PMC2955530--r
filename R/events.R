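#' Label connected regions of a detection mask
#'
#' Groups the "active" detected pixels of one frame pair into connected
#' regions (8-connectivity: diagonal neighbours belong to the same region)
#' and computes the unweighted barycenter of each region.
#'
#' @param mask logical H x W matrix.
#' @return data frame with one row per region: `region`, `x`, `y`
#'   (barycenter, 1-based pixel coordinates, x = column), `size`; the
#'   attribute `"pixels"` holds the list of linear pixel indices per region.
#' @export
label_regions <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  h <- nrow(mask)
  w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  pix <- list()
  idx <- which(mask)
  for (i0 in idx) {
    if (lab[i0] > 0L) next
    cur <- cur + 1L
    stack <- i0
    lab[i0] <- cur
    members <- integer(0L)
    while (length(stack) > 0L) {
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      members <- c(members, i)
      y <- (i - 1L) %% h + 1L
      x <- (i - 1L) %/% h + 1L
      for (dy in -1L:1L) {
        for (dx in -1L:1L) {
          yy <- y + dy
          xx <- x + dx
          if (yy < 1L || yy > h || xx < 1L || xx > w) next
          j <- (xx - 1L) * h + yy
          if (mask[j] && lab[j] == 0L) {
            lab[j] <- cur
            stack <- c(stack, j)
          }
        }
      }
    }
    pix[[cur]] <- members
  }
  if (cur == 0L) {
    out <- data.frame(region = integer(0L), x = numeric(0L),
                      y = numeric(0L), size = integer(0L))
    attr(out, "pixels") <- list()
    return(out)
  }
  xs <- vapply(pix, function(m) mean((m - 1L) %/% h + 1L), numeric(1L))
  ys <- vapply(pix, function(m) mean((m - 1L) %% h + 1L), numeric(1L))
  out <- data.frame(region = seq_len(cur), x = xs, y = ys,
                    size = vapply(pix, length, integer(1L)))
  attr(out, "pixels") <- pix
  out
}

#' Classify the polarity of a detected region
#'
#' A region is `appearing` when the mean temporal difference
#' `f(., t + interval) - f(., t)` over its pixels is positive (fluorescence
#' concentrated between the two frames), `vanishing` when negative. An
#' exact zero is classified as appearing (documented tie rule). Negating
#' the sequence flips every (non-tied) polarity.
#'
#' @param pixels integer vector of linear pixel indices of the region.
#' @param frame_a,frame_b the two frames of the pair.
#' @return `"appearing"` or `"vanishing"`.
#' @export
classify_polarity <- function(pixels, frame_a, frame_b) {
  stopifnot(length(pixels) >= 1L)
  if (mean(frame_b[pixels] - frame_a[pixels]) >= 0) "appearing" else "vanishing"
}

#' Extract polarity-tagged events from a detection result
#'
#' Labels the significant pixels of every frame pair and classifies each
#' region's polarity from the corresponding frames of the sequence.
#'
#' @param det a `detection_result` (from [detect()] or
#'   [framediff_detect()]).
#' @param seq the sequence the detection ran on (a `normalized_sequence`,
#'   `spot_sequence`, or array).
#' @param min_size smallest region (pixels) kept as an event (default 2:
#'   a diffraction-limited spot always activates several neighbouring
#'   sites, while isolated single-pixel rejections are the false
#'   discoveries an adaptive FDR threshold admits by construction).
#' @return data frame of events: `id`, `pair` (index of the first frame of
#'   the pair), `x`, `y`, `polarity`, `size`, `balance`.
#' @export
extract_events <- function(det, seq, min_size = 2L) {
  stopifnot(inherits(det, "detection_result"))
  if (inherits(seq, "normalized_sequence")) seq <- seq$sequence
  fr <- as_frames(seq)
  delta <- det$cfg$frame_interval
  rows <- list()
  for (tp in seq_along(det$pairs)) {
    regs <- label_regions(det$pairs[[tp]]$significant)
    pix <- attr(regs, "pixels")
    keep <- regs$size >= min_size
    regs <- regs[keep, , drop = FALSE]
    pix <- pix[keep]
    if (nrow(regs) == 0L) next
    a <- fr[, , tp]
    b <- fr[, , tp + delta]
    regs$polarity <- vapply(pix, classify_polarity, character(1L),
                            frame_a = a, frame_b = b)
    # polarity balance: a region where positive and negative temporal
    # differences carry comparable weight is a displacement dipole (the
    # vanishing old position and appearing new position of a moving spot
    # fused into one region), not a transient event
    regs$balance <- vapply(pix, function(px) {
      d <- b[px] - a[px]
      pos <- sum(d[d > 0])
      neg <- -sum(d[d < 0])
      if (max(pos, neg) == 0) 0 else min(pos, neg) / max(pos, neg)
    }, numeric(1L))
    regs$pair <- tp
    rows[[length(rows) + 1L]] <-
      regs[, c("pair", "x", "y", "polarity", "size", "balance")]
  }
  if (length(rows) == 0L) {
    return(data.frame(id = integer(0L), pair = integer(0L), x = numeric(0L),
                      y = numeric(0L), polarity = character(0L),
                      size = integer(0L), balance = numeric(0L)))
  }
  out <- do.call(rbind, rows)
  out <- cbind(id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

# Plain mean-shift in bandwidth-scaled coordinates; returns cluster ids
# and scaled mode matrix.
meanshift_modes <- function(pts, tol, max_iter) {
  n <- nrow(pts)
  modes <- pts
  for (it in seq_len(max_iter)) {
    # squared distances from every current mode to every original point
    d2 <- outer(rowSums(modes^2), rowSums(pts^2), "+") -
      2 * modes %*% t(pts)
    kw <- exp(-pmax(d2, 0) / 2)
    new_modes <- (kw %*% pts) / rowSums(kw)
    shift <- sqrt(max(rowSums((new_modes - modes)^2)))
    modes <- new_modes
    if (shift < tol) break
  }
  # merge modes within half a bandwidth (0.5 in scaled coordinates)
  cluster <- integer(n)
  centers <- NULL
  for (i in seq_len(n)) {
    assigned <- FALSE
    if (!is.null(centers)) {
      dd <- sqrt(rowSums((centers - matrix(modes[i, ], nrow(centers), 3L,
                                           byrow = TRUE))^2))
      j <- which(dd < 0.5)
      if (length(j) > 0L) {
        cluster[i] <- j[1L]
        assigned <- TRUE
      }
    }
    if (!assigned) {
      centers <- rbind(centers, modes[i, ])
      cluster[i] <- nrow(centers)
    }
  }
  list(cluster = cluster, centers = centers)
}

#' Mean-shift clustering of events in space-time
#'
#' Merges duplicate detections of one physical event and discards motion
#' artifacts. A laterally moving bright structure betrays itself in one of
#' two ways: a vanishing detection at its old position next to an appearing
#' detection at its new one (an opposite-polarity pair in the same
#' space-time neighbourhood), or a single "dipole" region in which positive
#' and negative temporal differences carry comparable weight. Events flagged
#' by either signature (opposite-polarity partner within one bandwidth, or
#' region balance above `dipole_balance`) are motion artifacts.
#'
#' Artifact and genuine events are then clustered separately by mean-shift
#' with a Gaussian kernel on the barycenters in bandwidth-scaled
#' coordinates `(x / h_s, y / h_s, pair / h_t)` (iterated until the largest
#' shift falls below `tol`, converged modes merged within half a
#' bandwidth). Artifact clusters are flagged `discarded`; each surviving
#' cluster counts as one event even when it spans several frame pairs.
#'
#' @param events data frame from [extract_events()].
#' @param h_s spatial bandwidth in pixels (default 3).
#' @param h_t temporal bandwidth in frame pairs (default 1: a transient
#'   event lives on a single frame pair; detections on adjacent pairs are
#'   merged, farther ones are distinct events).
#' @param tol convergence tolerance on the scaled shift (default 1e-3).
#' @param max_iter maximum mean-shift iterations (default 100).
#' @param motion_filter apply the motion-artifact discard rules
#'   (default TRUE).
#' @param dipole_balance region polarity balance above which a single
#'   region counts as a motion dipole (default 0.25; genuine transient spots
#'   show near-zero balance while displacement dipoles approach 1).
#' @return an object of class `event_clusters`: `clusters` (data frame with
#'   `cluster`, mode `x`, `y`, `pair`, `n`, `polarity`, `discarded`),
#'   `events` (the input with `cluster` and `artifact` columns).
#' @export
meanshift_cluster <- function(events, h_s = 3, h_t = 1, tol = 1e-3,
                              max_iter = 100L, motion_filter = TRUE,
                              dipole_balance = 0.25) {
  stopifnot(h_s > 0, h_t > 0)
  n <- nrow(events)
  if (n == 0L) {
    cl <- data.frame(cluster = integer(0L), x = numeric(0L), y = numeric(0L),
                     pair = numeric(0L), n = integer(0L),
                     polarity = character(0L), discarded = logical(0L))
    events$cluster <- integer(0L)
    events$artifact <- logical(0L)
    return(structure(list(clusters = cl, events = events, h_s = h_s,
                          h_t = h_t),
                     class = "event_clusters"))
  }
  pts <- cbind(events$x / h_s, events$y / h_s, events$pair / h_t)

  artifact <- rep(FALSE, n)
  if (motion_filter) {
    if (!is.null(events$balance)) {
      artifact <- events$balance > dipole_balance
    }
    # opposite-polarity partner of comparable size within one scaled
    # space-time bandwidth; a tiny satellite does not disqualify a large
    # region, but flags itself
    if (n > 1L) {
      d2 <- outer(rowSums(pts^2), rowSums(pts^2), "+") - 2 * pts %*% t(pts)
      opp <- outer(events$polarity, events$polarity, "!=")
      sz <- if (is.null(events$size)) rep(1, n) else events$size
      comparable <- outer(sz, sz, function(a, b) b >= 0.5 * a)
      near_opp <- (d2 <= 1 + 1e-9) & opp & comparable
      diag(near_opp) <- FALSE
      artifact <- artifact | apply(near_opp, 1L, any)
    }
  }

  cluster <- integer(n)
  centers <- NULL
  k_real <- 0L
  if (any(!artifact)) {
    ms <- meanshift_modes(pts[!artifact, , drop = FALSE], tol, max_iter)
    cluster[!artifact] <- ms$cluster
    centers <- ms$centers
    k_real <- nrow(centers)
  }
  if (any(artifact)) {
    ms_a <- meanshift_modes(pts[artifact, , drop = FALSE], tol, max_iter)
    cluster[artifact] <- k_real + ms_a$cluster
    centers <- rbind(centers, ms_a$centers)
  }
  events$cluster <- cluster
  events$artifact <- artifact
  k <- nrow(centers)
  pol <- character(k)
  nmem <- integer(k)
  for (j in seq_len(k)) {
    mem <- which(cluster == j)
    nmem[j] <- length(mem)
    w <- if (is.null(events$size)) rep(1, length(mem)) else events$size[mem]
    wapp <- sum(w[events$polarity[mem] == "appearing"])
    wvan <- sum(w) - wapp
    # size-weighted dominant polarity; comparable evidence on both sides is
    # the appearing/vanishing pair a moving structure leaves behind
    pol[j] <- if (min(wapp, wvan) > 0.5 * max(wapp, wvan)) "mixed" else
      if (wapp > wvan) "appearing" else "vanishing"
  }
  disc <- seq_len(k) > k_real
  if (motion_filter) disc <- disc | pol == "mixed"
  cl <- data.frame(cluster = seq_len(k),
                   x = centers[, 1L] * h_s, y = centers[, 2L] * h_s,
                   pair = centers[, 3L] * h_t, n = nmem, polarity = pol,
                   discarded = disc)
  structure(list(clusters = cl, events = events, h_s = h_s, h_t = h_t),
            class = "event_clusters")
}

#' @export
print.event_clusters <- function(x, ...) {
  cl <- x$clusters
  cat(sprintf(
    "event_clusters: %d clusters from %d events (%d discarded as motion)\n",
    nrow(cl), nrow(x$events), sum(cl$discarded)))
  invisible(x)
}

#' Event rate of a sequence
#'
#' Number of surviving (non-discarded) event clusters divided by the number
#' of frames, split by polarity.
#'
#' @param clusters an `event_clusters` object.
#' @param n_images number of frames in the sequence.
#' @return named numeric vector `c(appearing, vanishing, total)` of
#'   per-frame rates; `total = appearing + vanishing`.
#' @export
event_rate <- function(clusters, n_images) {
  stopifnot(n_images >= 1L)
  cl <- clusters$clusters
  keep <- cl[!cl$discarded, , drop = FALSE]
  napp <- sum(keep$polarity == "appearing")
  nvan <- sum(keep$polarity == "vanishing")
  c(appearing = napp, vanishing = nvan, total = napp + nvan) / n_images
}
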