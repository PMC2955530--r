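#' Anscombe transform for event counts
#'
#' `2 * sqrt(n + 3/8)` stabilizes the variance of Poisson-distributed
#' counts at approximately 1, which makes per-sequence event counts
#' homoscedastic before the rate ANOVA.
#'
#' @param n non-negative counts.
#' @return transformed values.
#' @export
anscombe_counts <- function(n) {
  if (any(n < 0)) stop("counts must be non-negative")
  2 * sqrt(n + 3 / 8)
}

#' Pairwise ANOVA of event rates against a reference group
#'
#' One-way two-group analysis of variance (equivalently the squared pooled
#' t statistic) comparing the stabilized event rates of a perturbation
#' group against the reference (wild type). Rates should be
#' count-stabilized first: `anscombe_counts(events) / n_images` per
#' sequence (see [batch_process()]).
#'
#' @param reference numeric vector of reference-group rates (n >= 2).
#' @param group numeric vector of perturbation-group rates (n >= 2).
#' @param label name of the perturbation group.
#' @return an object of class `group_comparison`: group sizes, means,
#'   standard deviations, the F statistic with df `(1, n1 + n2 - 2)`, and
#'   the p-value.
#' @export
pairwise_anova <- function(reference, group, label = "group") {
  stopifnot(length(reference) >= 2L, length(group) >= 2L)
  if (stats::sd(reference) == 0 && stats::sd(group) == 0) {
    if (mean(reference) == mean(group)) {
      # no variance anywhere and equal means: F = 0 / 0 taken as 0
      return(structure(
        list(label = label, n = c(length(reference), length(group)),
             mean = c(mean(reference), mean(group)),
             sd = c(0, 0), f = 0,
             df = c(1L, length(reference) + length(group) - 2L), p = 1),
        class = "group_comparison"))
    }
    stop("zero within-group variance in both groups")
  }
  y <- c(reference, group)
  g <- factor(rep(c("reference", label), c(length(reference), length(group))),
              levels = c("reference", label))
  fit <- stats::aov(y ~ g)
  tab <- summary(fit)[[1L]]
  f <- tab[["F value"]][1L]
  p <- tab[["Pr(>F)"]][1L]
  structure(
    list(label = label, n = c(length(reference), length(group)),
         mean = c(mean(reference), mean(group)),
         sd = c(stats::sd(reference), stats::sd(group)), f = f,
         df = c(tab[["Df"]][1L], tab[["Df"]][2L]), p = p),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "reference (n=%d): mean %.4g sd %.4g | %s (n=%d): mean %.4g sd %.4g\n",
    x$n[1L], x$mean[1L], x$sd[1L], x$label, x$n[2L], x$mean[2L], x$sd[2L]))
  cat(sprintf("F(%d, %d) = %.4g, p = %.4g\n", x$df[1L], x$df[2L], x$f, x$p))
  invisible(x)
}

# Run the pipeline on one sequence and build its summary row.
process_one_sequence <- function(seq, seq_id, method, patch_cfg, fd_cfg,
                                 seed, h_s, h_t, noise = NULL) {
  norm <- normalize_pipeline(seq, params = noise)
  det <- if (method == "ssd") {
    detect(norm, patch_cfg, seed = seed)
  } else {
    framediff_detect(norm, fd_cfg)
  }
  ev <- extract_events(det, norm)
  cl <- meanshift_cluster(ev, h_s = h_s, h_t = h_t)
  rate <- event_rate(cl, n_frames(seq))
  keep <- cl$clusters[!cl$clusters$discarded, , drop = FALSE]
  d <- dim(seq$frames)
  summary_row <- data.frame(
    seq_id = seq_id, status = "ok", n_images = d[3L], height = d[1L],
    width = d[2L], gain = norm$noise$gain, dark_mean = norm$noise$dark_mean,
    dark_sd = norm$noise$dark_sd,
    bleach_tau = if (is.null(norm$bleach)) NA_real_ else norm$bleach$tau,
    cell_area = norm$mask$area,
    n_appearing = sum(keep$polarity == "appearing"),
    n_vanishing = sum(keep$polarity == "vanishing"),
    rate = unname(rate["total"]),
    stabilized_rate = anscombe_counts(nrow(keep)) / d[3L],
    error = NA_character_)
  ev <- cl$events
  ev$cluster_discarded <- cl$clusters$discarded[ev$cluster]
  list(summary = summary_row, events = ev, clusters = cl)
}

failed_row <- function(seq_id, msg) {
  data.frame(
    seq_id = seq_id, status = "failed", n_images = NA_integer_,
    height = NA_integer_, width = NA_integer_, gain = NA_real_,
    dark_mean = NA_real_, dark_sd = NA_real_, bleach_tau = NA_real_,
    cell_area = NA_integer_, n_appearing = NA_integer_,
    n_vanishing = NA_integer_, rate = NA_real_, stabilized_rate = NA_real_,
    error = msg)
}

#' Batch-process a manifest of sequences
#'
#' Runs normalization, detection and event clustering on every sequence of
#' a manifest with one shared configuration, and collects one summary row
#' per sequence (number of images, image size, sensor calibration,
#' bleaching constant, segmented cell area, appearing/vanishing counts and
#' the event rate). A failing sequence is recorded as a failed row and does
#' not abort the batch.
#'
#' @param manifest data frame with columns `seq_id` and either `path`
#'   (multi-page TIFF file) or `sequence` (an in-memory `spot_sequence` in
#'   a list column), plus optional `modality` and `frame_period`.
#' @param method `"ssd"` or `"fd"`.
#' @param patch_cfg,fd_cfg detection configurations shared by all
#'   sequences.
#' @param seed integer seed (Monte-Carlo GEV initialization).
#' @param h_s,h_t mean-shift bandwidths.
#' @param out_dir optional directory: writes `summary.csv` and one
#'   `events_<seq_id>.csv` per sequence (0-based pixel coordinates).
#' @return an object of class `batch_result`: `summary` (data frame, one
#'   row per manifest entry) and `events` (named list of event data
#'   frames).
#' @export
batch_process <- function(manifest, method = c("ssd", "fd"),
                          patch_cfg = patch_config(), fd_cfg = fd_config(),
                          seed = 1L, h_s = 3, h_t = 1, out_dir = NULL) {
  method <- match.arg(method)
  rows <- list()
  events <- list()
  for (i in seq_len(nrow(manifest))) {
    seq_id <- as.character(manifest$seq_id[i])
    res <- tryCatch({
      seq <- if (!is.null(manifest$sequence)) {
        manifest$sequence[[i]]
      } else {
        read_sequence(
          manifest$path[i],
          frame_period = if (is.null(manifest$frame_period)) 1 else
            manifest$frame_period[i],
          modality = if (is.null(manifest$modality)) "TIRF" else
            as.character(manifest$modality[i]))
      }
      if (inherits(seq, "sim_sequence")) seq <- seq$sequence
      process_one_sequence(seq, seq_id, method, patch_cfg, fd_cfg, seed,
                           h_s, h_t)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      rows[[i]] <- failed_row(seq_id, res)
      events[[seq_id]] <- NULL
    } else {
      rows[[i]] <- res$summary
      events[[seq_id]] <- res$events
    }
  }
  summary <- if (length(rows) > 0L) {
    do.call(rbind, rows)
  } else {
    failed_row("none", "none")[0L, ]
  }
  rownames(summary) <- NULL
  out <- structure(list(summary = summary, events = events, method = method,
                        seed = seed),
                   class = "batch_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    for (id in names(events)) {
      ev <- events[[id]]
      ev_out <- data.frame(seq_id = id, pair_index = ev$pair - 1L,
                           x = ev$x - 1, y = ev$y - 1,
                           polarity = ev$polarity, region_size = ev$size,
                           cluster_id = ev$cluster,
                           discarded = ev$cluster_discarded)
      utils::write.csv(ev_out,
                       file.path(out_dir, paste0("events_", id, ".csv")),
                       row.names = FALSE)
    }
  }
  out
}

#' @export
print.batch_result <- function(x, ...) {
  ok <- sum(x$summary$status == "ok")
  cat(sprintf("batch_result (%s): %d sequences, %d ok, %d failed\n",
              x$method, nrow(x$summary), ok, nrow(x$summary) - ok))
  invisible(x)
}

#' Compare perturbation groups from batch summaries
#'
#' Convenience wrapper running [pairwise_anova()] of every non-reference
#' group against the reference, using the Anscombe-stabilized per-sequence
#' rates of one or more batch summaries.
#'
#' @param summary a batch summary data frame with a `group` column (or a
#'   named list of summaries, names taken as group labels).
#' @param reference label of the reference (wild type) group.
#' @return named list of `group_comparison` objects.
#' @export
compare_groups <- function(summary, reference = "wild_type") {
  if (is.list(summary) && !is.data.frame(summary)) {
    summary <- do.call(rbind, Map(function(s, g) {
      s$group <- g
      s
    }, summary, names(summary)))
  }
  stopifnot("group" %in% names(summary))
  ok <- summary[summary$status == "ok", , drop = FALSE]
  ref <- ok$stabilized_rate[ok$group == reference]
  other <- setdiff(unique(ok$group), reference)
  out <- lapply(other, function(g) {
    pairwise_anova(ref, ok$stabilized_rate[ok$group == g], label = g)
  })
  names(out) <- other
  out
}
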