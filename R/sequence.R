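#' Time-lapse image sequence
#'
#' The container every stage of the pipeline transforms: a stack of T
#' grayscale frames of H x W pixels with acquisition metadata. Frames are
#' stored as an H x W x T numeric array (rows = y, columns = x).
#'
#' @param frames H x W x T numeric array, or a list of equally sized
#'   matrices (one per frame).
#' @param frame_period seconds between consecutive frames.
#' @param modality `"WF"` (wide-field, bleaching-corrected) or `"TIRF"`
#'   (bleaching correction skipped).
#' @return an object of class `spot_sequence`.
#' @export
spot_sequence <- function(frames, frame_period = 1, modality = c("TIRF", "WF")) {
  modality <- match.arg(modality)
  if (is.list(frames)) {
    stopifnot(length(frames) >= 1L)
    frames <- simplify2array(frames)
  }
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  if (dim(frames)[3L] < 2L) stop("a sequence needs at least 2 frames")
  if (!all(is.finite(frames))) stop("all frame values must be finite")
  stopifnot(frame_period > 0)
  structure(
    list(frames = frames, frame_period = frame_period, modality = modality),
    class = "spot_sequence"
  )
}

#' @export
print.spot_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("spot_sequence: %d frames of %d x %d px, %.3g s/frame, %s\n",
              d[3L], d[1L], d[2L], x$frame_period, x$modality))
  invisible(x)
}

#' @export
dim.spot_sequence <- function(x) dim(x$frames)

n_frames <- function(seq) dim(seq$frames)[3L]

get_frame <- function(seq, t) seq$frames[, , t]

# Accept either a spot_sequence or a bare H x W x T array.
as_frames <- function(x) {
  if (inherits(x, "spot_sequence")) x$frames else x
}

#' Maximum intensity projection
#'
#' Reduce a z-stack to a single 2D image by taking, at every pixel, the
#' maximum over the axial (z) direction. Used to summarize 3D+time
#' wide-field acquisitions to 2D+time before detection.
#'
#' @param stack H x W x Z numeric array (Z >= 1) or a list of H x W planes.
#' @return H x W matrix of per-pixel maxima.
#' @export
max_intensity_project <- function(stack) {
  if (is.list(stack)) {
    if (length(stack) == 0L) stop("empty stack")
    stack <- simplify2array(stack)
  }
  if (is.matrix(stack)) return(stack)
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  nz <- dim(stack)[3L]
  if (nz == 0L) stop("empty stack")
  out <- stack[, , 1L]
  for (z in seq_len(nz)[-1L]) out <- pmax(out, stack[, , z])
  out
}

#' Read a multi-page TIFF as a sequence
#'
#' One page per frame. Integer TIFF data are read at their native values;
#' 32-bit float data are returned as stored. For 3D+time data supply one
#' multi-page TIFF per timepoint via `read_stack_sequence()`.
#'
#' @param path path to a multi-page TIFF file.
#' @inheritParams spot_sequence
#' @return a `spot_sequence`.
#' @export
read_sequence <- function(path, frame_period = 1, modality = c("TIRF", "WF")) {
  spot_sequence(read_pages(path), frame_period = frame_period,
                modality = modality)
}

# Integer TIFFs are read at their native values; 32-bit float TIFFs are
# returned as stored (the as.is raw read is only defined for integer data).
read_pages <- function(path) {
  probe <- tiff::readTIFF(path, info = TRUE)
  bits <- attr(probe, "bits.per.sample")
  if (!is.null(bits) && bits <= 16L) {
    tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  } else {
    tiff::readTIFF(path, all = TRUE)
  }
}

#' Read a 3D+time acquisition and project it to 2D+time
#'
#' Each file holds the z-stack of one timepoint (pages = z planes); files
#' are taken in the order given (sort them by filename beforehand if
#' needed). Every stack is reduced by maximum intensity projection.
#'
#' @param paths character vector of per-timepoint TIFF files.
#' @inheritParams spot_sequence
#' @return a `spot_sequence` of MIP frames.
#' @export
read_stack_sequence <- function(paths, frame_period = 1, modality = "WF") {
  frames <- lapply(paths, function(p) max_intensity_project(read_pages(p)))
  spot_sequence(frames, frame_period = frame_period, modality = modality)
}

#' Write a sequence to a multi-page TIFF
#'
#' `"uint16"` stores rounded native values (exact for camera-range data and
#' readable by any TIFF consumer); `"float"` stores 32-bit floats
#' affine-rescaled into \[0, 1\] (the range float TIFF storage supports
#' here), with the offset and scale returned invisibly so values can be
#' recovered exactly.
#'
#' @param seq a `spot_sequence` or H x W x T array.
#' @param path output file.
#' @param format `"float"` (stabilized data) or `"uint16"` (raw camera
#'   units in 0..65535).
#' @return invisibly, `c(offset, scale)` used for rescaling (`c(0, 65535)`
#'   for `"uint16"`).
#' @export
write_sequence <- function(seq, path, format = c("float", "uint16")) {
  format <- match.arg(format)
  fr <- as_frames(seq)
  if (format == "uint16") {
    stopifnot(min(fr) > -0.5, max(fr) < 65535.5)
    pages <- lapply(seq_len(dim(fr)[3L]),
                    function(t) round(fr[, , t]) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    return(invisible(c(offset = 0, scale = 65535)))
  }
  lo <- min(fr)
  hi <- max(fr)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(fr)[3L]), function(t) (fr[, , t] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(c(offset = lo, scale = scale))
}

#' Write a binary mask as an 8-bit TIFF
#'
#' @param mask logical (or 0/1) matrix.
#' @param path output file.
#' @export
write_mask <- function(mask, path) {
  tiff::writeTIFF(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path,
                  bits.per.sample = 8L)
  invisible(path)
}
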