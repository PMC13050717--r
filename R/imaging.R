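#' Fluorescence movie stack
#'
#' @param data Numeric array of raw fluorescence, dimension T x H x W
#'   (frames, rows, columns; 0-based pixel convention is used in exported
#'   coordinates, row 1/column 1 at the top-left).
#' @param fs Frame rate in Hz.
#' @return A `movie_stack`.
#' @export
movie_stack <- function(data, fs = 2) {
  stopifnot(is.array(data), length(dim(data)) == 3, dim(data)[1] >= 2,
            all(is.finite(data)), fs > 0)
  if (any(data < 0)) stop("fluorescence values must be nonnegative")
  structure(list(data = data, fs = as.numeric(fs)), class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<movie_stack> %d frames of %dx%d at %g Hz\n", d[1], d[2], d[3], x$fs))
  invisible(x)
}

#' Baseline image F0 as the per-pixel temporal median
#'
#' The baseline is the median Z-projection across the full recording; for
#' an even number of frames the mean of the two central order statistics
#' is used.
#'
#' @param movie A [movie_stack()].
#' @return An H x W matrix of baseline fluorescence.
#' @export
compute_baseline <- function(movie) {
  stopifnot(inherits(movie, "movie_stack"))
  apply(movie$data, c(2, 3), stats::median)
}

#' Normalised dF/F0 stack in percent
#'
#' `dff[t, y, x] = 100 * (F[t, y, x] - F0[y, x]) / F0[y, x]`. Pixels whose
#' baseline is not positive cannot be normalised; they are flagged invalid
#' (and set `NA` in the stack) rather than silently zeroed, and are excluded
#' from every downstream trace.
#'
#' @param movie A [movie_stack()].
#' @param f0 Baseline image from [compute_baseline()] (computed when omitted).
#' @return A `dff_stack` with elements `data` (T x H x W, percent), `fs`,
#'   and `valid` (H x W logical).
#' @export
compute_dff <- function(movie, f0 = compute_baseline(movie)) {
  stopifnot(inherits(movie, "movie_stack"), is.matrix(f0),
            all(dim(f0) == dim(movie$data)[2:3]), all(is.finite(f0)))
  valid <- f0 > 0
  if (!any(valid)) stop("baseline is nonpositive at every pixel; cannot normalise")
  d <- dim(movie$data)
  denom <- array(rep(f0, each = d[1]), dim = d)
  dff <- 100 * (movie$data - denom) / denom
  dff[array(rep(!valid, each = d[1]), dim = d)] <- NA_real_
  structure(list(data = dff, fs = movie$fs, valid = valid), class = "dff_stack")
}

#' @export
print.dff_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dff_stack> %d frames of %dx%d at %g Hz (%d invalid px)\n",
              d[1], d[2], d[3], x$fs, sum(!x$valid)))
  invisible(x)
}

#' Brain and region masks
#'
#' Bundles the whole-brain mask with the four hemispheric region masks
#' (left/right forebrain and midbrain). Regions must be pairwise disjoint,
#' nonempty, and contained in the brain mask.
#'
#' @param brain H x W logical matrix.
#' @param regions Named list of H x W logical matrices with names
#'   `FB_L`, `FB_R`, `MB_L`, `MB_R`.
#' @return A `region_masks` object.
#' @export
region_masks <- function(brain, regions) {
  stopifnot(is.matrix(brain), is.logical(brain), is.list(regions))
  need <- c("FB_L", "FB_R", "MB_L", "MB_R")
  if (!setequal(names(regions), need))
    stop("regions must be named FB_L, FB_R, MB_L, MB_R")
  regions <- regions[need]
  cover <- matrix(0L, nrow(brain), ncol(brain))
  for (nm in need) {
    r <- regions[[nm]]
    stopifnot(is.matrix(r), is.logical(r), all(dim(r) == dim(brain)))
    if (!any(r)) stop("region ", nm, " is empty")
    if (any(r & !brain)) stop("region ", nm, " extends outside the brain mask")
    cover <- cover + r
  }
  if (any(cover > 1L)) stop("region masks overlap")
  structure(list(brain = brain, regions = regions), class = "region_masks")
}

#' A region of interest: a labelled set of pixels
#'
#' @param label Integer label.
#' @param pixels Two-column integer matrix of (row, col) pixel coordinates.
#' @return A `ca_roi`.
#' @export
ca_roi <- function(label, pixels) {
  pixels <- as.matrix(pixels)
  stopifnot(ncol(pixels) == 2, nrow(pixels) >= 1)
  colnames(pixels) <- c("row", "col")
  structure(list(label = as.integer(label), pixels = pixels), class = "ca_roi")
}

#' Mean dF/F0 trace over an ROI
#'
#' Averages, frame by frame, the valid dF/F0 pixels of the ROI.
#'
#' @param dff A `dff_stack` from [compute_dff()].
#' @param roi A [ca_roi()], or an H x W logical mask.
#' @param provenance Provenance tag for the returned trace.
#' @return A [ca_trace()].
#' @export
extract_roi_trace <- function(dff, roi, provenance = NULL) {
  stopifnot(inherits(dff, "dff_stack"))
  if (inherits(roi, "ca_roi")) {
    px <- roi$pixels
    if (is.null(provenance)) provenance <- paste0("roi_", roi$label)
  } else {
    stopifnot(is.matrix(roi), is.logical(roi), all(dim(roi) == dim(dff$valid)))
    px <- which(roi, arr.ind = TRUE)
    if (is.null(provenance)) provenance <- "mask"
  }
  d <- dim(dff$data)
  ok <- dff$valid[px]
  px <- px[ok, , drop = FALSE]
  if (nrow(px) == 0) stop("ROI contains no valid pixels")
  ## index the T x H x W array at fixed pixel sets: frames vary fastest
  flat <- matrix(dff$data, nrow = d[1])        # T x (H*W)
  cols <- (px[, 2] - 1) * d[2] + px[, 1]
  vals <- rowMeans(flat[, cols, drop = FALSE])
  ca_trace(vals, dff$fs, provenance)
}

#' Whole-brain mean dF/F0 trace
#'
#' @param dff A `dff_stack`.
#' @param brain H x W logical whole-brain mask (or a [region_masks()]).
#' @return A [ca_trace()] with provenance `"whole_brain"`.
#' @export
whole_brain_trace <- function(dff, brain) {
  if (inherits(brain, "region_masks")) brain <- brain$brain
  extract_roi_trace(dff, brain, provenance = "whole_brain")
}
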