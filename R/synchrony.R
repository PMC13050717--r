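#' Fixed-area circular ROI at a region's geometric centroid
#'
#' The centroid is the mean of the member pixel coordinates. A circle of
#' nominal radius `sqrt(area_px / pi)` is grown in minimal increments until
#' it contains at least `area_px` pixel centres, then trimmed to exactly
#' `area_px` pixels by distance rank (ties broken in row-major order).
#' By construction the circle may cover pixels outside the region for
#' concave shapes; set `clip_to_region = TRUE` to restrict candidate pixels
#' to the region mask.
#'
#' @param region_mask H x W logical region mask.
#' @param area_px Exact number of pixels in the ROI (default 500).
#' @param region Region name used as the ROI label tag.
#' @param clip_to_region Restrict the circle to region pixels.
#' @return A `centroid_roi`: a [ca_roi()] with elements `region`, `center`
#'   (centroid as (row, col)), and `area_px`.
#' @export
centroid_circular_roi <- function(region_mask, area_px = 500, region = "region",
                                  clip_to_region = FALSE) {
  stopifnot(is.matrix(region_mask), is.logical(region_mask), area_px >= 1)
  member <- which(region_mask, arr.ind = TRUE)
  if (nrow(member) == 0) stop("region mask is empty")
  ctr <- colMeans(member)
  H <- nrow(region_mask); W <- ncol(region_mask)
  cand <- if (clip_to_region) member else
    as.matrix(expand.grid(row = seq_len(H), col = seq_len(W)))
  d2 <- (cand[, 1] - ctr[1])^2 + (cand[, 2] - ctr[2])^2
  if (nrow(cand) < area_px)
    stop("fewer than area_px candidate pixels around the centroid")
  ## distance-rank trim with row-major tie-break
  ord <- order(d2, cand[, 1], cand[, 2])
  px <- cand[ord[seq_len(area_px)], , drop = FALSE]
  roi <- ca_roi(0L, px)
  roi$region <- region
  roi$center <- c(row = unname(ctr[1]), col = unname(ctr[2]))
  roi$area_px <- as.integer(area_px)
  class(roi) <- c("centroid_roi", class(roi))
  roi
}

#' Interregional Pearson correlation matrix
#'
#' Extracts the four centroid-ROI mean dF/F0 traces and fills the 4 x 4
#' Pearson matrix. Zero-variance traces give flagged `NA` entries rather
#' than silent zeros.
#'
#' @param dff A `dff_stack`.
#' @param rois Named list of four [centroid_circular_roi()] objects
#'   (FB_L, FB_R, MB_L, MB_R), or a [region_masks()] from which centroid
#'   ROIs are built.
#' @param area_px Centroid ROI area when `rois` is a `region_masks`.
#' @return A `synchrony_matrix` (4 x 4 named numeric matrix).
#' @export
synchrony_matrix <- function(dff, rois, area_px = 500) {
  if (inherits(rois, "region_masks"))
    rois <- mapply(centroid_circular_roi, rois$regions, region = names(rois$regions),
                   MoreArgs = list(area_px = area_px), SIMPLIFY = FALSE)
  stopifnot(length(rois) == 4, !is.null(names(rois)))
  traces <- lapply(names(rois), function(nm)
    extract_roi_trace(dff, rois[[nm]], provenance = nm)$values)
  names(traces) <- names(rois)
  synchrony_matrix_from_traces(traces)
}

#' Pearson matrix from four region traces
#'
#' @param traces Named list of four equal-length numeric vectors (or
#'   [ca_trace()] objects).
#' @return A `synchrony_matrix`.
#' @export
synchrony_matrix_from_traces <- function(traces) {
  stopifnot(length(traces) == 4, !is.null(names(traces)))
  vals <- lapply(traces, function(x) if (inherits(x, "ca_trace")) x$values else as.numeric(x))
  n <- unique(vapply(vals, length, integer(1)))
  if (length(n) != 1) stop("traces have unequal lengths")
  m <- diag(1, 4)
  dimnames(m) <- list(names(traces), names(traces))
  for (i in 1:3) for (j in (i + 1):4) {
    a <- vals[[i]]; b <- vals[[j]]
    r <- if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_ else stats::cor(a, b)
    m[i, j] <- m[j, i] <- r
  }
  class(m) <- c("synchrony_matrix", class(m))
  m
}

#' Named homotopic and heterotopic synchrony values
#'
#' Pulls the four reported pairings out of a correlation matrix:
#' left-right midbrain, left-right forebrain, and the right/left
#' midbrain-forebrain pairs. Flagged (`NA`) entries propagate.
#'
#' @param mat A `synchrony_matrix` with labels FB_L, FB_R, MB_L, MB_R.
#' @return Named numeric vector `mb_lr`, `fb_lr`, `mbfb_right`, `mbfb_left`.
#' @export
synchrony_summary <- function(mat) {
  stopifnot(inherits(mat, "synchrony_matrix"),
            all(c("FB_L", "FB_R", "MB_L", "MB_R") %in% rownames(mat)))
  c(mb_lr = mat["MB_L", "MB_R"],
    fb_lr = mat["FB_L", "FB_R"],
    mbfb_right = mat["MB_R", "FB_R"],
    mbfb_left = mat["MB_L", "FB_L"])
}
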