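#' Segment calcium-active ROIs by tile correlation
#'
#' A deliberately simple, correlation-based stand-in for full event-driven
#' segmentation: the masked field of view is tiled into `tile_px` x `tile_px`
#' blocks, each tile's mean dF/F0 trace is computed, 4-connected neighbouring
#' tiles whose traces correlate at Pearson r >= `r_min` are merged
#' (union-find over the tile grid), and merged components of at least
#' `min_tiles` tiles become ROIs. Tiles with zero-variance traces never
#' merge. Output is deterministic: ROIs are labelled in row-major order of
#' their top-left tile.
#'
#' @param dff A `dff_stack`.
#' @param brain H x W logical mask restricting the analysis.
#' @param tile_px Tile side length in pixels.
#' @param r_min Minimum Pearson correlation for merging adjacent tiles.
#' @param min_tiles Minimum number of tiles for a component to be kept.
#' @return A list of [ca_roi()] objects (class `roi_set`), ROI pixels being
#'   the union of their tiles' masked pixels.
#' @export
segment_active_rois <- function(dff, brain, tile_px = 4, r_min = 0.7, min_tiles = 4) {
  if (inherits(brain, "region_masks")) brain <- brain$brain
  stopifnot(inherits(dff, "dff_stack"), is.matrix(brain), is.logical(brain))
  if (!any(brain)) stop("brain mask is empty")
  H <- nrow(brain); W <- ncol(brain)
  if (tile_px > H || tile_px > W) stop("tile_px exceeds the mask extent")
  nr <- as.integer(ceiling(H / tile_px)); nc <- as.integer(ceiling(W / tile_px))
  d <- dim(dff$data)
  flat <- matrix(dff$data, nrow = d[1])
  tile_id <- function(i, j) as.integer((j - 1L) * nr + i)
  traces <- vector("list", nr * nc)
  pixels <- vector("list", nr * nc)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    rows <- ((i - 1) * tile_px + 1):min(i * tile_px, H)
    cols <- ((j - 1) * tile_px + 1):min(j * tile_px, W)
    sub <- as.matrix(expand.grid(row = rows, col = cols))
    keep <- brain[sub] & dff$valid[sub]
    sub <- sub[keep, , drop = FALSE]
    if (nrow(sub) == 0) next
    id <- tile_id(i, j)
    pixels[[id]] <- sub
    traces[[id]] <- rowMeans(flat[, (sub[, 2] - 1) * d[2] + sub[, 1], drop = FALSE])
  }
  occupied <- !vapply(traces, is.null, logical(1))
  ## union-find over tiles
  parent <- seq_len(nr * nc)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  union_ <- function(x, y) { rx <- find(x); ry <- find(y); if (rx != ry) parent[max(rx, ry)] <<- min(rx, ry) }
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(-Inf)
    stats::cor(a, b)
  }
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    id <- tile_id(i, j)
    if (!occupied[id]) next
    if (i < nr && occupied[tile_id(i + 1, j)] &&
        safe_cor(traces[[id]], traces[[tile_id(i + 1, j)]]) >= r_min)
      union_(id, tile_id(i + 1, j))
    if (j < nc && occupied[tile_id(i, j + 1)] &&
        safe_cor(traces[[id]], traces[[tile_id(i, j + 1)]]) >= r_min)
      union_(id, tile_id(i, j + 1))
  }
  roots <- vapply(which(occupied), function(t) as.integer(find(t)), integer(1))
  comps <- split(which(occupied), roots)
  comps <- comps[vapply(comps, length, integer(1)) >= min_tiles]
  if (length(comps) == 0) return(structure(list(), class = "roi_set"))
  ## deterministic label order: row-major position of the first tile
  firsts <- vapply(comps, function(tt) {
    i <- (min(tt) - 1L) %% nr + 1L; j <- (min(tt) - 1L) %/% nr + 1L
    (i - 1L) * nc + j
  }, numeric(1))
  comps <- comps[order(firsts)]
  rois <- lapply(seq_along(comps), function(k) {
    px <- do.call(rbind, pixels[comps[[k]]])
    ca_roi(k, px[order(px[, 1], px[, 2]), , drop = FALSE])
  })
  structure(rois, class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d ROI(s); sizes: %s px\n", length(x),
              paste(vapply(x, function(r) nrow(r$pixels), integer(1)), collapse = ", ")))
  invisible(x)
}
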