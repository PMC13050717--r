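## File formats. Movies and masks are TIFF; every table is a plain
## comma-separated UTF-8 CSV with a header row, '.' decimal, times in
## seconds, frequencies in Hz, positions in mm. Region-mask images use the
## label map 1:FB_L, 2:FB_R, 3:MB_L, 4:MB_R.

#' Read / write a fluorescence movie as multi-page grayscale TIFF
#'
#' Movies are stored as 32-bit samples in the unit range; values are
#' preserved to 2^-32. RGB pages and pages of differing shapes are
#' rejected.
#'
#' @param path TIFF file path.
#' @param fs Frame rate attached to the returned stack.
#' @return [read_movie()] returns a [movie_stack()].
#' @export
read_movie <- function(path, fs = 2) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  for (p in pages) {
    if (length(dim(p)) != 2)
      stop("movie TIFF must be grayscale: page with ", length(dim(p)), " channels found")
    if (!all(dim(p) == dim(pages[[1]])))
      stop("movie TIFF pages have differing shapes")
  }
  d <- dim(pages[[1]])
  arr <- array(0, dim = c(length(pages), d[1], d[2]))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  movie_stack(arr, fs)
}

#' @rdname read_movie
#' @param movie A [movie_stack()] with values in `[0, 1]`.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "movie_stack"))
  if (max(movie$data) > 1)
    stop("movie values must lie in [0, 1] for TIFF storage; rescale first")
  pages <- lapply(seq_len(dim(movie$data)[1]), function(t) movie$data[t, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read / write mask images
#'
#' Plain masks are nonzero-equals-member images; region masks are a single
#' label image with the documented four-label map.
#'
#' @param path Image path (TIFF or PNG for reading; TIFF for writing).
#' @return `read_mask`: logical matrix. `read_region_masks`: a
#'   [region_masks()] built from a label image and a brain mask image.
#' @export
read_mask <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) != 2) stop("mask must be a single-channel image")
  img > 0
}

#' @rdname read_mask
#' @param mask Logical matrix.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask), is.logical(mask))
  tiff::writeTIFF(mask * 1, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname read_mask
#' @param labels_path Label image (values 1-4 scaled by 1/255 in 8-bit TIFF).
#' @param brain_path Brain mask image.
#' @export
read_region_masks <- function(labels_path, brain_path) {
  lab <- round(tiff::readTIFF(labels_path) * 255)
  brain <- read_mask(brain_path)
  region_masks(brain, list(FB_L = lab == 1, FB_R = lab == 2,
                           MB_L = lab == 3, MB_R = lab == 4))
}

#' @rdname read_mask
#' @param geometry A [region_masks()].
#' @export
write_region_masks <- function(geometry, labels_path, brain_path) {
  stopifnot(inherits(geometry, "region_masks"))
  lab <- matrix(0, nrow(geometry$brain), ncol(geometry$brain))
  for (i in seq_along(geometry$regions)) lab[geometry$regions[[i]]] <- i
  tiff::writeTIFF(lab / 255, labels_path, bits.per.sample = 8L)
  write_mask(geometry$brain, brain_path)
  invisible(labels_path)
}

check_columns <- function(df, expected, what) {
  missing <- setdiff(expected, names(df))
  extra <- setdiff(names(df), expected)
  if (length(missing) || length(extra))
    stop(what, " table has wrong columns.",
         if (length(missing)) paste0(" Missing: ", paste(missing, collapse = ", "), "."),
         if (length(extra)) paste0(" Unexpected: ", paste(extra, collapse = ", "), "."))
  df[expected]
}

#' Read / write the pipeline's tables
#'
#' Typed, schema-checked CSV round-trips for traces (`time_s`,
#' `value_pct`), events (`animal_id`, `peak_time_s`, `amplitude_pct`,
#' `width_s`; kept sorted by peak time), trajectories (`frame`, `x_mm`,
#' `y_mm`; frames must be consecutive), spectra (`freq_hz`, `power`,
#' `source`), and correlation matrices (4 x 4 with header labels). Errors
#' name the offending columns or rows.
#'
#' @param trace A [ca_trace()]; `path` a CSV path.
#' @return Readers return the corresponding object; writers the path.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "ca_trace"))
  utils::write.csv(data.frame(time_s = trace_times(trace), value_pct = trace$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @param fs,provenance Metadata for the rebuilt trace.
#' @export
read_trace_csv <- function(path, fs = NULL, provenance = "whole_brain") {
  df <- check_columns(utils::read.csv(path), c("time_s", "value_pct"), "trace")
  if (is.null(fs)) {
    dt <- diff(df$time_s)
    if (length(dt) == 0 || any(abs(dt - dt[1]) > 1e-9))
      stop("trace table has non-uniform time steps; pass fs explicitly")
    fs <- 1 / dt[1]
  }
  ca_trace(df$value_pct, fs, provenance)
}

#' @rdname write_trace_csv
#' @param events An `event_set`; `animal_id` an identifier column value.
#' @export
write_events_csv <- function(events, path, animal_id = 1) {
  stopifnot(inherits(events, "event_set"))
  df <- data.frame(animal_id = rep(animal_id, length.out = nrow(events)),
                   peak_time_s = events$peak_time_s,
                   amplitude_pct = events$amplitude, width_s = events$width_s)
  df <- df[order(df$peak_time_s), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_events_csv <- function(path) {
  df <- check_columns(utils::read.csv(path),
                      c("animal_id", "peak_time_s", "amplitude_pct", "width_s"),
                      "events")
  df[order(df$peak_time_s), , drop = FALSE]
}

#' @rdname write_trace_csv
#' @param traj A [swim_trajectory()].
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "swim_trajectory"))
  utils::write.csv(data.frame(frame = seq_len(nrow(traj)) - 1L,
                              x_mm = traj$x_mm, y_mm = traj$y_mm),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @param fps Frame rate of the stored trajectory.
#' @export
read_trajectory_csv <- function(path, fps = 50) {
  df <- check_columns(utils::read.csv(path), c("frame", "x_mm", "y_mm"), "trajectory")
  bad <- which(diff(df$frame) != 1)
  if (length(bad))
    stop("trajectory frame column is not consecutive at rows: ",
         paste(utils::head(bad + 1, 10), collapse = ", "))
  swim_trajectory(df$x_mm, df$y_mm, fps)
}

#' @rdname write_trace_csv
#' @param spec A `power_spectrum`.
#' @export
write_spectrum_csv <- function(spec, path) {
  stopifnot(inherits(spec, "power_spectrum"))
  utils::write.csv(data.frame(freq_hz = spec$freqs, power = spec$power,
                              source = spec$source), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_spectrum_csv <- function(path) {
  df <- check_columns(utils::read.csv(path), c("freq_hz", "power", "source"), "spectrum")
  structure(list(freqs = df$freq_hz, power = df$power, source = df$source[1]),
            class = "power_spectrum")
}

#' @rdname write_trace_csv
#' @param mat A `synchrony_matrix`.
#' @export
write_matrix_csv <- function(mat, path) {
  utils::write.csv(as.data.frame(unclass(mat)), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1)
  m <- as.matrix(df)
  dimnames(m) <- list(rownames(df), colnames(df))
  class(m) <- c("synchrony_matrix", class(m))
  m
}

#' Threshold model JSON round-trip
#'
#' @param model A `threshold_model`.
#' @param path JSON path.
#' @export
write_threshold_json <- function(model, path) {
  stopifnot(inherits(model, "threshold_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_threshold_json
#' @export
read_threshold_json <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE), class = "threshold_model")
}
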