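#' Global event-detection threshold from pooled control traces
#'
#' All samples of all high-pass-filtered control whole-brain traces are
#' pooled into a single distribution and the cutoff is set at
#' `multiplier` times its standard deviation (population form, denominator
#' n). The resulting threshold is fixed: it is applied unchanged to every
#' replicate and experimental group, with no per-trace adaptation.
#'
#' @param control_traces List of filtered traces (see [highpass_filter()]).
#' @param multiplier Threshold multiplier (default 3).
#' @return A `threshold_model` with `pooled_sd`, `multiplier`, `threshold`,
#'   `n_traces`, `n_samples`.
#' @export
derive_global_threshold <- function(control_traces, multiplier = 3) {
  if (inherits(control_traces, "ca_trace")) control_traces <- list(control_traces)
  stopifnot(length(control_traces) >= 1,
            all(vapply(control_traces, inherits, logical(1), "ca_trace")))
  pool <- unlist(lapply(control_traces, `[[`, "values"), use.names = FALSE)
  if (length(pool) == 0) stop("empty control pool")
  pooled_sd <- sqrt(mean(pool^2) - mean(pool)^2)
  if (pooled_sd == 0) stop("control pool has zero variance")
  structure(list(pooled_sd = pooled_sd, multiplier = multiplier,
                 threshold = multiplier * pooled_sd,
                 n_traces = length(control_traces), n_samples = length(pool)),
            class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf("<threshold_model> %g x pooled SD %.4f = %.4f (%d traces, %d samples)\n",
              x$multiplier, x$pooled_sd, x$threshold, x$n_traces, x$n_samples))
  invisible(x)
}

#' Detect calcium events on a filtered whole-brain trace
#'
#' Local maxima of the filtered trace are screened in three steps:
#' peaks whose full width at half prominence is below `min_width_s` are
#' dropped; among peaks closer than `min_distance_s` the higher one is kept
#' (ties resolved in favour of the earlier peak); remaining peaks must
#' exceed the fixed control-derived threshold. The event amplitude is the
#' filtered-trace value at the peak sample and plateaus peak at their first
#' sample. Prominence is measured down to the higher of the two minima
#' separating the peak from its nearest higher neighbours (or the trace
#' ends), the usual topographic convention; widths are linearly
#' interpolated at the half-prominence reference level.
#'
#' @param trace A filtered [ca_trace()].
#' @param model A `threshold_model` from [derive_global_threshold()], or a
#'   single numeric threshold in dF/F0 percent.
#' @param min_width_s Minimum full width at half prominence, seconds.
#' @param min_distance_s Minimum separation between retained peaks, seconds.
#' @return An `event_set`: a data frame with columns `peak_time_s`,
#'   `amplitude`, `width_s`, sorted by time (possibly zero rows).
#' @export
detect_events <- function(trace, model, min_width_s = 5, min_distance_s = 5) {
  stopifnot(inherits(trace, "ca_trace"), min_width_s > 0, min_distance_s > 0)
  threshold <- if (inherits(model, "threshold_model")) model$threshold else as.numeric(model)
  x <- trace$values
  fs <- trace$fs
  pk <- find_local_maxima(x)
  empty <- function() {
    structure(data.frame(peak_time_s = numeric(0), amplitude = numeric(0),
                         width_s = numeric(0)),
              class = c("event_set", "data.frame"), threshold = threshold)
  }
  if (length(pk) == 0) return(empty())
  pw <- peak_prominence_width(x, pk)
  keep <- pw$width / fs >= min_width_s
  pk <- pk[keep]; pw <- lapply(pw, `[`, keep)
  if (length(pk) == 0) return(empty())
  ## distance pruning: keep the higher peak; ties go to the earlier one
  ord <- order(-x[pk], pk)
  sel <- logical(length(pk)); taken <- integer(0)
  for (k in ord) {
    if (!length(taken) || all(abs(pk[k] - taken) >= min_distance_s * fs)) {
      sel[k] <- TRUE
      taken <- c(taken, pk[k])
    }
  }
  pk <- pk[sel]; pw <- lapply(pw, `[`, sel)
  keep <- x[pk] > threshold
  pk <- pk[keep]; pw <- lapply(pw, `[`, keep)
  o <- order(pk)
  structure(data.frame(peak_time_s = (pk[o] - 1) / fs,
                       amplitude = x[pk[o]],
                       width_s = pw$width[o] / fs),
            class = c("event_set", "data.frame"), threshold = threshold)
}

## indices of strict local maxima; a flat run counts once, at its first sample
find_local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  out <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L
      if (j < n && x[j + 1L] < x[j]) out <- c(out, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

## prominence and interpolated full width at half prominence for each peak
peak_prominence_width <- function(x, pk) {
  n <- length(x)
  prom <- width <- numeric(length(pk))
  for (k in seq_along(pk)) {
    p <- pk[k]; h <- x[p]
    il <- p; lmin <- h
    while (il > 1L && x[il - 1L] <= h) { il <- il - 1L; lmin <- min(lmin, x[il]) }
    if (il > 1L) lmin <- min(x[il:p])      # bounded by a higher sample on the left
    ir <- p; rmin <- h
    while (ir < n && x[ir + 1L] <= h) { ir <- ir + 1L; rmin <- min(rmin, x[ir]) }
    if (ir < n) rmin <- min(x[p:ir])
    prom[k] <- h - max(lmin, rmin)
    ref <- h - prom[k] / 2
    a <- p
    while (a > 1L && x[a - 1L] > ref) a <- a - 1L
    xl <- if (a > 1L) (a - 1) + (x[a - 1L] - ref) / (x[a - 1L] - x[a]) else 1
    b <- p
    while (b < n && x[b + 1L] > ref) b <- b + 1L
    xr <- if (b < n) (b + 1) - (x[b + 1L] - ref) / (x[b + 1L] - x[b]) else n
    width[k] <- xr - xl
  }
  list(prominence = prom, width = width)
}

#' Event-count and mean-amplitude summary of one recording
#'
#' @param events An `event_set` from [detect_events()].
#' @param duration_s Recording duration in seconds.
#' @return A list with `count`, `mean_amplitude` (`NA` when no events),
#'   `rate_per_min`, and `duration_s`.
#' @export
summarize_events <- function(events, duration_s) {
  stopifnot(inherits(events, "event_set"), duration_s > 0)
  n <- nrow(events)
  list(count = n,
       mean_amplitude = if (n > 0) mean(events$amplitude) else NA_real_,
       rate_per_min = n / (duration_s / 60),
       duration_s = duration_s)
}
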