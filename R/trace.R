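#' Fluorescence trace
#'
#' A regularly sampled \eqn{\Delta F/F_0}\% time series with its sampling rate
#' and a provenance tag (an ROI label or `"whole_brain"`).
#'
#' @param values Numeric vector of \eqn{\Delta F/F_0} values in percent.
#' @param fs Sampling rate in Hz.
#' @param provenance Character scalar identifying the source of the trace.
#' @return An object of class `ca_trace`.
#' @export
ca_trace <- function(values, fs, provenance = "whole_brain") {
  stopifnot(is.numeric(values), length(values) >= 1, all(is.finite(values)),
            is.numeric(fs), length(fs) == 1, fs > 0)
  structure(list(values = as.numeric(values), fs = as.numeric(fs),
                 provenance = as.character(provenance)[1]),
            class = "ca_trace")
}

#' @export
print.ca_trace <- function(x, ...) {
  cat(sprintf("<ca_trace> %s: %d samples at %g Hz (%.1f s)\n",
              x$provenance, length(x$values), x$fs, length(x$values) / x$fs))
  invisible(x)
}

#' @export
length.ca_trace <- function(x) length(x$values)

#' Sample times of a trace
#'
#' @param trace A [ca_trace()].
#' @return Numeric vector of times in seconds; sample `i` is at `(i-1)/fs`.
#' @export
trace_times <- function(trace) {
  (seq_along(trace$values) - 1) / trace$fs
}

is_filtered_trace <- function(x) inherits(x, "filtered_trace")
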