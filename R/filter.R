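#' Zero-phase high-pass filtering of fluorescence traces
#'
#' Removes slow baseline drift with a second-order Butterworth high-pass
#' applied forward and backward (zero phase, so peak timing is preserved;
#' the effective magnitude response is the square of the single-pass
#' response). The default 0.005 Hz cutoff passes calcium transients while
#' rejecting slow drift of the baseline image.
#'
#' The forward/backward passes are initialised at the filter's steady state
#' for a step of the first/last sample value and the input is extended by
#' odd reflection, so a constant trace maps to (numerically) zero and edge
#' transients are suppressed even at cutoffs far below the sampling rate.
#'
#' @param trace A [ca_trace()].
#' @param cutoff_hz High-pass cutoff frequency in Hz.
#' @param order Butterworth order of each pass.
#' @return A `filtered_trace` (also a `ca_trace`) with elements `cutoff_hz`
#'   and, when the input is shorter than three filter warm-up lengths
#'   (about `3 * fs / cutoff_hz` samples), a `warning` element naming the
#'   limitation.
#' @export
highpass_filter <- function(trace, cutoff_hz = 0.005, order = 2) {
  stopifnot(inherits(trace, "ca_trace"), cutoff_hz > 0)
  if (trace$fs <= 2 * cutoff_hz)
    stop("sampling rate must exceed twice the high-pass cutoff")
  bf <- signal::butter(order, cutoff_hz / (trace$fs / 2), type = "high")
  out <- trace
  out$values <- zero_phase_filter(bf$b, bf$a, trace$values)
  out$cutoff_hz <- cutoff_hz
  warmup <- trace$fs / cutoff_hz           # one filter time constant, in samples
  if (length(trace$values) < 3 * warmup)
    out$warning <- "trace shorter than three filter warm-up lengths; edge response may dominate"
  class(out) <- c("filtered_trace", class(trace))
  out
}

## Forward-backward IIR with steady-state initial conditions and odd
## reflection padding. signal::filtfilt leaves large edge transients at
## very low relative cutoffs, which breaks DC rejection on finite traces.
zero_phase_filter <- function(b, a, x) {
  nx <- length(x)
  ord <- max(length(a), length(b)) - 1
  padlen <- min(30 * ord, nx - 1)
  onepass <- function(z) {
    yss <- z[1] * sum(b) / sum(a)   # steady-state output for a step of z[1]
    as.numeric(signal::filter(b, a, z,
                              init.x = rep(z[1], ord), init.y = rep(yss, ord)))
  }
  if (padlen > 0) {
    ext <- c(2 * x[1] - x[(padlen + 1):2], x, 2 * x[nx] - x[(nx - 1):(nx - padlen)])
  } else ext <- x
  y <- onepass(ext)
  y <- rev(onepass(rev(y)))
  if (padlen > 0) y <- y[(padlen + 1):(padlen + nx)]
  y
}
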