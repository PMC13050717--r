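#' Common frequency grid for power spectra
#'
#' All spectra in a study are interpolated onto one fixed grid so they can
#' be averaged and compared pointwise. The grid spans 0.01-1 Hz; its
#' spacing (0.0001 Hz) is well below the native resolution of a 30-min
#' recording (1/1800 Hz), so trapezoidal integration over the linear
#' interpolant reproduces the native band integral even for line-like
#' spectra.
#'
#' @param lo,hi Band edges in Hz.
#' @param by Grid spacing in Hz.
#' @return Numeric vector of frequencies.
#' @export
psd_grid <- function(lo = 0.01, hi = 1, by = 0.0001) {
  stopifnot(lo > 0, hi > lo, by > 0)
  seq(lo, hi, by = by)
}

#' Power spectral density of a dF/F0 trace
#'
#' The trace is linearly detrended, tapered with a split-cosine bell over
#' `taper` of its length (the classic periodogram taper; set `taper = 0`
#' for a rectangular window), Fourier transformed, and converted to a
#' single-sided power density in (dF/F0)^2/Hz. The normalisation is
#' Parseval-consistent: the trapezoidal integral of the density over
#' (0, Nyquist] equals the variance of the detrended trace (taper power
#' compensated), so integrated band power is directly comparable to signal
#' variance. The density is then linearly interpolated onto the common
#' grid; grid frequencies outside the native support are set to zero with
#' a warning.
#'
#' @param trace A [ca_trace()] (raw dF/F0; detrending is internal).
#' @param grid Common frequency grid from [psd_grid()].
#' @param taper Total taper proportion (split between the two ends).
#' @param detrend Remove a least-squares line before transforming.
#' @return A `power_spectrum` with `freqs`, `power`, `source`.
#' @export
roi_power_spectrum <- function(trace, grid = psd_grid(), taper = 0.1, detrend = TRUE) {
  stopifnot(inherits(trace, "ca_trace"))
  x <- trace$values
  n <- length(x)
  fs <- trace$fs
  if (n < 2 / min(grid) * fs)
    stop("trace too short: need at least two cycles of the lowest grid frequency")
  if (detrend) x <- stats::residuals(stats::lm.fit(cbind(1, seq_len(n)), x))
  w <- split_cosine_bell(n, taper)
  xw <- x * w
  X <- stats::fft(xw)
  df <- fs / n
  half <- floor(n / 2)
  wnorm <- mean(w^2)
  f_nat <- (1:(half - 1)) * df
  p_nat <- (2 * Mod(X[2:half]) / n)^2 / (2 * df * wnorm)
  if (n %% 2 == 0) {          # Nyquist bin (not doubled)
    f_nat <- c(f_nat, fs / 2)
    p_nat <- c(p_nat, (Mod(X[half + 1]) / n)^2 / (df * wnorm))
  }
  inside <- grid >= f_nat[1] & grid <= f_nat[length(f_nat)]
  power <- numeric(length(grid))
  if (any(!inside))
    warning(sum(!inside), " grid frequencies outside the native support were set to 0")
  power[inside] <- stats::approx(f_nat, p_nat, xout = grid[inside])$y
  structure(list(freqs = grid, power = power, source = trace$provenance),
            class = "power_spectrum")
}

split_cosine_bell <- function(n, p = 0.1) {
  w <- rep(1, n)
  m <- floor(n * p / 2)
  if (m > 0) {
    ramp <- 0.5 * (1 - cos(pi * (seq_len(m) - 0.5) / m))
    w[1:m] <- ramp
    w[(n - m + 1):n] <- rev(ramp)
  }
  w
}

#' Per-animal mean spectrum across calcium-active ROIs
#'
#' @param roi_spectra List of `power_spectrum` objects on identical grids.
#' @return A `power_spectrum` with source `"animal_mean"`.
#' @export
animal_mean_spectrum <- function(roi_spectra) {
  if (inherits(roi_spectra, "power_spectrum")) roi_spectra <- list(roi_spectra)
  stopifnot(length(roi_spectra) >= 1)
  f <- roi_spectra[[1]]$freqs
  for (s in roi_spectra)
    if (!identical(s$freqs, f)) stop("spectra are not on identical grids")
  pw <- rowMeans(vapply(roi_spectra, `[[`, numeric(length(f)), "power"))
  structure(list(freqs = f, power = pw, source = "animal_mean"),
            class = "power_spectrum")
}

#' Integrated low-frequency power
#'
#' Trapezoidal area under the power spectrum over `band`, the per-animal
#' scalar used for group comparisons.
#'
#' @param spec A `power_spectrum`.
#' @param band Length-2 numeric band in Hz (must lie within the grid).
#' @return Integrated power (units of power times Hz, i.e. (dF/F0)^2).
#' @export
integrated_low_freq_power <- function(spec, band = c(0.01, 1)) {
  stopifnot(inherits(spec, "power_spectrum"), length(band) == 2, band[2] > band[1])
  idx <- spec$freqs >= band[1] & spec$freqs <= band[2]
  if (sum(idx) < 2) stop("band does not cover at least two grid points")
  f <- spec$freqs[idx]; p <- spec$power[idx]
  sum((p[-1] + p[-length(p)]) / 2 * diff(f))
}

#' Group-mean spectrum with pointwise 95% confidence envelope
#'
#' Pointwise mean across animals with a t-based confidence interval
#' (`mean +- t[0.975, n-1] * SEM`).
#'
#' @param animal_spectra List of per-animal `power_spectrum` objects on
#'   identical grids (n >= 2).
#' @param conf Confidence level.
#' @return A `group_spectrum` with `freqs`, `mean_power`, `ci_low`,
#'   `ci_high`, `n_animals`.
#' @export
group_spectrum <- function(animal_spectra, conf = 0.95) {
  stopifnot(length(animal_spectra) >= 2)
  f <- animal_spectra[[1]]$freqs
  for (s in animal_spectra)
    if (!identical(s$freqs, f)) stop("spectra are not on identical grids")
  m <- vapply(animal_spectra, `[[`, numeric(length(f)), "power")
  n <- ncol(m)
  mu <- rowMeans(m)
  sem <- apply(m, 1, stats::sd) / sqrt(n)
  tcrit <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
  structure(list(freqs = f, mean_power = mu,
                 ci_low = mu - tcrit * sem, ci_high = mu + tcrit * sem,
                 n_animals = n),
            class = "group_spectrum")
}
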