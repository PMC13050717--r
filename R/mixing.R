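#' Mix a correlated left/right trace pair
#'
#' Builds two traces with expected Pearson correlation `rho` from one
#' shared trace: the shared trace is standardised to `z` and combined with
#' independent standard-normal noise as
#' `left = sqrt(rho) z + sqrt(1 - rho) n_L` (and likewise for the right
#' side), so `cor(left, right)` converges to `rho`. Used to emulate
#' homotopic (left-right) synchrony in trace space, where the expected
#' correlation is exact.
#'
#' @param shared A [ca_trace()] (or numeric vector) with nonzero variance.
#' @param rho Target correlation in `[0, 1]`.
#' @param seed Integer seed for the independent noise.
#' @param fs Sampling rate when `shared` is a bare vector.
#' @return List with `ca_trace` elements `left` and `right`.
#' @export
mix_correlated_pair <- function(shared, rho, seed, fs = 2) {
  if (inherits(shared, "ca_trace")) {
    fs <- shared$fs
    shared <- shared$values
  }
  stopifnot(is.numeric(shared), length(shared) >= 2, rho >= 0, rho <= 1)
  s <- stats::sd(shared)
  if (s == 0) stop("shared trace is constant; cannot standardise")
  z <- (shared - mean(shared)) / s
  set.seed(fold_seed(seed))
  n_l <- stats::rnorm(length(z))
  n_r <- stats::rnorm(length(z))
  list(left = ca_trace(sqrt(rho) * z + sqrt(1 - rho) * n_l, fs, "left"),
       right = ca_trace(sqrt(rho) * z + sqrt(1 - rho) * n_r, fs, "right"))
}
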