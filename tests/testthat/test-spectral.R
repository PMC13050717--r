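test_that("spectra of trivial traces behave as required", {
  z <- roi_power_spectrum(ca_trace(rep(0, 3600), 2))
  expect_true(all(z$power == 0))
  expect_equal(integrated_low_freq_power(z), 0)
  ## flat spectrum: area over [0.01, 1] is 0.99 * P
  flat <- structure(list(freqs = psd_grid(), power = rep(4, length(psd_grid())),
                         source = "x"), class = "power_spectrum")
  expect_equal(integrated_low_freq_power(flat), 0.99 * 4, tolerance = 1e-9)
})

test_that("a pure sinusoid concentrates its variance at its frequency", {
  tt <- seq(0, 3600 - 0.5, by = 0.5)
  tr <- ca_trace(2 * sin(2 * pi * 0.1 * tt), 2)
  sp <- roi_power_spectrum(tr)
  ## Parseval: integrated power over the grid matches the variance (= 2)
  expect_lt(abs(integrated_low_freq_power(sp) - 2) / 2, 0.05)
  ## spectral mass concentrated near 0.1 Hz
  away <- abs(sp$freqs - 0.1) > 0.005
  expect_lt(sum(sp$power[away]) / sum(sp$power), 0.01)
})

test_that("white noise integrates to its variance across the band", {
  set.seed(12)
  err <- replicate(6, {
    x <- rnorm(3600, 0, 1.5)
    tr <- ca_trace(x, 2)
    integrated_low_freq_power(roi_power_spectrum(tr)) / var(x)
  })
  ## the 0.01-1 Hz band holds 99% of a white spectrum over (0, 1] Hz
  expect_lt(abs(mean(err) - 0.99), 0.05)
})

test_that("Parseval holds within 5% for smooth in-band signals", {
  set.seed(13)
  tt <- seq(0, 1800 - 0.5, by = 0.5)
  x <- rnorm(3600, 0, 0.7)
  for (f in c(0.03, 0.11, 0.41)) x <- x + runif(1, 1, 2) * sin(2 * pi * f * tt + runif(1))
  tr <- ca_trace(x, 2)
  expect_lt(abs(integrated_low_freq_power(roi_power_spectrum(tr)) - var(x)) / var(x), 0.05)
})

test_that("power scales quadratically with trace amplitude", {
  set.seed(14)
  x <- rnorm(3600)
  s1 <- roi_power_spectrum(ca_trace(x, 2))
  s3 <- roi_power_spectrum(ca_trace(3 * x, 2))
  expect_equal(s3$power, 9 * s1$power, tolerance = 1e-12)
  expect_equal(integrated_low_freq_power(s3), 9 * integrated_low_freq_power(s1),
               tolerance = 1e-12)
})

test_that("animal mean spectra average pointwise on a shared grid", {
  g <- psd_grid()
  mk <- function(p) structure(list(freqs = g, power = rep(p, length(g)), source = "r"),
                              class = "power_spectrum")
  expect_equal(animal_mean_spectrum(list(mk(2)))$power, rep(2, length(g)))
  expect_equal(animal_mean_spectrum(list(mk(1), mk(3)))$power, rep(2, length(g)))
  expect_equal(animal_mean_spectrum(rep(list(mk(5)), 4))$power, rep(5, length(g)))
  bad <- mk(1); bad$freqs <- bad$freqs + 1e-6
  expect_error(animal_mean_spectrum(list(mk(1), bad)), "identical grids")
})

test_that("all spectra in a run share a bit-identical grid", {
  set.seed(15)
  sp <- lapply(1:3, function(i) roi_power_spectrum(ca_trace(rnorm(3600), 2)))
  expect_identical(sp[[1]]$freqs, sp[[2]]$freqs)
  expect_identical(sp[[2]]$freqs, sp[[3]]$freqs)
})

test_that("group spectra carry t-based confidence envelopes", {
  g <- psd_grid()
  mk <- function(p) structure(list(freqs = g, power = p, source = "a"),
                              class = "power_spectrum")
  same <- group_spectrum(list(mk(rep(2, length(g))), mk(rep(2, length(g)))))
  expect_equal(same$ci_low, same$mean_power)
  expect_equal(same$ci_high, same$mean_power)
  two <- group_spectrum(list(mk(rep(1, length(g))), mk(rep(3, length(g)))))
  expect_equal(two$mean_power, rep(2, length(g)))
  ## closed-form t-interval oracle on random spectra
  set.seed(16)
  mats <- lapply(1:5, function(i) mk(runif(length(g))))
  gs <- group_spectrum(mats)
  m <- sapply(mats, `[[`, "power")
  sem <- apply(m, 1, sd) / sqrt(5)
  expect_equal(gs$ci_high, rowMeans(m) + qt(0.975, 4) * sem, tolerance = 1e-12)
  expect_true(all(gs$ci_low <= gs$mean_power & gs$mean_power <= gs$ci_high))
  expect_error(group_spectrum(list(mk(rep(1, length(g))))), ">= 2")
})

test_that("too-short traces are rejected", {
  expect_error(roi_power_spectrum(ca_trace(rnorm(100), 2)), "too short")
})
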