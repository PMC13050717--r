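test_that("baseline is the per-pixel temporal median", {
  expect_true(all(compute_baseline(const_movie(7)) == 7))
  m <- const_movie(0, t = 3)
  m$data[, 2, 2] <- c(10, 20, 10)
  expect_equal(compute_baseline(m)[2, 2], 10)
  set.seed(1)
  r <- movie_stack(array(runif(6 * 4 * 5), dim = c(6, 4, 5)))
  f0 <- compute_baseline(r)
  for (i in 1:4) for (j in 1:5) {
    v <- sort(r$data[, i, j])                 # sort-based oracle, even count
    expect_identical(f0[i, j], (v[3] + v[4]) / 2)
  }
})

test_that("dF/F0 arithmetic is exact and guards invalid baselines", {
  m <- const_movie(5)
  expect_true(all(compute_dff(m)$data == 0))
  m2 <- const_movie(10, t = 3)
  m2$data[, 1, 1] <- c(10, 20, 10)
  d <- compute_dff(m2)
  expect_equal(d$data[, 1, 1], c(0, 100, 0))
  ## a dark pixel is flagged invalid, not zeroed, and never enters traces
  m3 <- const_movie(10, t = 4)
  m3$data[, 2, 2] <- 0
  m3$data[, 1, 1] <- c(10, 12, 10, 10)
  d3 <- compute_dff(m3)
  expect_false(d3$valid[2, 2])
  expect_true(all(is.na(d3$data[, 2, 2])))
  mask <- matrix(TRUE, 3, 3)
  tr <- extract_roi_trace(d3, mask)
  expect_true(all(is.finite(tr$values)))
  dark <- const_movie(0)
  expect_error(compute_dff(dark), "nonpositive")
})

test_that("dF/F0 is invariant to rescaling the raw intensities", {
  set.seed(2)
  arr <- array(runif(5 * 4 * 4, 1, 2), dim = c(5, 4, 4))
  d1 <- compute_dff(movie_stack(arr))
  d2 <- compute_dff(movie_stack(arr * 37.5))
  expect_equal(d1$data, d2$data, tolerance = 1e-12)
})

test_that("pixels outside the brain mask never influence traces", {
  set.seed(3)
  arr <- array(runif(6 * 5 * 5, 1, 2), dim = c(6, 5, 5))
  brain <- matrix(FALSE, 5, 5); brain[2:4, 2:4] <- TRUE
  base <- whole_brain_trace(compute_dff(movie_stack(arr)), brain)
  arr2 <- arr
  for (t in 1:6) {
    fr <- arr2[t, , ]
    fr[!brain] <- fr[!brain] * 1000 + 5          # corrupt everything outside
    arr2[t, , ] <- fr
  }
  corrupted <- whole_brain_trace(compute_dff(movie_stack(arr2)), brain)
  expect_identical(base$values, corrupted$values)
})

test_that("ROI traces equal the explicit per-frame mean", {
  set.seed(4)
  arr <- array(runif(7 * 4 * 4, 1, 2), dim = c(7, 4, 4))
  d <- compute_dff(movie_stack(arr))
  ## single pixel: identity
  one <- extract_roi_trace(d, ca_roi(1, cbind(2, 3)))
  expect_equal(one$values, d$data[, 2, 3])
  ## forced two-pixel mean
  d2 <- d
  d2$data[, 1, 1] <- c(0, 2, 0, 2, 0, 2, 0)
  d2$data[, 1, 2] <- c(2, 0, 2, 0, 2, 0, 2)
  two <- extract_roi_trace(d2, ca_roi(1, rbind(c(1, 1), c(1, 2))))
  expect_equal(two$values, rep(1, 7))
  ## brute-force loop oracle on a random ROI
  px <- rbind(c(1, 2), c(2, 2), c(3, 4), c(4, 1))
  got <- extract_roi_trace(d, ca_roi(2, px))$values
  want <- vapply(1:7, function(t) mean(d$data[cbind(t, px)]), numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
  dead <- const_movie(10, t = 3)
  dead$data[, 1, 1] <- 0
  expect_error(extract_roi_trace(compute_dff(dead), ca_roi(1, cbind(1, 1))),
               "no valid pixels")
})

test_that("whole-brain trace reduces correctly for trivial masks", {
  set.seed(5)
  arr <- array(runif(5 * 3 * 3, 1, 2), dim = c(5, 3, 3))
  d <- compute_dff(movie_stack(arr))
  single <- matrix(FALSE, 3, 3); single[2, 2] <- TRUE
  expect_equal(whole_brain_trace(d, single)$values, d$data[, 2, 2])
  ## uniform frames: trace equals the frame value
  u <- const_movie(10, t = 4)
  u$data[3, , ] <- 12
  du <- compute_dff(u)
  expect_equal(whole_brain_trace(du, matrix(TRUE, 3, 3))$values, c(0, 0, 20, 0))
})

test_that("region mask invariants are enforced", {
  g <- default_region_geometry(32, 32)
  expect_s3_class(g, "region_masks")
  expect_true(all(vapply(g$regions, sum, numeric(1)) > 0))
  bad <- g$regions
  bad$FB_R <- bad$FB_L                      # overlap
  expect_error(region_masks(g$brain, bad), "overlap")
  out <- g$regions
  out$FB_L <- matrix(TRUE, 32, 32)          # escapes the brain mask
  expect_error(region_masks(g$brain, out), "outside")
})

test_that("synthetic movies round-trip through the imaging pipeline", {
  geom <- default_region_geometry(32, 32)
  preset <- cohort_preset("control")
  out <- synthesize_movie(preset, geom, seed = 21, duration_s = 240,
                          pixel_noise_sd = 0)
  expect_equal(dim(out$movie$data), c(480, 32, 32))
  expect_true(all(out$movie$data >= 0))
  dff <- compute_dff(out$movie)
  wb <- whole_brain_trace(dff, geom$brain)
  expect_length(wb$values, 480)
  if (nrow(out$truth) > 0) {
    ## the strongest planted event shows up at the right time in the
    ## whole-brain trace (within one sample of the planted peak)
    big <- out$truth[which.max(out$truth$amplitude), ]
    tp <- log(12 / 2) * 2 * 12 / 10
    t_max <- trace_times(wb)[which.max(wb$values)]
    expect_lt(abs(t_max - (big$event_time_s + tp)), 25)  # plateau shifts the max
  }
  ## static scene: zero events, zero noise reproduces F0 in every frame
  p0 <- preset
  p0$event_train$rate <- 0
  p0$noise <- noise_drift_config(noise_sd = 0, drift_amp = 0)
  still <- synthesize_movie(p0, geom, seed = 1, duration_s = 30, pixel_noise_sd = 0)
  expect_equal(nrow(still$truth), 0)
  for (t in c(1, 30)) expect_equal(still$movie$data[t, , ], still$movie$data[1, , ])
  d0 <- compute_dff(still$movie)
  for (t in c(1, 15, 30))
    expect_true(all(abs(d0$data[t, , ][geom$brain]) < 1e-9))
})
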