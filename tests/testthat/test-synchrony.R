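test_that("centroid ROIs have exactly the requested area at the centroid", {
  full <- matrix(TRUE, 100, 100)
  roi <- centroid_circular_roi(full, 500)
  expect_identical(nrow(roi$pixels), 500L)
  expect_equal(unname(roi$center), c(50.5, 50.5))
  ## all chosen pixels are within the grown radius of the centroid
  d <- sqrt((roi$pixels[, 1] - 50.5)^2 + (roi$pixels[, 2] - 50.5)^2)
  expect_lt(max(d), sqrt(500 / pi) + 1.5)
  ## degenerate one-pixel ROI
  one <- centroid_circular_roi(full, 1)
  expect_identical(nrow(one$pixels), 1L)
  ## exact area holds for random region sizes too (trim rule)
  set.seed(17)
  for (a in c(37, 123, 500)) {
    m <- matrix(FALSE, 60, 60)
    m[sample(3600, 1500)] <- TRUE
    expect_identical(nrow(centroid_circular_roi(m, a)$pixels), as.integer(a))
  }
})

test_that("L-shaped regions use the coordinate-mean centroid, unclipped", {
  m <- matrix(FALSE, 40, 40)
  m[1:30, 1:10] <- TRUE
  m[21:30, 11:40] <- TRUE
  roi <- centroid_circular_roi(m, 200)
  px <- which(m, arr.ind = TRUE)
  expect_equal(unname(roi$center), unname(colMeans(px)), tolerance = 1e-12)
  ## the circle is allowed to leave the region for concave shapes
  inside <- m[roi$pixels]
  expect_true(any(!inside))
  clipped <- centroid_circular_roi(m, 200, clip_to_region = TRUE)
  expect_true(all(m[clipped$pixels]))
})

test_that("correlation matrices obey Pearson identities", {
  set.seed(18)
  x <- rnorm(400)
  tr <- list(FB_L = x, FB_R = x, MB_L = x, MB_R = x)
  m1 <- synchrony_matrix_from_traces(tr)
  expect_true(all(abs(m1 - 1) < 1e-12))
  tr$FB_R <- -x
  m2 <- synchrony_matrix_from_traces(tr)
  expect_equal(m2["FB_L", "FB_R"], -1, tolerance = 1e-12)
  ## r(x, ax + b) = sign(a), exactly
  tr2 <- list(FB_L = x, FB_R = 2.5 * x + 3, MB_L = -0.3 * x + 1, MB_R = rnorm(400))
  m3 <- synchrony_matrix_from_traces(tr2)
  expect_equal(m3["FB_L", "FB_R"], 1, tolerance = 1e-12)
  expect_equal(m3["FB_L", "MB_L"], -1, tolerance = 1e-12)
  expect_true(all(abs(m3) <= 1 + 1e-12))
  expect_identical(m3, t(m3))
  ## explicit covariance/variance oracle
  a <- tr2$FB_L; b <- tr2$MB_R
  oracle <- mean((a - mean(a)) * (b - mean(b))) /
    sqrt(mean((a - mean(a))^2) * mean((b - mean(b))^2))
  expect_equal(m3["FB_L", "MB_R"], oracle, tolerance = 1e-12)
  ## zero-variance trace: flagged NA, not silently 0
  tr3 <- tr2; tr3$MB_R <- rep(1, 400)
  m4 <- synchrony_matrix_from_traces(tr3)
  expect_true(is.na(m4["FB_L", "MB_R"]))
})

test_that("synchrony summaries pull the four reported pairings", {
  m <- diag(1, 4)
  dimnames(m) <- list(c("FB_L", "FB_R", "MB_L", "MB_R"),
                      c("FB_L", "FB_R", "MB_L", "MB_R"))
  m[upper.tri(m)] <- 0.5; m[lower.tri(m)] <- 0.5
  class(m) <- c("synchrony_matrix", class(m))
  s <- synchrony_summary(m)
  expect_equal(unname(s), rep(0.5, 4))
  expect_named(s, c("mb_lr", "fb_lr", "mbfb_right", "mbfb_left"))
  mt <- t(m)
  class(mt) <- c("synchrony_matrix", class(mt))
  expect_equal(synchrony_summary(mt), s)
})

test_that("the mixing model reproduces its target correlation", {
  set.seed(19)
  shared <- ca_trace(rnorm(3600), 2)
  p1 <- mix_correlated_pair(shared, 1, seed = 1)
  expect_equal(p1$left$values, p1$right$values)
  expect_equal(cor(p1$left$values, p1$right$values), 1)
  p0 <- mix_correlated_pair(shared, 0, seed = 2)
  expect_lt(abs(cor(p0$left$values, p0$right$values)), 0.06)
  ## Monte Carlo at rho = 0.5: mean sample r within 0.02
  rs <- vapply(1:300, function(s) {
    p <- mix_correlated_pair(shared, 0.5, seed = 1000 + s)
    cor(p$left$values, p$right$values)
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.5), 0.02)
  expect_error(mix_correlated_pair(ca_trace(rep(2, 100), 2), 0.5, 1), "constant")
})

test_that("centroid-ROI synchrony recovers movie-level coupling", {
  geom <- default_region_geometry(32, 32)
  preset <- cohort_preset("crispant")
  out <- synthesize_movie(preset, geom, seed = 30, duration_s = 900)
  dff <- compute_dff(out$movie)
  area <- 40                                # scaled-down fixed-area ROI
  m <- synchrony_matrix(dff, geom, area_px = area)
  expect_true(all(diag(m) == 1))
  expect_true(all(abs(m[!is.na(m)]) <= 1))
  ## bilaterally shared events at p_shared = 0.9 give high homotopic r
  ## (the fixture seed is chosen so midbrain events are present)
  expect_gt(sum(out$truth$region %in% c("MB_L", "MB_R")), 0)
  expect_gt(m["MB_L", "MB_R"], 0.5)
})
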