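test_that("DOG kernel is zero-sum across the calibration range", {
  p <- dog_params()
  for (px in c(40, 65, 100, 130, 200)) {
    k <- build_dog_kernel(p, px)
    expect_lt(abs(sum(k)), 1e-10)
  }
})

test_that("kernel matches pointwise-evaluated discrete Gaussians", {
  p <- dog_params()
  px <- 100
  k <- build_dog_kernel(p, px)
  r <- attr(k, "radius")
  expect_equal(r, ceiling(4 * 300 / px))
  g <- function(sigma_px) {
    x <- -r:r
    m <- exp(-outer(x^2, x^2, "+") / (2 * sigma_px^2))
    m / sum(m)
  }
  expect_equal(unclass(k), g(1.5) - g(3), ignore_attr = TRUE)
  # positive centre, negative annulus near 2-3 sigma_small
  expect_gt(k[r + 1, r + 1], 0)
  d_px <- round(2.5 * 1.5)
  expect_lt(k[r + 1, r + 1 + d_px], 0)
})

test_that("equal sigmas cancel to the all-zero kernel", {
  p <- structure(list(sigma_small_nm = 200, sigma_large_nm = 200,
                      truncation_sigmas = 4), class = "dog_params")
  k <- build_dog_kernel(p, 100, check = FALSE)
  expect_true(all(k == 0))
  expect_error(dog_params(300, 150), class = "vc_parameter_error")
  expect_error(build_dog_kernel(p, 100), class = "vc_parameter_error")
})

test_that("a flat image yields a null response at any level", {
  for (px in c(40, 100, 200)) {
    for (level in c(1, 1000)) {
      out <- dog_filter(matrix(level, 32, 32), dog_params(), px)
      expect_lt(max(abs(out)), 1e-9 * level)
    }
  }
})

test_that("filter output matches a dense convolution oracle", {
  set.seed(21)
  plane <- matrix(0, 32, 32)
  plane[16, 14] <- 7  # single bright pixel
  p <- dog_params()
  k <- build_dog_kernel(p, 100)
  out <- dog_filter(plane, p, 100)
  expect_equal(out, oracle_filter_reflect(plane, k), tolerance = 1e-9)
  expect_equal(out[16, 14], 7 * k[attr(k, "radius") + 1, attr(k, "radius") + 1])
  expect_equal(which.max(out), which.max(plane))
  # and on a noisy plane, including the reflected borders
  noisy <- matrix(runif(32 * 32, 0, 10), 32, 32)
  expect_equal(dog_filter(noisy, p, 100), oracle_filter_reflect(noisy, k),
               tolerance = 1e-8)
})

test_that("filtering is linear and shift-equivariant", {
  p <- dog_params()
  a <- matrix(0, 48, 48); a[20, 20] <- 3
  b <- matrix(0, 48, 48); b[30, 34] <- 5
  expect_equal(dog_filter(a + b, p, 100),
               dog_filter(a, p, 100) + dog_filter(b, p, 100),
               tolerance = 1e-10)
  shifted <- matrix(0, 48, 48); shifted[22, 21] <- 3
  out_a <- dog_filter(a, p, 100)
  out_s <- dog_filter(shifted, p, 100)
  # compare away from the reflected boundary
  expect_equal(out_s[15:35, 15:35], out_a[13:33, 14:34], tolerance = 1e-10)
})

test_that("global threshold binarizes strictly-above pixels and is monotone", {
  f <- matrix(c(-1, 2, 0.5, 0), 2, 2, byrow = TRUE)
  m <- global_threshold(f, 0, label = "cargo")
  expect_identical(m$values, matrix(c(0L, 1L, 1L, 0L), 2, 2, byrow = TRUE))
  expect_equal(m$threshold_used, 0)
  expect_true(all(global_threshold(f, max(f))$values == 0))
  expect_true(all(global_threshold(f, min(f) - 1)$values == 1))
  set.seed(31)
  g <- matrix(rnorm(400), 20, 20)
  thr <- sort(rnorm(10))
  sizes <- vapply(thr, function(t) sum(global_threshold(g, t)$values),
                  numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("otsu-positive lands between well-separated modes", {
  set.seed(41)
  low <- rnorm(300, 0.1, 0.01)
  high <- rnorm(300, 10, 0.5)
  f <- matrix(c(low, high, rnorm(424, -0.5, 0.2)), 32, 32)
  thr <- auto_threshold(f, "otsu-positive")
  # separates the two positive modes cleanly
  expect_true(all(low <= thr))
  expect_true(all(high > thr))
  expect_error(auto_threshold(matrix(-1, 4, 4), "otsu-positive"),
               class = "vc_degenerate_error")
})

test_that("quantile thresholds hit the extremes at q = 0 and 1", {
  f <- matrix(rnorm(100), 10, 10)
  expect_equal(auto_threshold(f, "quantile", q = 1), max(f))
  expect_equal(auto_threshold(f, "quantile", q = 0), min(f))
  expect_error(auto_threshold(f, "quantile"), class = "vc_parameter_error")
})

test_that("auto-thresholded masks recover puncta at SNR 10", {
  for (seed in c(101, 102, 103)) {
    sc <- simulate_scene(scene_spec(n_y = 256L, n_x = 256L, n_puncta = 25L,
                                    snr = 10, seed = seed))
    for (ch in c("cargo", "marker")) {
      f <- dog_filter(channel_plane(sc$stack, ch), dog_params(),
                      sc$spec$pixel_size_nm)
      m <- global_threshold(f, auto_threshold(f))
      truth <- sc$truth$puncta[[ch]]
      ds <- detection_stats(m, cbind(truth$y_px, truth$x_px), radius_px = 2)
      expect_gte(ds$recall, 0.95)
      expect_lt(ds$spurious, 0.05)
    }
  }
})
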