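test_that("touchdown is the first sample strictly above 20 N", {
  expect_identical(detect_touchdown(c(0, 5, 19, 21, 400)), 4L)
  # noisy flight bouncing to 19.9 N is not a touchdown
  vz <- c(rep(c(5, 19.9), 10), 25, 400)
  expect_identical(detect_touchdown(vz), 21L)
  expect_error(detect_touchdown(rep(5, 100)), "crossing")
  expect_error(detect_touchdown(rep(100, 10)), "crossing")
})

test_that("stance end follows the post-peak minimum into the body-weight band", {
  bw <- 700
  vz <- c(rep(5, 10),
          seq(25, 3 * bw, length.out = 30),          # impact rise
          seq(3 * bw, 0.6 * bw, length.out = 40)[-1], # decay to the dip
          seq(0.6 * bw, 800, length.out = 50)[-1])   # settle through the band
  td <- detect_touchdown(vz)
  expect_identical(td, 11L)
  got <- detect_stance_end(vz, td, bw)
  # independent oracle: scan for the dip, then the first in-band sample
  dip <- which(diff(sign(diff(vz))) > 0)[1L] + 1L
  expected <- which(vz >= 0.975 * bw & vz <= 1.025 * bw)
  expected <- expected[expected >= dip][1L]
  expect_identical(got, expected)
  expect_gte(vz[got], 0.975 * bw)
  expect_lte(vz[got], 1.025 * bw)

  # a sample already inside the band right after the minimum is returned
  vz2 <- c(rep(5, 5), 30, 2000, 1500, 690, 695, 700)
  expect_identical(detect_stance_end(vz2, detect_touchdown(vz2), bw), 9L)

  # monotone decay that never re-enters the band rejects the trial
  vz3 <- c(rep(5, 5), 30, 2000 * exp(-(1:50) / 5) + 750)
  expect_error(detect_stance_end(vz3, detect_touchdown(vz3), bw))
})

test_that("time normalization yields the 100+200-point cycle and preserves ramps", {
  vz <- c(rep(5, 310), seq(25, 2100, length.out = 30),
          seq(2100, 420, length.out = 40)[-1],
          seq(420, 700, length.out = 200)[-1])
  seg <- segment_landing(vz, bodyweight = 700)
  x <- matrix(seq_along(vz), nrow = 1L)       # linear ramp channel
  out <- time_normalize(x, seg)
  expect_identical(ncol(out), 300L)
  # affine signals are resampled exactly, each phase separately
  flight <- out[1L, 1:100]
  stance <- out[1L, 101:300]
  expect_equal(diff(range(diff(flight))), 0, tolerance = 1e-9)
  expect_equal(diff(range(diff(stance))), 0, tolerance = 1e-9)
  expect_equal(out[1L, 101L], seg$touchdown_index)  # touchdown at point 101
  expect_false(anyNA(out))
  expect_true(all(diff(out[1L, ]) > 0))
})

test_that("normalization handles the mean stance duration without artifacts", {
  # flight of 300 samples, stance of 491 samples
  vz <- c(rep(5, 300), 25, seq(30, 2000, length.out = 40),
          seq(2000, 450, length.out = 60)[-1],
          seq(450, 700, length.out = 391)[-1])
  seg <- segment_landing(vz, bodyweight = 700)
  out <- time_normalize(matrix(seq_along(vz), 1L), seg)
  expect_identical(ncol(out), 300L)
  expect_false(anyNA(out))
  expect_true(all(diff(out[1L, ]) > 0))
})

test_that("CoP ellipse area matches the bivariate-normal expectation", {
  set.seed(99)
  sigma <- 0.01
  pts <- matrix(rnorm(2e4, sd = sigma), ncol = 2L)
  a <- cop_ellipse_area(pts)
  expect_equal(a, pi * qchisq(0.95, 2) * sigma^2, tolerance = 0.05)
  # covariance scaling: coordinates x k scale the area by k^2
  expect_equal(cop_ellipse_area(3 * pts), 9 * a, tolerance = 1e-10)
  # degenerate cloud
  expect_warning(a0 <- cop_ellipse_area(matrix(1, 10, 2)), "degenerate")
  expect_identical(a0, 0)
})

test_that("moment scalars implement the rate and range definitions", {
  seg <- structure(list(touchdown_index = 101L, interval_start_index = 1L,
                        stance_end_index = 400L, stance_duration = 0.3,
                        rate = 1000), class = "landing_segmentation")
  moment <- rep(0, 400)
  moment[101:151] <- seq(0, 100, length.out = 51)   # peak 100 Nm, 50 ms in
  moment[152:400] <- seq(100, 0, length.out = 249)
  ms <- moment_scalars(moment, seg)
  expect_equal(ms$max, 100)
  expect_equal(ms$time_to_peak, 0.05)
  expect_equal(ms$rate, 2000)
  expect_true(ms$rate_defined)

  expect_warning(msc <- moment_scalars(rep(7, 400), seg), "undefined")
  expect_false(msc$rate_defined)
  expect_true(is.na(msc$rate))

  angle <- rep(30, 400)                    # minimum equals touchdown angle
  ms2 <- moment_scalars(moment, seg, angle = angle)
  expect_equal(ms2$range_of_motion, 0)
  angle2 <- angle; angle2[200:250] <- 10
  ms3 <- moment_scalars(moment, seg, angle = angle2)
  expect_equal(ms3$range_of_motion, 20)
})
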