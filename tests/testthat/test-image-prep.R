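# Timepix expansion, gain estimation, spot finding, distortion maps and the
# rotation-axis azimuth heuristic.

test_that("timepix expansion splits boundary pixels and normalises gain", {
  set.seed(21)
  raw <- matrix(stats::rpois(512 * 512, 7), 512, 512)
  out <- timepix_expand(raw)
  expect_equal(dim(out$frame), c(516, 516))
  # six-pixel-wide cross along each axis
  expect_equal(sum(out$cross_mask[, 1]), 6)
  expect_equal(sum(out$cross_mask[10, ]), 6)
  expect_equal(out$gain, 3.0)
  # all-ones frame: cross pixels 1, others 3
  ones <- timepix_expand(matrix(1L, 512, 512))$frame
  expect_true(all(ones[out$cross_mask] == 1))
  expect_true(all(ones[!out$cross_mask] == 3))
  # integer-exact: non-cross pixels are exactly 3x their source values,
  # cross rows/columns replicate source values exactly
  expect_identical(out$frame[1:255, 1:255], raw[1:255, 1:255] * 3L)
  expect_identical(out$frame[262:516, 1:255], raw[258:512, 1:255] * 3L)
  expect_identical(out$frame[256, 262:516], raw[256, 258:512])
  expect_identical(out$frame[257, 1:255], raw[256, 1:255])
  expect_identical(out$frame[259, 300], raw[257, 296])
  expect_error(timepix_expand(matrix(0, 100, 100)), "512")
})

test_that("gain estimation recovers Poisson and scaled-Poisson statistics", {
  set.seed(31)
  frame <- matrix(stats::rpois(1e4, 50), 100, 100)
  expect_equal(estimate_gain(frame, c(1, 100, 1, 100)), 1.0, tolerance = 0.05)
  expect_equal(estimate_gain(frame * 3L, c(1, 100, 1, 100)), 3.0,
               tolerance = 0.15 / 3)
  expect_warning(g0 <- estimate_gain(matrix(5, 20, 20), c(1, 20, 1, 20)),
                 "constant")
  expect_equal(g0, 0)
  expect_error(estimate_gain(frame, c(10, 5, 1, 10)), "invalid")
  expect_error(estimate_gain(matrix(0, 10, 10), c(1, 10, 1, 10)), "gain")
})

test_that("dispersion spot finder recovers planted spots exactly", {
  ps <- planted_spot_frame()
  spots <- dispersion_find_spots(ps$frame, gain = 1, sigma_strong = 3)
  centres <- ps$centres
  d <- sapply(seq_len(nrow(centres)), function(i)
    min(sqrt((spots$x - centres$x[i])^2 + (spots$y - centres$y[i])^2)))
  expect_equal(nrow(spots), nrow(centres))       # no false positives
  expect_true(all(d < 0.5))                      # all 25 recovered, < 0.5 px
  expect_true(all(spots$n_pixels >= 2))
  expect_true(all(spots$x > spots$x0 & spots$x < spots$x1 &
                  spots$y > spots$y0 & spots$y < spots$y1))

  # all-zero frame finds nothing
  expect_equal(nrow(dispersion_find_spots(matrix(0L, 64, 64))), 0)
  # fully masked frame finds nothing
  expect_equal(nrow(dispersion_find_spots(ps$frame,
                                          mask = matrix(TRUE, 256, 256))), 0)
  # raising the gain parameter never increases the strong-pixel count
  n_strong <- sapply(c(0.5, 1, 2, 4), function(g)
    sum(dispersion_find_spots(ps$frame, gain = g, sigma_strong = 3)$n_pixels))
  expect_true(all(diff(n_strong) <= 0))
  expect_error(dispersion_find_spots(ps$frame, kernel = 4), "odd")
})

test_that("spot finder is translation-equivariant away from borders", {
  ps <- planted_spot_frame(seed = 8, n = 128)
  s0 <- dispersion_find_spots(ps$frame, gain = 1, sigma_strong = 3)
  dx <- 7L; dy <- 11L
  shifted <- matrix(5L, 128 + dx, 128 + dy)
  set.seed(99)
  shifted[] <- stats::rpois(length(shifted), 5)
  shifted[(dx + 1):(128 + dx), (dy + 1):(128 + dy)] <- ps$frame
  s1 <- dispersion_find_spots(shifted, gain = 1, sigma_strong = 3)
  for (i in seq_len(nrow(s0))) {
    d <- sqrt((s1$x - (s0$x[i] + dx))^2 + (s1$y - (s0$y[i] + dy))^2)
    expect_lt(min(d), 0.35)
  }
})

test_that("elliptical distortion maps follow the closed-form ellipse model", {
  pan <- panel_model(c(-10, -10, 100), c(1, 0, 0), c(0, 1, 0),
                     c(0.1, 0.1), c(200, 200))
  # unit scales: identically zero maps
  m0 <- generate_elliptical_distortion_maps(pan, c(100, 100), 1, 1, 17)
  expect_equal(max(abs(m0$offset_fast)), 0)
  expect_equal(max(abs(m0$offset_slow)), 0)
  # isotropic scale s: offset magnitude |1 - 1/s| r
  s <- 1.03
  mi <- generate_elliptical_distortion_maps(pan, c(100, 100), s, s, 0)
  px <- matrix(seq_len(200) - 0.5, 200, 200)
  py <- t(px)
  r <- sqrt((px - 100)^2 + (py - 100)^2)
  mag <- sqrt(mi$offset_fast^2 + mi$offset_slow^2)
  expect_lt(max(abs(mag - abs(1 - 1 / s) * r)), 1e-9)
  # points on the minor axis are unmoved when scale_minor = 1; put the
  # centre on a pixel centre so the axis passes through pixel centres
  mm <- generate_elliptical_distortion_maps(pan, c(100.5, 100.5), 1.05, 1, 0)
  expect_lt(max(abs(mm$offset_fast[101, ])), 1e-9)  # minor axis: x = 100.5
  expect_lt(max(abs(mm$offset_slow[101, ])), 1e-9)
  expect_error(generate_elliptical_distortion_maps(pan, c(0, 0), -1, 1), "invalid")
})

test_that("pixel/mm transforms honour the distortion application order", {
  pan <- panel_model(c(-10, -10, 100), c(1, 0, 0), c(0, 1, 0),
                     c(0.1, 0.1), c(200, 200))
  # zero maps: exact linear transform
  expect_equal(px_to_mm(pan, 40, 60), list(fast = 4.0, slow = 6.0))
  expect_equal(mm_to_px(pan, 4.0, 6.0), list(x = 40, y = 60))
  # constant +2 px fast offset: px_to_mm removes it before scaling
  pan2 <- pan
  pan2$distortion <- distortion_map_pair(matrix(2, 200, 200),
                                         matrix(0, 200, 200))
  expect_equal(px_to_mm(pan2, 40, 60)$fast, (40 - 2) * 0.1)
  expect_equal(mm_to_px(pan2, 3.8, 6.0)$x, 40)
  # smooth elliptical maps: round trip within one quantisation step
  pan3 <- pan
  pan3$distortion <- generate_elliptical_distortion_maps(pan, c(100, 100),
                                                         1.02, 0.99, 30)
  set.seed(14)
  X <- stats::runif(1e4, 2, 198); Y <- stats::runif(1e4, 2, 198)
  mm <- px_to_mm(pan3, X, Y)
  back <- mm_to_px(pan3, mm$fast, mm$slow)
  expect_lt(max(abs(back$x - X)), 1.01)
  expect_lt(max(abs(back$y - Y)), 1.01)
  expect_error(px_to_mm(pan, 300, 0), "out_of_range")
  expect_error(distortion_map_pair(matrix(0, 2, 2), matrix(0, 3, 3)), "share")
})

test_that("axis azimuth estimation finds the depleted direction", {
  set.seed(7)
  ang <- stats::runif(6000, 0, 360)
  keep <- abs(((ang %% 180) - 70)) > 5 & abs(((ang %% 180) - 70)) < 175
  r <- stats::runif(sum(keep), 20, 100)
  spots <- data.frame(x = 200 + r * cos(ang[keep] * pi / 180),
                      y = 150 + r * sin(ang[keep] * pi / 180))
  az <- estimate_axis_azimuth(spots, c(200, 150))
  expect_lt(min(abs(c(as.numeric(az) - 70, as.numeric(az) - 70 + 180,
                      as.numeric(az) - 70 - 180))), 5)
  expect_equal(attr(az, "confidence"), "ok")
  # rotating all spots rotates the answer (mod 180)
  th <- 40 * pi / 180
  rot <- data.frame(x = 200 + cos(th) * (spots$x - 200) - sin(th) * (spots$y - 150),
                    y = 150 + sin(th) * (spots$x - 200) + cos(th) * (spots$y - 150))
  az2 <- estimate_axis_azimuth(rot, c(200, 150))
  dd <- (as.numeric(az2) - as.numeric(az) - 40) %% 180
  expect_lt(min(dd, 180 - dd), 5 + 1e-9)
  # perfectly uniform field: low confidence
  u <- seq(0, 2 * pi, length.out = 721)[-1]
  uni <- data.frame(x = 200 + 50 * cos(u), y = 150 + 50 * sin(u))
  expect_warning(az3 <- estimate_axis_azimuth(uni, c(200, 150)), "low-confidence")
  expect_equal(attr(az3, "confidence"), "low")
})
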