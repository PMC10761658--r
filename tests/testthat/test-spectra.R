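# Spectral-image handling: file dialect round trips, energy-window
# extraction under the half-open bin convention, uniformity correction,
# automatic ROIs and ROI count rates.

test_that("energy windows validate bounds and the bin grid", {
  w <- energy_window("main", 100.5, 120.8)
  expect_s3_class(w, "energy_window")
  expect_error(energy_window("bad", 120.8, 100.5), "lo < hi")
  expect_error(energy_window("bad", -1, 10), "lo < hi|0 <=")
  expect_error(energy_window("bad", 100.55, 120.8), "0.1 keV")
})

test_that("the default Lu-177 window set matches the camera's window table", {
  ws <- lu177_windows()
  m113 <- ws[["113"]]$main
  expect_equal(c(m113$lo, m113$hi), c(100.5, 120.8))
  expect_equal(c(ws[["55"]]$main$lo, ws[["55"]]$main$hi), c(49.7, 59.7))
  expect_equal(c(ws[["208"]]$main$lo, ws[["208"]]$main$hi), c(193.8, 216.7))
  # scatter windows abut the main window exactly
  for (nm in names(ws)) {
    expect_equal(ws[[nm]]$lower_scatter$hi, ws[[nm]]$main$lo)
    expect_equal(ws[[nm]]$main$hi, ws[[nm]]$upper_scatter$lo)
  }
  # YAML round trip
  f <- withr::local_tempfile(fileext = ".yaml")
  write_window_set(ws, f)
  ws2 <- read_window_set(f)
  expect_equal(ws2[["113"]]$main$lo, 100.5)
  expect_equal(ws2[["208"]]$upper_scatter$hi, 224.0)
})

test_that("spectral images validate shape, counts and duration", {
  expect_error(spectral_image(array(0L, c(8, 8, 2500)), 10), "16 x 16 x 2500")
  bad <- empty_cube(); bad[1, 1, 1] <- -1L
  expect_error(spectral_image(bad, 10), "non-negative")
  expect_error(spectral_image(empty_cube(), 0), "positive")
  cube <- empty_cube(); cube[1, 1, 1131] <- 1L
  img <- spectral_image(cube, 10)
  expect_equal(sum(img$counts), 1L)
})

test_that("the CSV dialect round-trips a spectral image bit-identically", {
  cube <- random_cube(800, seed = 3)
  img <- spectral_image(cube, duration = 42.5, collimator = "LEHR",
                        radionuclide = "Lu-177")
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectral_image(img, f)
  img2 <- read_spectral_image(f)
  expect_identical(img2$counts, img$counts)
  expect_equal(img2$duration, 42.5)
  expect_equal(img2$collimator, "LEHR")
  expect_error(read_spectral_image(tempfile(fileext = ".csv")), "not found")
})

test_that("an optional global energy shift moves counts by whole bins", {
  cube <- empty_cube(); cube[4, 4, bin_at(113.0)] <- 7L
  img <- spectral_image(cube, 10)
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectral_image(img, f)
  shifted <- read_spectral_image(f, energy_shift_bins = 5L)
  expect_equal(shifted$counts[4, 4, bin_at(113.5)], 7L)
  expect_equal(sum(shifted$counts), 7L)
  # shifting off the grid drops counts
  edge <- empty_cube(); edge[1, 1, 2500] <- 3L
  img_e <- spectral_image(edge, 10)
  write_spectral_image(img_e, f)
  expect_equal(sum(read_spectral_image(f, energy_shift_bins = 1L)$counts), 0L)
})

test_that("window extraction follows the half-open [lo, hi) convention", {
  ws <- lu177_windows()
  cube <- empty_cube()
  cube[, , bin_at(113.0)] <- 2L        # inside the 113 main window
  img <- spectral_image(cube, 10)
  wi <- extract_window_image(img, ws[["113"]]$main)
  expect_equal(sum(wi$values), 2 * 256)

  cube2 <- empty_cube()
  cube2[, , bin_at(120.8)] <- 1L       # bin starting exactly at the upper edge
  img2 <- spectral_image(cube2, 10)
  expect_equal(sum(extract_window_image(img2, ws[["113"]]$main)$values), 0)
  expect_equal(sum(extract_window_image(img2, ws[["113"]]$upper_scatter)$values),
               256)
})

test_that("window extraction equals a brute-force per-pixel bin loop", {
  cube <- random_cube(2000, seed = 11)
  img <- spectral_image(cube, 30)
  w <- energy_window("test", 40.0, 75.3)
  wi <- extract_window_image(img, w)
  brute <- matrix(0, 16, 16)
  for (r in 1:16) for (cc in 1:16) for (b in 1:2500) {
    e <- 0.1 * (b - 1)
    if (e >= w$lo - 1e-9 && e + 0.1 <= w$hi + 1e-9)
      brute[r, cc] <- brute[r, cc] + cube[r, cc, b]
  }
  expect_equal(wi$values, brute)
})

test_that("abutting windows of one photopeak conserve counts", {
  ws <- lu177_windows()
  cube <- random_cube(3000, seed = 5)
  img <- spectral_image(cube, 10)
  for (nm in names(ws)) {
    p <- ws[[nm]]
    parts <- sum(extract_window_image(img, p$lower_scatter)$values) +
      sum(extract_window_image(img, p$main)$values) +
      sum(extract_window_image(img, p$upper_scatter)$values)
    enclosing <- energy_window("enclosing", p$lower_scatter$lo,
                               p$upper_scatter$hi)
    expect_equal(parts, sum(extract_window_image(img, enclosing)$values))
  }
})

test_that("uniformity correction is the element-wise product with scaled variance", {
  cube <- random_cube(1000, seed = 2)
  img <- spectral_image(cube, 20)
  wi <- extract_window_image(img, energy_window("w", 100.0, 130.0))
  expect_equal(apply_uniformity(wi, matrix(1, 16, 16))$values, wi$values)
  doubled <- apply_uniformity(wi, matrix(2, 16, 16))
  expect_equal(sum(doubled$values), 2 * sum(wi$values))
  expect_equal(doubled$var, 4 * wi$var)
  set.seed(8)
  corr <- matrix(runif(256, 0.5, 1.5), 16, 16)
  expect_equal(apply_uniformity(wi, corr)$values, wi$values * corr)
  bad <- corr; bad[3, 3] <- 0
  expect_error(apply_uniformity(wi, bad), "strictly positive")
})

test_that("constant uniformity correction commutes with window extraction", {
  cube <- random_cube(1500, seed = 9)
  img <- spectral_image(cube, 10)
  w <- energy_window("w", 50.0, 60.0)
  a <- apply_uniformity(extract_window_image(img, w), matrix(1.7, 16, 16))
  # scaling every bin first, then extracting, must give the same image
  scaled_vals <- extract_window_image(img, w)$values * 1.7
  expect_equal(a$values, scaled_vals)
})

test_that("auto_roi centers at the count-weighted centre of mass", {
  mk <- function(vals) structure(list(values = vals, var = vals,
                                      window = energy_window("w", 100, 121),
                                      duration = 10), class = "window_image")
  hot <- matrix(0, 16, 16); hot[8, 8] <- 100
  roi <- auto_roi(mk(hot), source_radius_mm = 10, fwhm_mm = 8)
  expect_equal(roi$center, c(8, 8))
  expect_equal(roi$radius_mm, 14)

  sym <- matrix(0, 16, 16); sym[4, 8] <- 50; sym[12, 8] <- 50
  expect_equal(auto_roi(mk(sym), 10, 8)$center, c(8, 8))

  set.seed(4)
  rnd <- matrix(rpois(256, 3), 16, 16)
  roi_r <- auto_roi(mk(rnd), 5, 6)
  rr <- matrix(1:16, 16, 16); cc <- t(rr)
  expect_equal(roi_r$center,
               c(sum(rr * rnd), sum(cc * rnd)) / sum(rnd))

  expect_error(auto_roi(mk(matrix(0, 16, 16)), 10, 8), "no counts")
})

test_that("auto_roi center is translation-equivariant away from edges", {
  mk <- function(vals) structure(list(values = vals, var = vals,
                                      window = energy_window("w", 100, 121),
                                      duration = 10), class = "window_image")
  set.seed(6)
  blob <- matrix(0, 16, 16)
  blob[5:8, 5:8] <- rpois(16, 20)
  c1 <- auto_roi(mk(blob), 5, 5)$center
  shifted <- matrix(0, 16, 16)
  shifted[8:11, 7:10] <- blob[5:8, 5:8]
  c2 <- auto_roi(mk(shifted), 5, 5)$center
  expect_equal(c2, c1 + c(3, 2))
})

test_that("ROI count rates match brute-force membership and conserve totals", {
  cube <- random_cube(1000, seed = 13)
  img <- spectral_image(cube, 100)
  wi <- extract_window_image(img, energy_window("all", 0, 250))
  # full-detector mask recovers every count
  full <- roi_count_rate(wi, roi_mask(matrix(TRUE, 16, 16)))
  expect_equal(full$rate * 100, sum(cube))
  expect_equal(full$variance, sum(cube) / 100^2)
  # wide circle covers the whole grid too
  wide <- roi_count_rate(wi, roi_circle(c(8.5, 8.5), radius_mm = 100))
  expect_equal(wide$rate, full$rate)
  # a circle in an empty corner has zero rate
  empty_corner <- empty_cube(); empty_corner[16, 16, 5] <- 9L
  wi2 <- extract_window_image(spectral_image(empty_corner, 10),
                              energy_window("all", 0, 250))
  expect_equal(roi_count_rate(wi2, roi_circle(c(2, 2), 2.46))$rate, 0)
  # random circle equals explicit membership loop
  set.seed(21)
  for (i in 1:5) {
    ctr <- runif(2, 3, 14); rad <- runif(1, 3, 20)
    roi <- roi_circle(ctr, rad)
    got <- roi_count_rate(wi, roi)
    acc <- 0
    for (r in 1:16) for (cc in 1:16)
      if (2.46 * sqrt((r - ctr[1])^2 + (cc - ctr[2])^2) <= rad)
        acc <- acc + wi$values[r, cc]
    expect_equal(got$rate, acc / 100)
  }
  expect_error(roi_count_rate(wi, roi_circle(c(-20, -20), 2)), "no pixels")
})
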