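test_that("16-bit PNG slices round-trip pixel-identically", {
  set.seed(11)
  px <- matrix(sample(0:65535, 40 * 56, replace = TRUE), 40, 56)
  sl <- ct_slice(px, spacing_mm = 2.5, index = 4L)
  f <- withr::local_tempfile(fileext = ".png")
  write_slice(sl, f)
  back <- read_slice(f, spacing_mm = 2.5, index = 4L)
  expect_identical(back$pixels, sl$pixels)
  expect_equal(back$spacing_mm, 2.5)
  expect_lte(max(back$pixels), 65535)
})

test_that("multi-channel and low-bit-depth PNGs are rejected with clear errors", {
  f_rgb <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(runif(16 * 16 * 3), c(16, 16, 3)), f_rgb)
  expect_error(read_slice(f_rgb, 1), "3 channels")
  f8 <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(runif(16 * 16), 16, 16), f8)
  expect_error(read_slice(f8, 1), "bit depth 8")
  expect_error(read_slice(tempfile(), 1), "no such file")
})

test_that("ct_slice validates its invariants", {
  expect_error(ct_slice(matrix(-1, 4, 4), 1), "non-negative")
  expect_error(ct_slice(matrix(1, 4, 4), 0), "positive")
  expect_error(ct_slice(1:4, 1), "matrix")
})

test_that("MaxIntensity divides by the 4095 ceiling and clips above it", {
  sl <- ct_slice(matrix(c(0, 4095, 8190, 1000), 2, 2), 1)
  out <- max_intensity_norm(sl)
  expect_equal(out[1, 1], 0)
  expect_equal(out[2, 1], 1)       # 4095 -> exactly 1
  expect_equal(out[1, 2], 1)       # 8190 clipped after division
  expect_equal(out[2, 2], 1000 / 4095)
})

test_that("MaxIntensity is linear below the ceiling", {
  set.seed(2)
  a <- matrix(sample(0:2000, 64, replace = TRUE), 8, 8)
  b <- matrix(sample(0:2000, 64, replace = TRUE), 8, 8)
  na <- max_intensity_norm(ct_slice(a, 1))
  nb <- max_intensity_norm(ct_slice(b, 1))
  nab <- max_intensity_norm(ct_slice(a + b, 1))
  expect_equal(na + nb, nab, tolerance = 1e-12)
})

test_that("MaxMinNorm spans [0, 1] on every non-constant slice", {
  sl <- ct_slice(matrix(c(0, 50, 100, 50), 2, 2), 1)
  expect_equal(sort(unique(c(max_min_norm(sl)))), c(0, 0.5, 1))
  set.seed(3)
  for (i in 1:100) {
    px <- matrix(sample(0:4095, 64, replace = TRUE), 8, 8)
    if (max(px) == min(px)) px[1, 1] <- px[1, 1] + 1
    out <- max_min_norm(ct_slice(px, 1))
    expect_equal(min(out), 0)
    expect_equal(max(out), 1)
  }
})

test_that("constant slices cannot be min-max normalized", {
  expect_error(max_min_norm(ct_slice(matrix(7, 4, 4), 1, index = 9L)),
               "index 9")
})

test_that("window count is N - L + 1 with center labels", {
  mk_vol <- function(n) {
    lapply(seq_len(n) - 1L, function(i) {
      ct_slice(matrix(i, 8, 8), spacing_mm = 2, index = i)
    })
  }
  vol <- mk_vol(10)
  labels <- rep(1L, 10)
  labels[c(3, 8)] <- c(0L, 2L)
  w <- make_windows(vol, labels, 5L)
  expect_length(w, 6)
  expect_equal(vapply(w, function(x) x$center_index, integer(1)), 2:7)
  expect_equal(vapply(w, function(x) x$label, integer(1)),
               labels[3:8])
  expect_length(make_windows(mk_vol(5), rep(1L, 5), 5L), 1)
  expect_error(make_windows(mk_vol(3), rep(1L, 3), 5L), "3 slices")
  expect_error(make_windows(mk_vol(8), rep(1L, 8), 4L), "3, 5 or 7")
  for (L in c(3L, 5L, 7L)) {
    for (n in seq(L, 30L, by = 6L)) {
      expect_length(make_windows(mk_vol(n), rep(1L, n), L), n - L + 1)
    }
  }
})

test_that("one-hot labels have a single 1 in the right position", {
  oh <- label_onehot(c(0L, 1L, 2L))
  expect_equal(oh, rbind(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L)))
  expect_error(label_onehot(3L), "0")
})

test_that("polygon masks rasterize like the scalar even-odd oracle", {
  sq <- cbind(c(10, 20, 20, 10), c(10, 10, 20, 20))
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    list(tissue = "SAT", polygons = list(apply(sq, 1, as.list))),
    f, auto_unbox = TRUE)
  mask <- read_mask_labels(f, c(64, 64))
  expect_equal(strip_attrs(mask), rasterize_oracle(list(sq), c(64, 64)))
  expect_equal(attr(mask, "tissue"), "SAT")
  # non-convex polygon against the oracle
  set.seed(8)
  ang <- sort(runif(7, 0, 2 * pi))
  rad <- runif(7, 4, 14)
  poly <- cbind(round(16 + rad * cos(ang), 2),
                round(16 + rad * sin(ang), 2))
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    list(tissue = "VAT", polygons = list(apply(poly, 1, as.list))),
    f2, auto_unbox = TRUE)
  expect_equal(strip_attrs(read_mask_labels(f2, c(32, 32))),
               rasterize_oracle(list(poly), c(32, 32)))
})

test_that("rasterization agrees with mgcv's point-in-polygon test", {
  skip_if_not_installed("mgcv")
  poly <- cbind(c(3.2, 24.7, 27.1, 12.5), c(4.1, 6.3, 25.2, 27.8))
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    list(tissue = "SAT", polygons = list(apply(poly, 1, as.list))),
    f, auto_unbox = TRUE)
  mask <- strip_attrs(read_mask_labels(f, c(32, 32)))
  pts <- cbind(rep(0:31, each = 32), rep(0:31, times = 32)) # (x, y)
  ref <- mgcv::in.out(rbind(poly, poly[1, ]), pts)
  ref_mask <- matrix(0L, 32, 32)
  ref_mask[cbind(pts[, 2] + 1L, pts[, 1] + 1L)] <- as.integer(ref)
  expect_equal(mask, ref_mask)
})

test_that("empty polygon lists and out-of-bounds vertices are handled", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"tissue": "VAT", "polygons": []}', f)
  expect_equal(sum(read_mask_labels(f, c(16, 16))), 0)
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    list(tissue = "SAT",
         polygons = list(list(list(700, 10), list(10, 10), list(10, 20)))),
    f2, auto_unbox = TRUE)
  expect_error(read_mask_labels(f2, c(512, 512)), "bounds")
  f3 <- withr::local_tempfile(fileext = ".json")
  writeLines('{"tissue": "SAT"}', f3)
  expect_error(read_mask_labels(f3, c(16, 16)), "malformed")
})

test_that("localization label CSVs round-trip", {
  labels <- c(1L, 0L, 1L, 1L, 2L, 1L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_loc_labels(labels, f)
  expect_identical(read_loc_labels(f), labels)
})
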