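test_that("phantom spec enforces its invariants", {
  expect_error(phantom_spec(n_slices = 5), ">= 7")
  expect_error(phantom_spec(image_size = 16), ">= 32")
  expect_error(phantom_spec(lung_first = 0), "lung_first")
  expect_error(phantom_spec(lung_first = 8, lung_last = 8), "lung_first")
  expect_error(phantom_spec(n_slices = 10, lung_last = 9), "lung_first")
  expect_error(phantom_spec(noise_sd = -1), "non-negative")
})

test_that("volumes are bit-exact reproductions of their seed", {
  sp <- phantom_spec(n_slices = 8L, image_size = 32L, lung_first = 2L,
                     lung_last = 5L, seed = 7L)
  v1 <- generate_volume(sp)
  v2 <- generate_volume(sp)
  expect_identical(v1, v2)
  sp2 <- phantom_spec(n_slices = 8L, image_size = 32L, lung_first = 2L,
                      lung_last = 5L, seed = 8L)
  v3 <- generate_volume(sp2)
  expect_false(identical(v1$slices[[1]]$pixels, v3$slices[[1]]$pixels))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  generate_volume(phantom_spec(seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("labels mark exactly one first and one last lung slice", {
  v <- generate_volume(phantom_spec(n_slices = 12L, image_size = 32L,
                                    lung_first = 3L, lung_last = 8L,
                                    seed = 1L))
  expect_equal(sum(v$loc_labels == 0L), 1)
  expect_equal(sum(v$loc_labels == 2L), 1)
  expect_equal(sum(v$loc_labels == 1L), 10)
  expect_equal(which(v$loc_labels == 0L) - 1L, 3L)
  expect_equal(which(v$loc_labels == 2L) - 1L, 8L)
})

test_that("SAT and VAT masks are disjoint and inside the body", {
  v <- fixture_volume()
  for (i in seq_along(v$slices)) {
    expect_equal(sum(v$sat_masks[[i]] * v$vat_masks[[i]]), 0)
  }
  # fat pixels carry the fat intensity band (noise-free volume)
  v0 <- generate_volume(phantom_spec(n_slices = 8L, image_size = 32L,
                                     lung_first = 2L, lung_last = 5L,
                                     noise_sd = 0, seed = 3L))
  sat_px <- v0$slices[[1]]$pixels[v0$sat_masks[[1]] == 1]
  expect_true(all(sat_px >= 1400 & sat_px <= 1800))
  lung_px <- v0$slices[[4]]$pixels[v0$slices[[4]]$pixels < 1000 &
                                     v0$slices[[4]]$pixels > 100]
  expect_true(all(lung_px < 400))
})

test_that("lung area is unimodal along the body axis", {
  v0 <- generate_volume(phantom_spec(n_slices = 14L, image_size = 64L,
                                     lung_first = 3L, lung_last = 10L,
                                     noise_sd = 0, seed = 9L))
  areas <- vapply(v0$slices, function(s) {
    sum(s$pixels >= 100 & s$pixels < 400)
  }, numeric(1))
  expect_true(all(areas[1:3] == 0))
  expect_true(all(areas[12:14] == 0))
  lung_areas <- areas[4:11]
  expect_true(all(lung_areas > 0))
  d <- diff(lung_areas)
  peak <- which.max(lung_areas)
  expect_true(all(d[seq_len(peak - 1)] >= 0))
  expect_true(all(d[seq(peak, length(d))] <= 0))
})

test_that("export writes the documented dialects and re-imports faithfully", {
  v <- fixture_volume()
  dir <- withr::local_tempdir()
  manifest <- export_dataset(v, dir)
  expect_length(readLines(manifest), length(v$slices) * 3 + 1)
  back <- import_dataset(dir, spacing_mm = v$spec$spacing_mm)
  expect_identical(back$loc_labels, v$loc_labels)
  for (i in seq_along(v$slices)) {
    expect_identical(back$slices[[i]]$pixels, v$slices[[i]]$pixels)
    for (kind in c("sat_masks", "vat_masks")) {
      a <- v[[kind]][[i]]
      b <- back[[kind]][[i]]
      if (sum(a) + sum(b) == 0) next
      expect_gte(classical_dice_oracle(a, b), 0.99)
    }
  }
})

test_that("empty masks export as empty polygon lists", {
  v <- fixture_volume()
  # slice 0 has no lungs; force an empty VAT mask and export it
  v$vat_masks[[1]][] <- 0L
  dir <- withr::local_tempdir()
  export_dataset(v, dir)
  obj <- jsonlite::fromJSON(file.path(dir, "vat_000.json"),
                            simplifyVector = FALSE)
  expect_length(obj$polygons, 0)
})

test_that("batches vary lung position but are seed-reproducible", {
  b1 <- generate_phantom_batch(3, n_slices = 10L, image_size = 32L,
                               seed = 5L)
  b2 <- generate_phantom_batch(3, n_slices = 10L, image_size = 32L,
                               seed = 5L)
  expect_identical(b1, b2)
  fls <- vapply(b1, function(v) which(v$loc_labels == 0L), integer(1))
  lls <- vapply(b1, function(v) which(v$loc_labels == 2L), integer(1))
  expect_true(all(fls < lls))
})
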