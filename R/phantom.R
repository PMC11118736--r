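# Synthetic chest-CT phantom volumes with known SAT/VAT masks and
# localization labels. The phantom reproduces the class topology the two
# networks rely on -- an elliptical body, a subcutaneous fat ring just inside
# the body contour, paired lung fields whose area grows then shrinks along
# the body axis, and irregular visceral fat blobs around the mediastinum --
# without attempting anatomical realism (no ribs, vessels or pathology).
#
# Intensity bands on the [0, 4095] scale follow the CT ordering
# air < lung < fat < soft tissue:
#   background 0-100, lung interior 100-400, fat 1400-1800,
#   soft tissue 2200-2800, Gaussian noise sd 50 by default.
# Absolute values are arbitrary because both normalizations are scale-free.

PHANTOM_BANDS <- list(
  background = 50, lung = 250, fat = 1600, body = 2500
)

#' Phantom volume specification
#'
#' @param n_slices Number of axial slices (>= 7).
#' @param image_size Square image side in pixels (>= 32). 64 keeps CPU
#'   training fast; 512 matches clinical resolution for integration runs.
#' @param lung_first 0-based index of the first lung-bearing slice.
#' @param lung_last 0-based index of the last lung-bearing slice; must
#'   satisfy `0 < lung_first < lung_last < n_slices - 1`.
#' @param spacing_mm Inter-slice distance in millimetres.
#' @param noise_sd Standard deviation of additive Gaussian intensity noise.
#' @param seed Integer seed; the volume is a deterministic function of it.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(n_slices = 14L, image_size = 64L, lung_first = 3L,
                         lung_last = 10L, spacing_mm = 2.5, noise_sd = 50,
                         seed = 1L) {
  n_slices <- as.integer(n_slices)
  image_size <- as.integer(image_size)
  lung_first <- as.integer(lung_first)
  lung_last <- as.integer(lung_last)
  if (n_slices < 7L) stop("n_slices must be >= 7")
  if (image_size < 32L) stop("image_size must be >= 32")
  if (!(0L < lung_first && lung_first < lung_last &&
        lung_last < n_slices - 1L)) {
    stop("need 0 < lung_first < lung_last < n_slices - 1")
  }
  if (spacing_mm <= 0) stop("spacing_mm must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(
    list(n_slices = n_slices, image_size = image_size,
         lung_first = lung_first, lung_last = lung_last,
         spacing_mm = spacing_mm, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's stream afterwards (no global state leaks).
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate one phantom volume
#'
#' Deterministic given `spec$seed`. Slices outside
#' `[lung_first, lung_last]` show only body, subcutaneous fat ring and
#' background; inside the range, two low-intensity lung fields appear whose
#' area follows a unimodal apex-to-base-to-apex profile. Visceral fat blobs
#' (2-6 per slice) are placed around the mediastinum, disjoint from the
#' subcutaneous ring. Intensities are quantized to integers in `[0, 4095]`.
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom_volume` with fields `slices` (list of [ct_slice()]),
#'   `loc_labels` (0/1/2 per slice), `sat_masks`, `vat_masks`, `spec`.
#' @export
generate_volume <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    S <- spec$image_size
    n <- spec$n_slices
    cx <- S / 2 + stats::runif(1, -0.02, 0.02) * S
    cy <- S / 2 + stats::runif(1, -0.02, 0.02) * S
    a <- S * stats::runif(1, 0.40, 0.45) # body semi-axis along x (columns)
    b <- S * stats::runif(1, 0.32, 0.37) # along y (rows)
    # smoothly varying subcutaneous ring thickness around the perimeter
    ring_base <- stats::runif(1, 0.10, 0.14)
    ring_amp <- stats::runif(1, 0.02, 0.04)
    ring_phase <- stats::runif(1, 0, 2 * pi)
    xs <- matrix(rep(0:(S - 1L), each = S), S, S) # column index (x)
    ys <- matrix(rep(0:(S - 1L), times = S), S, S) # row index (y)
    rho <- sqrt(((xs - cx) / a)^2 + ((ys - cy) / b)^2)
    theta <- atan2(ys - cy, xs - cx)
    thick <- ring_base + ring_amp * sin(theta + ring_phase) +
      0.5 * ring_amp * sin(2 * theta)
    body <- rho <= 1
    sat <- body & (rho >= 1 - thick) & (rho <= 0.97)
    lung_off <- stats::runif(1, 0.38, 0.46) # lung center offset from midline
    slices <- vector("list", n)
    sat_masks <- vector("list", n)
    vat_masks <- vector("list", n)
    n_lung <- spec$lung_last - spec$lung_first + 1L
    for (i in seq_len(n) - 1L) {
      img <- matrix(PHANTOM_BANDS$background, S, S)
      img[body] <- PHANTOM_BANDS$body
      img[sat] <- PHANTOM_BANDS$fat
      lung <- matrix(FALSE, S, S)
      if (i >= spec$lung_first && i <= spec$lung_last) {
        # unimodal area profile along the axis (apex -> base -> apex)
        frac <- sin(pi * (i - spec$lung_first + 0.5) / n_lung)
        sc <- sqrt(frac)
        for (side in c(-1, 1)) {
          lcx <- cx + side * lung_off * a
          lax <- 0.26 * a * sc
          lay <- 0.52 * b * sc
          lung <- lung | (((xs - lcx) / lax)^2 + ((ys - cy) / lay)^2 <= 1)
        }
        lung <- lung & (rho < 1 - thick) # lungs stay inside the fat ring
        img[lung] <- PHANTOM_BANDS$lung
      }
      # visceral fat: irregular blobs around the mediastinum
      vat <- matrix(FALSE, S, S)
      for (k in seq_len(sample(2:6, 1))) {
        bx <- cx + stats::runif(1, -0.15, 0.15) * a
        by <- cy + stats::runif(1, -0.55, 0.55) * b
        rx <- stats::runif(1, 0.028, 0.065) * S
        ry <- stats::runif(1, 0.028, 0.065) * S
        vat <- vat | (((xs - bx) / rx)^2 + ((ys - by) / ry)^2 <= 1)
      }
      vat <- vat & (rho < 0.8) & !lung & !sat
      img[vat] <- PHANTOM_BANDS$fat
      if (spec$noise_sd > 0) {
        img <- img + stats::rnorm(S * S, sd = spec$noise_sd)
      }
      img <- round(pmin(pmax(img, 0), 4095))
      slices[[i + 1L]] <- ct_slice(img, spacing_mm = spec$spacing_mm,
                                   index = i)
      sat_masks[[i + 1L]] <- matrix(as.integer(sat), S, S)
      vat_masks[[i + 1L]] <- matrix(as.integer(vat), S, S)
    }
    labels <- rep(LBL_OTHER, n)
    labels[spec$lung_first + 1L] <- LBL_FIRST
    labels[spec$lung_last + 1L] <- LBL_LAST
    structure(
      list(slices = slices, loc_labels = labels, sat_masks = sat_masks,
           vat_masks = vat_masks, spec = spec),
      class = "phantom_volume"
    )
  })
}

#' Generate a batch of phantom volumes
#'
#' Lung onset/offset indices vary randomly between volumes (within the valid
#' interior range) so a localizer cannot learn a fixed position; each volume
#' gets its own derived seed and is reproducible from `seed` alone.
#'
#' @param n_volumes Number of volumes.
#' @param n_slices,image_size,spacing_mm,noise_sd Passed to [phantom_spec()].
#' @param seed Integer master seed.
#' @return List of `phantom_volume` objects.
#' @export
generate_phantom_batch <- function(n_volumes, n_slices = 14L,
                                   image_size = 64L, spacing_mm = 2.5,
                                   noise_sd = 50, seed = 1L) {
  with_seed(seed, {
    specs <- lapply(seq_len(n_volumes), function(i) {
      fl <- sample(2:3, 1) # window length 5 needs centers >= 2
      ll <- sample((n_slices - 5L):(n_slices - 3L), 1)
      phantom_spec(n_slices = n_slices, image_size = image_size,
                   lung_first = fl, lung_last = ll,
                   spacing_mm = spacing_mm, noise_sd = noise_sd,
                   seed = sample.int(2147483646L, 1))
    })
    lapply(specs, generate_volume)
  })
}

#' Export a phantom volume in the package's on-disk dialects
#'
#' Writes, per slice, a 16-bit PNG (`image_###.png`), a SAT polygon JSON
#' (`sat_###.json`) and a VAT polygon JSON (`vat_###.json`), plus one
#' `labels.csv`, exactly as read back by [read_slice()],
#' [read_mask_labels()] and [read_loc_labels()]. A manifest file lists every
#' written file (3 per slice + the CSV).
#'
#' @param volume A `phantom_volume`.
#' @param directory Output directory (created if missing).
#' @return Path of the manifest file, invisibly.
#' @export
export_dataset <- function(volume, directory) {
  stopifnot(inherits(volume, "phantom_volume"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (file.access(directory, 2L) != 0L) {
    stop("directory not writable: ", directory)
  }
  files <- character(0)
  for (i in seq_along(volume$slices)) {
    tag <- sprintf("%03d", i - 1L)
    f_img <- file.path(directory, paste0("image_", tag, ".png"))
    write_slice(volume$slices[[i]], f_img)
    f_sat <- file.path(directory, paste0("sat_", tag, ".json"))
    write_mask_labels(volume$sat_masks[[i]], "SAT", f_sat)
    f_vat <- file.path(directory, paste0("vat_", tag, ".json"))
    write_mask_labels(volume$vat_masks[[i]], "VAT", f_vat)
    files <- c(files, f_img, f_sat, f_vat)
  }
  f_csv <- file.path(directory, "labels.csv")
  write_loc_labels(volume$loc_labels, f_csv)
  files <- c(files, f_csv)
  manifest <- file.path(directory, "manifest.txt")
  writeLines(basename(files), manifest)
  invisible(manifest)
}

#' Import a phantom-format dataset directory
#'
#' Reads back what [export_dataset()] wrote.
#'
#' @param directory Dataset directory containing `image_###.png`,
#'   `sat_###.json`, `vat_###.json` and `labels.csv`.
#' @param spacing_mm Inter-slice spacing to attach to the slices.
#' @return A list with fields `slices`, `loc_labels`, `sat_masks`,
#'   `vat_masks`.
#' @export
import_dataset <- function(directory, spacing_mm = 2.5) {
  imgs <- sort(list.files(directory, pattern = "^image_\\d+\\.png$",
                          full.names = TRUE))
  if (length(imgs) == 0L) stop("no image_###.png files in ", directory)
  slices <- lapply(seq_along(imgs), function(i) {
    read_slice(imgs[i], spacing_mm = spacing_mm, index = i - 1L)
  })
  shape <- c(slices[[1]]$height, slices[[1]]$width)
  tags <- sub("^image_(\\d+)\\.png$", "\\1", basename(imgs))
  sat <- lapply(tags, function(tg) {
    read_mask_labels(file.path(directory, paste0("sat_", tg, ".json")), shape)
  })
  vat <- lapply(tags, function(tg) {
    read_mask_labels(file.path(directory, paste0("vat_", tg, ".json")), shape)
  })
  labels <- read_loc_labels(file.path(directory, "labels.csv"))
  list(slices = slices, loc_labels = labels, sat_masks = sat, vat_masks = vat)
}
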