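# Slice containers, intensity normalizations, sliding windows, and the
# on-disk dialects (16-bit PNG slices, JSON polygon masks, label CSVs).

#' CT slice container
#'
#' Bundles one 16-bit axial slice with its inter-slice spacing and its
#' 0-based position along the body axis (index 0 = most superior slice).
#'
#' @param pixels Matrix of non-negative whole numbers (16-bit range). Rows
#'   are image rows (y), columns are image columns (x).
#' @param spacing_mm Positive inter-slice distance in millimetres; converts
#'   slice-index localization error into physical distance.
#' @param index 0-based position of the slice within its volume.
#' @return An object of class `ct_slice` with fields `pixels`, `height`,
#'   `width`, `spacing_mm`, `index`.
#' @export
ct_slice <- function(pixels, spacing_mm, index = 0L) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  storage.mode(pixels) <- "double"
  attributes(pixels) <- list(dim = dim(pixels))
  if (anyNA(pixels) || any(pixels < 0)) stop("pixel values must be non-negative")
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1L || spacing_mm <= 0) {
    stop("`spacing_mm` must be a single positive number")
  }
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
         spacing_mm = as.numeric(spacing_mm), index = as.integer(index)),
    class = "ct_slice"
  )
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf("<ct_slice %dx%d, index %d, spacing %.3g mm, range [%g, %g]>\n",
              x$height, x$width, x$index, x$spacing_mm,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

# Localization classes: 0 = first lung slice (FL), 1 = other (OS),
# 2 = last lung slice (LL).
LBL_FIRST <- 0L
LBL_OTHER <- 1L
LBL_LAST <- 2L

#' One-hot encode localization labels
#'
#' @param labels Integer vector with values in `{0, 1, 2}` (first lung
#'   slice / other / last lung slice).
#' @return Binary matrix `length(labels) x 3`; row `i` has a single 1 in
#'   column `labels[i] + 1`.
#' @export
label_onehot <- function(labels) {
  labels <- as.integer(labels)
  if (anyNA(labels) || any(!labels %in% 0:2)) {
    stop("localization labels must be 0 (first), 1 (other) or 2 (last)")
  }
  m <- matrix(0L, length(labels), 3L)
  m[cbind(seq_along(labels), labels + 1L)] <- 1L
  m
}

#' Read a 16-bit grayscale CT slice from PNG
#'
#' Pixels are returned exactly as stored in the file (no rescaling and no
#' intensity offset correction).
#'
#' @param path Path to a single-channel 16-bit PNG.
#' @param spacing_mm Inter-slice distance in millimetres.
#' @param index 0-based slice position within its volume.
#' @return A [ct_slice()].
#' @export
read_slice <- function(path, spacing_mm, index = 0L) {
  if (!file.exists(path)) stop("cannot read slice: no such file: ", path)
  img <- png::readPNG(path, info = TRUE)
  info <- attr(img, "info")
  if (length(dim(img)) == 3L) {
    stop(sprintf("expected a single-channel image, got %d channels: %s",
                 dim(img)[3], path))
  }
  if (info$bit.depth != 16L) {
    stop(sprintf("expected a 16-bit PNG, got bit depth %d: %s",
                 info$bit.depth, path))
  }
  ct_slice(round(img * 65535), spacing_mm = spacing_mm, index = index)
}

#' Write a CT slice as a 16-bit grayscale PNG
#'
#' @param slice A [ct_slice()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_slice <- function(slice, path) {
  stopifnot(inherits(slice, "ct_slice"))
  write_png16(slice$pixels, path)
}

#' Fixed-ceiling intensity normalization (MaxIntensity)
#'
#' Divides every pixel by the nominal 12-bit intensity ceiling 4095.
#' Stored values above 4095 (possible in 16-bit files) are clipped to 1 so
#' the output range contract holds.
#'
#' @param slice A [ct_slice()].
#' @return Numeric matrix with values in `[0, 1]`.
#' @export
max_intensity_norm <- function(slice) {
  stopifnot(inherits(slice, "ct_slice"))
  pmin(slice$pixels / 4095, 1)
}

#' Per-slice min-max intensity normalization (MaxMinNorm)
#'
#' Rescales the slice to `[0, 1]` using that slice's own minimum and maximum
#' intensity: `(f - min f) / (max f - min f)`.
#'
#' @param slice A [ct_slice()].
#' @return Numeric matrix whose minimum is 0 and maximum is 1.
#' @export
max_min_norm <- function(slice) {
  stopifnot(inherits(slice, "ct_slice"))
  lo <- min(slice$pixels)
  hi <- max(slice$pixels)
  if (hi == lo) {
    stop(sprintf("cannot min-max normalize constant slice (index %d)",
                 slice$index))
  }
  (slice$pixels - lo) / (hi - lo)
}

norm_fun <- function(normalization) {
  switch(normalization,
         MaxIntensity = max_intensity_norm,
         MaxMinNorm = max_min_norm,
         stop("unknown normalization: ", normalization))
}

#' Group an ordered slice sequence into sliding windows
#'
#' Slides a window of odd length `L` over the volume with stride 1. Each
#' window carries the localization label of its *center* slice, so the
#' bidirectional context around the labeled slice is symmetric. Slices too
#' close to either end of the volume are never window centers.
#'
#' @param volume List of [ct_slice()] objects, ordered by `index`.
#' @param labels Integer vector of per-slice localization labels (0/1/2),
#'   aligned with `volume`.
#' @param L Window length, one of 3, 5, 7.
#' @param volume_id Identifier stored on each window.
#' @return List of `slice_window` objects (`N - L + 1` of them), each with
#'   fields `slices`, `label`, `center_index`, `volume_id`, `spacing_mm`.
#' @export
make_windows <- function(volume, labels, L = 5L, volume_id = "vol") {
  L <- as.integer(L)
  if (!L %in% c(3L, 5L, 7L)) stop("window length L must be 3, 5 or 7")
  n <- length(volume)
  if (n < L) {
    stop(sprintf("volume has %d slices but window length is %d", n, L))
  }
  if (length(labels) != n) stop("labels must align with volume slices")
  label_onehot(labels) # validates values
  half <- (L - 1L) %/% 2L
  sp <- vapply(volume, function(s) s$spacing_mm, numeric(1))
  if (length(unique(sp)) != 1L) stop("all slices must share spacing_mm")
  idx <- vapply(volume, function(s) s$index, integer(1))
  if (any(diff(idx) != 1L)) stop("slice indices must be consecutive")
  lapply((half + 1L):(n - half), function(c) {
    structure(
      list(slices = volume[(c - half):(c + half)],
           label = as.integer(labels[c]),
           center_index = idx[c],
           volume_id = volume_id,
           spacing_mm = sp[1]),
      class = "slice_window"
    )
  })
}

# Even-odd polygon rasterization at integer pixel centers. `polygons` is a
# list of n x 2 matrices with 0-based (x = column, y = row) vertices. A pixel
# covered by an odd number of polygon windings is set, so a contour nested
# inside another (a hole, e.g. the inner boundary of the SAT ring) is
# subtracted automatically.
rasterize_polygons <- function(polygons, shape) {
  h <- shape[1]
  w <- shape[2]
  mask <- matrix(0L, h, w)
  if (length(polygons) == 0L) return(mask)
  X <- rep(0:(w - 1L), each = h) # column-major grid of pixel centers
  Y <- rep(0:(h - 1L), times = w)
  inside <- rep(FALSE, h * w)
  for (poly in polygons) {
    poly <- as.matrix(poly)
    if (ncol(poly) != 2L || nrow(poly) < 3L) {
      stop("each polygon needs >= 3 (x, y) vertices")
    }
    if (any(poly[, 1] < 0) || any(poly[, 1] > w - 1) ||
        any(poly[, 2] < 0) || any(poly[, 2] > h - 1)) {
      stop(sprintf("polygon vertex outside image bounds %dx%d", h, w))
    }
    parity <- rep(FALSE, h * w)
    nv <- nrow(poly)
    j <- nv
    for (i in seq_len(nv)) {
      xi <- poly[i, 1]; yi <- poly[i, 2]
      xj <- poly[j, 1]; yj <- poly[j, 2]
      if (yi != yj) {
        crosses <- ((yi > Y) != (yj > Y)) &
          (X < (xj - xi) * (Y - yi) / (yj - yi) + xi)
        parity <- xor(parity, crosses)
      }
      j <- i
    }
    inside <- xor(inside, parity)
  }
  mask[cbind(Y + 1L, X + 1L)] <- as.integer(inside)
  mask
}

#' Read a JSON polygon mask file
#'
#' The file encodes one tissue class as a list of closed polygons with
#' 0-based `(x = column, y = row)` vertices:
#' `{"tissue": "SAT"|"VAT", "polygons": [[[x,y], ...], ...]}`.
#' Polygons are rasterized with the even-odd rule, so nested contours cut
#' holes (the inner boundary of a subcutaneous fat ring).
#'
#' @param path Path to the JSON file.
#' @param shape Integer vector `c(height, width)` of the target mask.
#' @return Binary integer matrix of dimension `shape`; 1 inside the
#'   polygons. An empty polygon list yields an all-zero mask.
#' @export
read_mask_labels <- function(path, shape) {
  if (!file.exists(path)) stop("cannot read mask labels: no such file: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(obj$polygons)) stop("malformed mask JSON (no 'polygons'): ", path)
  polygons <- lapply(obj$polygons, function(p) {
    do.call(rbind, lapply(p, function(v) as.numeric(unlist(v))))
  })
  mask <- rasterize_polygons(polygons, shape)
  attr(mask, "tissue") <- obj$tissue
  mask
}

#' Write a binary mask as a JSON polygon file
#'
#' Traces the 0.5-level contours of the mask (outer boundaries and holes)
#' and stores them in the dialect read by [read_mask_labels()]. Tracing is
#' sub-pixel but not exact at corners; a write/read round trip reproduces
#' the mask up to its boundary pixels.
#'
#' @param mask Binary matrix.
#' @param tissue `"SAT"` or `"VAT"`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_mask_labels <- function(mask, tissue, path) {
  tissue <- match.arg(tissue, c("SAT", "VAT"))
  polys <- trace_mask_polygons(mask)
  obj <- list(tissue = tissue, polygons = polys)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Contours of a binary mask at level 0.5, as a list of polygons in the JSON
# dialect's (x = column, y = row) 0-based convention. contourLines() is run
# on a zero-padded copy so regions touching the image border still close.
trace_mask_polygons <- function(mask) {
  if (!all(mask %in% c(0, 1))) stop("mask must be binary")
  if (all(mask == 0)) return(list())
  h <- nrow(mask)
  w <- ncol(mask)
  padded <- matrix(0, h + 2L, w + 2L)
  padded[2:(h + 1L), 2:(w + 1L)] <- mask
  cl <- grDevices::contourLines(x = seq_len(h + 2L) - 2L, # row coord -> y
                                y = seq_len(w + 2L) - 2L, # col coord -> x
                                z = padded, levels = 0.5)
  lapply(cl, function(ct) {
    xy <- cbind(x = pmin(pmax(ct$y, 0), w - 1L),
                y = pmin(pmax(ct$x, 0), h - 1L))
    unname(round(xy, 3))
  })
}

#' Read / write per-volume localization labels
#'
#' CSV dialect: columns `index` (0-based slice index) and `label`
#' (0 = first lung slice, 1 = other, 2 = last lung slice).
#'
#' @param path CSV file path.
#' @return `read_loc_labels`: integer label vector ordered by slice index.
#' @export
read_loc_labels <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("index", "label") %in% names(df))) {
    stop("label CSV needs columns 'index' and 'label': ", path)
  }
  df <- df[order(df$index), ]
  label_onehot(df$label) # validates
  as.integer(df$label)
}

#' @rdname read_loc_labels
#' @param labels Integer vector of per-slice labels (0/1/2), in slice order.
#' @export
write_loc_labels <- function(labels, path) {
  label_onehot(labels) # validates
  utils::write.csv(
    data.frame(index = seq_along(labels) - 1L, label = as.integer(labels)),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
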