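# Independent reference implementations used as oracles. These deliberately
# avoid the package's vectorized code paths: scalar loops and direct
# arithmetic only.

# per-pixel dense GRU for 1x1 kernels (direct transcription of the gate
# equations, one pixel at a time)
scalar_gru_oracle <- function(x, h, p, literal = FALSE) {
  H <- dim(x)[1]; W <- dim(x)[2]
  hid <- p$hidden
  out <- array(0, c(H, W, hid))
  sig <- function(v) 1 / (1 + exp(-v))
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      v <- c(h[i, j, ], x[i, j, ])
      z <- sig(as.numeric(t(p$Wz$W) %*% v) + p$Wz$b)
      r <- sig(as.numeric(t(p$Wr$W) %*% v) + p$Wr$b)
      v2 <- c(r * h[i, j, ], x[i, j, ])
      a <- as.numeric(t(p$Wh$W) %*% v2) + p$Wh$b
      hc <- if (literal) tanh(sig(a)) else tanh(a)
      out[i, j, ] <- (1 - z) * h[i, j, ] + z * hc
    }
  }
  out
}

# even-odd point-in-polygon by scalar crossing count, one pixel at a time
rasterize_oracle <- function(polygons, shape) {
  h <- shape[1]; w <- shape[2]
  mask <- matrix(0L, h, w)
  point_in <- function(px, py) {
    inside <- FALSE
    for (poly in polygons) {
      nv <- nrow(poly)
      j <- nv
      for (i in seq_len(nv)) {
        xi <- poly[i, 1]; yi <- poly[i, 2]
        xj <- poly[j, 1]; yj <- poly[j, 2]
        if ((yi > py) != (yj > py) &&
            px < (xj - xi) * (py - yi) / (yj - yi) + xi) {
          inside <- !inside
        }
        j <- i
      }
    }
    inside
  }
  for (r in seq_len(h)) {
    for (cl in seq_len(w)) {
      if (point_in(cl - 1L, r - 1L)) mask[r, cl] <- 1L
    }
  }
  mask
}

# plain pixel-count confusion metrics
confusion_oracle <- function(t, p) {
  tp <- 0; fp <- 0; fn <- 0
  for (i in seq_along(t)) {
    if (t[i] == 1 && p[i] == 1) tp <- tp + 1
    if (t[i] == 0 && p[i] == 1) fp <- fp + 1
    if (t[i] == 1 && p[i] == 0) fn <- fn + 1
  }
  list(precision = if (tp + fp > 0) tp / (tp + fp) else 0,
       recall = if (tp + fn > 0) tp / (tp + fn) else 0)
}

# classical set-based Dice of two binary masks
classical_dice_oracle <- function(a, b) {
  inter <- sum(a == 1 & b == 1)
  2 * inter / (sum(a == 1) + sum(b == 1))
}

# drop non-dim attributes (e.g. the tissue tag) before matrix comparison
strip_attrs <- function(m) {
  attributes(m) <- list(dim = dim(m))
  m
}

# small shared phantom fixtures, built once per test run
fixture_env <- new.env(parent = emptyenv())

fixture_volume <- function() {
  if (is.null(fixture_env$vol)) {
    fixture_env$vol <- generate_volume(
      phantom_spec(n_slices = 12L, image_size = 32L, lung_first = 3L,
                   lung_last = 8L, seed = 42L))
  }
  fixture_env$vol
}
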