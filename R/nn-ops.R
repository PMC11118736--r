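# Neural-network primitives used by both networks: same-padded 2-D
# convolution via im2col + BLAS matrix products, 2x2 max pooling,
# nearest-neighbour 2x upsampling, activations, and the momentum form of
# stochastic gradient descent.
#
# Feature maps are numeric arrays of dimension c(H, W, C). A convolution's
# weights are kept as a matrix of dimension (C_in * k * k) x C_out whose rows
# are ordered channel-fastest, matching the im2col layout below.

as_feature_map <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (length(dim(x)) != 3L) stop("feature maps must be H x W x C arrays")
  x
}

# im2col is implemented as a single gather with cached index vectors: for a
# given (H, W, C, k) the patch matrix is x-with-a-trailing-zero indexed by a
# precomputed integer vector (out-of-image taps point at the trailing zero).
# This replaces per-offset array slicing, which dominates runtime otherwise.
.im2col_idx <- new.env(parent = emptyenv())

im2col_indices <- function(H, W, C, k) {
  key <- paste(H, W, C, k, sep = "x")
  idx <- .im2col_idx[[key]]
  if (!is.null(idx)) return(idx)
  p <- (k - 1L) %/% 2L
  N <- H * W * C
  blocks <- vector("list", k * k)
  o <- 0L
  ch_off <- rep((seq_len(C) - 1L) * H * W, each = H * W)
  for (dj in 0L:(k - 1L)) {
    for (di in 0L:(k - 1L)) {
      o <- o + 1L
      r <- seq_len(H) + di - p
      cl <- seq_len(W) + dj - p
      rv <- rep(r, times = W)
      cv <- rep(cl, each = H)
      lin <- rv + (cv - 1L) * H
      lin[rv < 1L | rv > H | cv < 1L | cv > W] <- NA
      full <- rep(lin, times = C) + ch_off
      full[is.na(full)] <- N + 1L
      blocks[[o]] <- full
    }
  }
  idx <- unlist(blocks, use.names = FALSE)
  .im2col_idx[[key]] <- idx
  idx
}

# (H*W) x (C*k*k) patch matrix of x under zero same-padding; columns are
# ordered channel-fastest, then kernel offset (row offset fastest).
im2col <- function(x, k) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]
  if (k == 1L) {
    dim(x) <- c(H * W, C)
    return(x)
  }
  cols <- c(x, 0)[im2col_indices(H, W, C, k)]
  dim(cols) <- c(H * W, C * k * k)
  cols
}

# Weight matrix of the adjoint convolution: correlating dy with the
# spatially flipped, channel-transposed kernels gives the input gradient of
# a stride-1 zero-padded same convolution. Rows are ordered to match
# im2col's (channel-fastest, then offset) layout over C_out.
rotated_weights <- function(par) {
  k2 <- par$k * par$k
  Wr <- matrix(0, par$c_out * k2, par$c_in)
  for (o in seq_len(k2)) {
    blk <- par$W[(k2 - o) * par$c_in + seq_len(par$c_in), , drop = FALSE]
    Wr[(o - 1L) * par$c_out + seq_len(par$c_out), ] <- t(blk)
  }
  Wr
}

# input gradient of conv_fwd: dy is an (H, W, c_out) array (or an
# (H*W) x c_out matrix with H, W supplied).
conv_bwd_input <- function(dy, par, H = NULL, W = NULL) {
  if (is.null(H)) {
    H <- dim(dy)[1]
    W <- dim(dy)[2]
  }
  if (par$k == 1L) {
    dim(dy) <- c(H * W, par$c_out)
    dx <- tcrossprod(dy, par$W)
  } else {
    dim(dy) <- c(H, W, par$c_out)
    dx <- im2col(dy, par$k) %*% rotated_weights(par)
  }
  dim(dx) <- c(H, W, par$c_in)
  dx
}

#' Convolution parameters
#'
#' He-style initialized weights for a same-padded 2-D convolution, drawn
#' from the caller's RNG stream. Used standalone to parameterize the
#' segmenter blocks ([multi_resolution_block()], [attention_gate()]).
#'
#' @param c_in,c_out Input / output channel counts.
#' @param k Odd kernel size.
#' @return List with fields `W` (`(c_in*k*k) x c_out` matrix), `b`, `k`,
#'   `c_in`, `c_out`.
#' @export
conv_param <- function(c_in, c_out, k) {
  sd <- sqrt(2 / (k * k * c_in))
  list(W = matrix(stats::rnorm(c_in * k * k * c_out, sd = sd),
                  c_in * k * k, c_out),
       b = numeric(c_out), k = as.integer(k),
       c_in = as.integer(c_in), c_out = as.integer(c_out))
}

conv_fwd <- function(x, par, cache = FALSE) {
  x <- as_feature_map(x)
  d <- dim(x)
  if (d[3] != par$c_in) {
    stop(sprintf("conv expected %d input channels, got %d", par$c_in, d[3]))
  }
  cols <- im2col(x, par$k)
  y <- cols %*% par$W
  y <- y + rep(par$b, each = nrow(y))
  dim(y) <- c(d[1], d[2], par$c_out)
  if (cache) list(y = y, cols = cols, H = d[1], W = d[2]) else y
}

# returns list(dx, dW, db); `cache` is conv_fwd(..., cache = TRUE) output.
conv_bwd <- function(dy, par, cache) {
  H <- cache$H; W <- cache$W
  dim(dy) <- c(H * W, par$c_out)
  dW <- crossprod(cache$cols, dy)
  db <- colSums(dy)
  dx <- conv_bwd_input(dy, par, H, W)
  list(dx = dx, dW = dW, db = db)
}

sigmoid <- function(x) 1 / (1 + exp(-x))
relu <- function(x) pmax(x, 0)

maxpool2_fwd <- function(x) {
  d <- dim(x)
  if (d[1] %% 2L != 0L || d[2] %% 2L != 0L) {
    stop("max pooling needs even spatial dimensions")
  }
  i1 <- seq(1L, d[1], 2L); i2 <- seq(2L, d[1], 2L)
  j1 <- seq(1L, d[2], 2L); j2 <- seq(2L, d[2], 2L)
  a <- x[i1, j1, , drop = FALSE]
  b <- x[i2, j1, , drop = FALSE]
  c_ <- x[i1, j2, , drop = FALSE]
  e <- x[i2, j2, , drop = FALSE]
  m <- pmax(a, b, c_, e)
  wa <- a == m
  wb <- (b == m) & !wa
  wc <- (c_ == m) & !wa & !wb
  we <- !(wa | wb | wc)
  list(y = m, masks = list(wa, wb, wc, we), dims = d)
}

maxpool2_bwd <- function(dy, cache) {
  d <- cache$dims
  dx <- array(0, d)
  i1 <- seq(1L, d[1], 2L); i2 <- seq(2L, d[1], 2L)
  j1 <- seq(1L, d[2], 2L); j2 <- seq(2L, d[2], 2L)
  ms <- cache$masks
  dx[i1, j1, ] <- dy * ms[[1]]
  dx[i2, j1, ] <- dy * ms[[2]]
  dx[i1, j2, ] <- dy * ms[[3]]
  dx[i2, j2, ] <- dy * ms[[4]]
  dx
}

# non-overlapping block-mean pooling by an integer factor (spatial dims
# must be divisible by it); used to shrink localizer inputs.
avgpool_fwd <- function(x, factor) {
  x <- as_feature_map(x)
  d <- dim(x)
  if (factor == 1L) return(x)
  if (d[1] %% factor != 0L || d[2] %% factor != 0L) {
    stop(sprintf("spatial dims %dx%d not divisible by pool factor %d",
                 d[1], d[2], factor))
  }
  H2 <- d[1] %/% factor
  W2 <- d[2] %/% factor
  dim(x) <- c(factor, H2 * factor * W2 * d[3])
  y <- colMeans(x) # rows pooled
  dim(y) <- c(H2, factor, W2 * d[3])
  out <- y[, 1, , drop = FALSE]
  for (f in seq_len(factor)[-1]) out <- out + y[, f, , drop = FALSE]
  out <- out / factor # columns pooled
  dim(out) <- c(H2, W2, d[3])
  out
}

upsample2_fwd <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), ,
    drop = FALSE]
}

upsample2_bwd <- function(dy) {
  d <- dim(dy)
  i1 <- seq(1L, d[1], 2L); i2 <- seq(2L, d[1], 2L)
  j1 <- seq(1L, d[2], 2L); j2 <- seq(2L, d[2], 2L)
  dy[i1, j1, , drop = FALSE] + dy[i2, j1, , drop = FALSE] +
    dy[i1, j2, , drop = FALSE] + dy[i2, j2, , drop = FALSE]
}

# SGD with momentum: v <- beta * v + (1 - beta) * g; theta <- theta - lr * v.
# params/grads/velocity are arbitrarily nested lists with numeric leaves;
# velocity starts at zero when NULL.
sgd_momentum_step <- function(params, grads, velocity, lr, beta = 0.9) {
  step <- function(p, g, v) {
    if (is.list(p)) {
      out_p <- p
      out_v <- if (is.null(v)) vector("list", length(p)) else v
      for (nm in names(p)) {
        if (is.numeric(p[[nm]]) || is.list(p[[nm]])) {
          if (is.null(g[[nm]])) next
          r <- step(p[[nm]], g[[nm]], out_v[[nm]])
          out_p[[nm]] <- r$p
          out_v[[nm]] <- r$v
        }
      }
      list(p = out_p, v = out_v)
    } else {
      if (is.null(v)) v <- p * 0
      v <- beta * v + (1 - beta) * g
      list(p = p - lr * v, v = v)
    }
  }
  step(params, grads, velocity)
}

# elementwise sum of two same-shaped nested gradient lists (a may be NULL)
acc_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(b)) {
    for (nm in names(b)) a[[nm]] <- acc_grads(a[[nm]], b[[nm]])
    a
  } else {
    a + b
  }
}
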