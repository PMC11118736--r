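# ConvBiGRU lung-slice localizer.
#
# The classifier labels the center slice of a short window of consecutive
# axial slices as first lung slice (0), other (1), or last lung slice (2).
# Gate transformations are same-padded convolutions over the channel
# concatenation [h_{t-1}, x_t]:
#   z_t  = sigma(W_z * [h_{t-1}, x_t])          update gate
#   r_t  = sigma(W_r * [h_{t-1}, x_t])          reset gate
#   h~_t = tanh(W * [r_t . h_{t-1}, x_t])       candidate state
#   h_t  = (1 - z_t) . h_{t-1} + z_t . h~_t
# The candidate is the standard GRU form by default; `literal_eq3 = TRUE`
# nests an extra sigmoid inside the tanh, reproducing a published variant of
# the candidate equation that bounds h~ to (0, tanh 1).
#
# Two recurrences run over the window in opposite directions from zero
# initial state; their final hidden states are concatenated channel-wise,
# globally average-pooled, and mapped by one linear layer to 3-class
# softmax probabilities.

#' ConvGRU gate parameters
#'
#' Three convolution kernels (update gate, reset gate, candidate), each
#' mapping the `hidden + input`-channel concatenation to `hidden` channels
#' under same padding. Weights use seeded He-style initialization drawn from
#' the caller's RNG stream.
#'
#' @param in_ch Input channels per slice (1 for grayscale CT).
#' @param hidden Hidden-state channels.
#' @param kernel_size Odd convolution kernel size.
#' @return A `conv_gru_params` list with fields `Wz`, `Wr`, `Wh`.
#' @export
conv_gru_params <- function(in_ch, hidden, kernel_size = 3L) {
  kernel_size <- as.integer(kernel_size)
  if (kernel_size %% 2L == 0L) stop("kernel_size must be odd")
  structure(
    list(Wz = conv_param(hidden + in_ch, hidden, kernel_size),
         Wr = conv_param(hidden + in_ch, hidden, kernel_size),
         Wh = conv_param(hidden + in_ch, hidden, kernel_size),
         in_ch = as.integer(in_ch), hidden = as.integer(hidden),
         kernel_size = kernel_size),
    class = "conv_gru_params"
  )
}

concat_maps <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

conv_from_cols <- function(cols, par, H, W) {
  y <- cols %*% par$W
  y <- y + rep(par$b, each = nrow(y))
  dim(y) <- c(H, W, par$c_out)
  y
}

#' One ConvGRU recurrence step
#'
#' @param x_t Input feature map (`H x W x in_ch`, a matrix is promoted to
#'   one channel).
#' @param h_prev Previous hidden state (`H x W x hidden`).
#' @param params A [conv_gru_params()].
#' @param literal_eq3 If `TRUE`, use the candidate `tanh(sigma(.))`
#'   composition instead of the standard `tanh(.)`.
#' @param cache If `TRUE`, return intermediates needed for backpropagation.
#' @return The new hidden state `h_t` (or a list with `h` and `cache`).
#' @export
gru_cell_step <- function(x_t, h_prev, params, literal_eq3 = FALSE,
                          cache = FALSE) {
  x_t <- as_feature_map(x_t)
  h_prev <- as_feature_map(h_prev)
  dx <- dim(x_t); dh <- dim(h_prev)
  if (!identical(dx[1:2], dh[1:2])) {
    stop(sprintf("spatial dims differ: input %dx%d vs hidden %dx%d",
                 dx[1], dx[2], dh[1], dh[2]))
  }
  H <- dx[1]; W <- dx[2]
  hid <- params$hidden
  concat1 <- concat_maps(h_prev, x_t)
  cols1 <- im2col(concat1, params$Wz$k)
  z <- sigmoid(conv_from_cols(cols1, params$Wz, H, W))
  r <- sigmoid(conv_from_cols(cols1, params$Wr, H, W))
  concat2 <- concat_maps(r * h_prev, x_t)
  cols2 <- im2col(concat2, params$Wh$k)
  ac <- conv_from_cols(cols2, params$Wh, H, W)
  if (literal_eq3) {
    s <- sigmoid(ac)
    hc <- tanh(s)
  } else {
    s <- NULL
    hc <- tanh(ac)
  }
  h <- (1 - z) * h_prev + z * hc
  if (!cache) return(h)
  list(h = h,
       cache = list(cols1 = cols1, cols2 = cols2, z = z, r = r, hc = hc,
                    s = s, h_prev = h_prev, H = H, W = W))
}

# Backpropagate one direction of the recurrence. `dh_final` is the gradient
# at the direction's last hidden state; `caches` are the per-step caches in
# processing order. Returns accumulated parameter gradients (input gradients
# are not needed: inputs are data).
gru_backprop <- function(dh_final, caches, params, literal_eq3 = FALSE) {
  hid <- params$hidden
  g <- list(Wz = list(W = params$Wz$W * 0, b = params$Wz$b * 0),
            Wr = list(W = params$Wr$W * 0, b = params$Wr$b * 0),
            Wh = list(W = params$Wh$W * 0, b = params$Wh$b * 0))
  dh <- dh_final
  for (t in rev(seq_along(caches))) {
    cc <- caches[[t]]
    H <- cc$H; W <- cc$W
    n <- H * W
    dz <- dh * (cc$hc - cc$h_prev)
    dhc <- dh * cc$z
    dhp <- dh * (1 - cc$z)
    dac <- if (literal_eq3) {
      dhc * (1 - cc$hc^2) * cc$s * (1 - cc$s)
    } else {
      dhc * (1 - cc$hc^2)
    }
    dim(dac) <- c(n, hid)
    g$Wh$W <- g$Wh$W + crossprod(cc$cols2, dac)
    g$Wh$b <- g$Wh$b + colSums(dac)
    dconcat2 <- conv_bwd_input(dac, params$Wh, H, W)
    dch <- dconcat2[, , seq_len(hid), drop = FALSE]
    dr <- dch * cc$h_prev
    dhp <- dhp + dch * cc$r
    daz <- dz * cc$z * (1 - cc$z)
    dar <- dr * cc$r * (1 - cc$r)
    dim(daz) <- c(n, hid)
    dim(dar) <- c(n, hid)
    g$Wz$W <- g$Wz$W + crossprod(cc$cols1, daz)
    g$Wz$b <- g$Wz$b + colSums(daz)
    g$Wr$W <- g$Wr$W + crossprod(cc$cols1, dar)
    g$Wr$b <- g$Wr$b + colSums(dar)
    dc1 <- conv_bwd_input(daz, params$Wz, H, W) +
      conv_bwd_input(dar, params$Wr, H, W)
    dhp <- dhp + dc1[, , seq_len(hid), drop = FALSE]
    dh <- dhp
  }
  g
}

#' Bidirectional ConvGRU over a slice window
#'
#' Runs the recurrence over the (already normalized) window in both
#' directions from zero initial hidden states and concatenates the two
#' final hidden states channel-wise.
#'
#' @param inputs List of `H x W x in_ch` arrays (or matrices), in slice
#'   order.
#' @param fwd,bwd [conv_gru_params()] for the two directions.
#' @param literal_eq3 Candidate-state variant flag, see [gru_cell_step()].
#' @param cache Keep per-step caches for training.
#' @return The `H x W x 2*hidden` concatenated state (or a list with
#'   `y`, `caches_f`, `caches_b`).
#' @export
bigru_forward <- function(inputs, fwd, bwd, literal_eq3 = FALSE,
                          cache = FALSE) {
  if (length(inputs) == 0L) stop("empty slice window")
  inputs <- lapply(inputs, as_feature_map)
  d <- dim(inputs[[1]])
  h0 <- array(0, c(d[1], d[2], fwd$hidden))
  run <- function(order, params) {
    h <- h0
    caches <- vector("list", length(order))
    for (i in seq_along(order)) {
      st <- gru_cell_step(inputs[[order[i]]], h, params,
                          literal_eq3 = literal_eq3, cache = cache)
      if (cache) {
        h <- st$h
        caches[[i]] <- st$cache
      } else {
        h <- st
      }
    }
    list(h = h, caches = caches)
  }
  f <- run(seq_along(inputs), fwd)
  b <- run(rev(seq_along(inputs)), bwd)
  y <- concat_maps(f$h, b$h)
  if (!cache) return(y)
  list(y = y, caches_f = f$caches, caches_b = b$caches)
}

#' Localizer configuration
#'
#' @param window_length Slices per window; 3, 5 or 7 (5 is the default
#'   working point).
#' @param hidden_channels Hidden-state channels of each GRU direction.
#' @param kernel_size Odd convolution kernel size.
#' @param normalization `"MaxMinNorm"` (per-slice min-max) or
#'   `"MaxIntensity"` (fixed /4095 ceiling).
#' @param input_pool Integer block-mean pooling factor applied to each
#'   normalized slice before the recurrence (1 disables). Slice
#'   classification needs coarse anatomy, not full resolution, so the
#'   default halves each spatial dimension and quarters the cost.
#' @param literal_eq3 Candidate-state variant flag, see [gru_cell_step()].
#' @return A `localizer_config` list (`n_classes` is fixed at 3).
#' @export
localizer_config <- function(window_length = 5L, hidden_channels = 8L,
                             kernel_size = 3L,
                             normalization = c("MaxMinNorm", "MaxIntensity"),
                             input_pool = 2L, literal_eq3 = FALSE) {
  window_length <- as.integer(window_length)
  if (!window_length %in% c(3L, 5L, 7L)) {
    stop("window_length must be 3, 5 or 7")
  }
  if (as.integer(kernel_size) %% 2L == 0L) stop("kernel_size must be odd")
  if (as.integer(input_pool) < 1L) stop("input_pool must be >= 1")
  structure(
    list(window_length = window_length,
         hidden_channels = as.integer(hidden_channels),
         kernel_size = as.integer(kernel_size),
         normalization = match.arg(normalization),
         input_pool = as.integer(input_pool),
         literal_eq3 = isTRUE(literal_eq3),
         n_classes = 3L),
    class = "localizer_config"
  )
}

#' Initialize an untrained localizer
#'
#' @param config A [localizer_config()].
#' @param in_ch Input channels per slice.
#' @param seed Integer seed for the weight draw.
#' @return A `localizer_model` with fields `config` and `params`
#'   (`fwd`, `bwd`, `head`).
#' @export
localizer_init <- function(config, in_ch = 1L, seed = 1L) {
  stopifnot(inherits(config, "localizer_config"))
  with_seed(seed, {
    hid <- config$hidden_channels
    structure(
      list(config = config,
           params = list(
             fwd = conv_gru_params(in_ch, hid, config$kernel_size),
             bwd = conv_gru_params(in_ch, hid, config$kernel_size),
             head = list(W = matrix(stats::rnorm(2 * hid * 3,
                                                 sd = sqrt(1 / (2 * hid))),
                                    2 * hid, 3),
                         b = numeric(3)))),
      class = "localizer_model"
    )
  })
}

window_inputs <- function(window, config) {
  nf <- norm_fun(config$normalization)
  lapply(window$slices, function(s) avgpool_fwd(nf(s), config$input_pool))
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

#' Classify one slice window
#'
#' Applies the bidirectional recurrence, global average pooling, and the
#' 3-way linear head with softmax.
#'
#' @param window A `slice_window` from [make_windows()].
#' @param model A `localizer_model`.
#' @return Length-3 probability vector (first / other / last), summing to 1.
#' @export
classify_window <- function(window, model) {
  stopifnot(inherits(model, "localizer_model"))
  if (length(window$slices) != model$config$window_length) {
    stop(sprintf("window has %d slices but model is configured for %d",
                 length(window$slices), model$config$window_length))
  }
  inputs <- window_inputs(window, model$config)
  y <- bigru_forward(inputs, model$params$fwd, model$params$bwd,
                     literal_eq3 = model$config$literal_eq3)
  gap <- apply(y, 3, mean)
  logits <- as.numeric(crossprod(model$params$head$W, gap)) +
    model$params$head$b
  softmax(logits)
}

#' Train the localizer on labeled windows
#'
#' Pure stochastic gradient descent with momentum (one update per window)
#' on the cross-entropy of the 3-class softmax. When `class_weights` is
#' supplied, the penalty `W` of each window's true class is *added* to that
#' window's loss term; the addition is a per-sample constant, so it shifts
#' the reported loss without altering gradients (imbalance is instead
#' handled by training on balanced subsets, see [balance_subsets()]).
#'
#' @param windows List of labeled `slice_window` objects.
#' @param config A [localizer_config()].
#' @param epochs,lr,momentum Optimizer settings.
#' @param class_weights Optional [compute_class_weights()] result.
#' @param seed Seed for initialization and epoch shuffling.
#' @param stop_accuracy Early-stop once training accuracy reaches this value
#'   (`NULL` = run all epochs).
#' @param verbose Print one line per epoch.
#' @return A trained `localizer_model`; `$history` holds per-epoch mean loss
#'   and accuracy.
#' @export
train_localizer <- function(windows, config, epochs = 30L, lr = 0.05,
                            momentum = 0.9, class_weights = NULL, seed = 1L,
                            stop_accuracy = NULL, verbose = FALSE) {
  model <- localizer_init(config, seed = seed)
  labels <- vapply(windows, function(w) w$label, integer(1))
  inputs <- lapply(windows, window_inputs, config = config)
  hid <- config$hidden_channels
  vel <- NULL
  hist_loss <- numeric(0)
  hist_acc <- numeric(0)
  with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample(length(windows))
      losses <- numeric(length(ord))
      correct <- logical(length(ord))
      for (ii in seq_along(ord)) {
        i <- ord[ii]
        fw <- bigru_forward(inputs[[i]], model$params$fwd, model$params$bwd,
                            literal_eq3 = config$literal_eq3, cache = TRUE)
        d <- dim(fw$y)
        gap <- apply(fw$y, 3, mean)
        logits <- as.numeric(crossprod(model$params$head$W, gap)) +
          model$params$head$b
        p <- softmax(logits)
        y1 <- labels[i] + 1L
        loss <- -log(max(p[y1], 1e-12))
        if (!is.null(class_weights)) loss <- loss + class_weights$W[y1]
        losses[ii] <- loss
        correct[ii] <- which.max(p) == y1
        dlogits <- p
        dlogits[y1] <- dlogits[y1] - 1
        ghead <- list(W = outer(gap, dlogits), b = dlogits)
        dgap <- as.numeric(model$params$head$W %*% dlogits)
        dHy <- array(rep(dgap / (d[1] * d[2]), each = d[1] * d[2]), d)
        gf <- gru_backprop(dHy[, , seq_len(hid), drop = FALSE],
                           fw$caches_f, model$params$fwd,
                           literal_eq3 = config$literal_eq3)
        gb <- gru_backprop(dHy[, , hid + seq_len(hid), drop = FALSE],
                           fw$caches_b, model$params$bwd,
                           literal_eq3 = config$literal_eq3)
        grads <- list(fwd = gf, bwd = gb, head = ghead)
        st <- sgd_momentum_step(model$params, grads, vel, lr, momentum)
        model$params <- st$p
        vel <- st$v
      }
      hist_loss <- c(hist_loss, mean(losses))
      hist_acc <- c(hist_acc, mean(correct))
      if (verbose) {
        message(sprintf("epoch %d: loss %.4f acc %.3f",
                        ep, mean(losses), mean(correct)))
      }
      if (!is.null(stop_accuracy) && mean(correct) >= stop_accuracy) break
    }
  })
  model$history <- data.frame(epoch = seq_along(hist_loss),
                              loss = hist_loss, accuracy = hist_acc)
  model
}

#' Logarithmic class-weight penalties
#'
#' Per-class occurrence counts are normalized to fractions
#' `w_i = n_i / sum(n)` and mapped to penalties `W_i = 1 / log(alpha + w_i)`
#' (natural logarithm), so rarer classes receive larger penalties. With the
#' default `alpha = 1.1` every `W_i` lies strictly inside
#' `(1/log 2.1, 1/log 1.1)`.
#'
#' @param counts Positive per-class occurrence counts.
#' @param alpha Offset keeping the log argument above 1; must exceed 1.
#' @return A `class_weights` list with fields `counts`, `normalized`, `W`,
#'   `alpha`.
#' @export
compute_class_weights <- function(counts, alpha = 1.1) {
  if (length(counts) == 0L || any(!is.finite(counts)) || any(counts <= 0)) {
    stop("all class counts must be positive")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 1) {
    stop("alpha must be a single number > 1")
  }
  normalized <- counts / sum(counts)
  structure(
    list(counts = counts, normalized = normalized,
         W = 1 / log(alpha + normalized), alpha = alpha),
    class = "class_weights"
  )
}

#' Mean localization distance in millimetres
#'
#' Converts per-volume slice-index errors into physical distance:
#' `MD = sum(|pred - true| * spacing) / N`.
#'
#' @param pred_indices,true_indices Aligned integer slice indices (the
#'   predicted slice is the one with the highest class score per volume).
#' @param spacing_mm Per-volume inter-slice spacings (recycled if scalar).
#' @return Mean distance in mm (non-negative; 0 iff every prediction is
#'   exact).
#' @export
mean_distance <- function(pred_indices, true_indices, spacing_mm) {
  n <- length(pred_indices)
  if (n == 0L) stop("empty prediction list")
  if (length(true_indices) != n) {
    stop(sprintf("length mismatch: %d predictions vs %d truths",
                 n, length(true_indices)))
  }
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, n)
  if (length(spacing_mm) != n) stop("spacing_mm must align with predictions")
  mean(abs(pred_indices - true_indices) * spacing_mm)
}

#' Split windows into positives-balanced disjoint subsets
#'
#' Positive windows are those whose center slice is a lung boundary (label
#' 0 or 2). Each subset receives the same number of positives (within
#' `tolerance` of `target_positive`); negatives are spread evenly. Surplus
#' positives beyond the per-subset target remain unassigned.
#'
#' @param windows List of labeled `slice_window` objects.
#' @param n_subsets Number of disjoint subsets.
#' @param target_positive Desired positives per subset.
#' @param tolerance Allowed shortfall per subset.
#' @param subset_size Optional total windows per subset (positives plus
#'   negatives); `NULL` spreads all negatives across the subsets.
#' @param seed Seed; the partition is deterministic given it.
#' @return List of `n_subsets` window lists, with attribute
#'   `positive_counts`.
#' @export
balance_subsets <- function(windows, n_subsets, target_positive,
                            tolerance = 0L, subset_size = NULL, seed = 1L) {
  labels <- vapply(windows, function(w) w$label, integer(1))
  pos <- which(labels != LBL_OTHER)
  neg <- which(labels == LBL_OTHER)
  per <- min(target_positive, length(pos) %/% n_subsets)
  if (per < target_positive - tolerance) {
    stop(sprintf(paste0("cannot balance: %d positive windows available, ",
                        "need %d per subset (+/- %d) across %d subsets"),
                 length(pos), target_positive, tolerance, n_subsets))
  }
  with_seed(seed, {
    pos <- sample(pos)
    neg <- sample(neg)
    subsets <- vector("list", n_subsets)
    npos <- integer(n_subsets)
    for (s in seq_len(n_subsets)) {
      p_idx <- pos[((s - 1L) * per + 1L):(s * per)]
      n_idx <- neg[seq_len(length(neg)) %% n_subsets == (s - 1L)]
      if (!is.null(subset_size)) {
        need_neg <- max(subset_size - per, 0L)
        if (need_neg > length(n_idx)) {
          stop(sprintf("not enough negatives for subset size %d",
                       subset_size))
        }
        n_idx <- n_idx[seq_len(need_neg)]
      }
      subsets[[s]] <- windows[sort(c(p_idx, n_idx))]
      npos[s] <- per
    }
    attr(subsets, "positive_counts") <- npos
    subsets
  })
}

#' Evaluate a localizer on whole volumes
#'
#' Builds all windows of each volume, scores them, and takes the center
#' index of the window with the highest first-class (respectively
#' last-class) probability as the predicted first (last) lung slice; ties
#' break toward the smaller index. Distances follow [mean_distance()], with
#' the first- and last-slice errors of every volume pooled.
#'
#' @param model A trained `localizer_model`.
#' @param volumes List of `phantom_volume`-like objects (fields `slices`,
#'   `loc_labels`).
#' @return List with `per_volume` (data frame: `volume_id`, `pred_fl`,
#'   `true_fl`, `pred_ll`, `true_ll`, `distance_mm`) and `md_mm`.
#' @export
evaluate_localizer <- function(model, volumes) {
  L <- model$config$window_length
  rows <- lapply(seq_along(volumes), function(vi) {
    vol <- volumes[[vi]]
    wins <- make_windows(vol$slices, vol$loc_labels, L,
                         volume_id = paste0("vol", vi))
    probs <- t(vapply(wins, classify_window, numeric(3), model = model))
    centers <- vapply(wins, function(w) w$center_index, integer(1))
    sp <- wins[[1]]$spacing_mm
    pred_fl <- centers[which.max(probs[, 1])]
    pred_ll <- centers[which.max(probs[, 3])]
    true_fl <- which(vol$loc_labels == LBL_FIRST) - 1L
    true_ll <- which(vol$loc_labels == LBL_LAST) - 1L
    data.frame(volume_id = paste0("vol", vi),
               pred_fl = pred_fl, true_fl = true_fl,
               pred_ll = pred_ll, true_ll = true_ll,
               spacing_mm = sp,
               distance_mm = mean_distance(c(pred_fl, pred_ll),
                                           c(true_fl, true_ll), sp))
  })
  per_volume <- do.call(rbind, rows)
  md <- mean_distance(c(per_volume$pred_fl, per_volume$pred_ll),
                      c(per_volume$true_fl, per_volume$true_ll),
                      rep(per_volume$spacing_mm, 2))
  list(per_volume = per_volume, md_mm = md)
}
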