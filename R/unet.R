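# Multi-module UNet for binary adipose-tissue segmentation.
#
# Backbone: depth-4 encoder/decoder, two same-padded 3x3 convolutions + ReLU
# per level, 2x2 max pooling, nearest-neighbour upsampling followed by a 1x1
# projection, and a 1-channel logistic output head. Three optional blocks
# modify the skip pathway, composed in the order MR -> ATTN -> CP:
#
#   MR   multi-resolution fusion: the next-deeper encoder features are
#        upsampled, projected by a 1x1 convolution to the skip's channel
#        count, and added to the skip.
#   ATTN additive attention gate: a per-pixel gate in (0,1), driven by the
#        upsampled decoder features at the peer level, scales the pathway.
#   CP   competitive Maxout: elementwise maximum of the pathway and the
#        projected decoder features, keeping the stronger activation.
#
# The (possibly modified) pathway is concatenated with the projected decoder
# features exactly as in a plain UNet. All 2^3 block combinations share this
# wiring, which is what the ablation harness sweeps.

#' Segmenter module configuration
#'
#' @param use_mr,use_cp,use_attn Enable the multi-resolution, competitive
#'   (Maxout) and attention-gate blocks on the skip pathway.
#' @param depth Number of encoder levels (>= 2).
#' @param base_channels Channels of the first encoder level; deeper levels
#'   double it. 16 keeps CPU training at desk scale.
#' @return A `unet_config` list.
#' @export
unet_config <- function(use_mr = FALSE, use_cp = FALSE, use_attn = FALSE,
                        depth = 4L, base_channels = 16L) {
  depth <- as.integer(depth)
  if (depth < 2L) stop("depth must be >= 2")
  structure(
    list(use_mr = isTRUE(use_mr), use_cp = isTRUE(use_cp),
         use_attn = isTRUE(use_attn), depth = depth,
         base_channels = as.integer(base_channels)),
    class = "unet_config"
  )
}

#' @export
print.unet_config <- function(x, ...) {
  blocks <- c("MR", "CP", "ATTN")[c(x$use_mr, x$use_cp, x$use_attn)]
  cat(sprintf("<unet_config depth %d, base %d, blocks: %s>\n",
              x$depth, x$base_channels,
              if (length(blocks)) paste(blocks, collapse = "+") else "none"))
  invisible(x)
}

#' Initialize UNet weights
#'
#' @param config A [unet_config()].
#' @param in_ch Input image channels.
#' @param seed Integer seed for the He-style weight draw.
#' @return A parameter list (`enc`, `bott`, `dec`, optional `mr`/`attn`,
#'   `final`).
#' @export
unet_init <- function(config, in_ch = 1L, seed = 1L) {
  stopifnot(inherits(config, "unet_config"))
  with_seed(seed, {
    depth <- config$depth
    ch <- config$base_channels * 2L^(seq_len(depth) - 1L)
    enc <- lapply(seq_len(depth), function(l) {
      cin <- if (l == 1L) in_ch else ch[l - 1L]
      list(conv1 = conv_param(cin, ch[l], 3L),
           conv2 = conv_param(ch[l], ch[l], 3L))
    })
    bott <- list(conv1 = conv_param(ch[depth], 2L * ch[depth], 3L),
                 conv2 = conv_param(2L * ch[depth], 2L * ch[depth], 3L))
    dec <- lapply(seq_len(depth), function(l) {
      list(up_proj = conv_param(2L * ch[l], ch[l], 1L),
           conv1 = conv_param(2L * ch[l], ch[l], 3L),
           conv2 = conv_param(ch[l], ch[l], 3L))
    })
    params <- list(enc = enc, bott = bott, dec = dec,
                   final = conv_param(ch[1], 1L, 1L))
    if (config$use_mr) {
      params$mr <- lapply(seq_len(depth), function(l) {
        conv_param(2L * ch[l], ch[l], 1L)
      })
    }
    if (config$use_attn) {
      params$attn <- lapply(seq_len(depth), function(l) {
        inter <- max(ch[l] %/% 2L, 1L)
        list(Ws = conv_param(ch[l], inter, 1L),
             Wg = conv_param(ch[l], inter, 1L),
             psi = conv_param(inter, 1L, 1L))
      })
    }
    params
  })
}

#' Multi-resolution fusion block
#'
#' Upsamples the deeper feature map to the shallow map's resolution (the
#' ratio must be a power of two), projects it with a 1x1 convolution to the
#' shallow channel count, and adds it elementwise.
#'
#' @param shallow Feature map at the skip level.
#' @param deep Feature map from a deeper level (lower resolution).
#' @param proj 1x1 projection parameters from [unet_init()] (`$mr[[l]]`).
#' @param cache Keep intermediates for backpropagation.
#' @return Fused feature map with `shallow`'s shape.
#' @export
multi_resolution_block <- function(shallow, deep, proj, cache = FALSE) {
  shallow <- as_feature_map(shallow)
  deep <- as_feature_map(deep)
  ratio <- dim(shallow)[1] / dim(deep)[1]
  m <- log2(ratio)
  if (ratio < 2 || m != round(m) ||
      dim(shallow)[2] / dim(deep)[2] != ratio) {
    stop(sprintf("resolution ratio must be a power of two, got %dx%d vs %dx%d",
                 dim(shallow)[1], dim(shallow)[2],
                 dim(deep)[1], dim(deep)[2]))
  }
  up <- deep
  for (i in seq_len(m)) up <- upsample2_fwd(up)
  cv <- conv_fwd(up, proj, cache = cache)
  if (!cache) return(shallow + cv)
  list(y = shallow + cv$y, conv = cv, m = m)
}

multi_resolution_bwd <- function(dy, proj, cache) {
  cb <- conv_bwd(dy, proj, cache$conv)
  ddeep <- cb$dx
  for (i in seq_len(cache$m)) ddeep <- upsample2_bwd(ddeep)
  list(dshallow = dy, ddeep = ddeep,
       grads = list(W = cb$dW, b = cb$db))
}

#' Competitive (Maxout) block
#'
#' Elementwise maximum of two same-shaped candidate feature maps.
#'
#' @param candidate_a,candidate_b Same-shaped feature maps.
#' @return Their elementwise maximum.
#' @export
competitive_block <- function(candidate_a, candidate_b) {
  candidate_a <- as_feature_map(candidate_a)
  candidate_b <- as_feature_map(candidate_b)
  if (!identical(dim(candidate_a), dim(candidate_b))) {
    stop(sprintf("candidate shapes differ: %s vs %s",
                 paste(dim(candidate_a), collapse = "x"),
                 paste(dim(candidate_b), collapse = "x")))
  }
  pmax(candidate_a, candidate_b)
}

#' Additive attention gate
#'
#' Computes a per-pixel gate
#' `alpha = sigma(psi * relu(Ws * skip + Wg * gating))` in `(0, 1)` and
#' returns `alpha * skip`. The gating signal is the upsampled, projected
#' decoder feature map at the peer level.
#'
#' @param skip Skip-pathway feature map.
#' @param gating Decoder feature map, same spatial dims and channels.
#' @param params List with 1x1 conv parameters `Ws`, `Wg`, `psi` (from
#'   [unet_init()], `$attn[[l]]`).
#' @param cache Keep intermediates for backpropagation.
#' @return Gated feature map (same shape as `skip`).
#' @export
attention_gate <- function(skip, gating, params, cache = FALSE) {
  skip <- as_feature_map(skip)
  gating <- as_feature_map(gating)
  if (!identical(dim(skip), dim(gating))) {
    stop(sprintf("skip/gating shapes differ: %s vs %s",
                 paste(dim(skip), collapse = "x"),
                 paste(dim(gating), collapse = "x")))
  }
  cs <- conv_fwd(skip, params$Ws, cache = cache)
  cg <- conv_fwd(gating, params$Wg, cache = cache)
  qpre <- (if (cache) cs$y else cs) + (if (cache) cg$y else cg)
  q <- relu(qpre)
  cp <- conv_fwd(q, params$psi, cache = cache)
  alpha <- sigmoid(if (cache) cp$y else cp)
  y <- skip * c(alpha)
  if (!cache) return(y)
  list(y = y, alpha = alpha, cs = cs, cg = cg, cpsi = cp, q = q,
       skip = skip)
}

attention_gate_bwd <- function(dy, params, cache) {
  d <- dim(cache$skip)
  n <- d[1] * d[2]
  dskip <- dy * c(cache$alpha)
  dprod <- dy * cache$skip
  dim(dprod) <- c(n, d[3])
  dalpha <- array(rowSums(dprod), c(d[1], d[2], 1L))
  da <- dalpha * cache$alpha * (1 - cache$alpha)
  cbp <- conv_bwd(da, params$psi, cache$cpsi)
  dq <- cbp$dx * (cache$q > 0)
  cbs <- conv_bwd(dq, params$Ws, cache$cs)
  cbg <- conv_bwd(dq, params$Wg, cache$cg)
  list(dskip = dskip + cbs$dx, dgating = cbg$dx,
       grads = list(Ws = list(W = cbs$dW, b = cbs$db),
                    Wg = list(W = cbg$dW, b = cbg$db),
                    psi = list(W = cbp$dW, b = cbp$db)))
}

#' Assemble the skip pathway for one decoder level
#'
#' Applies the enabled blocks in the order MR, ATTN, CP and returns the
#' pathway that is concatenated with the decoder features. With every flag
#' off this is the identity on `skip` (plain UNet).
#'
#' @param skip Encoder skip feature map at this level.
#' @param decoder_up Upsampled + projected decoder feature map (peer level,
#'   same shape as `skip`).
#' @param deeper_enc Next-deeper encoder output (half resolution), used by
#'   the MR block.
#' @param config A [unet_config()].
#' @param params Level parameters: `mr` (1x1 conv) and/or `attn`
#'   (`Ws`/`Wg`/`psi`) as produced by [unet_init()].
#' @return Feature map with `skip`'s shape.
#' @export
assemble_skip_pathway <- function(skip, decoder_up, deeper_enc, config,
                                  params = list()) {
  pathway <- as_feature_map(skip)
  if (config$use_mr) {
    pathway <- multi_resolution_block(pathway, deeper_enc, params$mr)
  }
  if (config$use_attn) {
    pathway <- attention_gate(pathway, decoder_up, params$attn)
  }
  if (config$use_cp) {
    pathway <- competitive_block(pathway, decoder_up)
  }
  pathway
}

#' UNet forward pass
#'
#' @param image Normalized input (`H x W` matrix or `H x W x C` array),
#'   spatial dims divisible by `2^depth`.
#' @param params Weights from [unet_init()].
#' @param config The matching [unet_config()].
#' @param cache Keep intermediates for backpropagation.
#' @return `H x W` matrix of foreground probabilities in `(0, 1)` (or a
#'   list with `prob` and `cache`).
#' @export
unet_forward <- function(image, params, config, cache = FALSE) {
  x <- as_feature_map(image)
  d <- dim(x)
  div <- 2L^config$depth
  if (d[1] %% div != 0L || d[2] %% div != 0L) {
    stop(sprintf("input dims %dx%d must be divisible by %d (2^depth)",
                 d[1], d[2], div))
  }
  depth <- config$depth
  K <- list() # caches
  enc_out <- vector("list", depth)
  pools <- vector("list", depth)
  ecache <- vector("list", depth)
  h <- x
  for (l in seq_len(depth)) {
    c1 <- conv_fwd(h, params$enc[[l]]$conv1, cache = TRUE)
    a1 <- relu(c1$y)
    c2 <- conv_fwd(a1, params$enc[[l]]$conv2, cache = TRUE)
    a2 <- relu(c2$y)
    enc_out[[l]] <- a2
    ecache[[l]] <- list(c1 = c1, a1 = a1, c2 = c2)
    pl <- maxpool2_fwd(a2)
    pools[[l]] <- pl
    h <- pl$y
  }
  b1 <- conv_fwd(h, params$bott$conv1, cache = TRUE)
  ba1 <- relu(b1$y)
  b2 <- conv_fwd(ba1, params$bott$conv2, cache = TRUE)
  bott_out <- relu(b2$y)
  K$bott <- list(c1 = b1, a1 = ba1, c2 = b2, out = bott_out)
  deep <- bott_out
  dcache <- vector("list", depth)
  for (l in rev(seq_len(depth))) {
    up <- upsample2_fwd(deep)
    gproj <- conv_fwd(up, params$dec[[l]]$up_proj, cache = TRUE)
    g <- gproj$y
    pathway <- enc_out[[l]]
    lc <- list(gproj = gproj)
    if (config$use_mr) {
      deeper <- if (l < depth) enc_out[[l + 1L]] else bott_out
      mr <- multi_resolution_block(pathway, deeper, params$mr[[l]],
                                   cache = TRUE)
      pathway <- mr$y
      lc$mr <- mr
    }
    if (config$use_attn) {
      ag <- attention_gate(pathway, g, params$attn[[l]], cache = TRUE)
      pathway <- ag$y
      lc$attn <- ag
    }
    if (config$use_cp) {
      lc$cp_mask <- pathway >= g
      pathway <- pmax(pathway, g)
    }
    cat_in <- concat_maps(pathway, g)
    d1 <- conv_fwd(cat_in, params$dec[[l]]$conv1, cache = TRUE)
    da1 <- relu(d1$y)
    d2 <- conv_fwd(da1, params$dec[[l]]$conv2, cache = TRUE)
    deep <- relu(d2$y)
    lc$c1 <- d1
    lc$a1 <- da1
    lc$c2 <- d2
    lc$out <- deep
    dcache[[l]] <- lc
  }
  fin <- conv_fwd(deep, params$final, cache = TRUE)
  prob <- sigmoid(fin$y[, , 1])
  if (!cache) return(prob)
  list(prob = prob,
       cache = list(enc_out = enc_out, pools = pools, ecache = ecache,
                    bott = K$bott, dcache = dcache, fin = fin,
                    depth = depth))
}

# Backward pass. `dprob` is the loss gradient at the probability map
# (H x W matrix). Returns parameter gradients mirroring unet_init().
unet_backward <- function(dprob, prob, params, config, cache) {
  depth <- cache$depth
  dlogit <- dprob * prob * (1 - prob)
  dlogit <- array(dlogit, c(dim(prob), 1L))
  fb <- conv_bwd(dlogit, params$final, cache$fin)
  grads <- list(final = list(W = fb$dW, b = fb$db),
                enc = vector("list", depth),
                dec = vector("list", depth))
  if (config$use_mr) grads$mr <- vector("list", depth)
  if (config$use_attn) grads$attn <- vector("list", depth)
  denc <- vector("list", depth) # accumulated grads w.r.t. enc_out
  dbott <- NULL
  ddeep <- fb$dx # grad w.r.t. decoder output at level 1
  for (l in seq_len(depth)) {
    lc <- cache$dcache[[l]]
    dd2 <- ddeep * (lc$out > 0)
    b2 <- conv_bwd(dd2, params$dec[[l]]$conv2, lc$c2)
    dd1 <- b2$dx * (lc$a1 > 0)
    b1 <- conv_bwd(dd1, params$dec[[l]]$conv1, lc$c1)
    ch <- params$dec[[l]]$conv2$c_out
    dpathway <- b1$dx[, , seq_len(ch), drop = FALSE]
    dg <- b1$dx[, , ch + seq_len(ch), drop = FALSE]
    if (config$use_cp) {
      dg <- dg + dpathway * !lc$cp_mask
      dpathway <- dpathway * lc$cp_mask
    }
    if (config$use_attn) {
      ab <- attention_gate_bwd(dpathway, params$attn[[l]], lc$attn)
      dpathway <- ab$dskip
      dg <- dg + ab$dgating
      grads$attn[[l]] <- ab$grads
    }
    if (config$use_mr) {
      mb <- multi_resolution_bwd(dpathway, params$mr[[l]], lc$mr)
      dpathway <- mb$dshallow
      grads$mr[[l]] <- mb$grads
      if (l < depth) {
        denc[[l + 1L]] <- acc_grads(denc[[l + 1L]], mb$ddeep)
      } else {
        dbott <- acc_grads(dbott, mb$ddeep)
      }
    }
    denc[[l]] <- acc_grads(denc[[l]], dpathway)
    ub <- conv_bwd(dg, params$dec[[l]]$up_proj, lc$gproj)
    dup <- upsample2_bwd(ub$dx)
    if (l < depth) {
      ddeep <- dup # grad w.r.t. decoder output at level l + 1
    } else {
      dbott <- acc_grads(dbott, dup)
    }
    grads$dec[[l]] <- list(up_proj = list(W = ub$dW, b = ub$db),
                           conv1 = list(W = b1$dW, b = b1$db),
                           conv2 = list(W = b2$dW, b = b2$db))
  }
  bo <- cache$bott
  db2 <- dbott * (bo$out > 0)
  bb2 <- conv_bwd(db2, params$bott$conv2, bo$c2)
  db1 <- bb2$dx * (bo$a1 > 0)
  bb1 <- conv_bwd(db1, params$bott$conv1, bo$c1)
  grads$bott <- list(conv1 = list(W = bb1$dW, b = bb1$db),
                     conv2 = list(W = bb2$dW, b = bb2$db))
  dpool_in <- bb1$dx
  for (l in rev(seq_len(depth))) {
    denc[[l]] <- acc_grads(denc[[l]], maxpool2_bwd(dpool_in, cache$pools[[l]]))
    ec <- cache$ecache[[l]]
    de2 <- denc[[l]] * (cache$enc_out[[l]] > 0)
    eb2 <- conv_bwd(de2, params$enc[[l]]$conv2, ec$c2)
    de1 <- eb2$dx * (ec$a1 > 0)
    eb1 <- conv_bwd(de1, params$enc[[l]]$conv1, ec$c1)
    grads$enc[[l]] <- list(conv1 = list(W = eb1$dW, b = eb1$db),
                           conv2 = list(W = eb2$dW, b = eb2$db))
    dpool_in <- eb1$dx
  }
  grads
}

#' Build segmentation samples from a phantom volume
#'
#' One sample per slice inside the lung range `[lung_first, lung_last]`
#' (the range the localizer hands to the segmenter), pairing the slice with
#' its SAT or VAT mask.
#'
#' @param volume A `phantom_volume` (or list with `slices`, `loc_labels`,
#'   `sat_masks`, `vat_masks`).
#' @param tissue `"SAT"` or `"VAT"`.
#' @param range Optional `c(first, last)` 0-based slice range; defaults to
#'   the labeled lung range.
#' @return List of `seg_sample` objects (fields `image`, `mask`, `tissue`).
#' @export
make_seg_samples <- function(volume, tissue = c("SAT", "VAT"),
                             range = NULL) {
  tissue <- match.arg(tissue)
  masks <- if (tissue == "SAT") volume$sat_masks else volume$vat_masks
  if (is.null(range)) {
    range <- c(which(volume$loc_labels == LBL_FIRST) - 1L,
               which(volume$loc_labels == LBL_LAST) - 1L)
  }
  idx <- (range[1] + 1L):(range[2] + 1L)
  lapply(idx, function(i) {
    m <- masks[[i]]
    if (!all(m %in% c(0L, 1L))) stop("mask must be binary")
    structure(list(image = volume$slices[[i]], mask = m, tissue = tissue),
              class = "seg_sample")
  })
}

#' Train the segmenter
#'
#' Pure stochastic gradient descent with momentum (`beta`, default 0.9),
#' one update per sample, minimizing the smoothed Dice loss
#' `DCL = 1 - (kappa + 2*sum(t*p)) / (kappa + sum(t^2) + sum(p^2))`. When
#' `loss$use_weight_penalty` is on, the foreground-class penalty from
#' [compute_class_weights()] over the training set's pixel counts is added
#' to every sample's loss; being a per-sample constant it shifts the
#' reported loss, not the gradients.
#'
#' @param samples List of `seg_sample` objects ([make_seg_samples()]).
#' @param config A [unet_config()].
#' @param loss A [loss_config()].
#' @param epochs Maximum training epochs.
#' @param lr,beta SGD learning rate and momentum.
#' @param dice_target Early-stop once the epoch's mean training Dice
#'   (binarized at `threshold`) reaches this value; `NULL` runs all epochs.
#' @param threshold Binarization threshold for the training Dice.
#' @param normalization Input normalization (`"MaxMinNorm"` or
#'   `"MaxIntensity"`).
#' @param seed Seed for initialization and shuffling.
#' @param verbose Print one line per epoch.
#' @return A `segmenter_model` (fields `config`, `loss`, `params`,
#'   `normalization`, `threshold`, `history`).
#' @export
train_segmenter <- function(samples, config, loss = loss_config(),
                            epochs = 50L, lr = 0.05, beta = 0.9,
                            dice_target = NULL, threshold = 0.5,
                            normalization = "MaxMinNorm", seed = 1L,
                            verbose = FALSE) {
  stopifnot(inherits(config, "unet_config"))
  nf <- norm_fun(normalization)
  inputs <- lapply(samples, function(s) nf(s$image))
  masks <- lapply(samples, function(s) s$mask)
  W_pen <- 0
  if (isTRUE(loss$use_weight_penalty)) {
    fg <- sum(vapply(masks, sum, numeric(1)))
    tot <- sum(vapply(masks, length, numeric(1)))
    cw <- compute_class_weights(c(pmax(tot - fg, 1), pmax(fg, 1)),
                                alpha = loss$alpha)
    W_pen <- cw$W[2]
  }
  params <- unet_init(config, seed = seed)
  vel <- NULL
  hist <- data.frame()
  with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample(length(samples))
      ep_loss <- numeric(length(ord))
      ep_dice <- numeric(length(ord))
      for (ii in seq_along(ord)) {
        i <- ord[ii]
        fw <- unet_forward(inputs[[i]], params, config, cache = TRUE)
        p <- fw$prob
        t <- masks[[i]]
        stp <- sum(t * p)
        denom <- loss$kappa + sum(t * t) + sum(p * p)
        dc <- (loss$kappa + 2 * stp) / denom
        ep_loss[ii] <- (1 - dc) + W_pen
        ep_dice[ii] <- dice_coefficient(t, (p >= threshold) + 0, kappa = 1)
        dprob <- -(2 * t * denom - (loss$kappa + 2 * stp) * 2 * p) / denom^2
        grads <- unet_backward(dprob, p, params, config, fw$cache)
        st <- sgd_momentum_step(params, grads, vel, lr, beta)
        params <- st$p
        vel <- st$v
      }
      hist <- rbind(hist, data.frame(epoch = ep, loss = mean(ep_loss),
                                     dice = mean(ep_dice)))
      if (verbose) {
        message(sprintf("epoch %d: loss %.4f dice %.4f",
                        ep, mean(ep_loss), mean(ep_dice)))
      }
      if (!is.null(dice_target) && mean(ep_dice) >= dice_target) break
    }
  })
  structure(
    list(config = config, loss = loss, params = params,
         normalization = normalization, threshold = threshold,
         history = hist),
    class = "segmenter_model"
  )
}

#' Predict a tissue mask for one slice
#'
#' @param model A trained `segmenter_model`.
#' @param slice A [ct_slice()] (or an already normalized matrix).
#' @return List with `prob` (probability matrix in `(0,1)`) and `mask`
#'   (binary matrix at the model's threshold).
#' @export
predict_mask <- function(model, slice) {
  stopifnot(inherits(model, "segmenter_model"))
  x <- if (inherits(slice, "ct_slice")) {
    norm_fun(model$normalization)(slice)
  } else {
    slice
  }
  p <- unet_forward(x, model$params, model$config)
  list(prob = p, mask = matrix(as.integer(p >= model$threshold), nrow(p)))
}

#' Evaluate a segmenter on held-out samples
#'
#' Metrics are computed per image on the binarized prediction and averaged
#' over the sample list.
#'
#' @param model A trained `segmenter_model`.
#' @param samples List of `seg_sample` objects.
#' @return A `metrics_report` (see [confusion_metrics()]).
#' @export
evaluate_segmenter <- function(model, samples) {
  reps <- lapply(samples, function(s) {
    pr <- predict_mask(model, s$image)
    confusion_metrics(s$mask, pr$mask)
  })
  avg <- function(f) mean(vapply(reps, function(r) r[[f]], numeric(1)))
  structure(
    list(dice = avg("dice"), f1 = avg("f1"), precision = avg("precision"),
         recall = avg("recall"), n_samples = length(samples)),
    class = "metrics_report"
  )
}
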