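test_that("all eight block combinations preserve shape and (0,1) range", {
  set.seed(31)
  x <- matrix(runif(32 * 32), 32, 32)
  for (mr in c(FALSE, TRUE)) {
    for (cp in c(FALSE, TRUE)) {
      for (at in c(FALSE, TRUE)) {
        cfg <- unet_config(use_mr = mr, use_cp = cp, use_attn = at,
                           depth = 3L, base_channels = 4L)
        p <- unet_forward(x, unet_init(cfg, seed = 7L), cfg)
        expect_equal(dim(p), c(32L, 32L))
        expect_true(all(p > 0 & p < 1))
      }
    }
  }
})

test_that("indivisible input dims raise a dimension error", {
  cfg <- unet_config(depth = 4L, base_channels = 2L)
  expect_error(
    unet_forward(matrix(0.5, 24, 24), unet_init(cfg, seed = 1L), cfg),
    "divisible by 16")
})

test_that("a zeroed output head yields the uniform 0.5 map", {
  cfg <- unet_config(depth = 2L, base_channels = 2L)
  params <- unet_init(cfg, seed = 2L)
  params$final$W[] <- 0
  params$final$b[] <- 0
  p <- unet_forward(matrix(runif(64), 8, 8), params, cfg)
  expect_equal(p, matrix(0.5, 8, 8))
})

test_that("competitive block is the brute-force elementwise max", {
  expect_equal(competitive_block(array(c(1, -2), c(1, 2, 1)),
                                 array(c(0, 5), c(1, 2, 1))),
               array(c(1, 5), c(1, 2, 1)))
  a <- array(rnorm(48), c(4, 4, 3))
  expect_equal(competitive_block(a, a), a)
  set.seed(32)
  for (i in 1:10) {
    a <- array(rnorm(48), c(4, 4, 3))
    b <- array(rnorm(48), c(4, 4, 3))
    m <- competitive_block(a, b)
    ref <- a
    for (j in seq_along(ref)) ref[j] <- max(a[j], b[j])
    expect_equal(m, ref)
    expect_true(all(m >= a & m >= b))
  }
  expect_error(competitive_block(array(0, c(2, 2, 1)),
                                 array(0, c(2, 2, 2))),
               "2x2x1 vs 2x2x2")
})

test_that("multi-resolution block upsamples, projects and adds", {
  set.seed(33)
  proj <- conv_param(16, 8, 1L)
  shallow <- array(rnorm(32 * 32 * 8), c(32, 32, 8))
  deep0 <- array(0, c(16, 16, 16))
  expect_equal(multi_resolution_block(shallow, deep0, proj), shallow)
  deep <- array(rnorm(16 * 16 * 16), c(16, 16, 16))
  out <- multi_resolution_block(shallow, deep, proj)
  expect_equal(dim(out), c(32L, 32L, 8L))
  # scalar 1x1 oracle: out = a + w * b
  pr <- conv_param(1, 1, 1L)
  a <- array(2, c(2, 2, 1))
  b <- array(3, c(1, 1, 1))
  got <- multi_resolution_block(a, b, pr)
  expect_equal(c(got), rep(2 + pr$W[1, 1] * 3 + pr$b, 4), tolerance = 1e-12)
  expect_error(multi_resolution_block(array(0, c(24, 24, 1)),
                                      array(0, c(9, 9, 1)), pr),
               "power of two")
})

test_that("attention gate interpolates between closed and open", {
  set.seed(34)
  ch <- 4L
  ap <- list(Ws = conv_param(ch, 2L, 1L), Wg = conv_param(ch, 2L, 1L),
             psi = conv_param(2L, 1L, 1L))
  skip <- array(rnorm(64 * ch), c(8, 8, ch))
  gating <- array(rnorm(64 * ch), c(8, 8, ch))
  out <- attention_gate(skip, gating, ap)
  expect_true(all(abs(out) <= abs(skip) + 1e-12)) # |alpha| < 1
  ap_closed <- ap
  ap_closed$psi$W[] <- 0
  ap_closed$psi$b[] <- -50
  expect_equal(attention_gate(skip, gating, ap_closed),
               skip * 0, tolerance = 1e-12)
  ap_open <- ap
  ap_open$psi$W[] <- 0
  ap_open$psi$b[] <- 50
  expect_equal(attention_gate(skip, gating, ap_open), skip,
               tolerance = 1e-9)
  # scalar oracle
  sp <- list(Ws = conv_param(1, 1, 1L), Wg = conv_param(1, 1, 1L),
             psi = conv_param(1, 1, 1L))
  s <- array(0.7, c(1, 1, 1)); g <- array(-0.2, c(1, 1, 1))
  q <- max(sp$Ws$W[1] * 0.7 + sp$Ws$b + sp$Wg$W[1] * -0.2 + sp$Wg$b, 0)
  alpha <- 1 / (1 + exp(-(sp$psi$W[1] * q + sp$psi$b)))
  expect_equal(c(attention_gate(s, g, sp)), alpha * 0.7, tolerance = 1e-12)
})

test_that("skip pathway assembly respects the configuration", {
  set.seed(35)
  skip <- array(rnorm(32), c(4, 4, 2))
  g <- array(rnorm(32), c(4, 4, 2))
  deeper <- array(rnorm(16), c(2, 2, 4))
  cfg_none <- unet_config()
  expect_equal(assemble_skip_pathway(skip, g, deeper, cfg_none), skip)
  cfg_cp <- unet_config(use_cp = TRUE)
  expect_equal(assemble_skip_pathway(skip, skip, deeper, cfg_cp), skip)
  cfg_all <- unet_config(use_mr = TRUE, use_cp = TRUE, use_attn = TRUE)
  params <- list(mr = conv_param(4, 2, 1L),
                 attn = list(Ws = conv_param(2, 1, 1L),
                             Wg = conv_param(2, 1, 1L),
                             psi = conv_param(1, 1, 1L)))
  out <- assemble_skip_pathway(skip, g, deeper, cfg_all, params)
  expect_equal(dim(out), dim(skip))
})

test_that("training reduces the Dice loss on a tiny problem", {
  v <- fixture_volume()
  samples <- make_seg_samples(v, "SAT")[1:4]
  cfg <- unet_config(depth = 2L, base_channels = 4L)
  m <- train_segmenter(samples, cfg, epochs = 8L, lr = 0.3, seed = 5L)
  expect_lt(tail(m$history$loss, 1), m$history$loss[1])
  pr <- predict_mask(m, samples[[1]]$image)
  expect_equal(dim(pr$prob), c(32L, 32L))
  expect_true(all(pr$mask %in% c(0L, 1L)))
})

test_that("seg samples pair lung-range slices with binary masks", {
  v <- fixture_volume()
  s <- make_seg_samples(v, "SAT")
  expect_length(s, 6) # slices 3..8
  expect_true(all(vapply(s, function(x) all(x$mask %in% 0:1), logical(1))))
  expect_identical(dim(s[[1]]$mask),
                   c(s[[1]]$image$height, s[[1]]$image$width))
  s2 <- make_seg_samples(v, "VAT", range = c(0L, 2L))
  expect_length(s2, 3)
})
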