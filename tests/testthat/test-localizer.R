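test_that("zeroed gates halve the previous hidden state", {
  p <- conv_gru_params(1, 2, 3)
  p$Wz$W[] <- 0; p$Wz$b[] <- 0
  p$Wr$W[] <- 0; p$Wr$b[] <- 0
  p$Wh$W[] <- 0; p$Wh$b[] <- 0
  h_prev <- array(rnorm(32), c(4, 4, 2))
  x <- matrix(rnorm(16), 4, 4)
  h <- gru_cell_step(x, h_prev, p)
  # z = sigma(0) = 0.5, candidate tanh(0) = 0, so h = 0.5 * h_prev
  expect_equal(h, 0.5 * h_prev, tolerance = 1e-12)
})

test_that("a saturated update gate fully replaces the state", {
  p <- conv_gru_params(1, 1, 1)
  p$Wz$W[] <- 0; p$Wz$b[] <- 50 # z -> 1
  h_prev <- array(5, c(3, 3, 1))
  x <- matrix(0.3, 3, 3)
  h <- gru_cell_step(x, h_prev, p)
  r <- plogis(p$Wr$W[1] * 5 + p$Wr$W[2] * 0.3 + p$Wr$b)
  hc <- tanh(p$Wh$W[1] * (r * 5) + p$Wh$W[2] * 0.3 + p$Wh$b)
  expect_equal(c(h), rep(hc, 9), tolerance = 1e-9)
})

test_that("1x1-kernel cells match the per-pixel scalar oracle", {
  set.seed(21)
  for (trial in 1:20) {
    p <- conv_gru_params(2, 3, 1)
    x <- array(rnorm(2 * 2 * 2), c(2, 2, 2))
    h <- array(rnorm(2 * 2 * 3), c(2, 2, 3))
    for (lit in c(FALSE, TRUE)) {
      expect_equal(gru_cell_step(x, h, p, literal_eq3 = lit),
                   scalar_gru_oracle(x, h, p, lit), tolerance = 1e-6)
    }
  }
})

test_that("the new state lies between the old state and the candidate", {
  set.seed(22)
  for (trial in 1:20) {
    p <- conv_gru_params(1, 2, 3)
    x <- matrix(rnorm(36), 6, 6)
    h_prev <- array(rnorm(72), c(6, 6, 2))
    st <- gru_cell_step(x, h_prev, p, cache = TRUE)
    lo <- pmin(h_prev, st$cache$hc)
    hi <- pmax(h_prev, st$cache$hc)
    expect_true(all(st$h >= lo - 1e-12 & st$h <= hi + 1e-12))
  }
})

test_that("cell rejects mismatched spatial dims", {
  p <- conv_gru_params(1, 2, 3)
  expect_error(
    gru_cell_step(matrix(0, 4, 4), array(0, c(6, 6, 2)), p),
    "input 4x4 vs hidden 6x6")
})

test_that("shared parameters make the two directions symmetric", {
  set.seed(23)
  p <- conv_gru_params(1, 2, 3)
  x <- matrix(runif(25), 5, 5)
  inputs <- list(x, x, x) # identical slices
  y <- bigru_forward(inputs, p, p)
  expect_equal(y[, , 1:2], y[, , 3:4], tolerance = 1e-12)
  # degenerate single-step window
  y1 <- bigru_forward(list(x), p, p)
  expect_equal(y1[, , 1:2], y1[, , 3:4], tolerance = 1e-12)
  expect_error(bigru_forward(list(), p, p), "empty")
})

test_that("a 3-step 1x1 recurrence matches a hand-unrolled scalar chain", {
  set.seed(24)
  p <- conv_gru_params(1, 1, 1)
  xs <- lapply(1:3, function(i) matrix(rnorm(1), 1, 1))
  step <- function(xv, hv) {
    z <- 1 / (1 + exp(-(p$Wz$W[1] * hv + p$Wz$W[2] * xv + p$Wz$b)))
    r <- 1 / (1 + exp(-(p$Wr$W[1] * hv + p$Wr$W[2] * xv + p$Wr$b)))
    hc <- tanh(p$Wh$W[1] * (r * hv) + p$Wh$W[2] * xv + p$Wh$b)
    (1 - z) * hv + z * hc
  }
  hf <- 0
  for (i in 1:3) hf <- step(xs[[i]][1], hf)
  hb <- 0
  for (i in 3:1) hb <- step(xs[[i]][1], hb)
  y <- bigru_forward(xs, p, p)
  expect_equal(c(y), c(hf, hb), tolerance = 1e-9)
})

test_that("window probabilities are a proper 3-class distribution", {
  v <- fixture_volume()
  cfg <- localizer_config(window_length = 5L, hidden_channels = 2L,
                          input_pool = 2L)
  model <- localizer_init(cfg, seed = 4L)
  w <- make_windows(v$slices, v$loc_labels, 5L)[[1]]
  pr <- classify_window(w, model)
  expect_length(pr, 3)
  expect_equal(sum(pr), 1, tolerance = 1e-6)
  expect_true(all(pr > 0 & pr < 1))
  # zeroed head -> uniform prediction
  model$params$head$W[] <- 0
  model$params$head$b[] <- 0
  expect_equal(classify_window(w, model), rep(1 / 3, 3), tolerance = 1e-12)
  # window length mismatch is a configuration error
  w3 <- make_windows(v$slices, v$loc_labels, 3L)[[1]]
  expect_error(classify_window(w3, model), "configured for 5")
})

test_that("class-weight penalties follow the log formula and its range", {
  cw <- compute_class_weights(c(10))
  expect_equal(cw$normalized, 1)
  expect_equal(cw$W, 1 / log(2.1), tolerance = 1e-9)
  cw2 <- compute_class_weights(c(1, 1))
  expect_equal(cw2$W, rep(1 / log(1.6), 2), tolerance = 1e-9)
  cw3 <- compute_class_weights(c(320, 320, 60))
  expect_equal(which.max(cw3$W), 3) # rarest class, largest penalty
  expect_error(compute_class_weights(c(0, 5)), "positive")
  expect_error(compute_class_weights(c(5, 5), alpha = 1), "> 1")
  set.seed(25)
  for (i in 1:200) {
    n <- sample(2:6, 1)
    cw <- compute_class_weights(sample(1:1000, n))
    expect_true(all(cw$W > 1 / log(2.1) & cw$W < 1 / log(1.1)))
    expect_equal(sum(cw$normalized), 1, tolerance = 1e-9)
  }
})

test_that("mean distance converts index errors to millimetres", {
  expect_equal(mean_distance(10, 8, 2.5), 5.0)
  expect_equal(mean_distance(c(3, 7), c(1, 7), c(2, 5)), 2.0)
  expect_equal(mean_distance(c(4, 9), c(4, 9), 1.25), 0)
  expect_error(mean_distance(1:3, 1:2, 1), "mismatch")
  set.seed(26)
  for (i in 1:20) {
    p <- sample(0:20, 5); t <- sample(0:20, 5)
    md <- mean_distance(p, t, 2)
    expect_gte(md, 0)
    expect_equal(md == 0, all(p == t))
  }
})

test_that("balanced subsets are disjoint, exact and reproducible", {
  v <- fixture_volume()
  wins <- rep(make_windows(v$slices, v$loc_labels, 5L), 8) # 16 positives
  s1 <- balance_subsets(wins, 3, 5, seed = 9)
  s2 <- balance_subsets(wins, 3, 5, seed = 9)
  expect_identical(s1, s2)
  npos <- vapply(s1, function(s) {
    sum(vapply(s, function(w) w$label != 1L, logical(1)))
  }, numeric(1))
  expect_equal(npos, rep(5, 3))
  expect_error(balance_subsets(wins, 3, 20), "cannot balance")
  s3 <- balance_subsets(wins, 2, 4, subset_size = 10, seed = 1)
  expect_equal(lengths(s3), c(10L, 10L))
})
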