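test_that("softmax output is a valid probability map", {
  bcfg <- tiny_backbone()
  w <- init_backbone(bcfg, seed = 1)
  x <- matrix(runif(16 * 16), 16, 16)
  out <- backbone_forward(w, bcfg, x)
  sums <- apply(out$probs, c(1, 2), sum)
  expect_true(all(abs(sums - 1) < 1e-5))
  expect_true(all(out$probs >= 0 & out$probs <= 1))
  expect_error(backbone_forward(w, bcfg, matrix(0, 15, 15)), "divisible")
})

test_that("forward pass is deterministic without dropout, seeded with it", {
  bcfg <- tiny_backbone(dropout_rate = 0.5)
  w <- init_backbone(bcfg, seed = 1)
  x <- matrix(runif(16 * 16), 16, 16)
  a <- backbone_forward(w, bcfg, x, stochastic = FALSE)
  b <- backbone_forward(w, bcfg, x, stochastic = FALSE)
  expect_identical(a$probs, b$probs)
  s1 <- backbone_forward(w, bcfg, x, stochastic = TRUE, seed = 5)
  s1b <- backbone_forward(w, bcfg, x, stochastic = TRUE, seed = 5)
  s2 <- backbone_forward(w, bcfg, x, stochastic = TRUE, seed = 6)
  expect_identical(s1$probs, s1b$probs)
  expect_false(identical(s1$probs, s2$probs))
})

test_that("default backbone stays under 1e5 parameters", {
  expect_lt(backbone_num_params(backbone_config(base_width = 8, depth = 3)),
            1e5)
})

test_that("interior predictions are equivariant to full-stride shifts", {
  bcfg <- backbone_config(base_width = 4, depth = 1, dropout_rate = 0)
  w <- init_backbone(bcfg, seed = 4)
  set.seed(9)
  S <- 24
  x <- matrix(runif(S * S), S, S)
  stride <- 2^bcfg$depth  # one stride unit at the coarsest level
  xs <- matrix(0, S, S)
  xs[(stride + 1):S, ] <- x[1:(S - stride), ]
  y <- backbone_forward(w, bcfg, x)$logits
  ys <- backbone_forward(w, bcfg, xs)$logits
  # xs[i + stride, ] == x[i, ], so interior logits shift the same way;
  # stay clear of the receptive-field reach of the padded borders
  ii <- 9:(S - 10); jj <- 9:(S - 8)
  expect_lt(max(abs(y[ii, jj, , , drop = FALSE] -
                      ys[ii + stride, jj, , , drop = FALSE])), 1e-8)
})

test_that("initialization is seeded and cloneable", {
  bcfg <- tiny_backbone()
  w1 <- init_backbone(bcfg, seed = 3)
  w2 <- init_backbone(bcfg, seed = 3)
  expect_params_identical(w1, w2)
  w3 <- init_backbone(bcfg, seed = 4)
  expect_false(identical(w1$enc1_w, w3$enc1_w))
  cp <- clone_weights(w1)
  w1$enc1_w[1] <- 99
  expect_false(identical(cp$enc1_w[1], 99))
})

test_that("compiled convolution matches a naive sliding-window oracle", {
  set.seed(15)
  H <- 7; W <- 6; Cin <- 3; Cout <- 2; k <- 3; pad <- 1
  x <- array(rnorm(H * W * Cin * 2), c(H, W, Cin, 2))
  w <- array(rnorm(k * k * Cin * Cout), c(k, k, Cin, Cout))
  b <- rnorm(Cout)
  y <- pemt:::conv2d_fwd(x, w, b)
  # naive zero-padded cross-correlation
  ref <- array(0, c(H, W, Cout, 2))
  for (n in 1:2) for (co in 1:Cout) for (i in 1:H) for (j in 1:W) {
    acc <- b[co]
    for (ci in 1:Cin) for (kh in 1:k) for (kw in 1:k) {
      ii <- i + kh - 1 - pad; jj <- j + kw - 1 - pad
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        acc <- acc + x[ii, jj, ci, n] * w[kh, kw, ci, co]
    }
    ref[i, j, co, n] <- acc
  }
  expect_equal(y, ref, tolerance = 1e-12)
  # backward consistency: dw/db against finite differences of sum(y * dy)
  dy <- array(rnorm(length(y)), dim(y))
  g <- pemt:::conv2d_bwd(x, w, dy)
  f <- function(wv) sum(pemt:::conv2d_fwd(x, array(wv, dim(w)), b) * dy)
  for (ii in sample(length(w), 5)) {
    h <- 1e-6
    wp <- as.numeric(w); wp[ii] <- wp[ii] + h
    wm <- as.numeric(w); wm[ii] <- wm[ii] - h
    expect_equal(g$dw[ii], (f(wp) - f(wm)) / (2 * h), tolerance = 1e-5)
  }
  fx <- function(xv) sum(pemt:::conv2d_fwd(array(xv, dim(x)), w, b) * dy)
  for (ii in sample(length(x), 5)) {
    h <- 1e-6
    xp <- as.numeric(x); xp[ii] <- xp[ii] + h
    xm <- as.numeric(x); xm[ii] <- xm[ii] - h
    expect_equal(g$dx[ii], (fx(xp) - fx(xm)) / (2 * h), tolerance = 1e-5)
  }
})
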