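# Compact 2D U-Net style encoder-decoder used for both the student and the
# teacher. The network is deliberately tiny (default < 1e5 parameters) so
# that full semi-supervised training runs finish in minutes on one CPU.
# Forward and backward passes are written out explicitly: convolutions run
# through the compiled kernels in src/conv_ops.cpp, everything else
# (pooling, nearest-neighbour upsampling, ReLU, dropout, softmax) is
# vectorised R on (H, W, C, N) arrays.

#' Backbone architecture configuration
#'
#' One encoder-decoder with `depth` 2x2 mean-pool downsamplings, channel
#' widths doubling per level from `base_width`, skip connections by channel
#' concatenation, nearest-neighbour upsampling, and a 1x1 output convolution
#' followed by a per-pixel softmax over `num_classes` channels. Dropout sits
#' at the two deepest levels (bottleneck and deepest decoder stage) so
#' Monte-Carlo passes perturb semantic features rather than raw edges.
#'
#' @param in_channels input image channels (default 1, grayscale)
#' @param num_classes number of softmax classes `C >= 2` (default 2)
#' @param base_width channels at the first level (default 8)
#' @param depth number of downsamplings (default 3); input height and width
#'   must be divisible by `2^depth`
#' @param dropout_rate dropout probability in `[0, 1)` (default 0.5)
#' @return an object of class `backbone_config`
#' @export
backbone_config <- function(in_channels = 1L, num_classes = 2L,
                            base_width = 8L, depth = 3L,
                            dropout_rate = 0.5) {
  if (num_classes < 2) stop("`num_classes` must be >= 2", call. = FALSE)
  if (depth < 1) stop("`depth` must be >= 1", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("`dropout_rate` must lie in [0, 1)", call. = FALSE)
  structure(list(in_channels = as.integer(in_channels),
                 num_classes = as.integer(num_classes),
                 base_width = as.integer(base_width),
                 depth = as.integer(depth),
                 dropout_rate = dropout_rate),
            class = "backbone_config")
}

bb_widths <- function(config) {
  w <- config$base_width * 2^(seq_len(config$depth) - 1L)
  list(enc = as.integer(w), bot = as.integer(config$base_width * 2^config$depth))
}

#' Initialize backbone weights
#'
#' He-style initialization: each kernel element drawn from
#' `N(0, 2 / (k^2 * c_in))`, biases zero.
#'
#' @param config a [backbone_config()]
#' @param seed integer seed for reproducible initialization
#' @return a parameter set: named, ordered list of numeric arrays
#' @export
init_backbone <- function(config, seed = 1L) {
  wd <- bb_widths(config)
  mk <- function(k, cin, cout)
    array(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
          dim = c(k, k, cin, cout))
  with_seed(seed, {
    p <- list()
    cin <- config$in_channels
    for (i in seq_len(config$depth)) {
      p[[paste0("enc", i, "_w")]] <- mk(3, cin, wd$enc[i])
      p[[paste0("enc", i, "_b")]] <- numeric(wd$enc[i])
      cin <- wd$enc[i]
    }
    p$bot_w <- mk(3, cin, wd$bot)
    p$bot_b <- numeric(wd$bot)
    up <- wd$bot
    for (i in rev(seq_len(config$depth))) {
      p[[paste0("dec", i, "_w")]] <- mk(3, up + wd$enc[i], wd$enc[i])
      p[[paste0("dec", i, "_b")]] <- numeric(wd$enc[i])
      up <- wd$enc[i]
    }
    p$out_w <- mk(1, wd$enc[1], config$num_classes)
    p$out_b <- numeric(config$num_classes)
    p
  })
}

#' Total number of trainable parameters
#' @param config a [backbone_config()]
#' @return integer parameter count
#' @export
backbone_num_params <- function(config) {
  sum(vapply(init_backbone(config, seed = 0L), length, integer(1)))
}

# ---- array layer primitives ----------------------------------------------

softmax_channels <- function(z) {
  d <- dim(z); C <- d[3]
  ch <- function(a, c) array(a[, , c, , drop = FALSE], d[c(1, 2, 4)])
  mx <- ch(z, 1)
  for (c in seq_len(C)[-1]) mx <- pmax(mx, ch(z, c))
  e <- array(0, d)
  s <- array(0, d[c(1, 2, 4)])
  for (c in seq_len(C)) {
    e[, , c, ] <- exp(ch(z, c) - mx)
    s <- s + ch(e, c)
  }
  for (c in seq_len(C)) e[, , c, ] <- ch(e, c) / s
  e
}

meanpool2 <- function(a) {
  d <- dim(a)
  io <- seq(1, d[1], 2); jo <- seq(1, d[2], 2)
  (a[io, jo, , , drop = FALSE] + a[io + 1, jo, , , drop = FALSE] +
     a[io, jo + 1, , , drop = FALSE] + a[io + 1, jo + 1, , , drop = FALSE]) / 4
}

upsample2 <- function(a) {
  d <- dim(a)
  a[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
    drop = FALSE]
}

concat_channels <- function(u, e) {
  du <- dim(u); de <- dim(e)
  o <- array(0, c(du[1], du[2], du[3] + de[3], du[4]))
  o[, , seq_len(du[3]), ] <- u
  o[, , du[3] + seq_len(de[3]), ] <- e
  o
}

#' Forward pass of the backbone
#'
#' @param weights parameter set from [init_backbone()]
#' @param config the matching [backbone_config()]
#' @param x matrix, list of matrices, or `(H, W, C, N)` array; spatial
#'   dimensions must be divisible by `2^depth`
#' @param stochastic logical; activate (seeded) dropout. With
#'   `stochastic = FALSE` the pass is deterministic.
#' @param seed integer seed for the dropout masks (ignored when
#'   deterministic)
#' @param want_cache keep intermediate activations for a backward pass
#'   (internal use by the trainer)
#' @return list with `probs` (`(H, W, C, N)` softmax output), `logits`, and
#'   optionally `cache`
#' @export
backbone_forward <- function(weights, config, x, stochastic = FALSE,
                             seed = NULL, want_cache = FALSE) {
  xb <- as_image_batch(x, config$in_channels)
  d <- dim(xb)
  if (d[1] %% 2^config$depth != 0 || d[2] %% 2^config$depth != 0)
    stop("spatial dims must be divisible by 2^depth", call. = FALSE)
  depth <- config$depth
  rate <- if (stochastic) config$dropout_rate else 0
  wd <- bb_widths(config)

  # pre-draw the dropout masks (inverted scaling) under the given seed
  masks <- NULL
  if (rate > 0) {
    hb <- d[1] / 2^depth; wb <- d[2] / 2^depth
    hd <- d[1] / 2^(depth - 1); wdd <- d[2] / 2^(depth - 1)
    masks <- with_seed(seed, list(
      bot = array((runif(hb * wb * wd$bot * d[4]) >= rate) / (1 - rate),
                  c(hb, wb, wd$bot, d[4])),
      dec = array((runif(hd * wdd * wd$enc[depth] * d[4]) >= rate) / (1 - rate),
                  c(hd, wdd, wd$enc[depth], d[4]))))
  }

  cache <- list(x = xb, masks = masks)
  a <- xb
  for (i in seq_len(depth)) {
    z <- conv2d_fwd(a, weights[[paste0("enc", i, "_w")]],
                    weights[[paste0("enc", i, "_b")]])
    e <- z * (z > 0)
    cache[[paste0("enc", i, "_in")]] <- a
    cache[[paste0("enc", i, "_z")]] <- z
    cache[[paste0("skip", i)]] <- e
    a <- meanpool2(e)
  }
  zb <- conv2d_fwd(a, weights$bot_w, weights$bot_b)
  b <- zb * (zb > 0)
  if (!is.null(masks)) b <- b * masks$bot
  cache$bot_in <- a; cache$bot_z <- zb
  dcur <- b
  for (i in rev(seq_len(depth))) {
    u <- upsample2(dcur)
    ct <- concat_channels(u, cache[[paste0("skip", i)]])
    z <- conv2d_fwd(ct, weights[[paste0("dec", i, "_w")]],
                    weights[[paste0("dec", i, "_b")]])
    dd <- z * (z > 0)
    if (i == depth && !is.null(masks)) dd <- dd * masks$dec
    cache[[paste0("dec", i, "_in")]] <- ct
    cache[[paste0("dec", i, "_z")]] <- z
    dcur <- dd
  }
  cache$out_in <- dcur
  logits <- conv2d_fwd(dcur, weights$out_w, weights$out_b)
  probs <- softmax_channels(logits)
  out <- list(probs = probs, logits = logits)
  if (want_cache) out$cache <- cache
  out
}

# Backward pass: gradient of a scalar loss w.r.t. every weight, given the
# gradient w.r.t. the logits. Returns a parameter set of gradients.
backbone_backward <- function(weights, config, cache, dlogits) {
  depth <- config$depth
  wd <- bb_widths(config)
  g <- list()

  bw <- conv2d_bwd(cache$out_in, weights$out_w, dlogits)
  g$out_w <- bw$dw; g$out_b <- bw$db
  dd <- bw$dx
  dskip <- vector("list", depth)
  for (i in seq_len(depth)) {
    if (i == depth && !is.null(cache$masks)) dd <- dd * cache$masks$dec
    dz <- dd * (cache[[paste0("dec", i, "_z")]] > 0)
    bw <- conv2d_bwd(cache[[paste0("dec", i, "_in")]],
                     weights[[paste0("dec", i, "_w")]], dz)
    g[[paste0("dec", i, "_w")]] <- bw$dw
    g[[paste0("dec", i, "_b")]] <- bw$db
    up_c <- if (i == depth) wd$bot else wd$enc[i + 1]
    du <- bw$dx[, , seq_len(up_c), , drop = FALSE]
    dskip[[i]] <- bw$dx[, , up_c + seq_len(wd$enc[i]), , drop = FALSE]
    dd <- meanpool2(du) * 4  # backward of nearest-neighbour upsampling
  }
  if (!is.null(cache$masks)) dd <- dd * cache$masks$bot
  dz <- dd * (cache$bot_z > 0)
  bw <- conv2d_bwd(cache$bot_in, weights$bot_w, dz)
  g$bot_w <- bw$dw; g$bot_b <- bw$db
  da <- bw$dx
  for (i in rev(seq_len(depth))) {
    de <- dskip[[i]] + upsample2(da) / 4  # backward of mean pooling
    dz <- de * (cache[[paste0("enc", i, "_z")]] > 0)
    bw <- conv2d_bwd(cache[[paste0("enc", i, "_in")]],
                     weights[[paste0("enc", i, "_w")]], dz)
    g[[paste0("enc", i, "_w")]] <- bw$dw
    g[[paste0("enc", i, "_b")]] <- bw$db
    da <- bw$dx
  }
  g[names(weights)]
}
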