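# Independent reference implementations used as oracles. These deliberately
# avoid the code paths (and where possible the primitives) of the package:
# the modulus oracle uses repeated subtraction instead of floor(), and the
# surface-distance oracle uses explicit all-pairs loops instead of a
# distance transform.

# floored modulus by repeated subtraction; result sign follows b
mod_scalar_ref <- function(a, b, eps = 1e-8) {
  if (abs(b) < eps) return(0)
  r <- a
  if (b > 0) {
    while (r >= b) r <- r - b
    while (r < 0) r <- r + b
  } else {
    while (r <= b) r <- r - b
    while (r > 0) r <- r + b
  }
  r
}

# surface pixels by explicit neighbour checks
surface_ref <- function(m) {
  m <- m != 0
  H <- nrow(m); W <- ncol(m)
  s <- matrix(FALSE, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (!m[i, j]) next
    # 4-neighbours; outside the image counts as background
    nb <- c(if (i > 1) m[i - 1, j] else FALSE,
            if (i < H) m[i + 1, j] else FALSE,
            if (j > 1) m[i, j - 1] else FALSE,
            if (j < W) m[i, j + 1] else FALSE)
    s[i, j] <- any(!nb) || i == 1 || i == H || j == 1 || j == W
  }
  s
}

# directed distances from surface(p) to surface(y), all pairs
directed_dists_ref <- function(p, y, spacing = c(1, 1)) {
  a <- which(surface_ref(p), arr.ind = TRUE)
  b <- which(surface_ref(y), arr.ind = TRUE)
  vapply(seq_len(nrow(a)), function(i) {
    min(sqrt(((a[i, 1] - b[, 1]) * spacing[1])^2 +
               ((a[i, 2] - b[, 2]) * spacing[2])^2))
  }, numeric(1))
}

hd_ref <- function(p, y, spacing = c(1, 1), percentile = 95) {
  max(quantile(directed_dists_ref(p, y, spacing), percentile / 100,
               names = FALSE),
      quantile(directed_dists_ref(y, p, spacing), percentile / 100,
               names = FALSE))
}

asd_ref <- function(p, y, spacing = c(1, 1)) {
  mean(directed_dists_ref(p, y, spacing))
}

dice_ref <- function(p, y) {
  p <- p != 0; y <- y != 0
  2 * sum(p & y) / (sum(p) + sum(y))
}

jac_ref <- function(p, y) {
  p <- p != 0; y <- y != 0
  sum(p & y) / sum(p | y)
}

# random connected-ish blob mask for metric tests
random_mask <- function(S = 32, n_seeds = 3) {
  m <- matrix(FALSE, S, S)
  for (k in seq_len(n_seeds)) {
    ci <- sample.int(S, 1); cj <- sample.int(S, 1)
    r <- runif(1, 2, S / 4)
    d2 <- (row(m) - ci)^2 + (col(m) - cj)^2
    m <- m | (d2 <= r^2)
  }
  m
}

# small shared configs keeping trainer tests fast
tiny_backbone <- function(dropout_rate = 0.5)
  backbone_config(base_width = 4, depth = 2, dropout_rate = dropout_rate)

tiny_dataset <- function(n_total = 10, labeled_fraction = 0.5, seed = 5,
                         image_size = 16, n_val = 2) {
  generate_dataset(dataset_spec(n_total = n_total,
                                labeled_fraction = labeled_fraction,
                                image_size = image_size, n_val = n_val,
                                seed = seed))
}

tiny_config <- function(variant = "pemt", seed = 7, t_max = 10, ...) {
  train_config(variant = variant, t_max = t_max, batch_labeled = 2,
               batch_unlabeled = 2, K = 3, backbone = tiny_backbone(),
               seed = seed, ...)
}

# weight-set equality helpers
expect_params_identical <- function(a, b) {
  expect_identical(names(a), names(b))
  for (nm in names(a)) expect_identical(a[[nm]], b[[nm]])
}

expect_params_close <- function(a, b, tol = 1e-10) {
  for (nm in names(a)) expect_lt(max(abs(a[[nm]] - b[[nm]])), tol)
}
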