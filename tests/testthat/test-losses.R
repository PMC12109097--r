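test_that("supervised CE+Dice loss matches hand evaluation", {
  # perfect prediction: both parts vanish (up to the log clip)
  lab <- matrix(c(0L, 0L, 1L, 1L), 2, 2)
  hot <- array(0, c(2, 2, 2))
  hot[, , 1] <- (lab == 0) * (1 - 1e-7) + (lab == 1) * 1e-7
  hot[, , 2] <- 1 - hot[, , 1]
  expect_lt(supervised_loss(hot, lab, smooth = 0), 1e-5)
  # uniform 0.5 prediction, 2 of 4 pixels foreground:
  # CE = log 2, Dice loss = 1 - 2*1/(2+2) = 0.5
  unif <- array(0.5, c(2, 2, 2))
  l <- supervised_loss(unif, lab, smooth = 0)
  expect_equal(attr(l, "ce"), log(2), tolerance = 1e-12)
  expect_equal(attr(l, "dice"), 0.5, tolerance = 1e-12)
  expect_equal(as.numeric(l), log(2) + 0.5, tolerance = 1e-12)
  # disjoint hard masks: Dice loss 1 at smooth = 0
  pred_wrong <- array(0, c(2, 2, 2))
  pred_wrong[, , 2] <- (lab == 0)  # predicts exactly the complement
  pred_wrong[, , 1] <- (lab == 1)
  expect_equal(attr(supervised_loss(pred_wrong, lab, smooth = 0), "dice"), 1)
  expect_error(supervised_loss(unif, matrix(5L, 2, 2)), "class set")
  expect_error(supervised_loss(unif, matrix(0L, 3, 3)), "mismatch")
})

test_that("consistency MSE is the mean squared simplex difference", {
  p1 <- array(c(0.8, 0.2), c(1, 1, 2))
  p2 <- array(c(0.6, 0.4), c(1, 1, 2))
  expect_equal(consistency_mse(p1, p1), 0)
  expect_equal(consistency_mse(p1, p2), 0.04, tolerance = 1e-12)
  set.seed(8)
  for (i in 1:20) {
    a <- runif(12); b <- runif(12)
    pa <- array(c(a, 1 - a), c(3, 4, 2))
    pb <- array(c(b, 1 - b), c(3, 4, 2))
    expect_lte(consistency_mse(pa, pb), 2)
  }
})

test_that("masked consistency averages only below-threshold pixels", {
  set.seed(2)
  a <- runif(12); b <- runif(12)
  p_s <- array(c(a, 1 - a), c(3, 4, 2))
  p_t <- array(c(b, 1 - b), c(3, 4, 2))
  u0 <- matrix(0, 3, 4)
  expect_equal(as.numeric(masked_consistency(p_s, p_t, u0, tau = 0.5)),
               consistency_mse(p_s, p_t), tolerance = 1e-15)
  # empty mask: zero with fraction 0
  l <- masked_consistency(p_s, p_t, u0 + 2, tau = 1)
  expect_identical(as.numeric(l), 0)
  expect_identical(attr(l, "masked_fraction"), 0)
  # two-pixel toy: squared channel-mean diffs (0.04, 0.16), only pixel 1 kept
  ps <- array(c(0.8, 0.5, 0.2, 0.5), c(2, 1, 2))
  pt <- array(c(0.6, 0.9, 0.4, 0.1), c(2, 1, 2))
  u <- matrix(c(0.1, 0.9), 2, 1)
  expect_equal(as.numeric(masked_consistency(ps, pt, u, tau = 0.5)), 0.04,
               tolerance = 1e-12)
  # masked fraction is nondecreasing in tau; full mask recovers the MSE
  um <- matrix(runif(12), 3, 4)
  fr <- vapply(seq(0, 1.2, by = 0.1), function(tau)
    attr(masked_consistency(p_s, p_t, um, tau), "masked_fraction"),
    numeric(1))
  expect_true(all(diff(fr) >= 0))
  expect_equal(as.numeric(masked_consistency(p_s, p_t, um, max(um) + 1e-9)),
               consistency_mse(p_s, p_t), tolerance = 1e-10)
})

test_that("total loss combines terms with the ramp weight", {
  ds <- tiny_dataset()
  cfg <- tiny_config(variant = "mt", t_max = 100)
  st <- init_train_state(cfg)
  lb <- list(images = list(ds$labeled[[1]]$image),
             labels = list(ds$labeled[[1]]$mask))
  ub <- list(images = list(ds$unlabeled[[1]]$image))
  b0 <- total_loss(lb, ub, st$student, st$teacher, 0, cfg)
  expect_equal(b0$total, b0$supervised + b0$lambda_t * b0$consistency,
               tolerance = 1e-6)
  # at t = 0 the ramp is ~6.7e-4, so total ~= supervised
  expect_lt(abs(b0$total - b0$supervised), 2e-3)
  # identical weights, no noise, no dropout: consistency vanishes
  cfg0 <- tiny_config(variant = "mt", t_max = 100, noise_scale = 0)
  cfg0$backbone <- tiny_backbone(dropout_rate = 0)
  st0 <- init_train_state(cfg0)
  b1 <- total_loss(lb, ub, st0$student, st0$teacher, 50, cfg0)
  expect_equal(b1$consistency, 0)
  expect_error(total_loss(list(images = list()), ub, st$student,
                          st$teacher, 0, cfg), "non-empty")
})

test_that("backprop matches central finite differences", {
  set.seed(42)
  bcfg <- backbone_config(base_width = 2, depth = 2, dropout_rate = 0)
  cfg <- train_config(variant = "pemt", t_max = 100, noise_scale = 0,
                      backbone = bcfg, seed = 7, K = 2)
  x <- matrix(runif(256), 16, 16)
  lab <- matrix(0L, 16, 16); lab[5:10, 5:10] <- 1L
  lb <- list(images = list(x), labels = list(lab))
  ub <- list(images = list(matrix(runif(256), 16, 16)))
  st <- init_train_state(cfg)
  st$teacher <- lapply(st$teacher, function(v) v + 0.05 * sin(seq_along(v)))
  # the deterministic toy model makes the Monte-Carlo passes degenerate,
  # which mc_mean_probability rightly warns about
  sc <- suppressWarnings(
    pemt:::step_compute(lb, ub, st$student, st$teacher, 50, cfg,
                        want_grads = TRUE))
  f_at <- function(w) suppressWarnings(
    pemt:::step_compute(lb, ub, w, st$teacher, 50, cfg,
                        want_grads = FALSE))$bundle$total
  errs <- c()
  for (nm in c("enc1_w", "bot_w", "dec1_w", "out_w", "enc2_b")) {
    idx <- sample(length(st$student[[nm]]), min(3, length(st$student[[nm]])))
    for (ii in idx) {
      h <- 1e-6
      wp <- st$student; wp[[nm]][ii] <- wp[[nm]][ii] + h; f1 <- f_at(wp)
      wm <- st$student; wm[[nm]][ii] <- wm[[nm]][ii] - h; f2 <- f_at(wm)
      num <- (f1 - f2) / (2 * h)
      ana <- sc$grads[[nm]][ii]
      errs <- c(errs, abs(num - ana) / max(1e-6, abs(num) + abs(ana)))
    }
  }
  expect_lt(median(errs), 1e-6)
  expect_lt(max(errs), 1e-3)  # allows an occasional ReLU-kink crossing
})
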