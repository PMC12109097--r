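test_that("variant contracts: supervised ignores the teacher", {
  ds <- tiny_dataset()
  cfg <- tiny_config(variant = "supervised", t_max = 3)
  st <- init_train_state(cfg)
  te0 <- clone_weights(st$teacher)
  f <- fit_pemt(ds, cfg)
  expect_params_identical(f$state$teacher, te0)
  expect_true(all(f$log$consistency == 0))
  expect_true(all(is.na(f$log$masked_fraction)))
})

test_that("mean teacher at t = 1 copies the student exactly", {
  ds <- tiny_dataset()
  cfg <- tiny_config(variant = "mt", t_max = 1)
  f <- fit_pemt(ds, cfg)
  expect_params_identical(f$state$teacher, f$state$student)
})

test_that("teacher changes only through the coupling update", {
  ds <- tiny_dataset()
  cfg <- tiny_config(variant = "uamt", t_max = 1)
  st <- init_train_state(cfg)
  lb <- list(images = list(ds$labeled[[1]]$image),
             labels = list(ds$labeled[[1]]$mask))
  ub <- list(images = list(ds$unlabeled[[1]]$image))
  te_before <- clone_weights(st$teacher)
  # the loss/gradient computation must leave the teacher untouched
  sc <- pemt:::step_compute(lb, ub, st$student, st$teacher, 1, cfg)
  expect_params_identical(st$teacher, te_before)
  # after a full step the teacher equals exactly the EMA of its previous
  # value with the updated student - no gradient leaks in
  res <- train_step(st, lb, ub, 2, cfg)
  expect_params_identical(
    res$state$teacher,
    ema_update(te_before, res$state$student, ema_alpha(2)))
})

test_that("variant lattice: pEMA with beta = 0 degenerates to uamt_rum", {
  ds <- tiny_dataset()
  f1 <- fit_pemt(ds, tiny_config(variant = "pemt", beta = 0, t_max = 10))
  f2 <- fit_pemt(ds, tiny_config(variant = "uamt_rum", t_max = 10))
  expect_params_identical(f1$state$student, f2$state$student)
  expect_params_identical(f1$state$teacher, f2$state$teacher)
})

test_that("variant lattice: uamt with an infinite threshold is mt", {
  ds <- tiny_dataset()
  f1 <- fit_pemt(ds, tiny_config(variant = "uamt", tau_fixed = Inf,
                                 t_max = 10))
  f2 <- fit_pemt(ds, tiny_config(variant = "mt", t_max = 10))
  expect_params_identical(f1$state$student, f2$state$student)
  expect_params_identical(f1$state$teacher, f2$state$teacher)
})

test_that("variant lattice: mt with a zero ramp is supervised", {
  ds <- tiny_dataset()
  f1 <- fit_pemt(ds, tiny_config(variant = "mt", lambda_scale = 0,
                                 t_max = 10))
  f2 <- fit_pemt(ds, tiny_config(variant = "supervised", t_max = 10))
  expect_params_identical(f1$state$student, f2$state$student)
})

test_that("training is reproducible and t_max = 0 is a no-op", {
  ds <- tiny_dataset()
  cfg <- tiny_config(variant = "pemt", t_max = 6)
  f1 <- fit_pemt(ds, cfg)
  f2 <- fit_pemt(ds, cfg)
  expect_params_identical(f1$state$student, f2$state$student)
  expect_identical(f1$log, f2$log)
  cfg0 <- tiny_config(variant = "pemt", t_max = 0)
  f0 <- fit_pemt(ds, cfg0)
  expect_params_identical(f0$state$student, init_train_state(cfg0)$student)
  expect_equal(nrow(f0$log), 0)
})

test_that("prediction is deterministic and argmax-consistent", {
  ds <- tiny_dataset()
  cfg <- tiny_config(variant = "mt", t_max = 4)
  f <- fit_pemt(ds, cfg)
  img <- ds$validation[[1]]$image
  p1 <- predict(f, img)
  p2 <- predict(f, img)
  expect_identical(p1, p2)
  expect_true(all(p1[[1]] %in% 0:1))
  # freshly initialized run: teacher is a copy, so predictions agree
  f0 <- fit_pemt(ds, tiny_config(variant = "pemt", t_max = 0))
  expect_identical(predict(f0, img, use_teacher = TRUE),
                   predict(f0, img, use_teacher = FALSE))
  # argmax of a one-hot map returns the hot class everywhere
  hot <- array(0, c(4, 4, 3)); hot[, , 3] <- 1
  expect_true(all(pemt:::prob_argmax(hot) == 2L))
})

test_that("loss bundle internal identity holds along a short run", {
  ds <- tiny_dataset()
  f <- fit_pemt(ds, tiny_config(variant = "uamt", t_max = 8))
  with(f$log, expect_lt(max(abs(total - (supervised + lambda * consistency))),
                        1e-6))
  expect_true(all(f$log$supervised >= 0))
  expect_true(all(f$log$consistency >= 0))
})

test_that("checkpoints and logs round-trip through disk", {
  ds <- tiny_dataset()
  f <- fit_pemt(ds, tiny_config(variant = "mt", t_max = 2))
  tmp <- tempfile(fileext = ".rds")
  save_checkpoint(f, tmp)
  f2 <- load_checkpoint(tmp)
  expect_params_identical(f$state$student, f2$state$student)
  csv <- tempfile(fileext = ".csv")
  write_training_log(f, csv)
  expect_equal(nrow(read.csv(csv)), 2)
  unlink(c(tmp, csv))
})

test_that("evaluation helper reports per-case metric rows", {
  ds <- tiny_dataset(n_val = 3)
  f <- fit_pemt(ds, tiny_config(variant = "supervised", t_max = 5))
  ev <- suppressWarnings(evaluate_fit(f, ds$validation))
  expect_equal(sort(unique(ev$case)), 1:3)
  expect_true(all(ev$dsc >= 0 & ev$dsc <= 1))
})
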