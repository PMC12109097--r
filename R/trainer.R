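# Semi-supervised training loop binding schedules, losses, uncertainty
# maps and the teacher/student weight coupling, with a variant switchboard:
#   supervised  - labeled data only, no teacher
#   mt          - mean teacher: EMA coupling, unmasked consistency
#   uamt        - EMA coupling, entropy-masked consistency (EUM)
#   uamt_rum    - EMA coupling, residual-guided masking (RUM)
#   pemt        - pEMA coupling, residual-guided masking (RUM)

VARIANTS <- c("supervised", "mt", "uamt", "uamt_rum", "pemt")

#' Training configuration
#'
#' All hyperparameters, schedules, variant flags and seeds for one run.
#' Defaults follow the reference mean-teacher setup: SGD with momentum 0.9
#' and weight decay 1e-4, initial learning rate 0.01 decayed ten-fold every
#' 2500 iterations, consistency ramp to 0.1, EMA decay capped at 0.99,
#' pEMA perturbation `beta = 0.001`, RUM shape `upsilon = 2`, `K = 8`
#' Monte-Carlo passes, equal labeled/unlabeled batch halves, additive input
#' noise of scale 0.1 clipped at 0.2, and random 90-degree rotation / flip
#' augmentation.
#'
#' @param variant one of `"supervised"`, `"mt"`, `"uamt"`, `"uamt_rum"`,
#'   `"pemt"`
#' @param t_max maximum iteration number (default 6000)
#' @param batch_labeled,batch_unlabeled items per batch from each pool
#'   (equal by default)
#' @param lr0,decay_every learning-rate schedule, see [learning_rate()]
#' @param lambda_scale plateau of the consistency ramp, see
#'   [lambda_weight()]; 0 disables the consistency term
#' @param alpha_cap EMA decay cap, see [ema_alpha()]
#' @param beta pEMA perturbation strength, see [pema_update()]
#' @param upsilon RUM shape coefficient, see [rum()]
#' @param K Monte-Carlo forward passes for the uncertainty map
#' @param noise_scale,noise_clip additive input-noise model for the
#'   student/teacher perturbations eta1/eta2 and the Monte-Carlo passes
#' @param tau_fixed optional fixed uncertainty threshold overriding the
#'   [tau_threshold()] ramp (e.g. `Inf` to disable masking)
#' @param consistency_on_labeled include labeled images in the consistency
#'   term (default TRUE)
#' @param redraw_mc_noise redraw input noise on every Monte-Carlo pass
#' @param momentum,weight_decay SGD settings; weight decay acts on kernels
#'   only, not biases
#' @param mod_eps near-zero-divisor guard of [floored_mod()]
#' @param smooth Dice smoothing constant
#' @param augment_rotate,augment_flip random 90-degree rotations and flips
#' @param seed master seed; every random draw of a run derives from it
#' @param backbone a [backbone_config()]
#' @return an object of class `train_config`
#' @export
train_config <- function(variant = "pemt", t_max = 6000,
                         batch_labeled = 2, batch_unlabeled = 2,
                         lr0 = 0.01, decay_every = 2500,
                         lambda_scale = 0.1, alpha_cap = 0.99,
                         beta = 0.001, upsilon = 2, K = 8,
                         noise_scale = 0.1, noise_clip = 0.2,
                         tau_fixed = NULL, consistency_on_labeled = TRUE,
                         redraw_mc_noise = TRUE,
                         momentum = 0.9, weight_decay = 1e-4,
                         mod_eps = 1e-8, smooth = 1e-5,
                         augment_rotate = TRUE, augment_flip = TRUE,
                         seed = 1L, backbone = backbone_config()) {
  variant <- match.arg(variant, VARIANTS)
  if (t_max < 0) stop("`t_max` must be >= 0", call. = FALSE)
  structure(as.list(environment()), class = "train_config")
}

uses_teacher <- function(variant) variant != "supervised"
uncertainty_kind <- function(variant) {
  switch(variant, supervised = "none", mt = "none", uamt = "eum",
         uamt_rum = "rum", pemt = "rum")
}

# ---- one evaluation of the objective (optionally with gradients) ---------

step_compute <- function(labeled_batch, unlabeled_batch, student, teacher,
                         t, config, want_grads = TRUE) {
  bcfg <- config$backbone
  n_lab <- length(labeled_batch$images)
  n_unl <- length(unlabeled_batch$images)
  if (n_lab == 0) stop("labeled batch must be non-empty", call. = FALSE)
  imgs <- c(labeled_batch$images, unlabeled_batch$images)
  n_all <- n_lab + n_unl
  x <- as_image_batch(imgs, bcfg$in_channels)
  sd0 <- config$seed

  add_noise <- function(xb, seed) {
    if (config$noise_scale <= 0) return(xb)
    with_seed(seed, xb + clip(
      array(rnorm(length(xb), sd = config$noise_scale), dim(xb)),
      -config$noise_clip, config$noise_clip))
  }
  x_s <- add_noise(x, derive_seed(sd0, t, "eta1"))

  fw_s <- backbone_forward(student, bcfg, x_s, stochastic = TRUE,
                           seed = derive_seed(sd0, t, "sdrop"),
                           want_cache = want_grads)
  lambda_t <- lambda_weight(min(t, config$t_max), config$t_max,
                            config$lambda_scale)
  # threshold ramp on the scale of the variant's own uncertainty map:
  # log(C) for the entropy map, the simplex maximum for the RUM
  u_max <- switch(uncertainty_kind(config$variant),
                  eum = log(bcfg$num_classes),
                  rum = rum_max(config$upsilon, bcfg$num_classes),
                  log(2))
  tau_t <- if (!is.null(config$tau_fixed)) config$tau_fixed
           else tau_threshold(min(t, config$t_max), config$t_max, u_max)

  C <- bcfg$num_classes
  dlogits <- if (want_grads) array(0, dim(fw_s$logits)) else NULL

  sup <- 0
  for (i in seq_len(n_lab)) {
    p_i <- array(fw_s$probs[, , , i], dim(fw_s$probs)[1:3])
    sup <- sup + supervised_loss(p_i, labeled_batch$labels[[i]],
                                 config$smooth) / n_lab
    if (want_grads)
      dlogits[, , , i] <- dlogits[, , , i] +
        supervised_loss_grad(p_i, labeled_batch$labels[[i]],
                             config$smooth) / n_lab
  }
  sup <- as.numeric(sup)

  cons <- 0; mfrac <- NA_real_
  do_cons <- uses_teacher(config$variant) && lambda_t > 0
  if (do_cons) {
    x_t <- add_noise(x, derive_seed(sd0, t, "eta2"))
    fw_t <- backbone_forward(teacher, bcfg, x_t, stochastic = TRUE,
                             seed = derive_seed(sd0, t, "tdrop"))
    ukind <- uncertainty_kind(config$variant)
    d2 <- dim(fw_s$probs)[1:2]
    if (ukind == "none") {
      u_all <- array(0, c(d2, n_all))
      tau_use <- 1
    } else {
      p_bar <- mc_mean_probability(teacher, bcfg, x, K = config$K,
                                   noise_scale = config$noise_scale,
                                   noise_clip = config$noise_clip,
                                   seed = derive_seed(sd0, t, "mc"),
                                   dropout = TRUE,
                                   redraw_noise = config$redraw_mc_noise)
      u_all <- if (ukind == "rum") rum(p_bar, config$upsilon) else eum(p_bar)
      u_all <- array(u_all, c(d2, n_all))
      tau_use <- tau_t
    }
    idx <- if (config$consistency_on_labeled) seq_len(n_all)
           else n_lab + seq_len(n_unl)
    if (length(idx) > 0) {
      fr <- 0
      for (i in idx) {
        p_si <- array(fw_s$probs[, , , i], dim(fw_s$probs)[1:3])
        p_ti <- array(fw_t$probs[, , , i], dim(fw_t$probs)[1:3])
        u_i <- matrix(u_all[, , i], d2[1], d2[2])
        li <- masked_consistency(p_si, p_ti, u_i, tau_use)
        cons <- cons + li / length(idx)
        fr <- fr + attr(li, "masked_fraction") / length(idx)
        if (want_grads)
          dlogits[, , , i] <- dlogits[, , , i] + lambda_t *
            masked_consistency_grad(p_si, p_ti, u_i, tau_use) / length(idx)
      }
      mfrac <- fr
    }
    cons <- as.numeric(cons)
  }

  bundle <- list(supervised = sup, consistency = cons,
                 total = sup + lambda_t * cons,
                 lambda_t = lambda_t, tau_t = tau_t,
                 masked_fraction = mfrac)
  class(bundle) <- "loss_bundle"
  grads <- if (want_grads)
    backbone_backward(student, bcfg, fw_s$cache, dlogits) else NULL
  list(bundle = bundle, grads = grads)
}

# ---- one optimization step ------------------------------------------------

#' One semi-supervised training step
#'
#' Takes one SGD step on the student from the gradients of the total
#' objective, then applies the variant's teacher/student coupling:
#' EMA for `mt`/`uamt`/`uamt_rum`, pEMA for `pemt`, none for
#' `supervised`. Uncertainty masking follows the variant (`uamt` uses the
#' entropy map, `uamt_rum` and `pemt` the residual-guided map). The teacher
#' is never touched by gradients.
#'
#' @param state trainer state from [init_train_state()] or a previous step
#' @param labeled_batch list with `images` and `labels`
#' @param unlabeled_batch list with `images` (may be empty)
#' @param t iteration number, `>= 1`
#' @param config a [train_config()]
#' @return list with the updated `state` and the `bundle` of loss values
#' @export
train_step <- function(state, labeled_batch, unlabeled_batch, t, config) {
  sc <- step_compute(labeled_batch, unlabeled_batch, state$student,
                     state$teacher, t, config, want_grads = TRUE)
  lr <- learning_rate(t, config$lr0, config$decay_every)
  student <- state$student
  mom <- state$mom
  for (nm in names(student)) {
    g <- sc$grads[[nm]]
    if (!endsWith(nm, "_b")) g <- g + config$weight_decay * student[[nm]]
    mom[[nm]] <- config$momentum * mom[[nm]] + g
    student[[nm]] <- student[[nm]] - lr * mom[[nm]]
  }
  teacher <- state$teacher
  if (uses_teacher(config$variant)) {
    alpha <- ema_alpha(t, config$alpha_cap)
    if (config$variant == "pemt") {
      up <- pema_update(teacher, student, alpha, config$beta, config$mod_eps)
      teacher <- up$teacher
      student <- up$student
    } else {
      teacher <- ema_update(teacher, student, alpha)
    }
  }
  list(state = list(student = student, teacher = teacher, mom = mom, t = t),
       bundle = sc$bundle)
}

#' Initialize trainer state
#'
#' Student weights are drawn from the seeded He initialization; the teacher
#' starts as an exact deep copy; momentum buffers start at zero.
#'
#' @param config a [train_config()]
#' @return list with `student`, `teacher`, `mom`, `t = 0`
#' @export
init_train_state <- function(config) {
  student <- init_backbone(config$backbone, derive_seed(config$seed, 0, "init"))
  list(student = student, teacher = clone_weights(student),
       mom = lapply(student, function(w) w * 0), t = 0L)
}

# ---- full training loop ---------------------------------------------------

rot90k <- function(m, k) {
  k <- k %% 4
  for (i in seq_len(k)) m <- t(m[nrow(m):1, , drop = FALSE])
  m
}

augment_pair <- function(image, mask, rotate = TRUE, flip = TRUE) {
  k <- if (rotate) sample.int(4, 1) - 1L else 0L
  fl <- flip && runif(1) < 0.5
  image <- rot90k(image, k)
  if (!is.null(mask)) mask <- rot90k(mask, k)
  if (fl) {
    image <- image[, ncol(image):1, drop = FALSE]
    if (!is.null(mask)) mask <- mask[, ncol(mask):1, drop = FALSE]
  }
  list(image = image, mask = mask)
}

#' Fit a semi-supervised segmentation model
#'
#' Runs `t = 1 .. t_max` iterations of [train_step()] with seeded batch
#' sampling (uniform with replacement from each pool) and seeded
#' rotation/flip augmentation. Fully reproducible: every random draw
#' derives from `config$seed` and the iteration number, so two runs with
#' the same seed produce identical weights.
#'
#' @param dataset a dataset from [generate_dataset()] (or any list with
#'   `labeled` and `unlabeled` pools of samples carrying `image`/`mask`)
#' @param config a [train_config()]
#' @return an object of class `pemt_fit`: list with `state` (final
#'   weights), `log` (per-iteration tibble: t, lr, lambda, tau, supervised,
#'   consistency, masked_fraction, total) and `config`
#' @export
fit_pemt <- function(dataset, config) {
  if (length(dataset$labeled) < 1)
    stop("dataset must contain at least one labeled sample", call. = FALSE)
  state <- init_train_state(config)
  t_max <- config$t_max
  n_lab_pool <- length(dataset$labeled)
  n_unl_pool <- length(dataset$unlabeled)
  cols <- c("t", "lr", "lambda", "tau", "supervised", "consistency",
            "masked_fraction", "total")
  logm <- matrix(NA_real_, nrow = t_max, ncol = length(cols),
                 dimnames = list(NULL, cols))
  for (t in seq_len(t_max)) {
    draw <- with_seed(derive_seed(config$seed, t, "sample"), {
      li <- sample.int(n_lab_pool, config$batch_labeled, replace = TRUE)
      ui <- if (n_unl_pool > 0 && config$batch_unlabeled > 0)
        sample.int(n_unl_pool, config$batch_unlabeled, replace = TRUE)
      else integer(0)
      list(li = li, ui = ui)
    })
    batches <- with_seed(derive_seed(config$seed, t, "aug"), {
      lb <- list(images = list(), labels = list())
      for (i in seq_along(draw$li)) {
        s <- dataset$labeled[[draw$li[i]]]
        a <- augment_pair(s$image, s$mask, config$augment_rotate,
                          config$augment_flip)
        lb$images[[i]] <- a$image; lb$labels[[i]] <- a$mask
      }
      ub <- list(images = list())
      for (i in seq_along(draw$ui)) {
        s <- dataset$unlabeled[[draw$ui[i]]]
        a <- augment_pair(s$image, NULL, config$augment_rotate,
                          config$augment_flip)
        ub$images[[i]] <- a$image
      }
      list(lb = lb, ub = ub)
    })
    res <- train_step(state, batches$lb, batches$ub, t, config)
    state <- res$state
    b <- res$bundle
    logm[t, ] <- c(t, learning_rate(t, config$lr0, config$decay_every),
                   b$lambda_t, b$tau_t, b$supervised, b$consistency,
                   b$masked_fraction, b$total)
  }
  structure(list(state = state, log = tibble::as_tibble(as.data.frame(logm)),
                 config = config),
            class = "pemt_fit")
}

#' Predict segmentation masks
#'
#' Deterministic forward pass (dropout off) of the chosen model followed by
#' a per-pixel argmax.
#'
#' @param object a `pemt_fit`
#' @param images matrix or list of matrices
#' @param use_teacher predict with the teacher instead of the student
#' @param ... unused
#' @return list of integer class-label matrices (values `0..C-1`)
#' @export
predict.pemt_fit <- function(object, images, use_teacher = FALSE, ...) {
  if (is.matrix(images)) images <- list(images)
  w <- if (use_teacher) object$state$teacher else object$state$student
  bcfg <- object$config$backbone
  probs <- backbone_forward(w, bcfg, images, stochastic = FALSE)$probs
  lapply(seq_along(images), function(i)
    prob_argmax(array(probs[, , , i], dim(probs)[1:3])))
}

prob_argmax <- function(p) {
  d <- dim(p)
  best <- p[, , 1]; lab <- matrix(0L, d[1], d[2])
  for (c in seq_len(d[3])[-1]) {
    upd <- p[, , c] > best
    lab[upd] <- c - 1L
    best[upd] <- p[, , c][upd]
  }
  lab
}

#' Evaluate a fitted model on a labeled pool
#'
#' Predicts every sample and computes the per-class overlap and surface
#' metrics; see [evaluate_masks()].
#'
#' @param fit a `pemt_fit`
#' @param samples list of samples with `image` and `mask`
#' @param use_teacher evaluate the teacher instead of the student
#' @param spacing per-axis pixel spacing for the surface metrics
#' @return tibble with one row per (case, class): `case`, `class`, `dsc`,
#'   `jac`, `hd95`, `asd`
#' @export
evaluate_fit <- function(fit, samples, use_teacher = FALSE,
                         spacing = c(1, 1)) {
  preds <- predict(fit, lapply(samples, `[[`, "image"),
                   use_teacher = use_teacher)
  rows <- lapply(seq_along(samples), function(i) {
    m <- evaluate_masks(preds[[i]], samples[[i]]$mask, spacing = spacing)
    m$case <- i
    m
  })
  out <- do.call(rbind, rows)
  out[, c("case", setdiff(names(out), "case"))]
}

#' Ablation sweep over the RUM shape and the pEMA strength
#'
#' Trains the `pemt` variant once per setting, sweeping `upsilon` at the
#' base config's `beta` and then `beta` at the base config's `upsilon`
#' (one-factor-at-a-time, as ablation tables are usually reported), and
#' evaluates mean validation metrics for each run.
#'
#' @param dataset a dataset from [generate_dataset()] with a `validation`
#'   pool
#' @param config base [train_config()]
#' @param upsilon values of the RUM shape to sweep (default 1, 2, 3)
#' @param beta values of the pEMA strength to sweep
#'   (default 0.005, 0.001, 0.0005, 0.0001)
#' @return tibble: `sweep`, `upsilon`, `beta`, `dsc`, `jac`, `hd95`, `asd`
#' @export
ablate <- function(dataset, config, upsilon = c(1, 2, 3),
                   beta = c(0.005, 0.001, 0.0005, 0.0001)) {
  run_one <- function(sweep, u, b) {
    cfg <- config
    cfg$variant <- "pemt"; cfg$upsilon <- u; cfg$beta <- b
    f <- fit_pemt(dataset, cfg)
    ev <- evaluate_fit(f, dataset$validation)
    tibble::tibble(sweep = sweep, upsilon = u, beta = b,
                   dsc = mean(ev$dsc), jac = mean(ev$jac),
                   hd95 = mean(ev$hd95, na.rm = TRUE),
                   asd = mean(ev$asd, na.rm = TRUE))
  }
  rows <- c(lapply(upsilon, function(u) run_one("upsilon", u, config$beta)),
            lapply(beta, function(b) run_one("beta", config$upsilon, b)))
  do.call(rbind, rows)
}
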