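# Training objective: supervised cross-entropy + soft Dice on labeled
# images, and a (possibly uncertainty-masked) mean-squared-error consistency
# term between student and teacher predictions on all images, combined with
# the ramp-up weight lambda(t). Gradients flow only through the student;
# teacher predictions and uncertainty masks are constants.

# one-hot encode an integer mask (values 0..C-1) to (H, W, C)
one_hot_mask <- function(label, C) {
  d <- dim(label)
  y <- array(0, c(d[1], d[2], C))
  for (c in seq_len(C)) y[, , c] <- (label == c - 1L)
  y
}

#' Supervised segmentation loss: cross-entropy + soft Dice
#'
#' `CE + DiceLoss` for one image. CE is the per-pixel mean
#' `-(1/|Omega|) sum_c y_c log p_c`; the Dice loss is
#' `1 - (2 sum p y + smooth) / (sum p + sum y + smooth)` computed on soft
#' probabilities of each foreground channel and averaged over foreground
#' classes. The smoothing constant guards the empty-mask 0/0 case.
#'
#' @param pred `(H, W, C)` probability array for one image
#' @param label integer matrix of class labels in `0..C-1` on the same grid
#' @param smooth Dice smoothing constant (default 1e-5)
#' @return non-negative scalar with attributes `ce` and `dice`
#' @export
supervised_loss <- function(pred, label, smooth = 1e-5) {
  d <- dim(pred)
  if (length(d) != 3L) stop("`pred` must be an (H, W, C) array", call. = FALSE)
  if (!all(dim(label) == d[1:2])) stop("grid mismatch", call. = FALSE)
  C <- d[3]
  if (any(label < 0 | label > C - 1)) stop("label outside class set", call. = FALSE)
  if (smooth < 0) stop("`smooth` must be >= 0", call. = FALSE)
  y <- one_hot_mask(label, C)
  n_pix <- d[1] * d[2]
  ce <- -sum(y * log(pmax(pred, 1e-12))) / n_pix
  dice <- 0
  for (c in 2:C) {
    num <- 2 * sum(pred[, , c] * y[, , c]) + smooth
    den <- sum(pred[, , c]) + sum(y[, , c]) + smooth
    dice <- dice + (1 - num / den)
  }
  dice <- dice / (C - 1)
  structure(ce + dice, ce = ce, dice = dice)
}

# gradient of supervised_loss w.r.t. the logits of one image,
# using d softmax: dL/dz_j = p_j * (g_j - sum_c g_c p_c) for the Dice part
# and the closed form (p - y)/|Omega| for the CE part.
supervised_loss_grad <- function(pred, label, smooth = 1e-5) {
  d <- dim(pred); C <- d[3]; n_pix <- d[1] * d[2]
  y <- one_hot_mask(label, C)
  dlogits <- (pred - y) / n_pix
  gp <- array(0, d)  # dDice/dp
  for (c in 2:C) {
    num <- 2 * sum(pred[, , c] * y[, , c]) + smooth
    den <- sum(pred[, , c]) + sum(y[, , c]) + smooth
    gp[, , c] <- -(2 * y[, , c] * den - num) / den^2 / (C - 1)
  }
  inner <- array(0, d[1:2])
  for (c in seq_len(C)) inner <- inner + gp[, , c] * pred[, , c]
  for (c in seq_len(C)) dlogits[, , c] <- dlogits[, , c] +
      pred[, , c] * (gp[, , c] - inner)
  dlogits
}

#' Plain consistency loss: mean squared error between probability maps
#'
#' Mean over all pixels and channels of the squared student-teacher
#' probability difference. Bounded by 2 for simplex-valued maps.
#'
#' @param p_s,p_t conformable probability arrays (student, teacher)
#' @return non-negative scalar
#' @export
consistency_mse <- function(p_s, p_t) {
  if (!identical(dim(p_s), dim(p_t))) stop("grid mismatch", call. = FALSE)
  mean((p_s - p_t)^2)
}

#' Uncertainty-masked consistency loss
#'
#' Pixels whose uncertainty `u` is at or above the threshold `tau` are
#' excluded; over the retained pixels the per-pixel channel-mean squared
#' student-teacher difference is averaged:
#' `sum_Omega 1[u < tau] * ||p_s - p_t||^2 / sum_Omega 1[u < tau]`.
#' An everywhere-empty mask returns 0.
#'
#' @param p_s,p_t `(H, W, C)` probability arrays (student, teacher)
#' @param u `H x W` uncertainty map (from [rum()] or [eum()])
#' @param tau non-negative threshold, typically [tau_threshold()]
#' @return non-negative scalar with attribute `masked_fraction`
#' @export
masked_consistency <- function(p_s, p_t, u, tau) {
  d <- dim(p_s)
  if (!identical(d, dim(p_t))) stop("grid mismatch", call. = FALSE)
  if (!all(dim(u) == d[1:2])) stop("uncertainty grid mismatch", call. = FALSE)
  if (tau < 0) stop("`tau` must be >= 0", call. = FALSE)
  mask <- u < tau
  n_keep <- sum(mask)
  if (n_keep == 0) return(structure(0, masked_fraction = 0))
  sq <- array(0, d[1:2])
  for (c in seq_len(d[3])) sq <- sq + (p_s[, , c] - p_t[, , c])^2
  sq <- sq / d[3]
  structure(sum(sq[mask]) / n_keep,
            masked_fraction = n_keep / (d[1] * d[2]))
}

# gradient of masked_consistency w.r.t. student logits (teacher constant):
# dL/dp_s = 2 * mask * (p_s - p_t) / (C * n_keep), chained through softmax.
masked_consistency_grad <- function(p_s, p_t, u, tau) {
  d <- dim(p_s); C <- d[3]
  mask <- u < tau
  n_keep <- sum(mask)
  dlogits <- array(0, d)
  if (n_keep == 0) return(dlogits)
  gp <- array(0, d)
  for (c in seq_len(C)) gp[, , c] <- 2 * mask * (p_s[, , c] - p_t[, , c]) /
      (C * n_keep)
  inner <- array(0, d[1:2])
  for (c in seq_len(C)) inner <- inner + gp[, , c] * p_s[, , c]
  for (c in seq_len(C)) dlogits[, , c] <- p_s[, , c] * (gp[, , c] - inner)
  dlogits
}

#' Total semi-supervised objective for one batch
#'
#' Evaluates (without updating any weights) the loss the trainer minimises
#' at iteration `t`: the supervised CE+Dice term averaged over the labeled
#' items plus `lambda(t)` times the consistency term over all items
#' (labeled and unlabeled), masked by the variant's uncertainty map. See
#' [train_step()] for the update itself.
#'
#' @param labeled_batch list with `images` (list of matrices) and `labels`
#'   (list of integer matrices)
#' @param unlabeled_batch list with `images`, possibly empty
#' @param student,teacher parameter sets
#' @param t current iteration
#' @param config a [train_config()]
#' @return a `loss_bundle`: list with `supervised`, `consistency`, `total`,
#'   `lambda_t`, `tau_t`, `masked_fraction`
#' @export
total_loss <- function(labeled_batch, unlabeled_batch, student, teacher,
                       t, config) {
  if (length(labeled_batch$images) == 0)
    stop("labeled batch must be non-empty", call. = FALSE)
  step_compute(labeled_batch, unlabeled_batch, student, teacher, t, config,
               want_grads = FALSE)$bundle
}
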