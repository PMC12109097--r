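# Seeded generator of 2D segmentation datasets with the statistical
# structure the semi-supervised method targets: compact foreground
# structures (ellipses and myocardium-like annuli), fuzzy blurred
# boundaries, additive noise, optional smooth intensity bias, and a small
# labeled fraction. Everything is determined by (seed, index), so datasets
# are reproducible without storing any files.

#' Synthetic dataset specification
#'
#' @param n_total training samples (labeled + unlabeled)
#' @param labeled_fraction fraction of training samples whose labels the
#'   trainer may see, in `(0, 1]`; the rest keep hidden ground truth for
#'   diagnostics only
#' @param image_size square image side; must be divisible by `2^depth` of
#'   the backbone that will consume it
#' @param n_classes 2 (background/foreground) or 4 (cardiac-like layout:
#'   background, inner disk, ring, side blob)
#' @param blob_count_range integer range of structures per image
#' @param boundary_blur_sigma Gaussian blur width (pixels) applied to the
#'   rendered intensities; this is what makes object boundaries fuzzy
#' @param noise_sigma standard deviation of the additive Gaussian noise
#' @param bias_field multiply by a smooth random intensity bias
#' @param fg_range acceptable foreground-fraction interval; structures are
#'   redrawn (deterministically) until the fraction falls inside it
#' @param n_val validation samples (disjoint from training)
#' @param seed master seed of the dataset
#' @return object of class `dataset_spec`
#' @export
dataset_spec <- function(n_total = 100, labeled_fraction = 0.05,
                         image_size = 64, n_classes = 2,
                         blob_count_range = c(1, 3),
                         boundary_blur_sigma = 1.5, noise_sigma = 0.15,
                         bias_field = TRUE, fg_range = c(0.02, 0.5),
                         n_val = 20, seed = 1L) {
  if (labeled_fraction <= 0 || labeled_fraction > 1)
    stop("`labeled_fraction` must lie in (0, 1]", call. = FALSE)
  if (ceiling(n_total * labeled_fraction) < 1)
    stop("at least one labeled sample required", call. = FALSE)
  if (!n_classes %in% c(2, 4))
    stop("`n_classes` must be 2 or 4", call. = FALSE)
  structure(as.list(environment()), class = "dataset_spec")
}

# filled ellipse indicator on an S x S grid
ellipse_mask <- function(S, cx, cy, ax, ay, theta) {
  gx <- matrix(seq_len(S), S, S) - cx
  gy <- matrix(seq_len(S), S, S, byrow = TRUE) - cy
  xr <- gx * cos(theta) + gy * sin(theta)
  yr <- -gx * sin(theta) + gy * cos(theta)
  (xr / ax)^2 + (yr / ay)^2 <= 1
}

draw_structures <- function(spec) {
  S <- spec$image_size
  mask <- matrix(0L, S, S)
  levels <- matrix(0, S, S)
  if (spec$n_classes == 2) {
    k <- sample(seq(spec$blob_count_range[1], spec$blob_count_range[2]), 1)
    for (b in seq_len(k)) {
      cx <- runif(1, 0.25 * S, 0.75 * S); cy <- runif(1, 0.25 * S, 0.75 * S)
      ax <- runif(1, 0.08 * S, 0.22 * S); ay <- runif(1, 0.08 * S, 0.22 * S)
      th <- runif(1, 0, pi)
      if (runif(1) < 0.5) {  # annulus: ring around a hole
        outer <- ellipse_mask(S, cx, cy, ax, ay, th)
        inner <- ellipse_mask(S, cx, cy, 0.55 * ax, 0.55 * ay, th)
        m <- outer & !inner
      } else {
        m <- ellipse_mask(S, cx, cy, ax, ay, th)
      }
      mask[m] <- 1L
      levels[m] <- runif(1, 0.55, 0.8)
    }
  } else {
    # cardiac-like: ventricle-like disk (1) inside a myocardium-like
    # ring (2), plus a separate blob (3)
    cx <- runif(1, 0.35 * S, 0.6 * S); cy <- runif(1, 0.35 * S, 0.6 * S)
    ax <- runif(1, 0.12 * S, 0.2 * S); ay <- runif(1, 0.12 * S, 0.2 * S)
    th <- runif(1, 0, pi)
    outer <- ellipse_mask(S, cx, cy, ax, ay, th)
    inner <- ellipse_mask(S, cx, cy, 0.6 * ax, 0.6 * ay, th)
    mask[outer & !inner] <- 2L; levels[outer & !inner] <- 0.5
    mask[inner] <- 1L; levels[inner] <- 0.8
    bx <- runif(1, 0.15 * S, 0.85 * S); by <- runif(1, 0.7 * S, 0.85 * S)
    blob <- ellipse_mask(S, bx, by, runif(1, 0.06 * S, 0.12 * S),
                         runif(1, 0.06 * S, 0.12 * S), runif(1, 0, pi))
    blob <- blob & mask == 0L
    mask[blob] <- 3L; levels[blob] <- 0.9
  }
  list(mask = mask, levels = levels)
}

#' Generate one synthetic sample
#'
#' Fully determined by `(spec$seed, index)`: draws random ellipse/annulus
#' structures, renders class-dependent intensity levels over a darker
#' background, blurs the image (fuzzy boundaries), adds Gaussian noise and
#' an optional smooth multiplicative bias field, and clips to `[0, 1]`.
#'
#' @param spec a [dataset_spec()]
#' @param index sample index (any integer)
#' @return list with `image` (matrix in `[0, 1]`), `mask` (integer
#'   matrix), `meta` (seed, index, foreground fraction)
#' @export
generate_sample <- function(spec, index) {
  S <- spec$image_size
  with_seed(derive_seed(spec$seed, index, "sample_gen"), {
    for (try in 1:25) {
      st <- draw_structures(spec)
      fg <- mean(st$mask > 0)
      if (fg >= spec$fg_range[1] && fg <= spec$fg_range[2]) break
    }
    img <- matrix(0.2, S, S)  # background level
    img[st$mask > 0L] <- st$levels[st$mask > 0L]
    if (spec$boundary_blur_sigma > 0)
      img <- EBImage::gblur(img, sigma = spec$boundary_blur_sigma)
    if (spec$bias_field) {
      u <- matrix(seq_len(S) / S, S, S); v <- t(u)
      coef <- runif(3, -0.25, 0.25)
      img <- img * (1 + coef[1] * (u - 0.5) + coef[2] * (v - 0.5) +
                      coef[3] * (u - 0.5) * (v - 0.5))
    }
    if (spec$noise_sigma > 0)
      img <- img + matrix(rnorm(S * S, sd = spec$noise_sigma), S, S)
    img <- clip(img, 0, 1)
    list(image = img, mask = st$mask,
         meta = list(seed = spec$seed, index = index, fg_fraction = fg))
  })
}

#' Generate a full semi-supervised dataset
#'
#' Draws `n_total` training samples and `n_val` validation samples on
#' disjoint index ranges, then splits training into a labeled pool (a
#' seeded random subset of size `ceiling(n_total * labeled_fraction)`) and
#' an unlabeled pool. Unlabeled samples carry their ground truth in a
#' `truth_mask` field that is intended for evaluation and diagnostics
#' only — the trainer never reads it.
#'
#' @param spec a [dataset_spec()]
#' @return list with pools `labeled`, `unlabeled`, `validation` and the
#'   `spec`
#' @export
generate_dataset <- function(spec) {
  train <- lapply(seq_len(spec$n_total), function(i) generate_sample(spec, i))
  val <- lapply(spec$n_total + seq_len(spec$n_val),
                function(i) generate_sample(spec, i))
  n_lab <- ceiling(spec$n_total * spec$labeled_fraction)
  lab_idx <- with_seed(derive_seed(spec$seed, 0, "split"),
                       sample.int(spec$n_total, n_lab))
  unlabeled <- lapply(train[setdiff(seq_len(spec$n_total), lab_idx)],
                      function(s) {
                        s$truth_mask <- s$mask
                        s$mask <- NULL
                        s
                      })
  list(labeled = train[lab_idx], unlabeled = unlabeled, validation = val,
       spec = spec)
}

#' Hidden ground truth of an unlabeled sample
#'
#' Accessor making the diagnostics-only nature of unlabeled ground truth
#' explicit at call sites.
#'
#' @param sample an element of the `unlabeled` pool
#' @return integer mask matrix, or `NULL` for genuinely unlabeled data
#' @export
hidden_truth <- function(sample) sample$truth_mask
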