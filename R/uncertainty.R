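# Per-pixel uncertainty of the teacher's prediction, estimated from the
# mean softmax over K stochastic forward passes (Monte-Carlo dropout plus
# additive input noise), then quantified by either the residual-guided map
# (RUM) or the entropy map (EUM).

# Apply a per-pixel reduction over the channel dimension of a probability
# container: a length-C vector, an (H, W, C) array or an (H, W, C, N) batch.
reduce_channels <- function(p, fun) {
  if (is.null(dim(p))) return(fun(matrix(p, nrow = 1))[1])
  d <- dim(p)
  if (length(d) == 3L) {
    m <- fun(matrix(p, ncol = d[3]))
    return(matrix(m, d[1], d[2]))
  }
  if (length(d) == 4L) {
    m <- fun(matrix(aperm(p, c(1, 2, 4, 3)), ncol = d[3]))
    return(array(m, d[c(1, 2, 4)]))
  }
  stop("probability input must be a C-vector or (H, W, C[, N]) array")
}

#' Residual-guided uncertainty map (RUM)
#'
#' Per pixel, `sum_c pbar_c * (1 - pbar_c)^(upsilon - pbar_c)` where
#' `pbar` is the mean class probability over stochastic forward passes
#' ([mc_mean_probability()]) and `upsilon` tunes how sharply the map peaks
#' around ambiguous probabilities. For binary tasks the map is symmetric
#' under `p <-> 1 - p` and, at `upsilon = 2`, attains its maximum at
#' `p = 0.5`, so fuzzy object boundaries light up while confident interior
#' and background pixels stay near 0. The indeterminate power `0^0`
#' (reachable only when `upsilon - pbar_c` hits 0 at a probability
#' endpoint) is taken as 1, the continuous limit; this makes the
#' `upsilon = 1` curve approach 1 at the endpoints and is one reason
#' `upsilon = 2` is the default.
#'
#' @param p_bar mean class probabilities: length-`C` vector, `(H, W, C)`
#'   array, or `(H, W, C, N)` batch, channel values summing to 1 per pixel
#' @param upsilon positive shape coefficient (default 2)
#' @return non-negative uncertainty values: scalar, `H x W` matrix, or
#'   `(H, W, N)` array matching the input
#' @examples
#' rum(c(0.5, 0.5), upsilon = 2)  # ~0.3536, the binary maximum
#' rum(c(1, 0), upsilon = 2)      # 0
#' @export
rum <- function(p_bar, upsilon = 2) {
  stop_if_not_scalar(upsilon, "upsilon")
  if (upsilon <= 0) stop("`upsilon` must be positive", call. = FALSE)
  reduce_channels(p_bar, function(m) {
    rowSums(m * (1 - m)^(upsilon - m))  # R's 0^0 == 1 matches the convention
  })
}

#' Maximum attainable RUM value
#'
#' Largest per-pixel value [rum()] can reach over the probability simplex,
#' used to put the threshold ramp [tau_threshold()] on the map's own scale.
#' Evaluated over the sub-uniform distributions `p = (1/k, ..., 1/k, 0,
#' ..., 0)`, `k = 1..C`, where the summand structure attains its extrema;
#' for `upsilon = 2, C = 2` this is `0.5^1.5 ~= 0.354` (at `p = 0.5`), and
#' for `upsilon = 1` the endpoint value 1 (the `0^0` limit).
#'
#' @inheritParams rum
#' @param C number of classes (default 2)
#' @return positive scalar
#' @export
rum_max <- function(upsilon = 2, C = 2) {
  k <- seq_len(C)
  vals <- (1 - 1 / k)^(upsilon - 1 / k)  # k = 1 gives 0^(upsilon-1)
  max(vals)
}

#' Entropy uncertainty map (EUM)
#'
#' Per-pixel Shannon entropy `-sum_c pbar_c * log(pbar_c)` of the mean
#' class probability, with the `0 * log 0 := 0` convention. Bounded by
#' `log(C)`, attained at the uniform distribution. This is the classical
#' uncertainty measure of the uncertainty-aware mean teacher.
#'
#' @inheritParams rum
#' @return non-negative values in `[0, log(C)]`, same shape as [rum()]
#' @export
eum <- function(p_bar) {
  reduce_channels(p_bar, function(m) {
    term <- m * log(m)
    term[m == 0] <- 0
    -rowSums(term)
  })
}

#' Boundary-to-interior uncertainty ratio
#'
#' Diagnostic for whether an uncertainty map concentrates on object
#' boundaries, where the ambiguity a trained teacher faces actually lives:
#' the mean uncertainty over the boundary band of a reference mask divided
#' by the mean over all other pixels. The band contains every pixel within
#' `width` (Euclidean) of the opposite class. Ratios well above 1 indicate
#' boundary-concentrated uncertainty.
#'
#' @param u `H x W` uncertainty matrix ([rum()] or [eum()])
#' @param mask integer reference mask on the same grid
#' @param width band half-width in pixels (default 1)
#' @return positive scalar (ratio of means)
#' @export
boundary_uncertainty_ratio <- function(u, mask, width = 1) {
  fg <- mask > 0
  if (!any(fg) || all(fg)) stop("mask must contain both classes", call. = FALSE)
  band <- mask_surface(fg) | mask_surface(!fg)
  if (width > 1) {
    dt <- EBImage::distmap(1 - band)
    band <- dt <= (width - 1)
  }
  mean(u[band]) / mean(u[!band])
}

#' Mean class probability over K stochastic forward passes
#'
#' Runs the network `K` times with its stochastic elements active —
#' dropout resampled every pass and (optionally) additive Gaussian input
#' noise redrawn per pass — and averages the softmax outputs per pixel and
#' class. The mean stays on the probability simplex. This is the input to
#' [rum()] and [eum()]; in the training loop it is always computed from the
#' teacher's weights.
#'
#' @param weights parameter set of the network (see [init_backbone()])
#' @param config a [backbone_config()]
#' @param x input image(s): matrix, list of matrices, or `(H, W, C, N)` array
#' @param K number of forward passes, `>= 1` (default 8)
#' @param noise_scale standard deviation of the per-pass additive input
#'   noise (default 0.1; 0 disables it)
#' @param noise_clip symmetric clip applied to the noise (default 0.2)
#' @param seed integer seed making the K passes reproducible
#' @param dropout logical; keep dropout active during the passes
#' @param redraw_noise logical; redraw the input noise each pass (default)
#'   or draw it once and reuse it across passes
#' @return `(H, W, C)` probability array (single image) or `(H, W, C, N)`
#' @export
mc_mean_probability <- function(weights, config, x, K = 8, noise_scale = 0.1,
                                noise_clip = 0.2, seed = NULL,
                                dropout = TRUE, redraw_noise = TRUE) {
  stop_if_not_scalar(K, "K")
  if (K < 1) stop("`K` must be >= 1", call. = FALSE)
  single <- is.matrix(x)
  xb <- as_image_batch(x, config$in_channels)
  stochastic <- (dropout && config$dropout_rate > 0) || noise_scale > 0
  if (!stochastic)
    warning("model has no stochastic element: all passes are identical")
  acc <- with_seed(seed, {
    fixed_noise <- NULL
    if (!redraw_noise && noise_scale > 0)
      fixed_noise <- clip(array(rnorm(length(xb), sd = noise_scale), dim(xb)),
                          -noise_clip, noise_clip)
    a <- 0
    for (k in seq_len(K)) {
      xk <- xb
      if (noise_scale > 0) {
        eta <- if (redraw_noise || is.null(fixed_noise))
          clip(array(rnorm(length(xb), sd = noise_scale), dim(xb)),
               -noise_clip, noise_clip) else fixed_noise
        xk <- xb + eta
      }
      out <- backbone_forward(weights, config, xk,
                              stochastic = dropout,
                              seed = if (is.null(seed)) NULL
                                     else derive_seed(seed, k, "mcpass"))
      a <- a + out$probs
    }
    a
  })
  p <- acc / K
  if (single) array(p, dim = dim(p)[1:3]) else p
}
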