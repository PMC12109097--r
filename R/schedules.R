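#' Consistency ramp-up weight
#'
#' Sigmoid-shaped ramp for the consistency-loss weight: `scale *
#' exp(-5 * (1 - t/t_max)^2)`. Starts near zero so the early, unreliable
#' teacher contributes little, and reaches `scale` (default 0.1) at
#' `t = t_max`.
#'
#' @param t current iteration, `0 <= t <= t_max`
#' @param t_max maximum iteration, positive
#' @param scale plateau value reached at `t_max` (default 0.1)
#' @return a non-negative scalar, nondecreasing in `t`
#' @examples
#' lambda_weight(0, 6000)     # ~ 6.74e-4
#' lambda_weight(6000, 6000)  # 0.1
#' @export
lambda_weight <- function(t, t_max, scale = 0.1) {
  check_iteration(t, t_max)
  scale * exp(-5 * (1 - t / t_max)^2)
}

#' Uncertainty-threshold ramp
#'
#' Iteration-dependent cutoff `tau(t) = (0.75 + 0.25 * exp(-5 * (1 -
#' t/t_max))) * max_value` applied to uncertainty maps when masking the
#' consistency loss. Pixels with uncertainty at or above the threshold are
#' excluded. The ramp factor relaxes from ~0.75 to 1, so more pixels
#' participate as the teacher matures. `max_value` defaults to `log(2)`,
#' the maximum of the binary entropy map; when thresholding a map whose
#' range differs (the RUM maximum at `upsilon = 2`, `C = 2` is ~0.354, well
#' below `log(2)`), pass that map's maximum ([rum_max()]) so the ramp
#' cuts at the same relative height — otherwise the mask never excludes
#' anything.
#'
#' @inheritParams lambda_weight
#' @param max_value uncertainty value the threshold reaches at `t_max`
#'   (default `log(2)`)
#' @return a positive scalar, nondecreasing in `t`; equals `max_value` at
#'   `t_max`
#' @examples
#' tau_threshold(6000, 6000)  # log(2)
#' @export
tau_threshold <- function(t, t_max, max_value = log(2)) {
  check_iteration(t, t_max)
  (0.75 + 0.25 * exp(-5 * (1 - t / t_max))) * max_value
}

#' EMA decay coefficient
#'
#' `alpha(t) = min(1 - 1/t, cap)`: the teacher starts as an exact copy of the
#' student (`alpha(1) = 0`) and the averaging horizon grows until the decay
#' saturates at `cap` (default 0.99, reached at `t = 100`).
#'
#' @param t update step, `t >= 1`
#' @param cap saturation value in `[0, 1)` (default 0.99)
#' @return scalar in `[0, cap]`
#' @export
ema_alpha <- function(t, cap = 0.99) {
  stop_if_not_scalar(t, "t")
  if (t < 1) stop("`t` must be >= 1 (first teacher update)", call. = FALSE)
  min(1 - 1 / t, cap)
}

#' Step-decayed learning rate
#'
#' `lr(t) = lr0 * 0.1^floor(t / decay_every)`.
#'
#' @param t current iteration (non-negative)
#' @param lr0 initial learning rate, positive (default 0.01)
#' @param decay_every iterations between ten-fold decays, positive
#'   (default 2500)
#' @return positive scalar
#' @export
learning_rate <- function(t, lr0 = 0.01, decay_every = 2500) {
  stop_if_not_scalar(t, "t")
  stop_if_not_scalar(lr0, "lr0")
  stop_if_not_scalar(decay_every, "decay_every")
  if (lr0 <= 0) stop("`lr0` must be positive", call. = FALSE)
  if (decay_every <= 0) stop("`decay_every` must be positive", call. = FALSE)
  if (t < 0) stop("`t` must be non-negative", call. = FALSE)
  lr0 * 0.1^floor(t / decay_every)
}

check_iteration <- function(t, t_max) {
  stop_if_not_scalar(t, "t")
  stop_if_not_scalar(t_max, "t_max")
  if (t_max <= 0) stop("`t_max` must be positive", call. = FALSE)
  if (t < 0 || t > t_max)
    stop("`t` must lie in [0, t_max]", call. = FALSE)
  invisible(TRUE)
}
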