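#' Element-wise floored modulus with a near-zero-divisor guard
#'
#' Computes `a - b * floor(a / b)` element-wise. Under the floored
#' convention the result carries the sign of the divisor `b` and satisfies
#' `|result| < |b|`, so a modulus residual of network weights is always
#' smaller in magnitude than the weight it is taken against. Wherever
#' `|b| < eps` the result is defined as 0 (a near-zero weight receives a
#' near-zero perturbation anyway, and `a/b` would overflow).
#'
#' @param a numeric vector/array (dividend)
#' @param b numeric vector/array, same shape as `a` (divisor)
#' @param eps guard threshold for `|b|` (default 1e-8)
#' @return array of the common shape
#' @examples
#' floored_mod(0.7, 0.3)   # 0.1
#' floored_mod(-0.7, 0.3)  # 0.2
#' @export
floored_mod <- function(a, b, eps = 1e-8) {
  if (!identical(dim(a), dim(b)) || length(a) != length(b))
    stop("`a` and `b` must have identical shapes", call. = FALSE)
  stop_if_not_scalar(eps, "eps")
  if (eps <= 0) stop("`eps` must be positive", call. = FALSE)
  guard <- abs(b) < eps
  bs <- b
  bs[guard] <- 1  # dummy divisor, result overwritten below
  r <- a - bs * floor(a / bs)
  r[guard] <- 0
  r
}

# ---- ParameterSet ---------------------------------------------------------

# A ParameterSet is a named list of numeric arrays (the flat, ordered weight
# collection of one network). Two sets are conformable iff names, order and
# shapes match exactly.
check_conformable <- function(x, y) {
  if (!identical(names(x), names(y)))
    stop("parameter sets differ in names/order", call. = FALSE)
  for (nm in names(x)) {
    if (!identical(dim(x[[nm]]), dim(y[[nm]])) ||
        length(x[[nm]]) != length(y[[nm]]))
      stop(sprintf("parameter `%s` differs in shape", nm), call. = FALSE)
  }
  invisible(TRUE)
}

#' Exponential moving average (EMA) update of teacher weights
#'
#' `teacher_new = alpha * teacher + (1 - alpha) * student`, applied
#' element-wise across every tensor of the two parameter sets. With
#' `alpha = 0` the teacher becomes a copy of the student; with `alpha = 1`
#' it is unchanged.
#'
#' @param teacher,student conformable parameter sets (named lists of
#'   numeric arrays with matching names, order and shapes)
#' @param alpha decay coefficient in `[0, 1]`
#' @return the updated teacher parameter set
#' @seealso [pema_update()], [ema_alpha()]
#' @export
ema_update <- function(teacher, student, alpha) {
  check_conformable(teacher, student)
  stop_if_not_scalar(alpha, "alpha")
  if (alpha < 0 || alpha > 1) stop("`alpha` must lie in [0, 1]", call. = FALSE)
  out <- teacher
  for (nm in names(teacher))
    out[[nm]] <- alpha * teacher[[nm]] + (1 - alpha) * student[[nm]]
  out
}

#' Perturbation-enhanced EMA (pEMA) update
#'
#' The teacher is first updated by the plain EMA from the *unperturbed*
#' student; the student then receives an adaptive weight perturbation
#' `student + beta * mod(teacher_new, student)`, where `mod` is the
#' element-wise floored modulus ([floored_mod()]). Because the modulus
#' residual is bounded by the student's own weight magnitude, the
#' perturbation is small and scale-proportional; it decouples the two
#' models, which an unperturbed EMA drives towards near-identical
#' predictions. With `beta = 0` the update reduces exactly to
#' [ema_update()].
#'
#' @inheritParams ema_update
#' @param beta perturbation strength, `>= 0` (default of the training loop:
#'   0.001)
#' @param eps near-zero-divisor guard passed to [floored_mod()]
#' @return list with elements `teacher` (post-EMA) and `student` (perturbed)
#' @export
pema_update <- function(teacher, student, alpha, beta, eps = 1e-8) {
  stop_if_not_scalar(beta, "beta")
  if (beta < 0) stop("`beta` must be non-negative", call. = FALSE)
  new_teacher <- ema_update(teacher, student, alpha)
  new_student <- student
  if (beta > 0) {
    for (nm in names(student))
      new_student[[nm]] <- student[[nm]] +
        beta * floored_mod(new_teacher[[nm]], student[[nm]], eps)
  }
  list(teacher = new_teacher, student = new_student)
}

#' Deep copy of a parameter set
#'
#' @param weights a parameter set
#' @return an independent copy; mutating one does not affect the other
#' @export
clone_weights <- function(weights) {
  lapply(weights, function(w) w + 0)
}

#' Per-layer perturbation-magnitude summary
#'
#' Diagnostic companion to [pema_update()]: the element-wise magnitude of
#' `beta * mod(teacher, student)` summarised per layer.
#'
#' @inheritParams pema_update
#' @return a tibble with columns `layer`, `n`, `max_abs`, `mean_abs`
#' @export
perturbation_summary <- function(teacher, student, beta, eps = 1e-8) {
  check_conformable(teacher, student)
  rows <- lapply(names(student), function(nm) {
    d <- beta * floored_mod(teacher[[nm]], student[[nm]], eps)
    tibble::tibble(layer = nm, n = length(d),
                   max_abs = max(abs(d)), mean_abs = mean(abs(d)))
  })
  do.call(rbind, rows)
}
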