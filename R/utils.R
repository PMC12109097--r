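#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state so callers' random streams are not disturbed.
#' With `seed = NULL` the code runs on the current stream.
#'
#' @param seed integer seed or `NULL`
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-(seed, step, purpose) sub-seed, kept below 2^31 so it is
# a valid R integer. Distinct purposes get disjoint streams so that adding
# or removing one source of randomness (e.g. the Monte-Carlo uncertainty
# passes of one training variant) never shifts the draws of another.
derive_seed <- function(seed, t = 0L, purpose = "") {
  pid <- sum(utf8ToInt(purpose) * seq_len(nchar(purpose))) %% 99991
  as.integer((as.numeric(seed) %% 65521) * 31013 +
               (as.numeric(t) %% 100003) * 9176 + pid * 17 + 1) %% 2147483629L
}

stop_if_not_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
}

# ---- image/batch plumbing -------------------------------------------------

# Coerce a single matrix, a list of matrices, or an (H, W, C, N) array to the
# canonical (H, W, Cin, N) batch array.
as_image_batch <- function(x, in_channels = 1L) {
  if (is.list(x)) {
    stopifnot(length(x) >= 1L)
    H <- nrow(x[[1]]); W <- ncol(x[[1]])
    out <- array(0, dim = c(H, W, in_channels, length(x)))
    for (i in seq_along(x)) {
      xi <- x[[i]]
      if (!all(dim(xi)[1:2] == c(H, W))) stop("images in a batch must share a grid")
      out[, , , i] <- xi
    }
    return(out)
  }
  d <- dim(x)
  if (is.matrix(x)) return(array(x, dim = c(d[1], d[2], 1L, 1L)))
  if (length(d) == 3L) return(array(x, dim = c(d, 1L)))
  if (length(d) == 4L) return(x)
  stop("cannot interpret input as an image batch")
}

# Validate an (H, W, C) or (H, W, C, N) probability array.
check_probability_map <- function(p, tol = 1e-5) {
  d <- dim(p)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop("probability map must be an (H, W, C[, N]) array")
  if (any(p < -tol) || any(p > 1 + tol))
    stop("probability values must lie in [0, 1]")
  sums <- apply(p, setdiff(seq_along(d), 3L), sum)
  if (any(abs(sums - 1) > tol))
    stop("per-pixel channel sums must equal 1")
  invisible(TRUE)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
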