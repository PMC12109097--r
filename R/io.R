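# Runtime persistence and import helpers. Checkpoints are plain RDS files
# holding (backbone config, student and teacher parameter sets, iteration,
# momentum buffers, train config), so training and evaluation can resume
# reproducibly.

#' Save / load a fitted model
#'
#' @param fit a `pemt_fit`
#' @param path file path (RDS)
#' @return `load_checkpoint` returns the `pemt_fit`
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "pemt_fit"))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  fit <- readRDS(path)
  stopifnot(inherits(fit, "pemt_fit"))
  fit
}

#' Write a training log as CSV
#'
#' Columns: t, lr, lambda, tau, supervised, consistency, masked_fraction,
#' total — one row per iteration.
#'
#' @param fit a `pemt_fit` (or its `log` tibble)
#' @param path output CSV path
#' @export
write_training_log <- function(fit, path) {
  log <- if (inherits(fit, "pemt_fit")) fit$log else fit
  write.csv(log, path, row.names = FALSE)
  invisible(path)
}

#' Export an uncertainty map
#'
#' Writes the raw values as CSV and, when the `png` package is available,
#' a grayscale heatmap PNG (values rescaled to the map's range).
#'
#' @param u `H x W` uncertainty matrix
#' @param csv_path path for the CSV (or `NULL` to skip)
#' @param png_path path for the PNG (or `NULL` to skip)
#' @export
export_uncertainty <- function(u, csv_path = NULL, png_path = NULL) {
  if (!is.null(csv_path))
    write.csv(u, csv_path, row.names = FALSE)
  if (!is.null(png_path)) {
    if (!requireNamespace("png", quietly = TRUE))
      stop("the `png` package is required for PNG export", call. = FALSE)
    rng <- range(u)
    scaled <- if (diff(rng) > 0) (u - rng[1]) / diff(rng) else u * 0
    png::writePNG(t(scaled), png_path)
  }
  invisible(NULL)
}

#' Extract 2D slices from a NIfTI volume
#'
#' Import path for real MRI data: reads a volume with `RNifti` and returns
#' axial slices rescaled to `[0, 1]`, ready for [predict.pemt_fit()] or for
#' assembling a dataset in the same list-of-samples shape the synthetic
#' generator produces.
#'
#' @param path NIfTI file
#' @param slices slice indices along the third axis (default: all)
#' @return list of matrices in `[0, 1]`
#' @export
read_nifti_slices <- function(path, slices = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("the `RNifti` package is required to read NIfTI volumes",
         call. = FALSE)
  vol <- RNifti::asNifti(RNifti::readNifti(path))
  arr <- as.array(vol)
  if (length(dim(arr)) < 3) arr <- array(arr, c(dim(arr), 1))
  if (is.null(slices)) slices <- seq_len(dim(arr)[3])
  rng <- range(arr, finite = TRUE)
  lapply(slices, function(k) {
    m <- arr[, , k]
    if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
  })
}
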