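# Evaluation metrics: region-cropped PSNR and contour-accuracy distances.

#' Peak signal-to-noise ratio
#'
#' `10 * log10(peak^2 / MSE)` in dB; higher means closer. Identical images
#' have no finite PSNR: a classed warning (`levelseg_infinite_psnr`) is
#' signalled and `Inf` returned.
#'
#' @param reference,test same-shape [gray_image]s or matrices.
#' @param peak peak intensity; defaults to 255 (8-bit convention)
#'   regardless of float storage.
#' @return PSNR in dB.
#' @export
psnr <- function(reference, test, peak = 255) {
  a <- as_pixels(reference); b <- as_pixels(test)
  if (!all(dim(a) == dim(b))) stop("image shapes differ", call. = FALSE)
  if (peak <= 0) stop("peak must be positive", call. = FALSE)
  mse <- mean((a - b)^2)
  if (mse == 0) {
    warning(structure(
      class = c("levelseg_infinite_psnr", "warning", "condition"),
      list(message = "images are identical: PSNR is infinite", call = NULL)))
    return(Inf)
  }
  10 * log10(peak^2 / mse)
}

# Per-point nearest distance from each row of `a` to the point set `b`.
nearest_dists <- function(a, b) {
  # chunked to keep the distance matrix small
  n <- nrow(a)
  out <- numeric(n)
  step <- 2048L
  for (s in seq(1L, n, by = step)) {
    idx <- s:min(s + step - 1L, n)
    d2 <- outer(a[idx, 1], b[, 1], "-")^2 + outer(a[idx, 2], b[, 2], "-")^2
    out[idx] <- sqrt(apply(d2, 1L, min))
  }
  out
}

#' Mean contour-to-truth distance
#'
#' Mean over contour points of the distance to the nearest ground-truth
#' boundary point. Zero iff every contour point lies on the truth set.
#'
#' @param contour a contour (from [extract_zero_contour]), list of contours,
#'   or an n x 2 point matrix (row, col).
#' @param truth ground-truth boundary points, same forms accepted.
#' @return Mean distance in pixels.
#' @export
mean_contour_distance <- function(contour, truth) {
  a <- contour_points(contour); b <- contour_points(truth)
  if (is.null(a) || nrow(a) == 0L) stop("empty contour", call. = FALSE)
  if (is.null(b) || nrow(b) == 0L) stop("empty truth set", call. = FALSE)
  mean(nearest_dists(a, b))
}

#' Hausdorff distance between point sets
#'
#' Symmetric worst-case distance: `max(sup_a inf_b d, sup_b inf_a d)`.
#' Always at least [mean_contour_distance].
#'
#' @inheritParams mean_contour_distance
#' @return Hausdorff distance in pixels.
#' @export
hausdorff <- function(contour, truth) {
  a <- contour_points(contour); b <- contour_points(truth)
  if (is.null(a) || nrow(a) == 0L) stop("empty contour", call. = FALSE)
  if (is.null(b) || nrow(b) == 0L) stop("empty truth set", call. = FALSE)
  max(max(nearest_dists(a, b)), max(nearest_dists(b, a)))
}
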