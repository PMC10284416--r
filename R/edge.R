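# Edge indicator g = 1 / (1 + |grad(smoothed I)|^2): close to 1 in flat
# regions, small at intensity edges; it gates the contour's motion. g is
# computed once from the input image (on the 0-255 scale, so defaults are
# meaningful) and held fixed during evolution.

#' Gradient magnitude of a 2-D field
#'
#' Central differences in the interior, one-sided differences at the
#' borders; magnitude is `sqrt(dx^2 + dy^2)`. Exact for affine fields.
#'
#' @param field numeric matrix (or [gray_image]); at least 3x3.
#' @return Numeric matrix of the same shape.
#' @export
gradient_magnitude <- function(field) {
  px <- as_pixels(field)
  g <- grad_onesided(px)
  sqrt(g$dr^2 + g$dc^2)
}

# d/drow and d/dcol, central interior / one-sided borders (the semantics of
# numpy.gradient and MATLAB gradient).
grad_onesided <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3L || nc < 3L) stop("field must be at least 3x3", call. = FALSE)
  up <- m[c(2:nr, nr), , drop = FALSE]
  dn <- m[c(1L, 1:(nr - 1L)), , drop = FALSE]
  dr <- (up - dn) / 2
  dr[1L, ] <- m[2L, ] - m[1L, ]
  dr[nr, ] <- m[nr, ] - m[nr - 1L, ]
  rt <- m[, c(2:nc, nc), drop = FALSE]
  lf <- m[, c(1L, 1:(nc - 1L)), drop = FALSE]
  dc <- (rt - lf) / 2
  dc[, 1L] <- m[, 2L] - m[, 1L]
  dc[, nc] <- m[, nc] - m[, nc - 1L]
  list(dr = dr, dc = dc)
}

new_edge_map <- function(values, variant) {
  structure(list(values = values, variant = variant), class = "edge_map")
}

#' @export
print.edge_map <- function(x, ...) {
  cat(sprintf("<edge_map (%s) %dx%d, range [%.4g, %.4g]>\n", x$variant,
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

# g from an already-smoothed intensity field.
edge_map_from_smoothed <- function(smoothed, variant) {
  m <- gradient_magnitude(smoothed)
  new_edge_map(1 / (1 + m^2), variant)
}

#' Gaussian edge indicator
#'
#' `g = 1 / (1 + |grad(G_sigma * I)|^2)` where `G_sigma * I` is the
#' Gaussian-smoothed image. Values lie in (0, 1]; g equals 1 wherever the
#' smoothed gradient vanishes.
#'
#' @param image a [gray_image] or matrix on the 0-255 scale.
#' @param spec a [gaussian_spec].
#' @return An `edge_map`.
#' @export
edge_indicator_gaussian <- function(image, spec = gaussian_spec()) {
  edge_map_from_smoothed(as_pixels(gaussian_smooth(image, spec)), "gaussian")
}

#' Bilateral edge indicator
#'
#' As [edge_indicator_gaussian] but the smoothing stage is the
#' edge-preserving bilateral filter, so noise gradients in flat regions are
#' suppressed while genuine edges keep a strong gradient (small g).
#'
#' @param image a [gray_image] or matrix on the 0-255 scale.
#' @param spec a [bilateral_spec].
#' @return An `edge_map`.
#' @export
edge_indicator_bilateral <- function(image, spec = bilateral_spec()) {
  edge_map_from_smoothed(as_pixels(bilateral_smooth(image, spec)), "bilateral")
}

# Accept edge_map or bare matrix where g is needed.
as_g <- function(g) {
  if (inherits(g, "edge_map")) g$values
  else if (is.matrix(g) && is.numeric(g)) g
  else stop("expected an edge_map or numeric matrix", call. = FALSE)
}
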