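# Synthetic test scenes with known ground truth. These stand in for the
# classic cell/coin/microbe toolbox images: piecewise-constant objects on a
# flat background, optionally corrupted by additive Gaussian noise.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Dense sub-pixel samples of a circle, 1-based pixel-center coordinates.
circle_points <- function(center, radius, n = max(360L, ceiling(8 * radius))) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(row = center[1] + radius * sin(th), col = center[2] + radius * cos(th))
}

new_scene_truth <- function(mask, boundary, noise_sigma = 0, seed = NA_integer_) {
  structure(list(mask = mask, boundary = boundary,
                 noise_sigma = noise_sigma, seed = seed),
            class = "scene_truth")
}

#' Synthetic disk scene with ground truth
#'
#' Builds a piecewise-constant image: intensity `fg` on the closed disk of
#' the given radius, `bg` elsewhere, plus a `scene_truth` carrying the exact
#' foreground mask and a dense sub-pixel sampling of the true circle.
#' The disk must keep a margin of at least 2 pixels to every frame edge.
#'
#' @param height,width image size in pixels (at least 3).
#' @param center numeric `c(row, col)` of the disk center, 1-based
#'   pixel-center coordinates.
#' @param radius disk radius in pixels, at least 3.
#' @param fg,bg foreground / background intensity (0-255 scale).
#' @return A list with elements `image` ([gray_image]) and `truth`
#'   (`scene_truth` with fields `mask`, `boundary`, `noise_sigma`, `seed`).
#' @examples
#' sc <- make_disk_image(64, 64, c(32, 32), 10, fg = 200, bg = 50)
#' sum(sc$truth$mask)
#' @export
make_disk_image <- function(height, width, center, radius,
                            fg = 200, bg = 50) {
  height <- as.integer(height); width <- as.integer(width)
  if (radius < 3) stop("radius must be at least 3 px", call. = FALSE)
  if (center[1] - radius < 3 || center[1] + radius > height - 2 ||
      center[2] - radius < 3 || center[2] + radius > width - 2) {
    stop("disk must lie fully inside the frame with a 2 px margin",
         call. = FALSE)
  }
  r <- matrix(seq_len(height), height, width)
  c_ <- matrix(seq_len(width), height, width, byrow = TRUE)
  mask <- (r - center[1])^2 + (c_ - center[2])^2 <= radius^2
  px <- matrix(bg, height, width)
  px[mask] <- fg
  list(image = gray_image(px, value_range = 255),
       truth = new_scene_truth(mask, circle_points(center, radius)))
}

#' Synthetic multi-blob scene with ground truth
#'
#' Union of disks (`fg` over `bg`); emulates multi-object scenes such as
#' coins or microbial colonies. Each disk obeys the same margin rule as
#' [make_disk_image].
#'
#' @param height,width image size in pixels.
#' @param centers numeric matrix, one `c(row, col)` center per row.
#' @param radii vector of radii, one per center.
#' @inheritParams make_disk_image
#' @return As [make_disk_image]; `truth$boundary` concatenates every circle.
#' @export
make_blobs_image <- function(height, width, centers, radii,
                             fg = 200, bg = 50) {
  centers <- rbind(centers)
  stopifnot(nrow(centers) == length(radii))
  mask <- matrix(FALSE, height, width)
  boundary <- NULL
  for (k in seq_len(nrow(centers))) {
    d <- make_disk_image(height, width, centers[k, ], radii[k], fg, bg)
    mask <- mask | d$truth$mask
    boundary <- rbind(boundary, d$truth$boundary)
  }
  px <- matrix(bg, height, width)
  px[mask] <- fg
  list(image = gray_image(px, value_range = 255),
       truth = new_scene_truth(mask, boundary))
}

#' Add clipped Gaussian noise
#'
#' Adds i.i.d. `N(0, sigma^2)` noise to every pixel and clips the result to
#' `[0, value_range]`. The same seed reproduces the output bit for bit; the
#' caller's RNG state is untouched.
#'
#' @param image a [gray_image].
#' @param sigma noise standard deviation in intensity units; non-negative.
#' @param seed integer RNG seed.
#' @return A noisy [gray_image] with the same `value_range`.
#' @export
add_gaussian_noise <- function(image, sigma, seed = 0L) {
  px <- as_pixels(image)
  vr <- if (inherits(image, "gray_image")) image$value_range else 255
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  if (sigma == 0) return(gray_image(px, value_range = vr))
  noise <- with_seed(seed, matrix(stats::rnorm(length(px), 0, sigma),
                                  nrow(px), ncol(px)))
  out <- px + noise
  out[out < 0] <- 0
  out[out > vr] <- vr
  gray_image(out, value_range = vr)
}

#' Standard noisy-disk evaluation fixture
#'
#' The canonical scene used throughout the package's evaluation protocol:
#' a radius-30 disk of intensity 200 on background 50, centered in a
#' 128x128 frame, corrupted by clipped Gaussian noise.
#'
#' @param noise_sigma noise standard deviation (8-bit intensity units).
#' @param seed RNG seed for the noise.
#' @param height,width,radius scene geometry overrides.
#' @return A list with `clean` and `noisy` ([gray_image]) and `truth`.
#' @export
noisy_disk_fixture <- function(noise_sigma = 10, seed = 0L,
                               height = 128L, width = 128L, radius = 30) {
  sc <- make_disk_image(height, width,
                        center = c((height + 1) / 2, (width + 1) / 2),
                        radius = radius, fg = 200, bg = 50)
  noisy <- add_gaussian_noise(sc$image, noise_sigma, seed = seed)
  list(clean = sc$image, noisy = noisy,
       truth = new_scene_truth(sc$truth$mask, sc$truth$boundary,
                               noise_sigma = noise_sigma, seed = seed))
}
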