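#' Grayscale image container
#'
#' A `gray_image` is a 2-D field of finite, non-negative intensities stored as
#' a numeric matrix (rows are the first index) together with its declared peak
#' value. Images read from 8-bit files carry `value_range = 255`; float data
#' in \[0, 1\] carries `value_range = 1`. Evolution needs interior pixels, so
#' images smaller than 3x3 are rejected.
#'
#' @param pixels numeric matrix of intensities.
#' @param value_range declared peak intensity (255 for 8-bit provenance,
#'   1 for float data).
#' @return An object of class `gray_image` with fields `pixels`, `height`,
#'   `width`, `value_range`.
#' @examples
#' img <- gray_image(matrix(128, 8, 8))
#' img$height
#' @export
gray_image <- function(pixels, value_range = 255) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  pixels <- unname(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 3L || ncol(pixels) < 3L) {
    stop(sprintf("image must be at least 3x3, got %dx%d",
                 nrow(pixels), ncol(pixels)), call. = FALSE)
  }
  if (!all(is.finite(pixels))) {
    stop("image contains non-finite pixel values", call. = FALSE)
  }
  if (min(pixels) < 0 || max(pixels) > value_range) {
    stop(sprintf("pixel values [%g, %g] outside declared range [0, %g]",
                 min(pixels), max(pixels), value_range), call. = FALSE)
  }
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
         value_range = as.numeric(value_range)),
    class = "gray_image"
  )
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %dx%d, range [%g, %g] of %g>\n",
              x$height, x$width, min(x$pixels), max(x$pixels), x$value_range))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) c(x$height, x$width)

# Accept either a gray_image or a bare matrix where a pixel field is needed.
as_pixels <- function(image) {
  if (inherits(image, "gray_image")) return(image$pixels)
  if (is.matrix(image) && is.numeric(image)) return(image)
  stop("expected a gray_image or numeric matrix", call. = FALSE)
}

# ---- NetPBM I/O -------------------------------------------------------------
# PGM (P2 ascii / P5 binary) and PPM (P3 / P6) readers; multi-channel input is
# collapsed by the unweighted channel mean. PNG/TIFF decoding is unavailable
# in this toolchain, so those extensions get an informative error.

read_pnm_tokens <- function(con, n) {
  # ascii header/body tokens, skipping '#' comments
  out <- numeric(0)
  while (length(out) < n) {
    tok <- scan(con, what = character(), n = n - length(out), quiet = TRUE,
                comment.char = "#")
    if (length(tok) == 0L) stop("truncated PNM stream", call. = FALSE)
    out <- c(out, as.numeric(tok))
  }
  out
}

#' Read a grayscale image
#'
#' Reads a PGM (P2/P5) or PPM (P3/P6) raster and normalizes it to an 8-bit
#' convention: pixels are floats in \[0, 255\] and `value_range` is 255.
#' Multi-channel (PPM) input is converted to luminance by the unweighted
#' channel mean. 16-bit files are rescaled to peak 255.
#'
#' @param path path to a `.pgm`/`.ppm` file.
#' @return A [gray_image].
#' @export
read_gray <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read image: no such file '%s'", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png", "tif", "tiff", "jpg", "jpeg")) {
    stop(sprintf(
      "'%s': only PGM/PPM (NetPBM) input is supported by this build; convert with e.g. ImageMagick or scikit-image",
      path), call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P3", "P5", "P6")) {
    stop(sprintf("'%s' is not a supported PGM/PPM file (magic '%s')",
                 path, magic), call. = FALSE)
  }
  hdr <- read_pnm_tokens(con, 3L)
  width <- as.integer(hdr[1]); height <- as.integer(hdr[2]); maxval <- hdr[3]
  if (is.na(width) || is.na(height) || width < 1L || height < 1L) {
    stop(sprintf("'%s': invalid PNM dimensions", path), call. = FALSE)
  }
  channels <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- width * height * channels
  if (magic %in% c("P2", "P3")) {
    vals <- read_pnm_tokens(con, n)
  } else {
    if (maxval > 255) {
      vals <- readBin(con, "integer", n = n, size = 2L, signed = FALSE,
                      endian = "big")
    } else {
      vals <- as.numeric(readBin(con, "integer", n = n, size = 1L,
                                 signed = FALSE))
    }
    if (length(vals) < n) stop("truncated PNM stream", call. = FALSE)
  }
  # raster order: rows top to bottom, channels interleaved
  if (channels == 3L) {
    vals <- (vals[seq(1, n, 3)] + vals[seq(2, n, 3)] + vals[seq(3, n, 3)]) / 3
  }
  px <- matrix(vals, nrow = height, ncol = width, byrow = TRUE)
  if (maxval != 255) px <- px * (255 / maxval)
  gray_image(px, value_range = 255)
}

#' Write a grayscale image as 8-bit ASCII PGM
#'
#' Pixels are rescaled to peak 255 if the image's `value_range` is not 255,
#' then rounded to integers. Round-tripping integer-valued 8-bit data through
#' [read_gray] is bit-exact.
#'
#' @param image a [gray_image] or numeric matrix.
#' @param path output path (`.pgm`).
#' @return `path`, invisibly.
#' @export
write_gray <- function(image, path) {
  px <- as_pixels(image)
  vr <- if (inherits(image, "gray_image")) image$value_range else 255
  px <- round(px * (255 / vr))
  px[px < 0] <- 0; px[px > 255] <- 255
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(px), nrow(px)), "255"), con)
  # one image row per line keeps lines short and the file diffable
  body <- apply(px, 1L, paste, collapse = " ")
  writeLines(body, con)
  invisible(path)
}
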