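#' Rectangular image region (1-based, inclusive)
#'
#' Regions use the `{[r0:r1],[c0:c1]}` convention of segmentation evaluation
#' tables: 1-based inclusive row and column ranges, rows first.
#'
#' @param rows integer vector `c(row_start, row_end)`.
#' @param cols integer vector `c(col_start, col_end)`.
#' @return An object of class `region`.
#' @examples
#' region(c(5, 145), c(145, 160))
#' @export
region <- function(rows, cols) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (length(rows) != 2L || length(cols) != 2L ||
      anyNA(rows) || anyNA(cols)) {
    stop("`rows` and `cols` must each be two integers", call. = FALSE)
  }
  if (rows[1] < 1L || rows[1] > rows[2]) {
    stop(sprintf("invalid row range [%d:%d]", rows[1], rows[2]), call. = FALSE)
  }
  if (cols[1] < 1L || cols[1] > cols[2]) {
    stop(sprintf("invalid column range [%d:%d]", cols[1], cols[2]),
         call. = FALSE)
  }
  structure(list(row_start = rows[1], row_end = rows[2],
                 col_start = cols[1], col_end = cols[2]),
            class = "region")
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("<region rows [%d:%d], cols [%d:%d]>\n",
              x$row_start, x$row_end, x$col_start, x$col_end))
  invisible(x)
}

#' Crop a rectangular region out of an image
#'
#' @param image a [gray_image].
#' @param reg a [region]; must lie within the image bounds.
#' @return A [gray_image] of size
#'   `(row_end - row_start + 1) x (col_end - col_start + 1)`.
#' @export
crop_region <- function(image, reg) {
  px <- as_pixels(image)
  stopifnot(inherits(reg, "region"))
  if (reg$row_end > nrow(px)) {
    stop(sprintf("region row %d exceeds image height %d",
                 reg$row_end, nrow(px)), call. = FALSE)
  }
  if (reg$col_end > ncol(px)) {
    stop(sprintf("region column %d exceeds image width %d",
                 reg$col_end, ncol(px)), call. = FALSE)
  }
  out <- px[reg$row_start:reg$row_end, reg$col_start:reg$col_end, drop = FALSE]
  vr <- if (inherits(image, "gray_image")) image$value_range else 255
  gray_image(out, value_range = vr)
}

#' Parse a region string of the form "r0:r1,c0:c1"
#'
#' @param text e.g. `"5:145,145:160"`.
#' @return A [region].
#' @export
parse_region <- function(text) {
  parts <- strsplit(text, ",", fixed = TRUE)[[1]]
  if (length(parts) != 2L) {
    stop("region must look like 'r0:r1,c0:c1'", call. = FALSE)
  }
  rng <- lapply(parts, function(p) as.integer(strsplit(p, ":")[[1]]))
  region(rng[[1]], rng[[2]])
}
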