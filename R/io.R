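#' Read and write RGB images
#'
#' PNG rasters are read into the package's working representation: a numeric
#' `H x W x 3` array of 0-255 intensities (row-major, y then x). Alpha
#' channels are dropped; grayscale PNGs are replicated across channels.
#'
#' @param path File path (PNG).
#' @param image Numeric array `H x W x 3`, intensities 0-255.
#' @return `read_rgb_image()` returns the array; `write_rgb_image()` returns
#'   `path` invisibly.
#' @export
read_rgb_image <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("No such image file: %s", path),
          class = "labripe_input_error")
  }
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3), c(dim(x), 3L))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  round(x * 255)
}

#' @rdname read_rgb_image
#' @export
write_rgb_image <- function(image, path) {
  check_image(image)
  png::writePNG(pmin(pmax(image, 0), 255) / 255, path)
  invisible(path)
}

#' Read spectrometer CIE L*a*b* readings from CSV
#'
#' Expects a header `L,a,b` (extra columns such as `group`, `day`, `fruit`
#' are kept), one reading per row.
#'
#' @param path CSV file path.
#' @return A tibble with at least columns `L`, `a`, `b`.
#' @export
read_lab_csv <- function(path) {
  x <- as_tibble(utils::read.csv(path, check.names = TRUE))
  if (!all(c("L", "a", "b") %in% names(x))) {
    abort("Lab CSV must have columns `L`, `a`, `b`.",
          class = "labripe_input_error")
  }
  x
}
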