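#' Bounding boxes and cropping
#'
#' Boxes are 0-based, half-open pixel rectangles `[x0, x1) x [y0, y1)` with x
#' along image columns and y along rows, the convention of the external object
#' detectors this package can consume. `whole_image_box()` is the packaged
#' trivial provider used when no detector is attached.
#'
#' @param x0,y0,x1,y1 Integer pixel coordinates, `x0 < x1`, `y0 < y1`.
#' @param image Numeric array `H x W x 3`.
#' @param box A `bounding_box`.
#' @return `bounding_box()` returns a classed list; `crop_image()` the cropped
#'   `H x W x 3` array.
#' @export
bounding_box <- function(x0, y0, x1, y1) {
  if (!(x0 < x1 && y0 < y1) || any(c(x0, y0) < 0)) {
    abort("Bounding box requires 0 <= x0 < x1 and 0 <= y0 < y1.",
          class = "labripe_input_error")
  }
  structure(list(x0 = as.integer(x0), y0 = as.integer(y0),
                 x1 = as.integer(x1), y1 = as.integer(y1)),
            class = "bounding_box")
}

#' @rdname bounding_box
#' @export
whole_image_box <- function(image) {
  check_image(image)
  bounding_box(0, 0, dim(image)[2], dim(image)[1])
}

#' @rdname bounding_box
#' @export
crop_image <- function(image, box) {
  check_image(image)
  stopifnot(inherits(box, "bounding_box"))
  d <- dim(image)
  if (box$x1 > d[2] || box$y1 > d[1]) {
    abort("Bounding box exceeds image bounds.", class = "labripe_input_error")
  }
  image[(box$y0 + 1):box$y1, (box$x0 + 1):box$x1, , drop = FALSE]
}

#' Grayscale conversion with standard luma weights
#'
#' @param image Numeric array `H x W x 3`, intensities 0-255.
#' @return An `H x W` matrix of intensities.
#' @export
grayscale <- function(image) {
  check_image(image)
  0.2989 * image[, , 1] + 0.5870 * image[, , 2] + 0.1140 * image[, , 3]
}

#' Otsu's global threshold
#'
#' Finds the threshold T over the 256-bin histogram of an 8-bit grayscale
#' raster that maximises the between-class variance
#' \eqn{\omega_0 \omega_1 (\mu_0 - \mu_1)^2} of the split
#' `{intensity <= T} / {intensity > T}`. Ties are broken towards the lowest
#' such T. Intensities are clamped to `[0, 255]` and binned by `floor()`.
#'
#' @param gray Numeric matrix of intensities on the 0-255 scale, with at least
#'   two distinct levels.
#' @return The threshold T (integer in 0-254).
#' @export
otsu_threshold <- function(gray) {
  if (!is.matrix(gray) || length(gray) == 0L) {
    abort("`gray` must be a non-empty matrix.", class = "labripe_input_error")
  }
  lev <- pmin(pmax(floor(gray), 0), 255)
  h <- tabulate(as.integer(lev) + 1L, nbins = 256L)
  if (sum(h > 0) < 2L) {
    abort("Constant image: Otsu threshold undefined.",
          class = "labripe_degenerate_error")
  }
  n <- sum(h)
  p <- h / n
  levels <- 0:255
  w0 <- cumsum(p)
  mu <- cumsum(p * levels)
  mu_total <- mu[256]
  # between-class variance for T = 0..254 (split at <= T)
  w0_t <- w0[1:255]
  mu0_t <- mu[1:255]
  valid <- w0_t > 0 & w0_t < 1
  sigma_b <- rep(-Inf, 255)
  sigma_b[valid] <- (mu_total * w0_t[valid] - mu0_t[valid])^2 /
    (w0_t[valid] * (1 - w0_t[valid]))
  which.max(sigma_b) - 1L  # which.max takes the first (lowest T) maximiser
}

#' Binarize a crop into a foreground mask
#'
#' Converts the crop to grayscale with the standard luma weights and marks a
#' pixel foreground (1) iff its intensity strictly exceeds the threshold T --
#' the lightbox convention of a bright fruit on a dark backdrop. Set
#' `polarity = "dark-foreground"` to invert (fruit darker than background), or
#' `polarity = "auto"` to pick the class whose pixel centroid lies nearer the
#' crop centre, which suits hand-held photographs with arbitrary backgrounds.
#'
#' @param crop Numeric array `H x W x 3`, intensities 0-255.
#' @param T Threshold in `[0, 255]`, typically from [otsu_threshold()].
#' @param polarity `"bright-foreground"` (default), `"dark-foreground"`, or
#'   `"auto"`.
#' @return An object of class `foreground_mask`: an `H x W` 0/1 matrix with
#'   attributes `threshold` and `polarity`.
#' @export
binarize <- function(crop, T,
                     polarity = c("bright-foreground", "dark-foreground",
                                  "auto")) {
  check_image(crop)
  polarity <- match.arg(polarity)
  if (!is.numeric(T) || length(T) != 1L || !is.finite(T) || T < 0 || T > 255) {
    abort("`T` must be a single value in [0, 255].",
          class = "labripe_input_error")
  }
  g <- grayscale(crop)
  mask <- (g > T) * 1
  if (polarity == "dark-foreground") {
    mask <- 1 - mask
  } else if (polarity == "auto") {
    mask <- resolve_auto_polarity(mask)
  }
  structure(mask, threshold = T, polarity = polarity,
            class = c("foreground_mask", class(mask)))
}

resolve_auto_polarity <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  centre <- c((h + 1) / 2, (w + 1) / 2)
  dist_to_centre <- function(m) {
    idx <- which(m == 1, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(Inf)
    sqrt(mean(((idx[, 1] - centre[1]) / h)^2 + ((idx[, 2] - centre[2]) / w)^2))
  }
  if (dist_to_centre(1 - mask) < dist_to_centre(mask)) 1 - mask else mask
}

#' Mean RGB color of the foreground
#'
#' Averages each channel over foreground pixels only, yielding the single
#' "as if measured at one point" color that feeds the CIELAB conversion.
#' Background pixel values never influence the result.
#'
#' @param crop Numeric array `H x W x 3`, intensities 0-255.
#' @param mask A [binarize()] mask (or any 0/1 matrix of matching size).
#' @return A one-row tibble with columns `r`, `g`, `b` and `n_foreground`.
#' @export
foreground_mean_rgb <- function(crop, mask) {
  check_image(crop)
  if (!all(dim(mask) == dim(crop)[1:2])) {
    abort("Mask and crop dimensions differ.", class = "labripe_input_error")
  }
  sel <- mask == 1
  n <- sum(sel)
  if (n == 0L) {
    abort("Empty foreground: segmentation found no fruit pixels.",
          class = "labripe_empty_foreground_error")
  }
  tibble(
    r = mean(crop[, , 1][sel]),
    g = mean(crop[, , 2][sel]),
    b = mean(crop[, , 3][sel]),
    n_foreground = n
  )
}
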