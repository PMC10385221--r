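#' Overall brightness of an RGB image
#'
#' The overall brightness (OB) of an image is the equal-weight average over
#' the three channels of each channel's Minkowski p-mean of pixel intensities,
#' \deqn{OB = \frac{1}{3}\sum_{ch \in \{R,G,B\}}
#'   \Big(\frac{\sum_{x,y} I_{ch}(x,y)^p}{MN}\Big)^{1/p}}
#' computed on the 0-255 intensity scale so that OB is commensurate with the
#' per-channel brightness components. With the default `p = 2` this is the
#' root-mean-square intensity; a constant image of value v has OB = v.
#'
#' @param image Numeric array `H x W x 3`, intensities 0-255.
#' @param p Minkowski exponent, > 0. Default 2.
#' @return A single non-negative number.
#' @examples
#' overall_brightness(array(100, c(4, 4, 3))) # 100
#' @export
overall_brightness <- function(image, p = 2) {
  check_image(image)
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0) {
    abort("`p` must be a single positive number.",
          class = "labripe_input_error")
  }
  mean(vapply(1:3, function(ch) {
    mean(image[, , ch]^p)^(1 / p)
  }, numeric(1)))
}

check_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L ||
      any(dim(image)[1:2] < 1L)) {
    abort("`image` must be a non-empty H x W x 3 numeric array.",
          class = "labripe_input_error")
  }
  invisible(image)
}

# mean central-difference gradient magnitude of one channel, replicated edges
channel_gradient_mean <- function(m) {
  h <- nrow(m); w <- ncol(m)
  right <- m[, c(2:w, w), drop = FALSE]
  left <- m[, c(1, 1:max(w - 1, 1)), drop = FALSE]
  down <- m[c(2:h, h), , drop = FALSE]
  up <- m[c(1, 1:max(h - 1, 1)), , drop = FALSE]
  gx <- (right - left) / 2
  gy <- (down - up) / 2
  mean(sqrt(gx^2 + gy^2))
}

#' Ten-component brightness signature of an image
#'
#' Summarises an image's illumination by ten brightness components (BCs): the
#' overall brightness `ob` ([overall_brightness()], p = 2) plus, for each of
#' the R, G, B channels, the mean intensity (`br`, `bg`, `bb`), the contrast
#' as population standard deviation (`cr`, `cg`, `cb`), and the mean
#' central-difference gradient magnitude \eqn{\sqrt{G_x^2 + G_y^2}} with
#' replicated edges (`gr`, `gg`, `gb`). All on the 0-255 scale.
#'
#' @param image Numeric array `H x W x 3`, intensities 0-255.
#' @return A one-row tibble of class `brightness_components` with columns
#'   `ob, br, bg, bb, cr, cg, cb, gr, gg, gb`.
#' @seealso [standard_brightness()], [brightness_difference()]
#' @export
brightness_components <- function(image) {
  check_image(image)
  ch <- lapply(1:3, function(k) image[, , k])
  means <- vapply(ch, mean, numeric(1))
  contrasts <- vapply(ch, function(m) sqrt(mean((m - mean(m))^2)), numeric(1))
  grads <- vapply(ch, channel_gradient_mean, numeric(1))
  out <- tibble(
    ob = overall_brightness(image),
    br = means[1], bg = means[2], bb = means[3],
    cr = contrasts[1], cg = contrasts[2], cb = contrasts[3],
    gr = grads[1], gg = grads[2], gb = grads[3]
  )
  class(out) <- c("brightness_components", class(out))
  out
}

bc_names <- c("ob", "br", "bg", "bb", "cr", "cg", "cb", "gr", "gg", "gb")

as_bc_row <- function(x) {
  if (inherits(x, "standard_brightness")) x <- x$components
  x <- as_tibble(as.data.frame(x))[, bc_names]
  x
}

#' Standard Brightness: reference signature of a lightbox image set
#'
#' The Standard Brightness (SB) is the component-wise arithmetic mean of the
#' [brightness_components()] of a set of reference images photographed under
#' controlled ("lightbox") illumination. Incoming photographs are normalised
#' towards it by [aplt_adjust()].
#'
#' `sb_reference()` returns the packaged reference constants measured on the
#' original lightbox acquisition (720 images). Its `ob` component is stored
#' verbatim from that source and is a composite value on a scale of its own;
#' it is kept for completeness but excluded from [adjustment_accuracy()].
#'
#' @param images A list of `H x W x 3` arrays, or a data frame with a
#'   list-column `image` (e.g. from [generate_fixture_set()]).
#' @return An object of class `standard_brightness`: a list with `components`
#'   (one-row `brightness_components` tibble) and `n_images`.
#' @examples
#' sb_reference()$components
#' @export
standard_brightness <- function(images) {
  if (is.data.frame(images)) images <- images$image
  if (!is.list(images) || length(images) == 0L) {
    abort("`images` must be a non-empty list of RGB arrays.",
          class = "labripe_input_error")
  }
  comps <- purrr::map(images, brightness_components)
  m <- colMeans(do.call(rbind, lapply(comps, as.matrix)))
  new_standard_brightness(as_tibble(as.list(m)), length(images))
}

new_standard_brightness <- function(components, n_images) {
  components <- as_bc_row(components)
  class(components) <- c("brightness_components", class(components))
  structure(list(components = components, n_images = as.integer(n_images)),
            class = "standard_brightness")
}

#' @rdname standard_brightness
#' @export
sb_reference <- function() {
  new_standard_brightness(
    tibble(
      ob = 6.14,
      br = 117.91, bg = 117.44, bb = 67.88,
      cr = 45.44, cg = 45.70, cb = 71.96,
      gr = 18.02, gg = 18.54, gb = 19.35
    ),
    n_images = 720L
  )
}

#' @export
print.standard_brightness <- function(x, ...) {
  cat("Standard Brightness (", x$n_images, " reference image",
      if (x$n_images != 1) "s", ")\n", sep = "")
  print(as_tibble(x$components))
  invisible(x)
}

#' @export
tidy.standard_brightness <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x$components), dplyr::everything(),
                      names_to = "component", values_to = "value")
}

#' Read or write a Standard Brightness file
#'
#' Plain YAML serialization of the ten named brightness components plus the
#' reference image count, so a rig-specific calibration can be reused.
#'
#' @param path File path.
#' @param sb A `standard_brightness` object.
#' @return `read_standard_brightness()` returns a `standard_brightness`;
#'   `write_standard_brightness()` returns `path` invisibly.
#' @export
read_standard_brightness <- function(path) {
  x <- yaml::read_yaml(path)
  new_standard_brightness(as_tibble(x$components[bc_names]), x$n_images)
}

#' @rdname read_standard_brightness
#' @export
write_standard_brightness <- function(sb, path) {
  stopifnot(inherits(sb, "standard_brightness"))
  yaml::write_yaml(list(
    components = as.list(as.data.frame(sb$components)),
    n_images = sb$n_images
  ), path)
  invisible(path)
}

#' Power-law (gamma) intensity transformation
#'
#' Applies the power-law transform \eqn{v \mapsto c\,v^\gamma} per pixel and
#' channel on intensities normalised to `[0, 1]`, clips to `[0, 1]`, and
#' rescales to 0-255 integers. On the normalised scale \eqn{\gamma > 1}
#' darkens and \eqn{\gamma < 1} brightens; `c = 1, gamma = 1` is the identity
#' up to rounding.
#'
#' @param image Numeric array `H x W x 3`, intensities 0-255.
#' @param c Positive multiplicative constant.
#' @param gamma Non-negative exponent (`gamma = 0` maps every pixel to 255).
#' @return An `H x W x 3` array of 0-255 integers (stored as doubles).
#' @export
power_law_transform <- function(image, c = 1, gamma = 1) {
  check_image(image)
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0) {
    abort("`c` must be a single positive number.",
          class = "labripe_input_error")
  }
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma < 0) {
    abort("`gamma` must be a single non-negative number.",
          class = "labripe_input_error")
  }
  v <- image / 255
  round(255 * pmin(pmax(c * v^gamma, 0), 1))
}

#' City-block Brightness Difference between two component signatures
#'
#' The L1 (city-block) distance over the ten brightness components with equal
#' weights: the sum of absolute component differences. Zero iff all ten
#' components match exactly.
#'
#' @param candidate A `brightness_components` row (or coercible one-row data
#'   frame with the ten component columns).
#' @param sb A `standard_brightness` or `brightness_components`.
#' @return A single non-negative number.
#' @export
brightness_difference <- function(candidate, sb) {
  a <- as.matrix(as_bc_row(candidate))
  b <- as.matrix(as_bc_row(sb))
  sum(abs(a - b))
}

#' Automatic Power-Law Transformation (APLT)
#'
#' Normalises the illumination of an image towards a [standard_brightness()]
#' by an exhaustive grid search over power-law candidates
#' \eqn{c \cdot v^\gamma}. The branch rule halves the search: if the image's
#' overall brightness is at or above the reference OB it is too bright and the
#' darkening grid \eqn{\gamma \in \{1, \dots, 10\}} is searched, otherwise the
#' brightening grid \eqn{\gamma \in \{0, 0.1, \dots, 0.9\}}; in both branches
#' \eqn{c \in \{1, \dots, 10\}}, giving exactly 100 candidate images. The
#' candidate minimising the [brightness_difference()] to the SB is returned;
#' ties are broken towards the least aggressive transform (smallest
#' \eqn{|\gamma - 1|}, then smallest c). Equality of the two OBs is assigned
#' to the darkening branch so the identity candidate `c = 1, gamma = 1`
#' remains reachable.
#'
#' Note the reference SB's `ob` enters the brightness difference, so an SB
#' whose `ob` is on a different scale than [overall_brightness()] (such as the
#' packaged [sb_reference()]) shifts all 100 candidate BDs by a near-constant
#' amount and rarely changes the argmin; SBs calibrated with
#' [standard_brightness()] are internally consistent.
#'
#' @param image Numeric array `H x W x 3`, intensities 0-255.
#' @param sb A `standard_brightness`.
#' @return An object of class `aplt_result`: list with `c`, `gamma`, `bd`,
#'   `branch` (`"darken"` or `"brighten"`), `ob_ui`, `image` (the adjusted
#'   raster), `components` (its signature) and `candidates` (a 100-row tibble
#'   of `c`, `gamma`, `bd`). `tidy()` returns the candidate grid, `glance()`
#'   the selected parameters.
#' @examples
#' img <- array(rep(c(60, 120, 180), each = 16), c(4, 4, 3))
#' res <- aplt_adjust(img, standard_brightness(list(img)))
#' glance(res) # c = 1, gamma = 1, bd = 0
#' @export
aplt_adjust <- function(image, sb) {
  check_image(image)
  stopifnot(inherits(sb, "standard_brightness"))
  ob_ui <- overall_brightness(image)
  ob_ref <- sb$components$ob
  darken <- ob_ui >= ob_ref
  gammas <- if (darken) 1:10 else round(seq(0, 0.9, by = 0.1), 1)
  cs <- 1:10
  v <- image / 255

  grid <- tidyr::expand_grid(gamma = gammas, c = cs)
  best <- NULL
  bds <- numeric(nrow(grid))
  i <- 0L
  for (g in gammas) {
    vg <- v^g
    for (cc in cs) {
      i <- i + 1L
      cand <- round(255 * pmin(pmax(cc * vg, 0), 1))
      bd <- brightness_difference(brightness_components(cand), sb)
      bds[i] <- bd
      better <- is.null(best) ||
        bd < best$bd - 1e-12 ||
        (abs(bd - best$bd) <= 1e-12 &&
           (abs(g - 1) < abs(best$gamma - 1) - 1e-12 ||
              (abs(abs(g - 1) - abs(best$gamma - 1)) <= 1e-12 && cc < best$c)))
      if (better) best <- list(c = cc, gamma = g, bd = bd, image = cand)
    }
  }
  grid$bd <- bds
  structure(list(
    c = best$c, gamma = best$gamma, bd = best$bd,
    branch = if (darken) "darken" else "brighten",
    ob_ui = ob_ui,
    image = best$image,
    components = brightness_components(best$image),
    candidates = grid[, c("c", "gamma", "bd")]
  ), class = "aplt_result")
}

#' @export
print.aplt_result <- function(x, ...) {
  cat(sprintf(
    "APLT: selected c = %d, gamma = %.1f (%s branch), BD = %.2f\n",
    x$c, x$gamma, x$branch, x$bd
  ))
  invisible(x)
}

#' @export
tidy.aplt_result <- function(x, ...) as_tibble(x$candidates)

#' @export
glance.aplt_result <- function(x, ...) {
  tibble(c = x$c, gamma = x$gamma, bd = x$bd, branch = x$branch,
         ob_ui = x$ob_ui, n_candidates = nrow(x$candidates))
}

#' @export
autoplot.aplt_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(factor(.data$c), factor(.data$gamma),
                               fill = .data$bd)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(
      data = glance(object),
      ggplot2::aes(factor(.data$c), factor(.data$gamma)),
      inherit.aes = FALSE, shape = 4, size = 3
    ) +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = "c", y = "gamma", fill = "BD",
                  title = "Brightness difference over the candidate grid")
}

#' Nine-component illumination adjustment accuracy
#'
#' Scores how closely an adjusted image's brightness signature matches the
#' Standard Brightness: each of the nine per-channel components (mean,
#' contrast, gradient; all bounded by 0-255) contributes its absolute
#' deviation as a fraction of 255, and
#' \deqn{accuracy = 100 \times \Big(1 - \frac{1}{9}\sum |\Delta_i| / 255\Big)}
#' The composite `ob` component is disregarded.
#'
#' @param adjusted A `brightness_components` row (e.g. from
#'   `aplt_adjust(...)$components`).
#' @param sb A `standard_brightness`.
#' @return Accuracy percentage in `[0, 100]` (can go below 0 only if a
#'   component deviates by more than 255, which bounded inputs cannot).
#' @export
adjustment_accuracy <- function(adjusted, sb) {
  a <- as.matrix(as_bc_row(adjusted))
  b <- as.matrix(as_bc_row(sb))
  keep <- setdiff(bc_names, "ob")
  100 * (1 - mean(abs(a[, keep] - b[, keep]) / 255))
}
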