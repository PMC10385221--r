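#' Colorimetric extraction from color data (CEFCD)
#'
#' Turns spectrometer CIE L*a*b* readings into an angle of ripening. Readings
#' (typically three points along the fruit) are averaged on the a*/b* plane —
#' L* is discarded as unrelated to hue — and the mean chromaticity is passed
#' through [ripening_angle()]. No error constant is applied: the spectrometer
#' is the reference instrument.
#'
#' @param readings A data frame with numeric columns `a` and `b` (an `L`
#'   column is ignored), one row per reading.
#' @param table A [stage_table()] used only to stage the resulting angle.
#' @return A one-row tibble with `theta_deg`, `adjusted = FALSE`,
#'   `n_readings`, and the stage columns of [stage_from_angle()].
#' @examples
#' cefcd(data.frame(L = 51.23, a = -19.97, b = 56.35))
#' @export
cefcd <- function(readings, table = default_stage_table()) {
  readings <- as_tibble(readings)
  if (nrow(readings) == 0L) {
    abort("`readings` must contain at least one row.",
          class = "labripe_input_error")
  }
  check_lab_frame(readings)
  mean_color <- tibble(a = mean(readings$a), b = mean(readings$b))
  out <- stage_from_angle(ripening_angle(mean_color), table)
  out$n_readings <- nrow(readings)
  out
}

#' Colorimetric extraction from image (CEFI)
#'
#' The full photograph-to-ripeness pipeline: crop to the fruit bounding box,
#' normalise illumination to the Standard Brightness with [aplt_adjust()],
#' remove the background by [otsu_threshold()] + [binarize()], average the
#' foreground color ([foreground_mean_rgb()]), convert to CIELAB
#' ([rgb_to_lab()]), apply the error-constant-adjusted angle
#' ([adjusted_ripening_angle()]), and stage it ([stage_from_angle()]).
#'
#' A failure at any stage (degenerate crop, constant grayscale, empty
#' foreground) raises a `labripe_pipeline_error` naming the failed stage.
#' Intermediate artifacts (crop, APLT result, mask) are attached to the
#' result as the `"artifacts"` attribute for inspection.
#'
#' @param image Numeric array `H x W x 3`, intensities 0-255.
#' @param sb A [standard_brightness()] to normalise towards.
#' @param box Optional [bounding_box()] from an external detector; defaults to
#'   the whole image.
#' @param table A [stage_table()].
#' @param polarity Foreground polarity passed to [binarize()].
#' @param apply_error_constant Apply the table's error constant to the angle
#'   (default `TRUE`); set `FALSE` when calibrating the constant itself.
#' @return A one-row tibble of class `cefi_result` with the angle, stage,
#'   edibility and RDFC columns plus diagnostics: `theta_raw` (pre-adjustment
#'   angle), selected `c`/`gamma`/`bd`, the foreground mean color
#'   (`mean_r/g/b`, `n_foreground`) and its CIELAB rendering (`L`, `a`, `b`).
#' @export
cefi <- function(image, sb, box = NULL, table = default_stage_table(),
                 polarity = "bright-foreground",
                 apply_error_constant = TRUE) {
  at_stage <- function(stage_name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("CEFI failed at stage '%s': %s",
                    stage_name, conditionMessage(e)),
            class = "labripe_pipeline_error")
    })
  }
  crop <- at_stage("crop", {
    if (is.null(box)) box <- whole_image_box(image)
    crop_image(image, box)
  })
  aplt <- at_stage("aplt", aplt_adjust(crop, sb))
  mask <- at_stage("segment", {
    T <- otsu_threshold(grayscale(aplt$image))
    binarize(aplt$image, T, polarity)
  })
  fg <- at_stage("average-color", foreground_mean_rgb(aplt$image, mask))
  lab <- at_stage("rgb-to-lab", rgb_to_lab(fg))
  ang <- at_stage("angle", {
    if (apply_error_constant) adjusted_ripening_angle(lab, table)
    else ripening_angle(lab)
  })
  raw <- ripening_angle(lab)$theta_deg
  res <- at_stage("stage", stage_from_angle(ang, table))

  out <- tibble(
    theta_deg = res$theta_deg, adjusted = res$adjusted,
    stage = res$stage, edible = res$edible,
    rdfc_days = res$rdfc_days, days_to_ripe = res$days_to_ripe,
    theta_raw = raw,
    c = aplt$c, gamma = aplt$gamma, bd = aplt$bd,
    mean_r = fg$r, mean_g = fg$g, mean_b = fg$b,
    n_foreground = fg$n_foreground,
    L = lab$L, a = lab$a, b = lab$b
  )
  attr(out, "artifacts") <- list(crop = crop, aplt = aplt, mask = mask)
  class(out) <- c("cefi_result", class(out))
  out
}

#' @export
glance.cefi_result <- function(x, ...) {
  as_tibble(x)[, c("theta_deg", "stage", "edible", "rdfc_days",
                   "days_to_ripe")]
}

#' @export
autoplot.cefi_result <- function(object, ...) {
  art <- attr(object, "artifacts")
  m <- art$mask
  df <- tidyr::expand_grid(y = seq_len(nrow(m)), x = seq_len(ncol(m)))
  df$foreground <- as.vector(m) == 1
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$foreground)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("stage %d, theta = %.1f deg, RDFC = %s day(s)",
                      object$stage, object$theta_deg,
                      format(object$rdfc_days)),
      fill = "foreground"
    )
}

#' Error rate between paired spectrometer and image angles
#'
#' The calibration statistic behind the stage table's error constant: the
#' mean absolute difference between paired angles derived from color data
#' (CEFCD) and from images (CEFI), in degrees, across all groups and days.
#' (Counting every angle of both modalities as M values, the divisor M/2 is
#' the number of pairs, i.e. this is a mean absolute pairwise difference.)
#' It is symmetric in the two series and zero iff they agree exactly.
#'
#' @param series A data frame with numeric columns `theta_cefcd` and
#'   `theta_cefi`, one row per paired observation.
#' @return Mean absolute angular difference in degrees.
#' @export
error_rate <- function(series) {
  series <- as_tibble(series)
  if (nrow(series) == 0L) {
    abort("`series` must contain at least one pair.",
          class = "labripe_input_error")
  }
  if (!all(c("theta_cefcd", "theta_cefi") %in% names(series))) {
    abort("`series` must have columns `theta_cefcd` and `theta_cefi`.",
          class = "labripe_input_error")
  }
  mean(abs(series$theta_cefcd - series$theta_cefi))
}

#' Run the illumination-adjustment validation experiment
#'
#' Reproduces the validation design for the automatic power-law
#' transformation: the Standard Brightness is computed from the clean base
#' set; every base image is copied once per corruption gamma (default one
#' brightened copy at 0.5 and one darkened at 1.5, i.e. two validation images
#' per base image); every corrupted copy is re-normalised with
#' [aplt_adjust()]; and the nine-component [adjustment_accuracy()] is scored
#' against the SB.
#'
#' @param base_images A list of `H x W x 3` arrays or a data frame with an
#'   `image` list-column (e.g. [generate_fixture_set()]).
#' @param corruption_gammas Gammas used to corrupt each base image
#'   (default `c(0.5, 1.5)`).
#' @param sb Optional [standard_brightness()]; computed from the base set if
#'   `NULL`.
#' @return An object of class `validation_result`. `tidy()` gives the
#'   per-validation-image table (`image_id`, `corrupt_gamma`, selected
#'   `c`/`gamma`/`bd`, `accuracy`); `glance()` the summary (`n_base`,
#'   `n_validation`, `mean_accuracy`, `sd_accuracy`); `autoplot()` the
#'   selected-gamma distribution per corruption.
#' @export
run_validation_experiment <- function(base_images,
                                      corruption_gammas = c(0.5, 1.5),
                                      sb = NULL) {
  if (is.data.frame(base_images)) base_images <- base_images$image
  if (!is.list(base_images) || length(base_images) == 0L) {
    abort("`base_images` must be a non-empty list of RGB arrays.",
          class = "labripe_input_error")
  }
  if (is.null(sb)) sb <- standard_brightness(base_images)
  per <- purrr::map_dfr(seq_along(base_images), function(i) {
    purrr::map_dfr(corruption_gammas, function(g) {
      vi <- corrupt_brightness(base_images[[i]], g)
      res <- aplt_adjust(vi, sb)
      tibble(
        image_id = i, corrupt_gamma = g,
        c = res$c, gamma = res$gamma, bd = res$bd,
        accuracy = adjustment_accuracy(res$components, sb)
      )
    })
  })
  structure(list(per_image = per, sb = sb,
                 n_base = length(base_images),
                 n_validation = nrow(per)),
            class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "Illumination validation: %d base images, %d validation images\n",
    g$n_base, g$n_validation
  ))
  cat(sprintf("mean adjustment accuracy %.2f%% (SD %.2f)\n",
              g$mean_accuracy, g$sd_accuracy))
  invisible(x)
}

#' @export
tidy.validation_result <- function(x, ...) x$per_image

#' @export
glance.validation_result <- function(x, ...) {
  tibble(
    n_base = x$n_base, n_validation = x$n_validation,
    mean_accuracy = mean(x$per_image$accuracy),
    sd_accuracy = sd(x$per_image$accuracy)
  )
}

#' @export
autoplot.validation_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(factor(.data$gamma))) +
    ggplot2::geom_bar() +
    ggplot2::facet_wrap(~corrupt_gamma, scales = "free_x",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "selected gamma", y = "images",
                  title = "APLT gamma selection by corruption")
}
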