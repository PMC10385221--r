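#' Angle of ripening from CIELAB chromaticity
#'
#' Computes the hue statistic used to stage lady finger bananas: in the
#' green-yellow quadrant of CIELAB (negative a*, positive b*) the a* and b*
#' coordinates define a right triangle, and the angle opposite the b* side is
#' the angle of ripening,
#' \deqn{\theta = \arctan\!\big(b^* / |a^*|\big)}
#' in degrees. \eqn{\theta} runs from 0 (pure green) towards 90 (yellow/brown)
#' as the fruit ripens. Negative b* lies outside the green-yellow quadrant and
#' is clamped to 0; `a = 0` is handled as the degenerate limit (90 when
#' `b > 0`, 0 when `b = 0`) so the map is total.
#'
#' `adjusted_ripening_angle()` additionally applies the stage table's error
#' constant \eqn{E_\theta} (degrees, additive in the angle domain, signed by
#' the table's `error_sign`), which compensates the systematic offset of
#' camera-derived angles relative to spectrometer readings.
#'
#' @param colors A data frame with numeric columns `a` and `b` (CIELAB
#'   chromaticity; an `L` column is ignored). One row per reading.
#' @param table A [stage_table()]; its `error_constant` and `error_sign` drive
#'   the adjustment.
#' @return The input as a tibble with columns `theta_deg` (degrees) and
#'   `adjusted` (logical) appended.
#' @examples
#' ripening_angle(data.frame(a = -19.97, b = 56.35)) # theta ~ 70.5 degrees
#' adjusted_ripening_angle(data.frame(a = -1, b = 1), default_stage_table())
#' @export
ripening_angle <- function(colors) {
  colors <- as_tibble(colors)
  check_lab_frame(colors)
  a <- colors$a
  b <- pmax(colors$b, 0)
  theta <- ifelse(a == 0,
                  ifelse(b > 0, 90, 0),
                  atan(b / abs(a)) * 180 / pi)
  colors$theta_deg <- theta
  colors$adjusted <- FALSE
  colors
}

#' @rdname ripening_angle
#' @export
adjusted_ripening_angle <- function(colors, table = default_stage_table()) {
  stopifnot(inherits(table, "stage_table"))
  out <- ripening_angle(colors)
  e <- attr(table, "error_constant") * attr(table, "error_sign")
  out$theta_deg <- out$theta_deg + e
  out$adjusted <- TRUE
  out
}

check_lab_frame <- function(colors) {
  if (!all(c("a", "b") %in% names(colors))) {
    abort("`colors` must have columns `a` and `b`.",
          class = "labripe_input_error")
  }
  if (!all(is.finite(colors$a)) || !all(is.finite(colors$b))) {
    abort("Non-finite a*/b* values.", class = "labripe_input_error")
  }
  invisible(colors)
}

#' Convert mean RGB colors to CIE L*a*b*
#'
#' Standard sRGB to CIELAB conversion (D65 illuminant, 2 degree observer) for
#' 0-255 per-channel values, as applied to the average foreground color of a
#' segmented fruit. The white point is a convention of this package (the
#' acquisition rig's illuminant is not modelled); it can matter at the third
#' decimal but not at the scale of a 4-5 degree stage interval.
#'
#' @param colors A data frame with numeric columns `r`, `g`, `b` in `[0, 255]`.
#' @return A tibble with columns `L`, `a`, `b` (one row per input row).
#' @examples
#' rgb_to_lab(data.frame(r = 255, g = 255, b = 255)) # L = 100, a = b = 0
#' @export
rgb_to_lab <- function(colors) {
  colors <- as_tibble(colors)
  if (!all(c("r", "g", "b") %in% names(colors))) {
    abort("`colors` must have columns `r`, `g`, `b`.",
          class = "labripe_input_error")
  }
  m <- as.matrix(colors[, c("r", "g", "b")])
  if (!all(is.finite(m)) || any(m < 0) || any(m > 255)) {
    abort("RGB channels must be finite and in [0, 255].",
          class = "labripe_input_error")
  }
  lab <- unname(farver::convert_colour(unname(m), from = "rgb", to = "lab"))
  tibble(L = lab[, 1], a = lab[, 2], b = lab[, 3])
}

# inverse conversion used by the fixture generator; clips out-of-gamut values
lab_to_rgb <- function(lab) {
  m <- farver::convert_colour(as.matrix(lab[, c("L", "a", "b")]),
                              from = "lab", to = "rgb")
  pmin(pmax(m, 0), 255)
}

#' Map angles of ripening to ripeness stage, edibility and RDFC
#'
#' Locates each angle in the stage table's intervals (left-closed, right-open)
#' and derives the quantities a grower or distributor acts on:
#' \describe{
#'   \item{`stage`}{1-9 within the table; 0 below stage 1 (pre-ripe, the fruit
#'     will shrivel rather than ripen if cut); 10 at or beyond stage 9's upper
#'     bound (overripe).}
#'   \item{`edible`}{`TRUE` iff the stage is inside the table's edible window
#'     (default stages 5-9).}
#'   \item{`rdfc_days`}{Remaining days for consumption, counting the current
#'     day: `last_edible - stage + 1` within the window (5 at stage 5 down to
#'     1 at stage 9), 0 once overripe, the full window length before the fruit
#'     is ripe, and `NA` at the pre-ripe sentinel stage 0.}
#'   \item{`days_to_ripe`}{Days until the first edible stage
#'     (`first_edible - stage`, 0 once edible or overripe, `Inf` at stage 0).}
#' }
#' One ripeness stage corresponds to approximately 24 h of ripening.
#'
#' @param angles A data frame with a numeric `theta_deg` column (degrees),
#'   e.g. the output of [ripening_angle()].
#' @param table A [stage_table()].
#' @return The input as a tibble with `stage`, `edible`, `rdfc_days` and
#'   `days_to_ripe` columns appended.
#' @examples
#' stage_from_angle(data.frame(theta_deg = c(47, 67.5, 92)))
#' @export
stage_from_angle <- function(angles, table = default_stage_table()) {
  stopifnot(inherits(table, "stage_table"))
  angles <- as_tibble(angles)
  if (!"theta_deg" %in% names(angles) || !all(is.finite(angles$theta_deg))) {
    abort("`angles` must have a finite numeric `theta_deg` column.",
          class = "labripe_input_error")
  }
  breaks <- c(table$theta_low, table$theta_high[nrow(table)])
  stage <- findInterval(angles$theta_deg, breaks,
                        rightmost.closed = FALSE, left.open = FALSE)
  # findInterval: 0 below all breaks; length(breaks) = n_stages + 1 at/above
  # the last boundary, which is exactly the overripe sentinel n_stages + 1 - 1
  overripe <- nrow(table) + 1L
  stage[stage > nrow(table)] <- overripe
  first <- attr(table, "first_edible_stage")
  last <- attr(table, "last_edible_stage")
  window <- last - first + 1L
  edible <- stage >= first & stage <= last
  rdfc <- dplyr::case_when(
    stage == 0L ~ NA_real_,
    stage > last ~ 0,
    stage >= first ~ as.numeric(last - stage + 1L),
    TRUE ~ as.numeric(window)
  )
  dtr <- dplyr::case_when(
    stage == 0L ~ Inf,
    stage >= first ~ 0,
    TRUE ~ as.numeric(first - stage)
  )
  angles$stage <- as.integer(ifelse(stage == overripe, overripe, stage))
  angles$edible <- edible
  angles$rdfc_days <- rdfc
  angles$days_to_ripe <- dtr
  angles
}

#' @export
autoplot.stage_table <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$theta_low, xmax = .data$theta_high,
      ymin = 0, ymax = 1, fill = factor(.data$stage)
    ), colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(
      x = (.data$theta_low + .data$theta_high) / 2, y = 0.5,
      label = .data$stage
    )) +
    ggplot2::scale_fill_manual(
      values = grDevices::hcl.colors(nrow(df), "Green-Yellow"),
      guide = "none"
    ) +
    ggplot2::labs(x = "angle of ripening (degrees)", y = NULL,
                  title = "Ripeness stage intervals") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
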