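#' Stage table: hue-angle intervals defining ripeness stages
#'
#' A stage table maps the angle of ripening \eqn{\theta} (degrees) to ripeness
#' stages 1-9. It is an ordered set of contiguous, non-overlapping, left-closed
#' right-open intervals `[theta_low, theta_high)`, one per stage, together with
#' the calibration error constant \eqn{E_\theta} applied to image-derived
#' angles and the edible stage window.
#'
#' The default table spans \eqn{\theta \in [45^\circ, 90^\circ]} in nine 5
#' degree intervals (stage *s* covers `[40 + 5s, 45 + 5s)`), uses
#' \eqn{E_\theta = 2.8^\circ} with positive sign, and marks stages 5-9 as
#' edible. Angles below stage 1 map to the pre-ripe sentinel stage 0; angles at
#' or above stage 9's upper bound map to the overripe sentinel stage 10.
#'
#' @param boundaries A data frame with columns `stage`, `theta_low`,
#'   `theta_high` (degrees). Defaults to the nine 5-degree intervals above.
#' @param error_constant Error constant \eqn{E_\theta} in degrees, the mean
#'   absolute angular offset between image-derived and spectrometer-derived
#'   angles. Must be >= 0. Default 2.8.
#' @param error_sign Direction in which the constant is applied to
#'   image-derived angles, `+1` or `-1`. Default `+1`.
#' @param first_edible_stage,last_edible_stage Bounds of the edible window
#'   (defaults 5 and 9).
#' @return A tibble of class `stage_table` with one row per stage and the
#'   calibration settings stored as attributes.
#' @seealso [stage_from_angle()], [read_stage_table()]
#' @examples
#' tb <- default_stage_table()
#' attr(tb, "error_constant")
#' @export
stage_table <- function(boundaries = NULL,
                        error_constant = 2.8,
                        error_sign = 1L,
                        first_edible_stage = 5L,
                        last_edible_stage = 9L) {
  if (is.null(boundaries)) {
    boundaries <- tibble(
      stage = 1:9,
      theta_low = 40 + 5 * (1:9),
      theta_high = 45 + 5 * (1:9)
    )
  }
  boundaries <- as_tibble(boundaries)[, c("stage", "theta_low", "theta_high")]
  validate_stage_table_frame(boundaries)
  if (!is.numeric(error_constant) || length(error_constant) != 1L ||
      !is.finite(error_constant) || error_constant < 0) {
    abort("`error_constant` must be a single non-negative number.",
          class = "labripe_config_error")
  }
  if (!error_sign %in% c(-1, 1)) {
    abort("`error_sign` must be +1 or -1.", class = "labripe_config_error")
  }
  n <- max(boundaries$stage)
  if (!(first_edible_stage >= 1 && first_edible_stage <= last_edible_stage &&
        last_edible_stage <= n)) {
    abort("Edible window must satisfy 1 <= first <= last <= max stage.",
          class = "labripe_config_error")
  }
  structure(
    boundaries,
    error_constant = as.numeric(error_constant),
    error_sign = as.integer(error_sign),
    first_edible_stage = as.integer(first_edible_stage),
    last_edible_stage = as.integer(last_edible_stage),
    class = c("stage_table", class(boundaries))
  )
}

#' @rdname stage_table
#' @export
default_stage_table <- function() stage_table()

validate_stage_table_frame <- function(b) {
  ok <- nrow(b) >= 1 &&
    all(b$stage == seq_len(nrow(b))) &&
    all(is.finite(b$theta_low)) && all(is.finite(b$theta_high)) &&
    all(b$theta_low < b$theta_high)
  if (ok && nrow(b) > 1) {
    # contiguity: each interval starts where the previous one ends
    ok <- all(abs(b$theta_low[-1] - b$theta_high[-nrow(b)]) < 1e-9)
  }
  if (!ok) {
    abort(paste0(
      "Malformed stage table: intervals must be contiguous, non-overlapping ",
      "and strictly increasing, with stages numbered 1..n."
    ), class = "labripe_config_error")
  }
  invisible(b)
}

#' Read or write a stage table as a YAML config file
#'
#' The on-disk format is a plain YAML document holding the stage boundaries in
#' degrees, the error constant and sign, and the edible window, so that a table
#' calibrated for another camera rig can be shipped alongside an analysis.
#'
#' @param path File path.
#' @param table A `stage_table`.
#' @return `read_stage_table()` returns a `stage_table`;
#'   `write_stage_table()` returns `path` invisibly.
#' @export
read_stage_table <- function(path) {
  x <- yaml::read_yaml(path)
  stage_table(
    boundaries = tibble(
      stage = vapply(x$stages, `[[`, numeric(1), "stage"),
      theta_low = vapply(x$stages, `[[`, numeric(1), "theta_low"),
      theta_high = vapply(x$stages, `[[`, numeric(1), "theta_high")
    ),
    error_constant = x$error_constant,
    error_sign = x$error_sign,
    first_edible_stage = x$first_edible_stage,
    last_edible_stage = x$last_edible_stage
  )
}

#' @rdname read_stage_table
#' @export
write_stage_table <- function(table, path) {
  stopifnot(inherits(table, "stage_table"))
  yaml::write_yaml(list(
    stages = lapply(seq_len(nrow(table)), function(i) list(
      stage = table$stage[i],
      theta_low = table$theta_low[i],
      theta_high = table$theta_high[i]
    )),
    error_constant = attr(table, "error_constant"),
    error_sign = attr(table, "error_sign"),
    first_edible_stage = attr(table, "first_edible_stage"),
    last_edible_stage = attr(table, "last_edible_stage")
  ), path)
  invisible(path)
}
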