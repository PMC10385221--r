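#' Specification for synthetic lightbox fixtures
#'
#' Describes the simulated acquisition the generators emulate: four
#' experimental groups of fruit (wrapped/unwrapped at 25/30 degrees C), 20
#' fruit per group followed for nine days with one ripeness stage per day,
#' photographed on a dark lightbox backdrop. The fruit's skin hue follows a
#' green-to-yellow trajectory through the stage-table intervals (4-5 degrees
#' per stage), with per-fruit jitter, stage-increasing dark freckles, and a
#' small camera-side hue depression (`camera_bias_deg`) emulating the
#' systematic offset of image-derived angles from spectrometer readings that
#' the stage table's error constant corrects.
#'
#' @param groups Group labels. Default `c("P25", "P30", "N25", "N30")`.
#' @param fruit_per_group Fruit per group (default 20).
#' @param n_days Days of observation, one stage per day (default 9).
#' @param img_size Square image side in pixels (default 256).
#' @param table The [stage_table()] anchoring the hue trajectory.
#' @param camera_bias_deg Degrees subtracted from the painted hue angle
#'   relative to the ground-truth (spectrometer-frame) angle; defaults to the
#'   table's error constant so the full image pipeline recovers the true
#'   stage.
#' @param jitter_sd Per-fruit angular jitter SD in degrees (default 0.8, which
#'   keeps draws inside their stage interval in >99% of cases).
#' @param freckle_rate Freckles added per stage above 1 (default 1.5; capped
#'   in effect so the foreground mean hue shifts by well under 2 degrees).
#' @param background Backdrop intensity, 0-255 (default 30).
#' @param noise_sd Per-pixel Gaussian noise SD in counts (default 2).
#' @param chroma CIELAB chroma of the skin color (default 58).
#' @param L_start,L_slope Lightness at stage 1 and change per stage
#'   (defaults 70 and -1.2; skins dull slightly as they ripen).
#' @param group_rates Named ripening-rate offsets in stages/day relative to
#'   the one-stage-per-day baseline (warmer is faster, wrapping slower).
#' @param reading_noise_sd Spectrometer per-reading noise SD on a*/b*
#'   (default 0.5).
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(groups = c("P25", "P30", "N25", "N30"),
                         fruit_per_group = 20L,
                         n_days = 9L,
                         img_size = 256L,
                         table = default_stage_table(),
                         camera_bias_deg = attr(table, "error_constant"),
                         jitter_sd = 0.8,
                         freckle_rate = 1.5,
                         background = 30,
                         noise_sd = 2,
                         chroma = 58,
                         L_start = 70,
                         L_slope = -1.2,
                         group_rates = c(P25 = 0, P30 = 0.05,
                                         N25 = -0.05, N30 = 0.02),
                         reading_noise_sd = 0.5) {
  stopifnot(fruit_per_group >= 1, n_days >= 1, img_size >= 8,
            inherits(table, "stage_table"), jitter_sd >= 0,
            background >= 0, background <= 255)
  structure(list(
    groups = groups, fruit_per_group = as.integer(fruit_per_group),
    n_days = as.integer(n_days), img_size = as.integer(img_size),
    table = table, camera_bias_deg = camera_bias_deg,
    jitter_sd = jitter_sd, freckle_rate = freckle_rate,
    background = background, noise_sd = noise_sd, chroma = chroma,
    L_start = L_start, L_slope = L_slope,
    group_rates = group_rates, reading_noise_sd = reading_noise_sd
  ), class = "fixture_spec")
}

# hue-angle midpoint for a (possibly fractional) stage position, degrees;
# linear extrapolation beyond the table keeps trajectories strictly monotone
stage_midpoint_theta <- function(table, stage) {
  mids <- (table$theta_low + table$theta_high) / 2
  n <- length(mids)
  if (n == 1L) return(rep(mids, length(stage)))
  out <- stats::approx(seq_len(n), mids, xout = pmin(pmax(stage, 1), n))$y
  below <- stage < 1
  above <- stage > n
  out[below] <- mids[1] + (stage[below] - 1) * (mids[2] - mids[1])
  out[above] <- mids[n] + (stage[above] - n) * (mids[n] - mids[n - 1])
  out
}

# Lab color of banana skin at a given image-frame hue angle and stage position
skin_lab <- function(spec, theta_deg, stage_pos) {
  th <- theta_deg * pi / 180
  tibble(
    L = spec$L_start + spec$L_slope * (stage_pos - 1),
    a = -spec$chroma * cos(th),
    b = spec$chroma * sin(th)
  )
}

#' Generate one synthetic lightbox fruit image
#'
#' Renders an elliptical fruit on a uniform dark backdrop. The fruit's base
#' color is the sRGB rendering of a CIELAB color whose hue angle is the stage
#' interval's midpoint plus per-fruit jitter, minus the spec's
#' `camera_bias_deg`; dark elliptical freckles accumulate with stage, and mild
#' pixel noise gives realistic nonzero contrast and gradients. Ground truth
#' (stage, painted mean color, fruit mask, both hue angles) is returned for
#' oracle tests. With a fixed `seed` the output is reproducible.
#'
#' @param spec A [fixture_spec()].
#' @param stage Ripeness stage 1-9 (within the spec's stage table).
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   consumed.
#' @return A list of class `fruit_fixture`: `image` (`H x W x 3`, 0-255),
#'   `stage`, `theta_true` (spectrometer-frame angle), `theta_image` (painted
#'   camera-frame angle), `mean_rgb` (one-row tibble of the base skin color),
#'   `mask` (0/1 fruit ellipse).
#' @export
generate_fruit_image <- function(spec, stage, seed = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!(length(stage) == 1L && stage %in% seq_len(nrow(spec$table)))) {
    abort("`stage` must be a single stage within the spec's stage table.",
          class = "labripe_input_error")
  }
  render <- function() {
    n <- spec$img_size
    jitter <- stats::rnorm(1, 0, spec$jitter_sd)
    theta_true <- stage_midpoint_theta(spec$table, stage) + jitter
    theta_img <- theta_true - spec$camera_bias_deg
    base_rgb <- lab_to_rgb(skin_lab(spec, theta_img, stage))

    yy <- matrix(seq_len(n), n, n)
    xx <- t(yy)
    cx <- (n + 1) / 2; cy <- (n + 1) / 2
    rx <- 0.42 * n; ry <- 0.28 * n
    mask <- ((xx - cx) / rx)^2 + ((yy - cy) / ry)^2 <= 1

    img <- array(spec$background, c(n, n, 3))
    for (k in 1:3) {
      ch <- img[, , k]
      ch[mask] <- base_rgb[k]
      img[, , k] <- ch
    }

    n_freckles <- round(spec$freckle_rate * (stage - 1))
    if (n_freckles > 0) {
      fr_col <- c(70, 50, 30)
      r_fr <- max(1, round(0.02 * n))
      inside <- which(mask, arr.ind = TRUE)
      centres <- inside[sample.int(nrow(inside), n_freckles, replace = TRUE), ,
                        drop = FALSE]
      for (i in seq_len(n_freckles)) {
        spot <- (yy - centres[i, 1])^2 + (xx - centres[i, 2])^2 <= r_fr^2
        spot <- spot & mask
        for (k in 1:3) {
          ch <- img[, , k]
          ch[spot] <- fr_col[k]
          img[, , k] <- ch
        }
      }
    }

    if (spec$noise_sd > 0) {
      img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd), dim(img))
    }
    img <- round(pmin(pmax(img, 0), 255))

    structure(list(
      image = img, stage = as.integer(stage),
      theta_true = theta_true, theta_image = theta_img,
      mean_rgb = tibble(r = base_rgb[1], g = base_rgb[2], b = base_rgb[3]),
      mask = mask * 1
    ), class = "fruit_fixture")
  }
  if (is.null(seed)) render() else withr::with_seed(seed, render())
}

#' Generate a set of fixtures as a tibble
#'
#' Convenience driver producing `n` fixtures with stages cycling through the
#' table (1..9, 1..9, ...) under a single seed.
#'
#' @param spec A [fixture_spec()].
#' @param n Number of images.
#' @param seed Integer seed.
#' @param stages Stage for each image; defaults to cycling 1..9.
#' @return A tibble with columns `id`, `stage`, `theta_true` and list-columns
#'   `image`, `mean_rgb`, `mask`.
#' @export
generate_fixture_set <- function(spec, n, seed = 1L,
                                 stages = rep_len(seq_len(nrow(spec$table)),
                                                  n)) {
  stopifnot(length(stages) == n)
  withr::with_seed(seed, {
    fx <- purrr::map(stages, function(s) generate_fruit_image(spec, s))
    tibble(
      id = seq_len(n),
      stage = as.integer(stages),
      theta_true = purrr::map_dbl(fx, "theta_true"),
      image = purrr::map(fx, "image"),
      mean_rgb = purrr::map(fx, "mean_rgb"),
      mask = purrr::map(fx, "mask")
    )
  })
}

#' Corrupt an image's brightness with a pure gamma curve
#'
#' Emulates the validation-image construction: per channel,
#' \eqn{v \mapsto v^\gamma} on `[0, 1]`-normalised intensities over the full
#' input/output range, rescaled to 0-255 (the behaviour of a gamma-only
#' `imadjust`-style mapping). `gamma = 0.5` brightens ("decreases brightness
#' attenuation"), `gamma = 1.5` darkens; `gamma = 1` is the identity up to
#' rounding.
#'
#' @param image Numeric array `H x W x 3`, intensities 0-255.
#' @param gamma Positive exponent.
#' @return An `H x W x 3` array of 0-255 integers.
#' @export
corrupt_brightness <- function(image, gamma) {
  check_image(image)
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma <= 0) {
    abort("`gamma` must be a single positive number.",
          class = "labripe_input_error")
  }
  round(255 * (image / 255)^gamma)
}

#' Generate a synthetic spectrometer time series
#'
#' Emulates the daily spectrometer acquisition: for every group, fruit and
#' day, one CIE L*a*b* reading whose hue angle follows the stage trajectory
#' (day d sits at stage position `1 + (d - 1) * (1 + rate_g)` for the group's
#' ripening-rate offset), with per-fruit jitter and per-reading noise on
#' a*/b*. The default design (4 groups x 20 fruit x 9 days) yields 720
#' records. Angles are in the spectrometer frame (no camera bias).
#'
#' @param spec A [fixture_spec()].
#' @param seed Integer seed.
#' @return A tibble with columns `group`, `fruit`, `day`, `stage`, `L`, `a`,
#'   `b`, `theta_true`.
#' @export
generate_spectrometer_series <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(seed, {
    design <- tidyr::expand_grid(
      group = spec$groups,
      fruit = seq_len(spec$fruit_per_group),
      day = seq_len(spec$n_days)
    )
    rates <- spec$group_rates[design$group]
    rates[is.na(rates)] <- 0
    stage_pos <- 1 + (design$day - 1) * (1 + rates)
    fruit_key <- paste(design$group, design$fruit)
    jit <- stats::rnorm(length(unique(fruit_key)), 0, spec$jitter_sd)
    names(jit) <- unique(fruit_key)
    theta <- stage_midpoint_theta(spec$table, stage_pos) + jit[fruit_key]
    lab <- skin_lab(spec, theta, stage_pos)
    if (spec$reading_noise_sd > 0) {
      lab$a <- lab$a + stats::rnorm(nrow(lab), 0, spec$reading_noise_sd)
      lab$b <- lab$b + stats::rnorm(nrow(lab), 0, spec$reading_noise_sd)
    }
    tibble(
      group = design$group, fruit = design$fruit, day = design$day,
      stage = pmin(round(stage_pos), nrow(spec$table)),
      L = lab$L, a = lab$a, b = lab$b,
      theta_true = unname(theta)
    )
  })
}
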