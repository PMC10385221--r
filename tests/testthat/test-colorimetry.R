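test_that("ripening angle follows the green-yellow right-triangle geometry", {
  cases <- tibble::tribble(
    ~a, ~b, ~theta,
    -19.97, 56.35, 70.48607,  # atan(56.35 / 19.97) in degrees
    -1, 0, 0,
    -1, 1, 45,
    0, 5, 90,                 # degenerate limit a = 0, b > 0
    0, 0, 0,
    -1, -3, 0                 # negative b clamped to the quadrant edge
  )
  out <- ripening_angle(cases)
  expect_equal(out$theta_deg, cases$theta, tolerance = 1e-5)
  expect_false(any(out$adjusted))
})

test_that("non-finite chromaticity is rejected", {
  expect_error(ripening_angle(data.frame(a = NA, b = 1)),
               class = "labripe_input_error")
  expect_error(ripening_angle(data.frame(a = -1, b = Inf)),
               class = "labripe_input_error")
  expect_error(ripening_angle(data.frame(x = 1)),
               class = "labripe_input_error")
})

test_that("error-constant adjustment is additive in the angle domain", {
  tb <- default_stage_table()
  colors <- data.frame(a = c(-19.97, -1, -40), b = c(56.35, 1, 20))
  raw <- ripening_angle(colors)
  adj <- adjusted_ripening_angle(colors, tb)
  expect_equal(adj$theta_deg - raw$theta_deg, rep(2.8, 3))
  expect_true(all(adj$adjusted))
  expect_equal(adjusted_ripening_angle(data.frame(a = -1, b = 1),
                                       tb)$theta_deg, 47.8)
  # zero constant collapses to the raw angle
  tb0 <- stage_table(error_constant = 0)
  expect_equal(adjusted_ripening_angle(colors, tb0)$theta_deg, raw$theta_deg)
  # the correction direction is configurable
  tbneg <- stage_table(error_sign = -1L)
  expect_equal(adjusted_ripening_angle(colors, tbneg)$theta_deg,
               raw$theta_deg - 2.8)
})

test_that("sRGB -> CIELAB conversion matches an independent reference", {
  white <- rgb_to_lab(data.frame(r = 255, g = 255, b = 255))
  expect_equal(white$L, 100, tolerance = 1e-3)
  expect_lt(abs(white$a), 0.01)
  expect_lt(abs(white$b), 0.01)
  expect_equal(unlist(rgb_to_lab(data.frame(r = 0, g = 0, b = 0))),
               c(L = 0, a = 0, b = 0), tolerance = 1e-6)
  green <- rgb_to_lab(data.frame(r = 0, g = 255, b = 0))
  expect_equal(green$L, 87.73, tolerance = 0.01)
  expect_equal(green$a, -86.18, tolerance = 0.01)
  expect_equal(green$b, 83.18, tolerance = 0.01)

  # frozen 100-point grid computed with an independent implementation
  ref <- utils::read.csv(test_path("fixtures-srgb-lab-reference.csv"))
  got <- rgb_to_lab(ref[, c("r", "g", "b")])
  expect_lt(max(abs(got$L - ref$L_ref)), 0.05)
  expect_lt(max(abs(got$a - ref$a_ref)), 0.05)
  expect_lt(max(abs(got$b - ref$b_ref)), 0.05)

  expect_error(rgb_to_lab(data.frame(r = -1, g = 0, b = 0)),
               class = "labripe_input_error")
  expect_error(rgb_to_lab(data.frame(r = 256, g = 0, b = 0)),
               class = "labripe_input_error")
})

test_that("stage mapping yields the edible window, RDFC and sentinels", {
  tb <- default_stage_table()
  mids <- (tb$theta_low + tb$theta_high) / 2
  res <- stage_from_angle(data.frame(theta_deg = mids), tb)
  expect_equal(res$stage, 1:9)
  expect_equal(res$edible, c(rep(FALSE, 4), rep(TRUE, 5)))
  expect_equal(res$rdfc_days[5:9], c(5, 4, 3, 2, 1))
  expect_equal(res$rdfc_days[1:4], rep(5, 4))
  expect_equal(res$days_to_ripe[1:4], c(4, 3, 2, 1))
  expect_equal(res$days_to_ripe[5:9], rep(0, 5))

  # sentinels: below stage 1 and at/above stage 9's upper bound
  lo <- stage_from_angle(data.frame(theta_deg = 40), tb)
  expect_equal(lo$stage, 0L)
  expect_false(lo$edible)
  expect_true(is.na(lo$rdfc_days))
  expect_equal(lo$days_to_ripe, Inf)
  hi <- stage_from_angle(data.frame(theta_deg = c(90, 92.8)), tb)
  expect_equal(hi$stage, c(10L, 10L))
  expect_false(any(hi$edible))
  expect_equal(hi$rdfc_days, c(0, 0))

  # interval convention: left-closed, right-open
  bounds <- stage_from_angle(data.frame(theta_deg = c(45, 50 - 1e-9, 50)), tb)
  expect_equal(bounds$stage, c(1L, 1L, 2L))
})

test_that("angle and stage maps are monotone", {
  withr::with_seed(99, {
    b <- sort(runif(50, 0, 120))
    th <- ripening_angle(data.frame(a = -30, b = b))$theta_deg
    expect_true(all(diff(th) >= 0))
    a <- sort(runif(50, 1, 100))  # |a| increasing at fixed b
    th2 <- ripening_angle(data.frame(a = -a, b = 40))$theta_deg
    expect_true(all(diff(th2) <= 0))
    theta <- sort(runif(100, 30, 100))
    st <- stage_from_angle(data.frame(theta_deg = theta))$stage
    expect_true(all(diff(st) >= 0))
  })
})

test_that("malformed stage tables are rejected and YAML round-trips", {
  expect_error(
    stage_table(data.frame(stage = 1:2, theta_low = c(45, 52),
                           theta_high = c(50, 57))),
    class = "labripe_config_error"  # gap between intervals
  )
  expect_error(stage_table(error_constant = -1),
               class = "labripe_config_error")
  expect_error(stage_table(first_edible_stage = 7, last_edible_stage = 5),
               class = "labripe_config_error")
  expect_error(stage_from_angle(data.frame(theta_deg = 50), table = list()))

  tb <- stage_table(error_constant = 3.1, error_sign = -1L,
                    first_edible_stage = 4L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_stage_table(tb, path)
  tb2 <- read_stage_table(path)
  expect_equal(as.data.frame(tb2), as.data.frame(tb))
  expect_equal(attr(tb2, "error_constant"), 3.1)
  expect_equal(attr(tb2, "error_sign"), -1L)
  expect_equal(attr(tb2, "first_edible_stage"), 4L)
})
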