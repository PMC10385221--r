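test_that("overall brightness is the channel-averaged Minkowski p-mean", {
  expect_equal(overall_brightness(array(100, c(4, 5, 3))), 100)
  expect_equal(overall_brightness(array(0, c(3, 3, 3))), 0)
  two <- array(c(0, 255), c(2, 1, 3))  # {0, 255} identically per channel
  expect_equal(overall_brightness(two), sqrt(255^2 / 2), tolerance = 1e-9)
  withr::with_seed(1, {
    img <- random_image(7, 5)
    expect_equal(overall_brightness(img), brute_overall_brightness(img),
                 tolerance = 1e-9)
    expect_equal(overall_brightness(img, p = 3),
                 brute_overall_brightness(img, p = 3), tolerance = 1e-9)
    # homogeneity before clipping
    for (alpha in c(0.2, 0.5, 1)) {
      expect_equal(overall_brightness(img * alpha),
                   alpha * overall_brightness(img), tolerance = 1e-9)
    }
  })
  expect_error(overall_brightness(array(1, c(2, 2, 2))),
               class = "labripe_input_error")
  expect_error(overall_brightness(array(1, c(2, 2, 3)), p = 0),
               class = "labripe_input_error")
})

test_that("brightness components match brute-force pixel loops", {
  const <- array(42, c(6, 6, 3))
  bc <- brightness_components(const)
  expect_equal(unlist(as.data.frame(bc)),
               c(ob = 42, br = 42, bg = 42, bb = 42, cr = 0, cg = 0, cb = 0,
                 gr = 0, gg = 0, gb = 0))

  # balanced two-point mass: population SD = half the spread
  step <- array(30, c(4, 4, 3))
  step[, 1:2, 1] <- 0; step[, 3:4, 1] <- 255
  expect_equal(brightness_components(step)$cr, 127.5)

  withr::with_seed(2, {
    for (i in 1:5) {
      img <- random_image(sample(3:8, 1), sample(3:8, 1))
      expect_equal(unlist(as.data.frame(brightness_components(img))),
                   brute_components(img), tolerance = 1e-9)
    }
  })
})

test_that("the packaged reference Standard Brightness holds the published constants", {
  sb <- sb_reference()
  expect_equal(
    unlist(as.data.frame(sb$components)),
    c(ob = 6.14, br = 117.91, bg = 117.44, bb = 67.88,
      cr = 45.44, cg = 45.70, cb = 71.96, gr = 18.02, gg = 18.54, gb = 19.35)
  )
  expect_equal(sb$n_images, 720L)
})

test_that("standard brightness is the component-wise mean of the set", {
  img <- array(80, c(4, 4, 3))
  one <- standard_brightness(list(img))
  expect_equal(as.data.frame(one$components),
               as.data.frame(brightness_components(img)))
  expect_equal(one$n_images, 1L)

  two <- standard_brightness(list(array(40, c(3, 3, 3)),
                                  array(100, c(3, 3, 3))))
  expect_equal(two$components$br, 70)
  expect_equal(two$components$ob, 70)

  withr::with_seed(3, {
    imgs <- replicate(10, random_image(5, 5), simplify = FALSE)
    sb <- standard_brightness(imgs)
    manual <- Reduce(`+`, lapply(imgs, brute_components)) / 10
    expect_equal(unlist(as.data.frame(sb$components)), manual,
                 tolerance = 1e-9)
  })
  expect_error(standard_brightness(list()), class = "labripe_input_error")
})

test_that("SB YAML serialization round-trips", {
  withr::with_seed(4, {
    sb <- standard_brightness(list(random_image(5, 5), random_image(4, 6)))
    path <- withr::local_tempfile(fileext = ".yaml")
    write_standard_brightness(sb, path)
    sb2 <- read_standard_brightness(path)
    expect_equal(as.data.frame(sb2$components), as.data.frame(sb$components),
                 tolerance = 1e-9)
    expect_equal(sb2$n_images, 2L)
  })
})

test_that("power-law transform behaves on the normalised scale", {
  withr::with_seed(5, {
    img <- random_image(6, 6)
    expect_lte(max(abs(power_law_transform(img, 1, 1) - img)), 1)
    expect_true(all(power_law_transform(img, 1, 0) == 255))  # v^0 = 1
  })
  quarter <- array(255 * 0.25, c(2, 2, 3))
  expect_equal(unique(as.vector(power_law_transform(quarter, 1, 2))),
               round(255 * 0.0625))
  expect_error(power_law_transform(quarter, c = 0),
               class = "labripe_input_error")
  expect_error(power_law_transform(quarter, gamma = -1),
               class = "labripe_input_error")
})

test_that("brightness difference is a city-block metric on the 10 components", {
  img <- array(60, c(4, 4, 3))
  bc <- brightness_components(img)
  sb <- standard_brightness(list(img))
  expect_equal(brightness_difference(bc, sb), 0)

  shifted <- bc
  shifted$bg <- shifted$bg + 7.5
  expect_equal(brightness_difference(shifted, sb), 7.5)

  withr::with_seed(6, {
    for (i in 1:5) {
      x <- brightness_components(random_image(4, 4))
      y <- brightness_components(random_image(4, 4))
      z <- brightness_components(random_image(4, 4))
      expect_equal(brightness_difference(x, y), brute_bd(x, y),
                   tolerance = 1e-9)
      expect_gte(brightness_difference(x, y), 0)
      expect_equal(brightness_difference(x, y), brightness_difference(y, x))
      expect_lte(brightness_difference(x, z),
                 brightness_difference(x, y) + brightness_difference(y, z) +
                   1e-9)
    }
  })
})

test_that("APLT selects the exact inverse for gamma-corrupted images", {
  spec <- fixture_spec(img_size = 32)
  fx <- generate_fruit_image(spec, 4, seed = 21)
  sb <- standard_brightness(list(fx$image))

  # the image itself: identity candidate is exact
  self <- aplt_adjust(fx$image, sb)
  expect_equal(glance(self)[, c("c", "gamma", "bd")],
               tibble::tibble(c = 1L, gamma = 1, bd = 0))
  expect_equal(self$image, fx$image)
  expect_equal(nrow(tidy(self)), 100L)

  # brightened copy (gamma 0.5): exact analytic inverse gamma = 2 on the grid
  bright <- aplt_adjust(corrupt_brightness(fx$image, 0.5), sb)
  expect_equal(bright$gamma, 2)
  expect_equal(bright$c, 1L)
  expect_equal(bright$branch, "darken")
  expect_lte(max(abs(bright$image - fx$image)), 2)

  # darkened copy (gamma 1.5): nearest grid inverse
  dark <- aplt_adjust(corrupt_brightness(fx$image, 1.5), sb)
  expect_true(dark$gamma %in% c(0.6, 0.7, 0.8))
  expect_equal(dark$c, 1L)
  expect_equal(dark$branch, "brighten")
  expect_lt(mean(abs(dark$image - fx$image)), 5)
})

test_that("APLT never does worse than the identity candidate in its branch", {
  withr::with_seed(7, {
    for (i in 1:5) {
      img <- random_image(8, 8)
      sb <- standard_brightness(list(random_image(8, 8)))
      res <- aplt_adjust(img, sb)
      if (res$branch == "darken") {
        bd_id <- brightness_difference(
          brightness_components(power_law_transform(img, 1, 1)), sb)
        expect_lte(res$bd, bd_id + 1e-9)
      }
    }
  })
})

test_that("adjustment accuracy scores the nine bounded components", {
  img <- array(77, c(4, 4, 3))
  sb <- standard_brightness(list(img))
  expect_equal(adjustment_accuracy(brightness_components(img), sb), 100)

  off <- brightness_components(img)
  off$cb <- off$cb + 255
  expect_equal(adjustment_accuracy(off, sb), 100 * (1 - 1 / 9),
               tolerance = 1e-9)

  uniform <- brightness_components(img)
  for (n in c("br", "bg", "bb", "cr", "cg", "cb", "gr", "gg", "gb")) {
    uniform[[n]] <- uniform[[n]] + 25.5
  }
  expect_equal(adjustment_accuracy(uniform, sb), 90)
  # the composite OB component is disregarded
  uniform$ob <- uniform$ob + 1e6
  expect_equal(adjustment_accuracy(uniform, sb), 90)
})
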