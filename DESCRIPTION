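Package: labripe
Title: Colorimetric Ripeness Staging of Lady Finger Bananas from Photographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimates the ripeness stage and remaining days for consumption of
    lady finger bananas (Musa AA 'Kluai Khai') from RGB photographs or
    spectrometer CIE L*a*b* readings. Implements an angle-of-ripening hue
    statistic in the green-yellow quadrant of CIELAB, an automatic power-law
    (gamma) illumination normalisation against a reference lightbox brightness
    standard, Otsu background removal, and a stage table mapping hue angle to
    ripeness stages 1-9 and edibility. Includes a synthetic fixture generator
    emulating lightbox fruit photographs and spectrometer time series for
    testing and calibration.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    farver,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
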