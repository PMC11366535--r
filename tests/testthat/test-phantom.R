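test_that("marbling-free configuration yields zero marbling ground truth", {
  cfg <- helperPhantomConfig(seed = 3, intensity = 0)
  ph <- generatePhantom(cfg)
  tr <- truthTraits(ph)
  marb <- tr$value[grepl("marb_pct|fineness|coarse_pct", tr$trait)]
  expect_true(all(marb == 0))
  expect_equal(sum(ph@marbling), 0)
})

test_that("generation is deterministic for a fixed seed", {
  cfg <- helperPhantomConfig(seed = 11)
  a <- generatePhantom(cfg)
  b <- generatePhantom(cfg)
  expect_identical(a@image, b@image)
  expect_identical(a@labels, b@labels)
  expect_identical(a@truth, b@truth)
})

test_that("a rectangular muscle has exact pixel-count area and chord thickness", {
  rs <- wagyuIAT:::rectSpec
  ## 40 x 10 px rectangle at 10 px/cm (half-integer bounds put 40 x 10 pixel
  ## centres inside)
  cfg <- phantomConfig(
    heightCm = 8, widthCm = 10, pxPerCm = 10,
    body = rs(0.55, 0.55, 9.55, 7.55),
    muscles = list(ld = rs(2.05, 2.05, 6.05, 3.05)),
    sfBandMm = 0, ifRegions = list(),
    targetPolygon = cbind(c(0.6, 9.5, 9.5, 0.6), c(0.6, 0.6, 7.5, 7.5)),
    marbling = list(ld = wagyuIAT:::marblingSpec(intensity = 0)),
    seed = 1
  )
  ph <- generatePhantom(cfg)
  expect_equal(sum(labelMap(ph) == 1L), 400)
  expect_equal(truthValue(ph, "ld_area"), 4.0)
  geo <- regionGeometry(labelMap(ph) == 1L, 10)
  expect_equal(geo$thickness_mm, 10.0, tolerance = 0.03)
})

test_that("ground-truth label areas sum to the field pixel count", {
  ph <- generatePhantom(helperPhantomConfig(seed = 7))
  inside <- wagyuIAT:::rasterPolygon(nrow(ph@labels), ncol(ph@labels),
                                     ph@targetPolygon)
  fieldPx <- sum(inside & ph@labels != 0L)
  expect_equal(truthValue(ph, "field_area"),
               fieldPx / calibration(ph)^2)
  ifPx <- sum(inside & ph@labels == 6L)
  sfPx <- sum(inside & ph@labels == 7L)
  expect_equal(truthValue(ph, "if_area"), ifPx / calibration(ph)^2)
  expect_equal(truthValue(ph, "sf_area"), sfPx / calibration(ph)^2)
})

test_that("marbling percentage increases with particle intensity", {
  seeds <- 1:12
  meanMarb <- vapply(c(2, 5, 8), function(int) {
    mean(vapply(seeds, function(s) {
      ph <- generatePhantom(helperPhantomConfig(seed = s, intensity = int))
      truthValue(ph, "ld_marb_pct")
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meanMarb) > 0))
})

test_that("coarse particle specs raise coarseness and lower fineness", {
  seeds <- 1:12
  run <- function(intensity, meanlog) {
    t(vapply(seeds, function(s) {
      ph <- generatePhantom(helperPhantomConfig(seed = s,
                                                intensity = intensity,
                                                meanlog = meanlog,
                                                sdlog = 0.4))
      c(marb = truthValue(ph, "ld_marb_pct"),
        coarse = truthValue(ph, "ld_coarse_pct"),
        fine = truthValue(ph, "ld_fineness"))
    }, numeric(3)))
  }
  ## matched expected coverage: intensity * E[area] equal
  coarse <- run(intensity = 1.1, meanlog = log(0.5))
  fine <- run(intensity = 11, meanlog = log(0.05))
  expect_lt(abs(mean(coarse[, "marb"]) - mean(fine[, "marb"])), 8)
  expect_gt(mean(coarse[, "coarse"]), mean(fine[, "coarse"]))
  expect_lt(mean(coarse[, "fine"]), mean(fine[, "fine"]))
})

test_that("overlapping muscle specs are a configuration error", {
  es <- wagyuIAT:::ellipseSpec
  cfg <- helperPhantomConfig(seed = 1)
  cfg$muscles$ssc <- es(13, 7.5, 2.0, 1.5, 0)  # on top of ld
  expect_error(generatePhantom(cfg), "overlap")
})

test_that("particles too small to rasterize warn and leave zero marbling", {
  cfg <- helperPhantomConfig(seed = 2, intensity = 0)
  cfg$marbling$ld <- wagyuIAT:::marblingSpec(intensity = 0.2,
                                             meanlog = log(1e-4),
                                             sdlog = 0.01)
  expect_warning(ph <- generatePhantom(cfg), "rasterized")
  expect_equal(truthValue(ph, "ld_marb_pct"), 0)
})

test_that("groundTruthTraits marks absent regions as NA, not zero", {
  ph <- generatePhantom(helperPhantomConfig(seed = 4))
  ph@labels[ph@labels == 2L] <- 8L   # erase M. semispinalis capitis
  ph@marbling[ph@labels == 8L] <- FALSE
  tr <- groundTruthTraits(ph)
  expect_true(all(is.na(tr$value[grepl("^ssc_", tr$trait)])))
  expect_false(anyNA(tr$value[grepl("^ld_", tr$trait)]))
})

test_that("phantoms round-trip through disk files", {
  ph <- generatePhantom(helperPhantomConfig(seed = 6))
  d <- tempfile()
  writePhantom(ph, d, "p1")
  back <- readPhantom(d, "p1", calibration(ph))
  expect_identical(back$labels, ph@labels)
  expect_lt(max(abs(back$image - ph@image)), 1 / 255)
  expect_equal(back$truth$value, ph@truth$value)
})
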