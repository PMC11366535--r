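## Synthetic carcass cross-section phantoms. Region geometry is specified in
## physical cm coordinates and rasterized at a chosen calibration, so the
## same configuration (and seed) describes the same physical carcass at any
## rendering resolution. Ground truth is defined on the rasterized pixel
## masks, not the continuous shapes.

## run expr with a local, restored RNG state
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  force(expr)
}

ellipseSpec <- function(cx, cy, rx, ry, theta = 0)
  list(shape = "ellipse", cx = cx, cy = cy, rx = rx, ry = ry, theta = theta)

polygonSpec <- function(poly)
  list(shape = "polygon", poly = as.matrix(poly))

rectSpec <- function(x0, y0, x1, y1)
  polygonSpec(cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1)))

scaleSpec <- function(spec, s) {
  if (spec$shape == "ellipse") {
    ellipseSpec(spec$cx * s, spec$cy * s, spec$rx * s, spec$ry * s,
                spec$theta)
  } else {
    polygonSpec(spec$poly * s)
  }
}

marblingSpec <- function(intensity = 3, meanlog = log(0.15), sdlog = 0.5,
                         aspectRange = c(1, 2.5)) {
  list(intensity = intensity, meanlog = meanlog, sdlog = sdlog,
       aspectRange = aspectRange)
}

#' Phantom configuration
#'
#' Describes a synthetic carcass cross-section in physical cm coordinates:
#' image extent, calibration, the five muscle regions
#' (a = *M. longissimus dorsi*, b = *M. semispinalis capitis*,
#' c = *M. semispinalis dorsi*, d = *M. trapezius dorsi*,
#' e = *M. latissimus dorsi*), the target-field polygon, subcutaneous fat
#' band, intermuscular fat channels, and a per-muscle marbling specification
#' (`intensity` = expected particles per cm^2 of muscle; particle areas are
#' log-normal in cm^2, so `meanlog`/`sdlog` control coarse vs fine marbling).
#'
#' @param heightCm,widthCm physical image extent in cm.
#' @param pxPerCm linear calibration (pixels per cm), must be positive.
#' @param muscles named list (`ld`, `ssc`, `ssd`, `td`, `lat`) of region
#'   specs built with the internal `ellipseSpec`/`polygonSpec` helpers; the
#'   defaults place realistically sized, disjoint regions.
#' @param body region spec of the whole cross-section ("other tissue").
#' @param sfBandMm width of the subcutaneous fat band along the lower body
#'   boundary, mm (0 for none).
#' @param ifRegions list of region specs for intermuscular fat channels.
#' @param targetPolygon two-column matrix of (x, y) vertices in cm.
#' @param marbling named list of per-muscle marbling specs, see
#'   [marblingSpec]; intensity 0 gives a marbling-free muscle.
#' @param leanIntensity,fatIntensity,backgroundIntensity rendering levels in
#'   \[0, 1\].
#' @param noiseSd additive Gaussian rendering noise SD (default off).
#' @param coarseThreshold particle area (cm^2) defining a coarse particle.
#' @param minParticleArea minimum particle area retained, cm^2; the default
#'   0.04 cm^2 equals the 4-pixel segmentation floor at the reference
#'   calibration of 10 px/cm and, being physical, is resolution invariant.
#' @param seed random seed.
#' @return an object of class `"PhantomConfig"` (a validated list).
#' @export
phantomConfig <- function(heightCm = 42, widthCm = 52, pxPerCm = 10,
                          muscles = NULL, body = NULL,
                          sfBandMm = 25, ifRegions = NULL,
                          targetPolygon = NULL, marbling = NULL,
                          leanIntensity = 0.30, fatIntensity = 0.85,
                          backgroundIntensity = 0.05, noiseSd = 0,
                          coarseThreshold = 0.3, minParticleArea = 0.04,
                          seed = 1L) {
  if (is.null(muscles)) {
    muscles <- list(
      ld  = ellipseSpec(34, 20, 5.0, 4.0, 0.30),
      ssc = ellipseSpec(12, 12, 2.7, 1.75, -0.20),
      ssd = ellipseSpec(23, 13, 4.5, 2.8, 0.10),
      td  = ellipseSpec(26, 6.5, 8.5, 2.0, 0.00),
      lat = ellipseSpec(30, 28.5, 7.0, 1.8, -0.15)
    )
  }
  if (is.null(body)) body <- ellipseSpec(26, 21, 24.5, 19.5, 0)
  if (is.null(ifRegions)) {
    ifRegions <- list(rectSpec(15.0, 4, 17.4, 32),
                      rectSpec(20, 24.6, 38, 25.4))
  }
  if (is.null(targetPolygon))
    targetPolygon <- cbind(c(8, 36, 36, 8), c(4, 4, 41, 41))
  if (is.null(marbling))
    marbling <- setNames(rep(list(marblingSpec()), 5),
                         c("ld", "ssc", "ssd", "td", "lat"))
  cfg <- structure(
    list(heightCm = heightCm, widthCm = widthCm, pxPerCm = pxPerCm,
         muscles = muscles, body = body, sfBandMm = sfBandMm,
         ifRegions = ifRegions, targetPolygon = as.matrix(targetPolygon),
         marbling = marbling, leanIntensity = leanIntensity,
         fatIntensity = fatIntensity,
         backgroundIntensity = backgroundIntensity, noiseSd = noiseSd,
         coarseThreshold = coarseThreshold,
         minParticleArea = minParticleArea,
         seed = as.integer(seed)),
    class = "PhantomConfig")
  validatePhantomConfig(cfg)
  cfg
}

validatePhantomConfig <- function(cfg) {
  if (!is.finite(cfg$pxPerCm) || cfg$pxPerCm <= 0)
    stop("calibration (pxPerCm) must be positive")
  for (m in cfg$marbling) {
    if (!all(is.finite(c(m$intensity, m$meanlog, m$sdlog, m$aspectRange))))
      stop("marbling parameters must be finite")
    if (m$intensity < 0) stop("marbling intensity must be non-negative")
  }
  invisible(TRUE)
}

#' Generate a synthetic carcass cross-section phantom
#'
#' Rasterizes the configured regions, draws marbling particles (axis-
#' unaligned ellipses with log-normal areas; overlapping particles within a
#' muscle merge by union), renders the grayscale image (lean dark, fat
#' bright) and computes the exact ground-truth trait table from the
#' rasterized masks using the same definitions as [extractIAT()].
#'
#' Particle parameters are drawn in physical cm coordinates against the
#' analytic region shapes, so a fixed seed yields the same physical particle
#' set at any `pxPerCm`.
#'
#' @param cfg a [phantomConfig()].
#' @return a [CarcassPhantom-class].
#' @export
generatePhantom <- function(cfg) {
  stopifnot(inherits(cfg, "PhantomConfig"))
  validatePhantomConfig(cfg)
  s <- cfg$pxPerCm
  nr <- round(cfg$heightCm * s)
  nc <- round(cfg$widthCm * s)

  labels <- matrix(0L, nr, nc)
  body <- rasterRegionSpec(scaleSpec(cfg$body, s), nr, nc)
  labels[body] <- OTHER_LABEL

  for (ifr in cfg$ifRegions) {
    m <- rasterRegionSpec(scaleSpec(ifr, s), nr, nc) & body
    labels[m] <- IF_LABEL
  }

  if (cfg$sfBandMm > 0) {
    bandPx <- cfg$sfBandMm / 10 * s
    for (j in seq_len(nc)) {
      rows <- which(body[, j])
      if (length(rows))
        labels[rows[rows > max(rows) - bandPx], j] <- SF_LABEL
    }
  }

  muscleMasks <- lapply(cfg$muscles, function(sp)
    rasterRegionSpec(scaleSpec(sp, s), nr, nc))
  ## muscles must be pairwise disjoint
  cover <- Reduce(`+`, lapply(muscleMasks, function(m) m * 1L))
  if (any(cover > 1)) stop("muscle regions overlap")
  for (m in names(muscleMasks)) labels[muscleMasks[[m]]] <- muscleCodes[[m]]

  marbling <- withSeed(cfg$seed, {
    mk <- matrix(FALSE, nr, nc)
    for (m in names(cfg$muscles)) {
      spec <- cfg$muscles[[m]]
      mspec <- cfg$marbling[[m]]
      if (is.null(mspec) || mspec$intensity == 0) next
      areaCm2 <- regionSpecArea(spec)  # spec is in cm, so area is cm^2
      np <- rpois(1, mspec$intensity * areaCm2)
      if (np == 0) next
      placed <- FALSE
      mask <- muscleMasks[[m]]
      bb <- specBBox(spec)
      for (k in seq_len(np)) {
        a <- stats::rlnorm(1, mspec$meanlog, mspec$sdlog)       # cm^2
        asp <- runif(1, mspec$aspectRange[1], mspec$aspectRange[2])
        th <- runif(1, 0, pi)
        ctr <- sampleInsideSpec(spec, bb)
        if (is.null(ctr)) next
        rx <- sqrt(a * asp / pi) * s  # px
        ry <- sqrt(a / (asp * pi)) * s
        r0 <- max(1L, floor(ctr[2] * s - rx - ry))
        r1 <- min(nr, ceiling(ctr[2] * s + rx + ry))
        c0 <- max(1L, floor(ctr[1] * s - rx - ry))
        c1 <- min(nc, ceiling(ctr[1] * s + rx + ry))
        if (r0 > r1 || c0 > c1) next
        sub <- rasterEllipse(r1 - r0 + 1, c1 - c0 + 1,
                             ctr[1] * s - c0 + 1, ctr[2] * s - r0 + 1,
                             rx, ry, th)
        sub <- sub & mask[r0:r1, c0:c1]
        if (any(sub)) placed <- TRUE
        mk[r0:r1, c0:c1] <- mk[r0:r1, c0:c1] | sub
      }
      if (!placed)
        warning(sprintf("no marbling particle could be rasterized in '%s'", m))
    }
    mk
  })

  img <- matrix(cfg$backgroundIntensity, nr, nc)
  img[labels %in% c(muscleCodes, OTHER_LABEL)] <- cfg$leanIntensity
  img[labels %in% c(IF_LABEL, SF_LABEL)] <- cfg$fatIntensity
  img[marbling] <- cfg$fatIntensity
  if (cfg$noiseSd > 0) {
    img <- withSeed(cfg$seed + 1L,
                    img + rnorm(length(img), 0, cfg$noiseSd))
    img <- pmin(pmax(img, 0), 1)
  }

  ph <- new("CarcassPhantom", image = img, labels = labels,
            marbling = marbling, calibration = s,
            targetPolygon = cfg$targetPolygon * s,
            truth = data.frame(), seed = cfg$seed)
  ph@truth <- groundTruthTraits(ph, coarseThreshold = cfg$coarseThreshold,
                                minArea = cfg$minParticleArea)
  validObject(ph)
  ph
}

specBBox <- function(spec) {
  if (spec$shape == "ellipse") {
    e <- max(spec$rx, spec$ry)
    c(spec$cx - e, spec$cx + e, spec$cy - e, spec$cy + e)
  } else {
    c(range(spec$poly[, 1]), range(spec$poly[, 2]))
  }
}

sampleInsideSpec <- function(spec, bb, maxTries = 200) {
  for (i in seq_len(maxTries)) {
    x <- runif(1, bb[1], bb[2])
    y <- runif(1, bb[3], bb[4])
    if (insideRegionSpec(spec, x, y)) return(c(x, y))
  }
  NULL
}

#' Ground-truth trait table of a phantom
#'
#' Recomputes every image-analysis trait from the phantom's label map and
#' exact marbling mask, using the same definitions as [extractIAT()] (the
#' fat mask replaces intensity thresholding). Serves as the oracle for
#' round-trip tests. Regions absent from the label map yield `NA`, not zero.
#'
#' @param phantom a [CarcassPhantom-class].
#' @param coarseThreshold particle area (cm^2) defining a coarse particle.
#' @param minArea minimum particle area retained, cm^2 (resolution
#'   invariant; converted to the pixel floor at the phantom's calibration).
#' @return data.frame with columns `trait` and `value`, one row per
#'   region-trait (the 28 traits of [iatTraitNames()]).
#' @export
groundTruthTraits <- function(phantom, coarseThreshold = 0.3,
                              minArea = 0.04) {
  stopifnot(is(phantom, "CarcassPhantom"))
  minSize <- max(1L, round(minArea * phantom@calibration^2))
  row <- iatRow(phantom@image, phantom@labels, phantom@targetPolygon,
                phantom@calibration, coarseThreshold = coarseThreshold,
                minSize = minSize, fatMask = phantom@marbling)
  data.frame(trait = names(row), value = as.numeric(row[1, ]))
}

#' Re-render a phantom at an integer multiple of its resolution
#'
#' Pixel-replicates the label map and marbling mask and re-renders the image,
#' scaling the calibration and target polygon accordingly; physical areas are
#' preserved exactly.
#'
#' @param phantom a [CarcassPhantom-class].
#' @param factor integer upscale factor.
#' @param coarseThreshold,minArea ground-truth settings, as in
#'   [groundTruthTraits()].
#' @return a new [CarcassPhantom-class].
#' @export
upscalePhantom <- function(phantom, factor = 2, coarseThreshold = 0.3,
                           minArea = 0.04) {
  lab <- upscaleMatrix(phantom@labels, factor)
  mk <- upscaleMatrix(phantom@marbling, factor)
  img <- upscaleMatrix(phantom@image, factor)
  ph <- new("CarcassPhantom", image = img, labels = lab, marbling = mk,
            calibration = phantom@calibration * factor,
            targetPolygon = phantom@targetPolygon * factor,
            truth = data.frame(), seed = phantom@seed)
  ph@truth <- groundTruthTraits(ph, coarseThreshold = coarseThreshold,
                                minArea = minArea)
  ph
}

#' Write a phantom to disk
#'
#' Image as 8-bit grayscale PNG, label map as 16-bit grayscale TIFF, ground
#' truth as CSV.
#'
#' @param phantom a [CarcassPhantom-class].
#' @param dir output directory (created if needed).
#' @param name file stem.
#' @return invisibly, the written paths.
#' @export
writePhantom <- function(phantom, dir, name = paste0("phantom_", phantom@seed)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pImg <- file.path(dir, paste0(name, ".png"))
  pLab <- file.path(dir, paste0(name, "_labels.tif"))
  pCsv <- file.path(dir, paste0(name, "_truth.csv"))
  png::writePNG(phantom@image, pImg)
  tiff::writeTIFF(phantom@labels / 65535, pLab, bits.per.sample = 16)
  write.csv(phantom@truth, pCsv, row.names = FALSE)
  invisible(c(image = pImg, labels = pLab, truth = pCsv))
}
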