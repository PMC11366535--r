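## Image-analysis traits (IAT) of a carcass cross-section: per-muscle area,
## marbling percentage, coarseness index, new fineness index and inertia-axis
## thickness, plus the six target-field fat traits.

muscleCodes <- c(ld = 1L, ssc = 2L, ssd = 3L, td = 4L, lat = 5L)
IF_LABEL <- 6L
SF_LABEL <- 7L
OTHER_LABEL <- 8L

#' Names of the 28 image-analysis traits
#'
#' Column order of the table produced by [extractIAT()]: four traits (area,
#' marbling percentage, new fineness index, coarseness index) for each of the
#' five muscles, thickness for *M. trapezius dorsi* and *M. latissimus
#' dorsi*, and six target-field traits.
#'
#' @return character vector of length 28.
#' @export
iatTraitNames <- function() {
  per <- c("area", "marb_pct", "fineness", "coarse_pct")
  c(as.vector(t(outer(names(muscleCodes), per, paste, sep = "_"))),
    "td_thick_mm", "lat_thick_mm",
    "field_area", "field_thick_mm",
    "if_area", "if_pct", "sf_area", "sf_pct")
}

#' Segment marbling particles inside a muscle mask
#'
#' Particles are maximal connected components (8-connectivity by default) of
#' above-threshold pixels inside the mask; components smaller than `minSize`
#' pixels are dropped. Perimeters are boundary crack lengths with the
#' isotropic pi/4 correction (set `correctedPerimeter = FALSE` for the raw
#' crack count).
#'
#' @param image numeric matrix in \[0, 1\].
#' @param mask logical matrix, the muscle region.
#' @param pxPerCm linear calibration, pixels per cm.
#' @param threshold intensity threshold; `NULL` picks Otsu's threshold on the
#'   within-mask pixels.
#' @param minSize minimum particle size in pixels.
#' @param connectivity 4 or 8.
#' @param correctedPerimeter apply the isotropic perimeter correction.
#' @return data.frame with one row per particle: `npx`, `area_cm2`,
#'   `perimeter_cm`; the component label matrix is attached as attribute
#'   `"labels"` and the threshold used as attribute `"threshold"`.
#' @export
segmentParticles <- function(image, mask, pxPerCm, threshold = NULL,
                             minSize = 4, connectivity = 8,
                             correctedPerimeter = TRUE) {
  if (!all(dim(image) == dim(mask)))
    stop("image and mask must have identical dimensions")
  mask <- mask != 0
  if (!any(mask)) stop("empty mask")
  if (is.null(threshold)) {
    v <- image[mask]
    if (diff(range(v)) < 1e-6) {
      ## no contrast inside the mask: Otsu is undefined, nothing to segment
      return(particlesFromMask(mask & FALSE, pxPerCm, minSize = minSize,
                               connectivity = connectivity,
                               correctedPerimeter = correctedPerimeter))
    }
    threshold <- EBImage::otsu(matrix(v, ncol = 1), range = c(0, 1))
  }
  if (threshold < 0 || threshold > 1)
    stop("threshold outside the [0, 1] intensity range")
  fat <- image > threshold & mask
  particlesFromMask(fat, pxPerCm, minSize = minSize,
                    connectivity = connectivity,
                    correctedPerimeter = correctedPerimeter,
                    threshold = threshold)
}

## Shared worker: particle table from a binary fat mask. Used both by
## segmentParticles (thresholded image) and by the phantom ground truth
## (exact marbling mask), so the two routes share one definition.
particlesFromMask <- function(fat, pxPerCm, minSize = 4, connectivity = 8,
                              correctedPerimeter = TRUE, threshold = NA_real_) {
  lab <- labelComponents(fat, connectivity = connectivity)
  if (max(lab) > 0 && minSize > 1) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    drop <- which(sizes < minSize)
    if (length(drop)) {
      lab[lab %in% drop] <- 0L
      u <- sort(unique(lab[lab > 0]))
      lab <- matrix(match(lab, u, nomatch = 0L), nrow(lab), ncol(lab))
    }
  }
  nlab <- max(lab)
  if (nlab == 0) {
    out <- data.frame(npx = integer(0), area_cm2 = numeric(0),
                      perimeter_cm = numeric(0))
  } else {
    npx <- tabulate(lab[lab > 0], nbins = nlab)
    per <- crackLengths(lab, corrected = correctedPerimeter)
    out <- data.frame(npx = npx,
                      area_cm2 = npx / pxPerCm^2,
                      perimeter_cm = per / pxPerCm)
  }
  attr(out, "labels") <- lab
  attr(out, "threshold") <- threshold
  out
}

#' Geometry of a binary region: area, centroid, inertia axes, thickness
#'
#' The centroid is the mean pixel coordinate; the inertia principal axes are
#' the eigenvectors of the 2x2 second central moment matrix of the pixel
#' coordinates (first axis = larger eigenvalue; on a tie, e.g. a disk, the
#' horizontal image axis is taken as first axis). Thickness is the length of
#' the intersection of the mask with the line through the centroid along the
#' *second* axis; if the line exits and re-enters the mask the in-mask chord
#' lengths are summed.
#'
#' @param mask logical matrix.
#' @param pxPerCm linear calibration.
#' @param step sampling step along the thickness line, in pixels.
#' @return list with `area_cm2`, `centroid` (row, col), `axes` (2x2 matrix,
#'   columns = first/second axis unit vectors in (row, col) coordinates),
#'   `eigenvalues`, and `thickness_mm`.
#' @export
regionGeometry <- function(mask, pxPerCm, step = 0.25) {
  mask <- mask != 0
  if (!any(mask)) stop("empty mask")
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  lab <- labelComponents(mask, connectivity = 8)
  if (max(lab) > 1)
    warning("mask is disconnected; geometry computed on the union")
  rbar <- mean(idx[, 1]); cbar <- mean(idx[, 2])
  dr <- idx[, 1] - rbar; dc <- idx[, 2] - cbar
  M <- matrix(c(mean(dr^2), mean(dr * dc), mean(dr * dc), mean(dc^2)), 2, 2)
  ev <- eigen(M, symmetric = TRUE)
  if (abs(ev$values[1] - ev$values[2]) < 1e-9 * max(ev$values[1], 1e-12)) {
    axes <- cbind(c(0, 1), c(1, 0))  # tie: horizontal axis first
  } else {
    axes <- ev$vectors  # columns ordered by decreasing eigenvalue
  }
  v <- axes[, 2]  # second axis, (row, col)
  L <- sqrt(diff(range(idx[, 1]))^2 + diff(range(idx[, 2]))^2) / 2 + 2
  t <- seq(-L, L, by = step)
  rr <- round(rbar + t * v[1])
  cc <- round(cbar + t * v[2])
  ok <- rr >= 1 & rr <= nrow(mask) & cc >= 1 & cc <= ncol(mask)
  inmask <- logical(length(t))
  inmask[ok] <- mask[cbind(rr[ok], cc[ok])]
  thick_px <- sum(inmask) * step
  list(area_cm2 = n / pxPerCm^2,
       centroid = c(row = rbar, col = cbar),
       axes = axes,
       eigenvalues = ev$values,
       thickness_mm = thick_px / pxPerCm * 10)
}

#' Marbling percentage, coarseness index and new fineness index
#'
#' Marbling percentage is 100 x (total particle area) / (muscle area). The
#' new fineness index is the total particle circumference (cm) divided by the
#' square root of the muscle area (cm^2); higher values mean finer marbling.
#' The coarseness index is the area percentage contributed by particles at or
#' above `coarseThreshold` cm^2; higher values mean coarser marbling.
#'
#' @param particles data.frame from [segmentParticles()] (columns `area_cm2`,
#'   `perimeter_cm`).
#' @param geometry list from [regionGeometry()] of the muscle mask.
#' @param coarseThreshold particle area (cm^2) from which a particle counts
#'   as coarse.
#' @return list with `marb_pct`, `coarse_pct`, `fineness`.
#' @export
marblingIndices <- function(particles, geometry, coarseThreshold = 0.3) {
  if (coarseThreshold <= 0) stop("coarseThreshold must be positive")
  A <- geometry$area_cm2
  if (!is.finite(A) || A <= 0) stop("muscle area must be positive")
  list(
    marb_pct = 100 * sum(particles$area_cm2) / A,
    coarse_pct = 100 *
      sum(particles$area_cm2[particles$area_cm2 >= coarseThreshold]) / A,
    fineness = sum(particles$perimeter_cm) / sqrt(A)
  )
}

#' Target-field area, thickness and IF/SF fat traits
#'
#' The target field is the set of non-background pixels inside the supplied
#' polygon. Field thickness is the chord along the second inertia principal
#' axis through the field centroid. IF and SF areas are counted inside the
#' field; percentages are relative to field area.
#'
#' @param labels integer label map (0 background, 6 intermuscular fat,
#'   7 subcutaneous fat).
#' @param polygon two-column matrix (col, row) in pixel coordinates.
#' @param pxPerCm linear calibration.
#' @return list with `field_area`, `field_thick_mm`, `if_area`, `if_pct`,
#'   `sf_area`, `sf_pct`.
#' @export
targetFieldTraits <- function(labels, polygon, pxPerCm) {
  polygon <- as.matrix(polygon)
  if (max(polygon[, 1]) < 0.5 || min(polygon[, 1]) > ncol(labels) + 0.5 ||
      max(polygon[, 2]) < 0.5 || min(polygon[, 2]) > nrow(labels) + 0.5)
    stop("target polygon lies outside the image")
  inside <- rasterPolygon(nrow(labels), ncol(labels), polygon)
  field <- inside & labels != 0L
  if (!any(field)) stop("target polygon encloses no pixel")
  geo <- regionGeometry(field, pxPerCm)
  npxif <- sum(inside & labels == IF_LABEL)
  npxsf <- sum(inside & labels == SF_LABEL)
  a2 <- pxPerCm^2
  list(field_area = geo$area_cm2,
       field_thick_mm = geo$thickness_mm,
       if_area = npxif / a2,
       if_pct = 100 * (npxif / a2) / geo$area_cm2,
       sf_area = npxsf / a2,
       sf_pct = 100 * (npxsf / a2) / geo$area_cm2)
}

## One 28-trait row from an image + label map (+ optional exact fat mask for
## ground-truth mode). Missing muscle labels propagate NA, row retained.
iatRow <- function(image, labels, polygon, pxPerCm, threshold = NULL,
                   minSize = 4, connectivity = 8, coarseThreshold = 0.3,
                   fatMask = NULL) {
  out <- setNames(as.list(rep(NA_real_, length(iatTraitNames()))),
                  iatTraitNames())
  for (m in names(muscleCodes)) {
    mask <- labels == muscleCodes[[m]]
    if (!any(mask)) next
    geo <- regionGeometry(mask, pxPerCm)
    parts <- if (is.null(fatMask)) {
      segmentParticles(image, mask, pxPerCm, threshold = threshold,
                       minSize = minSize, connectivity = connectivity)
    } else {
      particlesFromMask(fatMask & mask, pxPerCm, minSize = minSize,
                        connectivity = connectivity)
    }
    ind <- marblingIndices(parts, geo, coarseThreshold = coarseThreshold)
    out[[paste0(m, "_area")]] <- geo$area_cm2
    out[[paste0(m, "_marb_pct")]] <- ind$marb_pct
    out[[paste0(m, "_fineness")]] <- ind$fineness
    out[[paste0(m, "_coarse_pct")]] <- ind$coarse_pct
    if (m %in% c("td", "lat"))
      out[[paste0(m, "_thick_mm")]] <- geo$thickness_mm
  }
  if (!is.null(polygon)) {
    tf <- targetFieldTraits(labels, polygon, pxPerCm)
    out[names(tf)] <- tf
  }
  as.data.frame(out)
}

#' Extract the 28 image-analysis traits
#'
#' @param x a [CarcassPhantom-class], or a list of them.
#' @param threshold,minSize,connectivity,coarseThreshold segmentation and
#'   index settings, see [segmentParticles()] and [marblingIndices()].
#' @param ... passed through.
#' @return data.frame with one row per carcass and the 28 trait columns of
#'   [iatTraitNames()], plus an `id` column.
#' @export
setGeneric("extractIAT", function(x, ...) standardGeneric("extractIAT"))

#' @rdname extractIAT
#' @export
setMethod("extractIAT", "CarcassPhantom",
  function(x, threshold = NULL, minSize = NULL, connectivity = 8,
           coarseThreshold = 0.3) {
    ## default pixel floor = 0.04 cm^2 at the phantom's calibration, the
    ## same physical filter groundTruthTraits() applies
    if (is.null(minSize)) minSize <- max(1L, round(0.04 * x@calibration^2))
    row <- iatRow(x@image, x@labels, x@targetPolygon, x@calibration,
                  threshold = threshold, minSize = minSize,
                  connectivity = connectivity,
                  coarseThreshold = coarseThreshold)
    cbind(data.frame(id = paste0("phantom_", x@seed)), row)
  })

#' @rdname extractIAT
#' @export
setMethod("extractIAT", "list", function(x, ...) {
  rows <- lapply(x, extractIAT, ...)
  out <- do.call(rbind, rows)
  out$id <- make.unique(out$id)
  rownames(out) <- NULL
  out
})
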