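## Low-level raster helpers shared by the phantom generator and the trait
## extractor. Pixel convention: matrices are indexed [row, col]; the centre of
## pixel (r, c) sits at continuous coordinate (r, c); a pixel belongs to
## exactly one label.

#' Rasterize an ellipse onto a pixel grid
#'
#' @param nrow,ncol grid dimensions in pixels.
#' @param cx,cy centre (col, row) in pixel coordinates.
#' @param rx,ry semi-axes in pixels.
#' @param theta rotation of the rx axis, radians, counter-clockwise.
#' @return logical matrix, `TRUE` inside the ellipse.
#' @keywords internal
rasterEllipse <- function(nrow, ncol, cx, cy, rx, ry, theta = 0) {
  r <- matrix(seq_len(nrow), nrow, ncol)
  c <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  dx <- c - cx
  dy <- r - cy
  u <- cos(theta) * dx + sin(theta) * dy
  v <- -sin(theta) * dx + cos(theta) * dy
  (u / rx)^2 + (v / ry)^2 <= 1
}

#' Rasterize a polygon onto a pixel grid
#'
#' Uses even-odd point-in-polygon on pixel centres (via [mgcv::in.out]).
#'
#' @param nrow,ncol grid dimensions.
#' @param poly two-column matrix of vertices, columns (col, row) i.e. (x, y).
#' @return logical matrix, `TRUE` for pixels whose centre is inside.
#' @keywords internal
rasterPolygon <- function(nrow, ncol, poly) {
  poly <- as.matrix(poly)
  stopifnot(ncol(poly) == 2)
  ## close the ring
  if (any(poly[1, ] != poly[nrow(poly), ]))
    poly <- rbind(poly, poly[1, ])
  pts <- cbind(
    x = as.numeric(matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)),
    y = as.numeric(matrix(seq_len(nrow), nrow, ncol))
  )
  inside <- mgcv::in.out(poly, pts)
  matrix(inside, nrow, ncol)
}

#' Analytic point-in-region test for a region spec
#'
#' Resolution-independent membership test used when drawing marbling particle
#' centres, so the same seed yields the same physical particles at any
#' rendering resolution.
#'
#' @param spec a region spec list (see [phantomConfig()]).
#' @param x,y point in *physical* region coordinates already scaled to pixels
#'   of the reference grid (col, row).
#' @keywords internal
insideRegionSpec <- function(spec, x, y) {
  if (spec$shape == "ellipse") {
    u <- cos(spec$theta) * (x - spec$cx) + sin(spec$theta) * (y - spec$cy)
    v <- -sin(spec$theta) * (x - spec$cx) + cos(spec$theta) * (y - spec$cy)
    (u / spec$rx)^2 + (v / spec$ry)^2 <= 1
  } else {
    as.logical(mgcv::in.out(rbind(spec$poly, spec$poly[1, , drop = FALSE]),
                            cbind(x, y)))
  }
}

## Analytic area (px^2) of a region spec; shoelace for polygons.
regionSpecArea <- function(spec) {
  if (spec$shape == "ellipse") {
    pi * spec$rx * spec$ry
  } else {
    p <- spec$poly
    n <- nrow(p)
    j <- c(2:n, 1)
    abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
  }
}

rasterRegionSpec <- function(spec, nrow, ncol) {
  if (spec$shape == "ellipse") {
    rasterEllipse(nrow, ncol, spec$cx, spec$cy, spec$rx, spec$ry, spec$theta)
  } else {
    rasterPolygon(nrow, ncol, spec$poly)
  }
}

#' 8-connected component labelling of a binary mask
#'
#' 4-connected components from [EBImage::bwlabel] are merged whenever two
#' labels touch diagonally, giving 8-connectivity.
#'
#' @param mask logical or 0/1 matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of component labels, 0 = background.
#' @keywords internal
labelComponents <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (connectivity == 4 || nlab <= 1) return(lab)
  ## diagonal adjacencies between distinct 4-connected labels
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]     # down-right
  a2 <- lab[-nr, -1]; b2 <- lab[-1, -nc]     # down-left
  e <- rbind(cbind(as.integer(a1), as.integer(b1)),
             cbind(as.integer(a2), as.integer(b2)))
  e <- e[e[, 1] > 0 & e[, 2] > 0 & e[, 1] != e[, 2], , drop = FALSE]
  if (nrow(e) == 0) return(lab)
  g <- igraph::graph_from_edgelist(matrix(as.character(e), ncol = 2),
                                   directed = FALSE)
  comp <- igraph::components(g)
  remap <- seq_len(nlab)
  vids <- as.integer(igraph::V(g)$name)
  remap[vids] <- comp$membership + nlab  # temporary ids, then compress
  remap0 <- c(0L, remap)                 # index shift so label 0 maps to 0
  newlab <- matrix(remap0[lab + 1L], nr, nc)
  u <- sort(unique(newlab[newlab > 0]))
  matrix(match(newlab, u, nomatch = 0L), nr, nc)
}

#' Boundary crack length of each labelled component
#'
#' Counts, per label, the pixel edges ("cracks") between a labelled pixel and
#' a pixel of a different label (or the image border). With
#' `corrected = TRUE` the count is multiplied by pi/4, the standard isotropic
#' correction for the city-block overestimate of smooth boundaries.
#'
#' @param lab integer label matrix (0 = background).
#' @param corrected apply the isotropic pi/4 correction.
#' @return named numeric vector of crack lengths in pixel units per label.
#' @keywords internal
crackLengths <- function(lab, corrected = TRUE) {
  nr <- nrow(lab); nc <- ncol(lab)
  nlab <- max(lab)
  if (nlab == 0) return(numeric(0))
  counts <- numeric(nlab)
  pad <- function(m, side) {
    switch(side,
      up    = rbind(0L, m[-nr, , drop = FALSE]),
      down  = rbind(m[-1, , drop = FALSE], 0L),
      left  = cbind(0L, m[, -nc, drop = FALSE]),
      right = cbind(m[, -1, drop = FALSE], 0L))
  }
  for (side in c("up", "down", "left", "right")) {
    nb <- pad(lab, side)
    sel <- lab > 0 & nb != lab
    counts <- counts + tabulate(lab[sel], nbins = nlab)
  }
  if (corrected) counts <- counts * (pi / 4)
  counts
}

## Nearest-neighbour upscale of a matrix by an integer factor (pixel
## replication); used to re-render masks at higher resolution.
upscaleMatrix <- function(m, factor) {
  stopifnot(factor >= 1, factor == round(factor))
  m[rep(seq_len(nrow(m)), each = factor), rep(seq_len(ncol(m)), each = factor)]
}

## Minimum-norm least-squares solve via SVD; returns coefficients, rank and
## the pseudo-inverse factors needed for coefficient standard errors.
pinvFit <- function(X, y, tol = 1e-10) {
  s <- svd(X)
  keep <- s$d > tol * max(s$d, 1)
  r <- sum(keep)
  dinv <- ifelse(keep, 1 / s$d, 0)
  coef <- s$v %*% (dinv * crossprod(s$u, y))
  fitted <- X %*% coef
  ## diag of (X^+)(X^+)' = V D^-2 V' restricted to kept directions
  xpxp <- rowSums((s$v %*% diag(dinv, length(dinv)))^2)
  list(coef = drop(coef), fitted = drop(fitted), rank = r, pinv_diag = xpxp)
}
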