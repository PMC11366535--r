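#' @import methods
#' @importFrom stats rnorm rpois runif rchisq var sd pf pt quantile acf
#'   lm residuals model.matrix complete.cases setNames
#' @importFrom utils write.csv read.csv read.table write.table head
#' @useDynLib wagyuIAT, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Synthetic carcass cross-section phantom
#'
#' A rendered grayscale cross-section image of a beef carcass between the 6th
#' and 7th rib, together with its region label map, marbling mask, target
#' field polygon and the exact ground-truth trait table computed from the
#' rasterized masks.
#'
#' Label codes: 0 background, 1 *M. longissimus dorsi*, 2 *M. semispinalis
#' capitis*, 3 *M. semispinalis dorsi*, 4 *M. trapezius dorsi*,
#' 5 *M. latissimus dorsi*, 6 intermuscular fat, 7 subcutaneous fat,
#' 8 other tissue.
#'
#' @slot image numeric matrix in \[0, 1\], the rendered image.
#' @slot labels integer matrix of region labels, same dimensions.
#' @slot marbling logical matrix; `TRUE` where a marbling particle was drawn.
#' @slot calibration pixels per cm (linear).
#' @slot targetPolygon two-column matrix (col, row) of target-field vertices.
#' @slot truth data.frame of ground-truth traits, one row per region-trait.
#' @slot seed integer seed used for generation.
#' @export
setClass("CarcassPhantom",
  representation(
    image = "matrix",
    labels = "matrix",
    marbling = "matrix",
    calibration = "numeric",
    targetPolygon = "matrix",
    truth = "data.frame",
    seed = "integer"
  )
)

setValidity("CarcassPhantom", function(object) {
  msg <- character(0)
  if (!all(dim(object@image) == dim(object@labels)))
    msg <- c(msg, "image and label map must share dimensions")
  if (!all(dim(object@image) == dim(object@marbling)))
    msg <- c(msg, "image and marbling mask must share dimensions")
  if (length(object@calibration) != 1 || object@calibration <= 0)
    msg <- c(msg, "calibration must be a single positive number")
  ## every marbling pixel lies inside a muscle label
  if (any(object@marbling & !(object@labels %in% 1:5)))
    msg <- c(msg, "marbling pixels must lie inside a muscle region")
  if (length(msg)) msg else TRUE
})

#' Ordered pedigree with inbreeding coefficients
#'
#' Animals are stored in a topological order (parents precede offspring).
#' `sire` and `dam` are indices into that order, `NA_integer_` for unknown
#' parents. Inbreeding coefficients follow the Meuwissen-Luo recursion;
#' founders have F = 0.
#'
#' @slot id character animal identifiers, in topological order.
#' @slot sire,dam integer parent indices (NA = unknown).
#' @slot inbreeding numeric inbreeding coefficient per animal.
#' @slot phenotyped logical; whether the animal carries a phenotype record.
#' @export
setClass("Pedigree",
  representation(
    id = "character",
    sire = "integer",
    dam = "integer",
    inbreeding = "numeric",
    phenotyped = "logical"
  )
)

setValidity("Pedigree", function(object) {
  n <- length(object@id)
  msg <- character(0)
  if (length(object@sire) != n || length(object@dam) != n ||
      length(object@inbreeding) != n || length(object@phenotyped) != n)
    msg <- c(msg, "all slots must have one entry per animal")
  if (anyDuplicated(object@id))
    msg <- c(msg, "duplicated animal ids")
  ok <- function(p) all(is.na(p) | (p >= 1 & p < seq_along(p)))
  if (!ok(object@sire) || !ok(object@dam))
    msg <- c(msg, "parents must precede offspring in the ordering")
  if (any(object@inbreeding < 0 | object@inbreeding >= 1))
    msg <- c(msg, "inbreeding coefficients must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Retained Gibbs samples from an animal model
#'
#' @slot samples data.frame, one row per retained cycle: variance components
#'   and per-sample derived heritabilities/correlations.
#' @slot config list: the [gibbsConfig()] used.
#' @slot traits character trait names (length 1 or 2).
#' @slot metadata list: priors, data dimensions, sampler notes.
#' @export
setClass("GibbsChains",
  representation(
    samples = "data.frame",
    config = "list",
    traits = "character",
    metadata = "list"
  )
)

setValidity("GibbsChains", function(object) {
  msg <- character(0)
  cfg <- object@config
  if (!is.null(cfg$cycles)) {
    expected <- floor((cfg$cycles - cfg$burnin) / cfg$thin)
    if (nrow(object@samples) != expected)
      msg <- c(msg, sprintf("retained count %d != floor((cycles-burnin)/thin) = %d",
                            nrow(object@samples), expected))
  }
  vcols <- grep("^(va|ve)", names(object@samples), value = TRUE)
  for (v in vcols)
    if (any(object@samples[[v]] <= 0))
      msg <- c(msg, sprintf("non-positive sampled variance in %s", v))
  if (length(msg)) msg else TRUE
})

#' Fitted fixed-effects price model
#'
#' Least-squares fit (minimum-norm solution on rank-deficient designs) of a
#' carcass unit-price model with categorical fixed effects and optionally one
#' continuous image-analysis covariate.
#'
#' @slot coefficients named numeric vector of coefficients.
#' @slot terms character term label per design column.
#' @slot rss residual sum of squares.
#' @slot rank numeric rank of the design.
#' @slot dfResidual residual degrees of freedom (n - rank).
#' @slot n number of observations.
#' @slot responseSD,covariateSD standard deviations used for standardization.
#' @slot pinvDiag diagonal of (X^+)(X^+)', for coefficient standard errors.
#' @export
setClass("PriceModelFit",
  representation(
    coefficients = "numeric",
    terms = "character",
    rss = "numeric",
    rank = "numeric",
    dfResidual = "numeric",
    n = "numeric",
    responseSD = "numeric",
    covariateSD = "numeric",
    pinvDiag = "numeric"
  )
)

## ---- generics -------------------------------------------------------------

#' @export
setGeneric("labelMap", function(x) standardGeneric("labelMap"))
#' @export
setGeneric("phantomImage", function(x) standardGeneric("phantomImage"))
#' @export
setGeneric("calibration", function(x) standardGeneric("calibration"))
#' @export
setGeneric("truthTraits", function(x) standardGeneric("truthTraits"))
#' @export
setGeneric("inbreeding", function(x) standardGeneric("inbreeding"))
#' @export
setGeneric("nAnimals", function(x) standardGeneric("nAnimals"))
#' @export
setGeneric("chainSamples", function(x) standardGeneric("chainSamples"))
#' @export
setGeneric("posteriorSummary", function(x, ...) standardGeneric("posteriorSummary"))

#' @describeIn CarcassPhantom the integer label map.
#' @param x object.
#' @export
setMethod("labelMap", "CarcassPhantom", function(x) x@labels)
#' @describeIn CarcassPhantom the rendered grayscale image.
#' @export
setMethod("phantomImage", "CarcassPhantom", function(x) x@image)
#' @describeIn CarcassPhantom pixels per cm.
#' @export
setMethod("calibration", "CarcassPhantom", function(x) x@calibration)
#' @describeIn CarcassPhantom the ground-truth trait table.
#' @export
setMethod("truthTraits", "CarcassPhantom", function(x) x@truth)

#' @describeIn Pedigree inbreeding coefficients, named by animal id.
#' @param x object.
#' @export
setMethod("inbreeding", "Pedigree",
          function(x) setNames(x@inbreeding, x@id))
#' @describeIn Pedigree number of animals.
#' @export
setMethod("nAnimals", "Pedigree", function(x) length(x@id))

#' @describeIn GibbsChains retained samples, one row per kept cycle.
#' @param x object.
#' @export
setMethod("chainSamples", "GibbsChains", function(x) x@samples)

setMethod("show", "CarcassPhantom", function(object) {
  d <- dim(object@image)
  cat("CarcassPhantom:", d[1], "x", d[2], "px at",
      object@calibration, "px/cm\n")
  lab <- table(factor(object@labels, levels = 0:8))
  cat("  marbling pixels:", sum(object@marbling),
      "| muscle pixels:", sum(object@labels %in% 1:5), "\n")
  cat("  ground truth:", nrow(object@truth), "region-trait rows; seed",
      object@seed, "\n")
  invisible(NULL)
})

setMethod("show", "Pedigree", function(object) {
  cat("Pedigree:", length(object@id), "animals,",
      sum(object@phenotyped), "phenotyped\n")
  cat("  founders:", sum(is.na(object@sire) & is.na(object@dam)),
      "| mean F:", signif(mean(object@inbreeding), 3), "\n")
  invisible(NULL)
})

setMethod("show", "GibbsChains", function(object) {
  cat("GibbsChains:", nrow(object@samples), "retained samples,",
      length(object@traits), "trait(s):",
      paste(object@traits, collapse = ", "), "\n")
  cfg <- object@config
  cat("  cycles:", cfg$cycles, "| burn-in:", cfg$burnin,
      "| thin:", cfg$thin, "\n")
  invisible(NULL)
})

setMethod("show", "PriceModelFit", function(object) {
  cat("PriceModelFit: n =", object@n, ", rank =", object@rank,
      ", residual df =", object@dfResidual, "\n")
  cat("  RSS =", signif(object@rss, 6), "\n")
  invisible(NULL)
})
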