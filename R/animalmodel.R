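## Bayesian animal models fitted by Gibbs sampling: single-trait
## (heritability) and two-trait (genetic/residual/phenotypic correlations),
## with flat priors on fixed effects and weakly informative scaled
## inverse chi-square / inverse-Wishart priors on the (co)variances.

#' Gibbs sampler configuration
#'
#' @param cycles total chain length.
#' @param burnin cycles discarded before retention; must be < `cycles`.
#' @param thin retention interval (>= 1); `floor((cycles - burnin) / thin)`
#'   samples are retained.
#' @param nuA,nuE prior degrees of freedom for the genetic and residual
#'   (co)variances.
#' @param priorSplit fraction of the phenotypic variance assigned to the
#'   genetic prior scale in the default ANOVA-style split.
#' @param seed random seed for the chain.
#' @return an object of class `"GibbsConfig"` (validated list).
#' @export
gibbsConfig <- function(cycles = 20000, burnin = 5000, thin = 10,
                        nuA = 4, nuE = 4, priorSplit = 0.5, seed = 1L) {
  if (burnin >= cycles) stop("burn-in must be smaller than the cycle count")
  if (thin < 1) stop("thinning interval must be >= 1")
  if (nuA <= 0 || nuE <= 0) stop("prior degrees of freedom must be positive")
  if (priorSplit <= 0 || priorSplit >= 1) stop("priorSplit must be in (0,1)")
  structure(list(cycles = as.integer(cycles), burnin = as.integer(burnin),
                 thin = as.integer(thin), nuA = nuA, nuE = nuE,
                 priorSplit = priorSplit, seed = as.integer(seed)),
            class = "GibbsConfig")
}

#' Number of retained samples implied by a configuration
#'
#' @param cfg a [gibbsConfig()].
#' @return `floor((cycles - burnin) / thin)`.
#' @export
retainedSamples <- function(cfg) {
  floor((cfg$cycles - cfg$burnin) / cfg$thin)
}

#' Assemble animal-model data
#'
#' Builds the sparse incidence of the model
#' `y = farm + season + sex + age + animal + e` (full-dummy coding, as in
#' blupf90-family software; the singular fixed-effect block is harmless for
#' the Gibbs conditionals) and links each record to its pedigree index.
#'
#' @param phenotypes data.frame with an `id` column, the trait column(s) and
#'   the fixed-effect columns.
#' @param ped a [Pedigree-class] containing every recorded animal.
#' @param traits character, 1 or 2 trait column names.
#' @param fixed character, categorical fixed-effect columns (possibly empty).
#' @return list with sparse `W = [X Z]`, response matrix `y`, `p` (fixed
#'   columns), `q` (pedigree animals), and bookkeeping.
#' @export
buildAnimalModelData <- function(phenotypes, ped, traits,
                                 fixed = c("farm", "season", "sex", "age")) {
  stopifnot(is(ped, "Pedigree"))
  if (!all(traits %in% names(phenotypes)))
    stop("trait column(s) not found")
  cc <- complete.cases(phenotypes[, c(traits, fixed), drop = FALSE])
  phenotypes <- phenotypes[cc, , drop = FALSE]
  n <- nrow(phenotypes)
  if (n < 2) stop("need at least two complete records")
  aidx <- match(as.character(phenotypes$id), ped@id)
  if (any(is.na(aidx)))
    stop("some records map to no pedigree animal: ",
         paste(head(phenotypes$id[is.na(aidx)]), collapse = ", "))
  blocks <- list(Matrix::sparseMatrix(i = seq_len(n), j = rep(1L, n), x = 1,
                                      dims = c(n, 1)))  # overall mean
  for (f in fixed) {
    v <- factor(phenotypes[[f]])
    blocks[[length(blocks) + 1]] <-
      Matrix::sparseMatrix(i = seq_len(n), j = as.integer(v), x = 1,
                           dims = c(n, nlevels(v)))
  }
  X <- do.call(cbind, blocks)
  q <- nAnimals(ped)
  Z <- Matrix::sparseMatrix(i = seq_len(n), j = aidx, x = 1, dims = c(n, q))
  W <- cbind(X, Z)
  y <- as.matrix(phenotypes[, traits, drop = FALSE])
  list(W = W, y = y, p = ncol(X), q = q, n = n, traits = traits,
       animalIndex = aidx)
}

runGibbs <- function(data, ainv, cfg, Sa0, Se0) {
  W <- methods::as(data$W, "CsparseMatrix")
  WtW <- methods::as(methods::as(Matrix::crossprod(W), "generalMatrix"),
                     "CsparseMatrix")
  Ainv <- methods::as(methods::as(ainv, "generalMatrix"), "CsparseMatrix")
  if (nrow(Ainv) != data$q) stop("A-inverse not conformable with pedigree")
  Wty <- as.matrix(Matrix::crossprod(W, data$y))
  nt <- ncol(data$y)
  res <- withSeed(cfg$seed,
    gibbs_animal_cpp(WtW, Ainv, W, data$y, Wty,
                     as.integer(data$p), as.integer(data$q), as.integer(nt),
                     cfg$cycles, cfg$burnin, cfg$thin,
                     cfg$nuA, cfg$nuE, as.matrix(Sa0), as.matrix(Se0)))
  res
}

## ANOVA-style prior scale: phenotypic variance after sweeping out the fixed
## effects with an ordinary linear model, split priorSplit / (1-priorSplit).
priorScales <- function(phenotypes, traits, fixed, priorSplit) {
  vp <- vapply(traits, function(tr) {
    f <- fixed[vapply(fixed, function(x)
      length(unique(phenotypes[[x]])) >= 2, logical(1))]
    if (length(f)) {
      fml <- stats::as.formula(paste(tr, "~",
        paste(sprintf("factor(%s)", f), collapse = "+")))
      var(residuals(lm(fml, data = phenotypes)))
    } else var(phenotypes[[tr]])
  }, numeric(1))
  list(Sa0 = diag(priorSplit * vp, length(vp)),
       Se0 = diag((1 - priorSplit) * vp, length(vp)))
}

#' Single-trait animal model by Gibbs sampling
#'
#' Cycles through the full conditionals of the model `y = Xb + Za + e` with
#' `a ~ N(0, A * va)`: each location effect from its normal conditional
#' given the current variances, `va` from a scaled inverse chi-square with
#' quadratic form `a' A^-1 a`, and `ve` from the residual quadratic form.
#' Deterministic given the seed in `cfg`.
#'
#' @param phenotypes data.frame with `id`, the trait and fixed-effect
#'   columns.
#' @param ped a [Pedigree-class].
#' @param trait trait column name.
#' @param cfg a [gibbsConfig()].
#' @param fixed categorical fixed-effect columns.
#' @param ainv optional precomputed [aInverse()] of `ped`.
#' @return a [GibbsChains-class] with per-sample `va`, `ve` and `h2`.
#' @export
gibbsSingleTrait <- function(phenotypes, ped, trait, cfg = gibbsConfig(),
                             fixed = c("farm", "season", "sex", "age"),
                             ainv = NULL) {
  stopifnot(inherits(cfg, "GibbsConfig"))
  if (is.null(ainv)) ainv <- aInverse(ped)
  data <- buildAnimalModelData(phenotypes, ped, trait, fixed)
  pr <- priorScales(phenotypes, trait, fixed, cfg$priorSplit)
  res <- runGibbs(data, ainv, cfg, pr$Sa0, pr$Se0)
  samples <- as.data.frame(res$samples[, 1:3, drop = FALSE])
  names(samples) <- c("va", "ve", "h2")
  new("GibbsChains", samples = samples, config = unclass(cfg),
      traits = trait,
      metadata = list(n = data$n, p = data$p, q = data$q,
                      priors = pr, jitters = res$jitters))
}

#' Two-trait animal model by Gibbs sampling
#'
#' As [gibbsSingleTrait()], with 2x2 genetic and residual covariance
#' matrices drawn from inverse-Wishart full conditionals; genetic, residual
#' and phenotypic correlations are recorded per retained sample. Records
#' must be complete cases on both traits.
#'
#' @param phenotypes data.frame with `id`, both trait columns and the
#'   fixed-effect columns.
#' @param ped a [Pedigree-class].
#' @param traits character of length 2.
#' @param cfg a [gibbsConfig()].
#' @param fixed categorical fixed-effect columns.
#' @param ainv optional precomputed [aInverse()].
#' @return a [GibbsChains-class] with per-sample (co)variances, `h2_1`,
#'   `h2_2`, `rg`, `re`, `rp`.
#' @export
gibbsTwoTrait <- function(phenotypes, ped, traits, cfg = gibbsConfig(),
                          fixed = c("farm", "season", "sex", "age"),
                          ainv = NULL) {
  stopifnot(inherits(cfg, "GibbsConfig"), length(traits) == 2)
  if (is.null(ainv)) ainv <- aInverse(ped)
  data <- buildAnimalModelData(phenotypes, ped, traits, fixed)
  pr <- priorScales(phenotypes, traits, fixed, cfg$priorSplit)
  res <- runGibbs(data, ainv, cfg, pr$Sa0, pr$Se0)
  samples <- as.data.frame(res$samples)
  names(samples) <- c("va1", "cova", "va2", "ve1", "cove", "ve2",
                      "h2_1", "h2_2", "rg", "re", "rp")
  new("GibbsChains", samples = samples, config = unclass(cfg),
      traits = traits,
      metadata = list(n = data$n, p = data$p, q = data$q,
                      priors = pr, jitters = res$jitters))
}

## initial-monotone-sequence effective sample size
essIMS <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(n)
  rho <- acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  s <- 0
  for (k in seq_along(rho)) {
    if (rho[k] < 0) break
    s <- s + rho[k]
  }
  n / (1 + 2 * s)
}

#' Posterior means and standard deviations of a chain
#'
#' Derived quantities (heritabilities, correlations) are averaged per sample
#' and then summarized, never formed as ratios of means. An effective sample
#' size (initial positive sequence estimator) and a split-chain mean
#' difference diagnostic are included.
#'
#' @param x a [GibbsChains-class].
#' @param ... unused.
#' @return data.frame: `parameter`, `mean`, `sd`, `ess`, `split_diff` (first
#'   minus second half-chain mean).
#' @export
setMethod("posteriorSummary", "GibbsChains", function(x, ...) {
  s <- x@samples
  if (nrow(s) < 2) stop("need at least two retained samples")
  half <- nrow(s) %/% 2
  out <- lapply(names(s), function(p) {
    v <- s[[p]]
    data.frame(parameter = p, mean = mean(v), sd = sd(v),
               ess = essIMS(v),
               split_diff = mean(v[seq_len(half)]) -
                 mean(v[(half + 1):nrow(s)]))
  })
  do.call(rbind, out)
})

#' Write chains and posterior summary to disk
#'
#' @param chains a [GibbsChains-class].
#' @param dir output directory.
#' @param name file stem.
#' @return invisibly, the written paths.
#' @export
writeChains <- function(chains, dir, name = "animal_model") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pChain <- file.path(dir, paste0(name, "_chain.csv"))
  pSumm <- file.path(dir, paste0(name, "_summary.csv"))
  write.csv(chains@samples, pChain, row.names = FALSE)
  write.csv(posteriorSummary(chains), pSumm, row.names = FALSE)
  invisible(c(chain = pChain, summary = pSumm))
}
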