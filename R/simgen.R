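## Synthetic pedigrees and phenotypes with the statistical structure the
## animal model assumes: additive breeding values transmitted as parent
## average plus Mendelian sampling (with parental inbreeding), categorical
## fixed effects, and Gaussian residuals at user-set true variance
## components.

#' Configuration for the genetic-stage simulator
#'
#' The default ("desk-scale") preset mirrors the shape of a typical Wagyu
#' field data set at reduced size: a 3-generation pedigree of ~4,000
#' animals with ~1,500 phenotyped, and fixed effects farm (40 levels,
#' collapsed from the study-scale ~166 so small designs stay estimable),
#' season (4), sex (2) and month of age (9).
#'
#' @param founders number of unrelated founder animals.
#' @param generations number of descendant generations.
#' @param offspringPerGeneration offspring produced in each generation.
#' @param activeSires number of sires in service per generation. Japanese
#'   Black breeding is dominated by artificial insemination from few bulls,
#'   so offspring form large paternal half-sib families; set to `Inf` for
#'   fully random sire choice.
#' @param nPhenotyped number of animals carrying a phenotype (sampled from
#'   the non-founder generations).
#' @param farmLevels,seasonLevels,ageLevels factor sizes (sex is always 2).
#' @param effectSD named numeric SDs of the fixed-effect level effects, in
#'   phenotypic-SD units of the simulated trait.
#' @param varA additive genetic variance: a scalar (single trait) or 2x2
#'   matrix G0 (two traits).
#' @param varE residual variance: scalar or 2x2 matrix R0.
#' @param seed random seed.
#' @return an object of class `"GeneticSimConfig"` (validated list).
#' @export
geneticSimConfig <- function(founders = 1000, generations = 3,
                             offspringPerGeneration = 1000,
                             activeSires = 25,
                             nPhenotyped = 1500,
                             farmLevels = 40, seasonLevels = 4,
                             ageLevels = 9,
                             effectSD = c(farm = 0.30, season = 0.20,
                                          sex = 0.20, age = 0.10),
                             varA = 0.5, varE = 0.5, seed = 1L) {
  varA <- as.matrix(varA); varE <- as.matrix(varE)
  if (!all(dim(varA) == dim(varE)))
    stop("varA and varE must have matching dimensions")
  if (any(eigen(varA, symmetric = TRUE, only.values = TRUE)$values <= 0) ||
      any(eigen(varE, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("varA and varE must be positive definite")
  if (founders < 1) stop("need at least one founder")
  structure(list(founders = founders, generations = generations,
                 offspringPerGeneration = offspringPerGeneration,
                 activeSires = activeSires,
                 nPhenotyped = nPhenotyped, farmLevels = farmLevels,
                 seasonLevels = seasonLevels, ageLevels = ageLevels,
                 effectSD = effectSD, varA = varA, varE = varE,
                 seed = as.integer(seed)),
            class = "GeneticSimConfig")
}

#' Simulate a multi-generation pedigree
#'
#' Founders are unrelated; each offspring receives a sire and a dam drawn at
#' random from the males and females of the previous generation (selfing is
#' impossible since sexes differ). Deterministic for a fixed seed.
#'
#' @param cfg a [geneticSimConfig()].
#' @param seed optional override of `cfg$seed`.
#' @return a [Pedigree-class]; animal sex is attached as attribute `"sex"`
#'   and generation as attribute `"generation"`.
#' @export
simulatePedigree <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "GeneticSimConfig"))
  withSeed(seed, {
    nf <- cfg$founders
    id <- paste0("G0_", seq_len(nf))
    sire <- rep(NA_character_, nf)
    dam <- rep(NA_character_, nf)
    sex <- rep(c("M", "F"), length.out = nf)
    gen <- rep(0L, nf)
    prev <- data.frame(id = id, sex = sex, stringsAsFactors = FALSE)
    for (g in seq_len(cfg$generations)) {
      males <- prev$id[prev$sex == "M"]
      females <- prev$id[prev$sex == "F"]
      if (!length(males) || !length(females))
        stop("a generation lost one sex entirely; increase founders")
      if (is.finite(cfg$activeSires) && length(males) > cfg$activeSires)
        males <- sample(males, cfg$activeSires)
      no <- cfg$offspringPerGeneration
      oid <- paste0("G", g, "_", seq_len(no))
      osire <- sample(males, no, replace = TRUE)
      odam <- sample(females, no, replace = TRUE)
      osex <- sample(c("M", "F"), no, replace = TRUE)
      id <- c(id, oid); sire <- c(sire, osire); dam <- c(dam, odam)
      sex <- c(sex, osex); gen <- c(gen, rep(g, no))
      prev <- data.frame(id = oid, sex = osex, stringsAsFactors = FALSE)
    }
    ped <- newPedigree(id, sire, dam)
    ord <- match(ped@id, id)
    attr(ped, "sex") <- sex[ord]
    attr(ped, "generation") <- gen[ord]
    ped
  })
}

#' Simulate phenotypes over a pedigree
#'
#' Founder breeding values are drawn with (co)variance `varA`; a
#' descendant's breeding value is the parent average plus a Mendelian
#' deviation with variance `0.5 * varA * (1 - (F_s + F_d) / 2)` (a missing
#' parent contributes 0 with its half of the variance restored). Fixed-
#' effect levels are assigned uniformly at random and their effects drawn
#' once per level; the phenotype is the sum of fixed effects, breeding value
#' and residual. True breeding values are kept in the output for recovery
#' tests.
#'
#' @param ped a [Pedigree-class] (e.g. from [simulatePedigree()]).
#' @param cfg a [geneticSimConfig()].
#' @param seed optional override of `cfg$seed`.
#' @return data.frame with one row per phenotyped animal: `id`, fixed-effect
#'   columns (`farm`, `season`, `sex`, `age`), trait value(s) `y` (or `y1`,
#'   `y2`) and true breeding value(s) `tbv` (`tbv1`, `tbv2`). The full
#'   per-animal breeding-value matrix is attached as attribute `"bv"`, and
#'   the per-record fixed-effect sums as attribute `"fixedPart"`.
#' @export
simulatePhenotypes <- function(ped, cfg, seed = cfg$seed + 1L) {
  stopifnot(is(ped, "Pedigree"), inherits(cfg, "GeneticSimConfig"))
  nt <- nrow(cfg$varA)
  n <- nAnimals(ped)
  withSeed(seed, {
    La <- chol(cfg$varA)
    bv <- matrix(0, n, nt)
    Fc <- ped@inbreeding
    for (i in seq_len(n)) {
      s <- ped@sire[i]; d <- ped@dam[i]
      pa <- numeric(nt)
      nKnown <- 0
      Fsum <- 0
      if (!is.na(s)) { pa <- pa + 0.5 * bv[s, ]; nKnown <- nKnown + 1; Fsum <- Fsum + Fc[s] }
      if (!is.na(d)) { pa <- pa + 0.5 * bv[d, ]; nKnown <- nKnown + 1; Fsum <- Fsum + Fc[d] }
      ## Mendelian-sampling variance: 1 - 0.25*nKnown adjusts for unknown
      ## parents; parental inbreeding shrinks the within-family variance.
      vm <- (1 - 0.25 * nKnown) - 0.25 * Fsum
      bv[i, ] <- pa + sqrt(vm) * drop(rnorm(nt) %*% La)
    }
    gen <- attr(ped, "generation")
    candidates <- if (!is.null(gen)) which(gen > 0) else seq_len(n)
    np <- min(cfg$nPhenotyped, length(candidates))
    rec <- sort(sample(candidates, np))
    eff <- function(nlev, s, m) {
      lev <- sample(seq_len(nlev), m, replace = TRUE)
      val <- rnorm(nlev, 0, s)
      list(lev = lev, val = val[lev])
    }
    farm <- eff(cfg$farmLevels, cfg$effectSD[["farm"]], np)
    season <- eff(cfg$seasonLevels, cfg$effectSD[["season"]], np)
    age <- eff(cfg$ageLevels, cfg$effectSD[["age"]], np)
    sexLev <- attr(ped, "sex")
    if (is.null(sexLev)) sexLev <- sample(c("M", "F"), n, replace = TRUE)
    sexVal <- setNames(rnorm(2, 0, cfg$effectSD[["sex"]]), c("M", "F"))
    fixedPart <- farm$val + season$val + age$val + sexVal[sexLev[rec]]
    Le <- chol(cfg$varE)
    resid <- matrix(rnorm(np * nt), np, nt) %*% Le
    y <- matrix(fixedPart, np, nt) + bv[rec, , drop = FALSE] + resid
    out <- data.frame(id = ped@id[rec],
                      farm = farm$lev, season = season$lev,
                      sex = sexLev[rec], age = age$lev)
    if (nt == 1) {
      out$y <- y[, 1]; out$tbv <- bv[rec, 1]
    } else {
      out$y1 <- y[, 1]; out$y2 <- y[, 2]
      out$tbv1 <- bv[rec, 1]; out$tbv2 <- bv[rec, 2]
    }
    attr(out, "bv") <- bv
    attr(out, "fixedPart") <- unname(fixedPart)
    out
  })
}

#' One-call genetic simulation at desk scale
#'
#' Convenience wrapper: pedigree + phenotypes for given true heritabilities
#' (and genetic correlation for two traits) on the unit phenotypic scale
#' (`varA = h2`, `varE = 1 - h2`).
#'
#' @param h2 numeric of length 1 or 2: true heritabilities.
#' @param rg true genetic correlation (two-trait case).
#' @param re true residual correlation (two-trait case).
#' @param seed random seed.
#' @param ... further arguments to [geneticSimConfig()].
#' @return list with elements `ped` ([Pedigree-class]), `phenotypes`
#'   (data.frame) and `cfg`.
#' @export
simulateGeneticData <- function(h2, rg = 0, re = 0, seed = 1L, ...) {
  if (length(h2) == 1) {
    cfg <- geneticSimConfig(varA = h2, varE = 1 - h2, seed = seed, ...)
  } else {
    sa <- sqrt(h2)
    se <- sqrt(1 - h2)
    G0 <- diag(sa) %*% matrix(c(1, rg, rg, 1), 2) %*% diag(sa)
    R0 <- diag(se) %*% matrix(c(1, re, re, 1), 2) %*% diag(se)
    cfg <- geneticSimConfig(varA = G0, varE = R0, seed = seed, ...)
  }
  ped <- simulatePedigree(cfg)
  ped@phenotyped <- rep(FALSE, nAnimals(ped))
  phen <- simulatePhenotypes(ped, cfg)
  ped@phenotyped <- ped@id %in% phen$id
  list(ped = ped, phenotypes = phen, cfg = cfg)
}

#' Write a simulated data set to disk
#'
#' Phenotypes as CSV; pedigree as 3-column whitespace-delimited text with 0
#' for unknown parents.
#'
#' @param sim list from [simulateGeneticData()].
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
writeGeneticData <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pPhen <- file.path(dir, "phenotypes.csv")
  pPed <- file.path(dir, "pedigree.txt")
  write.csv(sim$phenotypes, pPhen, row.names = FALSE)
  ped <- sim$ped
  pid <- function(p) ifelse(is.na(p), "0", ped@id[p])
  write.table(data.frame(ped@id, pid(ped@sire), pid(ped@dam)),
              pPed, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(c(phenotypes = pPhen, pedigree = pPed))
}
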