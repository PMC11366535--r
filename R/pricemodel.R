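## Fixed-effects models of carcass unit price (UP, yen/kg): least-squares
## fits with marginal (full-vs-reduced) F tests per term and standardized
## partial regression coefficients of one image-analysis trait (IAT) per
## meat-quality (MQ) grade.

## Build the design matrix for a term list. Factors enter as full indicator
## blocks (no reference level), so fits are reference-level free; the
## minimum-norm solution handles the implied rank deficiency.
buildDesign <- function(data, factors = character(0), covariate = NULL,
                        interaction = NULL) {
  n <- nrow(data)
  X <- matrix(1, n, 1)
  terms <- "(Intercept)"
  cn <- "(Intercept)"
  for (f in factors) {
    v <- factor(data[[f]])
    if (nlevels(v) < 2) {
      warning(sprintf("factor '%s' has a single observed level; term dropped", f))
      next
    }
    M <- model.matrix(~ v - 1)
    X <- cbind(X, M)
    terms <- c(terms, rep(f, ncol(M)))
    cn <- c(cn, paste0(f, levels(v)))
  }
  if (!is.null(covariate)) {
    x <- data[[covariate]]
    if (!is.numeric(x)) stop("covariate must be numeric")
    X <- cbind(X, x)
    terms <- c(terms, covariate)
    cn <- c(cn, covariate)
  }
  if (!is.null(interaction)) {
    ## factor-by-covariate interaction in sum-to-zero coding, so the
    ## covariate main effect (the average slope) stays estimable and its
    ## marginal test carries the usual Type-III meaning
    f <- interaction[1]; cv <- interaction[2]
    v <- factor(data[[f]])
    C <- stats::contr.sum(nlevels(v))
    M <- C[as.integer(v), , drop = FALSE] * data[[cv]]
    X <- cbind(X, M)
    nm <- paste0(f, head(levels(v), -1), ":", cv)
    terms <- c(terms, rep(paste0(f, ":", cv), ncol(M)))
    cn <- c(cn, nm)
  }
  colnames(X) <- cn
  list(X = X, terms = terms)
}

#' Fit a fixed-effects model of unit price
#'
#' Least squares with full-indicator dummy coding for every factor; the
#' rank-deficient system is solved by the minimum-norm (pseudo-inverse)
#' solution, so estimable functions do not depend on a reference-level
#' choice.
#'
#' @param data data.frame of per-animal records.
#' @param response response column name (carcass unit price).
#' @param factors character vector of categorical fixed-effect columns.
#' @param covariate optional continuous covariate column (one IAT per fit).
#' @param interaction optional length-2 character vector `c(factor,
#'   covariate)` adding a factor-by-covariate interaction.
#' @return a [PriceModelFit-class].
#' @export
fitPriceModel <- function(data, response, factors = character(0),
                          covariate = NULL, interaction = NULL) {
  if (nrow(data) < 2) stop("need at least two records")
  y <- data[[response]]
  if (any(is.na(y))) stop("missing response values")
  d <- buildDesign(data, factors, covariate, interaction)
  fit <- pinvFit(d$X, y)
  if (nrow(d$X) <= fit$rank)
    stop("more parameters than observations (n <= rank)")
  rss <- sum((y - fit$fitted)^2)
  new("PriceModelFit",
      coefficients = setNames(fit$coef, colnames(d$X)),
      terms = d$terms,
      rss = rss,
      rank = fit$rank,
      dfResidual = nrow(d$X) - fit$rank,
      n = nrow(d$X),
      responseSD = sd(y),
      covariateSD = if (is.null(covariate)) NA_real_ else sd(data[[covariate]]),
      pinvDiag = fit$pinv_diag)
}

#' Per-term marginal F table
#'
#' Each term's F statistic compares the full model with the model refit
#' after deleting that term's design columns (marginal, Type-III-style
#' test); p-values come from the F distribution and are flagged at 0.05 and
#' 0.01. A term whose deletion does not change the design rank is aliased
#' and reported as `NA`.
#'
#' @inheritParams fitPriceModel
#' @return data.frame with columns `term`, `df`, `F`, `p`, `signif`.
#' @export
anovaFTable <- function(data, response, factors = character(0),
                        covariate = NULL, interaction = NULL) {
  y <- data[[response]]
  full <- buildDesign(data, factors, covariate, interaction)
  ffit <- pinvFit(full$X, y)
  rssF <- sum((y - ffit$fitted)^2)
  dfeF <- nrow(full$X) - ffit$rank
  if (dfeF <= 0) stop("no residual degrees of freedom in the full model")
  terms <- setdiff(unique(full$terms), "(Intercept)")
  out <- lapply(terms, function(tm) {
    keep <- full$terms != tm
    Xr <- full$X[, keep, drop = FALSE]
    rfit <- pinvFit(Xr, y)
    rssR <- sum((y - rfit$fitted)^2)
    df1 <- ffit$rank - rfit$rank
    if (df1 <= 0)
      return(data.frame(term = tm, df = NA_real_, F = NA_real_,
                        p = NA_real_, signif = ""))
    Fv <- ((rssR - rssF) / df1) / (rssF / dfeF)
    p <- pf(Fv, df1, dfeF, lower.tail = FALSE)
    data.frame(term = tm, df = df1, F = Fv, p = p,
               signif = if (p < 0.01) "**" else if (p < 0.05) "*" else "")
  })
  do.call(rbind, out)
}

#' Standardized partial regression coefficient of an IAT on unit price
#'
#' Fits the per-MQ model (grading date + month of age + sex + one continuous
#' IAT; no farm, no MQ) on the records of a single meat-quality grade and
#' reports the standardized partial regression coefficient
#' `b * SD(IAT) / SD(UP)` together with the coefficient's t statistic. Both
#' are reported because published tables of this analysis carry magnitudes
#' well beyond the usual standardized-coefficient range.
#'
#' @param data data.frame of records.
#' @param iat name of the continuous IAT column.
#' @param response response column (unit price).
#' @param factors categorical fixed effects of the per-MQ model.
#' @param mq optional value: subset `data` to rows with `data$MQ == mq`.
#' @return one-row data.frame: `iat`, `mq`, `n`, `b`, `std_coef`, `t`, `p`.
#' @export
standardizedCoefficients <- function(data, iat, response = "UP",
                                     factors = c("date", "age", "sex"),
                                     mq = NULL) {
  if (!is.null(mq)) data <- data[data$MQ == mq, , drop = FALSE]
  if (nrow(data) == 0) stop("empty subset")
  x <- data[[iat]]
  if (sd(x) == 0) stop("covariate has zero variance in the subset")
  factors <- factors[vapply(factors, function(f)
    length(unique(data[[f]])) >= 2, logical(1))]
  fit <- fitPriceModel(data, response, factors = factors, covariate = iat)
  b <- fit@coefficients[[iat]]
  sigma2 <- fit@rss / fit@dfResidual
  se <- sqrt(sigma2 * fit@pinvDiag[length(fit@pinvDiag)])
  tv <- b / se
  data.frame(iat = iat, mq = if (is.null(mq)) NA else mq, n = nrow(data),
             b = b, std_coef = b * fit@covariateSD / fit@responseSD,
             t = tv, p = 2 * pt(abs(tv), fit@dfResidual, lower.tail = FALSE))
}

#' Simulate a unit-price table from an IAT table
#'
#' Generating model for pipeline smoke tests and sign-recovery checks:
#' `UP = date + age + sex + farm + MQ + beta * IAT + noise`, with level
#' effects drawn once per level. MQ grades 2-5 are assigned from the
#' quartiles of the chosen IAT (better marbling, higher grade), mimicking
#' grading.
#'
#' @param iatTable data.frame from [extractIAT()] (or any table with the
#'   chosen trait column).
#' @param trait IAT column driving the price.
#' @param beta yen/kg per trait unit.
#' @param nDates,nFarms,nAges numbers of factor levels.
#' @param effectSD named numeric SDs of the level effects.
#' @param noiseSD residual SD (yen/kg).
#' @param mean baseline price (yen/kg).
#' @param seed random seed.
#' @return the input table with `UP`, `date`, `age`, `sex`, `farm`, `MQ`
#'   columns appended.
#' @export
simulateUnitPrice <- function(iatTable, trait, beta = 10, nDates = 17,
                              nFarms = 20, nAges = 9,
                              effectSD = c(date = 60, age = 10, sex = 20,
                                           farm = 40, MQ = 120),
                              noiseSD = 80, mean = 2200, seed = 1L) {
  withSeed(seed, {
    n <- nrow(iatTable)
    d <- iatTable
    d$date <- sample(seq_len(nDates), n, replace = TRUE)
    d$age <- sample(seq_len(nAges), n, replace = TRUE)
    d$sex <- sample(c("steer", "heifer"), n, replace = TRUE)
    d$farm <- sample(seq_len(nFarms), n, replace = TRUE)
    x <- d[[trait]]
    d$MQ <- 2 + findInterval(x, quantile(x, c(0.25, 0.5, 0.75)))
    eff <- function(v, s) {
      lev <- sort(unique(v))
      setNames(rnorm(length(lev), 0, s), lev)[as.character(v)]
    }
    d$UP <- mean + eff(d$date, effectSD[["date"]]) +
      eff(d$age, effectSD[["age"]]) + eff(d$sex, effectSD[["sex"]]) +
      eff(d$farm, effectSD[["farm"]]) + eff(d$MQ, effectSD[["MQ"]]) +
      beta * x + rnorm(n, 0, noiseSD)
    d
  })
}
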