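makeToyData <- function(n, seed = 1, nf1 = 3, nf2 = 4, noise = 1) {
  set.seed(seed)
  d <- data.frame(f1 = sample(letters[1:nf1], n, replace = TRUE),
                  f2 = sample(LETTERS[1:nf2], n, replace = TRUE),
                  x = rnorm(n))
  a <- setNames(rnorm(nf1, 0, 2), letters[1:nf1])
  b <- setNames(rnorm(nf2, 0, 2), LETTERS[1:nf2])
  d$y <- a[d$f1] + b[d$f2] + 0.8 * d$x + rnorm(n, 0, noise)
  d
}

test_that("a noiseless factor-sum response is fitted with zero residual", {
  d <- makeToyData(60, seed = 2, noise = 0)
  d$y <- d$y - 0.8 * d$x  # pure factor sum
  fit <- fitPriceModel(d, "y", factors = c("f1", "f2"))
  expect_lt(fit@rss, 1e-18 * var(d$y) * 60 + 1e-20)
})

test_that("a single two-level factor fits the group means", {
  set.seed(3)
  d <- data.frame(g = rep(c("u", "v"), each = 10), y = rnorm(20))
  fit <- fitPriceModel(d, "y", factors = "g")
  X <- wagyuIAT:::buildDesign(d, "g")$X
  fitted <- unname(drop(X %*% fit@coefficients))
  expect_equal(fitted, unname(ave(d$y, d$g)), tolerance = 1e-10)
})

test_that("minimum-norm coefficients match the pseudo-inverse oracle", {
  d <- makeToyData(200, seed = 4)
  des <- wagyuIAT:::buildDesign(d, c("f1", "f2"), covariate = "x")
  fit <- fitPriceModel(d, "y", factors = c("f1", "f2"), covariate = "x")
  oracle <- ginvCoef(des$X, d$y)
  expect_lt(max(abs(unname(fit@coefficients) - oracle)), 1e-8)
})

test_that("one-way F equals the squared pooled-t statistic", {
  set.seed(5)
  d <- data.frame(g = rep(c("u", "v"), c(12, 15)), y = rnorm(27))
  ft <- anovaFTable(d, "y", factors = "g")
  tt <- t.test(y ~ g, data = d, var.equal = TRUE)
  expect_equal(ft$F[ft$term == "g"], unname(tt$statistic)^2,
               tolerance = 1e-10)
  expect_equal(ft$df[ft$term == "g"], 1)
})

test_that("marginal F values match brute-force nested refits", {
  d <- makeToyData(120, seed = 6)
  d$MQ <- sample(2:5, 120, replace = TRUE)
  ft <- anovaFTable(d, "y", factors = c("f1", "f2", "MQ"),
                    covariate = "x", interaction = c("MQ", "x"))
  full <- wagyuIAT:::buildDesign(d, c("f1", "f2", "MQ"), "x", c("MQ", "x"))
  rssF <- lmRss(full$X, d$y)
  rankF <- qr(full$X)$rank
  dfe <- nrow(d) - rankF
  for (tm in unique(ft$term)) {
    Xr <- full$X[, full$terms != tm, drop = FALSE]
    rssR <- lmRss(Xr, d$y)
    df1 <- rankF - qr(Xr)$rank
    Fo <- ((rssR - rssF) / df1) / (rssF / dfe)
    expect_equal(ft$F[ft$term == tm], Fo, tolerance = 1e-8)
  }
})

test_that("balanced two-factor F agrees with stats::anova", {
  set.seed(7)
  d <- expand.grid(f1 = letters[1:3], f2 = LETTERS[1:4],
                   rep = 1:5, KEEP.OUT.ATTRS = FALSE)
  d$y <- rnorm(nrow(d)) + as.integer(factor(d$f1)) * 0.5
  ft <- anovaFTable(d, "y", factors = c("f1", "f2"))
  ao <- anova(lm(y ~ f1 + f2, data = d))
  expect_equal(ft$F[ft$term == "f1"], ao["f1", "F value"], tolerance = 1e-8)
  expect_equal(ft$F[ft$term == "f2"], ao["f2", "F value"], tolerance = 1e-8)
})

test_that("a truly null term rejects at the nominal 5% level", {
  set.seed(8)
  rej <- 0
  for (r in 1:1000) {
    d <- data.frame(g = sample(c("u", "v"), 40, replace = TRUE),
                    x = rnorm(40))
    d$y <- 0.5 * d$x + rnorm(40)  # g has no effect
    ft <- anovaFTable(d, "y", factors = "g", covariate = "x")
    if (ft$p[ft$term == "g"] < 0.05) rej <- rej + 1
  }
  expect_gte(rej / 1000, 0.03)
  expect_lte(rej / 1000, 0.07)
})

test_that("standardized coefficients follow the b * sx / sy definition", {
  set.seed(9)
  d <- data.frame(IAT = rnorm(50))
  d$UP <- 2 * d$IAT
  sc <- standardizedCoefficients(d, "IAT", factors = character(0))
  expect_equal(sc$std_coef, 1.0, tolerance = 1e-10)
  ## multi-term fit equals the dense-oracle formula
  d2 <- makeToyData(150, seed = 10)
  names(d2)[names(d2) == "x"] <- "IAT"
  names(d2)[names(d2) == "y"] <- "UP"
  sc2 <- standardizedCoefficients(d2, "IAT", factors = c("f1", "f2"))
  des <- wagyuIAT:::buildDesign(d2, c("f1", "f2"), covariate = "IAT")
  bo <- ginvCoef(des$X, d2$UP)
  expect_equal(sc2$std_coef,
               bo[length(bo)] * sd(d2$IAT) / sd(d2$UP), tolerance = 1e-10)
  expect_error(standardizedCoefficients(
    data.frame(IAT = rep(1, 10), UP = rnorm(10)), "IAT",
    factors = character(0)), "zero variance")
})

test_that("a null covariate has a near-zero standardized coefficient", {
  vals <- vapply(1:20, function(s) {
    set.seed(100 + s)
    d <- data.frame(IAT = rnorm(500), UP = rnorm(500))
    standardizedCoefficients(d, "IAT", factors = character(0))$std_coef
  }, numeric(1))
  expect_lt(max(abs(vals)), 0.2)
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("F and standardized coefficients are invariant to affine rescaling", {
  d <- makeToyData(100, seed = 11)
  names(d)[3:4] <- c("IAT", "UP")
  f1 <- anovaFTable(d, "UP", factors = c("f1", "f2"), covariate = "IAT")
  s1 <- standardizedCoefficients(d, "IAT", factors = c("f1", "f2"))
  d2 <- d
  d2$IAT <- 3.7 * d2$IAT - 12
  d2$UP <- 0.2 * d2$UP + 1000
  f2 <- anovaFTable(d2, "UP", factors = c("f1", "f2"), covariate = "IAT")
  s2 <- standardizedCoefficients(d2, "IAT", factors = c("f1", "f2"))
  expect_equal(f1$F, f2$F, tolerance = 1e-8)
  expect_equal(s1$std_coef, s2$std_coef, tolerance = 1e-8)
  ## and to factor level relabelling
  d3 <- d
  d3$f1 <- chartr("abc", "zqm", d3$f1)
  f3 <- anovaFTable(d3, "UP", factors = c("f1", "f2"), covariate = "IAT")
  expect_equal(sort(f1$F), sort(f3$F), tolerance = 1e-8)
})

test_that("a known positive price effect is recovered with the right sign", {
  traits <- data.frame(ld_marb_pct = rnorm(500, 50, 8))
  hits <- 0
  for (r in 1:100) {
    d <- simulateUnitPrice(traits, "ld_marb_pct", beta = 10, seed = r)
    sc <- standardizedCoefficients(d, "ld_marb_pct",
                                   factors = c("date", "age", "sex"))
    if (sc$std_coef > 0) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("aliased terms are reported as absent, single-level factors dropped", {
  d <- makeToyData(50, seed = 12)
  d$dup <- d$f1  # perfectly aliased with f1
  ft <- anovaFTable(d, "y", factors = c("f1", "dup"))
  expect_true(any(is.na(ft$F)))
  d$one <- "same"
  expect_warning(fitPriceModel(d, "y", factors = c("f1", "one")),
                 "single observed level")
})
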