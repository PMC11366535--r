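## Shared fixtures: a compact phantom configuration (160 x 200 px at
## 10 px/cm) with the same region inventory as the full-size default, random
## pedigree generators for oracle tests, and a dense least-squares oracle.

helperPhantomConfig <- function(seed = 1, pxPerCm = 10, intensity = 3,
                                meanlog = log(0.15), sdlog = 0.5,
                                noiseSd = 0) {
  es <- wagyuIAT:::ellipseSpec
  rs <- wagyuIAT:::rectSpec
  marb <- lapply(setNames(nm = c("ld", "ssc", "ssd", "td", "lat")),
                 function(m) wagyuIAT:::marblingSpec(intensity = intensity,
                                                    meanlog = meanlog,
                                                    sdlog = sdlog))
  phantomConfig(
    heightCm = 16, widthCm = 20, pxPerCm = pxPerCm,
    body = es(10, 8, 9.5, 7.5),
    muscles = list(
      ld  = es(13, 7.5, 2.2, 1.6, 0.30),
      ssc = es(4.5, 4.5, 1.4, 0.9, -0.20),
      ssd = es(8.5, 4.5, 1.8, 1.1, 0.10),
      td  = es(10, 2.2, 3.2, 0.8, 0),
      lat = es(11, 11.2, 2.8, 0.7, -0.10)
    ),
    sfBandMm = 10,
    ifRegions = list(rs(6.0, 1.5, 6.6, 12), rs(8, 9.5, 14, 10.1)),
    targetPolygon = cbind(c(2, 17, 17, 2), c(1.5, 1.5, 15.2, 15.2)),
    marbling = marb, noiseSd = noiseSd, seed = seed
  )
}

## random valid pedigree: founders + animals whose parents are sampled from
## earlier animals (possibly unknown); exercises mixed known/unknown parents
## and incidental inbreeding
randomPedigree <- function(n, founders = 8, seed = 1) {
  set.seed(seed)
  id <- paste0("a", seq_len(n))
  sire <- rep(NA_character_, n)
  dam <- rep(NA_character_, n)
  for (i in (founders + 1):n) {
    if (runif(1) < 0.9) sire[i] <- id[sample(i - 1, 1)]
    if (runif(1) < 0.9) {
      repeat {
        cand <- id[sample(i - 1, 1)]
        if (is.na(sire[i]) || cand != sire[i]) break
      }
      dam[i] <- cand
    }
  }
  newPedigree(id, sire, dam)
}

## dense minimum-norm least squares through an independent route
ginvCoef <- function(X, y) {
  drop(MASS::ginv(crossprod(X)) %*% crossprod(X, y))
}

## RSS through lm.fit on an explicit design (independent of pinvFit)
lmRss <- function(X, y) {
  f <- lm.fit(X, y)
  sum(f$residuals^2)
}

truthValue <- function(phantom, trait) {
  tr <- truthTraits(phantom)
  tr$value[tr$trait == trait]
}
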