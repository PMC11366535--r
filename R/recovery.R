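#' Simulation-based parameter-recovery experiment
#'
#' Simulates a desk-scale data set at user-set true parameters (3-generation
#' sire-limited pedigree, ~4,000 animals, ~1,500 phenotyped by default),
#' fits the matching single- or two-trait Gibbs animal model, and returns
#' the posterior means of the quantities of interest next to their truths.
#' This is the package's calibration harness: if the machinery is sound,
#' posterior means land near the simulated truth up to posterior spread
#' (and, for correlations near the boundary, a small shrinkage of the
#' posterior-mean estimator toward zero).
#'
#' @param h2 true heritability (length 1) or heritabilities (length 2).
#' @param rg,re true genetic and residual correlations (two-trait case).
#' @param simSeed,gibbsSeed seeds for the simulation and the chain.
#' @param cfg a [gibbsConfig()]; its seed is overridden by `gibbsSeed`.
#' @param ... further arguments to [geneticSimConfig()] (sizes etc.).
#' @return list with `estimate` (named posterior means), `truth`, `n`
#'   (phenotyped records), `chains` (the [GibbsChains-class]).
#' @export
recoveryExperiment <- function(h2, rg = 0, re = 0, simSeed = 1,
                               gibbsSeed = 2,
                               cfg = gibbsConfig(cycles = 20000,
                                                 burnin = 5000, thin = 10),
                               ...) {
  cfg$seed <- as.integer(gibbsSeed)
  sim <- simulateGeneticData(h2 = h2, rg = rg, re = re, seed = simSeed, ...)
  if (length(h2) == 1) {
    ch <- gibbsSingleTrait(sim$phenotypes, sim$ped, "y", cfg)
    cs <- chainSamples(ch)
    est <- c(h2 = mean(cs$h2))
    truth <- c(h2 = h2)
  } else {
    ch <- gibbsTwoTrait(sim$phenotypes, sim$ped, c("y1", "y2"), cfg)
    cs <- chainSamples(ch)
    est <- c(h2_1 = mean(cs$h2_1), h2_2 = mean(cs$h2_2),
             rg = mean(cs$rg), re = mean(cs$re), rp = mean(cs$rp))
    truth <- c(h2_1 = h2[1], h2_2 = h2[2], rg = rg, re = re, rp = NA)
  }
  list(estimate = est, truth = truth, n = nrow(sim$phenotypes), chains = ch)
}
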