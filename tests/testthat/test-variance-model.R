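test_that("replicate variance splits into Poisson and non-Poisson parts", {
  expect_equal(replicateNonPoissonSD(c(90, 110)),
               c(sigma_m = 0.1, R = 100))
  ## identical replicates measure zero excess, clamped not negative
  expect_equal(replicateNonPoissonSD(c(100, 100))[["sigma_m"]], 0)
  for (c0 in c(1, 7, 500)) {
    expect_equal(replicateNonPoissonSD(c(c0, c0))[["sigma_m"]], 0)
  }
  ## spread below Poisson expectation also clamps to zero
  expect_equal(replicateNonPoissonSD(c(99, 101))[["sigma_m"]], 0)
  expect_error(replicateNonPoissonSD(c(5)), "2 replicates")
  ## matrix form agrees with the scalar form row-wise
  m <- rbind(a = c(90, 110), b = c(100, 100), c = c(10, 40))
  got <- replicateNonPoissonSD(m)
  for (g in rownames(m)) {
    expect_equal(got[g, "sigma_m"], oracleRepSD(m[g, ])[["sigma_m"]])
    expect_equal(got[g, "R"], oracleRepSD(m[g, ])[["R"]])
  }
  ## three replicates use the n-1 sample variance
  expect_equal(replicateNonPoissonSD(c(80, 100, 120))[["sigma_m"]],
               oracleRepSD(c(80, 100, 120))[["sigma_m"]])
})

test_that("the technical floor is a max and is monotone", {
  expect_equal(applyTechnicalFloor(0.05, 0.16), 0.16)
  expect_equal(applyTechnicalFloor(0.30, 0.16), 0.30)
  expect_equal(applyTechnicalFloor(0, 0), 0)
  expect_equal(applyTechnicalFloor(c(0, 0.1, 0.5), 0.16),
               c(0.16, 0.16, 0.5))
  ## raising the floor never lowers any sigma
  s <- c(0, 0.05, 0.2, 0.4)
  expect_true(all(applyTechnicalFloor(s, 0.25) >= applyTechnicalFloor(s, 0.1)))
  expect_error(applyTechnicalFloor(-0.1, 0.2), "non-negative")
})

test_that("pooling weights by reads, drops unreliable estimates, and falls back", {
  ## constant sigma pools to itself under any weights
  expect_equal(pooledGeneVariance(rep(0.2, 4), c(40, 100, 35, 1000),
                                  sigmaT = 0.1)$sigma, 0.2)
  ## hand-computed weighted mean: (0.1*100 + 0.3*300) / 400 = 0.25
  got <- pooledGeneVariance(c(0.1, 0.3, 0.5, 0.9), c(100, 300, 10, 5),
                            sigmaT = 0.1)
  expect_equal(got$sigma, 0.25)
  expect_false(got$fallback)
  ## all species below the 30-read threshold: fall back to species U
  got <- pooledGeneVariance(c(0.1, 0.3), c(10, 20), sigmaT = 0.1)
  expect_true(got$fallback)
  expect_true(is.na(got$sigma))
  ## the floor applies after pooling
  expect_equal(pooledGeneVariance(c(0.05, 0.05), c(100, 100),
                                  sigmaT = 0.16)$sigma, 0.16)
})

test_that("species rescaling multiplies by U_s over the mean U", {
  expect_equal(speciesRescale(0.2, 0.3, c(0.1, 0.2, 0.2, 0.3)), 0.3)
  expect_equal(speciesRescale(0.2, 0.2, rep(0.2, 4)), 0.2)   # shared U
  expect_equal(speciesRescale(0, 0.4, c(0.2, 0.4)), 0)
  expect_error(speciesRescale(0.2, 0, c(0.1)), "positive")
})

test_that("calibration finds the minimal grid U achieving the target", {
  pair <- simulateReplicatePair(nGenes = 4000L, U = 0.16, seed = 91)
  cal <- calibrateU(pair$rep1, pair$rep2, alpha = 0.05)
  expect_false(cal@underdispersed)
  expect_lte(cal@nPositive, 0.05 * cal@nGenesCalibrated)
  ## one grid step below, the target is exceeded (minimality)
  shared <- intersect(names(pair$rep1), names(pair$rep2))
  r1 <- pair$rep1[shared]; r2 <- pair$rep2[shared]
  keep <- (r1 + r2) / 2 >= 10
  r1 <- as.numeric(r1[keep]); r2 <- as.numeric(r2[keep])
  m <- medianRatioSlope(setNames(r1, seq_along(r1)), setNames(r2, seq_along(r2)))
  below <- uValue(cal) - cal@gridStep
  nPos <- sum(pValue(chi2Statistic(r1, r2, m, below, below)) < 0.05)
  expect_gt(nPos, 0.05 * cal@nGenesCalibrated)
  ## identical replicates are under-dispersed: U = 0 with a warning
  same <- setNames(rep(100L, 50), paste0("g", 1:50))
  expect_warning(cal0 <- calibrateU(same, same, alpha = 0.05), "not over-dispersed")
  expect_equal(uValue(cal0), 0)
  expect_true(cal0@underdispersed)
})

test_that("the positive count is non-increasing in U", {
  pair <- simulateReplicatePair(nGenes = 3000L, U = 0.2, seed = 7)
  shared <- intersect(names(pair$rep1), names(pair$rep2))
  r1 <- as.numeric(pair$rep1[shared]); r2 <- as.numeric(pair$rep2[shared])
  keep <- (r1 + r2) / 2 >= 10
  r1 <- r1[keep]; r2 <- r2[keep]
  m <- medianRatioSlope(setNames(r1, seq_along(r1)), setNames(r2, seq_along(r2)))
  counts <- vapply(seq(0, 0.5, by = 0.025), function(u)
    sum(pValue(chi2Statistic(r1, r2, m, u, u)) < 0.05), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the variance model resolves gene sigmas, rescaling and fallbacks", {
  spec <- simulationSpec(nGenes = 800L, nSpecies = 2L, U = 0.2)
  sim <- simulateDataset(spec, seed = 5)
  genes <- referenceGenes(sim$orthologs)
  speciesU <- c(Scer = 0.18, Spar = 0.22)
  vm <- buildVarianceModel(sim$counts, sim$orthologs, genes, speciesU,
                           sigmaT = 0.16)
  sig <- sigmaFor(vm, genes, "Scer")
  expect_length(sig, length(genes))
  expect_true(all(sig > 0))
  ## rescaling: gene-specific sigmas differ between species by U_a / U_b
  sigB <- sigmaFor(vm, genes, "Spar")
  gs <- genes[!vm@fallback[genes]]
  expect_equal(sig[gs] / sigB[gs], rep(0.18 / 0.22, length(gs)),
               ignore_attr = TRUE)
  ## fallback genes use the species U untouched
  fb <- genes[vm@fallback[genes]]
  if (length(fb)) {
    expect_equal(unname(sig[fb]), rep(0.18, length(fb)))
    expect_equal(unname(sigB[fb]), rep(0.22, length(fb)))
  }
  ## floored at sigma_t
  expect_true(all(vm@geneSigma >= 0.16, na.rm = TRUE))
  ## a uniform model returns the species U for every gene
  um <- uniformVarianceModel(c(Scer = 0.3, Spar = 0.1))
  expect_equal(unname(sigmaFor(um, c("x", "y"), "Spar")), c(0.1, 0.1))
  expect_error(sigmaFor(um, "x", "Smik"), "no calibrated U")
})
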