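test_that("the chi-square statistic matches the explicit two-term oracle", {
  ## hand-checked reference case: counts (100, 300), m = 2, sigma 0.16
  ## means (125, 250): 625/(125 + 20^2) + 2500/(250 + 40^2)
  expect_equal(chi2Statistic(100, 300, 2, 0.16, 0.16),
               625 / 525 + 2500 / 1850)
  cases <- expand.grid(C = c(0, 5, 100, 300, 1200),
                       T = c(0, 8, 90, 450),
                       m = c(0.5, 1, 2),
                       s = c(0, 0.16, 0.4))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    expect_equal(chi2Statistic(cs$C, cs$T, cs$m, cs$s, cs$s),
                 oracleChi2(cs$C, cs$T, cs$m, cs$s, cs$s),
                 tolerance = 1e-12)
  }
  ## equal counts at m = 1 sit exactly on the null line
  expect_equal(chi2Statistic(250, 250, 1, 0.2, 0.2), 0)
  ## infinite variance absorbs any difference
  expect_lt(chi2Statistic(100, 10000, 1, 1e6, 1e6), 1e-6)
  ## both-zero genes return 0 by convention
  expect_equal(chi2Statistic(0, 0, 2, 0.16, 0.16), 0)
  expect_error(chi2Statistic(-1, 5, 1, 0.1, 0.1), "non-negative")
})

test_that("the statistic is symmetric in the two species", {
  set.seed(3)
  for (i in 1:20) {
    C <- rpois(1, 200); T <- rpois(1, 500)
    m <- runif(1, 0.3, 3)
    sC <- runif(1, 0, 0.4); sT <- runif(1, 0, 0.4)
    expect_equal(chi2Statistic(C, T, m, sC, sT),
                 chi2Statistic(T, C, 1 / m, sT, sC), tolerance = 1e-12)
  }
})

test_that("larger sigma never decreases the p-value (conservatism)", {
  set.seed(8)
  for (i in 1:30) {
    C <- rpois(1, 300); T <- rpois(1, 600)
    s <- sort(runif(2, 0, 0.6))
    p1 <- pValue(chi2Statistic(C, T, 1.5, s[1], s[1]))
    p2 <- pValue(chi2Statistic(C, T, 1.5, s[2], s[2]))
    expect_gte(p2, p1)
  }
})

test_that("p-values follow the one-degree chi-square upper tail", {
  expect_equal(pValue(0), 1)
  expect_equal(pValue(qchisq(0.95, 1)), 0.05)
  x <- c(0.1, 1, 2, 5, 10)
  expect_true(all(diff(pValue(x)) < 0))
  expect_equal(pValue(3, df = 2), exp(-3 / 2))   # chi2(2) closed form
})

test_that("Fisher combination matches the closed form for two batches", {
  expect_equal(combineBatches(c(1, 1)), 1)
  cases <- rbind(c(0.05, 0.05), c(0.5, 1), c(0.01, 0.8), c(0.3, 0.3),
                 c(1e-6, 0.9), c(0.2, 0.04), c(0.99, 0.99), c(0.5, 0.002),
                 c(0.12, 0.34), c(1e-3, 1e-3))
  for (i in seq_len(nrow(cases))) {
    expect_equal(combineBatches(cases[i, ]),
                 oracleFisher2(cases[i, 1], cases[i, 2]), tolerance = 1e-12)
  }
  ## frozen reference value for (0.05, 0.05)
  expect_equal(combineBatches(c(0.05, 0.05)), 0.01747866136776996,
               tolerance = 1e-12)
  ## combining with p = 1 is never more significant than p alone
  for (p in c(0.01, 0.1, 0.5)) {
    expect_gte(combineBatches(c(p, 1)), p)
  }
  expect_error(combineBatches(c(0, 0.5)), "\\(0, 1\\]")
})

test_that("fold-change intervals propagate both sides' uncertainty", {
  ## Poisson-only limit at T = C: sigma_fc = sqrt(2 / C) / ln 2
  for (C in c(100, 1000, 10000)) {
    got <- foldChangeCI(C, C, 0, 0)
    expect_equal(got$log2_fc, 0)
    expect_equal(got$sigma_fc, sqrt(2 / C) / log(2))
  }
  ## doubling both counts shrinks the Poisson-only sigma by sqrt(2)
  a <- foldChangeCI(200, 400, 0, 0)$sigma_fc
  b <- foldChangeCI(400, 800, 0, 0)$sigma_fc
  expect_equal(a / b, sqrt(2))
  ## agreement with finite-difference propagation on a case grid
  cases <- expand.grid(C = c(20, 150, 2000), T = c(35, 600, 9000),
                       s = c(0, 0.16, 0.3))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    got <- foldChangeCI(cs$C, cs$T, cs$s, cs$s)
    expect_equal(got$log2_fc, log2(cs$T / cs$C))
    expect_equal(got$sigma_fc,
                 oracleFoldChangeSigma(cs$C, cs$T, cs$s, cs$s),
                 tolerance = 1e-6)
    expect_equal(got$fc_ci_low, got$log2_fc - 2 * got$sigma_fc)
    expect_equal(got$fc_ci_high, got$log2_fc + 2 * got$sigma_fc)
  }
  ## zero counts have no defined fold change
  got <- foldChangeCI(c(0, 10), c(5, 0), 0.1, 0.1)
  expect_true(all(is.na(unlist(got))))
})

test_that("callDE pairs batches, combines them, and flags calls", {
  spec <- simulationSpec(nGenes = 1500L, nSpecies = 2L, U = 0.16,
                         deFraction = 0.02, effectModel = "fixed",
                         effectSize = 4)
  sim <- simulateDataset(spec, seed = 17)
  vm <- uniformVarianceModel(c(Scer = 0.16, Spar = 0.16), sigmaT = 0.16)
  res <- callDE(sim$counts, sim$orthologs, vm, c("Scer", "Spar"),
                genes = referenceGenes(sim$orthologs), alpha = 0.01)
  expect_s4_class(res, "DEResults")
  expect_equal(nrow(res), 1500)
  md <- S4Vectors::metadata(res)
  expect_equal(md$batches, c("d1", "d2"))
  expect_length(md$slopes, 2)
  ## combined p comes from the two per-batch p-values
  i <- which(!is.na(res$p_rep1) & !is.na(res$p_rep2))[1:20]
  expect_equal(res$p_combined[i],
               mapply(function(a, b) oracleFisher2(a, b),
                      res$p_rep1[i], res$p_rep2[i]),
               tolerance = 1e-12)
  ## a 16x injected change at high counts dominates the p-value ranking
  truthDE <- sim$truth$gene_id[sim$truth$is_de & sim$truth$mu > 200]
  expect_true(all(res$p_combined[match(truthDE, res$gene_id)] <
                  quantile(res$p_combined, 0.05)))
  ## power at this effect size is high, and most nulls stay quiet
  ev <- evaluateFprPower(res, sim$truth, alpha = 0.01)
  expect_lt(ev$fpr, 0.03)
  expect_gt(ev$power, 0.8)
})

test_that("swapping the species inverts fold changes, not significance", {
  spec <- simulationSpec(nGenes = 301L, nSpecies = 2L, U = 0.16)
  sim <- simulateDataset(spec, seed = 23)
  vm <- uniformVarianceModel(c(Scer = 0.16, Spar = 0.16))
  genes <- referenceGenes(sim$orthologs)
  ## an odd-sized slope set with no zero counts makes the median-ratio
  ## slope exactly reciprocal under the swap
  nz <- genes[sapply(counts(sim$counts), function(ct) unname(ct) > 0) |>
                apply(1, all)]
  sg <- nz[seq_len(length(nz) - (1 - length(nz) %% 2))]
  ab <- callDE(sim$counts, sim$orthologs, vm, c("Scer", "Spar"),
               genes = genes, slopeGenes = sg)
  ba <- callDE(sim$counts, sim$orthologs, vm, c("Spar", "Scer"),
               genes = genes, slopeGenes = sg)
  ok <- !is.na(ab$log2_fc)
  expect_equal(ab$log2_fc[ok], -ba$log2_fc[ok], tolerance = 1e-9)
  expect_equal(ab$p_combined, ba$p_combined, tolerance = 1e-9)
  expect_equal(ab$chi2_rep1, ba$chi2_rep1, tolerance = 1e-9)
})

test_that("genes absent in one species are excluded; zero-zero genes are null", {
  counts <- list(
    A_r1 = c(g1 = 100L, g2 = 50L, g3 = 0L, g4 = 80L, g5 = 40L),
    B_r1 = c(pg1 = 110L, pg2 = 45L, pg3 = 0L, pg4 = 90L, pg5 = 35L))
  cs <- CountSet(counts, species = c("A", "B"), replicate = 1L, batch = "d1")
  orth <- OrthologSet(list(
    g1 = list(B = "pg1"), g2 = list(B = "pg2"), g3 = list(B = "pg3"),
    g4 = list(B = "pg4"), g5 = list(B = "pg5"),
    gMissing = list(B = character(0))), "A")
  vm <- uniformVarianceModel(c(A = 0.16, B = 0.16))
  res <- callDE(cs, orth, vm, c("A", "B"),
                genes = referenceGenes(orth), minReads = 10)
  expect_false("gMissing" %in% res$gene_id)
  z <- res[res$gene_id == "g3", ]
  expect_equal(z$chi2_rep1, 0)
  expect_equal(z$p_rep1, 1)
  expect_true(is.na(z$log2_fc))
  expect_true(z$low_count)
})

test_that("the replicate-based FDR estimator follows its definition", {
  expect_equal(estimateFDR(3000, 600, 0.01), 0.05)
  expect_equal(estimateFDR(3000, 600, 0), 0)
  expect_equal(estimateFDR(1000, 10, 0.01), 1)      # boundary
  expect_true(is.na(estimateFDR(1000, 0, 0.01)))
})
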