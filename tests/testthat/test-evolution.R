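test_that("lineage assignment requires consistent significant direction", {
  tree <- yeastPhylogeny()
  ## per-gene per-species expression levels; pairwise tables derive
  ## significance and sign from level differences
  levels <- rbind(
    rme1_like = c(Scer = 2, Spar = 0, Smik = 0, Sbay = 0),   # up in Scer only
    tsc3_like = c(Scer = 1, Spar = 0, Smik = 1, Sbay = 0),   # inconsistent
    internal  = c(Scer = 1, Spar = 1, Smik = 0, Sbay = 0),   # clade shift
    bay_down  = c(Scer = 0, Spar = 0, Smik = 0, Sbay = -1),  # down in Sbay
    multi     = c(Scer = 2, Spar = 0, Smik = 0, Sbay = -2),  # two branches
    quiet     = c(Scer = 0, Spar = 0, Smik = 0, Sbay = 0))
  tabs <- lineageTables(levels)
  br <- assignLineage(tabs, tree, alpha = 0.01)
  ## the internal split is named by its lexicographically first side
  expect_setequal(names(br),
                  c("Scer", "Spar", "Smik", "Sbay", "Sbay+Smik"))
  expect_setequal(br$Scer$gene_id, c("rme1_like", "multi"))
  expect_equal(br$Scer$direction[br$Scer$gene_id == "rme1_like"], "up")
  ## a gene not significant against one species of the lineage is
  ## unassigned anywhere
  for (b in names(br)) expect_false("tsc3_like" %in% br[[b]]$gene_id)
  for (b in names(br)) expect_false("quiet" %in% br[[b]]$gene_id)
  ## internal branch: all four cross-split pairs consistent; the
  ## mik+bay side of the "internal" gene sits lower
  expect_true("internal" %in% br[["Sbay+Smik"]]$gene_id)
  expect_equal(br[["Sbay+Smik"]]$direction[
    br[["Sbay+Smik"]]$gene_id == "internal"], "down")
  expect_equal(br$Sbay$direction[br$Sbay$gene_id == "bay_down"], "down")
  ## genes may land on more than one branch
  hits <- vapply(br, function(d) "multi" %in% d$gene_id, logical(1))
  expect_gte(sum(hits), 2)
})

test_that("assigned genes re-check as significant and directional", {
  set.seed(41)
  n <- 60
  levels <- matrix(sample(c(-1, 0, 0, 0, 1), 4 * n, replace = TRUE), n, 4,
                   dimnames = list(sprintf("g%02d", 1:n), fixtureSpecies))
  tabs <- lineageTables(levels)
  tree <- yeastPhylogeny()
  br <- assignLineage(tabs, tree, alpha = 0.01)
  ## terminal branches: the species' level must strictly exceed (or
  ## fall below) every other species' level
  for (sp in fixtureSpecies) {
    for (i in seq_len(nrow(br[[sp]]))) {
      g <- br[[sp]]$gene_id[i]
      others <- setdiff(fixtureSpecies, sp)
      if (br[[sp]]$direction[i] == "up")
        expect_true(all(levels[g, sp] > levels[g, others]))
      else
        expect_true(all(levels[g, sp] < levels[g, others]))
    }
  }
  ## partition arithmetic: recomputing from the same tables reproduces
  ## the assignment exactly
  br2 <- assignLineage(tabs, tree, alpha = 0.01)
  expect_identical(br, br2)
  ## a missing pairwise table is a design error
  expect_error(assignLineage(tabs[-1], tree), "missing pairwise")
})

test_that("the divergence clock recovers planted slope and intercept", {
  set.seed(101)
  a <- 0.30; b <- 1.20
  rates <- c(ScerR = 0, SparR = 0, cp = 0.231, pm = 0.359, cm = 0.394,
             pb = 0.521, mb = 0.538, cb = 0.556)
  fcs <- lapply(rates, function(r) rnorm(20000, 0, sqrt(a + b * r)))
  fit <- divergenceRegression(fcs, rates)
  expect_s4_class(fit, "DivergenceFit")
  expect_lt(abs(fit@slope - b) / b, 0.05)
  expect_lt(abs(fit@intercept - a) / a, 0.05)
  expect_gt(fit@r2, 0.98)
  ## equal variances everywhere give slope ~ 0
  flat <- lapply(rates, function(r) rnorm(5000, 0, 1))
  fit0 <- divergenceRegression(flat, rates)
  expect_lt(abs(fit0@slope), 0.05)
  expect_error(divergenceRegression(fcs[1:2], rates), "at least 3 points")
})

test_that("ANCOVA separates class slopes when they differ", {
  set.seed(7)
  rates <- c(r1 = 0, r2 = 0, r3 = 0.231, r4 = 0.394, r5 = 0.556,
             r6 = 0.359, r7 = 0.521, r8 = 0.538)
  mk <- function(b, label, n = 20000) {
    fcs <- lapply(rates, function(r) rnorm(n, 0, sqrt(0.3 + b * r)))
    divergenceRegression(fcs, rates, classLabel = label)
  }
  ## well-separated slopes at low noise
  out <- compareClassSlopes(mk(1.0, "slow"), mk(2.0, "fast"))
  expect_lt(out$p_value, 0.01)
  ## identically distributed classes give a large p
  out0 <- compareClassSlopes(mk(1.0, "a"), mk(1.0, "b"))
  expect_gt(out0$p_value, 0.1)
  tiny <- mk(1.0, "tiny"); tiny@points <- tiny@points[1, , drop = FALSE]
  expect_error(compareClassSlopes(tiny, mk(2.0, "fast")), "at least 3")
})

test_that("Spearman-distance clustering has the expected geometry", {
  set.seed(9)
  base <- matrix(rnorm(200), 50, 4)
  expr <- cbind(base[, 1], base[, 1], base[, 2], base[, 3])  # duplicate pair
  colnames(expr) <- c("s1", "s1b", "s2", "s3")
  hc <- clusterSamples(expr)
  ## the duplicate pair merges first at height 0
  first <- sort(hc$labels[-hc$merge[1, ]])
  expect_equal(first, c("s1", "s1b"))
  expect_equal(hc$height[1], 0)
  ## a perfectly anti-correlated pair sits at distance 2
  anti <- cbind(a = 1:50 + rnorm(50, 0, 1e-4), b = 50:1, c = rnorm(50))
  d <- 1 - cor(anti, method = "spearman")
  expect_equal(d["a", "b"], 2, tolerance = 1e-3)
  expect_error(clusterSamples(cbind(a = rep(1, 10), b = rnorm(10),
                                    c = rnorm(10))), "constant")
})

test_that("clustering recovers the species topology from clock data", {
  ## clock-structured profiles: shared drift along the tree's branches
  set.seed(13)
  n <- 400
  anc <- rnorm(n, 0, 2)
  inner <- anc + rnorm(n, 0, 0.5)          # ancestor of (Scer,Spar)
  inner2 <- anc + rnorm(n, 0, 0.5)         # ancestor of (Smik,Sbay)
  expr <- cbind(Scer = inner + rnorm(n, 0, 0.2),
                Spar = inner + rnorm(n, 0, 0.2),
                Smik = inner2 + rnorm(n, 0, 0.2),
                Sbay = inner2 + rnorm(n, 0, 0.2))
  hc <- clusterSamples(expr)
  phy <- ape::as.phylo(hc)
  target <- yeastPhylogeny()
  expect_equal(ape::dist.topo(ape::unroot(phy), ape::unroot(target))[1], 0)
})

test_that("paralog contrasts recover a planted heir-and-spare cohort", {
  ## 14 duplicated genes in Sbay; in 10, the diverged copy drops to 10%
  ## of the reference level; conserved copies track the reference
  nDup <- 14; nDrop <- 10
  genes <- sprintf("dup%02d", seq_len(nDup))
  ref <- setNames(rep(2000L, nDup), genes)
  onames <- sprintf("sbay_%s", genes)
  cA <- setNames(c(rep(200L, nDrop), rep(2000L, nDup - nDrop)),
                 paste0(onames, "_a"))            # diverged copies
  cB <- setNames(rep(2000L, nDup), paste0(onames, "_b"))
  ## 1:1 background genes anchor the normalization slope at 1
  bg <- sprintf("bg%03d", 1:101)
  entries <- c(
    setNames(lapply(genes, function(g)
      list(Sbay = paste0("sbay_", g, c("_a", "_b")))), genes),
    setNames(lapply(bg, function(g) list(Sbay = paste0("sbay_", g))), bg))
  orth <- OrthologSet(entries, "Scer")
  set.seed(2)
  bgRef <- setNames(rpois(101, 500) + 1L, bg)
  bgBay <- setNames(as.integer(bgRef), paste0("sbay_", bg))
  cs <- CountSet(list(
    Scer_r1 = c(ref, bgRef),
    Sbay_r1 = c(cA, cB, bgBay)),
    species = c("Scer", "Sbay"), replicate = 1L, batch = "d1")
  cand <- data.frame(reference_gene = genes,
                     copy1 = paste0(onames, "_a"),
                     copy2 = paste0(onames, "_b"))
  diverged <- setNames(paste0(onames, "_a"), genes)
  out <- paralogExpressionContrast(cand, cs, orth, "Sbay", diverged,
                                   U = 0.16, alpha = 0.01)
  expect_equal(nrow(out), nDup)
  expect_equal(sum(out$diverged_class == "significantly_below"), nDrop)
  expect_true(all(out$conserved_class == "consistent"))
  ## both copies at reference level stay consistent
  both <- out[out$reference_gene == "dup14", ]
  expect_equal(both$diverged_class, "consistent")
  ## a missing divergence ordering skips the pair with a warning
  expect_warning(
    out2 <- paralogExpressionContrast(cand[1:2, ], cs, orth, "Sbay",
                                      diverged[1], U = 0.16),
    "skipped")
  expect_equal(nrow(out2), 1)
})
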