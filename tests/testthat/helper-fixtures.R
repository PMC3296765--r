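## Programmatic fixtures shared across test files.

## A four-species ortholog/annotation fixture with known measurability:
## genes good1..good7 pass every criterion everywhere; the others each
## violate exactly one criterion in one species.
fixtureSpecies <- c("Scer", "Spar", "Smik", "Sbay")

fixtureOrthologs <- function() {
  genes <- c(paste0("good", 1:7), "shortlen", "lowuniq", "dup_mik")
  entries <- lapply(genes, function(g) {
    e <- list(Spar = paste0("spar_", g),
              Smik = paste0("smik_", g),
              Sbay = paste0("sbay_", g))
    if (g == "dup_mik") e$Smik <- c("smik_a", "smik_b")
    e
  })
  names(entries) <- genes
  OrthologSet(entries, "Scer")
}

fixtureAnnotations <- function() {
  orth <- fixtureOrthologs()
  rows <- list()
  for (g in referenceGenes(orth)) {
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = g, species = "Scer", annotated_length = 1000L,
      complete_orf = TRUE, unique_fraction = 0.98, biotype = "coding")
    for (sp in c("Spar", "Smik", "Sbay")) {
      for (oid in orthologIds(orth, g, sp)[[1]]) {
        len <- if (g == "shortlen" && sp == "Sbay") 850L else 1050L
        uf <- if (g == "lowuniq" && sp == "Spar") 0.80 else 0.95
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = oid, species = sp, annotated_length = len,
          complete_orf = TRUE, unique_fraction = uf, biotype = "coding")
      }
    }
  }
  do.call(rbind, rows)
}

## Minimal DEResults for lineage tests: per gene, a combined p and a
## log2 FC sign for the comparison (control, test); positive sign means
## higher in `test`.
makeDE <- function(control, test, genes, p, lfc) {
  df <- S4Vectors::DataFrame(gene_id = genes,
                             comparison = paste(control, test, sep = "_vs_"),
                             p_combined = p, log2_fc = lfc)
  res <- new("DEResults", df)
  S4Vectors::metadata(res) <- list(comparison = c(control, test),
                                   alpha = 0.01)
  res
}

## All six pairwise DE tables over four species from a per-species
## "expression level" profile per gene: gene is DE between a and b iff
## their levels differ, with sign level[b] - level[a].
lineageTables <- function(levels, species = fixtureSpecies, pSig = 1e-4) {
  genes <- rownames(levels)
  pairs <- utils::combn(species, 2, simplify = FALSE)
  lapply(pairs, function(pr) {
    d <- levels[, pr[2]] - levels[, pr[1]]
    makeDE(pr[1], pr[2], genes,
           p = ifelse(d != 0, pSig, 0.9),
           lfc = d)
  })
}

## Two-sample count fixture with exact ratios for normalization tests.
fixtureCounts <- function() {
  ctl <- c(a = 100L, b = 200L, c = 50L, d = 400L, e = 10L)
  tst <- c(a = 200L, b = 400L, c = 100L, d = 800L, e = 20L)
  list(control = ctl, test = tst)
}
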