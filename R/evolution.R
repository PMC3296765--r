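#' The fixed four-taxon phylogeny
#'
#' A rooted tree over the four yeast species with the sister pairing of
#' the two closest species: `((Scer,Spar),(Smik,Sbay))`. Any species
#' names can be supplied, mapped onto the same shape.
#'
#' @param species length-4 character vector, ordered so that the first
#'   two form one sister pair and the last two the other.
#' @return an [ape::phylo] object.
#' @export
yeastPhylogeny <- function(species = c("Scer", "Spar", "Smik", "Sbay")) {
  stopifnot(length(species) == 4, !anyDuplicated(species))
  ape::read.tree(text = sprintf("((%s,%s),(%s,%s));",
                                species[1], species[2],
                                species[3], species[4]))
}

## Unique non-trivial bipartitions of a tree's leaves, each named by one
## side (the smaller side; ties broken lexicographically).
treeSplits <- function(tree) {
  taxa <- tree$tip.label
  parts <- ape::prop.part(tree)
  splits <- list()
  add <- function(side) {
    side <- sort(side)
    other <- sort(setdiff(taxa, side))
    if (!length(other)) return()
    named <- if (length(side) < length(other)) side
             else if (length(other) < length(side)) other
             else if (paste(side, collapse = "+") <=
                      paste(other, collapse = "+")) side else other
    key <- paste(named, collapse = "+")
    if (!key %in% names(splits))
      splits[[key]] <<- list(side = named, other = sort(setdiff(taxa, named)))
  }
  for (tip in taxa) add(tip)
  for (p in parts) add(taxa[p])
  splits
}

#' Assign differential-expression changes to phylogenetic branches
#'
#' A gene's expression change is attributed to a branch when, for every
#' species pair split by that branch, the pairwise comparison is
#' significant at `alpha` (Fisher-combined p-value) and the fold-change
#' direction is consistent: every species on the branch's named side is
#' higher than every species on the other side (direction `"up"`), or
#' lower (`"down"`). Terminal branches require the species to be
#' consistently DE against each of the other three; the internal branch
#' requires all four cross-split pairs. A gene may be assigned to more
#' than one branch.
#'
#' @param deTables list of [DEResults-class], one per unordered species
#'   pair (all pairs over the tree's taxa must be present).
#' @param tree an [ape::phylo] over the species, e.g.
#'   [yeastPhylogeny()].
#' @param alpha significance level, default 0.01.
#' @return named list (one element per branch) of data.frames with
#'   columns `gene_id` and `direction` (`"up"` = the branch's named side
#'   is higher).
#' @export
assignLineage <- function(deTables, tree, alpha = 0.01) {
  taxa <- tree$tip.label
  ## index pairwise p and signed direction: sign > 0 means second
  ## species of the key is higher
  pmap <- list(); smap <- list()
  for (tab in deTables) {
    cmp <- metadata(tab)$comparison
    if (is.null(cmp))
      stop("each DE table must carry its comparison in metadata()")
    key <- paste(cmp, collapse = "|")
    pmap[[key]] <- setNames(tab$p_combined, tab$gene_id)
    smap[[key]] <- setNames(sign(tab$log2_fc), tab$gene_id)
  }
  lookup <- function(a, b) {
    k1 <- paste(c(a, b), collapse = "|"); k2 <- paste(c(b, a), collapse = "|")
    if (!is.null(pmap[[k1]])) list(p = pmap[[k1]], s = smap[[k1]])
    else if (!is.null(pmap[[k2]])) list(p = pmap[[k2]], s = -smap[[k2]])
    else stop(sprintf("missing pairwise DE table for %s vs %s", a, b))
  }
  genes <- Reduce(intersect, lapply(pmap, names))
  splits <- treeSplits(tree)
  out <- list()
  for (key in names(splits)) {
    sideA <- splits[[key]]$side; sideB <- splits[[key]]$other
    up <- rep(TRUE, length(genes)); dn <- rep(TRUE, length(genes))
    sig <- rep(TRUE, length(genes))
    for (a in sideA) for (b in sideB) {
      lk <- lookup(b, a)            # control = b, test = a (named side)
      p <- lk$p[genes]; s <- lk$s[genes]
      sig <- sig & !is.na(p) & p < alpha
      up <- up & !is.na(s) & s > 0
      dn <- dn & !is.na(s) & s < 0
    }
    hit <- sig & (up | dn)
    out[[key]] <- data.frame(gene_id = genes[hit],
                             direction = ifelse(up[hit], "up", "down"),
                             row.names = NULL, stringsAsFactors = FALSE)
  }
  out
}

#' Per-gene log2 fold changes between two samples
#'
#' Helper producing the fold-change vector of one sample pair on the
#' reference gene scale: counts translated through the ortholog map,
#' rescaled to the pair's geometric-mean library size, restricted to
#' genes with at least `minReads` (raw) on both sides.
#'
#' @param x a [CountSet-class].
#' @param orthologs an [OrthologSet-class].
#' @param genes reference gene ids (e.g. the core set).
#' @param sampleA,sampleB sample ids (A = control/denominator).
#' @param minReads per-side minimum raw count, default 10.
#' @return named numeric vector of log2 fold changes (B over A).
#' @export
pairLog2FC <- function(x, orthologs, genes, sampleA, sampleB, minReads = 10) {
  sd <- sampleData(x)
  spA <- sd$species[sd$sample_id == sampleA]
  spB <- sd$species[sd$sample_id == sampleB]
  oidA <- orthologId(orthologs, genes, spA)
  oidB <- orthologId(orthologs, genes, spB)
  cA <- counts(x, sampleA)[oidA]; cB <- counts(x, sampleB)[oidB]
  cA[is.na(cA)] <- 0; cB[is.na(cB)] <- 0
  keep <- cA >= minReads & cB >= minReads & !is.na(oidA) & !is.na(oidB)
  tot <- sqrt(sum(as.numeric(counts(x, sampleA))) *
              sum(as.numeric(counts(x, sampleB))))
  An <- sizeNormalizedCount(as.numeric(cA[keep]),
                            sum(as.numeric(counts(x, sampleA))), tot)
  Bn <- sizeNormalizedCount(as.numeric(cB[keep]),
                            sum(as.numeric(counts(x, sampleB))), tot)
  setNames(log2(Bn / An), genes[keep])
}

#' Expression-divergence clock regression
#'
#' Ordinary least squares of the variance of per-pair log2 fold changes
#' on the intergenic substitution rate separating the pair. Replicate
#' self-comparisons enter at rate 0, anchoring the intercept at the
#' replicate (zero-divergence) variance; the slope measures the rate of
#' expression divergence. Fold changes that are undefined (zero counts)
#' are excluded gene-wise rather than imputed.
#'
#' @param fcList named list of numeric log2 fold-change vectors, one per
#'   sample pair (replicate self-pairs included).
#' @param rates named numeric vector of intergenic substitution rates,
#'   names matching `fcList` (0 for replicate pairs).
#' @param classLabel label for the gene class fitted, default `"all"`.
#' @return a [DivergenceFit-class].
#' @export
divergenceRegression <- function(fcList, rates, classLabel = "all") {
  if (is.null(names(fcList)) || !all(names(fcList) %in% names(rates)))
    stop("every fold-change vector needs a matching rate")
  pts <- data.frame(
    pair = names(fcList),
    rate = as.numeric(rates[names(fcList)]),
    var_log2fc = vapply(fcList, function(v) var(v[is.finite(v)]), numeric(1)),
    n_genes = vapply(fcList, function(v) sum(is.finite(v)), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  if (nrow(pts) < 3) stop("at least 3 points are required for the fit")
  fit <- lm(var_log2fc ~ rate, data = pts)
  new("DivergenceFit", points = pts,
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      r2 = summary(fit)$r.squared, classLabel = classLabel, fit = fit)
}

setMethod("show", "DivergenceFit", function(object) {
  cat(sprintf(
    "DivergenceFit [%s]: var(log2 FC) = %.4f + %.4f x rate (R^2 = %.3f, %d points)\n",
    object@classLabel, object@intercept, object@slope, object@r2,
    nrow(object@points)))
})

#' Compare divergence-clock slopes between two gene classes
#'
#' Analysis of covariance: the pooled points of both fits are modelled
#' as `var ~ rate * class` and the p-value of the interaction term
#' (class-specific slope) is returned. A small p-value means the two
#' classes diverge at significantly different rates.
#'
#' @param fitA,fitB [DivergenceFit-class] objects over the same rate
#'   design.
#' @return list with `p_value` (slope-difference p), `fit` (the pooled
#'   `lm`).
#' @export
compareClassSlopes <- function(fitA, fitB) {
  a <- fitA@points; b <- fitB@points
  if (nrow(a) < 3 || nrow(b) < 3)
    stop("each class needs at least 3 points for an ANCOVA")
  pts <- rbind(cbind(a, class = fitA@classLabel),
               cbind(b, class = fitB@classLabel))
  pts$class <- factor(pts$class)
  if (nlevels(pts$class) < 2)
    stop("the two fits must carry distinct class labels")
  fit <- lm(var_log2fc ~ rate * class, data = pts)
  tab <- anova(fit)
  list(p_value = tab["rate:class", "Pr(>F)"], fit = fit)
}

#' Hierarchical clustering of samples by expression
#'
#' Samples are clustered on the distance `1 - Spearman correlation`
#' between their expression profiles over a shared gene set, with
#' average linkage. Duplicate samples (distance 0) merge first;
#' perfectly anti-correlated samples are at distance 2.
#'
#' @param expr numeric matrix, genes x samples (>= 3 samples), e.g. log
#'   expression of the core genes.
#' @return an [stats::hclust] tree.
#' @export
clusterSamples <- function(expr) {
  if (ncol(expr) < 3) stop("at least 3 samples are required")
  sds <- apply(expr, 2L, function(v) stats::sd(v, na.rm = TRUE))
  if (any(is.na(sds)) || any(sds == 0))
    stop("constant expression vector: Spearman distance undefined")
  d <- 1 - cor(expr, method = "spearman", use = "pairwise.complete.obs")
  hclust(as.dist(d), method = "average")
}

#' Expression contrast of duplicated gene copies
#'
#' For each stringent duplication candidate (two copies in the target
#' species, one ortholog in the reference species), classifies each
#' copy's expression against the reference gene using the
#' over-dispersed chi-square machinery: `consistent` when not
#' significant at `alpha`, otherwise `significantly_below` /
#' `significantly_above` by the sign of the fold change. The externally
#' supplied sequence-divergence ordering says which copy is the more
#' diverged one.
#'
#' @param candidates data.frame from [duplicationCandidates()].
#' @param x a [CountSet-class] with the reference and target species.
#' @param orthologs an [OrthologSet-class] (used for the normalization
#'   slope over 1:1 orthologs).
#' @param targetSpecies species carrying the duplication.
#' @param divergedCopy named character vector: for each
#'   `reference_gene`, the id of the more sequence-diverged copy. Pairs
#'   without an ordering are skipped with a warning.
#' @param U uniform relative non-Poisson SD used on both sides.
#' @param alpha significance level, default 0.01.
#' @param batch batch label selecting the sample pair; default: first
#'   shared batch.
#' @return data.frame with columns `reference_gene`, `diverged_copy`,
#'   `conserved_copy`, `diverged_class`, `conserved_class`.
#' @export
paralogExpressionContrast <- function(candidates, x, orthologs,
                                      targetSpecies, divergedCopy,
                                      U = 0.16, alpha = 0.01,
                                      batch = NULL) {
  ref <- referenceSpecies(orthologs)
  sd <- sampleData(x)
  if (is.null(batch)) {
    batch <- intersect(sd$batch[sd$species == ref],
                       sd$batch[sd$species == targetSpecies])[1]
  }
  sRef <- samplesFor(x, species = ref, batch = batch)[1]
  sTgt <- samplesFor(x, species = targetSpecies, batch = batch)[1]
  cRef <- counts(x, sRef); cTgt <- counts(x, sTgt)
  ## slope over measurable 1:1 orthologs between the two samples
  genes11 <- referenceGenes(orthologs)
  oid <- orthologId(orthologs, genes11, targetSpecies)
  ok <- !is.na(oid)
  m <- medianRatioSlope(setNames(unname(cRef[genes11[ok]]), genes11[ok]),
                        setNames(unname(cTgt[oid[ok]]), genes11[ok]))
  classify <- function(gRef, gCopy) {
    C <- cRef[[gRef]]; T0 <- cTgt[[gCopy]]
    if (is.null(C) || is.na(C)) C <- 0
    if (is.null(T0) || is.na(T0)) T0 <- 0
    x2 <- chi2Statistic(C, T0, m, U, U)
    p <- pValue(x2)
    if (is.na(p) || p >= alpha) return("consistent")
    if (T0 < C * m) "significantly_below" else "significantly_above"
  }
  rows <- list()
  for (i in seq_len(nrow(candidates))) {
    g <- candidates$reference_gene[i]
    copies <- c(candidates$copy1[i], candidates$copy2[i])
    dv <- if (g %in% names(divergedCopy)) divergedCopy[[g]] else NA_character_
    if (is.na(dv) || !dv %in% copies) {
      warning(sprintf("no divergence ordering for '%s'; skipped", g))
      next
    }
    cons <- setdiff(copies, dv)
    rows[[g]] <- data.frame(reference_gene = g, diverged_copy = dv,
                            conserved_copy = cons,
                            diverged_class = classify(g, dv),
                            conserved_class = classify(g, cons),
                            stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(reference_gene = character(0),
                      diverged_copy = character(0),
                      conserved_copy = character(0),
                      diverged_class = character(0),
                      conserved_class = character(0)))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
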