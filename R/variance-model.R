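#' Relative non-Poisson SD of one gene from replicate counts
#'
#' The variance measured across replicates mixes Poisson counting noise
#' with everything else (technical imprecision, environmental response).
#' Poisson variance is estimated by the mean replicate count `R`, so the
#' non-Poisson variance is `sigma_reps^2 - R` (clamped at zero: sparse
#' replication measures some variances at zero by chance), and the
#' relative non-Poisson SD is its square root divided by `R`.
#'
#' @param repCounts numeric vector of >= 2 replicate counts for one
#'   gene, or a matrix (genes x replicates) for the vectorized form.
#' @return for a vector: `c(sigma_m = ..., R = ...)`; for a matrix: a
#'   data.frame with columns `sigma_m` and `R` (the weight carried into
#'   cross-species pooling).
#' @examples
#' replicateNonPoissonSD(c(90, 110))  # sigma_m = 0.1, R = 100
#' @export
replicateNonPoissonSD <- function(repCounts) {
  if (is.matrix(repCounts)) {
    if (ncol(repCounts) < 2) stop("at least 2 replicates are required")
    R <- rowMeans(repCounts)
    v <- apply(repCounts, 1L, var)
    s2 <- pmax(0, v - R)
    sm <- ifelse(R > 0, sqrt(s2) / R, 0)
    return(data.frame(sigma_m = sm, R = R,
                      row.names = rownames(repCounts)))
  }
  if (length(repCounts) < 2) stop("at least 2 replicates are required")
  R <- mean(repCounts)
  s2 <- max(0, var(repCounts) - R)
  c(sigma_m = if (R > 0) sqrt(s2) / R else 0, R = R)
}

#' Apply the technical resolution floor
#'
#' Replicate-measured relative SDs below the resolution of the assay
#' (the uniform over-dispersion calibrated on technical replicates,
#' `sigma_t`) are replaced by that floor: genes should not be called DE
#' between samples closer in expression than the technology can resolve.
#'
#' @param sigmaM measured relative non-Poisson SD(s), >= 0.
#' @param sigmaT technical floor, >= 0.
#' @return `pmax(sigmaM, sigmaT)`.
#' @export
applyTechnicalFloor <- function(sigmaM, sigmaT) {
  if (any(sigmaM < 0, na.rm = TRUE) || any(sigmaT < 0))
    stop("relative SDs must be non-negative")
  pmax(sigmaM, sigmaT)
}

#' Calibrate the uniform over-dispersion U on a replicate pair
#'
#' In a self-comparison of replicates the null hypothesis holds for
#' every gene, so the fraction of genes called DE at level `alpha`
#' should equal `alpha`. `U` is set to the smallest value on the search
#' grid at which the fraction of replicate genes with p < `alpha` (from
#' the over-dispersed chi-square test run with uniform relative SD `U`
#' on both sides) drops to at most `alpha`; e.g. with 10,000 calibrated
#' genes at `alpha` = 0.05, the minimal `U` with at most 500 positive
#' genes. Because each gene's statistic decreases monotonically in `U`,
#' the positive count is non-increasing in `U` and a bisection on the
#' grid is exact to grid resolution. Genes with a mean count below
#' `minMeanReads` across the two replicates are excluded so that the
#' calibration is not dominated by Poisson noise.
#'
#' @param rep1,rep2 named count vectors of the two replicates (matched
#'   by gene name), or unnamed vectors of equal length.
#' @param alpha calibration level in (0, 1), default 0.05.
#' @param minMeanReads minimum mean count across the two replicates,
#'   default 10.
#' @param gridStep,uMax search grid resolution and upper bound
#'   (defaults 0.001 and 2).
#' @param genes optional gene subset (e.g. coding genes for a
#'   technical-replicate calibration of `sigma_t`).
#' @return an [OverdispersionCalibration-class]. If even U = 0 meets the
#'   target the pair is under-dispersed at this level; U = 0 is returned
#'   with the `underdispersed` flag set and a warning.
#' @export
calibrateU <- function(rep1, rep2, alpha = 0.05, minMeanReads = 10,
                       gridStep = 0.001, uMax = 2, genes = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (!is.null(names(rep1)) && !is.null(names(rep2))) {
    shared <- intersect(names(rep1), names(rep2))
    if (!is.null(genes)) shared <- intersect(shared, genes)
    rep1 <- rep1[shared]; rep2 <- rep2[shared]
  } else if (length(rep1) != length(rep2)) {
    stop("unnamed replicate vectors must have equal length")
  }
  keep <- (rep1 + rep2) / 2 >= minMeanReads
  rep1 <- as.numeric(rep1[keep]); rep2 <- as.numeric(rep2[keep])
  n <- length(rep1)
  if (!n) stop("no genes pass the calibration mean-count filter")
  m <- medianRatioSlope(setNames(rep1, seq_len(n)), setNames(rep2, seq_len(n)))
  target <- alpha * n
  nPos <- function(u) {
    x2 <- chi2Statistic(rep1, rep2, m, u, u)
    sum(pchisq(x2, df = 1, lower.tail = FALSE) < alpha)
  }
  grid <- seq(0, uMax, by = gridStep)
  if (nPos(0) <= target) {
    warning("replicate pair is not over-dispersed at this level; U = 0")
    return(new("OverdispersionCalibration", U = 0, alpha = alpha,
               nGenesCalibrated = n, gridStep = gridStep, uMax = uMax,
               underdispersed = TRUE, nPositive = as.integer(nPos(0))))
  }
  if (nPos(uMax) > target)
    stop(sprintf("positive fraction still exceeds alpha at uMax = %g", uMax))
  lo <- 1L; hi <- length(grid)      # invariant: nPos(grid[lo]) > target >= ...
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (nPos(grid[mid]) <= target) hi <- mid else lo <- mid
  }
  new("OverdispersionCalibration", U = grid[hi], alpha = alpha,
      nGenesCalibrated = n, gridStep = gridStep, uMax = uMax,
      underdispersed = FALSE, nPositive = as.integer(nPos(grid[hi])))
}

#' Calibrate U for one species of a CountSet
#'
#' Convenience wrapper locating the replicate pair of `species` (two
#' samples of the requested kind) and running [calibrateU()].
#'
#' @param x a [CountSet-class].
#' @param species species name.
#' @param kind `"biological"` (default) or `"technical"`.
#' @param ... passed to [calibrateU()].
#' @return an [OverdispersionCalibration-class].
#' @export
calibrateSpecies <- function(x, species, kind = "biological", ...) {
  ids <- samplesFor(x, species = species, kind = kind)
  if (length(ids) < 2)
    stop(sprintf("species '%s' has no %s replicate pair", species, kind))
  calibrateU(counts(x, ids[1]), counts(x, ids[2]), ...)
}

setMethod("show", "OverdispersionCalibration", function(object) {
  cat(sprintf(
    "OverdispersionCalibration: U = %.3f (alpha = %g, %d genes, %d positive%s)\n",
    object@U, object@alpha, object@nGenesCalibrated, object@nPositive,
    if (object@underdispersed) ", under-dispersed" else ""))
})

#' @rdname calibrateU
#' @param object an [OverdispersionCalibration-class].
#' @export
uValue <- function(object) object@U

#' Pool per-species variance estimates for one gene
#'
#' Gene function, and hence a gene's environmental variance, is assumed
#' conserved across species, so per-species replicate estimates of the
#' relative non-Poisson SD are pooled: estimates based on a mean of
#' fewer than `minPoolReads` replicate reads are discarded as
#' Poisson-dominated; the survivors are averaged weighted by their mean
#' read counts; the result is floored at `sigmaT`. When no species
#' provides a reliable estimate the gene falls back to the uniform U of
#' the species being tested (`fallback = TRUE`, resolved per comparison
#' by [sigmaFor()]).
#'
#' @param sigmaM numeric vector of per-species relative non-Poisson SDs
#'   for one gene.
#' @param R numeric vector of the mean replicate read counts behind each
#'   estimate (the pooling weights).
#' @param sigmaT technical floor.
#' @param minPoolReads reliability threshold on `R`, default 30.
#' @return list with `sigma` (pooled, floored; `NA` on fallback) and
#'   `fallback` (logical).
#' @export
pooledGeneVariance <- function(sigmaM, R, sigmaT, minPoolReads = 30) {
  keep <- !is.na(sigmaM) & !is.na(R) & R >= minPoolReads
  if (!any(keep))
    return(list(sigma = NA_real_, fallback = TRUE))
  w <- R[keep]
  list(sigma = applyTechnicalFloor(sum(w * sigmaM[keep]) / sum(w), sigmaT),
       fallback = FALSE)
}

#' Rescale a pooled sigma for one species' replicate reproducibility
#'
#' Each species' replicate pair reproduces with a slightly different
#' overall over-dispersion U; when the pooled gene-specific sigma is
#' used in a test involving that species it is multiplied by the
#' species' U divided by the mean U across all species.
#'
#' @param sigma pooled relative non-Poisson SD(s).
#' @param uSpecies U of the species under test.
#' @param uAll numeric vector of the U values of all species.
#' @return rescaled sigma.
#' @export
speciesRescale <- function(sigma, uSpecies, uAll) {
  if (any(uAll <= 0) || uSpecies <= 0) stop("U values must be positive")
  sigma * uSpecies / mean(uAll)
}

#' Estimate per-gene, per-species replicate variances on the reference
#' gene scale
#'
#' For every species with a biological replicate pair, translates gene
#' ids through the ortholog map, rescales the pair to its common depth
#' scale via the median-ratio slope (so that differing library sizes do
#' not inflate the replicate variance), and applies
#' [replicateNonPoissonSD()] gene-wise.
#'
#' @param x a [CountSet-class].
#' @param orthologs an [OrthologSet-class].
#' @param genes reference gene ids to estimate.
#' @param species species to use; default: all species present in `x`
#'   with at least two biological replicates.
#' @return list of data.frames (one per species) with columns `sigma_m`
#'   and `R`, rows = `genes`.
#' @export
estimateGeneVariance <- function(x, orthologs, genes, species = NULL) {
  sd <- sampleData(x)
  if (is.null(species)) {
    species <- unique(sd$species[sd$kind == "biological"])
    species <- species[vapply(species, function(sp)
      length(samplesFor(x, species = sp, kind = "biological")) >= 2,
      logical(1))]
  }
  out <- list()
  for (sp in species) {
    ids <- samplesFor(x, species = sp, kind = "biological")
    if (length(ids) < 2)
      stop(sprintf("species '%s' lacks a biological replicate pair", sp))
    oid <- orthologId(orthologs, genes, sp)
    c1 <- counts(x, ids[1]); c2 <- counts(x, ids[2])
    v1 <- unname(c1[oid]); v2 <- unname(c2[oid])
    v1[is.na(v1)] <- 0; v2[is.na(v2)] <- 0
    v1[is.na(oid)] <- NA; v2[is.na(oid)] <- NA
    m <- medianRatioSlope(c1, c2)
    mat <- cbind(v1 * sqrt(m), v2 / sqrt(m))
    rownames(mat) <- genes
    out[[sp]] <- replicateNonPoissonSD(mat)
  }
  out
}

#' Build the variance model for cross-species testing
#'
#' Combines per-species replicate estimates ([estimateGeneVariance()]),
#' per-species uniform calibrations ([calibrateSpecies()]) and the
#' technical floor into a [VarianceModel-class]: per gene, estimates
#' with mean replicate reads below `minPoolReads` are discarded, the
#' rest are read-count weighted and averaged, the pooled value is
#' floored at `sigmaT`, and genes with no reliable estimate anywhere
#' fall back to the species U at test time.
#'
#' @param x a [CountSet-class].
#' @param orthologs an [OrthologSet-class].
#' @param genes reference gene ids the model should cover.
#' @param speciesU named numeric vector of calibrated per-species U
#'   values (see [calibrateSpecies()]).
#' @param sigmaT technical floor (a U calibrated on technical
#'   replicates, coding genes only).
#' @param minPoolReads pooling reliability threshold, default 30.
#' @return a [VarianceModel-class].
#' @export
buildVarianceModel <- function(x, orthologs, genes, speciesU, sigmaT,
                               minPoolReads = 30) {
  est <- estimateGeneVariance(x, orthologs, genes,
                              species = names(speciesU))
  sigM <- vapply(est, function(d) d$sigma_m, numeric(length(genes)))
  RW <- vapply(est, function(d) d$R, numeric(length(genes)))
  if (length(genes) == 1L) { sigM <- rbind(sigM); RW <- rbind(RW) }
  sigma <- numeric(length(genes)); fb <- logical(length(genes))
  for (i in seq_along(genes)) {
    p <- pooledGeneVariance(sigM[i, ], RW[i, ], sigmaT, minPoolReads)
    sigma[i] <- p$sigma; fb[i] <- p$fallback
  }
  new("VarianceModel", geneSigma = setNames(sigma, genes),
      fallback = setNames(fb, genes), speciesU = speciesU, sigmaT = sigmaT)
}

#' Uniform variance model
#'
#' A [VarianceModel-class] with no gene-specific component: every gene
#' uses the species' uniform U. Useful for calibration-style analyses
#' and for datasets without cross-species replicate information.
#'
#' @param speciesU named numeric vector (or a single unnamed value used
#'   for the species in `species`).
#' @param species species names, required when `speciesU` is unnamed.
#' @param sigmaT technical floor recorded on the model (default 0).
#' @return a [VarianceModel-class].
#' @export
uniformVarianceModel <- function(speciesU, species = names(speciesU),
                                 sigmaT = 0) {
  if (is.null(species)) stop("species names are required")
  if (is.null(names(speciesU)))
    speciesU <- setNames(rep_len(speciesU, length(species)), species)
  new("VarianceModel", geneSigma = numeric(0), fallback = logical(0),
      speciesU = speciesU, sigmaT = sigmaT)
}

#' Per-gene relative SD used when testing one species
#'
#' Resolves the variance model for a comparison side: gene-specific
#' pooled sigmas are rescaled by `U_species / mean(U)`; fallback genes
#' (and every gene of a uniform model) use the species' own U.
#'
#' @param object a [VarianceModel-class].
#' @param genes reference gene ids.
#' @param species the species on this side of the comparison.
#' @param ... unused.
#' @return named numeric vector of relative non-Poisson SDs.
#' @export
setMethod("sigmaFor", "VarianceModel", function(object, genes, species, ...) {
  if (!species %in% names(object@speciesU))
    stop(sprintf("no calibrated U for species '%s'", species))
  uS <- object@speciesU[[species]]
  if (!length(object@geneSigma))
    return(setNames(rep(uS, length(genes)), genes))
  sig <- object@geneSigma[genes]
  out <- speciesRescale(sig, uS, object@speciesU)
  out[is.na(sig)] <- uS
  setNames(unname(out), genes)
})

setMethod("show", "VarianceModel", function(object) {
  cat(sprintf("VarianceModel: sigma_t = %.3f; species U: %s\n",
              object@sigmaT,
              paste(sprintf("%s = %.3f", names(object@speciesU),
                            object@speciesU), collapse = ", ")))
  if (length(object@geneSigma))
    cat(sprintf("  %d genes (%d fallback to species U)\n",
                length(object@geneSigma), sum(object@fallback)))
  else cat("  uniform model (no gene-specific component)\n")
})
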