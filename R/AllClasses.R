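#' @import methods
#' @importFrom S4Vectors DataFrame DFrame metadata metadata<-
#' @importFrom stats median pchisq var cor setNames as.dist hclust lm coef
#'   anova rlnorm rnorm rpois runif quantile
#' @importFrom utils read.delim write.table
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' CountSet: unique-read count tables with sample metadata
#'
#' A `CountSet` holds one raw unique-read count table per sample together
#' with the sample metadata needed for cross-species testing: species,
#' replicate index, growth-batch label (used for same-day pairing of
#' comparisons) and replicate kind (biological or technical). Gene
#' universes may differ between species, so each sample keeps its own
#' named integer count vector rather than a shared matrix; counts are
#' raw unique-read integers and are never length-normalized.
#'
#' @slot counts named list of named non-negative integer vectors, one per
#'   sample, each mapping gene identifiers of that sample's species to
#'   unique-read counts.
#' @slot sampleData a [S4Vectors::DataFrame] with one row per sample and
#'   columns `sample_id`, `species`, `replicate`, `batch`, `kind`.
#'
#' @seealso [CountSet()], [readCountTable()], [readManifest()]
#' @export
setClass("CountSet",
  representation(counts = "list", sampleData = "DFrame"))

setValidity("CountSet", function(object) {
  sd <- object@sampleData
  need <- c("sample_id", "species", "replicate", "batch", "kind")
  if (!all(need %in% colnames(sd)))
    return(paste("sampleData must have columns:", paste(need, collapse = ", ")))
  if (length(object@counts) != nrow(sd))
    return("one count vector per sample row is required")
  if (anyDuplicated(sd$sample_id))
    return("sample_id values must be unique")
  if (!identical(names(object@counts), as.character(sd$sample_id)))
    return("names(counts) must equal sampleData$sample_id, in order")
  if (any(!nzchar(sd$batch)) || anyNA(sd$batch))
    return("batch labels must be non-empty (they drive same-day pairing)")
  if (any(sd$replicate < 1) || any(sd$replicate != round(sd$replicate)))
    return("replicate indices must be positive integers")
  if (!all(sd$kind %in% c("biological", "technical")))
    return("kind must be 'biological' or 'technical'")
  for (i in seq_along(object@counts)) {
    ct <- object@counts[[i]]
    if (length(ct) && is.null(names(ct)))
      return("count vectors must be named by gene id")
    if (anyDuplicated(names(ct)))
      return(sprintf("duplicate gene ids in sample '%s'", sd$sample_id[i]))
    if (anyNA(ct) || any(ct < 0) || any(ct != round(ct)))
      return(sprintf("counts in sample '%s' must be non-negative integers",
                     sd$sample_id[i]))
  }
  TRUE
})

#' OrthologSet: cross-species gene correspondences
#'
#' Maps reference-species gene identifiers to their annotated orthologs
#' in the other species. A gene is 1:1 in species `s` exactly when its
#' ortholog list for `s` has one element. The `coreFlags` slot marks the
#' core gene set (genes measurable as 1:1 orthologs under all inclusion
#' criteria in every species); it starts unset (`NA`) and is filled by
#' [coreGeneSet()] via [setCoreGenes()].
#'
#' @slot referenceSpecies single species name anchoring the gene ids.
#' @slot species the non-reference species covered by the map.
#' @slot entries named list (names = reference gene ids); each element is
#'   a named list mapping species to a character vector of ortholog ids
#'   (length 0 = absent, 1 = one ortholog, >1 = duplication).
#' @slot coreFlags named logical vector over reference gene ids.
#'
#' @seealso [readOrthologMap()], [coreGeneSet()], [orthologId()]
#' @export
setClass("OrthologSet",
  representation(referenceSpecies = "character", species = "character",
                 entries = "list", coreFlags = "logical"))

setValidity("OrthologSet", function(object) {
  if (length(object@referenceSpecies) != 1L)
    return("referenceSpecies must be a single species name")
  if (anyDuplicated(names(object@entries)))
    return("duplicate reference gene ids")
  if (!identical(names(object@coreFlags), names(object@entries)))
    return("coreFlags must be named by the reference gene ids")
  for (e in object@entries) {
    if (!all(object@species %in% names(e)))
      return("every entry must cover every non-reference species")
  }
  TRUE
})

#' OverdispersionCalibration: a replicate-calibrated uniform U
#'
#' Result of the minimal-U grid search: the smallest uniform relative
#' non-Poisson standard deviation `U` such that the fraction of genes
#' called differentially expressed between two replicates of the same
#' condition does not exceed the nominal level `alpha`. A calibration run
#' on technical replicates measures the resolution floor `sigma_t` of
#' the assay.
#'
#' @slot U calibrated uniform relative non-Poisson SD (>= 0).
#' @slot alpha calibration level in (0, 1).
#' @slot nGenesCalibrated number of genes passing the mean-count filter.
#' @slot gridStep,uMax resolution and upper bound of the search grid.
#' @slot underdispersed `TRUE` when even U = 0 met the target, i.e. the
#'   replicate pair shows no excess over Poisson at this level.
#' @slot nPositive number of genes with p < alpha at the calibrated U.
#'
#' @seealso [calibrateU()]
#' @export
setClass("OverdispersionCalibration",
  representation(U = "numeric", alpha = "numeric",
                 nGenesCalibrated = "integer", gridStep = "numeric",
                 uMax = "numeric", underdispersed = "logical",
                 nPositive = "integer"))

#' VarianceModel: per-gene pooled non-Poisson SD plus per-species U
#'
#' The variance model used by the chi-square test. `geneSigma` holds the
#' per-gene relative non-Poisson SD pooled across species with
#' read-count weighting and floored at the technical resolution
#' `sigmaT`; genes for which no species provided a reliable estimate
#' (mean replicate reads below the pooling threshold everywhere) carry
#' `NA` here and fall back to the species' own uniform `U`. When a
#' gene-specific sigma is used for species `s` it is rescaled by
#' `U_s / mean(U)` to reflect the species' overall replicate
#' reproducibility (see [sigmaFor()]).
#'
#' @slot geneSigma named numeric; pooled, floored relative non-Poisson SD
#'   per gene (`NA` = fallback to species U). May be empty, in which case
#'   the model is the uniform-U model for every gene.
#' @slot fallback named logical; `TRUE` where the species-U fallback
#'   applies.
#' @slot speciesU named numeric; calibrated uniform U per species.
#' @slot sigmaT technical floor (a U calibrated on technical replicates).
#'
#' @seealso [buildVarianceModel()], [uniformVarianceModel()], [sigmaFor()]
#' @export
setClass("VarianceModel",
  representation(geneSigma = "numeric", fallback = "logical",
                 speciesU = "numeric", sigmaT = "numeric"))

setValidity("VarianceModel", function(object) {
  if (length(object@sigmaT) != 1L || object@sigmaT < 0)
    return("sigmaT must be a single non-negative number")
  if (is.null(names(object@speciesU)) || any(object@speciesU < 0))
    return("speciesU must be a named non-negative numeric vector")
  if (length(object@geneSigma) &&
      any(object@geneSigma < object@sigmaT, na.rm = TRUE))
    return("geneSigma must be floored at sigmaT")
  TRUE
})

#' DEResults: per-gene differential-expression calls for one comparison
#'
#' A [S4Vectors::DFrame] subclass (one row per gene) holding, for a
#' single species pair: the raw counts of every sample used, the
#' per-batch chi-square statistics and p-values (same-day pairs tested
#' independently), the Fisher-combined p-value, the log2 fold change
#' with its error-propagated SD and 2-sigma interval, the DE call at the
#' stated alpha, and a low-count flag. `metadata()` carries the
#' comparison, alpha, the per-batch normalization slopes, and the sample
#' ids per batch.
#'
#' @seealso [callDE()], [writeResults()]
#' @export
setClass("DEResults", contains = "DFrame")

#' DivergenceFit: expression-divergence clock regression
#'
#' Ordinary least-squares fit of the variance of per-gene log2 fold
#' changes against the intergenic substitution rate separating the two
#' samples of each comparison. Replicate self-comparisons enter at rate
#' zero, so the intercept estimates the replicate (zero-divergence)
#' fold-change variance while the slope is the rate of expression
#' divergence.
#'
#' @slot points data.frame with columns `pair`, `rate`, `var_log2fc`,
#'   `n_genes`.
#' @slot slope,intercept,r2 fitted coefficients and coefficient of
#'   determination.
#' @slot classLabel label of the gene class the fit describes.
#' @slot fit the underlying `lm` object.
#'
#' @seealso [divergenceRegression()], [compareClassSlopes()]
#' @export
setClass("DivergenceFit",
  representation(points = "data.frame", slope = "numeric",
                 intercept = "numeric", r2 = "numeric",
                 classLabel = "character", fit = "ANY"))

#' SimulationSpec: generative conditions for synthetic count data
#'
#' Describes a synthetic RNA-Seq experiment with the statistical
#' structure the test assumes: per-gene expected counts spanning several
#' orders of magnitude (log-normal), Poisson sampling, multiplicative
#' latent non-Poisson noise of controlled relative SD, batch-paired
#' replicates across species, and injected differential expression of
#' controlled effect size. Defaults reproduce the regime of a deeply
#' sequenced yeast experiment: 10,000 genes with log-normal means
#' (meanlog 5, sdlog 1.5, so >95\\% of genes exceed 10 reads), uniform
#' over-dispersion 0.16, two batches of two replicates.
#'
#' @slot nGenes number of genes.
#' @slot meanLog,sdLog log-normal parameters of per-gene expected counts.
#' @slot overdispersionModel `"uniform"` (every gene at `U`) or
#'   `"lognormal"` (per-gene sigma drawn log-normally around `U`).
#' @slot U uniform relative non-Poisson SD (or the median when
#'   `overdispersionModel = "lognormal"`).
#' @slot sigmaSdLog log-scale SD of per-gene sigma under the log-normal
#'   over-dispersion model.
#' @slot deFraction fraction of genes with a true expression difference
#'   in the last species.
#' @slot effectModel `"cohen"` (shift = `effectSize` times the null log2
#'   fold-change SD at the gene's depth) or `"fixed"` (shift =
#'   `effectSize` log2 units).
#' @slot effectSize effect magnitude (Cohen's D or log2 units).
#' @slot nSpecies,speciesNames,nBatches experiment layout; each species
#'   contributes one replicate per batch, and replicate index equals the
#'   batch index so same-day pairs are well defined.
#' @slot depthFactors per-sample library depth multipliers (recycled).
#'
#' @seealso [simulationSpec()], [simulateDataset()]
#' @export
setClass("SimulationSpec",
  representation(nGenes = "integer", meanLog = "numeric", sdLog = "numeric",
                 overdispersionModel = "character", U = "numeric",
                 sigmaSdLog = "numeric", deFraction = "numeric",
                 effectModel = "character", effectSize = "numeric",
                 nSpecies = "integer", speciesNames = "character",
                 nBatches = "integer", depthFactors = "numeric"))

setValidity("SimulationSpec", function(object) {
  if (object@nGenes < 1) return("nGenes must be positive")
  if (!object@overdispersionModel %in% c("uniform", "lognormal"))
    return("overdispersionModel must be 'uniform' or 'lognormal'")
  if (object@U < 0) return("U must be non-negative")
  if (object@deFraction < 0 || object@deFraction > 1)
    return("deFraction must lie in [0, 1]")
  if (!object@effectModel %in% c("cohen", "fixed"))
    return("effectModel must be 'cohen' or 'fixed'")
  if (object@nSpecies < 1 || object@nSpecies > length(object@speciesNames))
    return("nSpecies must be between 1 and length(speciesNames)")
  if (object@nBatches < 1) return("nBatches must be positive")
  if (any(object@depthFactors <= 0)) return("depthFactors must be positive")
  TRUE
})
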