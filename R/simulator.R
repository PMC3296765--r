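#' Construct a SimulationSpec
#'
#' Defaults describe the study conditions the framework targets: 10,000
#' genes whose expected counts are log-normal with meanlog 5 and sdlog
#' 1.5 (tens to tens of thousands of reads; over 95\\% of genes above
#' the 10-read floor), uniform relative non-Poisson SD 0.16 (the
#' technical resolution of a deeply sequenced yeast experiment), two
#' same-day batches of one replicate each per species, equal library
#' depths, and no true differential expression.
#'
#' @param nGenes,meanLog,sdLog gene count and log-normal mean
#'   parameters.
#' @param overdispersionModel `"uniform"` or `"lognormal"` (per-gene
#'   sigma drawn log-normally with median `U` and log-SD `sigmaSdLog`).
#' @param U,sigmaSdLog over-dispersion magnitude / spread.
#' @param deFraction,effectModel,effectSize differential-expression
#'   injection: fraction of genes shifted in the last species, with a
#'   multiplicative log2 shift of `effectSize` null SDs (Cohen's D,
#'   `effectModel = "cohen"`) or `effectSize` log2 units (`"fixed"`);
#'   shift signs are random.
#' @param nSpecies,speciesNames,nBatches experiment layout: each species
#'   contributes one biological replicate per batch, replicate index =
#'   batch index.
#' @param depthFactors per-sample depth multipliers, recycled over
#'   samples.
#' @return a [SimulationSpec-class].
#' @export
simulationSpec <- function(nGenes = 10000L, meanLog = 5, sdLog = 1.5,
                           overdispersionModel = c("uniform", "lognormal"),
                           U = 0.16, sigmaSdLog = 0.5, deFraction = 0,
                           effectModel = c("cohen", "fixed"),
                           effectSize = 2, nSpecies = 2L,
                           speciesNames = c("Scer", "Spar", "Smik", "Sbay"),
                           nBatches = 2L, depthFactors = 1) {
  new("SimulationSpec", nGenes = as.integer(nGenes), meanLog = meanLog,
      sdLog = sdLog, overdispersionModel = match.arg(overdispersionModel),
      U = U, sigmaSdLog = sigmaSdLog, deFraction = deFraction,
      effectModel = match.arg(effectModel), effectSize = effectSize,
      nSpecies = as.integer(nSpecies), speciesNames = speciesNames,
      nBatches = as.integer(nBatches), depthFactors = depthFactors)
}

setMethod("show", "SimulationSpec", function(object) {
  cat(sprintf(
    paste0("SimulationSpec: %d genes, means ~ LogNormal(%g, %g), ",
           "%s over-dispersion U = %g\n  %d species x %d batches; ",
           "DE fraction %g (%s effect %g)\n"),
    object@nGenes, object@meanLog, object@sdLog, object@overdispersionModel,
    object@U, object@nSpecies, object@nBatches, object@deFraction,
    object@effectModel, object@effectSize))
})

#' Identity-style ortholog map for simulated data
#'
#' Builds the [OrthologSet-class] linking the simulated reference gene
#' ids to the species-local ids used in the other species' count tables
#' (`<species>.<gene>`), 1:1 everywhere.
#'
#' @param genes reference gene ids.
#' @param species all species of the experiment (first = reference).
#' @return an [OrthologSet-class].
#' @export
identityOrthologs <- function(genes, species) {
  ref <- species[1]; others <- species[-1]
  entries <- lapply(genes, function(g) {
    e <- lapply(others, function(sp) paste(sp, g, sep = "."))
    names(e) <- others
    e
  })
  names(entries) <- genes
  OrthologSet(entries, ref)
}

#' Simulate a cross-species RNA-Seq count dataset
#'
#' Generative model per gene `g`: an expected count `mu_g` is drawn
#' log-normally; a relative non-Poisson SD `sigma_g` is set by the
#' over-dispersion model; per sample, a latent multiplicative expression
#' factor `e` is drawn log-normally with mean 1 and relative SD
#' `sigma_g` (environmental plus technical noise acts multiplicatively),
#' and the observed count is `Poisson(mu_g * e * depth)`. A `deFraction`
#' of genes receives a true multiplicative shift of the requested effect
#' size in the last species (Cohen's D effects are `effectSize` times
#' the null log2 fold-change SD at the gene's depth,
#' `sqrt(2 (1/mu + sigma^2)) / ln 2`). With `deFraction = 0` the model
#' satisfies the test's null exactly. Identical seed and spec give
#' bitwise-identical output.
#'
#' @param spec a [SimulationSpec-class].
#' @param seed integer seed controlling all randomness.
#' @return list with components `counts` (a [CountSet-class]),
#'   `orthologs` (an [OrthologSet-class]), and `truth` (data.frame with
#'   `gene_id`, `mu`, `true_sigma`, `true_log2_fc`, `is_de`).
#' @export
simulateDataset <- function(spec, seed = 1L) {
  stopifnot(is(spec, "SimulationSpec"))
  set.seed(as.integer(seed))
  n <- spec@nGenes
  genes <- sprintf("g%05d", seq_len(n))
  mu <- rlnorm(n, spec@meanLog, spec@sdLog)
  sigma <- switch(spec@overdispersionModel,
    uniform = rep(spec@U, n),
    lognormal = rlnorm(n, log(spec@U), spec@sigmaSdLog))
  species <- spec@speciesNames[seq_len(spec@nSpecies)]
  ## true DE: multiplicative shift in the last species
  shift <- numeric(n)
  if (spec@deFraction > 0 && spec@nSpecies >= 2) {
    nDE <- round(spec@deFraction * n)
    deIdx <- sample.int(n, nDE)
    sdNull <- sqrt(2 * (1 / mu[deIdx] + sigma[deIdx]^2)) / log(2)
    mag <- switch(spec@effectModel,
                  cohen = spec@effectSize * sdNull,
                  fixed = rep(spec@effectSize, length(deIdx)))
    shift[deIdx] <- mag * sample(c(-1, 1), length(deIdx), replace = TRUE)
  }
  nSamples <- length(species) * spec@nBatches
  depth <- rep_len(spec@depthFactors, nSamples)
  lnSd <- sqrt(log(1 + sigma^2))
  countsList <- list(); meta <- NULL
  si <- 0L
  for (sp in species) {
    gid <- if (sp == species[1]) genes else paste(sp, genes, sep = ".")
    muSp <- if (sp == species[length(species)]) mu * 2^shift else mu
    for (k in seq_len(spec@nBatches)) {
      si <- si + 1L
      e <- rlnorm(n, -lnSd^2 / 2, lnSd)
      ct <- rpois(n, muSp * e * depth[si])
      id <- sprintf("%s_r%d", sp, k)
      countsList[[id]] <- setNames(as.integer(ct), gid)
      meta <- rbind(meta, data.frame(sample_id = id, species = sp,
                                     replicate = k, batch = sprintf("d%d", k),
                                     kind = "biological"))
    }
  }
  cs <- CountSet(countsList, species = meta$species,
                 replicate = meta$replicate, batch = meta$batch,
                 kind = meta$kind, sampleId = meta$sample_id)
  truth <- data.frame(gene_id = genes, mu = mu, true_sigma = sigma,
                      true_log2_fc = shift, is_de = shift != 0)
  list(counts = cs, orthologs = identityOrthologs(genes, species),
       truth = truth)
}

#' Simulate a single replicate pair
#'
#' Convenience for calibration studies: two replicate count vectors of
#' one condition (no true differences), drawn under the same generative
#' model as [simulateDataset()].
#'
#' @param nGenes,meanLog,sdLog,U as in [simulationSpec()].
#' @param seed integer seed.
#' @return list with named count vectors `rep1`, `rep2` and the
#'   per-gene `mu`.
#' @export
simulateReplicatePair <- function(nGenes = 10000L, meanLog = 5, sdLog = 1.5,
                                  U = 0.16, seed = 1L) {
  spec <- simulationSpec(nGenes = nGenes, meanLog = meanLog, sdLog = sdLog,
                         U = U, nSpecies = 1L, nBatches = 2L)
  sim <- simulateDataset(spec, seed = seed)
  ids <- sampleData(sim$counts)$sample_id
  list(rep1 = counts(sim$counts, ids[1]), rep2 = counts(sim$counts, ids[2]),
       mu = setNames(sim$truth$mu, sim$truth$gene_id))
}

#' Evaluate false-positive rate and power of a DE caller
#'
#' @param res a [DEResults-class] (or data.frame with `gene_id` and
#'   `p_combined`).
#' @param truth truth table from [simulateDataset()].
#' @param alpha call level.
#' @return list with `fpr` (false calls among true-null genes), `power`
#'   (true calls among true-DE genes, `NA` when none were injected),
#'   and `byVarianceQuantile`: the false-positive rate within quartile
#'   strata of the true sigma among null genes.
#' @export
evaluateFprPower <- function(res, truth, alpha = 0.05) {
  df <- as.data.frame(res)
  i <- match(df$gene_id, truth$gene_id)
  call <- df$p_combined < alpha
  null <- !truth$is_de[i]
  fpr <- mean(call[null], na.rm = TRUE)
  power <- if (any(!null)) mean(call[!null], na.rm = TRUE) else NA_real_
  sig <- truth$true_sigma[i][null]
  brk <- unique(quantile(sig, probs = seq(0, 1, 0.25)))
  if (length(brk) > 2) {
    qs <- cut(sig, breaks = brk, include.lowest = TRUE,
              labels = paste0("Q", seq_len(length(brk) - 1)))
  } else {
    qs <- factor(rep("Q1", length(sig)))   # constant-sigma generators
  }
  strat <- tapply(call[null], qs, mean, na.rm = TRUE)
  list(fpr = fpr, power = power,
       byVarianceQuantile = data.frame(quantile = names(strat),
                                       fpr = as.numeric(strat)))
}

#' Evaluate coverage of the 2-sigma fold-change intervals
#'
#' @param res a [DEResults-class] or data.frame with columns `gene_id`,
#'   `fc_ci_low`, `fc_ci_high` on the log2 scale.
#' @param truth truth table with `gene_id` and `true_log2_fc`.
#' @return list with `coverage` (fraction of defined intervals
#'   containing the true log2 fold change), `nDefined`, and `nNA`
#'   (genes whose interval is undefined, excluded but counted).
#' @export
evaluateCICoverage <- function(res, truth) {
  df <- as.data.frame(res)
  i <- match(df$gene_id, truth$gene_id)
  tl <- truth$true_log2_fc[i]
  ok <- !is.na(df$fc_ci_low) & !is.na(df$fc_ci_high)
  hit <- tl[ok] >= df$fc_ci_low[ok] & tl[ok] <= df$fc_ci_high[ok]
  list(coverage = mean(hit), nDefined = sum(ok), nNA = sum(!ok))
}
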