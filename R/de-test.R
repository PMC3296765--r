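#' Over-dispersed two-by-one chi-square statistic
#'
#' Tests whether the control and test counts of a gene were drawn from a
#' common distribution whose per-sample means lie on the normalization
#' slope line ([distributionMeans()]). Each squared deviation is divided
#' by the total variance of its sample, composed as Poisson variance
#' plus the squared relative non-Poisson SD times the mean:
#' `sigma^2(mu) = mu + (sigma_nP * mu)^2`. Because the common means are
#' estimated from the same two observations, the statistic follows a
#' chi-square distribution with one (not two) degree of freedom under
#' the null.
#'
#' @param C,T observed counts (vectorized).
#' @param m positive normalization slope (test over control).
#' @param sigmaC,sigmaT relative non-Poisson SDs for the control and
#'   test sides (after flooring / pooling / species rescaling).
#' @return non-negative statistic(s); genes with both means zero return
#'   0 by convention.
#' @seealso [pValue()], [callDE()]
#' @export
chi2Statistic <- function(C, T, m, sigmaC, sigmaT) {
  if (any(C < 0, na.rm = TRUE) || any(T < 0, na.rm = TRUE))
    stop("counts must be non-negative")
  if (any(sigmaC < 0, na.rm = TRUE) || any(sigmaT < 0, na.rm = TRUE))
    stop("relative SDs must be non-negative")
  mu <- distributionMeans(C, T, m)
  vC <- mu$mu_C + (sigmaC * mu$mu_C)^2
  vT <- mu$mu_T + (sigmaT * mu$mu_T)^2
  x2 <- (C - mu$mu_C)^2 / vC + (T - mu$mu_T)^2 / vT
  x2[mu$mu_C == 0 & mu$mu_T == 0] <- 0
  x2
}

#' Upper-tail chi-square p-value
#'
#' @param chi2 non-negative statistic(s).
#' @param df degrees of freedom; 1 for the two-by-one test (one degree
#'   is lost to estimating the common means from both samples).
#' @return p-value(s) in (0, 1].
#' @export
pValue <- function(chi2, df = 1) {
  if (any(chi2 < 0, na.rm = TRUE)) stop("chi2 must be non-negative")
  pchisq(chi2, df = df, lower.tail = FALSE)
}

#' Fisher's combined probability across same-day batches
#'
#' Independent per-batch p-values (replicate i of one species versus
#' replicate i of the other, grown the same day) are combined as
#' `X = -2 sum(log p_i)`, referred to a chi-square distribution with
#' `2k` degrees of freedom.
#'
#' @param pValues numeric vector of p-values in (0, 1].
#' @return combined p-value in (0, 1].
#' @export
combineBatches <- function(pValues) {
  pValues <- pValues[!is.na(pValues)]
  if (!length(pValues)) return(NA_real_)
  if (any(pValues <= 0) || any(pValues > 1))
    stop("p-values must lie in (0, 1]")
  X <- -2 * sum(log(pValues))
  pchisq(X, df = 2 * length(pValues), lower.tail = FALSE)
}

#' Log2 fold change with error-propagated confidence interval
#'
#' The fold change is the ratio of size-normalized counts,
#' `T_n / C_n`. Its uncertainty on the log2 scale propagates the total
#' SD of each side (`sigma_X^2 = X + (sigma_nP X)^2`):
#' `sigma_FC = sqrt((sigma_T / (T_n ln 2))^2 + (sigma_C / (C_n ln 2))^2)`,
#' and the 2-sigma (~95\\%) interval is `log2 FC +/- 2 sigma_FC`. Genes
#' with a zero count on either side have no defined fold change and
#' return `NA` throughout.
#'
#' @param Cn,Tn size-normalized counts (vectorized).
#' @param sigmaC,sigmaT relative non-Poisson SDs of the two sides.
#' @return data.frame with columns `log2_fc`, `sigma_fc`, `fc_ci_low`,
#'   `fc_ci_high` (log2-scale bounds).
#' @export
foldChangeCI <- function(Cn, Tn, sigmaC, sigmaT) {
  n <- max(length(Cn), length(Tn))
  Cn <- rep_len(Cn, n); Tn <- rep_len(Tn, n)
  sigmaC <- rep_len(sigmaC, n); sigmaT <- rep_len(sigmaT, n)
  ok <- !is.na(Cn) & !is.na(Tn) & Cn > 0 & Tn > 0
  l2 <- sfc <- rep(NA_real_, n)
  l2[ok] <- log2(Tn[ok] / Cn[ok])
  sT <- sqrt(Tn[ok] + (sigmaT[ok] * Tn[ok])^2)
  sC <- sqrt(Cn[ok] + (sigmaC[ok] * Cn[ok])^2)
  sfc[ok] <- sqrt((sT / (Tn[ok] * log(2)))^2 + (sC / (Cn[ok] * log(2)))^2)
  data.frame(log2_fc = l2, sigma_fc = sfc,
             fc_ci_low = l2 - 2 * sfc, fc_ci_high = l2 + 2 * sfc)
}

batchPairs <- function(x, comparison) {
  sd <- sampleData(x)
  a <- sd[sd$species == comparison[1] & sd$kind == "biological", , drop = FALSE]
  b <- sd[sd$species == comparison[2] & sd$kind == "biological", , drop = FALSE]
  batches <- intersect(a$batch, b$batch)
  if (!length(batches))
    stop(sprintf("no same-day batch pairs between '%s' and '%s'",
                 comparison[1], comparison[2]))
  lapply(sort(batches), function(bt) {
    ia <- a$sample_id[a$batch == bt][1]
    ib <- b$sample_id[b$batch == bt][1]
    list(batch = bt, control = ia, test = ib)
  })
}

#' Call differentially expressed genes between two species
#'
#' For each measurable gene the test is run once per same-day batch
#' (replicate i of the control species versus replicate i of the test
#' species): counts are translated through the ortholog map, a
#' median-ratio slope is fit over the slope gene set, the over-dispersed
#' chi-square statistic is computed with the model's per-gene relative
#' SDs, and the per-batch p-values are combined with Fisher's method.
#' The log2 fold change and its 2-sigma interval come from one batch
#' (`fcBatch`, default the first), with counts rescaled to the geometric
#' mean of that pair's library sizes. Genes with zero counts in both
#' samples of a batch contribute a statistic of 0 (p = 1) and an `NA`
#' fold change.
#'
#' @param x a [CountSet-class] containing both species.
#' @param orthologs an [OrthologSet-class].
#' @param model a [VarianceModel-class] covering both species.
#' @param comparison length-2 character vector `c(control, test)`.
#' @param genes reference gene ids to test; default: the core set if
#'   flagged on `orthologs`, otherwise every reference gene that is 1:1
#'   in both species. Genes without a 1:1 ortholog in either species are
#'   dropped.
#' @param alpha DE-call level on the combined p-value, default 0.01.
#' @param minReads genes whose mean count in any batch falls below this
#'   are still tested but flagged `low_count`, default 10.
#' @param fcBatch index of the batch whose counts give the reported fold
#'   change, default 1.
#' @param slopeGenes gene set for the normalization slope; default: the
#'   tested genes.
#' @return a [DEResults-class], one row per tested gene.
#' @export
callDE <- function(x, orthologs, model, comparison, genes = NULL,
                   alpha = 0.01, minReads = 10, fcBatch = 1L,
                   slopeGenes = NULL) {
  stopifnot(length(comparison) == 2)
  if (is.null(genes)) {
    genes <- coreGenes(orthologs)
    if (!length(genes)) {
      genes <- referenceGenes(orthologs)
    }
  }
  oidC <- orthologId(orthologs, genes, comparison[1])
  oidT <- orthologId(orthologs, genes, comparison[2])
  keep <- !is.na(oidC) & !is.na(oidT)
  genes <- genes[keep]; oidC <- oidC[keep]; oidT <- oidT[keep]
  if (!length(genes)) stop("no genes are 1:1 in both species")
  if (is.null(slopeGenes)) slopeGenes <- genes
  pairs <- batchPairs(x, comparison)
  if (fcBatch > length(pairs)) fcBatch <- 1L
  sigC <- unname(sigmaFor(model, genes, comparison[1]))
  sigT <- unname(sigmaFor(model, genes, comparison[2]))

  res <- DataFrame(gene_id = genes,
                   comparison = paste(comparison, collapse = "_vs_"))
  slopes <- numeric(length(pairs))
  pMat <- matrix(NA_real_, length(genes), length(pairs))
  lowCount <- rep(FALSE, length(genes))
  fc <- NULL
  for (k in seq_along(pairs)) {
    pr <- pairs[[k]]
    cC <- counts(x, pr$control); cT <- counts(x, pr$test)
    vC <- unname(cC[oidC]); vC[is.na(vC)] <- 0
    vT <- unname(cT[oidT]); vT[is.na(vT)] <- 0
    sg <- intersect(slopeGenes, genes)
    m <- medianRatioSlope(setNames(vC, genes), setNames(vT, genes),
                          genes = sg)
    slopes[k] <- m
    x2 <- chi2Statistic(vC, vT, m, sigC, sigT)
    pMat[, k] <- pValue(x2)
    lowCount <- lowCount | ((vC + vT) / 2 < minReads)
    res[[paste0("count_", pr$control)]] <- as.integer(vC)
    res[[paste0("count_", pr$test)]] <- as.integer(vT)
    res[[paste0("chi2_rep", k)]] <- x2
    res[[paste0("p_rep", k)]] <- pMat[, k]
    if (k == fcBatch) {
      tot <- sqrt(sum(as.numeric(cC)) * sum(as.numeric(cT)))
      Cn <- sizeNormalizedCount(vC, sum(as.numeric(cC)), tot)
      Tn <- sizeNormalizedCount(vT, sum(as.numeric(cT)), tot)
      fc <- foldChangeCI(Cn, Tn, sigC, sigT)
    }
  }
  res$p_combined <- apply(pMat, 1L, combineBatches)
  res$log2_fc <- fc$log2_fc
  res$sigma_fc <- fc$sigma_fc
  res$fc_ci_low <- fc$fc_ci_low
  res$fc_ci_high <- fc$fc_ci_high
  res$is_de <- res$p_combined < alpha
  res$low_count <- lowCount
  out <- new("DEResults", res)
  metadata(out) <- list(comparison = comparison, alpha = alpha,
                        slopes = slopes, minReads = minReads,
                        batches = vapply(pairs, `[[`, character(1), "batch"),
                        fcBatch = fcBatch)
  out
}

setMethod("show", "DEResults", function(object) {
  md <- metadata(object)
  if (!is.null(md$comparison))
    cat(sprintf("DEResults: %s vs %s, %d genes, %d DE at alpha = %g\n",
                md$comparison[1], md$comparison[2], nrow(object),
                sum(object$is_de, na.rm = TRUE),
                if (is.null(md$alpha)) NA else md$alpha))
  callNextMethod()
})

#' Replicate-based false discovery rate estimate
#'
#' With the DE fraction observed in replicate self-comparisons at the
#' same level serving as the per-gene false-positive rate, the expected
#' number of false discoveries among `nTested` genes is
#' `replicateDEFraction * nTested`, and the FDR is that count divided by
#' the number of genes actually called DE.
#'
#' @param nTested number of genes tested.
#' @param nDE number of genes called DE.
#' @param replicateDEFraction DE fraction observed in biological
#'   replicates at the same alpha.
#' @return estimated FDR (NA when `nDE` is 0).
#' @export
estimateFDR <- function(nTested, nDE, replicateDEFraction) {
  if (nDE == 0) return(NA_real_)
  (replicateDEFraction * nTested) / nDE
}
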