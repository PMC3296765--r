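#' Median-ratio normalization slope between two samples
#'
#' The between-sample scaling factor `m` is the median over genes of the
#' ratio of test to control counts. The median makes the slope robust to
#' a small number of highly expressed outlier genes that can dominate
#' total-read-count normalization. Genes with a zero control count are
#' excluded (their ratio is undefined), as are genes absent from either
#' sample.
#'
#' @param control,test named count vectors (or unnamed vectors of equal
#'   length, matched positionally).
#' @param genes optional gene subset over which to take the median;
#'   typically the measurable 1:1 orthologs of the comparison.
#' @param minCount optional additional threshold: only genes with
#'   control count >= `minCount` enter the median (default 0, i.e. all
#'   genes with a defined ratio).
#' @return the slope `m` (positive scalar).
#' @examples
#' medianRatioSlope(c(a = 10, b = 20, c = 40), c(a = 10, b = 40, c = 160))
#' @export
medianRatioSlope <- function(control, test, genes = NULL, minCount = 0) {
  if (!is.null(names(control)) && !is.null(names(test))) {
    shared <- intersect(names(control), names(test))
    if (!is.null(genes)) shared <- intersect(shared, genes)
    control <- control[shared]; test <- test[shared]
  } else if (length(control) != length(test)) {
    stop("unnamed count vectors must have equal length")
  }
  ok <- control > 0 & control >= minCount & !is.na(control) & !is.na(test)
  if (!any(ok)) stop("no eligible genes for the median-ratio slope")
  m <- median(test[ok] / control[ok])
  if (m <= 0) stop("median ratio is not positive; degenerate samples")
  m
}

#' Midpoint-projected distribution means for one gene
#'
#' Given the observed counts (`C`, `T`) and the normalization slope `m`,
#' the common-distribution means for the control and test samples are
#' the midpoint of the segment of the slope line bounded by the two
#' projections of the observation, `(C, C m)` and `(T/m, T)`:
#' `mu_C = (C + T/m) / 2` and `mu_T = (C m + T) / 2 = m mu_C`. Both
#' samples are weighted evenly regardless of sequencing depth and no
#' count rescaling is required.
#'
#' @param C,T non-negative observed counts (vectorized).
#' @param m positive normalization slope.
#' @return list with numeric components `mu_C` and `mu_T`.
#' @examples
#' distributionMeans(100, 300, 2)   # mu_C = 125, mu_T = 250
#' @export
distributionMeans <- function(C, T, m) {
  if (!is.numeric(m) || length(m) != 1L || m <= 0)
    stop("normalization slope m must be a single positive number")
  if (any(C < 0, na.rm = TRUE) || any(T < 0, na.rm = TRUE))
    stop("counts must be non-negative")
  muC <- (C + T / m) / 2
  list(mu_C = muC, mu_T = m * muC)
}

#' Rescale a count to a common library size
#'
#' Linear rescaling `count * referenceTotal / sampleTotal`, used to put
#' the two sides of a fold change on a common scale. Fold changes are
#' invariant to the choice of `referenceTotal`; the geometric mean of
#' the two library sizes is a convenient symmetric default (see
#' [foldChangeCI()] callers).
#'
#' @param count non-negative count(s).
#' @param sampleTotal library size of the sample the count came from
#'   (positive).
#' @param referenceTotal common reference library size (positive).
#' @return rescaled count (numeric).
#' @export
sizeNormalizedCount <- function(count, sampleTotal, referenceTotal) {
  if (any(sampleTotal <= 0)) stop("sampleTotal must be positive")
  if (any(referenceTotal <= 0)) stop("referenceTotal must be positive")
  count * referenceTotal / sampleTotal
}
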