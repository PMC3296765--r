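annLookup <- function(annotations, genes, species) {
  sel <- annotations$species == species
  idx <- match(genes, annotations$gene_id[sel])
  annotations[which(sel)[idx], , drop = FALSE]
}

#' Measurability of a gene as a 1:1 ortholog in one species
#'
#' A gene is measurable in species `s` when all inclusion criteria hold:
#' it is annotated in the reference species; for a non-reference species
#' it has exactly one annotated ortholog; that annotation is a complete
#' ORF (not running into an unfinished part of a draft genome); its
#' annotated length is within 90\\% to 110\\% of the reference length
#' (closed interval); at least 90\\% of the gene's aligned reads align
#' uniquely; and the gene is protein coding (non-coding genes reproduce
#' poorly and are excluded).
#'
#' @param genes character vector of reference gene ids.
#' @param species species to assess (may be the reference itself, in
#'   which case the 1:1 and length-ratio criteria hold trivially).
#' @param orthologs an [OrthologSet-class].
#' @param annotations data.frame as returned by [readAnnotations()],
#'   covering all species including the reference.
#' @return named logical vector over `genes`.
#' @seealso [coreGeneSet()]
#' @export
measurableOrtholog <- function(genes, species, orthologs, annotations) {
  ref <- referenceSpecies(orthologs)
  refAnn <- annLookup(annotations, genes, ref)
  ok <- !is.na(refAnn$gene_id)            # annotated in the reference
  if (species == ref) {
    spAnn <- refAnn
    hasOne <- ok
  } else {
    oid <- orthologId(orthologs, genes, species)
    hasOne <- !is.na(oid)
    spAnn <- annLookup(annotations, oid, species)
    mapped <- hasOne & is.na(spAnn$gene_id)
    if (any(mapped, na.rm = TRUE))
      stop(sprintf("ortholog(s) of %s lack a %s annotation (first: %s)",
                   genes[which(mapped)[1]], species, oid[which(mapped)[1]]))
  }
  lenRatio <- spAnn$annotated_length / refAnn$annotated_length
  crit <- ok & hasOne &
    !is.na(spAnn$complete_orf) & spAnn$complete_orf &
    !is.na(lenRatio) & lenRatio >= 0.90 & lenRatio <= 1.10 &
    !is.na(spAnn$unique_fraction) & spAnn$unique_fraction >= 0.90 &
    !is.na(spAnn$biotype) & spAnn$biotype == "coding"
  setNames(as.logical(crit) & !is.na(crit), genes)
}

#' Core gene set: measurable 1:1 orthologs in every species
#'
#' Returns the genes for which [measurableOrtholog()] is `TRUE` in every
#' listed species. Core genes are the common currency of cross-species
#' comparisons: adding a species can only shrink the set.
#'
#' @param orthologs an [OrthologSet-class].
#' @param annotations annotation data.frame covering every species.
#' @param species species to require; default: the reference plus every
#'   mapped species.
#' @return character vector of core reference gene ids. Use
#'   [setCoreGenes()] to record it on the `OrthologSet`.
#' @export
coreGeneSet <- function(orthologs, annotations,
                        species = c(referenceSpecies(orthologs),
                                    orthologSpecies(orthologs))) {
  if (length(species) < 2)
    stop("core genes are defined over at least two species")
  genes <- referenceGenes(orthologs)
  keep <- rep(TRUE, length(genes))
  for (sp in species)
    keep <- keep & measurableOrtholog(genes, sp, orthologs, annotations)
  genes[keep]
}

#' Stringent duplication candidates
#'
#' Among reference genes with exactly two orthologs in `species`, retain
#' the pairs where both copies cover more than 60\\% of the reference
#' gene and both satisfy a (pluggable) measurability predicate, by
#' default the unique-alignment criterion (unique fraction >= 0.90 in
#' the annotation table).
#'
#' @param orthologs an [OrthologSet-class].
#' @param species species in which the duplication occurred.
#' @param coverage data.frame with columns `reference_gene`, `paralog`,
#'   `coverage` (fraction of the reference gene covered, in \[0, 1\]).
#' @param annotations annotation data.frame (used by the default
#'   predicate).
#' @param measurable predicate `function(paralogIds) -> logical`;
#'   default checks `unique_fraction >= 0.90` in `annotations`.
#' @param minCoverage retention threshold; both copies must exceed it
#'   (strict), default 0.60.
#' @return data.frame with columns `reference_gene`, `copy1`, `copy2`.
#' @export
duplicationCandidates <- function(orthologs, species, coverage,
                                  annotations = NULL,
                                  measurable = NULL,
                                  minCoverage = 0.60) {
  if (is.null(measurable)) {
    measurable <- function(ids) {
      if (is.null(annotations)) return(rep(TRUE, length(ids)))
      ann <- annLookup(annotations, ids, species)
      !is.na(ann$unique_fraction) & ann$unique_fraction >= 0.90
    }
  }
  genes <- referenceGenes(orthologs)
  lst <- orthologIds(orthologs, genes, species)
  two <- genes[lengths(lst) == 2L]
  keep <- vapply(two, function(g) {
    pr <- lst[[g]]
    cv <- vapply(pr, function(p) {
      i <- which(coverage$reference_gene == g & coverage$paralog == p)
      if (length(i)) coverage$coverage[i[1]] else NA_real_
    }, numeric(1))
    all(!is.na(cv)) && all(cv > minCoverage) && all(measurable(pr))
  }, logical(1))
  ret <- two[keep]
  data.frame(reference_gene = ret,
             copy1 = vapply(lst[ret], `[`, character(1), 1L),
             copy2 = vapply(lst[ret], `[`, character(1), 2L),
             row.names = NULL, stringsAsFactors = FALSE)
}
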