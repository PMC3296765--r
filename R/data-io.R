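#' Construct a CountSet
#'
#' @param counts named list of named non-negative integer vectors, one
#'   per sample (names are gene ids of that sample's species).
#' @param species,replicate,batch character/integer vectors parallel to
#'   `counts` giving each sample's species, replicate index and
#'   growth-batch label.
#' @param kind `"biological"` (default) or `"technical"`, recycled.
#' @param sampleId sample identifiers; default `names(counts)`.
#'
#' @return a [CountSet-class] object.
#' @examples
#' cs <- CountSet(list(s1 = c(g1 = 10L, g2 = 0L), s2 = c(g1 = 12L, g2 = 1L)),
#'                species = "Scer", replicate = 1:2, batch = c("d1", "d2"))
#' totalCounts(cs)
#' @export
CountSet <- function(counts, species, replicate, batch,
                     kind = "biological", sampleId = names(counts)) {
  if (is.null(sampleId))
    sampleId <- paste0("sample", seq_along(counts))
  n <- length(counts)
  sd <- DataFrame(sample_id = as.character(sampleId),
                  species = rep_len(as.character(species), n),
                  replicate = rep_len(as.integer(replicate), n),
                  batch = rep_len(as.character(batch), n),
                  kind = rep_len(as.character(kind), n))
  rownames(sd) <- sd$sample_id
  counts <- lapply(counts, function(ct) {
    storage.mode(ct) <- "integer"
    ct
  })
  names(counts) <- sd$sample_id
  new("CountSet", counts = counts, sampleData = sd)
}

#' Accessors for CountSet objects
#'
#' `counts()` returns the list of per-sample count vectors (or a single
#' vector when `sample` is given); `sampleData()` the sample metadata;
#' `totalCounts()` the per-sample library sizes (sums of counts, always
#' recomputed from the stored counts); `samplesFor()` the sample ids
#' matching a species / batch / kind filter.
#'
#' @param object,x a [CountSet-class].
#' @param sample optional single sample id or index.
#' @param species,batch,kind optional filters for `samplesFor()`.
#' @param ... unused.
#' @name CountSet-accessors
NULL

#' @rdname CountSet-accessors
#' @export
setMethod("counts", "CountSet", function(object, sample = NULL, ...) {
  if (is.null(sample)) object@counts else object@counts[[sample]]
})

#' @rdname CountSet-accessors
#' @export
setMethod("sampleData", "CountSet", function(x, ...) x@sampleData)

#' @rdname CountSet-accessors
#' @export
setMethod("totalCounts", "CountSet", function(x, ...) {
  vapply(x@counts, function(ct) sum(as.numeric(ct)), numeric(1))
})

#' @rdname CountSet-accessors
#' @export
samplesFor <- function(x, species = NULL, batch = NULL, kind = NULL) {
  sd <- sampleData(x)
  keep <- rep(TRUE, nrow(sd))
  if (!is.null(species)) keep <- keep & sd$species %in% species
  if (!is.null(batch))   keep <- keep & sd$batch %in% batch
  if (!is.null(kind))    keep <- keep & sd$kind %in% kind
  sd$sample_id[keep]
}

#' @rdname CountSet-accessors
#' @export
setMethod("[", "CountSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@sampleData$sample_id)
  new("CountSet", counts = x@counts[i],
      sampleData = x@sampleData[i, , drop = FALSE])
})

setMethod("show", "CountSet", function(object) {
  sd <- object@sampleData
  cat(sprintf("CountSet with %d sample(s), %d species\n",
              nrow(sd), length(unique(sd$species))))
  ng <- vapply(object@counts, length, integer(1))
  tc <- totalCounts(object)
  for (i in seq_len(nrow(sd)))
    cat(sprintf("  %s: %s rep %d batch %s (%s), %d genes, %s reads\n",
                sd$sample_id[i], sd$species[i], sd$replicate[i], sd$batch[i],
                sd$kind[i], ng[i], format(tc[i], big.mark = ",")))
})

#' Read a two-column count table
#'
#' Reads a headerless two-column TSV (`gene_id`, `count`) of unique-read
#' counts for one sample. Counts must parse as non-negative integers and
#' gene ids must be unique; violations raise an error naming the
#' offending line.
#'
#' @param path file path.
#' @return named integer vector of counts (possibly length 0 for an
#'   empty file).
#' @seealso [writeCountTable()], [CountSet()]
#' @export
readCountTable <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(setNames(integer(0), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop(sprintf("malformed count table line %d in '%s': expected 2 fields",
                 bad[1], path))
  gene <- vapply(parts, `[`, character(1), 1L)
  val <- vapply(parts, `[`, character(1), 2L)
  cnt <- suppressWarnings(as.numeric(val))
  bad <- which(is.na(cnt) | cnt < 0 | cnt != round(cnt))
  if (length(bad))
    stop(sprintf("line %d in '%s': count '%s' is not a non-negative integer",
                 bad[1], path, val[bad[1]]))
  dup <- which(duplicated(gene))
  if (length(dup))
    stop(sprintf("duplicate gene id '%s' at line %d in '%s'",
                 gene[dup[1]], dup[1], path))
  setNames(as.integer(cnt), gene)
}

#' @rdname readCountTable
#' @param counts named integer vector as returned by [readCountTable()].
#' @export
writeCountTable <- function(counts, path) {
  writeLines(paste(names(counts), as.integer(counts), sep = "\t"), path)
  invisible(path)
}

#' Read a dataset manifest into a CountSet
#'
#' The manifest (JSON or YAML, by file extension) lists the samples of an
#' experiment: a top-level `samples` array whose elements have fields
#' `sample_id`, `species`, `replicate`, `batch`, `kind` and `path` (count
#' table TSV, relative to the manifest's directory unless absolute).
#'
#' @param path manifest file path.
#' @return a [CountSet-class].
#' @seealso [writeManifest()]
#' @export
readManifest <- function(path) {
  man <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(man$samples) || !length(man$samples))
    stop("manifest has no 'samples' entry")
  dir <- dirname(path)
  counts <- list(); meta <- list()
  for (s in man$samples) {
    need <- c("sample_id", "species", "replicate", "batch", "path")
    miss <- setdiff(need, names(s))
    if (length(miss))
      stop("manifest sample missing field(s): ", paste(miss, collapse = ", "))
    p <- s$path
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(dir, p)
    counts[[s$sample_id]] <- readCountTable(p)
    meta[[s$sample_id]] <- s
  }
  CountSet(counts,
           species = vapply(meta, `[[`, character(1), "species"),
           replicate = vapply(meta, function(m) as.integer(m$replicate),
                              integer(1)),
           batch = vapply(meta, function(m) as.character(m$batch),
                          character(1)),
           kind = vapply(meta, function(m)
             if (is.null(m$kind)) "biological" else m$kind, character(1)),
           sampleId = names(counts))
}

#' Write a CountSet as count tables plus a JSON manifest
#'
#' @param x a [CountSet-class].
#' @param dir output directory (created if needed).
#' @param name manifest file name.
#' @return path of the manifest, invisibly.
#' @export
writeManifest <- function(x, dir, name = "manifest.json") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sd <- as.data.frame(sampleData(x))
  sd$path <- paste0(sd$sample_id, ".counts.tsv")
  for (i in seq_len(nrow(sd)))
    writeCountTable(counts(x, sd$sample_id[i]), file.path(dir, sd$path[i]))
  man <- list(samples = lapply(seq_len(nrow(sd)), function(i) as.list(sd[i, ])))
  jsonlite::write_json(man, file.path(dir, name), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(file.path(dir, name))
}

#' Read an ortholog map
#'
#' The map is a TSV with a header line: the first column holds
#' reference-species gene ids and each remaining column is named for a
#' non-reference species and holds a comma-separated list of ortholog
#' ids in that species (empty = gene absent).
#'
#' @param path file path.
#' @param referenceSpecies name of the reference species whose gene ids
#'   key the map.
#' @param species optional character vector of expected species columns;
#'   an error is raised if the file's columns differ (guards against a
#'   misconfigured map).
#' @return an [OrthologSet-class] with core flags unset.
#' @export
readOrthologMap <- function(path, referenceSpecies, species = NULL) {
  tab <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                    check.names = FALSE)
  if (ncol(tab) < 2)
    stop("ortholog map needs a gene id column plus at least one species")
  spCols <- colnames(tab)[-1]
  if (referenceSpecies %in% spCols)
    stop(sprintf("reference species '%s' must not appear as a map column",
                 referenceSpecies))
  if (!is.null(species) && !setequal(spCols, species))
    stop(sprintf("unknown species column(s): map has [%s], expected [%s]",
                 paste(spCols, collapse = ", "),
                 paste(species, collapse = ", ")))
  gene <- tab[[1]]
  dup <- which(duplicated(gene))
  if (length(dup))
    stop(sprintf("duplicate reference gene id '%s' in ortholog map",
                 gene[dup[1]]))
  entries <- lapply(seq_along(gene), function(i) {
    e <- lapply(spCols, function(sp) {
      v <- tab[[sp]][i]
      if (is.na(v) || !nzchar(v)) character(0)
      else trimws(strsplit(v, ",", fixed = TRUE)[[1]])
    })
    names(e) <- spCols
    e
  })
  names(entries) <- gene
  OrthologSet(entries, referenceSpecies)
}

#' @rdname readOrthologMap
#' @param x an [OrthologSet-class] to serialize.
#' @export
writeOrthologMap <- function(x, path) {
  stopifnot(is(x, "OrthologSet"))
  sp <- orthologSpecies(x)
  lines <- c(paste(c("gene_id", sp), collapse = "\t"),
             vapply(referenceGenes(x), function(g) {
               cells <- vapply(sp, function(s)
                 paste(orthologIds(x, g, s)[[1]], collapse = ","),
                 character(1))
               paste(c(g, cells), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Construct an OrthologSet
#'
#' @param entries named list (reference gene id -> named list species ->
#'   character vector of ortholog ids).
#' @param referenceSpecies reference species name.
#' @return an [OrthologSet-class].
#' @export
OrthologSet <- function(entries, referenceSpecies) {
  sp <- if (length(entries)) names(entries[[1]]) else character(0)
  new("OrthologSet", referenceSpecies = referenceSpecies, species = sp,
      entries = entries,
      coreFlags = setNames(rep(NA, length(entries)), names(entries)))
}

#' Accessors for OrthologSet objects
#'
#' `referenceGenes()` returns the reference gene ids; `orthologSpecies()`
#' the non-reference species; `coreGenes()` the flagged core set;
#' `orthologId()` the 1:1 ortholog id of each gene in a species (`NA`
#' when the gene is absent or duplicated there, or the gene id itself
#' for the reference species); `setCoreGenes()` records the core set.
#'
#' @param x an [OrthologSet-class].
#' @param genes reference gene ids.
#' @param species a species name.
#' @param core character vector of core reference gene ids.
#' @param ... unused.
#' @name OrthologSet-accessors
NULL

#' @rdname OrthologSet-accessors
#' @export
setMethod("referenceSpecies", "OrthologSet", function(x, ...)
  x@referenceSpecies)

#' @rdname OrthologSet-accessors
#' @export
setMethod("referenceGenes", "OrthologSet", function(x, ...) names(x@entries))

#' @rdname OrthologSet-accessors
#' @export
setMethod("orthologSpecies", "OrthologSet", function(x, ...) x@species)

#' @rdname OrthologSet-accessors
#' @export
setMethod("coreGenes", "OrthologSet", function(x, ...) {
  names(x@coreFlags)[!is.na(x@coreFlags) & x@coreFlags]
})

#' @rdname OrthologSet-accessors
#' @export
setMethod("orthologId", "OrthologSet", function(x, genes, species, ...) {
  if (species == x@referenceSpecies)
    return(setNames(ifelse(genes %in% names(x@entries), genes, NA_character_),
                    genes))
  if (!species %in% x@species)
    stop(sprintf("species '%s' is not covered by this ortholog map", species))
  out <- vapply(genes, function(g) {
    e <- x@entries[[g]]
    if (is.null(e)) return(NA_character_)
    v <- e[[species]]
    if (length(v) == 1L) v else NA_character_
  }, character(1))
  setNames(out, genes)
})

#' @rdname OrthologSet-accessors
#' @export
orthologIds <- function(x, genes, species) {
  stopifnot(is(x, "OrthologSet"))
  if (species == x@referenceSpecies)
    return(setNames(as.list(genes), genes))
  setNames(lapply(genes, function(g) {
    e <- x@entries[[g]]
    if (is.null(e)) character(0) else e[[species]]
  }), genes)
}

#' @rdname OrthologSet-accessors
#' @export
setCoreGenes <- function(x, core) {
  stopifnot(is(x, "OrthologSet"))
  miss <- setdiff(core, names(x@entries))
  if (length(miss))
    stop("core genes absent from the map: ", paste(miss, collapse = ", "))
  x@coreFlags <- setNames(names(x@entries) %in% core, names(x@entries))
  x
}

setMethod("show", "OrthologSet", function(object) {
  nc <- sum(object@coreFlags, na.rm = TRUE)
  cat(sprintf("OrthologSet: %d reference (%s) genes x %d species [%s]; core: %s\n",
              length(object@entries), object@referenceSpecies,
              length(object@species), paste(object@species, collapse = ", "),
              if (all(is.na(object@coreFlags))) "unset" else nc))
})

#' Read per-gene annotation metadata
#'
#' TSV with header and columns `gene_id`, `species`, `annotated_length`,
#' `complete_orf` (TRUE/FALSE), `unique_fraction`, `biotype`
#' (coding/noncoding), one row per gene per species.
#'
#' @param path file path.
#' @return a data.frame.
#' @export
readAnnotations <- function(path) {
  ann <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", "species", "annotated_length", "complete_orf",
            "unique_fraction", "biotype")
  miss <- setdiff(need, colnames(ann))
  if (length(miss))
    stop("annotation table missing column(s): ", paste(miss, collapse = ", "))
  ann$complete_orf <- as.logical(ann$complete_orf)
  if (any(ann$unique_fraction < 0 | ann$unique_fraction > 1, na.rm = TRUE))
    stop("unique_fraction must lie in [0, 1]")
  ann
}

fmtNum <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write and read differential-expression result tables
#'
#' `writeResults()` serializes a [DEResults-class] (or compatible
#' data.frame) as TSV with an `NA` sentinel for undefined numeric fields
#' (e.g. fold-change intervals of zero-count genes); numeric fields are
#' written with full double precision so that `readResults()` restores
#' them losslessly.
#'
#' @param results a [DEResults-class] or data.frame.
#' @param path output (input) file path.
#' @return `writeResults()` the path invisibly; `readResults()` a
#'   [DEResults-class].
#' @export
writeResults <- function(results, path) {
  df <- as.data.frame(results)
  if (!nrow(df)) stop("refusing to write an empty result table")
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- fmtNum(out[[j]])
  }
  con <- file(path, "w")
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname writeResults
#' @export
readResults <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = "NA", check.names = FALSE)
  intCols <- grep("^count_", colnames(df), value = TRUE)
  for (j in intCols) df[[j]] <- as.integer(df[[j]])
  if ("is_de" %in% colnames(df)) df$is_de <- as.logical(df$is_de)
  if ("low_count" %in% colnames(df)) df$low_count <- as.logical(df$low_count)
  res <- new("DEResults", DataFrame(df, check.names = FALSE))
  cmp <- unique(df$comparison)
  if (length(cmp) == 1L)
    metadata(res)$comparison <- strsplit(cmp, "_vs_", fixed = TRUE)[[1]]
  res
}
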