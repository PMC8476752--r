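#' Construct a SignatureCollection
#'
#' @param sets Named list of character vectors of gene symbols; names are
#'   cell-type labels. Symbols are whitespace-trimmed; duplicates within a set
#'   are collapsed.
#' @param sources Optional named list of provenance strings parallel to
#'   `sets`; defaults to empty strings.
#' @param uppercase If `TRUE`, gene symbols are uppercased — useful when
#'   matching signatures across platforms whose symbol case differs. Symbols
#'   are otherwise compared case-sensitively.
#' @return A [SignatureCollection].
#' @examples
#' sc <- SignatureCollection(list(Bcell = c("CD19", "MS4A1"), NK = "NKG7"))
#' cellTypes(sc)
#' @export
SignatureCollection <- function(sets, sources = NULL, uppercase = FALSE) {
  if (!is.list(sets)) stop("'sets' must be a named list of character vectors")
  sets <- lapply(sets, function(g) {
    g <- trimws(as.character(g))
    g <- g[nzchar(g)]
    if (uppercase) g <- toupper(g)
    unique(g)
  })
  if (is.null(sources)) {
    sources <- lapply(sets, function(g) "")
    names(sources) <- names(sets)
  } else {
    sources <- lapply(sources, as.character)
  }
  new("SignatureCollection", sets = sets, sources = sources)
}

#' Read a GMT gene-set file
#'
#' Parses the Broad GMT format: one gene set per line,
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. The description field is
#' kept as the set's provenance; duplicate gene symbols within a line are
#' collapsed.
#'
#' @param path Path to a GMT file (UTF-8, LF newlines).
#' @inheritParams SignatureCollection
#' @return A [SignatureCollection] with sets in file order.
#' @export
readGMT <- function(path, uppercase = FALSE) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); sources <- list()
  for (k in seq_along(lines)) {
    fields <- strsplit(lines[[k]], "\t", fixed = TRUE)[[1]]
    fields <- trimws(fields)
    if (length(fields) < 3L) {
      stop(sprintf("malformed GMT line %d: expected >= 3 tab-separated fields, got %d",
                   k, length(fields)))
    }
    nm <- fields[1]
    if (!nzchar(nm)) stop(sprintf("malformed GMT line %d: empty set name", k))
    if (nm %in% names(sets)) stop(sprintf("duplicate gene-set name '%s' at line %d", nm, k))
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) stop(sprintf("malformed GMT line %d: no genes", k))
    sets[[nm]] <- genes
    sources[[nm]] <- fields[2]
  }
  SignatureCollection(sets, sources, uppercase = uppercase)
}

#' Write a SignatureCollection to a GMT file
#'
#' Genes are written in lexicographic order so output is deterministic;
#' membership round-trips exactly through [readGMT()].
#'
#' @param collection A [SignatureCollection].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeGMT <- function(collection, path) {
  stopifnot(is(collection, "SignatureCollection"))
  validObject(collection)
  lines <- vapply(seq_along(collection@sets), function(i) {
    src <- paste(collection@sources[[i]], collapse = "; ")
    if (!nzchar(src)) src <- "na"
    paste(c(names(collection@sets)[i], src,
            sort(collection@sets[[i]], method = "radix")), collapse = "\t")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Merge signature collections by cell type
#'
#' Gene sets that share a cell-type label — within or across collections — are
#' unioned and their provenance strings concatenated, mirroring the curation
#' step of integrating marker lists for the same immune cell type from
#' different literature sources. Output order is first-appearance order.
#'
#' @param collections A list of [SignatureCollection] objects (length >= 1).
#' @return A single merged [SignatureCollection] with unique cell-type labels.
#' @export
mergeByCellType <- function(collections) {
  if (is(collections, "SignatureCollection")) collections <- list(collections)
  if (!is.list(collections) || length(collections) == 0L) {
    stop("'collections' must be a non-empty list of SignatureCollection objects")
  }
  sets <- list(); sources <- list()
  for (sc in collections) {
    stopifnot(is(sc, "SignatureCollection"))
    for (i in seq_along(sc@sets)) {
      nm <- names(sc@sets)[i]
      if (is.null(sets[[nm]])) {
        sets[[nm]] <- sc@sets[[i]]
        sources[[nm]] <- sc@sources[[i]]
      } else {
        sets[[nm]] <- union(sets[[nm]], sc@sets[[i]])
        sources[[nm]] <- unique(c(sources[[nm]], sc@sources[[i]]))
      }
    }
  }
  SignatureCollection(sets, sources)
}

#' Restrict a collection to a gene universe
#'
#' Intersects every gene set with the genes measured on a platform and drops
#' sets whose retained fraction falls below `min_coverage`. Signature genes
#' absent from an expression matrix must be removed before enrichment
#' scoring; sets losing most of their members are no longer the signature
#' that was curated, so they are dropped (with a message per drop).
#'
#' @param collection A [SignatureCollection].
#' @param gene_universe Character vector of measured gene identifiers.
#' @param min_coverage Minimum fraction of a set's genes that must be present
#'   for the set to be retained, in (0, 1]. Default 0.5.
#' @return The filtered [SignatureCollection].
#' @export
filterToUniverse <- function(collection, gene_universe, min_coverage = 0.5) {
  stopifnot(is(collection, "SignatureCollection"))
  if (!(min_coverage > 0 && min_coverage <= 1)) {
    stop("'min_coverage' must be in (0, 1]")
  }
  gene_universe <- unique(as.character(gene_universe))
  sets <- list(); sources <- list()
  for (i in seq_along(collection@sets)) {
    nm <- names(collection@sets)[i]
    g <- collection@sets[[i]]
    kept <- g[g %in% gene_universe]
    if (length(kept) / length(g) < min_coverage) {
      message(sprintf("filterToUniverse: dropping '%s' (%d/%d genes in universe)",
                      nm, length(kept), length(g)))
      next
    }
    sets[[nm]] <- kept
    sources[[nm]] <- collection@sources[[i]]
  }
  if (length(sets) == 0L) {
    stop("no gene set survived the universe filter; ",
         "check that expression gene identifiers match the signature symbols ",
         "(consider uppercase = TRUE when reading)")
  }
  SignatureCollection(sets, sources)
}
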