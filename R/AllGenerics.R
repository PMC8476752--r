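#' Accessors for package classes
#'
#' `geneSets()` returns the named list of marker gene sets of a
#' [SignatureCollection]; `geneSources()` the parallel provenance list;
#' `cellTypes()` the cell-type labels of a collection or the catalogue of an
#' [ICPModel]; `selectedPairs()` the pair table of an [ICPModel];
#' `icpScores()`, `icpCutoff()` and `icpGroups()` the components of an
#' [ICPResult].
#'
#' @param x An object of the documented class.
#' @return See each accessor's description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))
#' @rdname accessors
#' @export
setGeneric("geneSources", function(x) standardGeneric("geneSources"))
#' @rdname accessors
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))
#' @rdname accessors
#' @export
setGeneric("selectedPairs", function(x) standardGeneric("selectedPairs"))
#' @rdname accessors
#' @export
setGeneric("icpScores", function(x) standardGeneric("icpScores"))
#' @rdname accessors
#' @export
setGeneric("icpCutoff", function(x) standardGeneric("icpCutoff"))
#' @rdname accessors
#' @export
setGeneric("icpGroups", function(x) standardGeneric("icpGroups"))

#' @rdname accessors
#' @export
setMethod("geneSets", "SignatureCollection", function(x) x@sets)
#' @rdname accessors
#' @export
setMethod("geneSources", "SignatureCollection", function(x) x@sources)
#' @rdname accessors
#' @export
setMethod("cellTypes", "SignatureCollection", function(x) names(x@sets))
#' @rdname accessors
#' @export
setMethod("cellTypes", "ICPModel", function(x) x@cellTypes)
#' @rdname accessors
#' @export
setMethod("selectedPairs", "ICPModel", function(x) x@pairs)
#' @rdname accessors
#' @export
setMethod("icpScores", "ICPResult", function(x) x@scores)
#' @rdname accessors
#' @export
setMethod("icpCutoff", "ICPResult", function(x) x@cutoff)
#' @rdname accessors
#' @export
setMethod("icpGroups", "ICPResult", function(x) x@group)

#' @describeIn accessors Number of gene sets in the collection.
#' @export
setMethod("length", "SignatureCollection", function(x) length(x@sets))

#' @describeIn accessors Cell-type labels of the collection.
#' @export
setMethod("names", "SignatureCollection", function(x) names(x@sets))

#' Extract one gene set by cell type or position
#' @param x A [SignatureCollection].
#' @param i Cell-type label or integer position.
#' @return Character vector of gene symbols.
#' @export
setMethod("[[", "SignatureCollection", function(x, i) x@sets[[i]])

setMethod("show", "SignatureCollection", function(object) {
  cat(sprintf("SignatureCollection with %d gene set(s)\n", length(object@sets)))
  if (length(object@sets)) {
    sz <- lengths(object@sets)
    cat(sprintf("  set sizes: %d-%d genes (median %g)\n",
                min(sz), max(sz), stats::median(sz)))
    show_n <- min(5L, length(object@sets))
    for (i in seq_len(show_n)) {
      cat(sprintf("  %s (%d genes)\n", names(object@sets)[i], sz[i]))
    }
    if (length(object@sets) > show_n) cat("  ...\n")
  }
})

setMethod("show", "ICPModel", function(object) {
  cat(sprintf("ICPModel: %d selected cell pair(s) over a %d cell-type catalogue\n",
              nrow(object@pairs), length(object@cellTypes)))
  if (nrow(object@pairs)) {
    p <- object@pairs
    for (i in seq_len(min(8L, nrow(p)))) {
      cat(sprintf("  %s > %s  C=%.3f HR=%.2f p=%.2g\n",
                  p$ci[i], p$cj[i], p$c_index[i], p$hr[i], p$p[i]))
    }
    if (nrow(p) > 8L) cat("  ...\n")
  }
  if (!is.null(object@parameters$alpha_pairs)) {
    cat(sprintf("  selection alpha: cells %g, pairs %g\n",
                object@parameters$alpha_cells, object@parameters$alpha_pairs))
  }
})

setMethod("show", "ICPResult", function(object) {
  cat(sprintf("ICPResult: %d sample(s), cutoff %.3f (%d high / %d low)\n",
              length(object@scores), object@cutoff,
              sum(object@group == "high"), sum(object@group == "low")))
  cat(sprintf("  score range: %d-%d\n", min(object@scores), max(object@scores)))
})
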