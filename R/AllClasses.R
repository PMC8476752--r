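#' @import methods
NULL

#' SignatureCollection: named immune-cell marker gene sets
#'
#' An ordered collection of marker gene sets, one per immune (or stromal) cell
#' type, as read from a GMT file. Iteration order is the input order and is
#' the canonical catalogue order used for all deterministic tie-breaks
#' downstream.
#'
#' @slot sets Named list; each element a character vector of unique gene
#'   symbols, names are cell-type labels (unique, non-empty).
#' @slot sources Named list parallel to `sets`; each element a character
#'   vector of free-text provenance strings (e.g. the GMT description field).
#'
#' @seealso [readGMT()], [mergeByCellType()], [filterToUniverse()]
#' @export
setClass("SignatureCollection",
  representation(sets = "list", sources = "list"),
  prototype(sets = list(), sources = list())
)

setValidity("SignatureCollection", function(object) {
  msgs <- character()
  nm <- names(object@sets)
  if (length(object@sets) > 0 && (is.null(nm) || any(!nzchar(nm)))) {
    msgs <- c(msgs, "every gene set must have a non-empty cell-type label")
  }
  if (anyDuplicated(nm)) {
    msgs <- c(msgs, sprintf("duplicate cell-type labels: %s",
                            paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  for (i in seq_along(object@sets)) {
    g <- object@sets[[i]]
    if (!is.character(g) || length(g) == 0) {
      msgs <- c(msgs, sprintf("gene set '%s' is empty", nm[i]))
    } else if (anyDuplicated(g)) {
      msgs <- c(msgs, sprintf("gene set '%s' has duplicate symbols", nm[i]))
    }
  }
  if (length(object@sources) != length(object@sets)) {
    msgs <- c(msgs, "sources must be parallel to sets")
  }
  if (length(msgs)) msgs else TRUE
})

#' ICPModel: a fitted immune cell pair signature
#'
#' The transferable result of pair selection: an ordered list of (anchor,
#' partner) cell-type pairs with their discovery-cohort statistics. Scoring a
#' cohort with the model recomputes each pair's within-sample indicator from
#' that cohort's own enrichment scores, so only the pair list (not any scale
#' information) is transferred.
#'
#' @slot pairs data.frame with columns `ci` (prognosis-associated anchor cell),
#'   `cj` (partner cell), `c_index`, `hr`, `p`, `beta`, `se`; ordered by
#'   anchor catalogue order; duplicate-free under unordered-pair identity;
#'   every row has `hr > 1` and `p <` the selection alpha.
#' @slot cellTypes character; the full cell-type catalogue (in catalogue
#'   order) the model was fitted against.
#' @slot parameters list of fitting parameters (alpha levels, tie rules,
#'   evaluation mode, schema version).
#' @slot provenance list describing the discovery cohorts (sizes, counts
#'   eliminated per selection step).
#' @export
setClass("ICPModel",
  representation(pairs = "data.frame", cellTypes = "character",
                 parameters = "list", provenance = "list")
)

setValidity("ICPModel", function(object) {
  msgs <- character()
  req <- c("ci", "cj", "c_index", "hr", "p")
  if (!all(req %in% names(object@pairs))) {
    return(sprintf("pairs must have columns %s", paste(req, collapse = ", ")))
  }
  p <- object@pairs
  if (any(p$ci == p$cj)) msgs <- c(msgs, "self-pairs are not allowed")
  key <- apply(cbind(pmin(p$ci, p$cj), pmax(p$ci, p$cj)), 1L, paste, collapse = "\r")
  if (anyDuplicated(key)) msgs <- c(msgs, "duplicate unordered cell pairs")
  if (nrow(p) > 0 && any(p$hr <= 1)) msgs <- c(msgs, "all retained pairs must have hr > 1")
  alpha <- object@parameters$alpha_pairs
  if (!is.null(alpha) && nrow(p) > 0 && any(p$p >= alpha)) {
    msgs <- c(msgs, sprintf("all retained pairs must have p < %g", alpha))
  }
  if (!all(c(p$ci, p$cj) %in% object@cellTypes)) {
    msgs <- c(msgs, "pair cell types missing from the catalogue")
  }
  if (any(p$c_index < 0 | p$c_index > 1)) msgs <- c(msgs, "c_index outside [0,1]")
  if (length(msgs)) msgs else TRUE
})

#' ICPResult: per-sample ICP scores with cutpoint and group labels
#'
#' @slot scores named integer vector; per-sample ICP score in
#'   `[0, number of selected pairs]`.
#' @slot cutoff numeric(1); maximally selected cutpoint on the score scale.
#' @slot group named character vector, `"high"` iff `score > cutoff`.
#' @slot cutpoint list with the full cutpoint scan (candidates and their
#'   standardized log-rank statistics).
#' @export
setClass("ICPResult",
  representation(scores = "integer", cutoff = "numeric",
                 group = "character", cutpoint = "list")
)

setValidity("ICPResult", function(object) {
  msgs <- character()
  if (length(object@scores) != length(object@group)) {
    msgs <- c(msgs, "scores and group must be parallel")
  }
  if (any(object@scores < 0)) msgs <- c(msgs, "scores must be non-negative")
  expect <- ifelse(object@scores > object@cutoff, "high", "low")
  if (!all(object@group == expect)) {
    msgs <- c(msgs, "group must be 'high' exactly when score > cutoff")
  }
  if (length(msgs)) msgs else TRUE
})
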