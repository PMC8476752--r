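#' Validate a genes-by-samples expression matrix
#'
#' @param x Numeric matrix, genes in rows, samples in columns, with unique
#'   non-empty dimnames, finite non-negative values, and at least 2 genes and
#'   2 samples.
#' @return Invisibly, `x`.
#' @keywords internal
checkExpressionMatrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("expression must be a numeric matrix")
  if (nrow(x) < 2L || ncol(x) < 2L) stop("expression needs >= 2 genes and >= 2 samples")
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("expression must have gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(x))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(x))) stop("duplicate sample identifiers")
  if (any(!is.finite(x))) stop("expression values must be finite")
  invisible(x)
}

#' Convert FPKM to TPM
#'
#' Rescales each sample (column) so it sums to 1e6:
#' `tpm_gj = fpkm_gj / sum_g(fpkm_gj) * 1e6`. TPM puts RNA-seq cohorts on a
#' per-sample relative-abundance scale comparable with array intensities.
#' Idempotent; columns already summing to 1e6 are unchanged.
#'
#' @param x Genes-by-samples numeric matrix of FPKM values (non-negative; each
#'   sample must have at least one positive value).
#' @return Matrix of the same shape with each column summing to 1e6.
#' @examples
#' m <- matrix(c(1, 1, 2, 4, 0, 4), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' colSums(fpkmToTpm(m))
#' @export
fpkmToTpm <- function(x) {
  checkExpressionMatrix(x)
  if (any(x < 0)) stop("FPKM values must be non-negative")
  cs <- colSums(x)
  bad <- cs <= 0
  if (any(bad)) {
    stop("all-zero expression for sample(s): ",
         paste(colnames(x)[bad], collapse = ", "))
  }
  sweep(x, 2L, cs / 1e6, "/")
}

#' ssGSEA enrichment score for one gene set in one sample
#'
#' Genes are ranked by decreasing expression; with `r_g` the rank from the
#' top (`N` for the most expressed gene, 1 for the least; average ranks for
#' ties) the running fractions at list position `i` are
#' `P_in(i) = sum of r_g^alpha over in-set genes at positions <= i / total
#' over the set` and `P_out(i) = count of out-of-set genes at positions <= i /
#' (N - set size)`. The (un-normalized) enrichment score is
#' `ES = sum_i [P_in(i) - P_out(i)]`. ES depends on expression only through
#' the within-sample ranking, which is what makes downstream pair scores
#' robust across platforms and normalizations.
#'
#' @param expr Named numeric vector of one sample's expression over all genes.
#' @param genes Character vector of the gene set's symbols. Must hit at least
#'   one and fewer than all of `names(expr)`.
#' @param alpha Rank weighting exponent, `>= 0`. Default 0.25.
#' @return The scalar enrichment score.
#' @export
ssgseaScore <- function(expr, genes, alpha = 0.25) {
  if (is.null(names(expr))) stop("'expr' must be named by gene")
  if (alpha < 0) stop("'alpha' must be >= 0")
  hits <- names(expr) %in% genes
  m <- sum(hits)
  N <- length(expr)
  if (m == 0L) stop("gene set has empty intersection with the expression genes")
  if (m == N) stop("gene set covers every gene; enrichment is undefined")
  ord <- order(expr, decreasing = TRUE)
  r <- N + 1 - rank(expr, ties.method = "average")
  w <- r^alpha
  hito <- hits[ord]
  wo <- w[ord]
  win <- ifelse(hito, wo, 0)
  p_in <- cumsum(win) / sum(wo[hito])
  p_out <- cumsum(!hito) / (N - m)
  sum(p_in - p_out)
}

#' ssGSEA enrichment over a collection of signatures
#'
#' Applies [ssgseaScore()] to every (gene set, sample) combination. With
#' `normalize = TRUE` (default) all scores are divided by the range
#' (max - min) of the whole output matrix, so scores are comparable in
#' magnitude across cell types within the cohort. Each cohort should be
#' scored independently; scores are never comparable across cohorts, which is
#' precisely why downstream modelling uses only within-sample comparisons.
#'
#' @param x Genes-by-samples numeric expression matrix (any per-sample
#'   monotone-equivalent scale: TPM, counts, log-intensities, ...).
#' @param collection A [SignatureCollection], already restricted to the
#'   matrix's gene universe (see [filterToUniverse()]).
#' @param alpha Rank weighting exponent passed to [ssgseaScore()].
#' @param normalize Divide by the output matrix range. Default `TRUE`.
#' @return Numeric matrix, cell types (collection order) by samples.
#' @examples
#' set.seed(1)
#' m <- matrix(rexp(200), nrow = 20,
#'             dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
#' sc <- SignatureCollection(list(A = paste0("g", 1:4), B = paste0("g", 11:15)))
#' ssgsea(m, sc)[, 1:3]
#' @export
ssgsea <- function(x, collection, alpha = 0.25, normalize = TRUE) {
  checkExpressionMatrix(x)
  stopifnot(is(collection, "SignatureCollection"))
  sets <- geneSets(collection)
  if (length(sets) == 0L) stop("empty signature collection")
  N <- nrow(x)
  hit_list <- lapply(sets, function(g) {
    h <- rownames(x) %in% g
    m <- sum(h)
    if (m == 0L || m == N) {
      stop("gene set with empty or full coverage of the matrix; ",
           "run filterToUniverse() first")
    }
    h
  })
  denom_out <- N - vapply(hit_list, sum, numeric(1))
  scores <- matrix(NA_real_, nrow = length(sets), ncol = ncol(x),
                   dimnames = list(names(sets), colnames(x)))
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    ord <- order(v, decreasing = TRUE)
    w <- (N + 1 - rank(v, ties.method = "average"))^alpha
    wo <- w[ord]
    for (k in seq_along(sets)) {
      hito <- hit_list[[k]][ord]
      win <- ifelse(hito, wo, 0)
      p_in <- cumsum(win) / sum(win)
      p_out <- cumsum(!hito) / denom_out[k]
      scores[k, j] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  scores
}

#' Read a tab-delimited genes-by-samples matrix
#'
#' Expected dialect: header row of sample identifiers, first column gene
#' identifiers, tab-delimited. Used for both expression and enrichment
#' matrices.
#'
#' @param path Input TSV path.
#' @return Numeric matrix with dimnames.
#' @export
readMatrixTSV <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("matrix file must have an ID column plus >= 1 sample")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate row identifiers in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write a genes-by-samples matrix as TSV
#'
#' @param x Numeric matrix with dimnames.
#' @param path Output path.
#' @param id_name Header label of the first (identifier) column.
#' @return Invisibly, `path`.
#' @export
writeMatrixTSV <- function(x, path, id_name = "gene") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
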