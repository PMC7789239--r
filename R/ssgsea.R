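#' Single-sample gene set enrichment score (ssGSEA)
#'
#' Computes the rank-weighted enrichment score of one gene set in one sample,
#' following the single-sample GSEA construction: genes are ordered by
#' decreasing expression, an in-set empirical CDF weighted by
#' \code{rank^alpha} is accumulated against the unweighted out-of-set CDF, and
#' the score is the sum of their differences over the whole ordered list.
#' Only the ranks of \code{expression} enter the score, so it is invariant
#' under any strictly increasing transform of the expression values.
#'
#' Ties are given average ranks; the position of tied genes in the ordered
#' list follows stable input order. Genes in \code{gene_set} that are absent
#' from \code{expression} are dropped with a warning.
#'
#' @param expression Named numeric vector of expression values (log2 scale is
#'   conventional but any monotone scale gives the same score).
#' @param gene_set Character vector of gene identifiers.
#' @param alpha Rank-weighting exponent (default 0.25, the usual ssGSEA
#'   choice).
#' @return A single numeric enrichment score (sign unrestricted).
#' @export
ssgsea_score <- function(expression, gene_set, alpha = 0.25) {
  if (is.null(names(expression)))
    stop("expression vector must be named by gene")
  if (anyDuplicated(names(expression)))
    stop("duplicate gene identifiers in expression vector")
  if (any(!is.finite(expression)))
    stop("expression values must be finite")
  present <- gene_set %in% names(expression)
  if (any(!present)) {
    warning(sprintf("%d gene(s) in set absent from expression matrix, dropped",
                    sum(!present)))
    gene_set <- gene_set[present]
  }
  if (length(gene_set) == 0L)
    stop("set not represented: no gene-set member in the gene universe")
  n <- length(expression)
  m <- length(unique(gene_set))
  if (m >= n)
    stop("empty complement: gene set covers the entire gene universe")
  r <- rank(expression, ties.method = "average")
  ord <- order(expression, decreasing = TRUE)  # stable for ties
  inset <- names(expression)[ord] %in% gene_set
  w <- r[ord]^alpha * inset
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!inset) / (n - m)
  sum(p_in - p_out)
}

#' ssGSEA scores for a gene-set collection over all samples
#'
#' Applies [ssgsea_score()] to every (set, sample) pair of an expression
#' matrix. With \code{normalization = "global_range"} all scores are divided
#' by the range (max - min) of the raw score matrix, the convention of the
#' standard ssGSEA implementation; this preserves all orderings.
#'
#' @param expr Numeric matrix, genes in rows (rownames = gene ids), samples in
#'   columns.
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param alpha Rank-weighting exponent, see [ssgsea_score()].
#' @param normalization "global_range" (default) or "raw".
#' @param zscore If TRUE, expression is z-scored per gene across samples
#'   before scoring (changes per-sample rankings, hence scores).
#' @return Numeric matrix, sets x samples, with attribute
#'   \code{normalization}.
#' @export
score_matrix <- function(expr, sets, alpha = 0.25,
                         normalization = c("global_range", "raw"),
                         zscore = FALSE) {
  normalization <- match.arg(normalization)
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(expr)) || anyDuplicated(colnames(expr)))
    stop("duplicate gene or sample identifiers")
  if (zscore) {
    mu <- rowMeans(expr)
    sdv <- apply(expr, 1, stats::sd)
    sdv[sdv == 0] <- 1
    expr <- (expr - mu) / sdv
  }
  universe <- rownames(expr)
  sets_use <- lapply(sets, function(s) unique(s[s %in% universe]))
  dropped <- vapply(sets, length, 1L) - vapply(sets_use, length, 1L)
  if (any(dropped > 0))
    warning(sprintf("%d gene(s) across %d set(s) absent from matrix, dropped",
                    sum(dropped), sum(dropped > 0)))
  valid <- vapply(sets_use, function(s)
    length(s) >= 1L && length(s) < nrow(expr), logical(1))
  if (!any(valid))
    stop("no valid gene set after intersection with the gene universe")
  if (any(!valid))
    warning(sprintf("set(s) dropped as empty or universe-covering: %s",
                    paste(names(sets_use)[!valid], collapse = ", ")))
  sets_use <- sets_use[valid]
  n <- nrow(expr)
  scores <- matrix(NA_real_, length(sets_use), ncol(expr),
                   dimnames = list(names(sets_use), colnames(expr)))
  for (j in seq_len(ncol(expr))) {
    x <- expr[, j]
    r <- rank(x, ties.method = "average")
    ord <- order(x, decreasing = TRUE)
    ra <- r[ord]^alpha
    genes_ord <- universe[ord]
    for (i in seq_along(sets_use)) {
      inset <- genes_ord %in% sets_use[[i]]
      m <- sum(inset)
      w <- ra * inset
      scores[i, j] <- sum(cumsum(w) / sum(w) - cumsum(!inset) / (n - m))
    }
  }
  if (normalization == "global_range") {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  attr(scores, "normalization") <- normalization
  scores
}
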