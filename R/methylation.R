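#' Global methylation level (GML)
#'
#' Mean beta-value per sample over a probe subset (all probes by default),
#' excluding missing values probe-wise.
#'
#' @param beta Probe x sample matrix of beta-values in [0, 1] (NAs allowed).
#' @param probe_subset Optional character vector of probe ids (e.g. a curated
#'   global-methylation probe list); defaults to all probes.
#' @return Named numeric vector, one GML per sample (NA when every subset
#'   probe is missing for a sample).
#' @export
gml <- function(beta, probe_subset = NULL) {
  if (!is.null(probe_subset)) {
    keep <- intersect(probe_subset, rownames(beta))
    if (length(keep) == 0) stop("probe subset absent from beta matrix")
    beta <- beta[keep, , drop = FALSE]
  }
  ok <- beta >= 0 & beta <= 1
  if (any(!ok, na.rm = TRUE)) stop("beta values must lie in [0, 1]")
  colMeans(beta, na.rm = TRUE)
}

#' Call epigenetically silenced genes (ESGs)
#'
#' Four-step caller integrating tumor methylation, matched-normal methylation
#' and expression:
#' \enumerate{
#'   \item Drop probes methylated in normal tissue (mean normal beta strictly
#'     greater than \code{normal_beta_max}) and probes methylated
#'     (beta >= \code{methylated_cutoff}) in fewer than
#'     \code{min_methylated_fraction} of tumors.
#'   \item Split tumors at \code{methylated_cutoff} into methylated
#'     (beta >= cutoff) and unmethylated groups per surviving probe.
#'   \item A probe is silenced iff mean expression of its gene in the
#'     unmethylated group exceeds that in the methylated group by strictly
#'     more than \code{sd_multiplier} standard deviations of the unmethylated
#'     group's expression. Probes whose split leaves an empty group are
#'     ineligible (counted as not silenced).
#'   \item A gene is an ESG iff strictly more than half of its surviving
#'     probes are silenced.
#' }
#'
#' @param tumor_beta Probe x tumor-sample beta matrix.
#' @param normal_beta Named numeric vector of per-probe mean beta in matched
#'   normals.
#' @param expr Gene x sample log2 expression matrix sharing samples with
#'   \code{tumor_beta}.
#' @param probe_map data.frame with columns probe and gene.
#' @param normal_beta_max Normal-methylation exclusion threshold (default
#'   0.2, strict >).
#' @param methylated_cutoff Beta cutoff separating methylated from
#'   unmethylated tumors (default 0.3; beta equal to the cutoff counts as
#'   methylated).
#' @param min_methylated_fraction Minimum fraction of tumors methylated for a
#'   probe to stay in play (default 0.1).
#' @param sd_multiplier Expression-suppression threshold in unmethylated-group
#'   SDs (default 1.64).
#' @return data.frame with one row per gene having at least one surviving
#'   probe: gene, n_probes, n_silenced, fraction_silenced, is_esg; the
#'   per-probe detail table is attached as attribute \code{probe_detail}.
#' @export
call_esgs <- function(tumor_beta, normal_beta, expr, probe_map,
                      normal_beta_max = 0.2, methylated_cutoff = 0.3,
                      min_methylated_fraction = 0.1, sd_multiplier = 1.64) {
  shared <- intersect(colnames(tumor_beta), colnames(expr))
  if (length(shared) < 4)
    stop("too few samples shared between beta and expression matrices")
  tb <- tumor_beta[, shared, drop = FALSE]
  ex <- expr[, shared, drop = FALSE]
  probes <- intersect(rownames(tb), probe_map$probe)
  genes_of <- stats::setNames(probe_map$gene, probe_map$probe)
  probes <- probes[genes_of[probes] %in% rownames(ex)]
  if (length(probes) == 0) stop("no probe maps to a gene in the matrix")
  nb <- normal_beta[probes]
  meth_frac <- rowMeans(tb[probes, , drop = FALSE] >= methylated_cutoff,
                        na.rm = TRUE)
  surviving <- probes[!(is.na(nb) | nb > normal_beta_max) &
                        meth_frac >= min_methylated_fraction]
  detail <- lapply(surviving, function(pr) {
    b <- tb[pr, ]
    meth <- which(!is.na(b) & b >= methylated_cutoff)
    unmeth <- which(!is.na(b) & b < methylated_cutoff)
    g <- genes_of[[pr]]
    if (length(meth) == 0 || length(unmeth) == 0)
      return(data.frame(probe = pr, gene = g, eligible = FALSE,
                        mean_expr_unmeth = NA_real_,
                        mean_expr_meth = NA_real_, sd_unmeth = NA_real_,
                        silenced = FALSE, stringsAsFactors = FALSE))
    mu_u <- mean(ex[g, unmeth])
    mu_m <- mean(ex[g, meth])
    sd_u <- stats::sd(ex[g, unmeth])
    sil <- isTRUE((mu_u - mu_m) > sd_multiplier * sd_u)
    data.frame(probe = pr, gene = g, eligible = TRUE, mean_expr_unmeth = mu_u,
               mean_expr_meth = mu_m, sd_unmeth = sd_u, silenced = sil,
               stringsAsFactors = FALSE)
  })
  detail <- do.call(rbind, detail)
  if (is.null(detail) || nrow(detail) == 0) {
    out <- data.frame(gene = character(), n_probes = integer(),
                      n_silenced = integer(), fraction_silenced = numeric(),
                      is_esg = logical(), stringsAsFactors = FALSE)
    attr(out, "probe_detail") <- detail
    return(out)
  }
  agg_n <- tapply(detail$silenced, detail$gene, length)
  agg_s <- tapply(detail$silenced, detail$gene, sum)
  out <- data.frame(gene = names(agg_n), n_probes = as.integer(agg_n),
                    n_silenced = as.integer(agg_s),
                    fraction_silenced = as.numeric(agg_s / agg_n),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$is_esg <- out$fraction_silenced > 0.5
  attr(out, "probe_detail") <- detail
  out
}

#' Averaged methylation-expression correlation per gene
#'
#' For each gene, computes the Spearman correlation between each of its
#' probes' beta-values and the gene's expression across shared samples, then
#' averages the probe-level coefficients into a single per-gene value.
#' Probes with a constant beta or expression vector have undefined correlation
#' and are excluded from the average.
#'
#' @param beta Probe x sample beta matrix.
#' @param expr Gene x sample expression matrix.
#' @param probe_map data.frame with columns probe and gene.
#' @param gene_list Genes to evaluate (default: all mapped genes present in
#'   \code{expr}).
#' @return data.frame: gene, rho (averaged Spearman), n_probes used.
#' @export
methylation_expression_correlation <- function(beta, expr, probe_map,
                                               gene_list = NULL) {
  shared <- intersect(colnames(beta), colnames(expr))
  if (length(shared) < 3) stop("need at least 3 shared samples")
  b <- beta[, shared, drop = FALSE]
  ex <- expr[, shared, drop = FALSE]
  map <- probe_map[probe_map$probe %in% rownames(b) &
                     probe_map$gene %in% rownames(ex), , drop = FALSE]
  if (is.null(gene_list)) gene_list <- unique(map$gene)
  res <- lapply(gene_list, function(g) {
    prs <- map$probe[map$gene == g]
    if (length(prs) == 0)
      return(data.frame(gene = g, rho = NA_real_, n_probes = 0L))
    rhos <- vapply(prs, function(pr) {
      x <- b[pr, ]; y <- ex[g, ]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
        return(NA_real_)
      stats::cor(x[ok], y[ok], method = "spearman")
    }, numeric(1))
    rhos <- rhos[!is.na(rhos)]
    data.frame(gene = g,
               rho = if (length(rhos)) mean(rhos) else NA_real_,
               n_probes = length(rhos), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
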