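#' Packaged immunomodulator annotation
#'
#' A curated list of 62 immunomodulator genes partitioned into 12 MHC class I,
#' 11 MHC class II, 27 checkpoint stimulator and 12 checkpoint inhibitor
#' genes, shipped as a plain TSV. Gene membership follows the field's
#' standard immunomodulator classes; supply your own annotation file to
#' override.
#'
#' @param path Optional path to a user annotation TSV (columns gene, class).
#' @return data.frame with columns gene and class.
#' @export
immunomodulator_annotation <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "immunomodulators.tsv",
                        package = "timephen")
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "class") %in% colnames(df)))
  if (anyDuplicated(df$gene)) stop("duplicate genes in annotation")
  df
}

#' Kruskal-Wallis expression test across phenotypes
#'
#' For every gene in \code{gene_list}, tests whether its expression
#' distribution differs across the phenotypes (rank-based, tie-corrected),
#' with BH adjustment over the supplied gene list.
#'
#' @param expr Gene x sample expression matrix.
#' @param labels Named character vector of phenotype labels.
#' @param gene_list Genes to test (default: the packaged immunomodulators).
#' @return data.frame: gene, statistic (H), df, p_value, adj_p. Genes absent
#'   from the matrix are skipped with a warning.
#' @export
expression_group_test <- function(expr, labels, gene_list = NULL) {
  if (is.null(gene_list)) gene_list <- immunomodulator_annotation()$gene
  labels <- labels[colnames(expr)]
  g <- factor(as.character(labels))
  if (nlevels(g) < 2) stop("need at least 2 phenotypes")
  missing <- setdiff(gene_list, rownames(expr))
  if (length(missing))
    warning(sprintf("%d gene(s) absent from matrix, skipped",
                    length(missing)))
  genes <- intersect(gene_list, rownames(expr))
  res <- lapply(genes, function(gene) {
    kt <- stats::kruskal.test(expr[gene, ], g)
    data.frame(gene = gene, statistic = unname(kt$statistic),
               df = unname(kt$parameter), p_value = kt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adj_p <- stats::p.adjust(out$p_value, "BH")
  out
}

#' Event (mutation / CNV) enrichment test across phenotypes
#'
#' For each gene, tests the phenotype x event contingency table with Fisher's
#' exact test (falling back to a simulated p-value and, if need be, the
#' chi-square test with a note, for tables the network algorithm cannot
#' handle). Genes whose event status is constant across all samples (all
#' TRUE or all FALSE) get p = 1 by convention and are flagged.
#'
#' @param events Gene x sample logical (or 0/1) matrix of event indicators.
#' @param labels Named character vector of phenotype labels.
#' @return data.frame: gene, p_value, adj_p, method, degenerate.
#' @export
event_enrichment_test <- function(events, labels) {
  labels <- labels[colnames(events)]
  g <- factor(as.character(labels))
  if (nlevels(g) < 2) stop("need at least 2 phenotypes")
  res <- lapply(rownames(events), function(gene) {
    e <- as.logical(events[gene, ])
    if (length(unique(e)) < 2)
      return(data.frame(gene = gene, p_value = 1, method = "constant",
                        degenerate = TRUE, stringsAsFactors = FALSE))
    tab <- table(e, g)
    p <- tryCatch(stats::fisher.test(tab)$p.value,
                  error = function(err)
                    tryCatch(stats::fisher.test(tab, simulate.p.value = TRUE,
                                                B = 10000)$p.value,
                             error = function(err2)
                               stats::chisq.test(tab)$p.value))
    data.frame(gene = gene, p_value = p, method = "fisher",
               degenerate = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adj_p <- stats::p.adjust(out$p_value, "BH")
  out[, c("gene", "p_value", "adj_p", "method", "degenerate")]
}

#' miRNA negative-regulation screen
#'
#' Within each phenotype, computes the Spearman correlation between every
#' miRNA and every target gene, BH-adjusts over all tested pairs within that
#' phenotype, and retains pairs that are significantly inversely correlated
#' (rho <= \code{rho_max}, adjusted p < \code{adjp_max}) AND predicted to
#' bind in the supplied binding catalogue. Phenotypes with fewer than 4
#' samples are skipped with a warning.
#'
#' @param mirna_expr miRNA x sample expression matrix.
#' @param expr Gene x sample expression matrix (shared samples required).
#' @param binding_pairs data.frame with columns mirna and gene (predicted
#'   binding catalogue, e.g. exported from a target-prediction database).
#' @param labels Named character vector of phenotype labels.
#' @param gene_list Candidate target genes (default: genes appearing in
#'   \code{binding_pairs} that are present in \code{expr}).
#' @param rho_max Spearman threshold, retained if rho <= rho_max (default
#'   -0.2).
#' @param adjp_max BH-adjusted p threshold (default 0.05).
#' @return data.frame of retained pairs: mirna, gene, phenotype, rho, adj_p,
#'   predicted_binding (all TRUE). The full tested table is attached as
#'   attribute \code{tested}.
#' @export
mirna_regulator_screen <- function(mirna_expr, expr, binding_pairs, labels,
                                   gene_list = NULL, rho_max = -0.2,
                                   adjp_max = 0.05) {
  shared <- intersect(colnames(mirna_expr), colnames(expr))
  if (length(shared) < 4) stop("need at least 4 shared samples")
  labels <- labels[shared]
  if (is.null(gene_list))
    gene_list <- intersect(unique(binding_pairs$gene), rownames(expr))
  gene_list <- intersect(gene_list, rownames(expr))
  if (!length(gene_list)) stop("no candidate target gene in matrix")
  bind_key <- paste(binding_pairs$mirna, binding_pairs$gene, sep = "\r")
  tested <- list()
  for (ph in sort(unique(as.character(labels)))) {
    samp <- shared[labels == ph]
    if (length(samp) < 4) {
      warning(sprintf("phenotype %s has < 4 samples, skipped", ph))
      next
    }
    # rank once per phenotype; Pearson on ranks = Spearman
    mr <- t(apply(mirna_expr[, samp, drop = FALSE], 1, rank))
    gr <- t(apply(expr[gene_list, samp, drop = FALSE], 1, rank))
    rho <- stats::cor(t(mr), t(gr))
    n <- length(samp)
    tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    df <- data.frame(mirna = rep(rownames(rho), times = ncol(rho)),
                     gene = rep(colnames(rho), each = nrow(rho)),
                     phenotype = ph, rho = as.vector(rho),
                     p_value = as.vector(p), stringsAsFactors = FALSE)
    df$adj_p <- stats::p.adjust(df$p_value, "BH")
    tested[[ph]] <- df
  }
  tested <- do.call(rbind, tested)
  if (is.null(tested)) stop("no phenotype with enough samples")
  tested$predicted_binding <-
    paste(tested$mirna, tested$gene, sep = "\r") %in% bind_key
  keep <- tested$rho <= rho_max & tested$adj_p < adjp_max &
    tested$predicted_binding & !is.na(tested$rho)
  out <- tested[keep, c("mirna", "gene", "phenotype", "rho", "adj_p",
                        "predicted_binding")]
  rownames(out) <- NULL
  attr(out, "tested") <- tested
  out
}
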