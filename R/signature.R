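#' One-vs-rest differential expression for a phenotype
#'
#' Computes, for every gene, the log2 fold change (mean in the contrast
#' phenotype minus mean in all other samples) and a two-group t-test p-value,
#' BH-adjusted across genes. By default the variance is moderated with
#' limma's empirical-Bayes shrinkage; \code{shrink = FALSE} gives the
#' ordinary (pooled-variance) two-sample t-statistic.
#'
#' @param expr Gene x sample log2 expression matrix.
#' @param labels Named character vector of phenotype labels covering the
#'   samples of \code{expr}.
#' @param contrast The phenotype tested against the rest.
#' @param shrink Use limma's moderated t (default TRUE).
#' @return data.frame: gene, contrast, logFC, p_value, adj_p.
#' @export
differential_expression <- function(expr, labels, contrast, shrink = TRUE) {
  labels <- labels[colnames(expr)]
  if (anyNA(labels)) stop("every sample must be labeled")
  grp <- factor(ifelse(labels == contrast, "grp", "rest"),
                levels = c("rest", "grp"))
  if (min(table(grp)) < 2 || nlevels(droplevels(grp)) < 2)
    stop("need at least 2 samples on each side of the contrast")
  design <- stats::model.matrix(~grp)
  fit <- limma::lmFit(expr, design)
  if (shrink) {
    fit <- limma::eBayes(fit)
    tt <- limma::topTable(fit, coef = "grpgrp", number = Inf,
                          sort.by = "none")
    p <- tt$P.Value
    lfc <- tt$logFC
  } else {
    lfc <- fit$coefficients[, "grpgrp"]
    tstat <- lfc / (fit$stdev.unscaled[, "grpgrp"] * fit$sigma)
    p <- 2 * stats::pt(-abs(tstat), df = fit$df.residual)
  }
  # genes with zero variance everywhere carry no evidence: p = 1
  p[!is.finite(p)] <- 1
  constant <- apply(expr, 1, function(x) length(unique(x)) == 1L)
  p[constant] <- 1
  lfc[constant] <- 0
  data.frame(gene = rownames(expr), contrast = contrast, logFC = unname(lfc),
             p_value = unname(p), adj_p = stats::p.adjust(unname(p), "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select phenotype-related differentially expressed genes
#'
#' Union, over the one-vs-rest contrasts, of genes with |logFC| strictly
#' greater than \code{lfc_threshold} and BH-adjusted p strictly below
#' \code{adjp_threshold}.
#'
#' @param tables A list of DEG tables from [differential_expression()] (or a
#'   single table).
#' @param lfc_threshold Absolute log2 fold-change threshold (default 1.5).
#' @param adjp_threshold Adjusted p threshold (default 0.05).
#' @return Character vector of gene identifiers (possibly empty, with a
#'   warning).
#' @export
select_degs <- function(tables, lfc_threshold = 1.5, adjp_threshold = 0.05) {
  if (is.data.frame(tables)) tables <- list(tables)
  hits <- unlist(lapply(tables, function(tb)
    tb$gene[abs(tb$logFC) > lfc_threshold & tb$adj_p < adjp_threshold]))
  out <- unique(hits)
  if (length(out) == 0)
    warning("no gene passed the DEG thresholds; empty signature")
  out
}

#' TIME index (TI) per sample
#'
#' The TI is the globally range-normalized ssGSEA score of the
#' phenotype-related DEG signature in each sample, summarising how strongly a
#' patient expresses the phenotype signature. By default the signature is
#' scored as one set; \code{mode = "directional"} scores up- and
#' down-regulated subsets separately and returns their difference.
#'
#' @param expr Gene x sample log2 expression matrix.
#' @param signature Character vector of signature genes, or for
#'   \code{mode = "directional"} a list with elements \code{up} and
#'   \code{down}.
#' @param mode "single" (default) or "directional".
#' @param alpha ssGSEA exponent passed to [score_matrix()].
#' @return data.frame with columns sample and ti.
#' @export
compute_ti <- function(expr, signature, mode = c("single", "directional"),
                       alpha = 0.25) {
  mode <- match.arg(mode)
  if (mode == "single") {
    sets <- list(TI = signature)
    sc <- score_matrix(expr, sets, alpha = alpha,
                       normalization = "global_range")
    ti <- sc["TI", ]
  } else {
    stopifnot(is.list(signature), all(c("up", "down") %in% names(signature)))
    sc <- score_matrix(expr, list(up = signature$up, down = signature$down),
                       alpha = alpha, normalization = "global_range")
    ti <- sc["up", ] - sc["down", ]
  }
  data.frame(sample = colnames(expr), ti = unname(ti),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Optimal survival cutoff for a continuous score
#'
#' Maximally selected log-rank statistic: every cutpoint between consecutive
#' ordered score values that leaves at least \code{min_group_fraction} of the
#' samples on each side is scanned, and the cutoff with the largest log-rank
#' chi-square for the resulting two-group split is returned. The p-value of
#' the selected split is not corrected for the cutoff search and is therefore
#' anticonservative; it is reported for ranking, not inference.
#'
#' @param ti data.frame with columns sample and ti (from [compute_ti()]), or
#'   a named numeric vector of scores.
#' @param survival_data data.frame with columns sample, time, event.
#' @param min_group_fraction Minimum fraction of samples per side
#'   (default 0.1).
#' @return list: cutoff, statistic (chi-square), p_value, groups (named
#'   character vector "high"/"low"), n_candidates.
#' @export
optimal_cutoff <- function(ti, survival_data, min_group_fraction = 0.1) {
  if (is.data.frame(ti)) ti <- stats::setNames(ti$ti, ti$sample)
  shared <- intersect(names(ti), survival_data$sample)
  if (length(shared) < 4) stop("too few samples with both score and survival")
  ti <- ti[shared]
  surv <- survival_data[match(shared, survival_data$sample), ]
  if (sum(surv$event) == 0) stop("no events in the survival table")
  o <- order(ti)
  x <- ti[o]
  n <- length(x)
  min_n <- ceiling(min_group_fraction * n)
  splits <- which(diff(x) > 0)                     # cut between i and i+1
  splits <- splits[splits >= min_n & (n - splits) >= min_n]
  if (length(splits) == 0)
    stop("no admissible cutoff (constant score or min_group_fraction too large)")
  best <- list(stat = -Inf)
  for (i in splits) {
    cut <- (x[i] + x[i + 1]) / 2
    grp <- ifelse(ti > cut, "high", "low")
    if (length(unique(grp)) < 2) next
    sd <- survival::survdiff(
      survival::Surv(surv$time, surv$event) ~ grp)
    if (sd$chisq > best$stat)
      best <- list(stat = sd$chisq, cutoff = unname(cut),
                   p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
  }
  grp <- stats::setNames(ifelse(ti > best$cutoff, "high", "low"), names(ti))
  list(cutoff = best$cutoff, statistic = best$stat, p_value = best$p,
       groups = grp, n_candidates = length(splits))
}

#' Log-rank test between survival groups
#'
#' Standard log-rank chi-square with (number of groups - 1) degrees of
#' freedom, via survival::survdiff.
#'
#' @param groups Named character vector mapping samples to group labels.
#' @param survival_data data.frame with columns sample, time, event.
#' @return list: statistic, df, p_value, n, n_events.
#' @export
logrank_test <- function(groups, survival_data) {
  shared <- intersect(names(groups), survival_data$sample)
  g <- factor(groups[shared])
  if (nlevels(droplevels(g)) < 2)
    stop("need at least 2 groups for a log-rank test")
  surv <- survival_data[match(shared, survival_data$sample), ]
  sd <- survival::survdiff(survival::Surv(surv$time, surv$event) ~ g)
  df <- length(sd$n) - 1
  list(statistic = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE),
       n = length(shared), n_events = sum(surv$event))
}
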