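#' Resampled consensus clustering of samples
#'
#' Discovers sample clusters by subsampling consensus clustering: in each of
#' \code{n_resamples} iterations a random \code{subsample_fraction} of samples
#' is drawn and clustered; the consensus matrix entry for a pair of samples is
#' the fraction of co-samplings in which they co-clustered. For each k the
#' final assignment is obtained by hierarchical clustering (average linkage)
#' of 1 - consensus. The number of clusters is selected by the lowest
#' proportion of ambiguous clustering (PAC, see [pac()]), and clusters at the
#' selected k are named \code{TIME-1 < TIME-2 < ...} in ascending order of
#' mean enrichment score, so TIME-1 is the least immune-infiltrated group.
#'
#' @param scores Numeric matrix of features x samples, typically the
#'   cell-type ssGSEA score matrix from [score_matrix()].
#' @param k_range Integer vector of cluster numbers to scan (default 2:9).
#' @param n_resamples Number of subsampling iterations (default 500).
#' @param subsample_fraction Fraction of samples drawn per iteration
#'   (default 0.8).
#' @param seed Optional integer seed; same seed gives an identical result.
#' @param base_method Base clustering algorithm applied to each subsample:
#'   "kmeans" (default) or "hclust" (agglomerative, average linkage).
#'   PAC-based model selection needs the base clusterer to express ambiguity
#'   at the wrong k; k-means does so through its random restarts, whereas
#'   average-linkage trees on subsamples of well-separated data are nearly
#'   deterministic at every k, which degenerates the PAC curve.
#' @param distance Distance between sample score profiles for the "hclust"
#'   base method: "euclidean" (default) or "pearson" (1 - correlation).
#'   Infiltration phenotypes are level-structured (low / intermediate / high
#'   mean scores), and correlation distance is blind to a uniform level
#'   shift, so Euclidean is the default here.
#' @param pac_window Lower/upper consensus bounds defining ambiguity for PAC
#'   (default c(0.1, 0.9)).
#' @return An object of class \code{time_consensus}: a list with
#'   \code{consensus} (per-k consensus matrices), \code{assignments} (per-k
#'   integer cluster vectors), \code{cdf} (per-k empirical CDF functions over
#'   upper-triangle consensus entries), \code{pac} (named numeric),
#'   \code{selected_k}, \code{labels} (named character vector of phenotype
#'   labels at the selected k, source "discovered"), \code{k_range},
#'   \code{degenerate} (TRUE when the PAC curve has no pronounced minimum and
#'   the smallest-k tie-break was applied).
#' @export
consensus_phenotypes <- function(scores, k_range = 2:9, n_resamples = 500,
                                 subsample_fraction = 0.8, seed = NULL,
                                 base_method = c("kmeans", "hclust"),
                                 distance = c("euclidean", "pearson"),
                                 pac_window = c(0.1, 0.9)) {
  base_method <- match.arg(base_method)
  distance <- match.arg(distance)
  n <- ncol(scores)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2)) stop("k_range entries must be >= 2")
  if (n < max(k_range) + 1L)
    stop("need at least max(k_range) + 1 samples")
  if (n_resamples < 2) stop("n_resamples must be >= 2")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  m <- ceiling(subsample_fraction * n)
  nk <- length(k_range)
  hits <- array(0, c(n, n, nk))
  tries <- matrix(0, n, n)
  for (b in seq_len(n_resamples)) {
    idx <- sort(sample.int(n, m))
    tries[idx, idx] <- tries[idx, idx] + 1
    if (base_method == "hclust") {
      d <- if (distance == "pearson")
        stats::as.dist(1 - stats::cor(scores[, idx]))
      else stats::dist(t(scores[, idx]))
      h <- stats::hclust(d, method = "average")
      for (ki in seq_len(nk)) {
        cl <- stats::cutree(h, k_range[ki])
        co <- outer(cl, cl, "==")
        hits[idx, idx, ki] <- hits[idx, idx, ki] + co
      }
    } else {
      for (ki in seq_len(nk)) {
        cl <- stats::kmeans(t(scores[, idx]), centers = k_range[ki],
                            nstart = 3)$cluster
        co <- outer(cl, cl, "==")
        hits[idx, idx, ki] <- hits[idx, idx, ki] + co
      }
    }
  }
  off <- upper.tri(tries)
  if (any(tries[off] == 0))
    stop("some sample pairs were never co-sampled; increase n_resamples")
  sample_ids <- colnames(scores)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  consensus <- assignments <- cdfs <- vector("list", nk)
  pac_vals <- numeric(nk)
  names(consensus) <- names(assignments) <- names(cdfs) <-
    names(pac_vals) <- paste0("k", k_range)
  for (ki in seq_len(nk)) {
    cm <- hits[, , ki] / tries
    diag(cm) <- 1
    cm <- (cm + t(cm)) / 2
    dimnames(cm) <- list(sample_ids, sample_ids)
    consensus[[ki]] <- cm
    h <- stats::hclust(stats::as.dist(1 - cm), method = "average")
    assignments[[ki]] <- stats::setNames(stats::cutree(h, k_range[ki]),
                                         sample_ids)
    ut <- cm[upper.tri(cm)]
    cdfs[[ki]] <- stats::ecdf(ut)
    pac_vals[ki] <- pac(cm, lower = pac_window[1], upper = pac_window[2])
  }
  sel_idx <- which.min(pac_vals)          # which.min takes the first minimum
  selected_k <- k_range[sel_idx]
  degenerate <- sum(pac_vals <= min(pac_vals) + 1e-12) > 1 ||
    (max(pac_vals) - min(pac_vals)) < 0.01
  labels <- label_phenotypes(assignments[[sel_idx]], scores)
  structure(list(consensus = consensus, assignments = assignments,
                 cdf = cdfs, pac = pac_vals, selected_k = selected_k,
                 labels = labels, k_range = k_range,
                 n_resamples = n_resamples,
                 subsample_fraction = subsample_fraction,
                 base_method = base_method, distance = distance,
                 degenerate = degenerate,
                 source = "discovered"),
            class = "time_consensus")
}

#' Name clusters by ascending mean immune score
#'
#' Clusters are relabelled \code{TIME-1, TIME-2, ...} so that TIME-1 has the
#' lowest mean enrichment score (least infiltrated) and the highest index the
#' greatest.
#'
#' @param assignment Integer cluster vector named by sample.
#' @param scores Feature x sample score matrix used for ordering.
#' @return Named character vector of phenotype labels.
#' @export
label_phenotypes <- function(assignment, scores) {
  overall <- colMeans(scores)
  cl_means <- tapply(overall[names(assignment)], assignment, mean)
  ord <- order(cl_means)
  new_idx <- match(as.character(assignment), names(cl_means)[ord])
  stats::setNames(paste0("TIME-", new_idx), names(assignment))
}

#' Proportion of ambiguous clustering (PAC)
#'
#' PAC = CDF(upper) - CDF(lower) of the upper-triangle entries of a consensus
#' matrix (diagonal excluded). Entries near 0 or 1 indicate pairs that almost
#' never or almost always co-cluster; the mass in between is ambiguous, so a
#' low PAC indicates a stable clustering.
#'
#' @param consensus_matrix Symmetric matrix with entries in [0, 1].
#' @param lower,upper Ambiguity window bounds (defaults 0.1 and 0.9).
#' @return PAC value in [0, 1].
#' @export
pac <- function(consensus_matrix, lower = 0.1, upper = 0.9) {
  if (!is.matrix(consensus_matrix) || nrow(consensus_matrix) < 2)
    stop("need a consensus matrix over at least 2 samples")
  if (!(lower >= 0 && lower < upper && upper <= 1))
    stop("require 0 <= lower < upper <= 1")
  ut <- consensus_matrix[upper.tri(consensus_matrix)]
  if (any(ut < 0 | ut > 1)) stop("consensus entries must lie in [0, 1]")
  f <- stats::ecdf(ut)
  unname(f(upper) - f(lower))
}

#' Select the number of clusters by lowest PAC
#'
#' @param result A \code{time_consensus} object or a named numeric vector of
#'   PAC values (names "k2", "k3", ... or plain integers).
#' @return The k minimising PAC; ties broken toward the smallest k.
#' @export
select_k <- function(result) {
  pv <- if (inherits(result, "time_consensus")) result$pac else result
  ks <- as.integer(sub("^k", "", names(pv)))
  if (anyNA(ks)) stop("PAC vector must be named by k")
  ord <- order(ks)
  pv <- pv[ord]; ks <- ks[ord]
  ks[which.min(pv)]
}

#' @export
print.time_consensus <- function(x, ...) {
  cat("Consensus phenotyping of", length(x$labels), "samples\n")
  cat("  k scanned:", paste(x$k_range, collapse = ", "),
      "| resamples:", x$n_resamples,
      "| subsample:", x$subsample_fraction, "\n")
  cat("  PAC:", paste(sprintf("%s=%.3f", names(x$pac), x$pac),
                      collapse = " "), "\n")
  cat("  selected k =", x$selected_k,
      if (x$degenerate) "(no pronounced PAC minimum; smallest-k tie-break)"
      else "", "\n")
  print(table(x$labels))
  invisible(x)
}

#' @export
summary.time_consensus <- function(object, ...) {
  out <- list(selected_k = object$selected_k, pac = object$pac,
              sizes = table(object$labels), degenerate = object$degenerate)
  class(out) <- "summary.time_consensus"
  out
}

#' @export
print.summary.time_consensus <- function(x, ...) {
  cat("Selected k:", x$selected_k, "\nPAC by k:\n")
  print(round(x$pac, 4))
  cat("Phenotype sizes:\n")
  print(x$sizes)
  invisible(x)
}

#' Consensus CDF and PAC diagnostics plot
#'
#' Left panel: empirical CDF of consensus entries per k. Right panel: PAC by
#' k with the selected k marked.
#'
#' @param x A \code{time_consensus} object.
#' @param ... Ignored.
#' @export
plot.time_consensus <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  cols <- grDevices::hcl.colors(length(x$k_range), "Dark 3")
  grid <- seq(0, 1, length.out = 201)
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "consensus index", ylab = "CDF",
                 main = "Consensus CDF")
  for (i in seq_along(x$cdf))
    graphics::lines(grid, x$cdf[[i]](grid), col = cols[i])
  graphics::legend("bottomright", legend = names(x$cdf), col = cols,
                   lty = 1, cex = 0.7, bty = "n")
  graphics::plot(x$k_range, x$pac, type = "b", xlab = "k", ylab = "PAC",
                 main = "PAC by k")
  graphics::abline(v = x$selected_k, lty = 2)
  invisible(x)
}
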