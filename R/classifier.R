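#' Build phenotype centroids
#'
#' The centroid of a phenotype is the arithmetic mean of its members' feature
#' vectors (cell-type enrichment scores by default, or signature-gene
#' expression for cohorts without full transcriptomes).
#'
#' @param features Feature x sample numeric matrix.
#' @param labels Named character vector of phenotype labels for the samples.
#' @return Object of class \code{time_centroids}: a feature x phenotype
#'   matrix with attribute \code{n_training}.
#' @export
build_centroids <- function(features, labels) {
  labels <- labels[colnames(features)]
  if (anyNA(labels)) stop("every sample must be labeled")
  phen <- sort(unique(as.character(labels)))
  if (length(phen) < 2) stop("need at least 2 phenotypes")
  sizes <- table(factor(labels, levels = phen))
  if (any(sizes == 0)) stop("phenotype with 0 samples")
  cents <- vapply(phen, function(p)
    rowMeans(features[, labels == p, drop = FALSE]), numeric(nrow(features)))
  rownames(cents) <- rownames(features)
  structure(cents, n_training = as.integer(sizes), class = "time_centroids")
}

#' Classify a single sample by nearest centroid
#'
#' Assigns the phenotype whose centroid has the highest Pearson correlation
#' with the sample's feature vector on the shared features. Ties are broken
#' toward the lower phenotype index and flagged. A margin (best minus
#' second-best correlation) below \code{low_confidence_margin} is flagged as a
#' low-confidence call rather than refused. Pearson correlation is invariant
#' to affine rescaling of the sample vector.
#'
#' @param sample_features Named numeric vector of features for one sample.
#' @param centroids A \code{time_centroids} object (or feature x phenotype
#'   matrix).
#' @param low_confidence_margin Margin below which the call is flagged
#'   (default 0.05).
#' @return list: phenotype, correlations (named), margin, tie,
#'   low_confidence.
#' @export
classify_sample <- function(sample_features, centroids,
                            low_confidence_margin = 0.05) {
  feats <- intersect(names(sample_features), rownames(centroids))
  if (length(feats) < 3)
    stop("need at least 3 features shared with the centroids")
  x <- sample_features[feats]
  if (stats::sd(x) == 0)
    stop("zero-variance sample vector; correlation undefined")
  cors <- stats::cor(x, centroids[feats, , drop = FALSE])[1, ]
  ord <- order(cors, decreasing = TRUE)
  margin <- if (length(cors) > 1) cors[ord[1]] - cors[ord[2]] else NA_real_
  tie <- isTRUE(margin == 0)
  best <- which(cors == max(cors))[1]   # ties toward lower phenotype index
  list(phenotype = colnames(centroids)[best], correlations = cors,
       margin = unname(margin), tie = tie,
       low_confidence = isTRUE(margin < low_confidence_margin))
}

#' Classify new samples against phenotype centroids
#'
#' @param object A \code{time_centroids} object.
#' @param newdata Feature x sample matrix of new samples.
#' @param ... Passed to [classify_sample()].
#' @return data.frame with one row per sample: sample, phenotype, margin,
#'   tie, low_confidence, plus one correlation column per phenotype.
#' @export
predict.time_centroids <- function(object, newdata, ...) {
  calls <- lapply(colnames(newdata), function(s) {
    v <- newdata[, s]
    names(v) <- rownames(newdata)
    classify_sample(v, object, ...)
  })
  out <- data.frame(sample = colnames(newdata),
                    phenotype = vapply(calls, `[[`, "", "phenotype"),
                    margin = vapply(calls, `[[`, 0, "margin"),
                    tie = vapply(calls, `[[`, FALSE, "tie"),
                    low_confidence = vapply(calls, `[[`, FALSE,
                                            "low_confidence"),
                    row.names = NULL, stringsAsFactors = FALSE)
  cors <- t(vapply(calls, `[[`, numeric(ncol(object)), "correlations"))
  colnames(cors) <- paste0("cor_", colnames(object))
  cbind(out, cors)
}

#' @export
print.time_centroids <- function(x, ...) {
  cat("Phenotype centroids:", ncol(x), "phenotypes over", nrow(x),
      "features\n")
  cat("  phenotypes:", paste(colnames(x), collapse = ", "), "\n")
  cat("  training sizes:", paste(attr(x, "n_training"), collapse = "/"), "\n")
  invisible(x)
}

#' Write/read centroid models as portable TSV
#'
#' @param centroids A \code{time_centroids} object.
#' @param path File path.
#' @return The path (write) or a \code{time_centroids} object (read).
#' @export
write_centroids <- function(centroids, path) {
  write_matrix_tsv(unclass(centroids), path, id_column = "feature")
}

#' @rdname write_centroids
#' @export
read_centroids <- function(path) {
  m <- read_matrix_tsv(path)
  structure(m, class = "time_centroids")
}
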