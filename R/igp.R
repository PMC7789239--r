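#' In-group proportion (IGP) cross-cohort validation
#'
#' Tests whether clusters discovered in one cohort reproduce in a second:
#' validation samples are assigned to the nearest discovery centroid under
#' Pearson correlation, and the IGP of a cluster is the fraction of its
#' validation samples whose nearest validation neighbour (distance =
#' 1 - Pearson) carries the same label. Significance comes from a
#' centroid-rotation permutation null: in each permutation the centred
#' discovery centroids are rotated by a random orthogonal matrix, validation
#' samples are re-assigned, and the permuted IGP is recomputed; the p-value is
#' the fraction of permutations with IGP at least as large as observed (with
#' the +1 correction, so p is in (0, 1]).
#'
#' When \code{validation_labels} is supplied the centroid-assignment step is
#' skipped and the IGP of those labels is evaluated directly (a diagnostic
#' mode: e.g. shuffled labels on well-mixed data give IGP near 0.5); the
#' permutation null is then a label permutation instead of a centroid
#' rotation.
#'
#' @param discovery_scores Feature x sample matrix of the discovery cohort.
#' @param discovery_labels Named character/factor vector of cluster labels for
#'   the discovery samples.
#' @param validation_scores Feature x sample matrix of the validation cohort;
#'   features must overlap the discovery features.
#' @param n_permutations Number of permutations (default 1000).
#' @param seed Optional integer seed.
#' @param validation_labels Optional named label vector for the validation
#'   samples, replacing nearest-centroid assignment (see above).
#' @return data.frame with one row per cluster: \code{cluster}, \code{n}
#'   (validation samples assigned), \code{igp} (NA when fewer than 2 samples
#'   were assigned), \code{p_value}, \code{n_permutations}.
#' @export
igp_validate <- function(discovery_scores, discovery_labels,
                         validation_scores, n_permutations = 1000,
                         seed = NULL, validation_labels = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  feats <- intersect(rownames(discovery_scores), rownames(validation_scores))
  if (length(feats) < 3)
    stop("need at least 3 shared features between cohorts")
  disc <- discovery_scores[feats, , drop = FALSE]
  val <- validation_scores[feats, , drop = FALSE]
  labels <- as.character(discovery_labels)
  names(labels) <- names(discovery_labels)
  if (!is.null(names(labels)) && all(names(labels) %in% colnames(disc)))
    disc <- disc[, names(labels), drop = FALSE]
  else if (length(labels) != ncol(disc))
    stop("discovery labels do not match discovery samples")
  clusters <- sort(unique(labels))
  centroids <- vapply(clusters, function(cl)
    rowMeans(disc[, labels == cl, drop = FALSE]), numeric(length(feats)))
  # nearest validation neighbour under 1 - Pearson, fixed across permutations
  vc <- stats::cor(val)
  diag(vc) <- -Inf
  nn <- apply(vc, 2, which.max)
  igp_of <- function(assigned) {
    igp <- stats::setNames(rep(NA_real_, length(clusters)), clusters)
    for (cl in clusters) {
      members <- which(assigned == cl)
      if (length(members) >= 2)
        igp[cl] <- mean(assigned[nn[members]] == cl)
    }
    igp
  }
  assign_to <- function(cents) {
    cc <- stats::cor(val, cents)
    clusters[max.col(cc, ties.method = "first")]
  }
  if (is.null(validation_labels)) {
    assigned_obs <- assign_to(centroids)
  } else {
    vl <- as.character(validation_labels)
    names(vl) <- names(validation_labels)
    assigned_obs <- unname(vl[colnames(val)])
    if (anyNA(assigned_obs))
      stop("validation_labels must cover every validation sample")
  }
  obs <- igp_of(assigned_obs)
  nobs <- table(factor(assigned_obs, levels = clusters))
  exceed <- stats::setNames(rep(0, length(clusters)), clusters)
  counted <- stats::setNames(rep(0, length(clusters)), clusters)
  center <- rowMeans(val)
  centred <- centroids - center
  p <- length(feats)
  for (b in seq_len(n_permutations)) {
    assigned_perm <- if (is.null(validation_labels)) {
      q <- qr.Q(qr(matrix(stats::rnorm(p * p), p, p)))
      assign_to(q %*% centred + center)
    } else {
      sample(assigned_obs)
    }
    perm <- igp_of(assigned_perm)
    for (cl in clusters) {
      if (!is.na(obs[cl])) {
        counted[cl] <- counted[cl] + 1
        if (!is.na(perm[cl]) && perm[cl] >= obs[cl])
          exceed[cl] <- exceed[cl] + 1
      }
    }
  }
  pval <- ifelse(is.na(obs), NA_real_, (exceed + 1) / (counted + 1))
  data.frame(cluster = clusters, n = as.integer(nobs),
             igp = unname(obs), p_value = unname(pval),
             n_permutations = n_permutations, row.names = NULL,
             stringsAsFactors = FALSE)
}
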