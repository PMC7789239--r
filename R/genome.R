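#' Fraction of genome altered, gained and lost
#'
#' From copy-number segments (segment mean = log2(copy-number/2)), computes
#' per sample the fraction of the genome basis covered by gained segments
#' (mean strictly above \code{amp_threshold}), lost segments (mean strictly
#' below \code{del_threshold}) and their sum: FGA = FGG + FGL by construction.
#' Segment length is end - start + 1 (1-based inclusive coordinates).
#'
#' @param segments data.frame as from [read_seg()]: sample, chromosome,
#'   start, end, segment_mean.
#' @param amp_threshold Gain threshold on the segment mean (default 0.2).
#' @param del_threshold Loss threshold (default -0.2).
#' @param chrom_sizes Named numeric vector of chromosome lengths defining the
#'   genome basis (conventionally autosomes only).
#' @return data.frame: sample, fga, fgg, fgl, plus attributes
#'   \code{genome_length} and \code{thresholds}.
#' @export
genome_fractions <- function(segments, amp_threshold = 0.2,
                             del_threshold = -0.2, chrom_sizes) {
  stopifnot(del_threshold < 0, amp_threshold > 0)
  if (any(segments$end < segments$start)) stop("segment with end < start")
  if (is.null(names(chrom_sizes))) stop("chrom_sizes must be named")
  segments <- segments[segments$chromosome %in% names(chrom_sizes), ,
                       drop = FALSE]
  if (any(segments$start < 1 |
            segments$end > chrom_sizes[segments$chromosome]))
    stop("segment beyond chromosome length")
  # per-sample, per-chromosome overlap check
  by_sc <- split(segments, list(segments$sample, segments$chromosome),
                 drop = TRUE)
  for (blk in by_sc) {
    if (nrow(blk) < 2) next
    o <- order(blk$start)
    if (any(blk$start[o][-1] <= blk$end[o][-nrow(blk)]))
      stop("overlapping segments within one sample and chromosome")
  }
  genome <- sum(chrom_sizes)
  len <- segments$end - segments$start + 1
  gained <- segments$segment_mean > amp_threshold
  lost <- segments$segment_mean < del_threshold
  samples <- unique(segments$sample)
  fgg <- vapply(samples, function(s)
    sum(len[gained & segments$sample == s]) / genome, numeric(1))
  fgl <- vapply(samples, function(s)
    sum(len[lost & segments$sample == s]) / genome, numeric(1))
  out <- data.frame(sample = samples, fga = fgg + fgl, fgg = fgg, fgl = fgl,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "genome_length") <- genome
  attr(out, "thresholds") <- c(amp = amp_threshold, del = del_threshold)
  out
}

#' Map copy-number segments to gene-level gain/loss events
#'
#' Convenience plumbing for downstream enrichment tests: a gene is called
#' gained (lost) in a sample when any overlapping segment has a mean above
#' (below) the threshold.
#'
#' @param segments Segment data.frame (sample, chromosome, start, end,
#'   segment_mean).
#' @param gene_table data.frame with columns gene, chromosome, start, end.
#' @param amp_threshold,del_threshold Segment-mean thresholds.
#' @return list of two gene x sample logical matrices: \code{gain},
#'   \code{loss}.
#' @export
segments_to_gene_events <- function(segments, gene_table,
                                    amp_threshold = 0.2,
                                    del_threshold = -0.2) {
  samples <- unique(segments$sample)
  gain <- loss <- matrix(FALSE, nrow(gene_table), length(samples),
                         dimnames = list(gene_table$gene, samples))
  for (i in seq_len(nrow(gene_table))) {
    g <- gene_table[i, ]
    ov <- segments$chromosome == g$chromosome &
      segments$start <= g$end & segments$end >= g$start
    if (!any(ov)) next
    sub <- segments[ov, ]
    gain[i, unique(sub$sample[sub$segment_mean > amp_threshold])] <- TRUE
    loss[i, unique(sub$sample[sub$segment_mean < del_threshold])] <- TRUE
  }
  list(gain = gain, loss = loss)
}

# Multiplicative-update NMF minimising generalized KL divergence.
# Returns list(W, H, kl) for one initialisation.
nmf_kl <- function(v, r, max_iter = 500, tol = 1e-6) {
  n <- nrow(v); m <- ncol(v)
  w <- matrix(stats::runif(n * r, 0.1, 1), n, r)
  h <- matrix(stats::runif(r * m, 0.1, 1), r, m)
  eps <- .Machine$double.eps
  kl_old <- Inf
  for (it in seq_len(max_iter)) {
    wh <- w %*% h
    h <- h * (t(w) %*% (v / (wh + eps))) / (colSums(w) + eps)
    wh <- w %*% h
    w <- w * ((v / (wh + eps)) %*% t(h)) / rep(rowSums(h) + eps,
                                               each = n)
    wh <- w %*% h
    kl <- sum(ifelse(v > 0, v * log(v / (wh + eps)), 0) - v + wh)
    if (is.finite(kl_old) && abs(kl_old - kl) < tol * (abs(kl_old) + eps))
      break
    kl_old <- kl
  }
  list(W = w, H = h, kl = kl)
}

#' Extract mutational signatures by NMF
#'
#' Factorises a 96-context mutation count matrix V (contexts x samples) into
#' non-negative signatures S (96 x r, columns summing to 1) and exposures E
#' (r x samples) by multiplicative-update NMF under generalized
#' Kullback-Leibler divergence, with multiple random restarts per rank. The
#' factorisation rank is selected by the elbow of the reconstruction error:
#' a baseline fit at one rank below the scanned range anchors the marginal
#' gain of each added signature, and the smallest rank whose next signature
#' improves the fit by less than \code{elbow_alpha} of its own gain is
#' chosen. When exposures concentrate on discrete sample groups the Brunet
#' cophenetic correlation of the restart-consensus is informative too; it is
#' computed and reported per rank, and used as the fallback selector when no
#' elbow exists. When even the first scanned rank adds little over the
#' baseline, the data support fewer signatures than the scanned floor and
#' the result is flagged (\code{rank_floor}).
#'
#' @param contexts Non-negative count matrix, 96 contexts x samples. All-zero
#'   samples are dropped with a warning.
#' @param rank_range Candidate ranks (default 2:5); every rank must be below
#'   the number of samples.
#' @param n_restarts Random restarts per rank (default 30).
#' @param seed Optional integer seed; the same seed reproduces the
#'   factorisation exactly.
#' @param max_iter,tol Convergence controls for the multiplicative updates.
#' @param elbow_alpha Relative-gain threshold defining the elbow
#'   (default 0.1).
#' @return Object of class \code{signature_set}: list with \code{signatures}
#'   (96 x r), \code{exposures} (r x samples), \code{rank},
#'   \code{cophenetic} (per rank), \code{reconstruction_error} (per rank,
#'   generalized KL, including the baseline rank), \code{rank_range},
#'   \code{rank_floor}, \code{elbow_found}.
#' @export
extract_mutation_signatures <- function(contexts, rank_range = 2:5,
                                        n_restarts = 30, seed = NULL,
                                        max_iter = 2000, tol = 1e-9,
                                        elbow_alpha = 0.1) {
  if (any(contexts < 0)) stop("negative counts")
  zero <- colSums(contexts) == 0
  if (any(zero)) {
    warning(sprintf("dropping %d all-zero sample(s)", sum(zero)))
    contexts <- contexts[, !zero, drop = FALSE]
  }
  if (ncol(contexts) < 2) stop("need at least 2 samples with mutations")
  if (sum(contexts) <= 0) stop("total mutation count must be positive")
  rank_range <- sort(unique(as.integer(rank_range)))
  if (max(rank_range) >= ncol(contexts))
    stop("rank must be smaller than the number of samples")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  v <- as.matrix(contexts)
  m <- ncol(v)
  base_rank <- max(1L, min(rank_range) - 1L)
  ranks_eval <- unique(c(base_rank, rank_range))
  coph <- stats::setNames(rep(NA_real_, length(rank_range)),
                          paste0("r", rank_range))
  err <- stats::setNames(numeric(length(ranks_eval)),
                         paste0("r", ranks_eval))
  best_fits <- vector("list", length(rank_range))
  for (ri in seq_along(ranks_eval)) {
    r <- ranks_eval[ri]
    in_range <- r %in% rank_range
    consensus <- matrix(0, m, m)
    best <- NULL
    for (b in seq_len(n_restarts)) {
      fit <- nmf_kl(v, r, max_iter = max_iter, tol = tol)
      dom <- apply(fit$H, 2, which.max)
      consensus <- consensus + outer(dom, dom, "==")
      if (is.null(best) || fit$kl < best$kl) best <- fit
    }
    err[ri] <- best$kl
    if (in_range) {
      ki <- match(r, rank_range)
      best_fits[[ki]] <- best
      consensus <- consensus / n_restarts
      d <- stats::as.dist(1 - consensus)
      coph[ki] <- if (stats::sd(as.vector(d)) == 0) {
        1  # perfectly stable (or degenerate) consensus
      } else {
        hc <- stats::hclust(d, method = "average")
        stats::cor(d, stats::cophenetic(hc))
      }
    }
  }
  # marginal KL gain of each scanned rank over the previous one
  gains <- -diff(err[paste0("r", c(base_rank, rank_range))])
  gains <- pmax(gains, 0)
  names(gains) <- paste0("r", rank_range)
  elbow_found <- FALSE
  sel <- length(rank_range)
  if (length(rank_range) > 1) {
    for (ri in seq_len(length(rank_range) - 1)) {
      if (gains[ri + 1] < elbow_alpha * gains[ri]) {
        sel <- ri
        elbow_found <- TRUE
        break
      }
    }
  } else {
    sel <- 1L
    elbow_found <- TRUE
  }
  if (!elbow_found) sel <- which.max(coph)  # fallback on restart stability
  fit <- best_fits[[sel]]
  scale <- colSums(fit$W)
  signatures <- sweep(fit$W, 2, scale, "/")
  exposures <- sweep(fit$H, 1, scale, "*")
  rownames(signatures) <- rownames(contexts)
  colnames(signatures) <- rownames(exposures) <-
    paste0("signature_", seq_len(rank_range[sel]))
  colnames(exposures) <- colnames(contexts)
  # duplicated extracted signatures mean the effective rank is below the
  # scanned floor (e.g. one planted signature scanned from rank 2 up)
  nrm <- sweep(signatures, 2, sqrt(colSums(signatures^2)), "/")
  cs <- crossprod(nrm)
  rank_floor <- any(cs[upper.tri(cs)] > 0.98)
  if (rank_floor)
    warning("near-duplicate signatures extracted; the true number of ",
            "signatures may lie below the scanned rank range")
  structure(list(signatures = signatures, exposures = exposures,
                 rank = rank_range[sel], cophenetic = coph,
                 reconstruction_error = err, gains = gains,
                 rank_range = rank_range, elbow_found = elbow_found,
                 rank_floor = rank_floor),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat("Mutational signature set: rank", x$rank, "over",
      ncol(x$exposures), "samples\n")
  cat("  cophenetic by rank:",
      paste(sprintf("%s=%.3f", names(x$cophenetic), x$cophenetic),
            collapse = " "), "\n")
  if (!is.null(x$matches)) {
    cat("  reference matches:\n")
    print(x$matches)
  }
  invisible(x)
}

#' Cosine-match extracted signatures to a reference catalogue
#'
#' Computes the cosine similarity of every extracted signature against every
#' reference column and names each after its best match when the cosine meets
#' \code{naming_cosine}, otherwise "unassigned". Row (context) order must be
#' identical between the two matrices.
#'
#' @param signatures A \code{signature_set} or a 96 x r non-negative matrix.
#' @param reference 96 x m reference catalogue matrix with matching rownames.
#' @param naming_cosine Minimum cosine for naming (default 0.8).
#' @return data.frame: signature, best_match, cosine, assigned.
#' @export
match_reference_signatures <- function(signatures, reference,
                                       naming_cosine = 0.8) {
  sig <- if (inherits(signatures, "signature_set")) signatures$signatures
         else signatures
  if (!identical(rownames(sig), rownames(reference)))
    stop("context row order differs between signatures and reference")
  norm_cols <- function(m) sweep(m, 2, sqrt(colSums(m^2)), "/")
  cs <- t(norm_cols(sig)) %*% norm_cols(reference)
  best <- max.col(cs, ties.method = "first")
  data.frame(signature = colnames(sig),
             best_match = colnames(reference)[best],
             cosine = cs[cbind(seq_len(nrow(cs)), best)],
             assigned = cs[cbind(seq_len(nrow(cs)), best)] >= naming_cosine,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Canonical 96 trinucleotide-context labels
#'
#' Labels in the conventional catalogue order: substitutions C>A, C>G, C>T,
#' T>A, T>C, T>G, each with 16 flanking-base combinations, formatted like
#' \code{"A[C>A]A"}.
#'
#' @return Character vector of length 96.
#' @export
context_labels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s)
    as.vector(t(outer(bases, bases, function(p, q)
      paste0(p, "[", s, "]", q))))))
}

#' Load the packaged reference signature catalogue
#'
#' A deterministic synthetic 96 x 30 catalogue in the layout of the COSMIC v2
#' single-base-substitution catalogue (30 columns named signature_1..30,
#' probabilities summing to 1 per column). It is a synthetic stand-in meant
#' for pipeline exercise and testing; substitute a real catalogue file via
#' \code{path} for biological interpretation.
#'
#' @param path Optional path to a user catalogue TSV (contexts x signatures).
#' @return Numeric matrix with 96 context rows.
#' @export
reference_signature_catalog <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "signature_catalog_synthetic.tsv",
                        package = "timephen")
  m <- read_matrix_tsv(path)
  if (nrow(m) != 96) stop("catalogue must have 96 context rows")
  m
}
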