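#' Configuration for the synthetic multi-omic cohort generator
#'
#' Collects the generator's parameters with validation. Defaults emulate a
#' three-phenotype immune-infiltration structure: TIME-1 has no marker-gene
#' shift (immune-deficient), TIME-2 an intermediate shift with an extra boost
#' on immunosuppressive cell sets (Treg, Th17), TIME-3 the largest shift
#' (immune-activated); hazards decrease from TIME-1 to TIME-3.
#'
#' @param n_per_phenotype Integer vector of samples per phenotype
#'   (default 50/50/50; each must be >= 2).
#' @param n_genes Total genes in the expression universe (default 5000).
#' @param n_cell_types Number of immune cell-type marker sets (default 24).
#' @param markers_per_set Genes per marker set, pairwise disjoint
#'   (default 30).
#' @param infiltration_effect Mean log2 shift of marker genes per phenotype
#'   (default 0 / 0.8 / 1.6 for TIME-1/2/3). Within a phenotype the shift is
#'   spread across cell-type sets with fixed weights in
#'   \code{set_weight_range}, so phenotypes differ in profile shape as well
#'   as level; the mean shift over sets equals the stated effect.
#' @param suppressive_boost Shift applied to suppressive-cell sets in TIME-2
#'   instead of the overall TIME-2 effect (default 1.6). Phenotypes above the
#'   intermediate one get no suppressive-set shift at all: the top phenotype
#'   is effector-high but suppressive-low, the intermediate one
#'   suppressive-high — the hallmark immune-suppressed profile.
#' @param suppressive_sets Names of the suppressive-cell sets (default Treg
#'   and Th17).
#' @param set_weight_range Range of the per-set effect weights (default
#'   c(0.6, 1.4), mean 1).
#' @param phenotype_heterogeneity_sd SD of a per-sample infiltration random
#'   effect added to all marker genes (default 0.25 log2 units), emulating
#'   purity and biological within-phenotype variation; identical across
#'   phenotypes.
#' @param noise_sd Residual gaussian SD on log2 expression (default 1.0).
#' @param survival_hazard_ratios Per-phenotype hazard multipliers (default
#'   2.0 / 1.4 / 1.0 for TIME-1/2/3).
#' @param baseline_hazard Exponential baseline hazard per time unit
#'   (default 0.03, months scale).
#' @param censor_time Administrative censoring horizon (default 120).
#' @param n_silenced_genes Genes with planted methylation silencing
#'   (default 20).
#' @param probes_per_gene Probes per methylation-annotated gene (default 3).
#' @param silencing_effect_sd Expression suppression of silenced genes, in
#'   units of noise_sd (default 2.5, comfortably above the 1.64-SD calling
#'   rule).
#' @param n_signatures_planted Mutational signatures mixed into the
#'   96-context counts (default 2).
#' @param mutations_per_sample Expected mutation count per sample
#'   (default 200).
#' @param n_mirna miRNAs simulated (default 30).
#' @param n_regulated_targets Genes with planted miRNA negative regulation
#'   (default 10).
#' @param marker_sets Optional user-supplied named list of marker sets
#'   (checked for disjointness); by default disjoint sets are carved from the
#'   gene universe.
#' @param seed Integer seed; the same configuration and seed give a
#'   byte-identical bundle.
#' @return Object of class \code{cohort_config} (a validated list).
#' @export
cohort_config <- function(n_per_phenotype = c(50, 50, 50), n_genes = 5000,
                          n_cell_types = 24, markers_per_set = 30,
                          infiltration_effect = c(0, 0.8, 1.6),
                          suppressive_boost = 1.6,
                          suppressive_sets = c("Treg", "Th17_cells"),
                          set_weight_range = c(0.6, 1.4),
                          phenotype_heterogeneity_sd = 0.25,
                          noise_sd = 1.0,
                          survival_hazard_ratios = c(2.0, 1.4, 1.0),
                          baseline_hazard = 0.03, censor_time = 120,
                          n_silenced_genes = 20, probes_per_gene = 3,
                          silencing_effect_sd = 2.5,
                          n_signatures_planted = 2,
                          mutations_per_sample = 200, n_mirna = 30,
                          n_regulated_targets = 10, marker_sets = NULL,
                          seed = 1) {
  n_phen <- length(n_per_phenotype)
  if (n_phen < 2) stop("need at least 2 phenotypes")
  if (any(n_per_phenotype < 2)) stop("n_per_phenotype must be >= 2")
  stopifnot(n_genes > 0, n_cell_types > 0, markers_per_set > 0,
            length(set_weight_range) == 2, all(set_weight_range > 0),
            diff(set_weight_range) >= 0, phenotype_heterogeneity_sd >= 0,
            noise_sd > 0, baseline_hazard > 0, censor_time > 0,
            n_silenced_genes >= 0, probes_per_gene >= 1,
            n_signatures_planted >= 1, n_mirna >= 0,
            length(infiltration_effect) == n_phen,
            length(survival_hazard_ratios) == n_phen)
  if (is.null(marker_sets)) {
    need <- n_cell_types * markers_per_set
    if (need + 3 * n_silenced_genes + n_regulated_targets > n_genes)
      stop("gene universe too small for the requested structure")
  } else {
    if (length(marker_sets) != n_cell_types)
      stop("marker_sets length must equal n_cell_types")
    all_m <- unlist(marker_sets)
    if (anyDuplicated(all_m))
      stop("configuration error: marker sets must be pairwise disjoint")
  }
  structure(list(n_per_phenotype = as.integer(n_per_phenotype),
                 n_genes = as.integer(n_genes),
                 n_cell_types = as.integer(n_cell_types),
                 markers_per_set = as.integer(markers_per_set),
                 infiltration_effect = infiltration_effect,
                 suppressive_boost = suppressive_boost,
                 suppressive_sets = suppressive_sets,
                 set_weight_range = set_weight_range,
                 phenotype_heterogeneity_sd = phenotype_heterogeneity_sd,
                 noise_sd = noise_sd,
                 survival_hazard_ratios = survival_hazard_ratios,
                 baseline_hazard = baseline_hazard,
                 censor_time = censor_time,
                 n_silenced_genes = as.integer(n_silenced_genes),
                 probes_per_gene = as.integer(probes_per_gene),
                 silencing_effect_sd = silencing_effect_sd,
                 n_signatures_planted = as.integer(n_signatures_planted),
                 mutations_per_sample = mutations_per_sample,
                 n_mirna = as.integer(n_mirna),
                 n_regulated_targets = as.integer(n_regulated_targets),
                 marker_sets = marker_sets, seed = as.integer(seed)),
            class = "cohort_config")
}

#' The 24 immune cell-type names used by the generator
#' @return Character vector of length 24.
#' @export
cell_type_names <- function() {
  c("aDC", "B_cells", "CD8_T_cells", "Cytotoxic_cells", "DC", "Eosinophils",
    "iDC", "Macrophages", "Mast_cells", "Neutrophils",
    "NK_CD56bright_cells", "NK_CD56dim_cells", "NK_cells", "pDC", "T_cells",
    "T_helper_cells", "Tcm", "Tem", "TFH", "Tgd", "Th1_cells", "Th2_cells",
    "Th17_cells", "Treg")
}

#' Autosome lengths used as the synthetic genome basis
#'
#' Approximate human autosome lengths (bp), the default genome basis for
#' fraction-of-genome computations on synthetic segments.
#'
#' @return Named numeric vector, chr1..chr22.
#' @export
autosome_sizes <- function() {
  stats::setNames(
    c(248e6, 242e6, 198e6, 190e6, 181e6, 171e6, 159e6, 145e6, 138e6, 134e6,
      135e6, 133e6, 114e6, 107e6, 102e6, 90e6, 83e6, 80e6, 59e6, 64e6,
      47e6, 51e6),
    paste0("chr", 1:22))
}

#' Simulate a multi-omic cohort with known ground truth
#'
#' Generates, under one seed, the full input bundle of the phenotyping
#' pipeline: a log2 expression matrix with three (by default) latent
#' phenotypes expressed as mean shifts on disjoint immune marker sets, a
#' methylation beta matrix with planted epigenetically silenced genes,
#' matched-normal mean betas, copy-number segments with phenotype-dependent
#' alteration burden, a 96-context mutation count matrix mixing planted
#' signatures with Poisson noise, miRNA expression with planted negative
#' regulation of selected targets, a binding-prediction table, and an
#' exponential survival table whose hazards follow the configured per-
#' phenotype ratios.
#'
#' @param config A [cohort_config()] object.
#' @return Object of class \code{cohort_bundle}: list with elements
#'   \code{expression}, \code{latent_labels}, \code{marker_sets},
#'   \code{beta}, \code{normal_beta}, \code{probe_map}, \code{silenced_genes},
#'   \code{segments}, \code{chrom_sizes}, \code{contexts},
#'   \code{planted_signatures}, \code{planted_exposures}, \code{mirna},
#'   \code{binding}, \code{regulated_pairs}, \code{clinical}, \code{config}.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)

  n_phen <- length(config$n_per_phenotype)
  phen_names <- paste0("TIME-", seq_len(n_phen))
  n <- sum(config$n_per_phenotype)
  samples <- sprintf("S%03d", seq_len(n))
  labels <- stats::setNames(rep(phen_names, config$n_per_phenotype), samples)

  genes <- sprintf("g%05d", seq_len(config$n_genes))
  # marker sets: disjoint blocks at the front of the universe
  if (is.null(config$marker_sets)) {
    set_names <- if (config$n_cell_types == 24) cell_type_names()
                 else sprintf("cell_type_%02d", seq_len(config$n_cell_types))
    marker_sets <- split(
      genes[seq_len(config$n_cell_types * config$markers_per_set)],
      rep(seq_len(config$n_cell_types), each = config$markers_per_set))
    names(marker_sets) <- set_names
  } else {
    marker_sets <- config$marker_sets
  }
  marker_genes <- unlist(marker_sets)
  suppressive <- intersect(config$suppressive_sets, names(marker_sets))
  if (length(suppressive) == 0 && length(marker_sets) >= 3) {
    # custom set names: designate the first two sets as the suppressive
    # compartment so the intermediate phenotype keeps a distinct shape
    suppressive <- names(marker_sets)[1:2]
  }

  # expression: baseline + shaped phenotype shift on markers + per-sample
  # infiltration heterogeneity + noise. Baselines are a deterministic
  # property of gene identity (drawn under a fixed internal seed before the
  # cohort stream starts) so that independently seeded cohorts share
  # gene-level baselines, as real cohorts do; everything else is seed-driven.
  set.seed(20200106L)
  baseline <- stats::runif(config$n_genes, 4, 10)
  set.seed(config$seed)
  expr <- matrix(stats::rnorm(config$n_genes * n, sd = config$noise_sd),
                 config$n_genes, n, dimnames = list(genes, samples)) +
    baseline
  shift <- stats::setNames(config$infiltration_effect, phen_names)
  n_sets <- length(marker_sets)
  w <- seq(config$set_weight_range[1], config$set_weight_range[2],
           length.out = n_sets)
  set_shift <- outer(w, shift)
  dimnames(set_shift) <- list(names(marker_sets), phen_names)
  if (n_phen >= 2 && length(suppressive) && shift[phen_names[2]] != 0) {
    # suppressive cells peak in the intermediate phenotype and are absent
    # from the more activated ones; with an all-zero infiltration effect
    # nothing is planted at all
    set_shift[suppressive, phen_names[2]] <- config$suppressive_boost
    if (n_phen > 2)
      set_shift[suppressive, phen_names[3:n_phen]] <- 0
  }
  set_of_gene <- rep(names(marker_sets),
                     vapply(marker_sets, length, 1L))
  for (ph in phen_names) {
    cols <- which(labels == ph)
    expr[marker_genes, cols] <- expr[marker_genes, cols] +
      set_shift[set_of_gene, ph]
  }
  u <- stats::rnorm(n, sd = config$phenotype_heterogeneity_sd)
  expr[marker_genes, ] <- expr[marker_genes, ] +
    rep(u, each = length(marker_genes))

  # methylation: silenced genes + filter-exercising background probes
  nonmarker <- setdiff(genes, marker_genes)
  silenced_genes <- nonmarker[seq_len(config$n_silenced_genes)]
  n_bg <- config$n_silenced_genes          # variably methylated, no silencing
  bg_var_genes <- nonmarker[config$n_silenced_genes + seq_len(n_bg)]
  bg_normal_genes <- nonmarker[2 * config$n_silenced_genes + seq_len(n_bg)]
  ppg <- config$probes_per_gene
  mk_probes <- function(gs, tag) {
    data.frame(probe = paste0("cg_", tag, "_",
                              rep(gs, each = ppg), "_", seq_len(ppg)),
               gene = rep(gs, each = ppg), stringsAsFactors = FALSE)
  }
  map <- rbind(mk_probes(silenced_genes, "sil"),
               mk_probes(bg_var_genes, "var"),
               mk_probes(bg_normal_genes, "nrm"))
  beta <- matrix(stats::runif(nrow(map) * n, 0.02, 0.15), nrow(map), n,
                 dimnames = list(map$probe, samples))
  normal_beta <- stats::setNames(stats::runif(nrow(map), 0.02, 0.15),
                                 map$probe)
  for (g in silenced_genes) {
    meth_samples <- sample(samples, round(0.4 * n))
    prs <- map$probe[map$gene == g]
    beta[prs, meth_samples] <-
      stats::runif(length(prs) * length(meth_samples), 0.6, 0.95)
    expr[g, meth_samples] <- expr[g, meth_samples] -
      config$silencing_effect_sd * config$noise_sd
  }
  for (g in bg_var_genes) {               # methylated in ~30%, no silencing
    meth_samples <- sample(samples, round(0.3 * n))
    prs <- map$probe[map$gene == g]
    beta[prs, meth_samples] <-
      stats::runif(length(prs) * length(meth_samples), 0.5, 0.9)
  }
  nrm_probes <- map$probe[map$gene %in% bg_normal_genes]
  normal_beta[nrm_probes] <- stats::runif(length(nrm_probes), 0.4, 0.8)
  beta[nrm_probes, ] <- stats::runif(length(nrm_probes) * n, 0.3, 0.9)

  # copy-number segments: altered chromosome count scales with hazard rank
  sizes <- autosome_sizes()
  burden_by_phen <- stats::setNames(
    round(seq(8, 2, length.out = n_phen)), phen_names)
  seg_list <- vector("list", n)
  for (si in seq_len(n)) {
    s <- samples[si]
    n_alt <- burden_by_phen[[labels[[s]]]]
    alt_chroms <- sample(names(sizes), n_alt)
    rows <- lapply(names(sizes), function(ch) {
      L <- sizes[[ch]]
      if (ch %in% alt_chroms) {
        a <- floor(L * stats::runif(1, 0.2, 0.4))
        b <- floor(L * stats::runif(1, 0.6, 0.8))
        mean_alt <- sample(c(stats::runif(1, 0.3, 0.8),
                             -stats::runif(1, 0.3, 0.8)), 1)
        data.frame(sample = s, chromosome = ch,
                   start = c(1, a + 1, b + 1), end = c(a, b, L),
                   segment_mean = c(stats::rnorm(1, 0, 0.03), mean_alt,
                                    stats::rnorm(1, 0, 0.03)),
                   stringsAsFactors = FALSE)
      } else {
        data.frame(sample = s, chromosome = ch, start = 1, end = L,
                   segment_mean = stats::rnorm(1, 0, 0.03),
                   stringsAsFactors = FALSE)
      }
    })
    seg_list[[si]] <- do.call(rbind, rows)
  }
  segments <- do.call(rbind, seg_list)

  # mutation contexts: counts ~ Poisson(S %*% E)
  r <- config$n_signatures_planted
  sig <- matrix(stats::rgamma(96 * r, shape = 0.3), 96, r)
  sig <- sweep(sig, 2, colSums(sig), "/")
  rownames(sig) <- context_labels()
  colnames(sig) <- paste0("planted_", seq_len(r))
  expo <- matrix(stats::rgamma(r * n, shape = 2), r, n)
  expo <- sweep(expo, 2, colSums(expo), "/") *
    config$mutations_per_sample
  dimnames(expo) <- list(colnames(sig), samples)
  contexts <- matrix(stats::rpois(96 * n, lambda = sig %*% expo), 96, n,
                     dimnames = list(context_labels(), samples))

  # miRNA expression and planted negative regulation
  mirna_ids <- sprintf("miR-%03d", seq_len(config$n_mirna))
  mirna <- matrix(stats::rnorm(config$n_mirna * n, 5, 1), config$n_mirna, n,
                  dimnames = list(mirna_ids, samples))
  n_reg <- min(config$n_regulated_targets, config$n_mirna)
  reg_targets <- nonmarker[3 * config$n_silenced_genes + seq_len(n_reg)]
  reg_mirnas <- mirna_ids[seq_len(n_reg)]
  for (i in seq_len(n_reg)) {
    expr[reg_targets[i], ] <- expr[reg_targets[i], ] -
      0.8 * (mirna[reg_mirnas[i], ] - 5)
  }
  pool <- setdiff(nonmarker, reg_targets)
  n_decoy <- min(30, length(pool), 3 * max(1, config$n_mirna))
  decoys <- data.frame(
    mirna = sample(mirna_ids, n_decoy, replace = TRUE),
    gene = sample(pool, n_decoy),
    stringsAsFactors = FALSE)
  binding <- unique(rbind(
    data.frame(mirna = reg_mirnas, gene = reg_targets,
               stringsAsFactors = FALSE), decoys))

  # survival: exponential with per-phenotype hazard multipliers
  hr <- stats::setNames(config$survival_hazard_ratios, phen_names)
  rate <- config$baseline_hazard * hr[labels]
  t_event <- stats::rexp(n, rate = rate)
  time <- pmin(t_event, config$censor_time)
  clinical <- data.frame(sample = samples, time = time,
                         event = as.integer(t_event <= config$censor_time),
                         row.names = NULL, stringsAsFactors = FALSE)

  structure(list(expression = expr, latent_labels = labels,
                 marker_sets = marker_sets, set_shifts = set_shift,
                 suppressive_sets = suppressive, beta = beta,
                 normal_beta = normal_beta, probe_map = map,
                 silenced_genes = silenced_genes, segments = segments,
                 chrom_sizes = sizes, contexts = contexts,
                 planted_signatures = sig, planted_exposures = expo,
                 mirna = mirna, binding = binding,
                 regulated_pairs = data.frame(mirna = reg_mirnas,
                                              gene = reg_targets,
                                              stringsAsFactors = FALSE),
                 clinical = clinical, config = config),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("Synthetic multi-omic cohort:", ncol(x$expression), "samples,",
      nrow(x$expression), "genes\n")
  print(table(x$latent_labels))
  cat("  marker sets:", length(x$marker_sets),
      "| silenced genes:", length(x$silenced_genes),
      "| planted signatures:", ncol(x$planted_signatures),
      "| miRNAs:", nrow(x$mirna), "\n")
  invisible(x)
}

#' Write a cohort bundle to standard on-disk formats
#'
#' Serialises every bundle component to its conventional plain-text format
#' (TSV matrices, GMT marker sets, SEG segments) and returns a manifest with
#' MD5 checksums. A bundle generated under a fixed seed writes identical
#' checksums on every run.
#'
#' @param bundle A \code{cohort_bundle}.
#' @param directory Output directory (created if missing).
#' @return data.frame manifest: component, path, md5.
#' @export
write_fixtures <- function(bundle, directory) {
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  if (file.access(directory, 2) != 0) stop("directory not writable")
  p <- function(f) file.path(directory, f)
  write_matrix_tsv(bundle$expression, p("expression.tsv"), "gene")
  write_matrix_tsv(bundle$beta, p("beta.tsv"), "probe")
  utils::write.table(bundle$probe_map, p("probe_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(probe = names(bundle$normal_beta),
               mean_beta = unname(bundle$normal_beta)),
    p("normal_beta.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_seg(bundle$segments, p("segments.seg"))
  write_matrix_tsv(bundle$contexts, p("contexts.tsv"), "context")
  write_matrix_tsv(bundle$mirna, p("mirna.tsv"), "mirna")
  utils::write.table(bundle$binding, p("binding.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$clinical, p("clinical.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(bundle$marker_sets, p("immune_sets.gmt"))
  utils::write.table(
    data.frame(sample = names(bundle$latent_labels),
               phenotype = unname(bundle$latent_labels)),
    p("truth_labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c("expression.tsv", "beta.tsv", "probe_map.tsv",
             "normal_beta.tsv", "segments.seg", "contexts.tsv", "mirna.tsv",
             "binding.tsv", "clinical.tsv", "immune_sets.gmt",
             "truth_labels.tsv")
  data.frame(component = sub("\\.[a-z]+$", "", files),
             path = file.path(directory, files),
             md5 = unname(tools::md5sum(file.path(directory, files))),
             row.names = NULL, stringsAsFactors = FALSE)
}
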