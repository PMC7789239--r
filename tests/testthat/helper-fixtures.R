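# Shared small fixtures. Cohorts are generated once per test run; sizes are
# kept small so the full suite stays fast.

small_config <- function(seed = 1, ...) {
  cohort_config(n_per_phenotype = c(25, 25, 25), n_genes = 1200,
                n_cell_types = 8, markers_per_set = 20,
                n_silenced_genes = 10, n_mirna = 12,
                n_regulated_targets = 6, seed = seed, ...)
}

# one default-sized cohort reused by several files
default_bundle <- local({
  b <- NULL
  function() {
    if (is.null(b)) b <<- simulate_cohort(cohort_config(seed = 3))
    b
  }
})

small_bundle <- local({
  b <- NULL
  function() {
    if (is.null(b)) b <<- simulate_cohort(small_config(seed = 5))
    b
  }
})

# independent brute-force ssGSEA oracle: explicit per-position running sums
ssgsea_oracle <- function(expression, gene_set, alpha = 0.25) {
  stopifnot(!is.null(names(expression)))
  gene_set <- intersect(gene_set, names(expression))
  n <- length(expression)
  m <- length(gene_set)
  r <- rank(expression, ties.method = "average")
  ord <- order(expression, decreasing = TRUE)
  genes <- names(expression)[ord]
  denom_in <- sum(r[gene_set]^alpha)
  p_in <- 0; p_out <- 0; es <- 0
  for (i in seq_len(n)) {
    if (genes[i] %in% gene_set) {
      p_in <- p_in + r[ord[i]]^alpha / denom_in
    } else {
      p_out <- p_out + 1 / (n - m)
    }
    es <- es + (p_in - p_out)
  }
  unname(es)
}

# independent two-group log-rank oracle: explicit risk-set summation
logrank_oracle <- function(time, event, group) {
  g1 <- sort(unique(group))[1]
  o <- e <- v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o - e)^2 / v
}
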