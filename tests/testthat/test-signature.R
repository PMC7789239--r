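test_that("null genes get logFC 0 and p 1", {
  set.seed(1)
  expr <- matrix(rnorm(20 * 12), 20, 12,
                 dimnames = list(paste0("g", 1:20), paste0("s", 1:12)))
  expr["g1", ] <- 5  # constant gene
  labels <- stats::setNames(rep(c("TIME-1", "TIME-2"), each = 6),
                            colnames(expr))
  tab <- differential_expression(expr, labels, "TIME-1")
  row <- tab[tab$gene == "g1", ]
  expect_equal(row$logFC, 0)
  expect_equal(row$p_value, 1)
})

test_that("planted shifts are recovered and the unshrunk statistic is the pooled t", {
  set.seed(2)
  n1 <- 50; n2 <- 100
  expr <- matrix(rnorm(300 * (n1 + n2)), 300, n1 + n2,
                 dimnames = list(paste0("g", 1:300),
                                 paste0("s", 1:(n1 + n2))))
  planted <- paste0("g", 1:100)
  expr[planted, 1:n1] <- expr[planted, 1:n1] + 2
  labels <- stats::setNames(rep(c("TIME-3", "rest"), c(n1, n2)),
                            colnames(expr))
  tab <- differential_expression(expr, labels, "TIME-3")
  est <- tab$logFC[match(planted, tab$gene)]
  # the standard error of the mean difference is sqrt(1/50 + 1/100) = 0.173,
  # so a 2-SE band (0.35) should cover ~95% of the planted genes
  expect_gte(mean(abs(est - 2) < 0.35), 0.9)
  expect_lt(abs(mean(est) - 2), 0.05)
  # shrink = FALSE reproduces the classical pooled-variance t-test p-value
  tab0 <- differential_expression(expr, labels, "TIME-3", shrink = FALSE)
  for (g in c("g1", "g100", "g250")) {
    p_ref <- stats::t.test(expr[g, 1:n1], expr[g, n1 + 1:n2],
                           var.equal = TRUE)$p.value
    expect_equal(tab0$p_value[tab0$gene == g], p_ref, tolerance = 1e-10)
  }
})

test_that("DEG selection uses strict thresholds and unions across contrasts", {
  mk <- function(genes, lfc, p)
    data.frame(gene = genes, contrast = "x", logFC = lfc, p_value = p / 2,
               adj_p = p)
  t1 <- mk(c("a", "b"), c(1.6, 1.5), c(0.01, 0.01))
  expect_setequal(select_degs(t1), "a")       # 1.5 excluded (strict)
  t2 <- mk(c("c", "d", "e"), c(2, -2, 1.8), c(0.04, 0.04, 0.05))
  expect_setequal(select_degs(t2), c("c", "d"))  # p = 0.05 excluded
  t3 <- mk(c("f", "g", "h", "i"), c(3, 3, 3, 3), c(0.01, 0.01, 0.01, 0.01))
  expect_setequal(select_degs(list(t1, t2, t3)),
                  c("a", "c", "d", "f", "g", "h", "i"))
  expect_warning(out <- select_degs(mk("z", 0.1, 0.9)), "no gene")
  expect_length(out, 0)
  # threshold monotonicity endpoints
  expect_length(suppressWarnings(
    select_degs(t3, lfc_threshold = Inf, adjp_threshold = 1)), 0)
  expect_setequal(select_degs(t3, lfc_threshold = 0, adjp_threshold = 1),
                  t3$gene)
})

test_that("TI rises with signature expression and tracks phenotype order", {
  b <- small_bundle()
  degs <- select_degs(lapply(sort(unique(b$latent_labels)), function(ph)
    differential_expression(b$expression, b$latent_labels, ph)),
    lfc_threshold = 0.8)
  expect_gt(length(degs), 0)
  ti <- compute_ti(b$expression, degs)
  means <- tapply(ti$ti, b$latent_labels[ti$sample], mean)
  expect_true(means[["TIME-1"]] < means[["TIME-2"]])
  expect_true(means[["TIME-2"]] < means[["TIME-3"]])
})

test_that("single-gene TI ordering equals the gene's within-sample rank order", {
  # construct 8 samples where gene g7 sits at a different within-sample rank
  genes <- paste0("g", 1:30)
  expr <- matrix(0, 30, 8, dimnames = list(genes, paste0("s", 1:8)))
  others <- setdiff(genes, "g7")
  for (j in 1:8) {
    expr[others, j] <- 1:29
    expr["g7", j] <- 3 * j + 0.5   # within-sample rank increases with j
  }
  ti <- compute_ti(expr, "g7")
  r7 <- apply(expr, 2, function(x) rank(x)[["g7"]])
  expect_equal(order(ti$ti), order(r7))
  expect_true(all(diff(ti$ti[order(r7)]) > 0))
})

test_that("TI ignores permutations of non-signature genes within a sample", {
  set.seed(4)
  expr <- matrix(rnorm(40 * 5), 40, 5,
                 dimnames = list(paste0("g", 1:40), paste0("s", 1:5)))
  sig <- paste0("g", 1:6)
  ti1 <- compute_ti(expr, sig)
  expr2 <- expr
  others <- setdiff(rownames(expr), sig)
  # permute the VALUES of non-signature genes within each sample
  for (s in colnames(expr)) expr2[others, s] <- sample(expr[others, s])
  ti2 <- compute_ti(expr2, sig)
  expect_equal(ti1$ti, ti2$ti, tolerance = 1e-12)
})

test_that("optimal cutoff lands between separated prognostic groups", {
  set.seed(5)
  n <- 60
  ti <- stats::setNames(c(runif(n / 2, 0, 1), runif(n / 2, 2, 3)),
                        paste0("s", 1:n))
  rate <- ifelse(ti <= 1, 0.5, 0.05)   # low score, ten-fold hazard
  surv <- data.frame(sample = names(ti), time = rexp(n, rate), event = 1)
  oc <- optimal_cutoff(ti, surv)
  expect_gt(oc$cutoff, 1)
  expect_lt(oc$cutoff, 2)
  # exhaustive-scan oracle over the same admissible splits
  xs <- sort(ti)
  min_n <- ceiling(0.1 * n)
  stats_all <- vapply(min_n:(n - min_n), function(i) {
    cut <- (xs[i] + xs[i + 1]) / 2
    if (xs[i] == xs[i + 1]) return(NA_real_)
    survival::survdiff(survival::Surv(surv$time, surv$event) ~
                         (ti > cut))$chisq
  }, numeric(1))
  expect_equal(oc$statistic, max(stats_all, na.rm = TRUE))
})

test_that("degenerate cutoff inputs are rejected", {
  surv <- data.frame(sample = paste0("s", 1:10), time = 1:10,
                     event = rep(1, 10))
  expect_error(optimal_cutoff(stats::setNames(rep(1, 10), surv$sample), surv),
               "no admissible cutoff")
  ti <- stats::setNames(1:10, surv$sample)
  expect_error(optimal_cutoff(ti, transform(surv, event = 0)), "no events")
  # min_group_fraction 0.5 on 10 samples: only the median split remains
  oc <- optimal_cutoff(ti, surv, min_group_fraction = 0.5)
  expect_equal(oc$n_candidates, 1)
  expect_equal(oc$cutoff, 5.5)
})

test_that("log-rank matches an explicit risk-set summation on 6 patients", {
  surv <- data.frame(sample = paste0("p", 1:6),
                     time = c(2, 4, 6, 1, 3, 5),
                     event = c(1, 1, 0, 1, 0, 1))
  groups <- stats::setNames(rep(c("A", "B"), each = 3), surv$sample)
  res <- logrank_test(groups, surv)
  expect_equal(res$statistic,
               logrank_oracle(surv$time, surv$event, groups[surv$sample]),
               tolerance = 1e-10)
  expect_equal(res$df, 1)
})

test_that("identical survival in both groups gives a null statistic", {
  surv <- data.frame(sample = paste0("p", 1:8),
                     time = rep(c(1, 2, 3, 4), 2),
                     event = rep(1, 8))
  groups <- stats::setNames(rep(c("A", "B"), each = 4), surv$sample)
  res <- logrank_test(groups, surv)
  expect_equal(res$statistic, 0, tolerance = 1e-10)
  expect_equal(res$p_value, 1, tolerance = 1e-10)
  expect_error(logrank_test(groups[1:4], surv), "2 groups")
})

test_that("high-TI group has better survival on synthetic truth", {
  b <- default_bundle()
  degs <- select_degs(lapply(sort(unique(b$latent_labels)), function(ph)
    differential_expression(b$expression, b$latent_labels, ph)),
    lfc_threshold = 1)
  ti <- compute_ti(b$expression, degs)
  oc <- optimal_cutoff(ti, b$clinical)
  km <- split(b$clinical$time * ifelse(b$clinical$event == 1, 1, NA),
              oc$groups[b$clinical$sample])
  # median observed event time larger in the high-TI group
  expect_gt(stats::median(km$high, na.rm = TRUE),
            stats::median(km$low, na.rm = TRUE))
  expect_lt(oc$p_value, 0.05)
})
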