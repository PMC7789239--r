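test_that("gml is the per-sample mean beta with pairwise NA handling", {
  beta <- matrix(c(0.2, 0.4, 0.9, 0.5, 0.5, 0.5), 3, 2,
                 dimnames = list(paste0("p", 1:3), c("s1", "s2")))
  g <- gml(beta)
  expect_equal(unname(g), c(0.5, 0.5))
  expect_equal(unname(gml(beta, "p2")), c(0.4, 0.5))
  beta[1, 1] <- NA
  expect_equal(unname(gml(beta)["s1"]), mean(c(0.4, 0.9)))
  beta[, 2] <- NA
  expect_true(is.nan(gml(beta)["s2"]))
  expect_error(gml(beta - 2), "\\[0, 1\\]")
  # invariant to probe and sample order
  b <- small_bundle()
  g1 <- gml(b$beta)
  g2 <- gml(b$beta[sample(nrow(b$beta)), sample(ncol(b$beta))])
  expect_equal(g1, g2[names(g1)])
})

test_that("ESG caller applies the four criteria with documented boundaries", {
  samples <- paste0("s", 1:20)
  # probe A: normal beta 0.25 -> excluded at step 1 despite strong pattern
  # probe B: methylated in 1/20 tumors -> excluded (under 10%)
  # probes C1, C2, C3 on gene gC: C1+C2 silenced, C3 not -> 2/3 silenced, ESG
  # probe D on gene gD: single probe silenced -> 1/1 > 0.5, ESG
  # probe E on gene gE: methylated but no suppression -> not ESG
  meth <- samples[1:8]
  mk_beta <- function(hi) ifelse(samples %in% hi, 0.8, 0.1)
  beta <- rbind(A = mk_beta(meth), B = mk_beta(samples[1]),
                C1 = mk_beta(meth), C2 = mk_beta(meth), C3 = mk_beta(meth),
                D = mk_beta(meth), E = mk_beta(meth))
  colnames(beta) <- samples
  normal <- c(A = 0.25, B = 0.1, C1 = 0.1, C2 = 0.1, C3 = 0.1, D = 0.1,
              E = 0.1)
  map <- data.frame(probe = rownames(beta),
                    gene = c("gA", "gB", "gC", "gC", "gC", "gD", "gE"))
  set.seed(1)
  expr <- matrix(rnorm(5 * 20, mean = 8, sd = 0.5), 5, 20,
                 dimnames = list(c("gA", "gB", "gC", "gD", "gE"), samples))
  expr[c("gA", "gB", "gD"), samples %in% meth] <-
    expr[c("gA", "gB", "gD"), samples %in% meth] - 4
  expr["gC", samples %in% meth] <- expr["gC", samples %in% meth] - 4
  # gC probe C3: break its silencing by a discordant beta pattern
  beta["C3", ] <- ifelse(samples %in% samples[13:20], 0.8, 0.1)
  res <- call_esgs(beta, normal, expr, map)
  detail <- attr(res, "probe_detail")
  expect_false("A" %in% detail$probe)        # normal beta > 0.2
  expect_false("B" %in% detail$probe)        # methylated in < 10%
  expect_true(res$is_esg[res$gene == "gC"])  # 2/3 probes silenced
  expect_equal(res$n_silenced[res$gene == "gC"], 2)
  expect_true(res$is_esg[res$gene == "gD"])  # single-probe gene
  expect_false(res$is_esg[res$gene == "gE"]) # no expression suppression
})

test_that("one of three silenced probes is not enough for an ESG call", {
  samples <- paste0("s", 1:20)
  meth <- samples[1:8]
  beta <- matrix(ifelse(rep(samples, each = 3) %in% meth, 0.8, 0.1), 3, 20,
                 dimnames = list(paste0("p", 1:3), samples))
  map <- data.frame(probe = paste0("p", 1:3), gene = "g")
  normal <- stats::setNames(rep(0.1, 3), paste0("p", 1:3))
  set.seed(2)
  expr <- matrix(rnorm(20, 8, 0.5), 1, 20, dimnames = list("g", samples))
  expr["g", samples %in% meth] <- expr["g", samples %in% meth] - 4
  # discordant betas on p2 and p3 destroy their silencing signal
  beta["p2", ] <- ifelse(samples %in% samples[11:18], 0.8, 0.1)
  beta["p3", ] <- ifelse(samples %in% samples[5:12], 0.45, 0.1)
  res <- call_esgs(beta, normal, expr, map)
  expect_equal(res$n_probes[res$gene == "g"], 3)
  expect_lte(res$n_silenced[res$gene == "g"], 1)
  expect_false(res$is_esg[res$gene == "g"])
})

test_that("planted silenced genes are recovered with high precision and recall", {
  b <- default_bundle()
  res <- call_esgs(b$beta, b$normal_beta, b$expression, b$probe_map)
  called <- res$gene[res$is_esg]
  precision <- mean(called %in% b$silenced_genes)
  recall <- mean(b$silenced_genes %in% called)
  expect_gte(precision, 0.9)
  expect_gte(recall, 0.9)
})

test_that("raising the SD multiplier never adds an ESG", {
  b <- small_bundle()
  r1 <- call_esgs(b$beta, b$normal_beta, b$expression, b$probe_map,
                  sd_multiplier = 1.64)
  r2 <- call_esgs(b$beta, b$normal_beta, b$expression, b$probe_map,
                  sd_multiplier = 2.5)
  expect_true(all(r2$gene[r2$is_esg] %in% r1$gene[r1$is_esg]))
})

test_that("step-1 probe filter ignores expression entirely", {
  b <- small_bundle()
  r1 <- call_esgs(b$beta, b$normal_beta, b$expression, b$probe_map)
  expr_perm <- b$expression[, sample(colnames(b$expression))]
  colnames(expr_perm) <- colnames(b$expression)
  r2 <- call_esgs(b$beta, b$normal_beta, expr_perm, b$probe_map)
  expect_setequal(attr(r1, "probe_detail")$probe,
                  attr(r2, "probe_detail")$probe)
})

test_that("methylation-expression correlation averages probe coefficients", {
  samples <- paste0("s", 1:12)
  beta <- rbind(p1 = seq(0.1, 0.9, length.out = 12),
                p2 = seq(0.9, 0.1, length.out = 12),
                p3 = rep(0.5, 12))
  colnames(beta) <- samples
  expr <- matrix(12:1, 1, 12, dimnames = list("g", samples))
  map <- data.frame(probe = paste0("p", 1:3), gene = "g")
  res <- methylation_expression_correlation(beta, expr, map)
  # p1 rho = -1, p2 rho = +1, p3 undefined and excluded -> mean 0 of 2 probes
  expect_equal(res$rho[res$gene == "g"], 0)
  expect_equal(res$n_probes[res$gene == "g"], 2)
  res1 <- methylation_expression_correlation(beta[1, , drop = FALSE], expr,
                                             map[1, ])
  expect_equal(res1$rho, -1)
  # shuffled beta: average |rho| near zero across many genes
  set.seed(3)
  G <- 60
  beta_many <- matrix(runif(G * 12), G, 12,
                      dimnames = list(paste0("q", 1:G), samples))
  expr_many <- matrix(rnorm(G * 12), G, 12,
                      dimnames = list(paste0("h", 1:G), samples))
  map_many <- data.frame(probe = paste0("q", 1:G), gene = paste0("h", 1:G))
  res_many <- methylation_expression_correlation(beta_many, expr_many,
                                                 map_many)
  expect_lt(abs(mean(res_many$rho)), 0.12)
})
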