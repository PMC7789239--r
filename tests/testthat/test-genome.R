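test_that("genome fractions match a brute-force per-base counter", {
  sizes <- c(chrA = 1000, chrB = 500)
  segs <- data.frame(
    sample = "s1",
    chromosome = c("chrA", "chrA", "chrA", "chrB", "chrB"),
    start = c(1, 101, 501, 1, 301),
    end = c(100, 500, 1000, 300, 500),
    segment_mean = c(0.5, 0.05, -0.4, 0.21, -0.2))
  fr <- genome_fractions(segs, chrom_sizes = sizes)
  # independent oracle: paint every base and count
  paint <- function(chrom, thr_fun) {
    hits <- 0
    for (i in seq_len(nrow(segs))) {
      if (segs$chromosome[i] == chrom && thr_fun(segs$segment_mean[i]))
        hits <- hits + segs$end[i] - segs$start[i] + 1
    }
    hits
  }
  gained <- paint("chrA", function(m) m > 0.2) +
    paint("chrB", function(m) m > 0.2)
  lost <- paint("chrA", function(m) m < -0.2) +
    paint("chrB", function(m) m < -0.2)
  expect_equal(fr$fgg, gained / 1500)
  expect_equal(fr$fgl, lost / 1500)
  expect_equal(fr$fga, (gained + lost) / 1500)
  # boundary: -0.2 exactly is NOT lost (strict), 0.21 is gained
  expect_equal(fr$fgg, (100 + 300) / 1500)
  expect_equal(fr$fgl, 500 / 1500)
})

test_that("FGA = FGG + FGL exactly and thresholds act monotonically", {
  b <- small_bundle()
  fr <- genome_fractions(b$segments, chrom_sizes = b$chrom_sizes)
  expect_equal(fr$fga, fr$fgg + fr$fgl)
  expect_true(all(fr$fga >= 0 & fr$fga <= 1))
  fr_tight <- genome_fractions(b$segments, amp_threshold = 0.1,
                               del_threshold = -0.1,
                               chrom_sizes = b$chrom_sizes)
  expect_true(all(fr_tight$fga >= fr$fga[match(fr_tight$sample, fr$sample)]))
})

test_that("invalid segment tables are rejected", {
  sizes <- c(chr1 = 100)
  overlapping <- data.frame(sample = "s", chromosome = "chr1",
                            start = c(1, 40), end = c(50, 90),
                            segment_mean = c(0, 0))
  expect_error(genome_fractions(overlapping, chrom_sizes = sizes),
               "overlapping")
  beyond <- data.frame(sample = "s", chromosome = "chr1", start = 50,
                       end = 150, segment_mean = 0)
  expect_error(genome_fractions(beyond, chrom_sizes = sizes),
               "beyond chromosome")
})

test_that("planted noise-free signature mixtures are recovered at rank 2", {
  set.seed(4)
  r <- 2
  sig <- matrix(rgamma(96 * r, 0.3), 96, r)
  sig <- sweep(sig, 2, colSums(sig), "/")
  rownames(sig) <- context_labels()
  # sparse exposures give signature-dominated samples (separability)
  expo <- matrix(rgamma(r * 30, 0.5), r, 30) * 3000
  v <- round(sig %*% expo)
  colnames(v) <- paste0("s", 1:30)
  res <- extract_mutation_signatures(v, rank_range = 2:4, n_restarts = 6,
                                     seed = 11)
  expect_equal(res$rank, 2)
  cos <- t(sweep(res$signatures, 2, sqrt(colSums(res$signatures^2)), "/")) %*%
    sweep(sig, 2, sqrt(colSums(sig^2)), "/")
  matched <- apply(cos, 2, max)
  expect_true(all(matched >= 0.99))
  # reconstruction error non-increasing in rank on the same data
  expect_true(all(diff(res$reconstruction_error) <= 1e-6))
  # determinism under a fixed seed
  res2 <- extract_mutation_signatures(v, rank_range = 2:4, n_restarts = 6,
                                      seed = 11)
  expect_identical(res$signatures, res2$signatures)
})

test_that("degenerate context inputs are handled", {
  v <- matrix(5, 96, 4, dimnames = list(context_labels(), paste0("s", 1:4)))
  v[, 4] <- 0
  expect_warning(res <- extract_mutation_signatures(v, rank_range = 2,
                                                    n_restarts = 2, seed = 1),
                 "all-zero")
  expect_equal(ncol(res$exposures), 3)
  expect_error(extract_mutation_signatures(v[, 1:3], rank_range = 5,
                                           n_restarts = 2, seed = 1),
               "smaller than the number of samples")
})

test_that("signature columns are normalized and exposures non-negative", {
  b <- small_bundle()
  res <- extract_mutation_signatures(b$contexts, rank_range = 2:3,
                                     n_restarts = 4, seed = 2)
  expect_equal(unname(colSums(res$signatures)), rep(1, res$rank),
               tolerance = 1e-8)
  expect_true(all(res$signatures >= 0))
  expect_true(all(res$exposures >= 0))
})

test_that("cosine matching follows the mixture algebra", {
  ref <- reference_signature_catalog()
  expect_equal(nrow(ref), 96)
  expect_equal(ncol(ref), 30)
  # identical column: cosine 1 and assigned
  m <- match_reference_signatures(ref[, c(3, 7), drop = FALSE], ref)
  expect_equal(m$best_match, c("signature_3", "signature_7"))
  expect_equal(m$cosine, c(1, 1), tolerance = 1e-9)
  expect_true(all(m$assigned))
  # orthogonal signature against a two-column toy catalogue: cosine 0
  toy <- matrix(c(1, 0, rep(0, 94), 0, 1, rep(0, 94)), 96, 2,
                dimnames = list(rownames(ref), c("r1", "r2")))
  probe <- matrix(c(0, 0, 1, rep(0, 93)), 96, 1,
                  dimnames = list(rownames(ref), "q"))
  mt <- match_reference_signatures(probe, toy)
  expect_equal(mt$cosine, 0)
  expect_false(mt$assigned)
  # 0.6/0.4 mixture of two reference columns: hand-computed best cosine
  a <- ref[, 1]; bb <- ref[, 2]
  mix <- 0.6 * a + 0.4 * bb
  cos_hand <- sum(mix * a) / sqrt(sum(mix^2) * sum(a^2))
  mm <- match_reference_signatures(matrix(mix, 96, 1,
                                          dimnames = list(rownames(ref),
                                                          "mix")), ref)
  expect_equal(mm$best_match, "signature_1")
  expect_equal(mm$cosine, cos_hand, tolerance = 1e-9)
  # row-order mismatch is an error
  shuffled <- ref[sample(96), ]
  expect_error(match_reference_signatures(ref[, 1, drop = FALSE], shuffled),
               "row order")
})
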