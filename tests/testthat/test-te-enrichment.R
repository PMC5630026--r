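gsize <- function(size) tibble::tibble(chrom = "chr1", size = size)

test_that("shuffling preserves length and respects chromosome bounds", {
  cres <- tibble::tibble(cre_id = c("a", "b"), chrom = "chr1",
                         start = c(0, 100), end = c(50, 400))
  sh <- shuffle_intervals(cres, gsize(1000), seed = 4)
  expect_equal(sh$end - sh$start, c(50, 300))
  expect_true(all(sh$start >= 0 & sh$end <= 1000))
  # forced placement when the chromosome length equals the CRE length
  one <- tibble::tibble(cre_id = "a", chrom = "chr1", start = 5, end = 105)
  sh1 <- shuffle_intervals(one, gsize(100), seed = 1)
  expect_equal(c(sh1$start, sh1$end), c(0, 100))
  expect_error(shuffle_intervals(one, gsize(99)), "longer than")
  # same seed -> identical shuffle
  expect_identical(shuffle_intervals(cres, gsize(1000), seed = 9),
                   shuffle_intervals(cres, gsize(1000), seed = 9))
})

test_that("placement of a 1 bp interval is uniform (chi-square)", {
  cre <- tibble::tibble(cre_id = sprintf("a%06d", seq_len(1e5)),
                        chrom = "chr1", start = 0, end = 1)
  starts <- shuffle_intervals(cre, gsize(1000), seed = 6)$start
  tab <- table(factor(starts %/% 100, levels = 0:9))  # 10 equal bins
  expect_gt(chisq.test(tab)$p.value, 0.01)
})

test_that("the exclusion mask is honored", {
  cre <- tibble::tibble(cre_id = "a", chrom = "chr1", start = 0, end = 10)
  excl <- tibble::tibble(chrom = "chr1", start = 0, end = 900)
  sh <- shuffle_intervals(cre, gsize(1000), exclude = excl, seed = 2)
  expect_gte(sh$start, 900)
})

test_that("saturated TE annotation gives empirical p of 1", {
  cres <- tibble::tibble(cre_id = c("a", "b"), chrom = "chr1",
                         start = c(0, 500), end = c(100, 600))
  te <- tibble::tibble(chrom = "chr1", start = 0, end = 1000,
                       subfamily = "LTR12C")
  res <- enrichment_test(cres, te, gsize(1000), n_shuffles = 50, seed = 3)
  expect_equal(res$empirical_p, 1)
  expect_equal(res$observed, 2L)
})

test_that("the smallest attainable p is 1/(n_shuffles + 1)", {
  # observed count can exceed every null count: TEs exactly under the CREs
  # on a huge chromosome
  cres <- tibble::tibble(cre_id = sprintf("c%d", 1:5), chrom = "chr1",
                         start = (0:4) * 1000, end = (0:4) * 1000 + 500)
  te <- tibble::tibble(chrom = "chr1", start = cres$start, end = cres$end,
                       subfamily = "SVA_F")
  res <- enrichment_test(cres, te, gsize(1e7), n_shuffles = 100, seed = 5)
  expect_equal(res$empirical_p, 1 / 101)
  expect_gt(res$fold, 1)
  expect_error(enrichment_test(cres, te, gsize(1e7), n_shuffles = 0),
               "n_shuffles")
})

test_that("toy enrichment p matches an exhaustive-placement oracle", {
  # 3 CREs of length 10 on a 100 bp chromosome; one subfamily
  cres <- tibble::tibble(cre_id = c("a", "b", "c"), chrom = "chr1",
                         start = c(0, 20, 40), end = c(10, 30, 50))
  te <- tibble::tibble(chrom = "chr1", start = c(0, 30), end = c(12, 36),
                       subfamily = "AluY")
  # oracle: per-CRE hit probability by enumerating all 91 placements
  hit <- vapply(0:90, function(s) {
    annotate_te_overlap(tibble::tibble(cre_id = "x", chrom = "chr1",
                                       start = s, end = s + 10),
                        te)$te_flag
  }, TRUE)
  p_hit <- mean(hit)
  observed <- sum(annotate_te_overlap(cres, te)$te_flag)
  # P(Binomial(3, p_hit) >= observed)
  p_exact <- sum(dbinom(observed:3, 3, p_hit))
  res <- enrichment_test(cres, te, gsize(100), n_shuffles = 2000, seed = 8)
  mc_se <- sqrt(p_exact * (1 - p_exact) / 2000)
  expect_lt(abs(res$empirical_p - p_exact), 4 * mc_se + 1e-3)
})

test_that("empirical p is approximately uniform under the null", {
  # dense design (200 CREs, ~30% hit rate per subfamily) so the count
  # statistic has enough resolution for the KS comparison
  set.seed(14)
  n_sub <- 200
  te <- tibble::tibble(
    chrom = "chr1",
    start = floor(runif(n_sub * 12) * 29600),
    subfamily = rep(sprintf("fam%03d", seq_len(n_sub)), each = 12)
  )
  te$end <- te$start + 400
  # CREs placed by the same mechanism that builds the null
  cres <- shuffle_intervals(
    tibble::tibble(cre_id = sprintf("c%03d", 1:200), chrom = "chr1",
                   start = 0, end = 500),
    gsize(3e4), seed = 15)
  res <- enrichment_test(cres, te, gsize(3e4), n_shuffles = 99, seed = 16)
  ks <- suppressWarnings(ks.test(res$empirical_p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(res$empirical_p >= 1 / 100))
})
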