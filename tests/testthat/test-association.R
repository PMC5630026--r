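# full hypergeometric enumeration oracle for the two-sided Fisher p
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

test_that("single-stratum CMH reduces to the plain odds ratio", {
  res <- cmh_test(list(c(10, 5, 5, 10)))
  expect_equal(res$odds_ratio, 4)
  expect_identical(res$stratum_count, 1L)
})

test_that("two-stratum CMH matches the hand-computed MH odds ratio", {
  res <- cmh_test(list(c(10, 10, 10, 10), c(20, 10, 10, 20)))
  expect_equal(res$odds_ratio, 2.2)
})

test_that("cmh_test agrees with the stats-package implementation", {
  tabs <- list(c(12, 7, 5, 14), c(30, 21, 17, 28), c(8, 2, 4, 9))
  res <- cmh_test(tabs)
  arr <- array(unlist(lapply(tabs, function(v) matrix(v, 2, byrow = TRUE))),
               dim = c(2, 2, 3))
  ht <- mantelhaen.test(arr, correct = FALSE)
  expect_equal(res$statistic, unname(ht$statistic), tolerance = 1e-10)
  expect_equal(res$p, ht$p.value, tolerance = 1e-10)
  expect_equal(res$odds_ratio, unname(ht$estimate), tolerance = 1e-10)
  expect_true(res$ci_low < res$odds_ratio & res$odds_ratio < res$ci_high)
})

test_that("null strata give OR 1 and p near 1", {
  res <- cmh_test(list(c(10, 10, 10, 10), c(7, 7, 7, 7)))
  expect_equal(res$odds_ratio, 1)
  expect_gt(res$p, 0.99)
})

test_that("degenerate strata are flagged", {
  res <- cmh_test(list(c(0, 0, 5, 5)))
  expect_true(res$degenerate)
  expect_true(is.na(res$odds_ratio))
})

test_that("Fisher p equals hypergeometric enumeration on hand tables", {
  expect_equal(fisher_exact(c(1, 9, 9, 1))$p, fisher_oracle(1, 9, 9, 1),
               tolerance = 1e-10)
  expect_equal(fisher_exact(c(5, 5, 5, 5))$p, 1)
  expect_equal(fisher_exact(c(0, 10, 10, 0))$p, fisher_oracle(0, 10, 10, 0),
               tolerance = 1e-10)
  # zero margin: p = 1, OR undefined
  z <- fisher_exact(c(0, 0, 3, 7))
  expect_equal(z$p, 1)
  expect_true(is.na(z$odds_ratio))
})

test_that("Fisher test is symmetric under simultaneous row/column swap", {
  set.seed(23)
  for (i in 1:20) {
    t0 <- sample(0:8, 4, TRUE)
    swapped <- c(t0[4], t0[3], t0[2], t0[1])
    expect_equal(fisher_exact(t0)$p, fisher_exact(swapped)$p,
                 tolerance = 1e-12)
  }
})

test_that("logistic slope on a binary covariate equals the collapsed log-OR", {
  x <- rep(c(1, 0), c(15, 15))
  y <- c(rep(1, 10), rep(0, 5), rep(1, 5), rep(0, 10))  # table (10,5,5,10)
  res <- logistic_conservation(y, x)
  expect_equal(res$slope, log(4), tolerance = 1e-6)
  expect_error(logistic_conservation(y, rep(1, 30)), "constant")
  expect_error(logistic_conservation(rep(1, 10), rnorm(10)), "classes")
})

test_that("logistic CI covers 0 under independence (coverage simulation)", {
  set.seed(27)
  covered <- vapply(1:100, function(i) {
    x <- rnorm(2000)
    y <- rbinom(2000, 1, 0.4)
    r <- logistic_conservation(y, x)
    abs(r$slope) < 1.959964 * r$se
  }, TRUE)
  expect_gte(mean(covered), 0.93)
})

test_that("complete separation is flagged with p omitted", {
  x <- c(rnorm(20, -3), rnorm(20, 3))
  y <- rep(c(0, 1), each = 20)
  res <- logistic_conservation(y, x)
  expect_true(res$separation)
  expect_true(is.na(res$p))
})

test_that("quantile bins are deciles with ties to the lower bin", {
  b <- quantile_bin(1:100)
  expect_identical(length(unique(b)), 10L)
  expect_true(all(table(b) == 10))
  expect_identical(range(quantile_bin(c(rep(0, 50), 1:50))), c(1L, 10L))
})

test_that("expression association builds one stratum per comparison", {
  de <- tibble::tibble(
    feature_id = rep(c("g1", "g2", "g3", "g4"), 2),
    comparison_id = rep(c("human_vs_chimp", "human_vs_rhesus"), each = 4),
    significant = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    status = "ok")
  dm <- tibble::tibble(
    feature_id = rep(c("c1", "c2", "c3", "c4"), 2),
    comparison_id = rep(c("human_vs_chimp", "human_vs_rhesus"), each = 4),
    significant = c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
    status = "ok")
  links <- tibble::tibble(cre_id = c("c1", "c2", "c3", "c4"),
                          gene_id = c("g1", "g2", "g3", "g4"))
  out <- expression_association(de, dm, links)
  expect_identical(nrow(out$strata), 2L)
  s1 <- out$strata[out$strata$comparison_id == "human_vs_chimp", ]
  expect_equal(unlist(s1[c("a", "b", "c", "d")]), c(a = 1, b = 1, c = 0, d = 2))
})
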