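test_that("size factors follow median-of-ratios", {
  m <- cbind(s1 = c(10, 20, 30), s2 = c(10, 20, 30))
  expect_equal(estimate_size_factors(m)$size_factor, c(1, 1))

  m2 <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
  expect_equal(estimate_size_factors(m2)$size_factor,
               c(1 / sqrt(2), sqrt(2)))

  # 3x3 hand oracle
  m3 <- cbind(s1 = c(4, 10, 20), s2 = c(8, 10, 10), s3 = c(16, 40, 40))
  geo <- exp(rowMeans(log(m3)))
  sf <- apply(m3 / geo, 2, median)
  sf <- sf / exp(mean(log(sf)))
  expect_equal(estimate_size_factors(m3)$size_factor, unname(sf))
})

test_that("size factors are scale-equivariant in ratio", {
  set.seed(5)
  m <- matrix(rpois(60, 50) + 1, ncol = 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  f0 <- estimate_size_factors(m)$size_factor
  m2 <- m; m2[, 2] <- m2[, 2] * 3
  f1 <- estimate_size_factors(m2)$size_factor
  expect_equal(f1[2] / f1[1], 3 * f0[2] / f0[1], tolerance = 1e-8)
})

test_that("all-zero-in-some-sample matrices fall back with a warning", {
  m <- cbind(s1 = c(0, 10), s2 = c(5, 0))
  expect_warning(sf <- estimate_size_factors(m), "positive")
  expect_true(all(sf$size_factor > 0))
})

test_that("dispersion ML recovers the truth and beats a grid", {
  set.seed(11)
  y_pois <- rpois(500, 50)
  expect_lt(estimate_dispersion(y_pois, rep(50, 500)), 0.01)

  y_nb <- rnbinom(200, mu = 100, size = 2)  # alpha = 0.5
  a_hat <- estimate_dispersion(y_nb, rep(100, 200))
  expect_gt(a_hat, 0.4); expect_lt(a_hat, 0.6)

  # grid oracle: the ML estimate is at least as good as 200 grid points
  grid <- exp(seq(log(1e-6), log(5), length.out = 200))
  ll_grid <- vapply(grid, function(a) creevo:::nb_loglik(y_nb, rep(100, 200), a), 0)
  ll_hat <- creevo:::nb_loglik(y_nb, rep(100, 200), a_hat)
  expect_gte(ll_hat, max(ll_grid) - 1e-6)
  expect_true(is.na(estimate_dispersion(rep(0, 10), rep(1, 10))))
})

test_that("NB GLM fits match closed-form cases", {
  # intercept-only, all counts k -> intercept ln k
  f <- fit_nb_glm(rep(7, 10), matrix(1, 10, 1), alpha = 0.3)
  expect_equal(unname(f$coefficients), log(7), tolerance = 1e-7)

  # two-group design: fitted group means equal sample means for any alpha
  y <- c(3, 5, 9, 20, 30, 25)
  X <- cbind(1, rep(c(0, 1), each = 3))
  for (a in c(0, 0.2, 1)) {
    f2 <- fit_nb_glm(y, X, alpha = a)
    expect_equal(unname(f2$fitted[1:3]), rep(mean(y[1:3]), 3),
                 tolerance = 1e-6)
    expect_equal(unname(f2$fitted[4:6]), rep(mean(y[4:6]), 3),
                 tolerance = 1e-6)
  }
})

test_that("IRLS matches a derivative-free optimizer on a 12-sample toy", {
  set.seed(3)
  X <- cbind(1, rep(c(0, 1), each = 6), rnorm(12))
  y <- rnbinom(12, mu = exp(3 + 0.8 * X[, 2] + 0.3 * X[, 3]), size = 5)
  offs <- rnorm(12, 0, 0.1)
  f <- fit_nb_glm(y, X, offs, alpha = 0.2)
  nll <- function(b) -creevo:::nb_loglik(y, exp(pmin(drop(X %*% b) + offs, 30)), 0.2)
  o <- optim(c(1, 0, 0), nll, method = "Nelder-Mead",
             control = list(maxit = 20000, reltol = 1e-14))
  expect_equal(unname(f$coefficients), o$par, tolerance = 1e-4)
  expect_lte(nll(f$coefficients), o$value + 1e-8)
})

test_that("log-likelihood never decreases across IRLS iterations", {
  set.seed(17)
  for (i in 1:100) {
    n <- sample(8:16, 1)
    X <- cbind(1, rbinom(n, 1, 0.5), rnorm(n))
    if (qr(X)$rank < 3) next
    y <- rnbinom(n, mu = exp(rnorm(1, 3, 1) + 0.5 * X[, 2]), size = 3)
    f <- fit_nb_glm(y, X, alpha = runif(1, 0, 1))
    expect_true(all(diff(f$ll_trace) >= -1e-9))
  }
})

test_that("rank-deficient designs are rejected naming columns", {
  X <- cbind(intercept = 1, a = c(0, 1, 0, 1), b = c(0, 2, 0, 2))
  expect_error(fit_nb_glm(c(1, 2, 3, 4), X), "collinear.*b")
})

test_that("Wald test matches the normal tail", {
  expect_equal(wald_test(0, 1)$p, 1)
  expect_equal(wald_test(1.959964, 1)$p, 0.05, tolerance = 1e-6)
  # quadrature oracle at z = 2.7
  tail_p <- 2 * integrate(dnorm, 2.7, Inf)$value
  expect_equal(wald_test(2.7, 1)$p, tail_p, tolerance = 1e-6)
  expect_true(wald_test(1, 0)$undefined)
})

test_that("BH adjustment equals the step-up oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
  set.seed(8)
  for (i in 1:6) {
    p <- runif(6)
    for (j in 1:3) {
      pp <- sample(p)
      expect_equal(bh_adjust(pp), bh_oracle(pp))
    }
  }
})
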