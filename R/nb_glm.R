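# Statistical core: median-of-ratios size factors, per-feature ML negative
# binomial dispersion, IRLS fitting of NB log-link GLMs with offsets, Wald
# tests, and Benjamini-Hochberg adjustment.

counts_matrix <- function(counts) {
  if (is_tibble(counts) || is.data.frame(counts)) {
    stopifnot("feature_id" %in% names(counts))
    m <- as.matrix(counts[setdiff(names(counts), "feature_id")])
    rownames(m) <- counts$feature_id
    storage.mode(m) <- "double"
    m
  } else {
    as.matrix(counts)
  }
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over reference features of
#' the ratio of its count to the feature's geometric mean across samples.
#' Reference features are those with positive counts in every sample; if
#' none exists, the ratio median is taken over the positive counts only,
#' with a warning. Factors are rescaled to geometric mean 1.
#'
#' @param counts Count tibble (`feature_id` + sample columns) or matrix.
#' @return Tibble `sample_id`, `size_factor` (all positive).
#' @export
estimate_size_factors <- function(counts) {
  m <- counts_matrix(counts)
  if (ncol(m) < 1 || nrow(m) < 1) stop("empty count matrix")
  all_pos <- rowSums(m > 0) == ncol(m)
  if (any(all_pos)) {
    ref <- m[all_pos, , drop = FALSE]
    geo <- exp(rowMeans(log(ref)))
    sf <- apply(ref / geo, 2, median)
  } else {
    warning("no feature with positive counts in all samples; ",
            "using positive-count-only medians")
    geo <- exp(apply(m, 1, function(r) mean(log(r[r > 0]))))
    sf <- vapply(seq_len(ncol(m)), function(j) {
      r <- m[, j] / geo
      median(r[m[, j] > 0], na.rm = TRUE)
    }, 0)
  }
  if (any(!is.finite(sf) | sf <= 0)) stop("degenerate size factors")
  sf <- sf / exp(mean(log(sf)))
  tibble(sample_id = colnames(m), size_factor = unname(sf))
}

nb_loglik <- function(y, mu, alpha) {
  if (alpha <= 0) return(sum(stats::dpois(y, mu, log = TRUE)))
  sum(dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
}

#' Maximum-likelihood NB dispersion for one feature
#'
#' Maximizes the NB log-likelihood in `alpha` (variance `mu + alpha mu^2`)
#' with the fitted means held fixed, over `[1e-8, 10]` on a log scale.
#' When the design matrix is supplied, the Cox-Reid adjustment
#' `-0.5 log det(X' W X)` is added to the profile likelihood, which removes
#' most of the downward bias of plain ML at the sample sizes used here
#' (a dozen samples against four coefficients).
#'
#' @param y Observed counts.
#' @param mu Fitted means (same length).
#' @param X Optional design matrix for the Cox-Reid adjustment.
#' @return Estimated `alpha`, or `NA` when all counts are zero.
#' @export
estimate_dispersion <- function(y, mu, X = NULL) {
  stopifnot(length(y) == length(mu), all(mu > 0))
  if (all(y == 0)) return(NA_real_)
  f <- function(la) {
    a <- exp(la)
    ll <- nb_loglik(y, mu, a)
    if (!is.null(X)) {
      w <- mu / (1 + a * mu)
      ll <- ll - 0.5 * determinant(t(X * w) %*% X)$modulus[1]
    }
    -ll
  }
  opt <- optimize(f, c(log(1e-8), log(10)), tol = 1e-6)
  exp(opt$minimum)
}

#' Fit a negative binomial GLM with log link by IRLS
#'
#' Fisher-scoring iteratively reweighted least squares with working weights
#' `mu / (1 + alpha mu)`, plus step-halving so the log-likelihood never
#' decreases. Convergence when the largest coefficient change is below
#' `tol` (default 1e-8), capped at `max_iter` (default 100) iterations.
#'
#' @param y Counts.
#' @param X Design matrix (full rank).
#' @param offsets Per-observation offsets on the log scale (e.g. log size
#'   factors); default 0.
#' @param alpha NB dispersion (0 = Poisson).
#' @param tol,max_iter Convergence controls.
#' @return Object of class `nbglm_fit`: list with `coefficients`, `se`,
#'   `cov` (inverse Fisher information), `fitted`, `alpha`, `converged`,
#'   `iterations`, `loglik`.
#' @export
fit_nb_glm <- function(y, X, offsets = 0, alpha = 0, tol = 1e-8,
                       max_iter = 100) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, all(y >= 0))
  offsets <- rep_len(offsets, n)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix not full rank; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  clamp <- function(eta) pmin(pmax(eta, -30), 30)
  beta <- qr.coef(qrX, log(y + 0.5) - offsets)
  eta <- clamp(drop(X %*% beta) + offsets)
  mu <- exp(eta)
  ll <- nb_loglik(y, mu, alpha)
  ll_trace <- ll
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    w <- mu / (1 + alpha * mu)
    z <- (eta - offsets) + (y - mu) / mu
    XtW <- t(X * w)
    beta_new <- drop(solve(XtW %*% X, XtW %*% z))
    step <- beta_new - beta
    # step-halving: never let the log-likelihood decrease
    fac <- 1
    repeat {
      cand <- beta + fac * step
      eta_c <- clamp(drop(X %*% cand) + offsets)
      ll_c <- nb_loglik(y, exp(eta_c), alpha)
      if (is.finite(ll_c) && ll_c >= ll - 1e-12) break
      fac <- fac / 2
      if (fac < 1e-10) { cand <- beta; eta_c <- eta; ll_c <- ll; break }
    }
    delta <- max(abs(cand - beta))
    beta <- cand; eta <- eta_c; mu <- exp(eta); ll <- ll_c
    ll_trace <- c(ll_trace, ll)
    if (delta < tol) { converged <- TRUE; break }
  }
  w <- mu / (1 + alpha * mu)
  info <- t(X * w) %*% X
  cov <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  coefs <- setNames(beta, colnames(X))
  structure(
    list(coefficients = coefs, se = sqrt(diag(cov)), cov = cov,
         fitted = mu, alpha = alpha, converged = converged,
         iterations = it, loglik = ll, ll_trace = ll_trace,
         y = y, X = X, offsets = offsets),
    class = "nbglm_fit"
  )
}

#' @export
print.nbglm_fit <- function(x, ...) {
  cat("<nbglm_fit> alpha =", format(x$alpha, digits = 4),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(tibble(term = names(x$coefficients),
               estimate = unname(x$coefficients), se = unname(x$se)))
  invisible(x)
}

#' Wald test of a coefficient
#'
#' @param coefficient Point estimate.
#' @param se Standard error (> 0).
#' @return Tibble `z`, `p` (two-sided normal); `se = 0` gives `NA` with a
#'   flag column `undefined`.
#' @export
wald_test <- function(coefficient, se) {
  undefined <- !is.finite(se) | se <= 0
  z <- if_else(undefined, NA_real_, coefficient / se)
  tibble(z = z, p = if_else(undefined, NA_real_, 2 * pnorm(-abs(z))),
         undefined = undefined)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control; rejects `p` outside `[0, 1]`.
#'
#' @param p Vector of p-values (`NA` allowed and preserved).
#' @return Adjusted p-values, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  p.adjust(p, method = "BH")
}
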