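# Association statistics linking regulatory divergence to expression
# divergence and genomic covariates: Cochran-Mantel-Haenszel over stratified
# 2x2 tables, Fisher's exact test, and logistic regression.

as_2x2 <- function(tab) {
  m <- matrix(as.numeric(tab), nrow = 2, byrow = TRUE)
  if (any(m < 0) || any(m != round(m))) stop("2x2 cells must be non-negative integers")
  m
}

#' Cochran-Mantel-Haenszel test over stratified 2x2 tables
#'
#' Combines one 2x2 table per stratum (here: one per species comparison,
#' cross-classifying differentially expressed genes by association with a
#' differentially modified CRE) into the Mantel-Haenszel common odds ratio
#' `sum(a_i d_i / n_i) / sum(b_i c_i / n_i)` and the CMH chi-square test
#' (continuity correction off).
#'
#' @param strata List of 2x2 tables (matrix or length-4 vector `a, b, c, d`
#'   read row-wise).
#' @return Tibble of class spirit `AssociationResult`: `test_name`,
#'   `statistic`, `odds_ratio`, `ci_low`, `ci_high`, `p`, `stratum_count`,
#'   `degenerate`.
#' @export
cmh_test <- function(strata) {
  stopifnot(length(strata) >= 1)
  mats <- lapply(strata, as_2x2)
  a <- vapply(mats, function(m) m[1, 1], 0); b <- vapply(mats, function(m) m[1, 2], 0)
  cc <- vapply(mats, function(m) m[2, 1], 0); d <- vapply(mats, function(m) m[2, 2], 0)
  n <- a + b + cc + d
  usable <- n > 0 & (a + b) > 0 & (cc + d) > 0 & (a + cc) > 0 & (b + d) > 0
  if (!any(usable)) {
    return(tibble(test_name = "cmh", statistic = NA_real_,
                  odds_ratio = NA_real_, ci_low = NA_real_,
                  ci_high = NA_real_, p = NA_real_,
                  stratum_count = length(strata), degenerate = TRUE))
  }
  a <- a[usable]; b <- b[usable]; cc <- cc[usable]; d <- d[usable]
  n <- n[usable]
  or_mh <- sum(a * d / n) / sum(b * cc / n)
  # CMH chi-square, continuity correction off
  e_a <- (a + b) * (a + cc) / n
  v_a <- (a + b) * (cc + d) * (a + cc) * (b + d) / (n^2 * (n - 1))
  stat <- (sum(a) - sum(e_a))^2 / sum(v_a)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  # Robins-Breslow-Greenland variance of log MH OR
  P <- (a + d) / n; Q <- (b + cc) / n
  R <- a * d / n; S <- b * cc / n
  var_log <- sum(P * R) / (2 * sum(R)^2) +
    sum(P * S + Q * R) / (2 * sum(R) * sum(S)) +
    sum(Q * S) / (2 * sum(S)^2)
  ci <- exp(log(or_mh) + c(-1, 1) * 1.959964 * sqrt(var_log))
  tibble(test_name = "cmh", statistic = stat,
         odds_ratio = or_mh, ci_low = ci[1], ci_high = ci[2],
         p = p, stratum_count = length(strata), degenerate = FALSE)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact p by summing hypergeometric probabilities no larger than
#' the observed table's, with the conditional-MLE odds ratio. A zero margin
#' gives p = 1 with an undefined odds ratio.
#'
#' @param table 2x2 matrix or length-4 vector `a, b, c, d` (row-wise).
#' @return Tibble: `test_name`, `odds_ratio`, `ci_low`, `ci_high`, `p`.
#' @export
fisher_exact <- function(table) {
  m <- as_2x2(table)
  zero_margin <- any(rowSums(m) == 0) || any(colSums(m) == 0)
  ht <- fisher.test(m)
  tibble(test_name = "fisher",
         odds_ratio = if (zero_margin) NA_real_ else unname(ht$estimate),
         ci_low = if (zero_margin) NA_real_ else ht$conf.int[1],
         ci_high = if (zero_margin) NA_real_ else ht$conf.int[2],
         p = ht$p.value)
}

#' Logistic regression of a conservation outcome on a covariate
#'
#' Newton-fitted binomial GLM with logit link and a Wald test on the slope.
#' Used for sequence divergence, TSS-distance quantiles, TFBS counts, and
#' cell-type-specificity quantiles as predictors of whether a CRE is
#' diverged. Complete separation is detected (fitted probabilities
#' numerically 0/1) and flagged, with the p-value omitted.
#'
#' @param outcome Logical or 0/1 vector (1 = diverged).
#' @param covariate Numeric vector; must vary.
#' @return Tibble: `test_name`, `slope`, `se`, `statistic` (Wald z), `p`,
#'   `separation`.
#' @export
logistic_conservation <- function(outcome, covariate) {
  outcome <- as.numeric(outcome)
  stopifnot(length(outcome) == length(covariate),
            all(outcome %in% c(0, 1)))
  if (length(unique(outcome)) < 2) stop("both outcome classes must be present")
  if (sd(covariate) == 0) stop("covariate is constant (no variation)")
  fit <- suppressWarnings(glm(outcome ~ covariate, family = binomial()))
  probs <- fitted(fit)
  sep <- !fit$converged || any(probs < 1e-10 | probs > 1 - 1e-10)
  slope <- unname(coef(fit)[2])
  se <- sqrt(diag(vcov(fit)))[2]
  wt <- wald_test(slope, unname(se))
  tibble(test_name = "logistic", slope = slope, se = unname(se),
         statistic = if (sep) NA_real_ else wt$z,
         p = if (sep) NA_real_ else wt$p,
         separation = sep)
}

#' Bin a covariate into quantiles
#'
#' Default deciles; ties are assigned to the lower bin. Used to put
#' TSS-distance-like covariates on a quantile axis before logistic
#' regression.
#'
#' @param x Numeric vector.
#' @param n_bins Number of quantile bins (default 10).
#' @return Integer bin index in `1..n_bins`.
#' @export
quantile_bin <- function(x, n_bins = 10) {
  qs <- quantile(x, probs = seq_len(n_bins - 1) / n_bins, type = 7)
  b <- rep(1L, length(x))
  for (q in qs) b <- b + as.integer(x > q)
  b
}

#' Regulatory-expression association across the comparison battery
#'
#' For each pairwise species comparison, cross-classifies genes by
#' differential expression and by association with a differentially
#' modified CRE, then combines the strata with [cmh_test()].
#'
#' @param de_results Stacked [diff_expression()] tables (one
#'   `comparison_id` per stratum).
#' @param dm_results Stacked merged [diff_histone()] tables with matching
#'   `comparison_id`s.
#' @param links Tibble `cre_id`, `gene_id` linking CREs to genes (e.g.
#'   nearest gene from the catalogue).
#' @return List with `strata` (tibble of per-comparison 2x2 cells) and
#'   `cmh` (the [cmh_test()] result).
#' @export
expression_association <- function(de_results, dm_results, links) {
  comps <- intersect(unique(de_results$comparison_id),
                     unique(dm_results$comparison_id))
  strata <- map(comps, function(cid) {
    de <- de_results |> filter(.data$comparison_id == cid, .data$status == "ok")
    dm <- dm_results |> filter(.data$comparison_id == cid, .data$status == "ok")
    dm_genes <- unique(links$gene_id[links$cre_id %in%
                                       dm$feature_id[dm$significant]])
    considered <- unique(links$gene_id[links$cre_id %in% dm$feature_id])
    de <- de |> filter(.data$feature_id %in% considered)
    a <- sum(de$significant & de$feature_id %in% dm_genes)
    b <- sum(de$significant & !de$feature_id %in% dm_genes)
    cc <- sum(!de$significant & de$feature_id %in% dm_genes)
    d <- sum(!de$significant & !de$feature_id %in% dm_genes)
    tibble(comparison_id = cid, a = a, b = b, c = cc, d = d)
  }) |> list_rbind()
  tabs <- pmap(strata[, c("a", "b", "c", "d")],
               function(a, b, c, d) c(a, b, c, d))
  list(strata = strata, cmh = cmh_test(tabs))
}
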