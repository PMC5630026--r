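# Differential histone modification (IP x input interaction design) and
# differential expression across species groups.

LN2 <- log(2)

# Fit one feature: NB GLM with dispersion estimated by ML from an initial
# fit, then refit. Returns estimate/se (natural log) of `term`.
fit_feature <- function(y, X, offsets, term, alpha_init = 0.1) {
  f0 <- fit_nb_glm(y, X, offsets, alpha = alpha_init)
  a <- estimate_dispersion(y, f0$fitted, X)
  if (!is.finite(a)) a <- alpha_init
  f1 <- fit_nb_glm(y, X, offsets, alpha = a)
  k <- match(term, colnames(X))
  list(est = unname(f1$coefficients[k]), se = unname(f1$se[k]),
       alpha = a, converged = f1$converged, df = length(y) - ncol(X))
}

# Wald p with a t reference at the residual degrees of freedom: at the
# sample sizes of this design (a dozen libraries, four coefficients) the
# normal reference is anti-conservative in the far tail because the
# dispersion, and hence the standard error, is itself estimated.
wald_t_p <- function(est, se, df) {
  undefined <- !is.finite(se) | se <= 0 | df < 1
  z <- if_else(undefined, NA_real_, est / se)
  list(z = z, p = if_else(undefined, NA_real_, 2 * stats::pt(-abs(z), df)),
       undefined = undefined)
}

comparison_samples <- function(metadata, group_a, group_b, assays, marks) {
  metadata |>
    filter(.data$species %in% c(group_a, group_b),
           .data$assay %in% assays, .data$mark %in% marks) |>
    mutate(condition = if_else(.data$species %in% group_a, 1, 0))
}

#' Differential histone modification between two species groups
#'
#' For each region, fits the interaction model
#' `count ~ assay + condition + assay:condition` (log link, NB errors),
#' where `assay` distinguishes IP from input and `condition` the two species
#' groups, and Wald-tests the interaction coefficient: a change in IP
#' enrichment over input between the groups, i.e. differential histone
#' modification uncontaminated by input (copy-number / mappability) shifts.
#' The Wald statistic is referred to a t distribution with the residual
#' degrees of freedom, which keeps the far tail calibrated at the small
#' per-comparison sample sizes of this design.
#' The two marks are analyzed independently and merged afterwards: a region
#' is differentially modified if either mark's BH-adjusted p is below `fdr`.
#'
#' Regions with all-zero IP counts in a mark are excluded from that mark's
#' testing (and from its BH denominator).
#'
#' @param chip_counts Tibble `feature_id` + one column per ChIP sample.
#' @param metadata Sample table (`sample_id`, `species`, `assay`, `mark`).
#' @param group_a,group_b Character vectors of species; `group_a` is the
#'   reference side, and positive log2 fold changes mean higher IP
#'   enrichment in `group_a`.
#' @param comparison_id Label stored in the result.
#' @param fdr Significance threshold on BH-adjusted p.
#' @param marks Histone marks to analyze and merge.
#' @param size_factors Optional tibble (`sample_id`, `size_factor`);
#'   estimated per mark from the comparison's samples when `NULL`.
#' @return Tibble: `feature_id`, `comparison_id`, `mark`, `log2fc`, `se`,
#'   `wald_z`, `p`, `padj`, `significant`, `status` (`ok`/`untested`),
#'   merged over marks (most significant mark reported).
#' @export
diff_histone <- function(chip_counts, metadata, group_a, group_b,
                         comparison_id = NULL, fdr = 0.10,
                         marks = c("H3K27ac", "H3K4me1"),
                         size_factors = NULL) {
  if (is.null(comparison_id)) {
    comparison_id <- paste(paste(group_a, collapse = "+"), "vs",
                           paste(group_b, collapse = "+"))
  }
  per_mark <- map(marks, function(mk) {
    meta <- comparison_samples(metadata, group_a, group_b,
                               c("IP", "input"), mk)
    ok <- meta |>
      count(.data$condition, .data$assay) |>
      filter(.data$n < 2)
    if (nrow(ok) > 0 || nrow(distinct(meta, .data$condition)) < 2 ||
        nrow(distinct(meta, .data$assay)) < 2) {
      stop("comparison refused (", comparison_id, ", ", mk,
           "): need >= 2 samples per assay in both groups")
    }
    cm <- counts_matrix(chip_counts)[, meta$sample_id, drop = FALSE]
    sf <- if (is.null(size_factors)) {
      estimate_size_factors(cm)
    } else {
      size_factors |> filter(.data$sample_id %in% meta$sample_id)
    }
    offs <- log(sf$size_factor[match(meta$sample_id, sf$sample_id)])
    X <- cbind(intercept = 1,
               assayIP = as.numeric(meta$assay == "IP"),
               condition = meta$condition,
               interaction = as.numeric(meta$assay == "IP") * meta$condition)
    ip_cols <- meta$assay == "IP"
    res <- map(seq_len(nrow(cm)), function(r) {
      y <- cm[r, ]
      if (all(y[ip_cols] == 0)) {
        return(tibble(feature_id = rownames(cm)[r], mark = mk,
                      log2fc = NA_real_, se = NA_real_, wald_z = NA_real_,
                      p = NA_real_, status = "untested"))
      }
      ft <- fit_feature(y, X, offs, "interaction")
      wt <- wald_t_p(ft$est, ft$se, ft$df)
      tibble(feature_id = rownames(cm)[r], mark = mk,
             log2fc = ft$est / LN2, se = ft$se / LN2, wald_z = wt$z,
             p = wt$p, status = if (wt$undefined) "untested" else "ok")
    }) |> list_rbind()
    tested <- res$status == "ok"
    res$padj <- NA_real_
    res$padj[tested] <- bh_adjust(res$p[tested])
    res
  })
  merged <- list_rbind(per_mark) |>
    mutate(comparison_id = comparison_id,
           significant = !is.na(.data$padj) & .data$padj < fdr) |>
    group_by(.data$feature_id) |>
    arrange(if_else(.data$status == "ok", .data$padj, Inf),
            if_else(.data$status == "ok", .data$p, Inf),
            .by_group = TRUE) |>
    summarise(
      comparison_id = first(.data$comparison_id),
      mark = first(.data$mark), log2fc = first(.data$log2fc),
      se = first(.data$se), wald_z = first(.data$wald_z),
      p = first(.data$p), padj = first(.data$padj),
      significant = any(.data$significant),
      status = if (all(.data$status == "untested")) "untested" else "ok",
      .groups = "drop"
    )
  merged[match(chip_counts$feature_id, merged$feature_id), ] |>
    filter(!is.na(.data$feature_id))
}

#' Differential expression between two species groups
#'
#' Fits `count ~ condition` per gene with offsets `log(size factor) +
#' log(gene length / 1000)`, Wald-tests the condition coefficient, and
#' applies BH adjustment (default significance threshold FDR < 5%).
#' Positive log2 fold changes mean higher expression in `group_a`.
#'
#' @param rna_counts Tibble `feature_id` + one column per RNA sample.
#' @param metadata Sample table; RNA samples have `assay == "RNA"`.
#' @param gene_lengths Tibble `gene_id`, `length` (bp) for length offsets;
#'   `NULL` drops the length offset.
#' @param group_a,group_b Species vectors (>= 2 samples each).
#' @param comparison_id Label stored in the result.
#' @param fdr Significance threshold.
#' @param size_factors Optional precomputed size factors.
#' @return Tibble: `feature_id`, `comparison_id`, `log2fc`, `se`, `wald_z`,
#'   `p`, `padj`, `significant`, `status`.
#' @export
diff_expression <- function(rna_counts, metadata, group_a, group_b,
                            gene_lengths = NULL, comparison_id = NULL,
                            fdr = 0.05, size_factors = NULL) {
  if (is.null(comparison_id)) {
    comparison_id <- paste(paste(group_a, collapse = "+"), "vs",
                           paste(group_b, collapse = "+"))
  }
  meta <- comparison_samples(metadata, group_a, group_b, "RNA",
                             unique(metadata$mark))
  if (sum(meta$condition == 1) < 2 || sum(meta$condition == 0) < 2) {
    stop("comparison refused (", comparison_id,
         "): need >= 2 RNA samples per group")
  }
  cm <- counts_matrix(rna_counts)[, meta$sample_id, drop = FALSE]
  sf <- if (is.null(size_factors)) estimate_size_factors(cm) else size_factors
  offs_sf <- log(sf$size_factor[match(meta$sample_id, sf$sample_id)])
  len_off <- rep(0, nrow(cm))
  if (!is.null(gene_lengths)) {
    len <- gene_lengths$length[match(rownames(cm), gene_lengths$gene_id)]
    stopifnot(all(is.finite(len) & len > 0))
    len_off <- log(len / 1000)
  }
  X <- cbind(intercept = 1, condition = meta$condition)
  res <- map(seq_len(nrow(cm)), function(r) {
    y <- cm[r, ]
    if (all(y == 0)) {
      return(tibble(feature_id = rownames(cm)[r], log2fc = NA_real_,
                    se = NA_real_, wald_z = NA_real_, p = NA_real_,
                    status = "untested"))
    }
    ft <- fit_feature(y, X, offs_sf + len_off[r], "condition")
    wt <- wald_t_p(ft$est, ft$se, ft$df)
    tibble(feature_id = rownames(cm)[r], log2fc = ft$est / LN2,
           se = ft$se / LN2, wald_z = wt$z, p = wt$p,
           status = if (wt$undefined) "untested" else "ok")
  }) |> list_rbind()
  tested <- res$status == "ok"
  res$padj <- NA_real_
  res$padj[tested] <- bh_adjust(res$p[tested])
  res |>
    mutate(comparison_id = comparison_id,
           significant = !is.na(.data$padj) & .data$padj < fdr) |>
    select("feature_id", "comparison_id", "log2fc", "se", "wald_z", "p",
           "padj", "significant", "status")
}
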