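# Reporter-assay statistics: Wilcoxon rank-sum comparison of construct
# activity against the empty-vector control, with activator/repressor
# classification.

#' Wilcoxon rank-sum test of construct activity vs control
#'
#' Two-sided rank-sum test. The p-value is exact (full enumeration of the
#' rank-sum null) when both groups have at most 25 replicates and there are
#' no ties; otherwise the normal approximation with tie correction is used.
#' Identical values across both groups give p = 1.
#'
#' @param construct,control Numeric activity vectors (>= 2 replicates each).
#' @return Tibble: `statistic` (rank-sum W), `p`, `exact`.
#' @export
wilcoxon_vs_control <- function(construct, control) {
  stopifnot(length(construct) >= 2, length(control) >= 2)
  if (length(unique(c(construct, control))) == 1) {
    return(tibble(statistic = length(construct) * length(control) / 2,
                  p = 1, exact = FALSE))
  }
  ties <- any(duplicated(c(construct, control)))
  use_exact <- !ties && length(construct) <= 25 && length(control) <= 25
  ht <- suppressWarnings(
    wilcox.test(construct, control, exact = use_exact, correct = !use_exact)
  )
  tibble(statistic = unname(ht$statistic), p = min(ht$p.value, 1),
         exact = use_exact)
}

#' Classify a construct as activator, repressor, or ns
#'
#' Activator when the test is significant at `alpha` and the construct's
#' median activity exceeds the control's; repressor when significant with a
#' lower median; otherwise `ns`.
#'
#' @param construct,control Activity vectors.
#' @param p Two-sided p-value from [wilcoxon_vs_control()].
#' @param alpha Significance level (default 0.05).
#' @return One of `"activator"`, `"repressor"`, `"ns"`.
#' @export
classify_direction <- function(construct, control, p, alpha = 0.05) {
  if (is.na(p) || p >= alpha) return("ns")
  if (median(construct) > median(control)) "activator" else "repressor"
}

#' Test a table of reporter constructs against the empty-vector control
#'
#' @param activities Tibble `construct_id`, `replicate`, `activity`,
#'   `is_control` (logical; all control rows pooled as the reference).
#' @param alpha Significance level for direction calls.
#' @param adjust Add a BH-adjusted p column across constructs
#'   (default `TRUE`; the direction call still uses the raw p).
#' @return Tibble: `construct_id`, `n_replicates`, `median_ratio`, `p`,
#'   `padj` (if requested), `direction`.
#' @export
reporter_screen <- function(activities, alpha = 0.05, adjust = TRUE) {
  stopifnot(all(c("construct_id", "activity", "is_control") %in%
                  names(activities)))
  control <- activities$activity[activities$is_control]
  if (length(control) < 2) stop("need >= 2 control replicates")
  out <- activities |>
    filter(!.data$is_control) |>
    group_by(.data$construct_id) |>
    summarise(
      n_replicates = n(),
      median_ratio = median(.data$activity) / median(control),
      p = wilcoxon_vs_control(.data$activity, control)$p,
      direction = classify_direction(.data$activity, control, p, alpha),
      .groups = "drop"
    )
  if (adjust) out$padj <- bh_adjust(out$p)
  out
}
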