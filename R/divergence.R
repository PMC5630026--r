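# Per-nucleotide pairwise divergence between human and each other species
# over aligned orthologous slices, plus Grubbs-type outlier flagging of the
# per-species divergence distributions.

#' Mismatch count between two aligned gapped sequences
#'
#' Columns where human has a gap are excluded entirely; columns where the
#' other species has a gap (but human a base) are excluded from the compared
#' count; `N` (any case) matches nothing and its columns are excluded.
#' Comparison is case-insensitive.
#'
#' @param human_seq,other_seq Gapped aligned sequences of equal length.
#' @return List with `mismatches`, `compared_columns`.
#' @export
pair_divergence <- function(human_seq, other_seq) {
  h <- toupper(strsplit(human_seq, "", fixed = TRUE)[[1]])
  o <- toupper(strsplit(other_seq, "", fixed = TRUE)[[1]])
  stopifnot(length(h) == length(o))
  keep <- h != "-"            # all human gaps excluded
  h <- h[keep]; o <- o[keep]
  comparable <- o != "-" & h != "N" & o != "N"
  list(mismatches = sum(h[comparable] != o[comparable]),
       compared_columns = sum(comparable))
}

#' Pairwise sequence divergence for mapped ortholog sets
#'
#' Computes, for every non-human species of every mapped CRE, the fraction of
#' mismatching aligned columns relative to human. Intended to be fed the
#' output of [map_orthologs()] run with `flank = 500` on six-way-alignable
#' CREs, mirroring the consensus-peak-plus-flank window of the study design.
#'
#' @param ortho Tibble from [map_orthologs()] (columns `cre_id`, `species`,
#'   `seq`, `human_seq`, `six_way`).
#' @param six_way_only Drop CREs not alignable in all six species
#'   (default `TRUE`).
#' @return Tibble: `cre_id`, `species`, `mismatches`, `compared_columns`,
#'   `divergence`, `undefined` (no comparable columns), `outlier`
#'   (initialized `FALSE`; see [flag_divergence_outliers()]).
#' @export
pairwise_divergence <- function(ortho, six_way_only = TRUE) {
  d <- ortho |>
    filter(.data$species != "human", !is.na(.data$seq))
  if (six_way_only && "six_way" %in% names(d)) d <- filter(d, .data$six_way)
  if (nrow(d) == 0) {
    return(tibble(cre_id = character(), species = character(),
                  mismatches = integer(), compared_columns = integer(),
                  divergence = numeric(), undefined = logical(),
                  outlier = logical()))
  }
  res <- map2(d$human_seq, d$seq, function(h, s) pair_divergence(h, s))
  tibble(
    cre_id = d$cre_id, species = d$species,
    mismatches = map_int(res, function(x) as.integer(x$mismatches)),
    compared_columns = map_int(res, function(x) as.integer(x$compared_columns))
  ) |>
    mutate(divergence = if_else(.data$compared_columns > 0,
                                .data$mismatches / .data$compared_columns,
                                NA_real_),
           undefined = .data$compared_columns == 0,
           outlier = FALSE)
}

# One-sided-maximum Grubbs statistic and its critical value at level alpha
grubbs_critical <- function(n, alpha = 0.05) {
  t2 <- qt(alpha / (2 * n), n - 2, lower.tail = FALSE)^2
  ((n - 1) / sqrt(n)) * sqrt(t2 / (n - 2 + t2))
}

#' Flag divergence outliers per species comparison
#'
#' Iterative two-sided Grubbs test applied within each pairwise species
#' comparison: the most extreme value is tested against the Grubbs critical
#' value at `alpha` and, if flagged, removed before re-testing, until no
#' further value is extreme. Groups with fewer than 3 defined values are
#' left unflagged with a warning. Flagged records are meant to be excluded
#' from downstream regressions on divergence.
#'
#' @param records Tibble from [pairwise_divergence()].
#' @param alpha Significance level of each Grubbs test.
#' @return `records` with the `outlier` column filled in.
#' @export
flag_divergence_outliers <- function(records, alpha = 0.05) {
  stopifnot(all(c("species", "divergence") %in% names(records)))
  records$outlier <- FALSE
  for (sp in unique(records$species)) {
    idx <- which(records$species == sp & !is.na(records$divergence))
    if (length(idx) < 3) {
      warning("species ", sp, ": fewer than 3 divergence values; no outlier test")
      next
    }
    active <- idx
    repeat {
      n <- length(active)
      if (n < 3) break
      x <- records$divergence[active]
      s <- sd(x)
      if (s == 0) break
      dev <- abs(x - mean(x))
      g <- max(dev) / s
      if (g > grubbs_critical(n, alpha)) {
        worst <- active[which.max(dev)]
        records$outlier[worst] <- TRUE
        active <- setdiff(active, worst)
      } else break
    }
  }
  records
}
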