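# The human-centric battery of nine comparisons and the conservation
# classifier over each region's significance vector.

#' The human-centric comparison battery
#'
#' Nine comparisons: human against each of the five other species, then the
#' four clade-level group contrasts (human vs the rest; apes, i.e. human +
#' chimp, vs the rest; Catarrhini vs the rest; Haplorrhini vs Strepsirrhini).
#'
#' @param centric Species at the centre of the battery (default `"human"`);
#'   passing `"chimp"` re-roots the pairwise comparisons for the
#'   chimpanzee-centric control analysis.
#' @return Tibble: `comparison_id`, `group_a` (list), `group_b` (list),
#'   `type` (`pairwise`/`group`).
#' @export
comparison_battery <- function(centric = "human") {
  sp <- species_tree()$species
  stopifnot(centric %in% sp)
  others <- setdiff(sp, centric)
  pairwise <- tibble(
    comparison_id = paste0(centric, "_vs_", others),
    group_a = map(others, function(x) centric),
    group_b = map(others, function(x) x),
    type = "pairwise"
  )
  groups <- tibble(
    comparison_id = c("human_group", "ape_group", "catarrhini_group",
                      "haplorrhini_group"),
    group_a = list("human", c("human", "chimp"),
                   c("human", "chimp", "rhesus"),
                   c("human", "chimp", "rhesus", "marmoset")),
    group_b = list(setdiff(sp, "human"),
                   setdiff(sp, c("human", "chimp")),
                   setdiff(sp, c("human", "chimp", "rhesus")),
                   c("mouse_lemur", "bushbaby")),
    type = "group"
  )
  bind_rows(pairwise, groups)
}

#' Run the full comparison battery on ChIP counts
#'
#' Applies [diff_histone()] to each of the nine comparisons and assembles
#' each region's significance vector: `sig+` / `sig-` (by the sign of the
#' interaction log2 fold change), `ns`, or `untested`.
#'
#' @param chip_counts,metadata As in [diff_histone()].
#' @param fdr Per-comparison BH significance threshold (default 0.10).
#' @param battery Comparison table from [comparison_battery()].
#' @param marks Histone marks analyzed and merged.
#' @return List with `results` (stacked [diff_histone()] tables) and
#'   `signif` (wide tibble: `feature_id` plus one column per comparison).
#' @export
run_comparison_battery <- function(chip_counts, metadata, fdr = 0.10,
                                   battery = comparison_battery(),
                                   marks = c("H3K27ac", "H3K4me1")) {
  results <- map(seq_len(nrow(battery)), function(i) {
    diff_histone(chip_counts, metadata,
                 group_a = battery$group_a[[i]],
                 group_b = battery$group_b[[i]],
                 comparison_id = battery$comparison_id[i],
                 fdr = fdr, marks = marks)
  }) |> list_rbind()
  list(results = results, signif = battery_significance(results, fdr))
}

#' Assemble signed significance flags from battery results
#'
#' Re-derives each region's significance vector from stacked battery result
#' tables at an arbitrary FDR threshold, without refitting.
#'
#' @param results Stacked [diff_histone()] tables across comparisons.
#' @param fdr Threshold applied to the stored BH-adjusted p-values.
#' @return Wide tibble: `feature_id` plus one flag column per comparison
#'   (`sig+`, `sig-`, `ns`, `untested`).
#' @export
battery_significance <- function(results, fdr = 0.10) {
  results |>
    mutate(sig = !is.na(.data$padj) & .data$padj < fdr,
           flag = case_when(
             .data$status == "untested" ~ "untested",
             .data$sig & .data$log2fc > 0 ~ "sig+",
             .data$sig & .data$log2fc < 0 ~ "sig-",
             TRUE ~ "ns"
           )) |>
    select("feature_id", "comparison_id", "flag") |>
    tidyr::pivot_wider(names_from = "comparison_id", values_from = "flag")
}

sig_of <- function(x) x %in% c("sig+", "sig-")

consistent_sign <- function(...) {
  v <- c(...)
  all(v == "sig+") || all(v == "sig-")
}

classify_one <- function(v, centric = "human", require_pairwise = TRUE) {
  pw <- function(sp) v[[paste0(centric, "_vs_", sp)]]
  others <- setdiff(species_tree()$species, centric)
  any_sig <- any(vapply(names(v), function(k) sig_of(v[[k]]), TRUE))
  if (!any_sig) return("conserved")

  lab_def <- list(
    human_specific = list(group = "human_group", ns = character(),
                          sig = others),
    ape_specific = list(group = "ape_group", ns = "chimp",
                        sig = c("rhesus", "marmoset", "mouse_lemur", "bushbaby")),
    catarrhini_specific = list(group = "catarrhini_group",
                               ns = c("chimp", "rhesus"),
                               sig = c("marmoset", "mouse_lemur", "bushbaby")),
    haplorrhini_specific = list(group = "haplorrhini_group",
                                ns = c("chimp", "rhesus", "marmoset"),
                                sig = c("mouse_lemur", "bushbaby"))
  )
  for (lab in names(lab_def)) {
    d <- lab_def[[lab]]
    group_ok <- sig_of(v[[d$group]])
    ns_ok <- all(vapply(d$ns, function(sp) pw(sp) == "ns", TRUE))
    sig_flags <- vapply(d$sig, function(sp) pw(sp), character(1))
    sig_ok <- all(sig_of(sig_flags)) && consistent_sign(sig_flags)
    if (require_pairwise) {
      if (group_ok && ns_ok && sig_ok) return(lab)
    } else {
      if (group_ok) return(lab)
    }
  }
  "other_divergent"
}

#' Classify conservation from a significance vector
#'
#' Deterministic mapping from the nine-comparison significance vector to a
#' conservation label. A region is `conserved` when no comparison is
#' significant. A lineage-specific label requires the clade's group test to
#' be significant, every pairwise comparison crossing the clade boundary to
#' be significant with one consistent sign, and the within-clade pairwise
#' comparisons to be non-significant (an `untested` entry in a required
#' comparison never supports a lineage-specific call). Everything else is
#' `other_divergent`. Setting `require_pairwise = FALSE` relaxes the rule to
#' the clade group test alone.
#'
#' @param signif Wide tibble from [run_comparison_battery()] (`feature_id`
#'   plus the nine comparison columns).
#' @param require_pairwise Demand sign-consistent pairwise significance in
#'   addition to the group test (default `TRUE`).
#' @return Tibble `feature_id`, `label`.
#' @export
classify_conservation <- function(signif, require_pairwise = TRUE) {
  cols <- setdiff(names(signif), "feature_id")
  stopifnot(length(cols) == 9)
  labels <- vapply(seq_len(nrow(signif)), function(i) {
    classify_one(as.list(signif[i, cols]),
                 require_pairwise = require_pairwise)
  }, character(1))
  tibble(feature_id = signif$feature_id, label = labels)
}

#' Summarize conservation calls over the CRE catalogue
#'
#' Counts and percentages of each conservation label, overall and stratified
#' by CRE class (promoter/enhancer), TE-overlap flag, and lineage age of the
#' overlapping TE when those columns are present in the catalogue.
#'
#' @param calls Tibble `feature_id`, `label` from [classify_conservation()].
#' @param catalogue Optional catalogue tibble (`cre_id`, `cre_class`,
#'   `te_flag`, ...) to stratify by.
#' @return Tibble: `stratum`, `stratum_value`, `label`, `n`, `total`,
#'   `percent` (one decimal).
#' @export
summarize_catalogue <- function(calls, catalogue = NULL) {
  if (nrow(calls) == 0) {
    return(tibble(stratum = character(), stratum_value = character(),
                  label = character(), n = integer(), total = integer(),
                  percent = numeric()))
  }
  one <- function(df, stratum, value) {
    df |>
      count(.data$label) |>
      mutate(stratum = stratum, stratum_value = value,
             total = sum(.data$n),
             percent = round(100 * .data$n / .data$total, 1)) |>
      select("stratum", "stratum_value", "label", "n", "total", "percent")
  }
  out <- one(calls, "overall", "all")
  if (!is.null(catalogue)) {
    joined <- calls |>
      left_join(catalogue, by = c(feature_id = "cre_id"))
    for (col in intersect(c("cre_class", "te_flag", "lineage_age"),
                          names(joined))) {
      vals <- unique(joined[[col]])
      vals <- vals[!is.na(vals)]
      for (v in vals) {
        out <- bind_rows(out, one(joined[joined[[col]] %in% v, ], col,
                                  as.character(v)))
      }
    }
  }
  out
}

#' Label percentages from headline counts
#'
#' Arithmetic helper turning a table of label counts and a denominator into
#' percentages: `percent` at full precision and `percent_1dp` rounded to one
#' decimal as printed in summaries.
#'
#' @param counts Named numeric vector or tibble (`label`, `n`).
#' @param total Denominator count.
#' @return Tibble `label`, `n`, `total`, `percent`, `percent_1dp`.
#' @export
label_percentages <- function(counts, total) {
  if (!is.data.frame(counts)) {
    counts <- tibble(label = names(counts), n = as.numeric(counts))
  }
  counts |> mutate(total = total, percent = 100 * .data$n / total,
                   percent_1dp = round(.data$percent, 1))
}
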