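# CRE catalogue construction: merging histone-mark peak sets, promoter vs
# enhancer classification by TSS distance, nearest-gene assignment, and
# TE-overlap annotation.

# 0-based half-open tibble -> IRanges (1-based closed)
as_iranges <- function(df) {
  IRanges::IRanges(start = df$start + 1, end = df$end)
}

#' Merge peak sets from two histone marks
#'
#' Takes the union of the two interval sets: any two input intervals sharing
#' at least one base end up in the same output interval. Each merged interval
#' records which marks contributed to it.
#'
#' @param peaks_k27ac,peaks_k4me1 Tibbles with `chrom`, `start`, `end`
#'   (0-based half-open). Either may be empty.
#' @return Tibble `chrom`, `start`, `end`, `marks` (comma-separated),
#'   sorted and pairwise disjoint.
#' @export
merge_marks <- function(peaks_k27ac, peaks_k4me1) {
  check_bed_cols <- function(df, nm) {
    if (nrow(df) == 0) return(invisible())
    bad <- which(!is.finite(df$start) | !is.finite(df$end) |
                   df$end <= df$start)
    if (length(bad)) stop("malformed BED line ", bad[1], " in ", nm)
  }
  check_bed_cols(peaks_k27ac, "H3K27ac peaks")
  check_bed_cols(peaks_k4me1, "H3K4me1 peaks")
  all_pk <- bind_rows(
    peaks_k27ac |> mutate(mark = "H3K27ac"),
    peaks_k4me1 |> mutate(mark = "H3K4me1")
  )
  if (nrow(all_pk) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  marks = character()))
  }
  out <- all_pk |>
    group_by(.data$chrom) |>
    group_split() |>
    map(function(g) {
      red <- IRanges::reduce(as_iranges(g))
      hits <- IRanges::findOverlaps(as_iranges(g), red)
      marks <- vapply(seq_along(red), function(i) {
        paste(sort(unique(g$mark[S4Vectors::queryHits(hits)[
          S4Vectors::subjectHits(hits) == i]])), collapse = ",")
      }, character(1))
      tibble(chrom = g$chrom[1], start = IRanges::start(red) - 1,
             end = as.numeric(IRanges::end(red)), marks = marks)
    }) |>
    list_rbind() |>
    arrange(.data$chrom, .data$start)
  out
}

#' Classify CREs as promoters or enhancers by TSS distance
#'
#' Distance is measured from the nearest CRE edge to the TSS point (0 when
#' the TSS falls inside the CRE). A CRE is a promoter when the distance to
#' the nearest TSS is strictly below `promoter_tss_bp` (default 1 kb);
#' a distance of exactly 1000 bp is an enhancer. Nearest-gene ties are
#' broken by the lexicographically smallest gene identifier. CREs on a
#' chromosome with no TSS get `NA` class and a `no_tss` flag.
#'
#' @param cres Tibble with `cre_id`, `chrom`, `start`, `end`.
#' @param tss Tibble with `gene_id`, `chrom`, `pos` (0-based TSS position).
#' @param promoter_tss_bp Promoter distance threshold in bp.
#' @return `cres` with added `tss_distance`, `cre_class`, `nearest_gene`,
#'   `no_tss`.
#' @export
classify_cres <- function(cres, tss, promoter_tss_bp = 1000) {
  stopifnot(promoter_tss_bp > 0)
  n <- nrow(cres)
  dist <- rep(NA_real_, n); gene <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    t_c <- tss[tss$chrom == cres$chrom[i], ]
    if (nrow(t_c) == 0) next
    d <- pmax(0, cres$start[i] - t_c$pos, t_c$pos - (cres$end[i] - 1))
    dist[i] <- min(d)
    gene[i] <- min(t_c$gene_id[d == min(d)])
  }
  cres |>
    mutate(tss_distance = dist,
           cre_class = case_when(
             is.na(dist) ~ NA_character_,
             dist < promoter_tss_bp ~ "promoter",
             TRUE ~ "enhancer"
           ),
           nearest_gene = gene,
           no_tss = is.na(dist))
}

#' Annotate CREs with transposable-element overlap
#'
#' The overlap fraction is the number of CRE bases covered by the union of
#' all TE intervals divided by CRE length, so nested or overlapping repeat
#' records are never double-counted. A CRE is flagged TE-derived when the
#' fraction is at least `min_fraction` (default 0.20, boundary inclusive).
#' `te_families` lists every subfamily contributing at least one base.
#'
#' @param cres Tibble with `cre_id`, `chrom`, `start`, `end`.
#' @param te_annotation Tibble with `chrom`, `start`, `end`, `subfamily`
#'   (and optionally `family`, `te_class`, `lineage_age`).
#' @param min_fraction Flagging threshold on the overlap fraction.
#' @return `cres` with added `te_overlap_fraction`, `te_flag`,
#'   `te_families` (comma-separated, `""` when none).
#' @export
annotate_te_overlap <- function(cres, te_annotation, min_fraction = 0.20) {
  if (any(cres$end <= cres$start)) {
    stop("zero-length CRE: ", cres$cre_id[which(cres$end <= cres$start)[1]])
  }
  n <- nrow(cres)
  frac <- numeric(n); fams <- character(n)
  for (ch in unique(cres$chrom)) {
    ci <- which(cres$chrom == ch)
    te_c <- te_annotation[te_annotation$chrom == ch, ]
    if (nrow(te_c) == 0) { frac[ci] <- 0; fams[ci] <- ""; next }
    ir_cre <- as_iranges(cres[ci, ])
    red <- IRanges::reduce(as_iranges(te_c))
    hits <- IRanges::findOverlaps(ir_cre, red)
    covered <- numeric(length(ci))
    if (length(hits)) {
      pi <- IRanges::pintersect(ir_cre[S4Vectors::queryHits(hits)],
                                red[S4Vectors::subjectHits(hits)])
      w <- tapply(IRanges::width(pi), S4Vectors::queryHits(hits), sum)
      covered[as.integer(names(w))] <- w
    }
    frac[ci] <- covered / (cres$end[ci] - cres$start[ci])
    hits2 <- IRanges::findOverlaps(ir_cre, as_iranges(te_c))
    fams[ci] <- vapply(seq_along(ci), function(k) {
      sub <- te_c$subfamily[S4Vectors::subjectHits(hits2)[
        S4Vectors::queryHits(hits2) == k]]
      paste(sort(unique(sub)), collapse = ",")
    }, character(1))
  }
  cres |>
    mutate(te_overlap_fraction = frac,
           te_flag = frac >= min_fraction,
           te_families = fams)
}

#' Build the full CRE catalogue
#'
#' Merges the two mark peak sets, assigns identifiers, classifies promoter vs
#' enhancer, and annotates TE overlap.
#'
#' @param peaks_k27ac,peaks_k4me1 Peak tibbles (`chrom`, `start`, `end`).
#' @param tss TSS tibble (`gene_id`, `chrom`, `pos`).
#' @param te_annotation TE tibble (see [annotate_te_overlap()]); optional.
#' @param promoter_tss_bp,te_min_fraction Thresholds.
#' @return Catalogue tibble: one row per merged CRE.
#' @export
build_catalogue <- function(peaks_k27ac, peaks_k4me1, tss,
                            te_annotation = NULL,
                            promoter_tss_bp = 1000, te_min_fraction = 0.20) {
  merged <- merge_marks(peaks_k27ac, peaks_k4me1) |>
    mutate(cre_id = sprintf("cre%05d", row_number())) |>
    select("cre_id", "chrom", "start", "end", "marks")
  out <- classify_cres(merged, tss, promoter_tss_bp)
  if (!is.null(te_annotation)) {
    out <- annotate_te_overlap(out, te_annotation, te_min_fraction)
  }
  out
}
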