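# Permutation-based TE-subfamily enrichment: CRE intervals are shuffled
# uniformly along their own chromosome (length preserved) and the >=20%
# union-coverage rule is re-applied to build the null.

#' Shuffle CRE intervals along their chromosomes
#'
#' Each interval is placed uniformly at random on its own chromosome with its
#' length preserved; shuffled intervals may overlap each other. When an
#' exclusion mask is supplied, placements overlapping it are rejected and
#' redrawn (up to 1000 attempts per interval).
#'
#' @param cres Tibble `cre_id`, `chrom`, `start`, `end`.
#' @param genome_sizes Tibble `chrom`, `size` (bp per chromosome).
#' @param exclude Optional tibble `chrom`, `start`, `end` of forbidden
#'   regions.
#' @param seed Optional integer; when given, the shuffle is a deterministic
#'   function of it (the ambient RNG state is restored afterwards).
#' @return `cres` with new `start`, `end`.
#' @export
shuffle_intervals <- function(cres, genome_sizes, exclude = NULL,
                              seed = NULL) {
  if (!is.null(seed)) {
    return(withr_seed(seed, shuffle_intervals(cres, genome_sizes, exclude)))
  }
  sizes <- setNames(genome_sizes$size, genome_sizes$chrom)
  len <- cres$end - cres$start
  maxstart <- sizes[cres$chrom] - len
  if (any(is.na(maxstart))) stop("chromosome missing from genome_sizes")
  if (any(maxstart < 0)) {
    stop("CRE longer than its chromosome: ",
         cres$cre_id[which(maxstart < 0)[1]])
  }
  maxstart <- unname(maxstart)
  new_start <- floor(runif(nrow(cres)) * (maxstart + 1))
  if (!is.null(exclude) && nrow(exclude) > 0) {
    for (i in seq_len(nrow(cres))) {
      ex <- exclude[exclude$chrom == cres$chrom[i], ]
      if (nrow(ex) == 0) next
      tries <- 0
      while (any(new_start[i] < ex$end & new_start[i] + len[i] > ex$start)) {
        tries <- tries + 1
        if (tries > 1000) stop("cannot place interval outside exclusion mask")
        new_start[i] <- floor(runif(1) * (maxstart[i] + 1))
      }
    }
  }
  cres |> mutate(start = new_start, end = new_start + len)
}

# Pre-reduced per-chromosome, per-subfamily TE ranges so each shuffle costs
# one overlap query per chromosome.
te_index <- function(te_annotation) {
  subfams <- sort(unique(te_annotation$subfamily))
  idx <- lapply(split(te_annotation, te_annotation$chrom), function(tc) {
    per <- lapply(split(tc, tc$subfamily), function(g) {
      IRanges::reduce(as_iranges(g))
    })
    list(ranges = do.call(c, unname(per)),
         subfam = rep(names(per), vapply(per, length, 0L)))
  })
  list(by_chrom = idx, subfams = subfams)
}

# per-subfamily count of CREs passing the >=min_fraction union-coverage rule
count_te_hits <- function(cres, index, min_fraction) {
  subfams <- index$subfams
  out <- setNames(integer(length(subfams)), subfams)
  for (ch in unique(cres$chrom)) {
    ix <- index$by_chrom[[ch]]
    if (is.null(ix)) next
    ci <- which(cres$chrom == ch)
    ir_cre <- as_iranges(cres[ci, ])
    hits <- IRanges::findOverlaps(ir_cre, ix$ranges)
    if (length(hits) == 0) next
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    w <- IRanges::width(IRanges::pintersect(ir_cre[q], ix$ranges[s]))
    frac <- w / (cres$end[ci][q] - cres$start[ci][q])
    sfi <- match(ix$subfam[s], subfams)
    ind <- (sfi - 1) * length(ci) + q
    cov <- rowsum(frac, ind)
    pass_sf <- (as.numeric(rownames(cov))[cov[, 1] >= min_fraction] - 1) %/%
      length(ci) + 1
    if (length(pass_sf)) {
      tab <- tabulate(pass_sf, nbins = length(subfams))
      out <- out + tab
    }
  }
  out
}

#' Permutation test of TE-subfamily enrichment in CREs
#'
#' The observed statistic per subfamily is the number of CREs at least
#' `min_fraction`-covered by that subfamily's intervals. The null
#' distribution is built by re-placing the CREs uniformly on their
#' chromosomes `n_shuffles` times ([shuffle_intervals()]) and recomputing the
#' same statistic. The one-sided empirical enrichment p-value is
#' `(r + 1) / (n + 1)` with `r` the number of shuffles reaching at least the
#' observed count, so the smallest attainable p is `1 / (n_shuffles + 1)`.
#' A depletion p-value is reported symmetrically but does not feed the
#' `enriched` flag. BH adjustment is applied across subfamilies and
#' enrichment is called at `fdr` (default 1%).
#'
#' @param cres Tibble `cre_id`, `chrom`, `start`, `end`.
#' @param te_annotation Tibble `chrom`, `start`, `end`, `subfamily`.
#' @param genome_sizes Tibble `chrom`, `size`.
#' @param n_shuffles Number of permutation replicates (default 1000).
#' @param min_fraction Coverage rule threshold (default 0.20).
#' @param fdr FDR threshold for the `enriched` flag (default 0.01).
#' @param exclude Optional exclusion mask passed to [shuffle_intervals()].
#' @param seed Optional integer making the whole permutation run
#'   deterministic.
#' @return Tibble: `subfamily`, `observed`, `null_mean`, `null_sd`, `fold`,
#'   `empirical_p`, `depletion_p`, `padj`, `enriched`.
#' @export
enrichment_test <- function(cres, te_annotation, genome_sizes,
                            n_shuffles = 1000, min_fraction = 0.20,
                            fdr = 0.01, exclude = NULL, seed = NULL) {
  if (!is.null(seed)) {
    return(withr_seed(seed, enrichment_test(cres, te_annotation, genome_sizes,
                                            n_shuffles, min_fraction, fdr,
                                            exclude)))
  }
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  if (nrow(te_annotation) == 0) stop("no TE subfamilies present")
  index <- te_index(te_annotation)
  observed <- count_te_hits(cres, index, min_fraction)
  nulls <- matrix(0L, nrow = n_shuffles, ncol = length(observed),
                  dimnames = list(NULL, names(observed)))
  for (s in seq_len(n_shuffles)) {
    sh <- shuffle_intervals(cres, genome_sizes, exclude)
    nulls[s, ] <- count_te_hits(sh, index, min_fraction)
  }
  r_ge <- colSums(nulls >= rep(observed, each = n_shuffles))
  r_le <- colSums(nulls <= rep(observed, each = n_shuffles))
  null_mean <- colMeans(nulls)
  out <- tibble(
    subfamily = names(observed),
    observed = unname(as.integer(observed)),
    null_mean = unname(null_mean),
    null_sd = unname(apply(nulls, 2, sd)),
    fold = unname(if_else(null_mean > 0, observed / null_mean, NA_real_)),
    empirical_p = unname((r_ge + 1) / (n_shuffles + 1)),
    depletion_p = unname((r_le + 1) / (n_shuffles + 1))
  )
  out$padj <- bh_adjust(out$empirical_p)
  out$enriched <- out$padj < fdr
  out
}
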