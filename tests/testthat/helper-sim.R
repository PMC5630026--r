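# Shared fixtures, built in code and cached per test run.

tiny_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_bundle(sim_config(n_cres = 40, n_genes = 30,
                                           seed = 7))
    }
    cache
  }
})

# Two-group ChIP toy (one mark): IP counts carry baseline enrichment plus a
# per-region `l2fc` extra in group A; input flat. `l2fc` recycles over
# regions (keep most regions null so size factors are estimable, as in real
# ChIP data). Returns counts + metadata.
make_chip_toy <- function(n_regions, n_per_group = 3, depth = 100,
                          l2fc = 0, alpha = 0.05, ip_log2 = 2, seed = 1) {
  set.seed(seed)
  l2fc <- rep_len(l2fc, n_regions)
  meta <- tidyr::crossing(species = c("A", "B"),
                          individual = seq_len(n_per_group),
                          assay = c("IP", "input")) |>
    dplyr::mutate(mark = "H3K27ac",
                  sample_id = sprintf("%s_%d_%s", species, individual, assay))
  m <- vapply(seq_len(nrow(meta)), function(j) {
    mu <- if (meta$assay[j] == "input") rep(depth, n_regions)
          else depth * 2^(ip_log2 + if (meta$species[j] == "A") l2fc else 0)
    if (alpha > 0) rnbinom(n_regions, mu = mu, size = 1 / alpha)
    else rpois(n_regions, mu)
  }, numeric(n_regions))
  if (n_regions == 1) m <- matrix(m, nrow = 1)
  colnames(m) <- meta$sample_id
  counts <- dplyr::bind_cols(
    tibble::tibble(feature_id = sprintf("r%04d", seq_len(n_regions))),
    tibble::as_tibble(m)
  )
  list(counts = counts, metadata = meta, l2fc = l2fc)
}

# one gapless alignment block over given species rows
make_block <- function(species, starts, seqs, chrom = "chr1", strand = NULL,
                       src_size = 1e6) {
  if (is.null(strand)) strand <- rep("+", length(species))
  tibble::tibble(
    species = species, chrom = chrom, start = starts,
    size = nchar(gsub("-", "", seqs)), strand = strand,
    src_size = src_size, text = seqs
  )
}

# step-up BH oracle, independent of stats::p.adjust
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
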