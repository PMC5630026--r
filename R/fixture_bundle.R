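# Materialize a complete synthetic dataset on disk: MSA, intervals,
# annotations, count matrices, metadata, ground truth, and a checksum
# manifest. Everything is plain text so the bundle can be regenerated and
# diffed byte-for-byte.

#' Simulate a complete in-memory dataset
#'
#' Convenience wrapper running [simulate_truth()], [simulate_msa()] and
#' [simulate_counts()] under one configuration.
#'
#' @param config A [sim_config()].
#' @return List of class `cre_sim_bundle` with elements `config`, `tree`,
#'   `truth`, `msa` (see [simulate_msa()]) and `counts`
#'   (see [simulate_counts()]).
#' @export
simulate_bundle <- function(config = sim_config()) {
  tree <- species_tree(config$branch_scale)
  truth <- simulate_truth(config, tree)
  msa <- simulate_msa(tree, config, truth)
  counts <- simulate_counts(msa$truth, config)
  structure(list(config = config, tree = tree, truth = msa$truth,
                 msa = msa, counts = counts),
            class = "cre_sim_bundle")
}

bundle_files <- function() {
  c(maf = "msa.maf", cres = "cres.bed", tss = "tss.bed",
    te = "te_annotation.tsv", chip = "chip_counts.tsv",
    rna = "rna_counts.tsv", metadata = "metadata.tsv",
    truth = "truth.tsv", genes = "gene_info.tsv",
    genomes = "genome_sizes.tsv")
}

#' Write a fixture bundle to a directory
#'
#' @param bundle A `cre_sim_bundle` from [simulate_bundle()], or a
#'   [sim_config()] (in which case the bundle is simulated first).
#' @param outdir Output directory (created if missing).
#' @return Tibble manifest (file, md5), invisibly also written as
#'   `manifest.json`.
#' @export
write_fixture_bundle <- function(bundle, outdir) {
  if (inherits(bundle, "sim_config")) bundle <- simulate_bundle(bundle)
  stopifnot(inherits(bundle, "cre_sim_bundle"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  fp <- function(nm) file.path(outdir, bundle_files()[[nm]])

  write_maf(bundle$msa$blocks, fp("maf"))
  write_bed6(bundle$msa$cres |>
               mutate(name = .data$cre_id, score = 0, strand = "+"),
             fp("cres"))
  write_bed6(bundle$msa$tss |>
               mutate(start = .data$pos, end = .data$pos + 1,
                      name = .data$gene_id, score = 0, strand = "+"),
             fp("tss"))
  readr::write_tsv(bundle$msa$te_annotation, fp("te"))
  readr::write_tsv(bundle$counts$chip_counts, fp("chip"))
  readr::write_tsv(bundle$counts$rna_counts, fp("rna"))
  readr::write_tsv(bundle$counts$metadata, fp("metadata"))
  readr::write_tsv(bundle$truth |>
                     left_join(bundle$msa$cres, by = "cre_id"),
                   fp("truth"))
  readr::write_tsv(bundle$counts$gene_info, fp("genes"))
  readr::write_tsv(bundle$msa$genome_sizes, fp("genomes"))

  files <- unname(bundle_files())
  manifest <- tibble(file = files,
                     md5 = unname(tools::md5sum(file.path(outdir, files))))
  jsonlite::write_json(
    list(files = manifest,
         config = bundle$config[setdiff(names(bundle$config), "prop_states")],
         prop_states = as.list(bundle$config$prop_states)),
    file.path(outdir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(manifest)
}

write_bed6 <- function(df, path) {
  out <- df |>
    select("chrom", "start", "end", "name", "score", "strand") |>
    mutate(start = format(.data$start, scientific = FALSE, trim = TRUE),
           end = format(.data$end, scientific = FALSE, trim = TRUE))
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a BED6 (or BED3+) file
#'
#' @param path BED file path; 0-based half-open intervals.
#' @return Tibble with columns `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        progress = FALSE, comment = "#")
  if (nrow(df) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  name = character()))
  }
  names(df) <- cols[seq_len(min(ncol(df), 6))]
  if (!is.numeric(df$start) || !is.numeric(df$end) ||
      any(is.na(df$start)) || any(is.na(df$end))) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$start))) |
                   is.na(suppressWarnings(as.numeric(df$end))))[1]
    stop("malformed BED line ", ifelse(is.na(bad), 1, bad), " in ", path)
  }
  as_tibble(df)
}

#' Read a fixture bundle from a directory
#'
#' @param dir Directory written by [write_fixture_bundle()].
#' @return List with `blocks`, `cres`, `tss`, `te_annotation`,
#'   `chip_counts`, `rna_counts`, `metadata`, `truth`, `gene_info`,
#'   `genome_sizes`, `manifest`.
#' @export
read_fixture_bundle <- function(dir) {
  fp <- function(nm) file.path(dir, bundle_files()[[nm]])
  for (f in unname(bundle_files())) {
    if (!file.exists(file.path(dir, f))) stop("bundle file missing: ", f)
  }
  rt <- function(p) readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
  cres <- read_bed(fp("cres"))
  tss <- read_bed(fp("tss"))
  list(
    blocks = parse_maf(fp("maf")),
    cres = if (nrow(cres)) cres |> rename(cre_id = "name") |>
      select("cre_id", "chrom", "start", "end") else
        tibble(cre_id = character(), chrom = character(),
               start = numeric(), end = numeric()),
    tss = if (nrow(tss)) tibble(gene_id = tss$name, chrom = tss$chrom,
                                pos = tss$start) else
      tibble(gene_id = character(), chrom = character(), pos = numeric()),
    te_annotation = rt(fp("te")),
    chip_counts = rt(fp("chip")),
    rna_counts = rt(fp("rna")),
    metadata = rt(fp("metadata")),
    truth = rt(fp("truth")),
    gene_info = rt(fp("genes")),
    genome_sizes = rt(fp("genomes")),
    manifest = jsonlite::read_json(file.path(dir, "manifest.json"))
  )
}
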