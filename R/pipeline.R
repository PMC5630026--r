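# End-to-end orchestration: catalogue -> orthology -> battery -> conservation
# -> divergence -> TE enrichment -> association, on a fixture bundle or an
# in-memory simulated dataset.

#' Pipeline parameters
#'
#' All thresholds of the analysis in one validated list. Defaults are the
#' study's: FDR 10% for differential histone modification, 5% for
#' differential expression, 1% for TE enrichment; the TE-derived rule at 20%
#' of CRE length; promoters within 1 kb of a TSS; orthologous presence at
#' 50% aligned coverage; 1000 shuffle replicates.
#'
#' @param fdr_histone,fdr_expression,fdr_te FDR thresholds in (0, 1).
#' @param te_min_fraction TE-overlap fraction rule threshold.
#' @param promoter_tss_bp Promoter TSS-distance threshold (bp).
#' @param min_coverage Orthologous-coverage threshold.
#' @param n_shuffles Permutation replicates for TE enrichment.
#' @param divergence_flank Flank (bp) added around CREs for divergence.
#' @param seed Integer seed controlling the permutation stage.
#' @return List of class `pipeline_params`.
#' @export
pipeline_params <- function(fdr_histone = 0.10, fdr_expression = 0.05,
                            fdr_te = 0.01, te_min_fraction = 0.20,
                            promoter_tss_bp = 1000, min_coverage = 0.5,
                            n_shuffles = 1000, divergence_flank = 500,
                            seed = 1L) {
  thr <- c(fdr_histone, fdr_expression, fdr_te, te_min_fraction, min_coverage)
  stopifnot(all(thr > 0 & thr < 1), promoter_tss_bp > 0, n_shuffles >= 1,
            divergence_flank >= 0)
  structure(list(fdr_histone = fdr_histone, fdr_expression = fdr_expression,
                 fdr_te = fdr_te, te_min_fraction = te_min_fraction,
                 promoter_tss_bp = promoter_tss_bp,
                 min_coverage = min_coverage, n_shuffles = n_shuffles,
                 divergence_flank = divergence_flank,
                 seed = as.integer(seed)),
            class = "pipeline_params")
}

# normalize input (bundle dir / sim bundle / prepared list) to one shape
as_pipeline_data <- function(x) {
  if (is.character(x) && length(x) == 1) return(read_fixture_bundle(x))
  if (inherits(x, "cre_sim_bundle")) {
    return(list(blocks = x$msa$blocks, cres = x$msa$cres, tss = x$msa$tss,
                te_annotation = x$msa$te_annotation,
                chip_counts = x$counts$chip_counts,
                rna_counts = x$counts$rna_counts,
                metadata = x$counts$metadata, truth = x$truth,
                gene_info = x$counts$gene_info,
                genome_sizes = x$msa$genome_sizes))
  }
  required <- c("blocks", "cres", "tss", "te_annotation", "chip_counts",
                "rna_counts", "metadata", "genome_sizes")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop("pipeline input lacks fields: ", paste(missing, collapse = ", "))
  }
  x
}

#' Run the full cross-species CRE analysis
#'
#' Executes the stages in dependency order on a fixture bundle (directory
#' path), an in-memory [simulate_bundle()], or an equivalent list of tables:
#' CRE catalogue annotation, orthologous-interval mapping, the
#' nine-comparison differential histone-modification battery, conservation
#' classification, pairwise sequence divergence with outlier flagging, TE
#' subfamily enrichment, the differential-expression battery, and the
#' regulatory-expression association statistics.
#'
#' @param data Bundle directory, `cre_sim_bundle`, or list of tables.
#' @param params A [pipeline_params()].
#' @param stages Character subset of
#'   `c("catalogue","orthology","battery","divergence","te","expression",
#'   "association")` to run (dependencies are not auto-added; later stages
#'   silently skip when their inputs are absent).
#' @return List of class `cre_pipeline_result` with one element per stage
#'   plus `params`.
#' @export
run_pipeline <- function(data, params = pipeline_params(),
                         stages = c("catalogue", "orthology", "battery",
                                    "divergence", "te", "expression",
                                    "association")) {
  stopifnot(inherits(params, "pipeline_params"))
  d <- as_pipeline_data(data)
  res <- list(params = params)

  if ("catalogue" %in% stages) {
    res$catalogue <- d$cres |>
      classify_cres(d$tss, params$promoter_tss_bp) |>
      annotate_te_overlap(d$te_annotation, params$te_min_fraction)
  }

  if ("orthology" %in% stages) {
    res$orthologs <- map_orthologs(d$cres, d$blocks,
                                   min_coverage = params$min_coverage)
    res$six_way <- res$orthologs |>
      distinct(.data$cre_id, .data$six_way)
  }

  six_ids <- if (!is.null(res$six_way)) {
    res$six_way$cre_id[res$six_way$six_way]
  } else d$cres$cre_id

  if ("battery" %in% stages) {
    chip <- d$chip_counts |> filter(.data$feature_id %in% six_ids)
    bat <- run_comparison_battery(chip, d$metadata, fdr = params$fdr_histone)
    res$battery <- bat$results
    res$signif <- bat$signif
    res$calls <- classify_conservation(bat$signif)
    res$conservation_summary <-
      summarize_catalogue(res$calls, res$catalogue)
  }

  if ("divergence" %in% stages) {
    six_cres <- d$cres |> filter(.data$cre_id %in% six_ids)
    ortho_fl <- map_orthologs(six_cres, d$blocks,
                              min_coverage = params$min_coverage,
                              flank = params$divergence_flank)
    res$divergence <- pairwise_divergence(ortho_fl, six_way_only = FALSE) |>
      flag_divergence_outliers()
  }

  if ("te" %in% stages && nrow(d$te_annotation) > 0) {
    gs <- d$genome_sizes |>
      filter(.data$species == "human") |>
      select("chrom", "size")
    res$te_enrichment <- enrichment_test(
      d$cres, d$te_annotation, gs,
      n_shuffles = params$n_shuffles,
      min_fraction = params$te_min_fraction, fdr = params$fdr_te,
      seed = params$seed
    )
  }

  if ("expression" %in% stages) {
    battery_spec <- comparison_battery()
    res$expression <- map(seq_len(nrow(battery_spec)), function(i) {
      diff_expression(d$rna_counts, d$metadata,
                      group_a = battery_spec$group_a[[i]],
                      group_b = battery_spec$group_b[[i]],
                      gene_lengths = d$gene_info,
                      comparison_id = battery_spec$comparison_id[i],
                      fdr = params$fdr_expression)
    }) |> list_rbind()
  }

  if ("association" %in% stages && !is.null(res$expression) &&
      !is.null(res$battery)) {
    pairwise_ids <- paste0("human_vs_",
                           setdiff(species_tree()$species, "human"))
    links <- res$catalogue |>
      select(cre_id = "cre_id", gene_id = "nearest_gene") |>
      filter(!is.na(.data$gene_id))
    res$association <- expression_association(
      res$expression |> filter(.data$comparison_id %in% pairwise_ids),
      res$battery |> filter(.data$comparison_id %in% pairwise_ids),
      links
    )
    if (!is.null(res$divergence)) {
      dmc <- res$battery |>
        filter(.data$comparison_id == "human_vs_chimp", .data$status == "ok")
      div <- res$divergence |>
        filter(.data$species == "chimp", !.data$outlier,
               !is.na(.data$divergence)) |>
        inner_join(dmc, by = c(cre_id = "feature_id"))
      if (nrow(div) > 3 && length(unique(div$significant)) == 2 &&
          sd(div$divergence) > 0) {
        res$divergence_logistic <-
          logistic_conservation(div$significant, div$divergence)
      }
    }
  }

  structure(res, class = "cre_pipeline_result")
}

#' @export
print.cre_pipeline_result <- function(x, ...) {
  cat("<cre_pipeline_result> stages:",
      paste(setdiff(names(x), "params"), collapse = ", "), "\n")
  if (!is.null(x$calls)) {
    tab <- table(x$calls$label)
    cat("conservation labels:\n")
    print(tab)
  }
  invisible(x)
}
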