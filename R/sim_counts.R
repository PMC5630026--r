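# Count simulator: negative-binomial ChIP (IP + input) and RNA counts with
# branch-specific activity effects and per-sample size-factor heterogeneity.

#' Expected IP means implied by the ground truth
#'
#' The noise-free expectation of IP counts per CRE and species, before
#' per-sample size factors: `mean_depth * 2^(ip_over_input_log2 +
#' true_log2fc)` for species in the gained/lost clade and
#' `mean_depth * 2^ip_over_input_log2` elsewhere. The ratio between a
#' clade species and an outgroup species is therefore exactly
#' `2^true_log2fc`.
#'
#' @param truth Tibble from [simulate_truth()].
#' @param config A [sim_config()].
#' @return Tibble with columns `cre_id`, `species`, `mu_ip`.
#' @export
expected_ip_means <- function(truth, config) {
  species <- species_tree()$species
  tidyr::crossing(truth[c("cre_id", "true_state", "true_log2fc")],
                  species = species) |>
    mutate(
      in_clade = map2_lgl(.data$true_state, .data$species,
                          function(st, sp) sp %in% state_clade(st)),
      mu_ip = config$mean_depth *
        2^(config$ip_over_input_log2 + if_else(.data$in_clade, .data$true_log2fc, 0))
    ) |>
    select("cre_id", "species", "mu_ip")
}

rnb <- function(n, mu, alpha) {
  if (alpha > 0) rnbinom(n, mu = mu, size = 1 / alpha) else rpois(n, mu)
}

#' Simulate ChIP-seq and RNA-seq count matrices
#'
#' Draws NB counts for every CRE x sample (both histone marks, IP and input)
#' and for every gene x RNA sample. IP means carry the baseline IP-over-input
#' enrichment plus the state-dependent activity effect on the gained/lost
#' clade; input means are flat. Expression of each linked gene is shifted by
#' `rna_effect_fraction` of its (first) CRE's effect. Log-normal per-sample
#' size factors inject depth heterogeneity.
#'
#' @param truth Tibble from [simulate_truth()].
#' @param config A [sim_config()].
#' @return List of class `cre_sim_counts`:
#'   \describe{
#'     \item{chip_counts}{tibble, `feature_id` plus one column per ChIP sample.}
#'     \item{rna_counts}{tibble, `feature_id` plus one column per RNA sample.}
#'     \item{metadata}{tibble: sample_id, species, individual, assay, mark, sex.}
#'     \item{gene_info}{tibble: gene_id, length, clade effect columns.}
#'     \item{size_factors}{tibble: sample_id, true_size_factor.}
#'   }
#' @export
simulate_counts <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(truth) == 0 && config$n_genes == 0) stop("truth must be non-empty")
  tree <- species_tree()
  species <- tree$species
  inds <- seq_len(config$individuals_per_species)

  meta_chip <- tidyr::crossing(species = species, individual = inds,
                               mark = c("H3K27ac", "H3K4me1"),
                               assay = c("IP", "input")) |>
    mutate(sample_id = sprintf("%s_%d_%s_%s", .data$species, .data$individual,
                               .data$mark, .data$assay))
  meta_rna <- tidyr::crossing(species = species, individual = inds) |>
    mutate(mark = "none", assay = "RNA",
           sample_id = sprintf("%s_%d_RNA", .data$species, .data$individual))
  sp_levels <- species
  metadata <- bind_rows(meta_chip, meta_rna) |>
    mutate(sex = if_else(.data$species == "bushbaby", "M",
                         c("F", "M")[(.data$individual %% 2) + 1])) |>
    select("sample_id", "species", "individual", "assay", "mark", "sex") |>
    arrange(match(.data$species, sp_levels), .data$individual, .data$mark,
            .data$assay)

  withr_seed(stage_seed(config, "counts"), {
    sf <- exp(rnorm(nrow(metadata), 0, config$size_factor_sd))
    sf <- sf / exp(mean(log(sf)))
    size_factors <- tibble(sample_id = metadata$sample_id,
                           true_size_factor = sf)

    mu_ip_tab <- expected_ip_means(truth, config)
    mu_ip <- matrix(NA_real_, nrow = nrow(truth), ncol = length(species),
                    dimnames = list(truth$cre_id, species))
    for (sp in species) {
      v <- mu_ip_tab$mu_ip[mu_ip_tab$species == sp]
      mu_ip[mu_ip_tab$cre_id[mu_ip_tab$species == sp], sp] <- v
    }

    chip_meta <- metadata[metadata$assay %in% c("IP", "input"), ]
    chip_mat <- matrix(0L, nrow = nrow(truth), ncol = nrow(chip_meta),
                       dimnames = list(truth$cre_id, NULL))
    chip_ids <- character(nrow(chip_meta))
    for (j in seq_len(nrow(chip_meta))) {
      m <- chip_meta[j, ]
      chip_ids[j] <- m$sample_id
      sfj <- sf[match(m$sample_id, metadata$sample_id)]
      mu <- if (m$assay == "IP") mu_ip[, m$species] * sfj
            else rep(config$mean_depth * sfj, nrow(truth))
      if (nrow(truth) > 0) chip_mat[, j] <- rnb(nrow(truth), mu, config$dispersion)
    }
    colnames(chip_mat) <- chip_ids

    # gene-level effects: the first CRE linked to each gene donates its state
    gene_ids <- sprintf("gene%05d", seq_len(config$n_genes))
    gene_len <- round(runif(config$n_genes, 500, 5000))
    gene_state <- rep("conserved", config$n_genes)
    gene_l2fc <- rep(0, config$n_genes)
    if (nrow(truth) > 0) {
      donor <- truth |> mutate(.row = row_number()) |>
        group_by(.data$linked_gene) |>
        summarise(.row = min(.data$.row), .groups = "drop")
      d <- truth[donor$.row, ]
      idx <- match(donor$linked_gene, gene_ids)
      gene_state[idx] <- d$true_state
      gene_l2fc[idx] <- d$true_log2fc * config$rna_effect_fraction
    }
    gene_info <- tibble(gene_id = gene_ids, length = gene_len,
                        state = gene_state,
                        true_log2fc_rna = gene_l2fc)

    rna_meta <- metadata[metadata$assay == "RNA", ]
    rna_mat <- matrix(0L, nrow = config$n_genes, ncol = nrow(rna_meta),
                      dimnames = list(gene_ids, rna_meta$sample_id))
    for (j in seq_len(nrow(rna_meta))) {
      m <- rna_meta[j, ]
      sfj <- sf[match(m$sample_id, metadata$sample_id)]
      in_clade <- vapply(gene_state, function(st) m$species %in% state_clade(st),
                         TRUE)
      mu <- config$mean_depth * (gene_len / 1000) *
        2^(if_else(in_clade, gene_l2fc, 0)) * sfj
      rna_mat[, j] <- rnb(config$n_genes, mu, config$dispersion)
    }

    structure(
      list(
        chip_counts = bind_cols(tibble(feature_id = truth$cre_id),
                                as_tibble(chip_mat)),
        rna_counts = bind_cols(tibble(feature_id = gene_ids),
                               as_tibble(rna_mat)),
        metadata = metadata, gene_info = gene_info,
        size_factors = size_factors
      ),
      class = "cre_sim_counts"
    )
  })
}
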