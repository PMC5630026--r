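#' Configuration for the synthetic six-species dataset
#'
#' Collects every tunable of the generator in one validated list. Defaults
#' describe the study conditions the downstream analysis assumes: three or
#' four individuals per species, negative-binomial (NB) counts with moderate
#' biological dispersion, IP enrichment over input, a two-unit log2 activity
#' effect on the branch where a CRE was gained or lost, and a realistic share
#' of CREs overlapping transposable elements.
#'
#' @param n_cres Number of CREs to simulate.
#' @param n_genes Number of genes; every CRE is linked to one gene
#'   (several CREs may share a gene when `n_genes < n_cres`).
#' @param individuals_per_species Integer in `[3, 4]`.
#' @param mean_depth Expected IP read count per region.
#' @param dispersion NB dispersion `alpha` (variance = mu + alpha * mu^2);
#'   `0` gives Poisson counts.
#' @param ip_over_input_log2 Baseline log2 enrichment of IP over input.
#' @param effect_log2fc Magnitude of the activity effect (|log2 fold change|)
#'   applied to non-conserved CREs on their gained/lost branch.
#' @param branch_scale Multiplier on all branch lengths (sequence divergence).
#' @param te_density Fraction of CREs carrying a planted TE.
#' @param rna_effect_fraction Fraction of the CRE activity effect propagated
#'   to the linked gene's expression.
#' @param indel_rate Indel events per substitution (relative rate).
#' @param cre_width Width of the conserved core of each CRE in bp.
#' @param flank Flank width (bp) on each side of the CRE within its
#'   alignment block.
#' @param prop_states Named numeric vector of true-state proportions over
#'   `conserved`, `human_specific`, `ape_specific`, `catarrhini_specific`,
#'   `haplorrhini_specific`, `other`; must sum to 1.
#' @param prop_promoter Fraction of CREs whose linked TSS falls inside the
#'   CRE (promoters); the rest get a TSS 2-20 kb away (enhancers).
#' @param size_factor_sd Standard deviation of per-sample log-normal
#'   size-factor heterogeneity.
#' @param seed Master seed; all per-stage seeds derive from it.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_cres = 2000,
                       n_genes = ceiling(n_cres * 0.8),
                       individuals_per_species = 4,
                       mean_depth = 100,
                       dispersion = 0.05,
                       ip_over_input_log2 = 2,
                       effect_log2fc = 2,
                       branch_scale = 1,
                       te_density = 0.25,
                       rna_effect_fraction = 0.5,
                       indel_rate = 0.1,
                       cre_width = 600,
                       flank = 500,
                       prop_states = c(conserved = 0.63, human_specific = 0.02,
                                       ape_specific = 0.06,
                                       catarrhini_specific = 0.06,
                                       haplorrhini_specific = 0.08,
                                       other = 0.15),
                       prop_promoter = 0.175,
                       size_factor_sd = 0.15,
                       seed = 1L) {
  stopifnot(
    n_cres >= 0, n_genes >= 1,
    individuals_per_species %in% 3:4,
    mean_depth > 0, dispersion >= 0,
    branch_scale >= 0, te_density >= 0, te_density <= 1,
    rna_effect_fraction >= 0, rna_effect_fraction <= 1,
    indel_rate >= 0, cre_width >= 1, flank >= 0,
    prop_promoter >= 0, prop_promoter <= 1,
    size_factor_sd >= 0, length(seed) == 1
  )
  states <- c("conserved", "human_specific", "ape_specific",
              "catarrhini_specific", "haplorrhini_specific", "other")
  stopifnot(setequal(names(prop_states), states),
            abs(sum(prop_states) - 1) < 1e-8, all(prop_states >= 0))
  structure(
    list(n_cres = as.integer(n_cres), n_genes = as.integer(n_genes),
         individuals_per_species = as.integer(individuals_per_species),
         mean_depth = mean_depth, dispersion = dispersion,
         ip_over_input_log2 = ip_over_input_log2,
         effect_log2fc = effect_log2fc, branch_scale = branch_scale,
         te_density = te_density, rna_effect_fraction = rna_effect_fraction,
         indel_rate = indel_rate, cre_width = as.integer(cre_width),
         flank = as.integer(flank), prop_states = prop_states[states],
         prop_promoter = prop_promoter, size_factor_sd = size_factor_sd,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Deterministic child seed for a named simulation stage, kept within the
# 32-bit integer range.
stage_seed <- function(config, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(config$seed) * 7919 + h * 104729) %% 2147483647)
}

# Clade of species whose activity differs from the rest, per true state.
state_clade <- function(state, tree = species_tree()) {
  switch(state,
    conserved            = character(),
    human_specific       = "human",
    ape_specific         = c("human", "chimp"),
    catarrhini_specific  = c("human", "chimp", "rhesus"),
    haplorrhini_specific = c("human", "chimp", "rhesus", "marmoset"),
    other                = c("chimp", "rhesus"),  # deliberately non-clade
    stop("unknown state: ", state)
  )
}

# Branch on which a planted TE is inserted, and the families used per branch.
te_branch_families <- function() {
  tibble(
    te_branch = c("human", "ape", "ape", "ape", "ape", "root", "root", "root"),
    subfamily = c("SVA_F", "SVA_B", "SVA_C", "SVA_D", "LTR12C",
                  "AluY", "L2", "MIR"),
    family    = c("SVA", "SVA", "SVA", "SVA", "ERV1", "Alu", "L2", "MIR"),
    te_class  = c("SVA", "SVA", "SVA", "SVA", "LTR", "SINE", "LINE", "SINE"),
    lineage_age = c("human", "ape", "ape", "ape", "ape",
                    "primate", "ancestral", "ancestral")
  )
}

#' Draw the ground-truth table for a synthetic dataset
#'
#' Assigns each CRE a true conservation state, a signed activity effect
#' (`true_log2fc`, zero iff conserved), a linked gene, a promoter/enhancer
#' class, and optionally a planted TE subfamily with its branch of insertion.
#' Recent subfamilies (SVA_F; SVA_B/C/D and LTR12C) are placed on the human
#' and ape branches, ancient families (AluY, L2, MIR) at the root.
#'
#' @param config A [sim_config()].
#' @param tree A [species_tree()].
#' @return Tibble with columns `cre_id`, `true_state`, `true_log2fc`,
#'   `linked_gene`, `cre_class`, `te_family`, `te_branch`.
#' @export
simulate_truth <- function(config, tree = species_tree(config$branch_scale)) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_cres
  states <- names(config$prop_states)
  withr_seed(stage_seed(config, "truth"), {
    true_state <- if (n > 0) {
      sample(states, n, replace = TRUE, prob = config$prop_states)
    } else character()
    sign <- sample(c(-1, 1), n, replace = TRUE)
    true_log2fc <- if_else(true_state == "conserved", 0,
                           sign * config$effect_log2fc)
    linked_gene <- sprintf("gene%05d", sample.int(config$n_genes, n,
                                                  replace = TRUE))
    cre_class <- if_else(runif(n) < config$prop_promoter,
                         "promoter", "enhancer")
    has_te <- runif(n) < config$te_density
    fams <- te_branch_families()
    idx <- sample.int(nrow(fams), n, replace = TRUE)
    tibble(
      cre_id = sprintf("cre%05d", seq_len(n)),
      true_state = true_state,
      true_log2fc = true_log2fc,
      linked_gene = linked_gene,
      cre_class = cre_class,
      te_family = if_else(has_te, fams$subfamily[idx], NA_character_),
      te_branch = if_else(has_te, fams$te_branch[idx], NA_character_)
    )
  })
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
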