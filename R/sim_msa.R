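# Alignment simulator: evolves each CRE block down the fixed primate tree
# under Jukes-Cantor substitutions with geometric indels, and realizes TE
# insertions as branch-specific inserted columns.

BASES <- c("A", "C", "G", "T")
BLOCK_SPACER <- 30000L  # unaligned bp between consecutive blocks, all species
TE_INSERT_LEN <- 300L   # planted TE length (bp)

# fixed processing order for branches, so event generation is reproducible
branch_order <- function(tree) tree$edges$branch

#' Simulate multiple-sequence-alignment blocks for a synthetic dataset
#'
#' Generates one alignment block per CRE: a root sequence of
#' `flank + cre_width + flank` bp evolved along the tree with per-branch
#' Jukes-Cantor substitutions (probability `3/4 * (1 - exp(-4/3 * t))` for a
#' branch of length `t`), geometric indels (mean length 3, rate
#' `indel_rate` per substitution), and planted TE insertions: subfamilies
#' assigned to the human or ape branch appear as inserted columns present
#' only in the descendant species, while root-age families are embedded in
#' the ancestral sequence and inherited by all six species.
#'
#' Blocks are laid out on a single chromosome (`chr1`) per species with a
#' fixed unaligned spacer between them, so per-species coordinates are
#' consistent with the emitted gapped rows.
#'
#' @param tree A [species_tree()].
#' @param config A [sim_config()]; `config$branch_scale` should match the
#'   scale used to build `tree`.
#' @param truth Ground-truth table from [simulate_truth()]; defaults to
#'   drawing one from `config`.
#' @return A list of class `cre_sim_msa` with elements
#'   `blocks` (list of alignment-block tibbles, the same shape
#'   [parse_maf()] returns), `cres` (tibble: cre_id, chrom, start, end),
#'   `tss` (tibble: gene_id, chrom, pos), `te_annotation`
#'   (tibble: chrom, start, end, subfamily, family, te_class, lineage_age),
#'   `truth` (input truth with `cre_class` updated to the realized class),
#'   and `genome_sizes` (tibble: species, chrom, size).
#' @export
simulate_msa <- function(tree, config, truth = simulate_truth(config, tree)) {
  stopifnot(inherits(tree, "species_tree"), inherits(config, "sim_config"))
  L <- config$flank + config$cre_width + config$flank
  if (L <= 0) stop("zero-length genome: flank + cre_width must be positive")
  fams <- te_branch_families()
  species <- tree$species
  paths <- lapply(setNames(species, species), function(sp) tree_path(tree, sp))
  br_len <- setNames(tree$edges$length, tree$edges$branch)
  brs <- branch_order(tree)

  withr_seed(stage_seed(config, "msa"), {
    blocks <- vector("list", config$n_cres)
    cre_rows <- vector("list", config$n_cres)
    te_rows <- vector("list", config$n_cres)
    ungapped <- matrix(0L, nrow = max(config$n_cres, 1), ncol = length(species),
                       dimnames = list(NULL, species))

    for (i in seq_len(config$n_cres)) {
      root_seq <- sample.int(4L, L, replace = TRUE) - 1L

      # planted TE for this CRE
      te_fam <- truth$te_family[i]
      te_root_cols <- integer()
      te_ins <- NULL
      if (!is.na(te_fam)) {
        info <- fams[fams$subfamily == te_fam, ]
        if (info$te_branch == "root") {
          a0 <- config$flank +
            sample.int(config$cre_width - min(TE_INSERT_LEN, config$cre_width - 1L), 1L)
          te_root_cols <- a0:(a0 + min(TE_INSERT_LEN, config$cre_width - 1L) - 1L)
        } else {
          anchor <- config$flank +
            sample.int(max(config$cre_width - 2L, 1L), 1L)
          te_ins <- list(anchor = anchor, len = TE_INSERT_LEN,
                         branch = info$te_branch,
                         seq = sample.int(4L, TE_INSERT_LEN, replace = TRUE) - 1L,
                         subfamily = te_fam)
        }
      }

      # per-branch events, generated in fixed branch order
      subs <- list(); dels <- list(); ins_list <- list()
      for (b in brs) {
        t_b <- br_len[[b]]
        p_sub <- 0.75 * (1 - exp(-4 / 3 * t_b))
        sites <- which(runif(L) < p_sub)
        subs[[b]] <- list(sites = sites,
                          shift = sample.int(3L, length(sites), replace = TRUE))
        n_indel <- rpois(2L, L * t_b * config$indel_rate / 3)
        dmask <- rep(FALSE, L)
        if (n_indel[1] > 0) {
          st <- sample.int(L, n_indel[1], replace = TRUE)
          ln <- rgeom(n_indel[1], 1 / 3) + 1L
          for (k in seq_len(n_indel[1])) {
            dmask[st[k]:min(L, st[k] + ln[k] - 1L)] <- TRUE
          }
        }
        dels[[b]] <- dmask
        if (n_indel[2] > 0) {
          an <- sample.int(L, n_indel[2], replace = TRUE)
          ln <- rgeom(n_indel[2], 1 / 3) + 1L
          for (k in seq_len(n_indel[2])) {
            ins_list[[length(ins_list) + 1L]] <-
              list(anchor = an[k], len = ln[k], branch = b,
                   seq = sample.int(4L, ln[k], replace = TRUE) - 1L,
                   subfamily = NA_character_)
          }
        }
      }
      if (!is.null(te_ins)) ins_list[[length(ins_list) + 1L]] <- te_ins

      # global column layout: root columns interleaved with insertion blocks
      # placed right after their anchor column, built as an explicit plan so
      # positions partition 1..C by construction
      n_ins <- length(ins_list)
      if (n_ins > 0) {
        ianch <- vapply(ins_list, function(x) as.integer(x$anchor), 0L)
        ilen <- vapply(ins_list, function(x) as.integer(x$len), 0L)
        ord <- order(ianch, seq_len(n_ins))
        ins_list <- ins_list[ord]; ianch <- ianch[ord]; ilen <- ilen[ord]
      } else {
        ianch <- integer(); ilen <- integer()
      }
      C <- L + sum(ilen)
      root_pos <- integer(L)
      ins_pos <- vector("list", n_ins)
      pos <- 0L
      prev_anchor <- 0L
      for (k in seq_len(n_ins)) {
        if (ianch[k] > prev_anchor) {
          seg <- (prev_anchor + 1L):ianch[k]
          root_pos[seg] <- pos + seq_along(seg)
          pos <- pos + length(seg)
          prev_anchor <- ianch[k]
        }
        ins_pos[[k]] <- pos + seq_len(ilen[k])
        pos <- pos + ilen[k]
      }
      if (prev_anchor < L) {
        seg <- (prev_anchor + 1L):L
        root_pos[seg] <- pos + seq_along(seg)
        pos <- pos + length(seg)
      }
      stopifnot(pos == C,
                identical(sort(c(root_pos, unlist(ins_pos))), seq_len(C)))

      # leaf rows
      rows <- matrix(-1L, nrow = length(species), ncol = C,
                     dimnames = list(species, NULL))
      for (si in seq_along(species)) {
        sp <- species[si]
        bases <- root_seq
        dmask <- rep(FALSE, L)
        for (b in paths[[sp]]) {
          ev <- subs[[b]]
          if (length(ev$sites)) {
            bases[ev$sites] <- (bases[ev$sites] + ev$shift) %% 4L
          }
          dmask <- dmask | dels[[b]]
        }
        vals <- ifelse(dmask, -1L, bases)
        rows[si, root_pos] <- vals
        if (n_ins > 0) {
          for (k in seq_len(n_ins)) {
            if (ins_list[[k]]$branch %in% paths[[sp]]) {
              rows[si, ins_pos[[k]]] <- ins_list[[k]]$seq
            }
          }
        }
      }

      # per-species coordinates for this block
      sizes <- rowSums(rows >= 0)
      starts <- ungapped[i, ] + (i - 1L) * BLOCK_SPACER
      if (i < config$n_cres) ungapped[i + 1L, ] <- ungapped[i, ] + as.integer(sizes)

      seq_txt <- apply(rows, 1, function(v) {
        paste(c("-", BASES)[v + 2L], collapse = "")
      })
      blocks[[i]] <- tibble(
        species = species, chrom = "chr1",
        start = as.numeric(starts[species]),
        size = as.integer(sizes[species]),
        strand = "+", src_size = NA_real_,
        text = unname(seq_txt[species])
      )

      # human CRE interval: non-gap human positions within the CRE columns
      cre_cols <- logical(C)
      cre_root <- (config$flank + 1L):(config$flank + config$cre_width)
      cre_cols[root_pos[cre_root]] <- TRUE
      if (n_ins > 0) {
        for (k in seq_len(n_ins)) {
          if (ianch[k] > config$flank && ianch[k] < config$flank + config$cre_width) {
            cre_cols[ins_pos[[k]]] <- TRUE
          }
        }
      }
      hrow <- rows["human", ]
      h_cum <- cumsum(hrow >= 0)
      h_in_cre <- sum(hrow >= 0 & cre_cols)
      first_cre_col <- which(cre_cols)[1]
      before <- if (first_cre_col > 1) h_cum[first_cre_col - 1L] else 0L
      cre_rows[[i]] <- tibble(
        cre_id = truth$cre_id[i], chrom = "chr1",
        start = starts[["human"]] + before,
        end = starts[["human"]] + before + h_in_cre
      )

      # TE annotation in human coordinates (TEs on the human lineage only)
      te_cols <- NULL
      if (length(te_root_cols)) te_cols <- root_pos[te_root_cols]
      if (!is.null(te_ins)) {
        k <- which(vapply(ins_list, function(x) identical(x$subfamily, te_fam), TRUE))
        if (length(k) && ins_list[[k[1]]]$branch %in% paths[["human"]]) {
          te_cols <- ins_pos[[k[1]]]
        }
      }
      if (!is.null(te_cols)) {
        h_in_te <- sum(hrow[te_cols] >= 0)
        if (h_in_te > 0) {
          before_te <- if (min(te_cols) > 1) h_cum[min(te_cols) - 1L] else 0L
          info <- fams[fams$subfamily == te_fam, ]
          te_rows[[i]] <- tibble(
            chrom = "chr1",
            start = starts[["human"]] + before_te,
            end = starts[["human"]] + before_te + h_in_te,
            subfamily = info$subfamily, family = info$family,
            te_class = info$te_class, lineage_age = info$lineage_age
          )
        }
      }
    }

    # genome sizes and src_size back-fill
    if (config$n_cres > 0) {
      last <- blocks[[config$n_cres]]
      gsize <- setNames(last$start + last$size + BLOCK_SPACER, last$species)
    } else {
      gsize <- setNames(rep(BLOCK_SPACER, length(species)), species)
    }
    blocks <- lapply(blocks, function(b) {
      b$src_size <- unname(gsize[b$species]); b
    })

    cres <- list_rbind(cre_rows)
    if (is.null(cres) || nrow(cres) == 0) {
      cres <- tibble(cre_id = character(), chrom = character(),
                     start = numeric(), end = numeric())
    }
    te_annotation <- list_rbind(te_rows)
    if (is.null(te_annotation) || nrow(te_annotation) == 0) {
      te_annotation <- tibble(chrom = character(), start = numeric(),
                              end = numeric(), subfamily = character(),
                              family = character(), te_class = character(),
                              lineage_age = character())
    }

    # TSS placement: the first CRE linked to a gene places its TSS
    # (inside the CRE for promoters, 2-20 kb downstream for enhancers);
    # remaining genes get a position in the tail spacer.
    tss <- place_tss(truth, cres, config, gsize[["human"]])
    truth$cre_class <- realized_class(truth, cres, tss)

    structure(
      list(blocks = blocks, cres = cres, tss = tss$tss,
           te_annotation = te_annotation, truth = truth,
           genome_sizes = tibble(species = names(gsize), chrom = "chr1",
                                 size = as.numeric(gsize))),
      class = "cre_sim_msa"
    )
  })
}

place_tss <- function(truth, cres, config, human_size) {
  if (nrow(truth) == 0) {
    return(list(tss = tibble(gene_id = character(), chrom = character(),
                             pos = numeric())))
  }
  # a gene's TSS is anchored at its first promoter-intent CRE when it has
  # one, so intended promoters realize as promoters
  owner <- truth |>
    mutate(.row = row_number()) |>
    arrange(.data$linked_gene, desc(.data$cre_class == "promoter"),
            .data$.row) |>
    group_by(.data$linked_gene) |>
    summarise(.row = first(.data$.row), .groups = "drop")
  own <- truth[owner$.row, ] |>
    mutate(gene_id = .data$linked_gene) |>
    left_join(cres, by = "cre_id")
  offset <- if_else(own$cre_class == "promoter",
                    floor((own$end - own$start) / 2),
                    2000 + round(runif(nrow(own)) * 18000))
  placed <- tibble(gene_id = own$gene_id, chrom = "chr1",
                   pos = pmin(own$start + offset, human_size - 1))
  all_genes <- sprintf("gene%05d", seq_len(config$n_genes))
  missing <- setdiff(all_genes, placed$gene_id)
  extra <- tibble(gene_id = missing, chrom = "chr1",
                  pos = human_size - 1 - seq_along(missing) * 50)
  list(tss = arrange(bind_rows(placed, extra), .data$gene_id))
}

realized_class <- function(truth, cres, tss_list) {
  if (nrow(truth) == 0) return(character())
  tssv <- tss_list$tss$pos
  vapply(seq_len(nrow(truth)), function(i) {
    s <- cres$start[i]; e <- cres$end[i]
    d <- min(pmax(0, pmax(s - tssv, tssv - (e - 1))))
    if (d < 1000) "promoter" else "enhancer"
  }, character(1))
}
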