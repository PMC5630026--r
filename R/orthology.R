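# Projection of human intervals through MAF blocks to orthologous intervals
# in each species, with coverage-based presence calls.

# split gapped rows of a block into a char matrix (rows = species)
block_char_matrix <- function(block) {
  m <- do.call(rbind, strsplit(block$text, "", fixed = TRUE))
  rownames(m) <- block$species
  m
}

# forward-strand 0-based coordinate of each non-gap character of row i
row_coords <- function(block, i, nongap_idx) {
  k <- seq_along(nongap_idx)
  if (block$strand[i] == "-") {
    block$start[i] + block$size[i] - k
  } else {
    block$start[i] + k - 1
  }
}

# project one human interval through one block; returns NULL if no human row
# overlaps, else a tibble (species, start, end, n_bases, seq, human_seq,
# human_bases, strand) over the column span of the interval within the block
project_block <- function(block, chars, chrom, start, end) {
  hi <- which(block$species == "human" & block$chrom == chrom)
  if (length(hi) == 0) return(NULL)
  if (length(hi) > 1) {
    # ambiguity rule: keep the human row with maximal ungapped coverage of
    # the interval; ties broken by lowest start
    cov <- vapply(hi, function(i) {
      idx <- which(chars[i, ] != "-")
      sum(row_coords(block, i, idx) >= start & row_coords(block, i, idx) < end)
    }, 0)
    hi <- hi[order(-cov, block$start[hi])][1]
  }
  hrow <- chars[hi, ]
  idx <- which(hrow != "-")
  if (length(idx) == 0) return(NULL)
  coords <- row_coords(block, hi, idx)
  sel <- coords >= start & coords < end
  if (!any(sel)) return(NULL)
  span <- range(idx[sel])
  cols <- span[1]:span[2]
  human_bases <- sum(sel)

  out <- map(seq_len(nrow(block)), function(i) {
    sp <- block$species[i]
    row <- chars[i, ]
    idx_i <- which(row != "-")
    coords_i <- row_coords(block, i, idx_i)
    in_span <- idx_i >= span[1] & idx_i <= span[2]
    n_b <- sum(in_span)
    if (n_b == 0 && sp != "human") return(NULL)
    tibble(
      species = sp, chrom = block$chrom[i],
      start = if (n_b > 0) min(coords_i[in_span]) else NA_real_,
      end = if (n_b > 0) max(coords_i[in_span]) + 1 else NA_real_,
      n_bases = n_b,
      seq = paste(row[cols], collapse = ""),
      human_seq = paste(hrow[cols], collapse = ""),
      strand = block$strand[i],
      human_bases = human_bases
    )
  })
  list_rbind(out[!vapply(out, is.null, TRUE)])
}

#' Map a human interval to its orthologous intervals
#'
#' Projects a human 0-based half-open interval through the alignment: for each
#' species, the orthologous interval is the forward-strand span of that
#' species' non-gap columns aligned to the human interval's columns. Species
#' whose aligned-base coverage is below `min_coverage` of the human interval
#' length are marked absent. Intervals spanning several blocks are stitched
#' when the per-block projections are collinear on the same strand; otherwise
#' the projection with the largest coverage is kept.
#'
#' @param blocks List of alignment blocks from [parse_maf()].
#' @param chrom,start,end The human interval (0-based half-open).
#' @param min_coverage Minimum fraction of human interval bases a species
#'   must align to count as present.
#' @param cre_id Optional identifier attached to the result.
#' @param char_cache Optional pre-computed list of character matrices
#'   (one per block), as built internally by [map_orthologs()].
#' @return Tibble with one row per species (human included when aligned):
#'   `cre_id`, `species`, `chrom`, `start`, `end`, `coverage`, `present`,
#'   `seq`, `human_seq`; attribute `six_way` is `TRUE` iff all six species
#'   are present.
#' @export
map_interval <- function(blocks, chrom, start, end, min_coverage = 0.5,
                         cre_id = NA_character_, char_cache = NULL) {
  stopifnot(end > start)
  width <- end - start
  pieces <- list()
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    hsel <- b$species == "human" & b$chrom == chrom &
      b$start < end & (b$start + b$size) > start
    if (!any(hsel)) next
    chars <- if (!is.null(char_cache)) char_cache[[bi]] else block_char_matrix(b)
    p <- project_block(b, chars, chrom, start, end)
    if (!is.null(p) && nrow(p)) pieces[[length(pieces) + 1L]] <- p
  }
  all_species <- species_tree()$species
  if (length(pieces) == 0) {
    out <- tibble(cre_id = cre_id, species = all_species,
                  chrom = chrom, start = NA_real_, end = NA_real_,
                  coverage = 0, present = FALSE,
                  seq = NA_character_, human_seq = NA_character_)
    attr(out, "six_way") <- FALSE
    return(out)
  }
  proj <- list_rbind(pieces)
  stitched <- proj |>
    group_by(.data$species) |>
    group_split() |>
    map(function(g) {
      g <- g[order(g$start), ]
      ok_stitch <- nrow(g) > 1 &&
        length(unique(g$strand)) == 1 &&
        all(!is.na(g$start)) &&
        all(head(g$end, -1) <= tail(g$start, -1) + 1e-9)
      if (nrow(g) == 1) {
        sel <- g
      } else if (ok_stitch) {
        sel <- tibble(species = g$species[1], chrom = g$chrom[1],
                      start = min(g$start), end = max(g$end),
                      n_bases = sum(g$n_bases),
                      seq = paste(g$seq, collapse = ""),
                      human_seq = paste(g$human_seq, collapse = ""),
                      strand = g$strand[1],
                      human_bases = sum(g$human_bases))
      } else {
        sel <- g[which.max(g$n_bases), ]
      }
      sel
    }) |>
    list_rbind()
  out <- stitched |>
    mutate(cre_id = cre_id,
           coverage = .data$n_bases / width,
           present = .data$coverage >= min_coverage & .data$n_bases >= 1) |>
    select("cre_id", "species", "chrom", "start", "end", "coverage",
           "present", "seq", "human_seq")
  absent <- setdiff(all_species, out$species[out$present])
  missing_rows <- setdiff(all_species, out$species)
  if (length(missing_rows)) {
    out <- bind_rows(out, tibble(cre_id = cre_id, species = missing_rows,
                                 chrom = chrom, start = NA_real_,
                                 end = NA_real_, coverage = 0,
                                 present = FALSE, seq = NA_character_,
                                 human_seq = NA_character_))
  }
  out <- arrange(out, match(.data$species, all_species))
  attr(out, "six_way") <- length(absent) == 0
  out
}

#' Map a table of human CREs to orthologous intervals in all species
#'
#' @param cres Tibble with columns `cre_id`, `chrom`, `start`, `end`.
#' @param blocks List of alignment blocks from [parse_maf()].
#' @param min_coverage See [map_interval()].
#' @param flank Bases added to both sides of each interval before mapping
#'   (0 for plain ortholog detection; 500 for divergence estimation).
#' @return Tibble of per-species projections with a `six_way` column
#'   (constant within each `cre_id`).
#' @export
map_orthologs <- function(cres, blocks, min_coverage = 0.5, flank = 0) {
  # index of human rows per block, for fast candidate lookup
  hidx <- map(seq_along(blocks), function(bi) {
    b <- blocks[[bi]]
    h <- b[b$species == "human", , drop = FALSE]
    if (nrow(h) == 0) return(NULL)
    tibble(block = bi, chrom = h$chrom, hstart = h$start,
           hend = h$start + h$size)
  }) |> list_rbind()
  cache <- new.env(parent = emptyenv())
  get_chars <- function(bi) {
    key <- as.character(bi)
    if (is.null(cache[[key]])) cache[[key]] <- block_char_matrix(blocks[[bi]])
    cache[[key]]
  }
  out <- map(seq_len(nrow(cres)), function(i) {
    s <- max(0, cres$start[i] - flank)
    e <- cres$end[i] + flank
    cand <- if (!is.null(hidx) && nrow(hidx)) {
      unique(hidx$block[hidx$chrom == cres$chrom[i] &
                          hidx$hstart < e & hidx$hend > s])
    } else integer()
    o <- map_interval(blocks[cand], cres$chrom[i], s, e,
                      min_coverage = min_coverage, cre_id = cres$cre_id[i],
                      char_cache = lapply(cand, get_chars))
    o$six_way <- attr(o, "six_way")
    o
  })
  list_rbind(out)
}
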