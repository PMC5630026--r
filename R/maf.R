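# Reading and writing Multiple Alignment Format (MAF) blocks.
#
# A block is represented as a tibble with one row per species:
#   species, chrom, start, size, strand, src_size, text
# `start` is always a forward-strand 0-based coordinate: minus-strand rows
# are normalized on parse (start = src_size - maf_start - size) with the
# original strand retained, so downstream interval projection can walk the
# alignment columns in the right direction.

#' Parse a MAF file into alignment blocks
#'
#' @param path Path to a MAF text file. The `src` field of each `s` line is
#'   split at the first `.` into species and chromosome.
#' @return A list of alignment-block tibbles (possibly empty). Every block is
#'   validated: all gapped rows must have equal length and the non-gap
#'   character count must equal the declared ungapped size.
#' @export
parse_maf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  blocks <- list()
  cur <- NULL
  bi <- 0L
  flush <- function(cur, bi) {
    if (is.null(cur) || nrow(cur) == 0) return(NULL)
    widths <- nchar(cur$text)
    if (length(unique(widths)) != 1) {
      stop("ragged MAF block ", bi, ": gapped row lengths ",
           paste(widths, collapse = ", "))
    }
    ungapped <- nchar(gsub("-", "", cur$text))
    if (any(ungapped != cur$size)) {
      stop("MAF block ", bi, ": declared size disagrees with non-gap count")
    }
    cur
  }
  for (ln in lines) {
    if (grepl("^a", ln)) {
      b <- flush(cur, bi)
      if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
      bi <- bi + 1L
      cur <- tibble(species = character(), chrom = character(),
                    start = numeric(), size = integer(), strand = character(),
                    src_size = numeric(), text = character())
    } else if (grepl("^s\\s", ln)) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(f) < 7) stop("malformed s line in MAF block ", bi)
      src <- f[2]
      dot <- regexpr(".", src, fixed = TRUE)
      sp <- if (dot > 0) substr(src, 1, dot - 1) else src
      chrom <- if (dot > 0) substr(src, dot + 1, nchar(src)) else "chr"
      start <- as.numeric(f[3]); size <- as.integer(f[4])
      strand <- f[5]; src_size <- as.numeric(f[6])
      if (strand == "-") start <- src_size - start - size
      cur <- bind_rows(cur, tibble(species = sp, chrom = chrom, start = start,
                                   size = size, strand = strand,
                                   src_size = src_size, text = f[7]))
    }
  }
  b <- flush(cur, bi)
  if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
  blocks
}

#' Write alignment blocks to a MAF file
#'
#' Inverse of [parse_maf()]: forward-normalized starts of minus-strand rows
#' are converted back to MAF (strand-local) starts on output.
#'
#' @param blocks List of alignment-block tibbles.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(blocks, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##maf version=1 scoring=none", con)
  for (b in blocks) {
    writeLines("a score=0", con)
    for (i in seq_len(nrow(b))) {
      start <- b$start[i]
      if (b$strand[i] == "-") start <- b$src_size[i] - b$start[i] - b$size[i]
      writeLines(sprintf("s %s.%s %d %d %s %d %s",
                         b$species[i], b$chrom[i], as.integer(start),
                         b$size[i], b$strand[i], as.integer(b$src_size[i]),
                         b$text[i]), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
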