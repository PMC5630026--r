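bed <- function(...) {
  v <- c(...)
  if (is.null(v)) v <- numeric()
  m <- matrix(v, ncol = 2, byrow = TRUE)
  tibble::tibble(chrom = rep("chr1", nrow(m)), start = m[, 1], end = m[, 2])
}

# bitmap coverage oracle over a small coordinate space
bitmap_union <- function(df, n = 10000) {
  v <- logical(n)
  for (i in seq_len(nrow(df))) v[(df$start[i] + 1):df$end[i]] <- TRUE
  v
}

test_that("merge_marks takes the interval union with provenance", {
  m <- merge_marks(bed(100, 200), bed(150, 250))
  expect_equal(c(m$start, m$end), c(100, 250))
  expect_identical(m$marks, "H3K27ac,H3K4me1")

  m2 <- merge_marks(bed(0, 10, 20, 30), bed())
  expect_identical(nrow(m2), 2L)
  expect_equal(m2$start, c(0, 20))

  # chain of 5 pairwise-overlapping intervals -> one union (bitmap oracle)
  chain <- bed(0, 10, 8, 20, 18, 30, 28, 40, 38, 50)
  m3 <- merge_marks(chain[1:3, ], chain[4:5, ])
  expect_identical(nrow(m3), 1L)
  expect_equal(sum(bitmap_union(chain)), sum(m3$end - m3$start))
})

test_that("merged intervals are disjoint, sorted, and coverage-preserving", {
  set.seed(4)
  a <- tibble::tibble(chrom = "chr1", start = sample(0:900, 30))
  a$end <- a$start + sample(10:120, 30, TRUE)
  b <- tibble::tibble(chrom = "chr1", start = sample(0:900, 30))
  b$end <- b$start + sample(10:120, 30, TRUE)
  m <- merge_marks(a, b)
  expect_true(all(diff(m$start) > 0))
  expect_true(all(head(m$end, -1) < tail(m$start, -1)))  # disjoint
  expect_equal(sum(m$end - m$start),
               sum(bitmap_union(dplyr::bind_rows(a, b))))
})

test_that("malformed peak intervals are rejected with a line number", {
  bad <- tibble::tibble(chrom = "chr1", start = c(0, 50), end = c(10, 40))
  expect_error(merge_marks(bad, bed()), "line 2")
})

test_that("promoter/enhancer split at 1 kb with edge distance", {
  cres <- tibble::tibble(cre_id = c("a", "b", "c", "d"),
                         chrom = "chr1",
                         start = c(5000, 5000, 5000, 5000),
                         end = c(6000, 6000, 6000, 6000))
  # TSS inside; at distance 999; exactly 1000; and 1001
  tss <- tibble::tibble(gene_id = c("g1", "g2", "g3", "g4"),
                        chrom = "chr1",
                        pos = c(5500, 6998, 6999, 7000))
  one <- function(i, g) classify_cres(cres[i, ], tss[tss$gene_id == g, ])
  expect_identical(one(1, "g1")$cre_class, "promoter")
  expect_equal(one(1, "g1")$tss_distance, 0)
  expect_identical(one(2, "g2")$cre_class, "promoter")   # 999 bp
  expect_identical(one(3, "g3")$cre_class, "enhancer")   # exactly 1000 bp
  expect_identical(one(4, "g4")$cre_class, "enhancer")   # 1001 bp
})

test_that("nearest-gene ties break lexicographically and no-TSS flags", {
  cres <- tibble::tibble(cre_id = "a", chrom = "chr1", start = 100, end = 200)
  tss <- tibble::tibble(gene_id = c("geneB", "geneA"), chrom = "chr1",
                        pos = c(250, 49))  # both at distance 51
  out <- classify_cres(cres, tss)
  expect_equal(out$tss_distance, 51)
  expect_identical(out$nearest_gene, "geneA")
  out2 <- classify_cres(cres, tss[tss$chrom == "chrX", ])
  expect_true(out2$no_tss)
  expect_true(is.na(out2$cre_class))
})

test_that("every CRE with a TSS on its chromosome gets exactly one class", {
  b <- tiny_bundle()
  cat <- classify_cres(b$msa$cres, b$msa$tss)
  expect_true(all(cat$cre_class %in% c("promoter", "enhancer")))
})

test_that("TE overlap uses union coverage with an inclusive 20% boundary", {
  cre <- tibble::tibble(cre_id = "a", chrom = "chr1", start = 0, end = 1000)
  te1 <- tibble::tibble(chrom = "chr1", start = 0, end = 200,
                        subfamily = "SVA_F")
  expect_true(annotate_te_overlap(cre, te1)$te_flag)       # exactly 0.20
  expect_equal(annotate_te_overlap(cre, te1)$te_overlap_fraction, 0.2)
  te2 <- te1; te2$end <- 199
  expect_false(annotate_te_overlap(cre, te2)$te_flag)      # 0.199

  # union of overlapping TEs (bitmap oracle): [0,100) + [50,250) -> 250 bp
  te3 <- tibble::tibble(chrom = "chr1", start = c(0, 50), end = c(100, 250),
                        subfamily = c("AluY", "L2"))
  out <- annotate_te_overlap(cre, te3)
  expect_equal(out$te_overlap_fraction, sum(bitmap_union(te3)) / 1000)
  expect_identical(out$te_families, "AluY,L2")
  expect_error(annotate_te_overlap(
    tibble::tibble(cre_id = "z", chrom = "chr1", start = 5, end = 5), te3),
    "zero-length")
})

test_that("TE flags on the synthetic bundle recover planted TEs", {
  b <- tiny_bundle()
  ann <- annotate_te_overlap(b$msa$cres, b$msa$te_annotation)
  planted <- !is.na(b$truth$te_family)
  expect_identical(ann$te_flag, planted)
})
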