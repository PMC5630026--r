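maf_text <- c(
  "##maf version=1",
  "a score=0",
  "s human.chr1 0 10 + 1000 ACGTACGTAC",
  "s chimp.chr1 500 10 + 2000 ACGTACGTAC",
  "",
  "a score=0",
  "s human.chr1 10 8 + 1000 ACG--TACGT",
  "s chimp.chr2 40 10 - 2000 ACGTTTACGT",
  ""
)

test_that("parse_maf round-trips blocks and normalizes minus strands", {
  f <- withr::local_tempfile(lines = maf_text)
  blocks <- parse_maf(f)
  expect_length(blocks, 2)
  expect_setequal(blocks[[1]]$species, c("human", "chimp"))
  # minus-strand start converted to forward coordinates
  mr <- blocks[[2]][blocks[[2]]$species == "chimp", ]
  expect_equal(mr$start, 2000 - 40 - 10)
  expect_identical(mr$strand, "-")
  # write -> parse returns the original MAF start
  f2 <- withr::local_tempfile()
  write_maf(blocks, f2)
  expect_match(grep("chimp.chr2", readLines(f2), value = TRUE), " 40 10 - ")
})

test_that("parse_maf rejects ragged blocks naming the block", {
  bad <- c("a score=0",
           "s human.chr1 0 10 + 1000 ACGTACGTAC",
           "s chimp.chr1 0 9 + 1000 ACGTACGTA")
  f <- withr::local_tempfile(lines = bad)
  expect_error(parse_maf(f), "block 1")
})

test_that("parse_maf on an empty file returns an empty collection", {
  f <- withr::local_tempfile(lines = character())
  expect_length(parse_maf(f), 0)
})

test_that("gapless identity block projects by offset shift", {
  seq100 <- strrep("ACGT", 25)
  blk <- make_block(c("human", "chimp"), c(100, 500), c(seq100, seq100))
  o <- map_interval(list(blk), "chr1", 100, 200)
  ch <- o[o$species == "chimp", ]
  expect_equal(c(ch$start, ch$end), c(500, 600))
  expect_true(attr(o, "six_way") == FALSE)  # only two species present
  expect_true(all(o$present[o$species %in% c("human", "chimp")]))
})

test_that("interval projection across an internal gap (column-walk oracle)", {
  # human columns: 30 bases; chimp has a 4-column gap inside human's 10-20
  h <- strrep("A", 30)
  c_seq <- paste0(strrep("C", 12), "----", strrep("C", 14))
  blk <- make_block(c("human", "chimp"), c(0, 0), c(h, c_seq))
  o <- map_interval(list(blk), "chr1", 10, 20)
  ch <- o[o$species == "chimp", ]
  # oracle: columns 11..20; chimp bases at columns 11,12,17,18,19,20 -> 6
  expect_equal(ch$end - ch$start, 6)
  expect_equal(c(ch$start, ch$end), c(10, 16))
})

test_that("species entirely gapped over the interval is absent", {
  h <- strrep("A", 20)
  other <- paste0(strrep("-", 10), strrep("G", 10))
  blk <- make_block(c("human", "chimp"), c(0, 0), c(h, other))
  o <- map_interval(list(blk), "chr1", 0, 10)
  expect_false(o$present[o$species == "chimp"])
  expect_false(attr(o, "six_way"))
})

test_that("interval with no overlapping block yields all-absent set", {
  blk <- make_block("human", 0, strrep("A", 10))
  o <- map_interval(list(blk), "chr1", 5000, 5100)
  expect_true(all(!o$present))
  expect_false(attr(o, "six_way"))
})

test_that("round-trip mapping over a gapless block recovers the interval", {
  set.seed(9)
  s <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  blk <- make_block(c("human", "chimp"), c(1000, 3000), c(s, s))
  o <- map_interval(list(blk), "chr1", 1040, 1120)
  ch <- o[o$species == "chimp", ]
  # map back with roles swapped
  blk_rev <- make_block(c("chimp", "human"), c(1000, 3000), c(s, s))
  names(blk_rev)[1] <- "species"
  blk_back <- make_block(c("human", "chimp"), c(3000, 1000), c(s, s))
  o2 <- map_interval(list(blk_back), "chr1", ch$start, ch$end)
  hb <- o2[o2$species == "chimp", ]
  expect_equal(c(hb$start, hb$end), c(1040, 1120))
})

test_that("minus-strand rows project to forward-strand coordinates", {
  # chimp row stored on '-' strand: forward start = 2000 - 100 - 20 = 1880
  blk <- tibble::tibble(
    species = c("human", "chimp"), chrom = "chr1",
    start = c(0, 1880), size = c(20, 20), strand = c("+", "-"),
    src_size = c(1000, 2000), text = c(strrep("A", 20), strrep("T", 20))
  )
  o <- map_interval(list(blk), "chr1", 5, 15)
  ch <- o[o$species == "chimp", ]
  # alignment column k (1-based) maps to forward coord 1880 + 20 - k
  # columns 6..15 -> coords 1885..1894
  expect_equal(c(ch$start, ch$end), c(1885, 1895))
})

test_that("six-way detection matches simulator ground truth", {
  b <- tiny_bundle()
  o <- map_orthologs(b$msa$cres[1:10, ], b$msa$blocks)
  expect_true(all(o$six_way))   # generous blocks: everything alignable
  expect_identical(nrow(o), 60L)
})
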