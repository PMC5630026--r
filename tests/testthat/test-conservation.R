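sig_vec <- function(...) {
  v <- list(...)
  base <- setNames(rep("ns", 9), c(
    "human_vs_chimp", "human_vs_rhesus", "human_vs_marmoset",
    "human_vs_mouse_lemur", "human_vs_bushbaby",
    "human_group", "ape_group", "catarrhini_group", "haplorrhini_group"
  ))
  base[names(v)] <- unlist(v)
  tibble::as_tibble(c(list(feature_id = "x"), as.list(base)))
}

test_that("the battery has 9 comparisons with disjoint groups", {
  bat <- comparison_battery()
  expect_identical(nrow(bat), 9L)
  for (i in seq_len(9)) {
    expect_length(intersect(bat$group_a[[i]], bat$group_b[[i]]), 0)
  }
  expect_identical(sum(bat$type == "pairwise"), 5L)
  # chimp-centric control re-roots the pairwise comparisons
  expect_true("chimp_vs_human" %in% comparison_battery("chimp")$comparison_id)
})

test_that("classification follows the definition cases", {
  expect_identical(classify_conservation(sig_vec())$label, "conserved")

  hs <- sig_vec(human_vs_chimp = "sig+", human_vs_rhesus = "sig+",
                human_vs_marmoset = "sig+", human_vs_mouse_lemur = "sig+",
                human_vs_bushbaby = "sig+", human_group = "sig+")
  expect_identical(classify_conservation(hs)$label, "human_specific")

  ape <- sig_vec(human_vs_rhesus = "sig-", human_vs_marmoset = "sig-",
                 human_vs_mouse_lemur = "sig-", human_vs_bushbaby = "sig-",
                 ape_group = "sig-")
  expect_identical(classify_conservation(ape)$label, "ape_specific")

  hap <- sig_vec(human_vs_mouse_lemur = "sig+", human_vs_bushbaby = "sig+",
                 haplorrhini_group = "sig+")
  expect_identical(classify_conservation(hap)$label, "haplorrhini_specific")

  # inconsistent signs across the clade boundary -> other_divergent
  mixed <- sig_vec(human_vs_rhesus = "sig+", human_vs_marmoset = "sig-",
                   human_vs_mouse_lemur = "sig+", human_vs_bushbaby = "sig+",
                   ape_group = "sig+")
  expect_identical(classify_conservation(mixed)$label, "other_divergent")
})

test_that("untested entries never support a lineage-specific call", {
  v <- sig_vec(human_vs_chimp = "sig+", human_vs_rhesus = "sig+",
               human_vs_marmoset = "sig+", human_vs_mouse_lemur = "sig+",
               human_vs_bushbaby = "untested", human_group = "sig+")
  expect_identical(classify_conservation(v)$label, "other_divergent")
  # all untested but one ns -> conserved (nothing significant)
  v2 <- sig_vec(human_vs_chimp = "untested")
  expect_identical(classify_conservation(v2)$label, "conserved")
})

test_that("group-test-only mode relaxes the pairwise requirement", {
  v <- sig_vec(ape_group = "sig+")
  expect_identical(classify_conservation(v)$label, "other_divergent")
  expect_identical(classify_conservation(v, require_pairwise = FALSE)$label,
                   "ape_specific")
})

test_that("every CRE receives exactly one label", {
  set.seed(19)
  flags <- c("sig+", "sig-", "ns", "untested")
  cols <- names(sig_vec())[-1]
  many <- tibble::as_tibble(setNames(
    lapply(cols, function(x) sample(flags, 200, TRUE)), cols))
  many$feature_id <- sprintf("f%03d", 1:200)
  calls <- classify_conservation(many)
  expect_identical(nrow(calls), 200L)
  expect_true(all(calls$label %in% c(
    "conserved", "human_specific", "ape_specific", "catarrhini_specific",
    "haplorrhini_specific", "other_divergent")))
})

test_that("summaries reproduce printed-style percentages", {
  pct <- label_percentages(c(conserved = 25067), total = 39710)
  expect_equal(pct$percent_1dp, 63.1)
  expect_equal(round(label_percentages(c(x = 57), 39710)$percent, 2), 0.14)
  expect_equal(label_percentages(c(x = 2259), 39710)$percent_1dp, 5.7)
  empty <- summarize_catalogue(tibble::tibble(feature_id = character(),
                                              label = character()))
  expect_identical(nrow(empty), 0L)
})

test_that("raising the FDR threshold never increases the conserved count", {
  b <- tiny_bundle()
  bat <- run_comparison_battery(b$counts$chip_counts, b$counts$metadata)
  conserved_at <- vapply(c(0.01, 0.05, 0.1, 0.2, 0.5), function(q) {
    sum(classify_conservation(
      battery_significance(bat$results, q))$label == "conserved")
  }, 0)
  expect_true(all(diff(conserved_at) <= 0))
})

test_that("the battery is deterministic and marks untested regions", {
  b <- tiny_bundle()
  chip <- b$counts$chip_counts
  ip_cols <- b$counts$metadata$sample_id[b$counts$metadata$assay == "IP"]
  chip[1, ip_cols] <- as.list(rep(0L, length(ip_cols)))
  bat1 <- run_comparison_battery(chip[1:12, ], b$counts$metadata)
  bat2 <- run_comparison_battery(chip[1:12, ], b$counts$metadata)
  expect_identical(bat1$results, bat2$results)
  first_row <- bat1$signif[bat1$signif$feature_id == chip$feature_id[1], ]
  expect_true(all(unlist(first_row[-1]) == "untested"))
})
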