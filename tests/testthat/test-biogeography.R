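test_that("abundance classification uses the inclusive 0.5% cutoff", {
  expect_equal(classify_abundance(144, 4997), "abundant")
  expect_equal(classify_abundance(15, 4997), "rare")
  # exactly at the cutoff counts as abundant
  expect_equal(classify_abundance(5, 1000), "abundant")
  expect_equal(classify_abundance(4, 1000), "rare")
  expect_error(classify_abundance(1, 0), "total > 0")
})

test_that("distribution matrix counts sequences per taxon and environment", {
  asg <- data.frame(id = c("a", "b", "c"),
                    suborder = "1", family = "1.1", genus = "1.1.1",
                    species = "1.1.1.1", stringsAsFactors = FALSE)
  recs <- make_records(c("a", "b", "c"), rep("ACGT", 3),
                       env_category = c("Soil", "Soil", "Seawater"))
  m <- distribution_matrix(asg, recs, "species")
  expect_equal(dim(m), c(1L, 10L))
  expect_equal(m[1, "Soil"], 2L)
  expect_equal(m[1, "Seawater"], 1L)
  expect_equal(sum(m), 3L)
  expect_true("The_unknown" %in% colnames(m))
  # empty assignment -> empty table
  expect_equal(nrow(distribution_matrix(asg[0, ], recs, "species")), 0)
  # id mismatch is an error listing the ids
  expect_error(distribution_matrix(asg, recs[-1, ], "species"), "\\ba\\b")
  # column sums are identical across ranks (same underlying records)
  cm <- shared_community()
  tot <- lapply(c("suborder", "family", "genus", "species"), function(r)
    colSums(distribution_matrix(cm$truth$taxonomy, cm$records, r)))
  expect_true(all(vapply(tot[-1], identical, logical(1), tot[[1]])))
  # row sums at a rank equal taxon sizes from truth
  ms <- distribution_matrix(cm$truth$taxonomy, cm$records, "genus")
  sizes <- table(cm$truth$taxonomy$genus)
  expect_equal(unname(rowSums(ms)[names(sizes)]), unname(as.integer(sizes)))
})

test_that("specificity criterion applies inclusive 80% dominance and >=5 obs", {
  p <- specificity_params()
  counts <- setNames(rep(0L, 10), env_categories())
  five_soil <- counts; five_soil["Soil"] <- 5L
  expect_equal(classify_specificity(five_soil, p), "specialist")
  four_soil <- counts; four_soil["Soil"] <- 4L
  expect_equal(classify_specificity(four_soil, p), "cosmopolitan")
  mixed <- counts; mixed["Soil"] <- 8L; mixed["Seawater"] <- 2L
  expect_equal(classify_specificity(mixed, p), "specialist")  # exactly 0.80
  mixed2 <- counts; mixed2["Soil"] <- 7L; mixed2["Seawater"] <- 3L
  expect_equal(classify_specificity(mixed2, p), "cosmopolitan")
  expect_error(classify_specificity(counts, p), "no observations")
  # doubling all counts never flips specialist to cosmopolitan
  set.seed(91)
  for (rep in 1:30) {
    v <- rmultinom(1, sample(5:40, 1), prob = runif(10))[, 1]
    if (sum(v) == 0) next
    v <- setNames(v, env_categories())
    if (classify_specificity(v, p) == "specialist")
      expect_equal(classify_specificity(2L * v, p), "specialist")
  }
  # excluding unknown-source observations when configured
  px <- specificity_params(exclude_unknown = TRUE)
  unk <- counts; unk["Soil"] <- 4L; unk["The_unknown"] <- 4L
  expect_equal(classify_specificity(unk, p), "cosmopolitan")
  expect_equal(classify_specificity(unk, px), "cosmopolitan")  # 4 obs < 5
  unk2 <- counts; unk2["Soil"] <- 5L; unk2["The_unknown"] <- 5L
  expect_equal(classify_specificity(unk2, p), "cosmopolitan")
  expect_equal(classify_specificity(unk2, px), "specialist")
})

test_that("specificity profile fractions sum to one and hit the edge cases", {
  # all taxa single-environment with >= 5 obs each
  asg <- data.frame(id = sprintf("s%02d", 1:10),
                    suborder = rep(c("1", "2"), each = 5),
                    family = rep(c("1.1", "2.1"), each = 5),
                    genus = rep(c("1.1.1", "2.1.1"), each = 5),
                    species = rep(c("1.1.1.1", "2.1.1.1"), each = 5),
                    stringsAsFactors = FALSE)
  recs <- make_records(asg$id, "ACGT",
                       env_category = rep(c("Soil", "M_sediment"), each = 5))
  prof <- specificity_profile(asg, recs)
  expect_equal(prof$specialist, rep(1, 4))
  expect_equal(prof$cosmopolitan, rep(0, 4))
  expect_equal(prof$specialist + prof$cosmopolitan, rep(1, 4))
  # all taxa under 5 observations -> all cosmopolitan
  asg2 <- asg[c(1:2, 6:7), ]
  recs2 <- recs[c(1:2, 6:7), ]
  prof2 <- specificity_profile(asg2, recs2)
  expect_equal(prof2$cosmopolitan, rep(1, 4))
})

test_that("culturability breakdown percentages are complete and consistent", {
  recs <- make_records(sprintf("c%d", 1:4), "ACGT",
                       env_category = "Soil",
                       cultured = c("cultured", "cultured",
                                    "uncultured", "uncultured"))
  br <- culturability_breakdown(recs)
  soil <- br$by_environment[br$by_environment$env_category == "Soil", ]
  expect_equal(soil$pct_cultured, 50)
  expect_equal(soil$pct_uncultured, 50)
  expect_equal(soil$pct_unknown, 0)
  expect_equal(unname(br$global), c(2L, 2L, 0L))
  # all unknown
  recs2 <- make_records(c("u1", "u2"), "ACGT", cultured = "unknown")
  br2 <- culturability_breakdown(recs2)
  expect_equal(br2$by_environment$pct_unknown[
    br2$by_environment$env_category == "Soil"], 100)
  # every row of percentages sums to 100 (or 0 for empty categories)
  sums <- rowSums(br$by_environment[, c("pct_cultured", "pct_uncultured",
                                        "pct_unknown")])
  expect_true(all(sums %in% c(0, 100)))
  # synthetic community: counts match the planted labels exactly
  cm <- shared_community()
  br3 <- culturability_breakdown(cm$records, cm$truth$taxonomy)
  expect_equal(unname(br3$global),
               unname(as.integer(table(factor(cm$records$cultured,
                                              c("cultured", "uncultured",
                                                "unknown"))))))
  expect_equal(sum(br3$by_suborder[, c("cultured", "uncultured", "unknown")]),
               nrow(cm$records))
})
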