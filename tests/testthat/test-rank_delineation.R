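test_that("complete-linkage clustering honours the strict threshold boundary", {
  m <- identity_from_pairs(c("a", "b", "c"),
                           list(list("a", "b", 0.99),
                                list("a", "c", 0.80),
                                list("b", "c", 0.80)))
  cl <- cluster_at_threshold(m, 0.97)
  expect_equal(cl[["a"]], cl[["b"]])
  expect_false(cl[["a"]] == cl[["c"]])
  # all identical -> single cluster
  ids <- c("x", "y", "z")
  ones <- identity_from_pairs(ids, list(), fill = 1)
  expect_equal(unname(cluster_at_threshold(ones, 0.97)), rep(1L, 3))
  # identity exactly at the threshold separates ("97.0% or lower" = distinct)
  pair <- identity_from_pairs(c("p", "q"), list(list("p", "q", 0.970)))
  expect_equal(length(unique(cluster_at_threshold(pair, 0.970))), 2)
  pair2 <- identity_from_pairs(c("p", "q"), list(list("p", "q", 0.9700001)))
  expect_equal(length(unique(cluster_at_threshold(pair2, 0.970))), 1)
})

test_that("clustering equals exhaustive complete-linkage enumeration", {
  set.seed(71)
  for (rep in 1:25) {
    n <- sample(3:8, 1)
    m <- random_identity_matrix(n)
    for (t in c(0.85, 0.945, 0.97)) {
      cl <- cluster_at_threshold(m, t)
      reachable <- oracle_complete_linkage(m, t)
      expect_true(canonical_partition(cl, rownames(m)) %in% reachable)
      # within-cluster guarantee
      for (g in split(rownames(m), cl))
        if (length(g) > 1) expect_gt(min(m[g, g]), t)
    }
  }
})

test_that("partition is invariant to input order", {
  set.seed(81)
  m <- random_identity_matrix(7)
  cl <- cluster_at_threshold(m, 0.9)
  perm <- sample(7)
  clp <- cluster_at_threshold(m[perm, perm], 0.9)
  expect_identical(canonical_partition(cl, names(cl)),
                   canonical_partition(clp, names(clp)))
})

test_that("nested delineation produces nested, threshold-true partitions", {
  # two well-separated blocks: 2 taxa at every rank
  ids <- c("a", "b", "c", "d")
  m <- identity_from_pairs(ids,
                           list(list("a", "b", 0.99), list("c", "d", 0.99)),
                           fill = 0.80)
  asg <- nested_delineation(m)
  for (rank in c("suborder", "family", "genus", "species"))
    expect_equal(length(unique(asg[[rank]])), 2)
  # nesting: each child label maps to exactly one parent label
  cm <- shared_community()
  im <- distance_matrix(cm$sequences, "identity")
  asg2 <- nested_delineation(im)
  pairs <- list(c("species", "genus"), c("genus", "family"),
                c("family", "suborder"))
  for (p in pairs) {
    parents_per_child <- tapply(asg2[[p[2]]], asg2[[p[1]]],
                                function(x) length(unique(x)))
    expect_true(all(parents_per_child == 1))
  }
  # single sequence: one taxon at every rank
  one <- matrix(1, 1, 1, dimnames = list("solo", "solo"))
  attr(one, "metric") <- "identity"
  asg3 <- nested_delineation(one)
  expect_equal(nrow(asg3), 1)
})

test_that("tree refinement splits non-monophyletic taxa and only splits", {
  tree <- ape::read.tree(text = "((a,b),(x,c));")
  ids <- c("a", "b", "x", "c")
  # species {a,b,x} is not monophyletic: x sits with c
  m <- identity_from_pairs(ids,
                           list(list("a", "b", 0.99), list("a", "x", 0.99),
                                list("b", "x", 0.99)),
                           fill = 0.80)
  asg <- nested_delineation(m)
  expect_equal(length(unique(asg$species)), 2)
  ref <- refine_with_tree(asg, tree)
  sp <- setNames(ref$species, ref$id)
  expect_equal(sp[["a"]], sp[["b"]])
  expect_false(sp[["a"]] == sp[["x"]])
  # already monophyletic assignments are unchanged as partitions
  m2 <- identity_from_pairs(ids,
                            list(list("a", "b", 0.99), list("x", "c", 0.99)),
                            fill = 0.80)
  asg2 <- nested_delineation(m2)
  ref2 <- refine_with_tree(asg2, tree)
  for (rank in c("suborder", "family", "genus", "species"))
    expect_identical(canonical_partition(asg2[[rank]], asg2$id),
                     canonical_partition(ref2[[rank]], ref2$id))
  # permuting tip order in the Newick string changes nothing
  tree_perm <- ape::read.tree(text = "((c,x),(b,a));")
  ref3 <- refine_with_tree(asg, tree_perm)
  expect_identical(canonical_partition(ref$species, ref$id),
                   canonical_partition(ref3$species, ref3$id))
  # missing tips are an error naming the ids
  expect_error(refine_with_tree(asg, ape::read.tree(text = "((a,b),c);")),
               "x")
})

test_that("refinement keeps partitions nested", {
  cm <- shared_community()
  im <- distance_matrix(cm$sequences, "identity")
  asg <- nested_delineation(im)
  tree <- ape::read.tree(text = myxotax:::.truth_newick(cm$truth$taxonomy))
  ref <- refine_with_tree(asg, tree)
  for (p in list(c("species", "genus"), c("genus", "family"),
                 c("family", "suborder"))) {
    parents <- tapply(ref[[p[2]]], ref[[p[1]]],
                      function(x) length(unique(x)))
    expect_true(all(parents == 1))
  }
})

test_that("taxon naming follows the size ordering and anchor rules", {
  ids <- sprintf("s%02d", 1:13)
  asg <- structure(
    data.frame(id = ids,
               suborder = c(rep("1", 10), rep("2", 3)),
               family = c(rep("1.1", 7), rep("1.2", 3), rep("2.1", 3)),
               genus = c(rep("1.1.1", 7), rep("1.2.1", 3), rep("2.1.1", 3)),
               species = c(rep("1.1.1.1", 4), rep("1.1.1.2", 3),
                           rep("1.2.1.1", 3), rep("2.1.1.1", 3)),
               stringsAsFactors = FALSE),
    class = c("taxonomy_assignment", "data.frame"))
  nm <- name_taxa(asg)
  expect_equal(unique(nm$suborder[asg$suborder == "1"]), "Suborder_1")
  expect_equal(unique(nm$suborder[asg$suborder == "2"]), "Suborder_2")
  # largest family within Suborder_1 numbered first
  expect_equal(unique(nm$family[asg$family == "1.1"]), "Suborder_1_Family_1")
  expect_equal(unique(nm$family[asg$family == "1.2"]), "Suborder_1_Family_2")
  expect_true(all(grepl("^Suborder_1_Family_1_Genus_1_Species_[12]$",
                        nm$species[asg$family == "1.1"])))
  # anchoring the large suborder shifts numbering
  nm2 <- name_taxa(asg, anchors = c(s01 = "Sorangiineae"))
  expect_equal(unique(nm2$suborder[asg$suborder == "1"]), "Sorangiineae")
  expect_equal(unique(nm2$suborder[asg$suborder == "2"]), "Suborder_1")
  expect_true(all(grepl("^Sorangiineae_Family_", nm2$family[asg$suborder == "1"])))
  # conflicting anchors in one suborder
  expect_error(name_taxa(asg, anchors = c(s01 = "Sorangiineae",
                                          s02 = "Cystobacterineae")),
               "conflicting")
  # every generated name matches the documented pattern
  cm <- shared_community()
  im <- distance_matrix(cm$sequences, "identity")
  nm3 <- name_taxa(nested_delineation(im))
  expect_true(all(grepl("^Suborder_\\d+$", nm3$suborder)))
  expect_true(all(grepl("^Suborder_\\d+_Family_\\d+_Genus_\\d+_Species_\\d+$",
                        nm3$species)))
})

test_that("taxon table totals, percentages and flags are consistent", {
  tt <- taxon_table(c("A", "B", "C"), c(2, 1, 1), c(3, 1, 2), c(5, 2, 2),
                    c(900, 96, 4))
  expect_equal(unname(attr(tt, "totals")),
               c(3, 4, 6, 9, 1000))
  body <- tt[tt$suborder != "Total", ]
  expect_equal(body$pct, c(90, 9.6, 0.4))
  expect_equal(body$status, c("abundant", "abundant", "rare"))
  expect_equal(tt$sequences[tt$suborder == "Total"], 1000)
  # single suborder -> 100.00
  t1 <- taxon_table("only", 1, 1, 1, 37)
  expect_equal(t1$pct[1], 100)
  # summarize_taxonomy counts children within parents
  cm <- shared_community()
  truth <- cm$truth$taxonomy
  tt2 <- summarize_taxonomy(truth)
  expect_equal(unname(attr(tt2, "totals")[["sequences"]]), nrow(truth))
  expect_equal(unname(attr(tt2, "totals")[["species"]]),
               length(unique(truth$species)))
})
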