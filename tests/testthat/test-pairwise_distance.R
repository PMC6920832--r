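test_that("compared sites exclude gaps and ambiguity codes per pair", {
  expect_equal(compared_sites("AC-G", "ACTG"), c(1L, 2L, 4L))
  expect_equal(compared_sites("ANCG", "AACG"), c(1L, 3L, 4L))
  set.seed(21)
  a <- paste(sample(c("A", "C", "G", "T", "-", "N"), 60, TRUE,
                    prob = c(rep(0.2, 4), 0.1, 0.1)), collapse = "")
  b <- paste(sample(c("A", "C", "G", "T", "-", "N"), 60, TRUE,
                    prob = c(rep(0.2, 4), 0.1, 0.1)), collapse = "")
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  brute <- which(av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T"))
  expect_equal(compared_sites(a, b), brute)
})

test_that("pairwise identity is matches over compared sites", {
  expect_equal(pairwise_identity("ACGTACGT", "ACGTACGT"), 1)
  a <- paste(rep("A", 100), collapse = "")
  b <- paste(c(rep("G", 3), rep("A", 97)), collapse = "")
  expect_equal(pairwise_identity(a, b), 0.97)
  # 10 sites, 2 gaps, 1 mismatch -> 7/8
  expect_equal(pairwise_identity("ACGTAC-TGA", "ACGTAG-TG-"), 7 / 8)
  expect_error(pairwise_identity("AC--", "--GT"), "non-overlapping")
})

test_that("K2P distance matches the closed form and a per-column tally", {
  ident <- k2p_distance("ACGTACGT", "ACGTACGT")
  expect_equal(ident[c("P", "Q", "d")], list(P = 0, Q = 0, d = 0))
  # 100 compared sites: 10 transitions, 5 transversions -> P=0.1, Q=0.05
  a <- paste(rep("A", 100), collapse = "")
  b <- paste(c(rep("G", 10), rep("C", 5), rep("A", 85)), collapse = "")
  k <- k2p_distance(a, b)
  expect_equal(k$P, 0.1)
  expect_equal(k$Q, 0.05)
  expect_equal(k$d, -0.5 * log((1 - 0.2 - 0.05) * sqrt(1 - 0.1)),
               tolerance = 1e-12)
  # toy alignment with mixed substitutions against the hand tally
  x <- "AAGGCCTTAC-GT"
  y <- "AGGACCTCACTG-"
  ko <- oracle_pair_k2p(x, y)
  ki <- k2p_distance(x, y)
  expect_equal(ki[c("P", "Q", "d", "n_sites")], ko)
  # Q = 0 reduces to the transition-only form
  tsonly <- k2p_distance(paste(rep("C", 50), collapse = ""),
                         paste(c(rep("T", 4), rep("C", 46)), collapse = ""))
  expect_equal(tsonly$Q, 0)
  expect_equal(tsonly$d, -0.5 * log(1 - 2 * tsonly$P))
})

test_that("saturated pairs raise unless capped", {
  a <- paste(rep(c("A", "C"), 10), collapse = "")
  b <- paste(rep(c("C", "A"), 10), collapse = "")  # all transversions, Q = 1
  expect_error(k2p_distance(a, b), "saturated")
  expect_equal(k2p_distance(a, b, max_distance = 3)$d, 3)
  expect_true(is.nan(k2p_closed_form(0.3, 0.45)))
})

test_that("distance matrices equal a brute-force double loop", {
  set.seed(31)
  n <- 8
  # derive all rows from one root so pairs stay unsaturated, then sprinkle
  # gaps and ambiguity to exercise pairwise deletion
  root <- strsplit(random_dna(120), "")[[1]]
  seqs <- setNames(vapply(seq_len(n), function(...) {
    v <- root
    sub <- sample(120, sample(0:15, 1))
    v[sub] <- sample(c("A", "C", "G", "T"), length(sub), TRUE)
    noise <- sample(120, 8)
    v[noise] <- sample(c("-", "N"), 8, TRUE)
    paste(v, collapse = "")
  }, character(1)), sprintf("s%d", seq_len(n)))
  im <- distance_matrix(seqs, "identity")
  km <- distance_matrix(seqs, "k2p", max_distance = 5)
  expect_true(isSymmetric(unname(unclass(im))))
  expect_equal(unname(diag(im)), rep(1, n))
  expect_equal(unname(diag(km)), rep(0, n))
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    expect_equal(im[i, j], oracle_pair_identity(seqs[i], seqs[j]))
    expect_equal(km[i, j], oracle_pair_k2p(seqs[i], seqs[j])$d)
  }
})

test_that("K2P matrix agrees with an independent phylogenetics implementation", {
  skip_if_not_installed("ape")
  set.seed(41)
  root <- strsplit(random_dna(400), "")[[1]]
  mat <- matrix(rep(root, 6), nrow = 6, byrow = TRUE,
                dimnames = list(sprintf("s%d", 1:6), NULL))
  for (k in 2:6) {
    sites <- sample(400, 30)
    mat[k, sites] <- sample(c("A", "C", "G", "T"), 30, TRUE)
  }
  seqs <- apply(mat, 1, paste, collapse = "")
  km <- distance_matrix(seqs, "k2p")
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(seqs), "")))
  ref <- as.matrix(ape::dist.dna(bin, model = "K80",
                                 pairwise.deletion = TRUE))
  expect_equal(unclass(km)[rownames(ref), colnames(ref)], ref,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("adding a mismatch at a compared site never increases identity", {
  set.seed(51)
  for (rep in 1:20) {
    a <- random_dna(80)
    b <- random_dna(80)
    base_id <- pairwise_identity(a, b)
    av <- strsplit(a, "")[[1]]
    bv <- strsplit(b, "")[[1]]
    match_sites <- which(av == bv)
    if (length(match_sites) == 0) next
    site <- sample(match_sites, 1)
    bv[site] <- setdiff(c("A", "C", "G", "T"), bv[site])[1]
    expect_lt(pairwise_identity(a, paste(bv, collapse = "")), base_id)
  }
})

test_that("long-format pairwise table is consistent with the matrices", {
  set.seed(61)
  seqs <- setNames(vapply(1:4, function(...) random_dna(200), character(1)),
                   c("a", "b", "c", "d"))
  tab <- pairwise_table(seqs)
  expect_equal(nrow(tab), 6)
  im <- distance_matrix(seqs, "identity")
  for (r in seq_len(nrow(tab)))
    expect_equal(tab$identity[r], im[tab$id1[r], tab$id2[r]])
})
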