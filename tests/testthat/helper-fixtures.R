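# Programmatic fixtures shared across test files.

make_records <- function(ids, residues, strain_key = ids,
                         env_category = "Soil", cultured = "unknown") {
  data.frame(id = ids, strain_key = strain_key,
             env_category = env_category, country = NA_character_,
             latitude = NA_real_, longitude = NA_real_,
             cultured = cultured, residues = residues,
             stringsAsFactors = FALSE)
}

random_dna <- function(n_bases) {
  paste(sample(c("A", "C", "G", "T"), n_bases, replace = TRUE),
        collapse = "")
}

# Sequence of given ungapped length with a given number of N's.
seq_with_ns <- function(len, n_ambiguous) {
  base <- rep(c("A", "C", "G", "T"), length.out = len)
  if (n_ambiguous > 0) base[seq_len(n_ambiguous)] <- "N"
  paste(base, collapse = "")
}

# Identity matrix from explicit pair values; all unspecified pairs `fill`.
identity_from_pairs <- function(ids, pairs, fill = 0.5) {
  n <- length(ids)
  m <- matrix(fill, n, n, dimnames = list(ids, ids))
  diag(m) <- 1
  for (p in pairs) {
    i <- p[[1]]; j <- p[[2]]
    m[i, j] <- m[j, i] <- as.numeric(p[[3]])
  }
  attr(m, "metric") <- "identity"
  m
}

# A small default community reused by several files (cached per session).
shared_community <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_community(sim_spec(seed = 1L))
    cache
  }
})
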