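# Independent oracles: deliberately naive re-derivations (per-element
# loops, exhaustive enumeration, resampling) kept separate from the
# package's vectorised implementations.

# Hand filter: apply the two QC rules record by record.
oracle_filter <- function(records, min_length, max_ratio) {
  kept <- character(0)
  rejected <- list()
  for (k in seq_len(nrow(records))) {
    ch <- strsplit(records$residues[k], "")[[1]]
    ng <- ch[ch != "-"]
    if (length(ng) < min_length) {
      rejected[[records$id[k]]] <- "too_short"
    } else if (sum(!ng %in% c("A", "C", "G", "T")) / length(ng) >= max_ratio) {
      rejected[[records$id[k]]] <- "too_ambiguous"
    } else {
      kept <- c(kept, records$id[k])
    }
  }
  list(kept = kept, rejected = rejected)
}

# Brute-force group max by (ungapped length, then smallest id).
oracle_dedupe_ids <- function(records) {
  out <- character(0)
  for (sk in unique(records$strain_key)) {
    grp <- records[records$strain_key == sk, ]
    lens <- nchar(gsub("-", "", grp$residues, fixed = TRUE))
    best <- grp$id[lens == max(lens)]
    out <- c(out, sort(best)[1])
  }
  sort(out)
}

# Per-column scan identity for one pair.
oracle_pair_identity <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  acgt <- c("A", "C", "G", "T")
  m <- 0L
  n <- 0L
  for (k in seq_along(x)) {
    if (x[k] %in% acgt && y[k] %in% acgt) {
      n <- n + 1L
      if (x[k] == y[k]) m <- m + 1L
    }
  }
  if (n == 0L) return(NA_real_)
  m / n
}

# Per-column transition/transversion tally for one pair.
oracle_pair_k2p <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  acgt <- c("A", "C", "G", "T")
  ts_pairs <- list(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"))
  n <- 0L; ts <- 0L; tv <- 0L
  for (k in seq_along(x)) {
    if (!(x[k] %in% acgt && y[k] %in% acgt)) next
    n <- n + 1L
    if (x[k] == y[k]) next
    hit <- any(vapply(ts_pairs, function(p) x[k] == p[1] && y[k] == p[2],
                      logical(1)))
    if (hit) ts <- ts + 1L else tv <- tv + 1L
  }
  P <- ts / n
  Q <- tv / n
  list(P = P, Q = Q, d = -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q)),
       n_sites = n)
}

# Canonical representation of a partition for set comparison.
canonical_partition <- function(labels, ids) {
  blocks <- split(ids, labels)
  blocks <- vapply(blocks, function(b) paste(sort(b), collapse = ","),
                   character(1))
  paste(sort(unname(blocks)), collapse = "|")
}

# Exhaustive complete-linkage agglomeration exploring every tie order:
# returns the set of reachable final partitions at cutoff t.
oracle_complete_linkage <- function(im, t) {
  ids <- rownames(im)
  seen <- new.env(parent = emptyenv())
  results <- new.env(parent = emptyenv())
  recurse <- function(clusters) {
    key <- paste(vapply(clusters, function(cl) paste(sort(cl), collapse = ","),
                        character(1))[order(vapply(clusters, min, numeric(1)))],
                 collapse = "|")
    if (!is.null(seen[[key]])) return(invisible())
    seen[[key]] <- TRUE
    k <- length(clusters)
    best <- -Inf
    pairs <- list()
    for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
      lk <- min(im[clusters[[i]], clusters[[j]]])
      if (lk > best + 1e-12) {
        best <- lk
        pairs <- list(c(i, j))
      } else if (abs(lk - best) <= 1e-12) {
        pairs <- c(pairs, list(c(i, j)))
      }
    }
    if (best <= t) {
      lab <- integer(length(ids))
      for (ci in seq_along(clusters)) lab[clusters[[ci]]] <- ci
      results[[canonical_partition(lab, ids)]] <- TRUE
      return(invisible())
    }
    for (p in pairs) {
      merged <- c(clusters[-p], list(c(clusters[[p[1]]], clusters[[p[2]]])))
      recurse(merged)
    }
  }
  recurse(as.list(seq_along(ids)))
  ls(results)
}

# Random symmetric identity-like matrix; values drawn from a coarse grid
# so linkage ties actually occur.
random_identity_matrix <- function(n, values = c(0.80, 0.86, 0.90, 0.95,
                                                 0.96, 0.975, 0.99)) {
  m <- matrix(1, n, n)
  v <- sample(values, n * (n - 1) / 2, replace = TRUE)
  m[upper.tri(m)] <- v
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  ids <- sprintf("t%02d", seq_len(n))
  dimnames(m) <- list(ids, ids)
  attr(m, "metric") <- "identity"
  m
}

# Resampling rarefaction: mean distinct species over random subsamples.
oracle_rarefy <- function(abundances, n, reps) {
  pool <- rep(seq_along(abundances), abundances)
  draws <- vapply(seq_len(reps),
                  function(...) length(unique(sample(pool, n))),
                  integer(1))
  list(mean = mean(draws), se = stats::sd(draws) / sqrt(reps))
}
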