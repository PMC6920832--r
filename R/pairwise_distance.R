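# Pairwise identity and Kimura two-parameter (K2P) distances over an
# aligned sequence set, under pairwise deletion: for each pair, only
# alignment columns where both residues are unambiguous bases (A/C/G/T)
# are compared; gap and ambiguity columns are dropped per pair, not
# globally.

# Encode an aligned character vector as an n x L integer matrix with
# A=1, C=2, G=3, T=4 and NA for gaps/ambiguity codes.
.encode_alignment <- function(seqs) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$residues, seqs$id)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("aligned sequences must carry unique names")
  L <- unique(nchar(seqs))
  if (length(L) != 1L)
    stop("sequences are not aligned: unequal lengths ",
         paste(sort(unique(nchar(seqs))), collapse = ", "))
  chars <- matrix(unlist(strsplit(toupper(seqs), "", fixed = FALSE), use.names = FALSE),
                  nrow = length(seqs), ncol = L, byrow = TRUE)
  code <- matrix(match(chars, DNA_BASES), nrow = length(seqs), ncol = L)
  rownames(code) <- names(seqs)
  code
}

#' Columns compared between two aligned rows
#'
#' Under pairwise deletion a column contributes to a pair only when both
#' residues are unambiguous bases (`A`, `C`, `G`, `T`); columns with a gap
#' or an IUPAC ambiguity code in either row are skipped for that pair.
#'
#' @param a,b Residue strings of equal length.
#' @return Integer vector of 1-based column indices.
#' @examples
#' compared_sites("AC-G", "ACTG")  # 1 2 4
#' @export
compared_sites <- function(a, b) {
  code <- .encode_alignment(c(x = a, y = b))
  which(!is.na(code[1L, ]) & !is.na(code[2L, ]))
}

#' Pairwise identity between two aligned rows
#'
#' Matching bases divided by compared sites (pairwise deletion).
#'
#' @param a,b Residue strings of equal length.
#' @return Fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  code <- .encode_alignment(c(x = a, y = b))
  both <- !is.na(code[1L, ]) & !is.na(code[2L, ])
  if (!any(both))
    stop("non-overlapping pair: no compared sites")
  mean(code[1L, both] == code[2L, both])
}

#' Kimura two-parameter distance from transition/transversion proportions
#'
#' Evaluates `d = -(1/2) * log((1 - 2P - Q) * sqrt(1 - 2Q))`, the K2P
#' substitutions-per-site correction, where `P` is the transition and `Q`
#' the transversion proportion over compared sites. Saturated inputs
#' (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`) yield `NaN`.
#'
#' @param P,Q Transition and transversion proportions (vectorised).
#' @return Corrected distance(s) in substitutions per site.
#' @examples
#' k2p_closed_form(0.1, 0.05)
#' @export
k2p_closed_form <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  d <- suppressWarnings(-0.5 * log(w1 * sqrt(w2)))
  d[w1 <= 0 | w2 <= 0] <- NaN
  d
}

#' Kimura two-parameter distance between two aligned rows
#'
#' Transitions are `A<->G` and `C<->T`; every other differing base pair is
#' a transversion. Proportions are taken over the pairwise-deletion
#' compared sites.
#'
#' @param a,b Residue strings of equal length.
#' @param max_distance Optional cap returned when the pair is saturated
#'   (the K2P logarithm undefined); by default saturation is an error.
#' @return A list with elements `P`, `Q`, `d` and `n_sites`.
#' @export
k2p_distance <- function(a, b, max_distance = NULL) {
  code <- .encode_alignment(c(x = a, y = b))
  both <- !is.na(code[1L, ]) & !is.na(code[2L, ])
  n <- sum(both)
  if (n == 0L)
    stop("non-overlapping pair: no compared sites")
  x <- code[1L, both]
  y <- code[2L, both]
  diff <- x != y
  # purines code 1 (A) and 3 (G); pyrimidines 2 (C) and 4 (T): a substitution
  # within the same parity is a transition.
  transition <- diff & ((x %% 2L) == (y %% 2L))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  d <- k2p_closed_form(P, Q)
  if (is.nan(d)) {
    if (is.null(max_distance))
      stop("saturated pair: K2P distance undefined (P = ", signif(P, 4),
           ", Q = ", signif(Q, 4), ")")
    d <- max_distance
  }
  list(P = P, Q = Q, d = d, n_sites = n)
}

#' Pairwise distance matrix over an aligned sequence set
#'
#' Computes all pairwise values under pairwise deletion, vectorised over the
#' whole alignment. For `metric = "identity"` the result has a unit
#' diagonal and values in `[0, 1]`; for `metric = "k2p"` a zero diagonal
#' and corrected distances in substitutions per site.
#'
#' @param seqs Named character vector of equal-length residue strings, or a
#'   records data.frame with `id` and `residues` columns.
#' @param metric `"identity"` or `"k2p"`.
#' @param max_distance Optional cap substituted for saturated K2P pairs;
#'   by default saturation is an error naming the offending pair.
#' @return Symmetric numeric matrix with sequence ids as dimnames and an
#'   attribute `metric`.
#' @export
distance_matrix <- function(seqs, metric = c("identity", "k2p"),
                            max_distance = NULL) {
  metric <- match.arg(metric)
  code <- .encode_alignment(seqs)
  n <- nrow(code)
  if (n < 2L) stop("need at least 2 sequences")
  ids <- rownames(code)

  valid_row <- !is.na(code)
  if (any(rowSums(valid_row) == 0L))
    stop("sequence(s) with no unambiguous bases: ",
         paste(ids[rowSums(valid_row) == 0L], collapse = ", "))
  V <- valid_row
  storage.mode(V) <- "double"
  valid <- tcrossprod(V)

  ind <- lapply(1:4, function(b) {
    M <- code == b
    M[is.na(M)] <- FALSE
    storage.mode(M) <- "double"
    M
  })
  matches <- Reduce(`+`, lapply(ind, tcrossprod))

  off <- upper.tri(valid)
  if (any(valid[off] == 0)) {
    bad <- which(valid == 0 & off, arr.ind = TRUE)
    stop("non-overlapping pair(s): ",
         paste(ids[bad[, 1L]], ids[bad[, 2L]], sep = "/", collapse = ", "))
  }

  if (metric == "identity") {
    m <- matches / valid
    diag(m) <- 1
  } else {
    ts <- tcrossprod(ind[[1L]], ind[[3L]]) + tcrossprod(ind[[3L]], ind[[1L]]) +
      tcrossprod(ind[[2L]], ind[[4L]]) + tcrossprod(ind[[4L]], ind[[2L]])
    P <- ts / valid
    Q <- (valid - matches - ts) / valid
    m <- k2p_closed_form(P, Q)
    diag(m) <- 0
    if (any(is.nan(m[off]))) {
      if (is.null(max_distance)) {
        bad <- which(is.nan(m) & off, arr.ind = TRUE)
        stop("saturated pair(s): K2P distance undefined for ",
             paste(ids[bad[, 1L]], ids[bad[, 2L]], sep = "/", collapse = ", "))
      }
      m[is.nan(m)] <- max_distance
      diag(m) <- 0
    }
  }
  dimnames(m) <- list(ids, ids)
  attr(m, "metric") <- metric
  m
}

#' Long-format pairwise table
#'
#' One row per unordered sequence pair with both the raw identity and the
#' K2P-corrected distance, the two values the delineation reports side by
#' side (thresholds are applied to raw identity).
#'
#' @inheritParams distance_matrix
#' @param max_distance Cap for saturated K2P pairs (default `NA`, recorded
#'   as a missing distance rather than an error).
#' @return A data.frame with columns `id1`, `id2`, `identity`, `k2p_d`.
#' @export
pairwise_table <- function(seqs, max_distance = NA_real_) {
  im <- distance_matrix(seqs, "identity")
  km <- distance_matrix(seqs, "k2p", max_distance = max_distance)
  ids <- rownames(im)
  idx <- which(upper.tri(im), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  data.frame(id1 = ids[idx[, 1L]],
             id2 = ids[idx[, 2L]],
             identity = im[idx],
             k2p_d = km[idx],
             stringsAsFactors = FALSE)
}

#' Write a square distance/identity matrix as TSV
#'
#' Ids appear in the first row and first column.
#'
#' @param m Matrix from [distance_matrix()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_distance_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
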