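# Sequence ingest and quality control.
#
# A "records" table is a plain data.frame with one row per sequence:
# id, strain_key, env_category, country, latitude, longitude, cultured,
# residues. Residues are upper-case IUPAC DNA characters plus '-' for
# alignment gaps; 'U' is normalised to 'T' on ingest.

#' Quality-control parameters
#'
#' Filtering thresholds for near-full-length 16S rRNA gene sequences: a
#' minimum ungapped length (default 1200 bases, the conventional cutoff for
#' near-full-length 16S sequences) and a strict upper bound on the ambiguous
#' base ratio (default 0.002, i.e. a sequence with 3 or more ambiguous bases
#' per 1500 is rejected).
#'
#' @param min_length Minimum ungapped sequence length in bases.
#' @param max_ambiguous_ratio Exclusive upper bound on the fraction of
#'   non-gap residues that are IUPAC ambiguity codes.
#' @return A named list with class `qc_params`.
#' @examples
#' qc_params()
#' @export
qc_params <- function(min_length = 1200L, max_ambiguous_ratio = 0.002) {
  min_length <- as.integer(min_length)
  stopifnot(length(min_length) == 1L, min_length > 0L,
            length(max_ambiguous_ratio) == 1L,
            max_ambiguous_ratio >= 0, max_ambiguous_ratio < 1)
  structure(list(min_length = min_length,
                 max_ambiguous_ratio = max_ambiguous_ratio),
            class = "qc_params")
}

.normalize_residues <- function(x) {
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  ok <- c(DNA_BASES, IUPAC_AMBIGUOUS, GAP_CHAR)
  bad <- setdiff(unique(unlist(strsplit(x, "", fixed = FALSE))), ok)
  if (length(bad) > 0L)
    stop("invalid residue character(s): ", paste(bad, collapse = ", "))
  x
}

.residues_of <- function(x) {
  if (is.data.frame(x)) {
    if (is.null(x$residues)) stop("records table has no 'residues' column")
    x$residues
  } else {
    as.character(x)
  }
}

#' Read a (possibly aligned) FASTA file
#'
#' Sequence names are truncated at the first whitespace to form ids.
#' Residues are upper-cased, `U` is normalised to `T`, and any character
#' outside the IUPAC DNA alphabet plus `-` is an error.
#'
#' @param path Path to a FASTA file (wrapped or single-line).
#' @return Named character vector of residue strings.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- .normalize_residues(as.character(set))
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param x Named character vector of residue strings, or a records
#'   data.frame with `id` and `residues` columns.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.data.frame(x)) x <- setNames(x$residues, x$id)
  set <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a per-sequence metadata table
#'
#' Tab-separated with header
#' `id  strain_key  env_category  country  latitude  longitude  cultured`;
#' empty fields are missing values. Missing `strain_key` defaults to the id
#' (each sequence its own strain), missing `env_category` to `The_unknown`,
#' missing `cultured` to `unknown`.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with typed columns.
#' @export
read_metadata <- function(path) {
  md <- read.delim(path, colClasses = "character", na.strings = "",
                   stringsAsFactors = FALSE)
  needed <- c("id", "strain_key", "env_category", "country",
              "latitude", "longitude", "cultured")
  missing_cols <- setdiff(needed, names(md))
  if (length(missing_cols) > 0L)
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(md$id))
    stop("duplicate ids in metadata: ",
         paste(unique(md$id[duplicated(md$id)]), collapse = ", "))
  md$strain_key[is.na(md$strain_key)] <- md$id[is.na(md$strain_key)]
  md$env_category[is.na(md$env_category)] <- "The_unknown"
  bad_env <- setdiff(unique(md$env_category), env_categories())
  if (length(bad_env) > 0L)
    stop("unknown environmental category: ", paste(bad_env, collapse = ", "))
  md$cultured[is.na(md$cultured)] <- "unknown"
  bad_cult <- setdiff(unique(md$cultured), c("cultured", "uncultured", "unknown"))
  if (length(bad_cult) > 0L)
    stop("invalid 'cultured' value: ", paste(bad_cult, collapse = ", "))
  md$latitude <- as.numeric(md$latitude)
  md$longitude <- as.numeric(md$longitude)
  if (any(md$latitude < -90 | md$latitude > 90, na.rm = TRUE))
    stop("latitude outside [-90, 90]")
  if (any(md$longitude < -180 | md$longitude > 180, na.rm = TRUE))
    stop("longitude outside [-180, 180]")
  md[needed]
}

#' Read sequences plus metadata into a records table
#'
#' @param fasta Path to a FASTA file.
#' @param metadata Optional path to a metadata TSV (see [read_metadata()]).
#'   When absent, defaults are filled in (strain_key = id, environment
#'   `The_unknown`, culturability `unknown`).
#' @return A records data.frame (one row per sequence, in FASTA order).
#' @export
read_sequences <- function(fasta, metadata = NULL) {
  seqs <- read_fasta(fasta)
  rec <- data.frame(id = names(seqs), stringsAsFactors = FALSE)
  if (is.null(metadata)) {
    rec$strain_key <- rec$id
    rec$env_category <- "The_unknown"
    rec$country <- NA_character_
    rec$latitude <- NA_real_
    rec$longitude <- NA_real_
    rec$cultured <- "unknown"
  } else {
    md <- read_metadata(metadata)
    miss <- setdiff(rec$id, md$id)
    if (length(miss) > 0L)
      stop("sequences missing from metadata: ", paste(miss, collapse = ", "))
    md <- md[match(rec$id, md$id), ]
    rec <- cbind(rec, md[setdiff(names(md), "id")])
  }
  rec$residues <- unname(seqs)
  rownames(rec) <- NULL
  rec
}

#' Ambiguous base ratio of a sequence
#'
#' The fraction of non-gap residues that are not one of `A`, `C`, `G`, `T`.
#' Gaps are excluded from both numerator and denominator, so the ratio is
#' identical whether a sequence is supplied aligned or unaligned.
#'
#' @param x Character vector of residue strings, or a records data.frame.
#' @return Numeric vector of ratios in `[0, 1]`.
#' @examples
#' ambiguous_ratio("ACGTACGT")       # 0
#' ambiguous_ratio("ACGTNNGT")       # 0.25
#' ambiguous_ratio("AC--GTNT")       # 1/6 (gaps ignored)
#' @export
ambiguous_ratio <- function(x) {
  vapply(.residues_of(x), function(s) {
    ch <- strsplit(s, "", fixed = FALSE)[[1L]]
    ng <- ch[ch != GAP_CHAR]
    if (length(ng) == 0L)
      stop("sequence contains only gap characters")
    mean(!(ng %in% DNA_BASES))
  }, numeric(1L), USE.NAMES = FALSE)
}

#' Ungapped sequence length
#'
#' @inheritParams ambiguous_ratio
#' @return Integer vector of non-gap residue counts.
#' @export
ungapped_length <- function(x) {
  res <- .residues_of(x)
  nchar(res) - nchar(gsub("[^-]", "", res))
}

#' Filter sequences by length and ambiguity
#'
#' A record is kept when its ungapped length is at least
#' `params$min_length` and its ambiguous base ratio is strictly below
#' `params$max_ambiguous_ratio`. With the defaults a 1500-base sequence
#' with three ambiguous bases (ratio exactly 0.002) is rejected while two
#' ambiguous bases pass. Rejections are reported with a reason code,
#' `too_short` taking precedence when both rules fail.
#'
#' @param records A records data.frame (see [read_sequences()]).
#' @param params A [qc_params()] object.
#' @return A list with elements `kept` (records, input order preserved) and
#'   `rejected` (data.frame with columns `id`, `reason`).
#' @export
filter_sequences <- function(records, params = qc_params()) {
  stopifnot(inherits(params, "qc_params"))
  if (nrow(records) == 0L) {
    return(list(kept = records,
                rejected = data.frame(id = character(0),
                                      reason = character(0),
                                      stringsAsFactors = FALSE)))
  }
  len_ok <- ungapped_length(records) >= params$min_length
  amb_ok <- ambiguous_ratio(records) < params$max_ambiguous_ratio
  keep <- len_ok & amb_ok
  reason <- ifelse(!len_ok, "too_short", "too_ambiguous")
  list(kept = records[keep, , drop = FALSE],
       rejected = data.frame(id = records$id[!keep],
                             reason = reason[!keep],
                             stringsAsFactors = FALSE))
}

#' Select one representative sequence per strain
#'
#' Duplicate deposits of the same strain (shared `strain_key`) are collapsed
#' to the longest sequence by ungapped length; length ties are broken by the
#' lexicographically smallest id so the choice is deterministic.
#'
#' @param records A records data.frame of QC-passed sequences.
#' @return A records data.frame with one row per distinct `strain_key`,
#'   in the input order of the retained rows.
#' @export
dedupe_by_strain <- function(records) {
  if (nrow(records) == 0L) return(records)
  len <- ungapped_length(records)
  keep <- logical(nrow(records))
  for (idx in split(seq_len(nrow(records)), records$strain_key)) {
    best <- idx[order(-len[idx], records$id[idx])][1L]
    keep[best] <- TRUE
  }
  records[keep, , drop = FALSE]
}

#' Write a QC rejection report
#'
#' @param rejected The `rejected` element from [filter_sequences()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_rejection_report <- function(rejected, path) {
  write.table(rejected, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
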