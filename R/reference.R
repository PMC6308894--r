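# Reference sequence sets: FASTA + taxonomy ingestion, species
# dereplication, priming-site localization within an alignment, and
# per-record site extraction.

#' Read reference sequences and taxonomy into a reference set
#'
#' Sequences are read with Biostrings; the taxonomy TSV (header `seq_id`,
#' `species`, `order`, `class`) is joined on the first whitespace-separated
#' token of each FASTA header. Records without a taxonomy row are retained
#' with empty taxonomy fields and counted in the load report
#' (`attr(x, "load_report")`).
#'
#' @param sequences path to a FASTA file. The input is treated as an
#'   alignment when any record contains `-` gap characters, or when two
#'   or more records all share one width (an indel-free alignment);
#'   override with `aligned`.
#' @param taxonomy optional path to the taxonomy TSV.
#' @param aligned force (`TRUE`) or suppress (`FALSE`) alignment
#'   handling; `NA` (default) auto-detects as described above.
#' @return an object of class `reference_set`: list with `records`
#'   (data.frame `seq_id`, `sequence` (ungapped), `species`, `order`,
#'   `class`), `aligned` (named character vector of gapped rows, or `NULL`),
#'   and `alignment_width`.
#' @export
read_reference <- function(sequences, taxonomy = NULL, aligned = NA) {
  if (!file.exists(sequences)) {
    stop(sprintf("FASTA file not found: %s", sequences), call. = FALSE)
  }
  x <- Biostrings::readBStringSet(sequences)
  if (length(x) == 0L) warning("empty FASTA: reference set has no records")
  seq_id <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(seq_id)) {
    stop(sprintf("duplicate seq_id in FASTA: %s",
                 seq_id[duplicated(seq_id)][1]), call. = FALSE)
  }
  raw <- toupper(as.character(x))
  names(raw) <- seq_id
  has_gap <- length(raw) > 0L && any(grepl("-", raw, fixed = TRUE))
  is_aligned <- if (is.na(aligned)) {
    has_gap || (length(raw) >= 2L && length(unique(nchar(raw))) == 1L)
  } else {
    isTRUE(aligned)
  }
  aligned_rows <- NULL
  width <- NA_integer_
  if (is_aligned) {
    widths <- nchar(raw)
    if (length(unique(widths)) != 1L) {
      stop("aligned FASTA rows do not share a common width", call. = FALSE)
    }
    width <- widths[1]
    aligned_rows <- raw
  }
  records <- data.frame(
    seq_id = seq_id,
    sequence = gsub("-", "", raw, fixed = TRUE),
    species = character(length(raw)), order = character(length(raw)),
    class = character(length(raw)),
    row.names = NULL, stringsAsFactors = FALSE)
  n_unjoined <- 0L
  if (!is.null(taxonomy)) {
    tax <- read_taxonomy(taxonomy)
    idx <- match(records$seq_id, tax$seq_id)
    hit <- !is.na(idx)
    records$species[hit] <- tax$species[idx[hit]]
    records$order[hit] <- tax$order[idx[hit]]
    records$class[hit] <- tax$class[idx[hit]]
    n_unjoined <- sum(!hit)
  }
  structure(
    list(records = records, aligned = aligned_rows,
         alignment_width = width),
    class = "reference_set",
    load_report = list(n_records = nrow(records), n_unjoined = n_unjoined,
                       aligned = is_aligned))
}

#' Read a taxonomy table
#'
#' @param path TSV with header columns `seq_id`, `species`, `order`,
#'   `class`.
#' @return data.frame with those four character columns.
#' @export
read_taxonomy <- function(path) {
  tax <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("seq_id", "species", "order", "class")
  if (!all(need %in% names(tax))) {
    stop("taxonomy TSV must have columns seq_id, species, order, class",
         call. = FALSE)
  }
  if (anyDuplicated(tax$seq_id)) {
    stop("duplicate seq_id in taxonomy", call. = FALSE)
  }
  tax[need]
}

#' Build a reference set from in-memory data
#'
#' Programmatic constructor used by the fixture generator and tests.
#'
#' @param sequences named character vector (names = seq_id); treated as
#'   an alignment when gapped or when two or more records share one
#'   width (override with `aligned`).
#' @param taxonomy optional data.frame with `seq_id`, `species`, `order`,
#'   `class`.
#' @param aligned force or suppress alignment handling (`NA` =
#'   auto-detect).
#' @return a `reference_set` (see [read_reference()]).
#' @export
reference_set <- function(sequences, taxonomy = NULL, aligned = NA) {
  stopifnot(is.character(sequences), !is.null(names(sequences)),
            !anyDuplicated(names(sequences)))
  raw <- toupper(sequences)
  has_gap <- any(grepl("-", raw, fixed = TRUE))
  is_aligned <- if (is.na(aligned)) {
    has_gap || (length(raw) >= 2L && length(unique(nchar(raw))) == 1L)
  } else {
    isTRUE(aligned)
  }
  width <- NA_integer_
  aligned_rows <- NULL
  if (is_aligned) {
    widths <- nchar(raw)
    stopifnot(length(unique(widths)) == 1L)
    width <- widths[[1]]
    aligned_rows <- raw
  }
  records <- data.frame(seq_id = names(raw),
                        sequence = gsub("-", "", raw, fixed = TRUE),
                        species = character(length(raw)),
                        order = character(length(raw)),
                        class = character(length(raw)),
                        row.names = NULL, stringsAsFactors = FALSE)
  n_unjoined <- 0L
  if (!is.null(taxonomy)) {
    idx <- match(records$seq_id, taxonomy$seq_id)
    hit <- !is.na(idx)
    records$species[hit] <- taxonomy$species[idx[hit]]
    records$order[hit] <- taxonomy$order[idx[hit]]
    records$class[hit] <- taxonomy$class[idx[hit]]
    n_unjoined <- sum(!hit)
  }
  structure(list(records = records, aligned = aligned_rows,
                 alignment_width = width),
            class = "reference_set",
            load_report = list(n_records = nrow(records),
                               n_unjoined = n_unjoined,
                               aligned = is_aligned))
}

#' @export
print.reference_set <- function(x, ...) {
  rep <- attr(x, "load_report")
  cat(sprintf("<reference_set> %d records%s\n", nrow(x$records),
              if (!is.null(x$aligned))
                sprintf(", aligned (width %d)", x$alignment_width) else ""))
  if (!is.null(rep) && rep$n_unjoined > 0) {
    cat(sprintf("  %d records without taxonomy\n", rep$n_unjoined))
  }
  invisible(x)
}

# normalized species key: collapsed whitespace, case-folded
.species_key <- function(species) {
  tolower(gsub("\\s+", " ", trimws(species)))
}

#' Dereplicate a reference set to one representative per species
#'
#' Keeps, for each distinct species key (whitespace-normalized, case-
#' folded), the record with the greatest ungapped length; ties are broken
#' by the lexicographically smallest `seq_id`. Records with an empty
#' species field are dropped and counted in `attr(x, "derep_report")`.
#' Indeterminate entries such as "Genus sp." are distinct keys by default.
#'
#' @param refset a `reference_set`.
#' @param drop_indeterminate drop species keys ending in " sp." as well.
#' @return the dereplicated `reference_set`.
#' @export
dereplicate_by_species <- function(refset, drop_indeterminate = FALSE) {
  stopifnot(inherits(refset, "reference_set"))
  rec <- refset$records
  key <- .species_key(rec$species)
  keep_mask <- nzchar(key)
  if (drop_indeterminate) keep_mask <- keep_mask & !grepl(" sp\\.?$", key)
  n_dropped <- sum(!keep_mask)
  rec <- rec[keep_mask, , drop = FALSE]
  key <- key[keep_mask]
  # order so that the preferred record per key comes first:
  # descending length, then ascending seq_id
  ord <- order(key, -nchar(rec$sequence), rec$seq_id)
  rec <- rec[ord, , drop = FALSE]
  key <- key[ord]
  rec <- rec[!duplicated(key), , drop = FALSE]
  # restore input order among kept records
  rec <- rec[order(match(rec$seq_id, refset$records$seq_id)), , drop = FALSE]
  row.names(rec) <- NULL
  out <- refset
  out$records <- rec
  if (!is.null(out$aligned)) out$aligned <- out$aligned[rec$seq_id]
  attr(out, "derep_report") <- list(
    n_in = nrow(refset$records), n_out = nrow(rec),
    n_dropped_no_species = n_dropped)
  attr(out, "load_report") <- attr(refset, "load_report")
  out
}

# character matrix (width x n) of alignment rows -> integer masks, 0 = gap
.alignment_masks <- function(aligned) {
  chars <- vapply(strsplit(aligned, "", fixed = TRUE), identity,
                  character(nchar(aligned[[1]])))
  if (is.null(dim(chars))) chars <- matrix(chars, nrow = 1L)
  m <- matrix(unname(.IUPAC_MASK[chars]), nrow = nrow(chars))
  m[chars == "-"] <- 0L
  m[is.na(m)] <- -1L  # invalid characters: never match, never covered
  m
}

#' Locate a primer's priming site within a reference alignment
#'
#' Slides a window of the primer's length along the alignment columns and
#' scores each window (on both strands) by the mean fraction of matching
#' positions over records whose window is gap-free; the best-scoring
#' window wins, ties going to the leftmost window and to the plus strand.
#' For speed the mean is taken over a seeded random subsample of records
#' (`max_records`); `exact = TRUE` uses all records.
#'
#' @param refset an aligned `reference_set`.
#' @param primer a [degenerate_primer()]; reverse primers are compared via
#'   their reverse complement, and their site is reported on the minus
#'   strand.
#' @param mode match semantics, see [symbols_match()].
#' @param max_records subsample cap for scoring (default 1000).
#' @param seed seed for the subsample draw.
#' @param exact score over all records.
#' @return an object of class `site_spec`: list with `primer_name`,
#'   `start`, `end` (0-based half-open columns), `strand` (`"plus"` or
#'   `"minus"`), `score`, `n_scored`.
#' @export
locate_site <- function(refset, primer, mode = c("intersection", "subset"),
                        max_records = 1000L, seed = 1L, exact = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(refset, "reference_set"),
            inherits(primer, "degenerate_primer"))
  if (is.null(refset$aligned)) {
    stop("locate_site() needs an aligned reference set", call. = FALSE)
  }
  L <- primer$length
  W <- refset$alignment_width
  if (W < L) stop("alignment is shorter than the primer", call. = FALSE)
  rows <- refset$aligned
  if (!exact && length(rows) > max_records) {
    rows <- rows[.with_seed(seed, sample.int(length(rows), max_records))]
  }
  M <- .alignment_masks(rows)
  pm_plus <- iupac_masks(primer$sequence)
  pm_minus <- rev(.MASK_COMPLEMENT[pm_plus])
  # strand records which pattern sits in the plus-strand text: "plus" when
  # the primer as written matches the window, "minus" when its reverse
  # complement does (the usual situation for a reverse primer)
  best <- list(score = -Inf, start = NA_integer_, strand = NA_character_,
               n = 0L)
  starts <- 0:(W - L)
  for (strand in c("plus", "minus")) {
    pat <- if (strand == "plus") pm_plus else pm_minus
    for (s in starts) {
      sub <- M[(s + 1L):(s + L), , drop = FALSE]
      cov <- colSums(sub > 0L) == L
      if (!any(cov)) next
      ok <- .match_masks(pat, sub[, cov, drop = FALSE], mode)
      score <- mean(colSums(matrix(ok, nrow = L)) / L)
      if (score > best$score + 1e-12) {
        best <- list(score = score, start = s, strand = strand,
                     n = sum(cov))
      }
    }
  }
  if (!is.finite(best$score)) {
    stop("no gap-free window covers the primer anywhere in the alignment",
         call. = FALSE)
  }
  structure(list(primer_name = primer$name, start = best$start,
                 end = best$start + L, strand = best$strand,
                 score = best$score, n_scored = best$n),
            class = "site_spec")
}

#' @export
print.site_spec <- function(x, ...) {
  cat(sprintf(
    "<site_spec> %s: columns %d-%d (1-based inclusive), strand %s, score %.3f\n",
    x$primer_name, x$start + 1L, x$end, x$strand, x$score))
  invisible(x)
}

#' Extract per-record site strings at a located priming site
#'
#' Takes the alignment columns `[start, end)` of every record, removes
#' gaps, and reports the degapped string as the (plus-strand) site sequence
#' when it has exactly the primer's length and contains only IUPAC
#' characters. Anything else is not covered, with a reason code:
#' `terminal_gap` (window begins or ends with a gap), `internal_indel`,
#' `length_mismatch`, or `invalid_character`.
#'
#' @param refset an aligned `reference_set`.
#' @param site a `site_spec` from [locate_site()].
#' @param primer_length expected site length; defaults to `site$end -
#'   site$start`.
#' @return data.frame with `seq_id`, `covered`, `site_seq`, `reason`.
#' @export
extract_site <- function(refset, site, primer_length = NULL) {
  stopifnot(inherits(refset, "reference_set"), inherits(site, "site_spec"))
  if (is.null(refset$aligned)) {
    stop("extract_site() needs an aligned reference set", call. = FALSE)
  }
  if (site$start < 0L || site$end > refset$alignment_width) {
    stop("site outside alignment bounds", call. = FALSE)
  }
  L <- if (is.null(primer_length)) site$end - site$start else primer_length
  win <- substr(refset$aligned, site$start + 1L, site$end)
  degap <- gsub("-", "", win, fixed = TRUE)
  has_gap <- grepl("-", win, fixed = TRUE)
  first_last_gap <- substr(win, 1L, 1L) == "-" |
    substr(win, nchar(win), nchar(win)) == "-"
  valid <- !grepl(sprintf("[^%s]", paste(names(.IUPAC_MASK), collapse = "")),
                  degap)
  covered <- nchar(degap) == L & valid
  reason <- rep(NA_character_, length(win))
  reason[!covered & first_last_gap] <- "terminal_gap"
  reason[!covered & !first_last_gap & has_gap] <- "internal_indel"
  reason[!covered & !has_gap & nchar(degap) != L] <- "length_mismatch"
  reason[!covered & is.na(reason)] <- "invalid_character"
  data.frame(seq_id = names(refset$aligned), covered = covered,
             site_seq = ifelse(covered, degap, NA_character_),
             reason = reason, row.names = NULL, stringsAsFactors = FALSE)
}
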