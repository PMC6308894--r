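# Binding-site scanning on unaligned sequences and amplicon prediction
# for a primer pair. Zoned mismatch counting is the same shared
# implementation used by the coverage evaluation.

# windows of length L starting at every offset, as an L x (n-L+1) mask
# matrix
.window_masks <- function(seq_masks, L) {
  n <- length(seq_masks)
  matrix(seq_masks[outer(seq_len(L), 0:(n - L), `+`)], nrow = L)
}

#' Find primer binding sites in an unaligned sequence
#'
#' Exhaustively scans both strands. A plus-strand site is a window matched
#' by the primer as written; a minus-strand site is a window matched by
#' its reverse complement. Zoned mismatches (`m3` within the primer's
#' 3'-terminal zone, `m5` in the remainder) are counted exactly as in
#' [mismatch_profile()]; sites meeting `m3 <= max_m3 & m5 <= max_m5` are
#' returned sorted by offset.
#'
#' @param primer a [degenerate_primer()].
#' @param sequence template string (plus strand), length >= primer length.
#' @param max_m3,max_m5 mismatch criterion (defaults 0 and 3).
#' @param mode match semantics.
#' @param zone3 width of the 3' zone.
#' @return data.frame `offset` (0-based plus-strand start), `strand`,
#'   `m3`, `m5`.
#' @export
find_binding_sites <- function(primer, sequence, max_m3 = 0L, max_m5 = 3L,
                               mode = c("intersection", "subset"),
                               zone3 = 4L) {
  mode <- match.arg(mode)
  stopifnot(inherits(primer, "degenerate_primer"))
  sm <- iupac_masks(sequence, what = "template")
  L <- primer$length
  if (length(sm) < L) {
    stop("template shorter than the primer", call. = FALSE)
  }
  pm <- iupac_masks(primer$sequence)
  win <- .window_masks(sm, L)
  hits <- list()
  for (strand in c("plus", "minus")) {
    if (strand == "plus") {
      pat <- pm
      zone_idx <- (L - zone3 + 1L):L        # primer 3' end at window end
    } else {
      pat <- rev(.MASK_COMPLEMENT[pm])
      zone_idx <- seq_len(zone3)            # primer 3' end at window start
    }
    mism <- matrix(!.match_masks(pat, win, mode), nrow = L)
    m3 <- colSums(mism[zone_idx, , drop = FALSE])
    m5 <- colSums(mism[-zone_idx, , drop = FALSE])
    ok <- m3 <= max_m3 & m5 <= max_m5
    if (any(ok)) {
      hits[[strand]] <- data.frame(
        offset = which(ok) - 1L, strand = strand,
        m3 = as.integer(m3[ok]), m5 = as.integer(m5[ok]),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(hits) == 0L) {
    data.frame(offset = integer(0), strand = character(0),
               m3 = integer(0), m5 = integer(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, c(unname(hits), make.row.names = FALSE))
  }
  res[order(res$offset, res$strand), , drop = FALSE]
}

#' Predict amplicons for a primer pair on one template
#'
#' Pairs every plus-strand forward-primer site with every downstream
#' minus-strand reverse-primer site (and the strand-swapped
#' configuration), emitting amplicons whose length — measured inclusive
#' of both primer footprints — lies within `[min_len, max_len]`.
#' Footprints must not overlap.
#'
#' @param fwd forward [degenerate_primer()].
#' @param rev reverse [degenerate_primer()].
#' @param sequence template string (plus strand).
#' @param max_m3,max_m5 binding criterion per primer (defaults 0 and 3).
#' @param min_len,max_len length window (defaults 50 and 2000).
#' @param mode match semantics.
#' @param zone3 width of the 3' zone.
#' @return data.frame `start`, `end` (0-based half-open, plus strand,
#'   footprints included), `length`, `fwd_offset`, `fwd_strand`,
#'   `rev_offset`, `rev_strand`, sorted by `start` then `length`.
#' @export
predict_amplicons <- function(fwd, rev, sequence, max_m3 = 0L, max_m5 = 3L,
                              min_len = 50L, max_len = 2000L,
                              mode = c("intersection", "subset"),
                              zone3 = 4L) {
  mode <- match.arg(mode)
  if (min_len > max_len) stop("min_len > max_len", call. = FALSE)
  stopifnot(fwd$orientation == "forward", rev$orientation == "reverse")
  sf <- find_binding_sites(fwd, sequence, max_m3, max_m5, mode, zone3)
  sr <- find_binding_sites(rev, sequence, max_m3, max_m5, mode, zone3)
  pair_up <- function(up, up_len, up_strand, down, down_len, down_strand) {
    up <- up[up$strand == up_strand, , drop = FALSE]
    down <- down[down$strand == down_strand, , drop = FALSE]
    if (nrow(up) == 0L || nrow(down) == 0L) return(NULL)
    combos <- expand.grid(i = seq_len(nrow(up)), j = seq_len(nrow(down)))
    start <- up$offset[combos$i]
    end <- down$offset[combos$j] + down_len
    len <- end - start
    keep <- down$offset[combos$j] >= up$offset[combos$i] + up_len &
      len >= min_len & len <= max_len
    if (!any(keep)) return(NULL)
    data.frame(start = start[keep], end = end[keep], length = len[keep],
               fwd_offset = if (up_strand == "plus") up$offset[combos$i][keep]
                            else down$offset[combos$j][keep],
               fwd_strand = if (up_strand == "plus") "plus" else "minus",
               rev_offset = if (up_strand == "plus") down$offset[combos$j][keep]
                            else up$offset[combos$i][keep],
               rev_strand = if (up_strand == "plus") "minus" else "plus",
               stringsAsFactors = FALSE)
  }
  res <- rbind(
    # canonical: forward primer on plus strand, reverse primer downstream
    pair_up(sf, fwd$length, "plus", sr, rev$length, "minus"),
    # strand-swapped: the same physical amplicon read off the minus strand
    pair_up(sr, rev$length, "plus", sf, fwd$length, "minus"))
  if (is.null(res)) {
    res <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), fwd_offset = integer(0),
                      fwd_strand = character(0), rev_offset = integer(0),
                      rev_strand = character(0), stringsAsFactors = FALSE)
  }
  res <- res[order(res$start, res$length), , drop = FALSE]
  row.names(res) <- NULL
  res
}

#' Predict amplicons across a reference set
#'
#' @param fwd,rev the primer pair.
#' @param refset a `reference_set` (ungapped sequences are scanned).
#' @param ... passed to [predict_amplicons()].
#' @return data.frame with a `seq_id` column prepended.
#' @export
predict_amplicons_refset <- function(fwd, rev, refset, ...) {
  out <- lapply(seq_len(nrow(refset$records)), function(i) {
    amp <- predict_amplicons(fwd, rev, refset$records$sequence[i], ...)
    if (nrow(amp) == 0L) return(NULL)
    cbind(seq_id = refset$records$seq_id[i], amp, stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      fwd_offset = integer(0), fwd_strand = character(0),
                      rev_offset = integer(0), rev_strand = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Write predicted amplicons as BED and FASTA
#'
#' BED is 0-based half-open; the FASTA holds the extracted amplicon
#' sequences (footprints included).
#'
#' @param amplicons data.frame from [predict_amplicons_refset()].
#' @param refset the `reference_set` the amplicons were predicted on.
#' @param bed,fasta output paths (either may be `NULL` to skip).
#' @export
write_amplicons <- function(amplicons, refset, bed = NULL, fasta = NULL) {
  if (!is.null(bed)) {
    bed_df <- data.frame(chrom = amplicons$seq_id, start = amplicons$start,
                         end = amplicons$end,
                         name = sprintf("amplicon_%d",
                                        seq_len(nrow(amplicons))),
                         score = amplicons$length,
                         strand = ifelse(amplicons$fwd_strand == "plus",
                                         "+", "-"))
    utils::write.table(bed_df, bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(fasta)) {
    seqs <- refset$records$sequence[match(amplicons$seq_id,
                                          refset$records$seq_id)]
    amp_seq <- substr(seqs, amplicons$start + 1L, amplicons$end)
    names(amp_seq) <- sprintf("%s:%d-%d", amplicons$seq_id,
                              amplicons$start, amplicons$end)
    Biostrings::writeXStringSet(Biostrings::BStringSet(amp_seq), fasta)
  }
  invisible(amplicons)
}
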