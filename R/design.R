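# Consensus-based degenerate primer design: per-column base frequencies of
# a priming-site alignment, threshold-based degenerate consensus with a
# degeneracy cap, coverage-gain quantification, and the universal-tail
# poor-fit check.

#' Per-column base-frequency profiles of a priming site
#'
#' Computes, for each primer position, the relative frequency of A/C/G/T
#' among covering sequences, on plus-strand site strings (to design a
#' reverse primer, reverse-complement the proposed plus-strand consensus).
#' Ambiguous template characters and gaps are excluded from the
#' frequencies but counted in `n_excluded`.
#'
#' @param refset an aligned `reference_set`.
#' @param site a `site_spec`; its width defines the number of columns.
#' @param site_strings optionally, precomputed covered site strings
#'   (bypasses `refset`/`site`).
#' @return data.frame with `position` (1-based within the site), `A`, `C`,
#'   `G`, `T` (frequencies summing to 1), `n`, `n_excluded`.
#' @export
column_profiles <- function(refset = NULL, site = NULL, site_strings = NULL) {
  if (is.null(site_strings)) {
    ext <- extract_site(refset, site)
    site_strings <- ext$site_seq[ext$covered]
  }
  if (length(site_strings) == 0L) {
    stop("no covering sequences at the site", call. = FALSE)
  }
  L <- nchar(site_strings[[1]])
  M <- .site_matrix(site_strings, L, what = "site string")
  rows <- lapply(seq_len(L), function(j) {
    masks <- M[j, ]
    plain <- masks %in% c(1L, 2L, 4L, 8L)
    counts <- vapply(c(1L, 2L, 4L, 8L),
                     function(b) sum(masks[plain] == b), numeric(1))
    n <- sum(plain)
    if (n == 0L) {
      freq <- rep(NA_real_, 4)
    } else {
      freq <- counts / n
    }
    data.frame(position = j, A = freq[1], C = freq[2], G = freq[3],
               T = freq[4], n = n, n_excluded = sum(!plain))
  })
  do.call(rbind, rows)
}

.column_entropy <- function(freq) {
  f <- freq[freq > 0]
  -sum(f * log(f))
}

#' Propose a degenerate consensus primer from column profiles
#'
#' Per column, every base with relative frequency at least `f_min` is
#' included, and the smallest IUPAC symbol containing exactly that base
#' set is emitted. If the resulting total degeneracy exceeds
#' `max_degeneracy`, the threshold is raised greedily on the
#' lowest-information columns first: among multi-base columns, the one
#' with the smallest base-frequency entropy (ties broken by 5'-most
#' position) loses its lowest-frequency included base, until the cap
#' holds. The pruning order is recorded in `attr(primer, "cap_log")`.
#'
#' @param profiles data.frame from [column_profiles()].
#' @param f_min inclusion threshold in (0, 1) (default 0.05).
#' @param max_degeneracy degeneracy cap (default 1024).
#' @param name,orientation passed to [degenerate_primer()].
#' @return a [degenerate_primer()] (plus-strand consensus).
#' @export
propose_degenerate_primer <- function(profiles, f_min = 0.05,
                                      max_degeneracy = 1024,
                                      name = "proposed",
                                      orientation = "forward") {
  stopifnot(f_min > 0, f_min < 1, max_degeneracy >= 1)
  freq <- as.matrix(profiles[, c("A", "C", "G", "T")])
  include <- !is.na(freq) & freq >= f_min
  bad <- which(rowSums(include) == 0L)
  if (length(bad) > 0L) {
    stop(sprintf("no base reaches f_min=%.3g at column %d", f_min, bad[1]),
         call. = FALSE)
  }
  entropy <- apply(freq, 1L, function(f) .column_entropy(f[!is.na(f)]))
  cap_log <- list()
  repeat {
    deg <- prod(rowSums(include))
    if (deg <= max_degeneracy) break
    multi <- which(rowSums(include) > 1L)
    # lowest-information column first; ties to the 5'-most position
    j <- multi[order(entropy[multi], multi)][1]
    f_j <- freq[j, ]
    inc <- which(include[j, ])
    drop_base <- inc[order(f_j[inc], .BASES[inc])][1]
    include[j, drop_base] <- FALSE
    cap_log[[length(cap_log) + 1L]] <- list(
      position = unname(j), dropped = .BASES[drop_base],
      freq = unname(f_j[drop_base]))
  }
  masks <- as.integer(include %*% c(1L, 2L, 4L, 8L))
  primer <- degenerate_primer(name, .masks_to_string(masks),
                              orientation = orientation)
  attr(primer, "cap_log") <- cap_log
  attr(primer, "f_min") <- f_min
  primer
}

#' Coverage gain of a redesigned primer over an existing one
#'
#' Evaluates both primers on the same covered site strings at one
#' mismatch criterion and reports per-group coverage for each plus the
#' difference, together with a per-position table of how many sequences
#' mismatch the old primer but match the new one at that position (the
#' columns that account for the gain).
#'
#' @param primer_old,primer_new two [degenerate_primer()]s of equal length
#'   and orientation.
#' @param refset an aligned `reference_set`.
#' @param site optional `site_spec` (default: located with `primer_old`).
#' @param max_m3,max_m5 the mismatch criterion (defaults 0 and 3).
#' @param mode match semantics.
#' @param zone3 width of the 3' zone.
#' @return list with `by_group` (data.frame `group`, `n_covering`,
#'   `coverage_old`, `coverage_new`, `gain`) and `by_position`
#'   (data.frame `position`, `n_old_mismatch`, `n_new_mismatch`,
#'   `n_rescued`).
#' @export
coverage_gain <- function(primer_old, primer_new, refset, site = NULL,
                          max_m3 = 0L, max_m5 = 3L,
                          mode = c("intersection", "subset"), zone3 = 4L) {
  mode <- match.arg(mode)
  stopifnot(inherits(primer_old, "degenerate_primer"),
            inherits(primer_new, "degenerate_primer"))
  if (primer_old$length != primer_new$length) {
    stop("primers differ in length", call. = FALSE)
  }
  if (primer_old$orientation != primer_new$orientation) {
    stop("primers differ in orientation", call. = FALSE)
  }
  site <- site %||% locate_site(refset, primer_old, mode = mode)
  ext <- extract_site(refset, site, primer_length = primer_old$length)
  cov <- ext[ext$covered, , drop = FALSE]
  if (nrow(cov) == 0L) stop("no covering sequences at the site", call. = FALSE)
  M <- .site_matrix(cov$site_seq, primer_old$length)
  prof_old <- .profile_masks(primer_old, M, mode, zone3)
  prof_new <- .profile_masks(primer_new, M, mode, zone3)
  ok_old <- prof_old$m3 <= max_m3 & prof_old$m5 <= max_m5
  ok_new <- prof_new$m3 <= max_m3 & prof_new$m5 <= max_m5
  cls <- refset$records$class[match(cov$seq_id, refset$records$seq_id)]
  cls[is.na(cls) | !nzchar(cls)] <- "(unclassified)"
  by_group <- do.call(rbind, lapply(
    c(sort(unique(cls)), "OVERALL"), function(g) {
      idx <- if (g == "OVERALL") rep(TRUE, length(cls)) else cls == g
      data.frame(group = g, n_covering = sum(idx),
                 coverage_old = mean(ok_old[idx]),
                 coverage_new = mean(ok_new[idx]),
                 gain = mean(ok_new[idx]) - mean(ok_old[idx]),
                 stringsAsFactors = FALSE)
    }))
  # per-position mismatch incidence, in primer coordinates (5'->3')
  pos_mism <- function(primer) {
    pm <- iupac_masks(primer$sequence)
    if (primer$orientation == "reverse") {
      pm <- rev(.MASK_COMPLEMENT[pm])
      template_mism <- matrix(!.match_masks(pm, M, mode), nrow = primer$length)
      template_mism[rev(seq_len(primer$length)), , drop = FALSE]
    } else {
      matrix(!.match_masks(pm, M, mode), nrow = primer$length)
    }
  }
  mo <- pos_mism(primer_old)
  mn <- pos_mism(primer_new)
  by_position <- data.frame(
    position = seq_len(primer_old$length),
    n_old_mismatch = rowSums(mo),
    n_new_mismatch = rowSums(mn),
    n_rescued = rowSums(mo & !mn))
  list(by_group = by_group, by_position = by_position,
       criterion = c(max_m3 = max_m3, max_m5 = max_m5), mode = mode)
}

#' Check that a universal tail fits poorly everywhere
#'
#' Slides the tail over every record (both strands, every offset) and
#' reports the maximum identity fraction found and the record carrying
#' it. The check fails when any match exceeds `threshold`: a tail that
#' anneals to template during the high-stringency first cycles would
#' defeat its purpose as a template-independent priming site.
#'
#' @param tail tail sequence (plain or IUPAC), length >= 8.
#' @param refset a `reference_set` (ungapped sequences are scanned).
#' @param threshold maximum tolerated identity fraction (default 0.85).
#' @param mode match semantics.
#' @return list of class `tail_check`: `status` (`"PASS"`/`"FAIL"`),
#'   `max_identity`, `seq_id`, `offset` (0-based), `strand`, `threshold`.
#' @export
check_tail <- function(tail, refset, threshold = 0.85,
                       mode = c("intersection", "subset")) {
  mode <- match.arg(mode)
  tail <- toupper(tail)
  tm <- iupac_masks(tail, what = "tail")
  L <- length(tm)
  if (L < 8L) stop("tail shorter than 8 nt", call. = FALSE)
  seqs <- refset$records$sequence
  if (length(seqs) == 0L) {
    warning("empty reference set: tail check passes vacuously")
    return(structure(list(status = "PASS", max_identity = 0,
                          seq_id = NA_character_, offset = NA_integer_,
                          strand = NA_character_, threshold = threshold),
                     class = "tail_check"))
  }
  tm_rc <- rev(.MASK_COMPLEMENT[tm])
  best <- list(identity = -1, seq_id = NA_character_, offset = NA_integer_,
               strand = NA_character_)
  for (i in seq_along(seqs)) {
    sm <- iupac_masks(seqs[[i]], what = refset$records$seq_id[i])
    n <- length(sm)
    if (n < L) next
    for (strand in c("plus", "minus")) {
      pat <- if (strand == "plus") tm else tm_rc
      # windowed identity via embed: rows are windows
      win <- matrix(sm[outer(1:L, 0:(n - L), `+`)], nrow = L)
      idents <- colSums(matrix(.match_masks(pat, win, mode), nrow = L)) / L
      j <- which.max(idents)
      if (idents[j] > best$identity) {
        best <- list(identity = idents[j],
                     seq_id = refset$records$seq_id[i],
                     offset = j - 1L, strand = strand)
      }
    }
  }
  structure(list(status = if (best$identity > threshold) "FAIL" else "PASS",
                 max_identity = best$identity, seq_id = best$seq_id,
                 offset = best$offset, strand = best$strand,
                 threshold = threshold),
            class = "tail_check")
}

#' @export
print.tail_check <- function(x, ...) {
  cat(sprintf(
    "<tail_check> %s: max identity %.3f (threshold %.2f) at %s offset %s (%s)\n",
    x$status, x$max_identity, x$threshold, x$seq_id %||% "NA",
    x$offset %||% "NA", x$strand %||% "NA"))
  invisible(x)
}
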