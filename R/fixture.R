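# Synthetic reference-set generator: indel-free COI-like alignments with
# primer sites planted at known offsets and controlled per-class mismatch
# injections, plus a machine-readable truth table. Stands in for a real
# species-dereplicated reference download so every evaluation path is
# testable offline; see the vignette for which features of real data it
# does and does not emulate.

#' Specify a synthetic reference fixture
#'
#' @param primers primer panel (list of [degenerate_primer()] or
#'   data.frame) whose sites are planted.
#' @param site_offsets named integer vector of 0-based alignment columns,
#'   one per primer; footprints must fit and must not overlap.
#' @param n_classes number of taxonomic classes (default 3).
#' @param n_per_class species per class (default 20).
#' @param seq_length alignment width (default 250).
#' @param rules data.frame of planted mismatch rules with columns
#'   `class` (e.g. `"classA"`), `primer`, `zone` (`"3prime"` or
#'   `"remainder"`), `fraction` (of that class's sequences affected, in
#'   \[0,1\]), `count` (substitutions per affected sequence). May be
#'   `NULL`.
#' @param seed mandatory RNG seed.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(primers, site_offsets, n_classes = 3L,
                         n_per_class = 20L, seq_length = 250L,
                         rules = NULL, seed) {
  stopifnot(!missing(seed), n_classes >= 1L, n_classes <= 26L,
            n_per_class >= 1L, seq_length >= 1L)
  primers <- .as_panel(primers)
  stopifnot(all(names(primers) %in% names(site_offsets)))
  site_offsets <- site_offsets[names(primers)]
  lens <- vapply(primers, `[[`, integer(1), "length")
  if (any(site_offsets < 0L) || any(site_offsets + lens > seq_length)) {
    stop("a primer footprint does not fit within seq_length", call. = FALSE)
  }
  iv <- cbind(start = site_offsets, end = site_offsets + lens)
  iv <- iv[order(iv[, 1L]), , drop = FALSE]
  if (nrow(iv) > 1L && any(iv[-1L, 1L] < iv[-nrow(iv), 2L])) {
    stop("planted primer sites overlap", call. = FALSE)
  }
  if (!is.null(rules)) {
    stopifnot(all(c("class", "primer", "zone", "fraction", "count") %in%
                    names(rules)),
              all(rules$zone %in% c("3prime", "remainder")),
              all(rules$fraction >= 0), all(rules$fraction <= 1),
              all(rules$count >= 1),
              all(rules$primer %in% names(primers)))
  }
  structure(list(primers = primers, site_offsets = site_offsets,
                 n_classes = n_classes, n_per_class = n_per_class,
                 seq_length = seq_length, rules = rules, seed = seed),
            class = "fixture_spec")
}

# positions within a primer (1-based, 5'->3') eligible for a forced
# mismatch in the given zone: N/I columns can never mismatch
.mismatchable_positions <- function(primer, zone, zone3 = 4L) {
  masks <- iupac_masks(primer$sequence)
  L <- primer$length
  idx <- if (zone == "3prime") (L - zone3 + 1L):L else seq_len(L - zone3)
  idx[masks[idx] != 15L]
}

#' Generate a synthetic reference fixture
#'
#' Emits an indel-free alignment in which every panel primer's site is
#' planted at its specified offset (each sequence carries a random plain
#' realization of the primer; reverse primers are planted as the reverse
#' complement of a realization). For each rule, exactly
#' `round(fraction * n_per_class)` sequences of the class receive `count`
#' substitutions in the stated primer zone, at positions where the primer
#' symbol is not fully degenerate, substituted to a base outside the
#' primer's set (a guaranteed mismatch). The truth table records the
#' planted `(seq_id, primer, m3, m5)` for every sequence.
#'
#' Identical specs (including the seed) produce byte-identical outputs.
#'
#' @param spec a [fixture_spec()].
#' @param dir if non-`NULL`, write `alignment.fasta`, `taxonomy.tsv` and
#'   `truth.tsv` there.
#' @return list with `refset` (a `reference_set` with taxonomy joined),
#'   `taxonomy` (data.frame), `truth` (data.frame `seq_id`, `primer`,
#'   `m3`, `m5`), `sites` (named list of `site_spec`), and `paths` (if
#'   written).
#' @export
generate_fixture <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  n_total <- spec$n_classes * spec$n_per_class
  classes <- rep(paste0("class", LETTERS[seq_len(spec$n_classes)]),
                 each = spec$n_per_class)
  seq_id <- sprintf("SYN%04d", seq_len(n_total))
  taxonomy <- data.frame(
    seq_id = seq_id,
    species = sprintf("Genus%s species%02d",
                      rep(LETTERS[seq_len(spec$n_classes)],
                          each = spec$n_per_class),
                      rep(seq_len(spec$n_per_class), spec$n_classes)),
    order = sprintf("order%s%d", rep(LETTERS[seq_len(spec$n_classes)],
                                     each = spec$n_per_class),
                    1L + (seq_len(n_total) - 1L) %% 2L),
    class = classes, stringsAsFactors = FALSE)

  primers <- spec$primers
  result <- .with_seed(spec$seed, {
    # background alignment
    mat <- matrix(sample(.BASES, n_total * spec$seq_length, replace = TRUE),
                  nrow = n_total)
    truth <- expand.grid(seq_id = seq_id, primer = names(primers),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    truth$m3 <- 0L
    truth$m5 <- 0L

    for (pn in names(primers)) {
      p <- primers[[pn]]
      off <- spec$site_offsets[[pn]]
      # per-sequence site string in primer orientation: a realization,
      # with rule substitutions applied to selected sequences
      site_chars <- t(vapply(seq_len(n_total), function(i) {
        vapply(iupac_masks(p$sequence), function(m) {
          sample(.BASES[bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L], 1L)
        }, character(1))
      }, character(p$length)))
      rules <- spec$rules
      if (!is.null(rules)) rules <- rules[rules$primer == pn, , drop = FALSE]
      if (!is.null(rules) && nrow(rules) > 0L) {
        for (r in seq_len(nrow(rules))) {
          rule <- rules[r, ]
          in_class <- which(classes == rule$class)
          n_hit <- round(rule$fraction * length(in_class))
          if (n_hit == 0L) next
          hit <- sort(sample(in_class, n_hit))
          pool <- .mismatchable_positions(p, rule$zone)
          if (length(pool) < rule$count) {
            stop(sprintf(
              "rule for %s/%s: only %d mismatchable positions in zone %s",
              rule$class, pn, length(pool), rule$zone), call. = FALSE)
          }
          for (i in hit) {
            pos <- if (length(pool) == 1L) pool else
              sort(sample(pool, rule$count))
            for (k in pos) {
              allowed <- nt_set(substr(p$sequence, k, k))
              site_chars[i, k] <- sample(setdiff(.BASES, allowed), 1L)
            }
            row <- truth$seq_id == seq_id[i] & truth$primer == pn
            if (rule$zone == "3prime") {
              truth$m3[row] <- truth$m3[row] + rule$count
            } else {
              truth$m5[row] <- truth$m5[row] + rule$count
            }
          }
        }
      }
      # plant on the plus strand: forward primers as written, reverse
      # primers as the reverse complement of the realization
      for (i in seq_len(n_total)) {
        s <- paste(site_chars[i, ], collapse = "")
        if (p$orientation == "reverse") s <- revcomp(s)
        mat[i, (off + 1L):(off + p$length)] <-
          strsplit(s, "", fixed = TRUE)[[1]]
      }
    }
    list(mat = mat, truth = truth)
  })

  aligned <- stats::setNames(apply(result$mat, 1L, paste, collapse = ""),
                             seq_id)
  refset <- reference_set(aligned, taxonomy)
  # the fixture alignment is indel-free, so "aligned" has no gaps; force
  # alignment bookkeeping so site operations work
  refset$aligned <- aligned
  refset$alignment_width <- spec$seq_length
  sites <- lapply(names(primers), function(pn) {
    p <- primers[[pn]]
    structure(list(primer_name = pn, start = spec$site_offsets[[pn]],
                   end = spec$site_offsets[[pn]] + p$length,
                   strand = if (p$orientation == "forward") "plus"
                            else "minus",
                   score = 1, n_scored = n_total),
              class = "site_spec")
  })
  names(sites) <- names(primers)

  out <- list(refset = refset, taxonomy = taxonomy, truth = result$truth,
              sites = sites, spec = spec)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(alignment = file.path(dir, "alignment.fasta"),
                  taxonomy = file.path(dir, "taxonomy.tsv"),
                  truth = file.path(dir, "truth.tsv"))
    writeLines(as.vector(rbind(paste0(">", seq_id), unname(aligned))),
               paths$alignment)
    utils::write.table(taxonomy, paths$taxonomy, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(result$truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$paths <- paths
  }
  out
}
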