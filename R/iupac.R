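# IUPAC nucleotide-set algebra. Base sets are encoded as 4-bit masks
# (A=1, C=2, G=4, T=8); every operation in the package that compares a
# degenerate primer symbol to a template symbol goes through this encoding.

.IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L,
  I = 15L  # inosine: universal base, pairs with A/C/G/T
)

# canonical symbol for each nonzero mask (I is never produced on output)
.MASK_SYMBOL <- c("A", "C", "M", "G", "R", "S", "V",
                  "T", "W", "Y", "H", "K", "D", "B", "N")

.MASK_POPCOUNT <- c(1L, 1L, 2L, 1L, 2L, 2L, 3L,
                    1L, 2L, 2L, 3L, 2L, 3L, 3L, 4L)

# Watson-Crick complement of a mask: swap the A/T and C/G bits
.MASK_COMPLEMENT <- vapply(1:15, function(m) {
  bitwOr(bitwOr(bitwShiftL(bitwAnd(m, 1L), 3L), bitwShiftR(bitwAnd(m, 8L), 3L)),
         bitwOr(bitwShiftL(bitwAnd(m, 2L), 1L), bitwShiftR(bitwAnd(m, 4L), 1L)))
}, integer(1))

.BASES <- c("A", "C", "G", "T")

#' Convert an IUPAC string to a vector of base-set bitmasks
#'
#' Case-insensitive; `U` is normalized to `T`. Internal workhorse behind all
#' matching operations.
#'
#' @param sequence a single IUPAC nucleotide string.
#' @param what label used in error messages (e.g. a primer name).
#' @return integer vector of 4-bit masks, one per position.
#' @keywords internal
iupac_masks <- function(sequence, what = "sequence") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  m <- unname(.IUPAC_MASK[chars])
  if (anyNA(m)) {
    bad <- which(is.na(m))[1]
    stop(sprintf("invalid nucleotide character '%s' at position %d of %s",
                 chars[bad], bad, what), call. = FALSE)
  }
  m
}

.masks_to_string <- function(masks) {
  paste(.MASK_SYMBOL[masks], collapse = "")
}

#' Base set of an IUPAC symbol
#'
#' Maps a single IUPAC ambiguity code (including inosine `I`, treated as a
#' universal base) to the set of plain nucleotides it stands for.
#'
#' @param symbol a single character in `A C G T U R Y S W K M B D H V N I`
#'   (either case).
#' @return character vector, a nonempty subset of `c("A","C","G","T")`.
#' @examples
#' nt_set("D")  # A G T
#' nt_set("I")  # A C G T
#' @export
nt_set <- function(symbol) {
  m <- iupac_masks(symbol, what = "symbol")
  if (length(m) != 1L) stop("'symbol' must be a single character", call. = FALSE)
  .BASES[bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L]
}

#' Degeneracy of an IUPAC sequence
#'
#' Product over positions of the number of plain bases each symbol stands
#' for; equals the number of distinct non-degenerate realizations.
#'
#' @param sequence IUPAC nucleotide string.
#' @return a positive number (double, to allow very large products).
#' @examples
#' iupac_degeneracy("ACGT")  # 1
#' iupac_degeneracy("GGDRCWGGWTGAACWGTWTAYCCNCC")  # 768
#' @export
iupac_degeneracy <- function(sequence) {
  prod(.MASK_POPCOUNT[iupac_masks(sequence)])
}

#' Expand an IUPAC sequence into all plain realizations
#'
#' @param sequence IUPAC nucleotide string.
#' @param cap refuse to expand beyond this many realizations (use
#'   [iupac_degeneracy()] for a count instead).
#' @return character vector of distinct A/C/G/T strings, length
#'   `iupac_degeneracy(sequence)`.
#' @examples
#' iupac_expand("RY")  # "AC" "AT" "GC" "GT"
#' @export
iupac_expand <- function(sequence, cap = 1e6) {
  masks <- iupac_masks(sequence)
  d <- prod(.MASK_POPCOUNT[masks])
  if (d > cap) {
    stop(sprintf(
      "degeneracy %.0f exceeds cap %.0f; use iupac_degeneracy() for counting",
      d, cap), call. = FALSE)
  }
  out <- ""
  for (m in masks) {
    out <- as.vector(outer(out, .BASES[bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L],
                           paste0))
  }
  out
}

#' Reverse complement of an IUPAC sequence
#'
#' Each symbol is replaced by the canonical symbol whose base set is the
#' Watson-Crick complement of the original set, and the order is reversed.
#' An involution at the base-set level; note that inosine `I` (base set
#' `{A,C,G,T}`) complements to `N`, so strings containing `I` come back with
#' `N` in its place after two applications.
#'
#' @param sequence IUPAC nucleotide string.
#' @return IUPAC string of the same length.
#' @examples
#' revcomp("ACGT")   # "ACGT"
#' revcomp("GGDRCW") # "WGYHCC"
#' @export
revcomp <- function(sequence) {
  masks <- iupac_masks(sequence)
  .masks_to_string(rev(.MASK_COMPLEMENT[masks]))
}

#' Primer-vs-template symbol match predicate
#'
#' Under `"intersection"` semantics two symbols match when their base sets
#' share at least one base (ambiguity on both sides is honored; a template
#' `N` matches any primer symbol). Under `"subset"` semantics the template
#' set must be contained in the primer set, so an ambiguous template only
#' matches a primer symbol guaranteed to pair with every base it could be.
#'
#' @param primer_symbol,template_symbol single IUPAC characters (vectorized;
#'   recycled to common length).
#' @param mode `"intersection"` (default) or `"subset"`.
#' @return logical vector.
#' @examples
#' symbols_match("W", "A")            # TRUE
#' symbols_match("R", "Y")            # FALSE
#' symbols_match("W", "N", "subset")  # FALSE
#' @export
symbols_match <- function(primer_symbol, template_symbol,
                          mode = c("intersection", "subset")) {
  mode <- match.arg(mode)
  pm <- unname(.IUPAC_MASK[toupper(primer_symbol)])
  tm <- unname(.IUPAC_MASK[toupper(template_symbol)])
  if (anyNA(pm)) stop("invalid primer symbol", call. = FALSE)
  if (anyNA(tm)) stop("invalid template symbol", call. = FALSE)
  .match_masks(pm, tm, mode)
}

# vectorized mask-level predicate shared by all scanning code
.match_masks <- function(primer_masks, template_masks, mode) {
  if (mode == "subset") {
    bitwAnd(template_masks, primer_masks) == template_masks
  } else {
    bitwAnd(template_masks, primer_masks) > 0L
  }
}
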