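# Degenerate primer objects and primer-panel I/O.

#' Construct a degenerate primer
#'
#' A named 5'-to-3' IUPAC sequence with an orientation and role. A lowercase
#' prefix in `sequence` is interpreted, following the usual panel-table
#' convention, as a universal-tail annotation: it is recorded in `$tail` and
#' the stored sequence is uppercased. Case never changes matching.
#'
#' @param name primer identifier.
#' @param sequence 5'-to-3' IUPAC string, length >= 5 (so that the 4-base
#'   3' zone plus at least one remainder base exist). A lowercase prefix is
#'   taken as the tail annotation.
#' @param orientation `"forward"` or `"reverse"`.
#' @param role one of `"locus"`, `"tail1"`, `"tail2"`, `"sequencing"`.
#' @return an object of class `degenerate_primer`: a list with fields
#'   `name`, `sequence` (uppercase), `orientation`, `role`, `tail`
#'   (uppercase prefix or `NULL`), `length`, `degeneracy`.
#' @examples
#' degenerate_primer("Sauron-S878", "GGDRCWGGWTGAACWGTWTAYCCNCC", "forward")
#' @export
degenerate_primer <- function(name, sequence,
                              orientation = c("forward", "reverse"),
                              role = c("locus", "tail1", "tail2", "sequencing")) {
  orientation <- match.arg(orientation)
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  lower <- chars %in% letters
  tail <- NULL
  if (any(lower)) {
    # tail = maximal lowercase prefix; must be a strict prefix
    n_tail <- which(!lower)[1] - 1L
    if (is.na(n_tail)) n_tail <- length(chars)
    if (n_tail == length(chars)) {
      stop("lowercase tail must be a strict prefix of the primer", call. = FALSE)
    }
    if (any(lower[(n_tail + 1L):length(chars)])) {
      stop("lowercase characters are only allowed as a 5' tail prefix",
           call. = FALSE)
    }
    tail <- toupper(substr(sequence, 1L, n_tail))
  }
  sequence <- toupper(sequence)
  masks <- iupac_masks(sequence, what = sprintf("primer '%s'", name))
  if (length(masks) < 5L) {
    stop(sprintf("primer '%s' is shorter than 5 nt", name), call. = FALSE)
  }
  structure(
    list(name = name, sequence = sequence, orientation = orientation,
         role = role, tail = tail, length = length(masks),
         degeneracy = prod(.MASK_POPCOUNT[masks])),
    class = "degenerate_primer")
}

#' @export
print.degenerate_primer <- function(x, ...) {
  cat(sprintf("<degenerate_primer> %s (%s, %s)\n  5'-%s-3'  L=%d  degeneracy=%.0f%s\n",
              x$name, x$orientation, x$role, x$sequence, x$length,
              x$degeneracy,
              if (!is.null(x$tail)) sprintf("  tail=%s", x$tail) else ""))
  invisible(x)
}

#' Read a primer panel
#'
#' Tab-separated panels need columns `name`, `sequence`, `orientation`
#' (`forward`/`reverse`) and optionally `role`. FASTA input is also
#' accepted: the orientation is then given as the second whitespace-
#' separated token of each header (`>name forward`), defaulting to
#' `forward`.
#'
#' @param path TSV or FASTA file.
#' @param format `"auto"` (by extension), `"tsv"`, or `"fasta"`.
#' @return named list of [degenerate_primer()] objects.
#' @export
read_primer_panel <- function(path, format = c("auto", "tsv", "fasta")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE))
      "fasta" else "tsv"
  }
  if (format == "fasta") {
    x <- Biostrings::readBStringSet(path)
    heads <- names(x)
    name <- sub("\\s.*$", "", heads)
    orient <- rep("forward", length(heads))
    tok2 <- sub("^\\S+\\s+(\\S+).*$", "\\1", heads)
    orient[tok2 %in% c("reverse", "rev", "R")] <- "reverse"
    tab <- data.frame(name = name, sequence = as.character(x),
                      orientation = orient, role = "locus",
                      stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             comment.char = "#")
    need <- c("name", "sequence", "orientation")
    if (!all(need %in% names(tab))) {
      stop("primer panel TSV must have columns name, sequence, orientation",
           call. = FALSE)
    }
    if (is.null(tab$role)) tab$role <- "locus"
  }
  if (anyDuplicated(tab$name)) {
    stop("duplicate primer names in panel", call. = FALSE)
  }
  panel <- lapply(seq_len(nrow(tab)), function(i) {
    degenerate_primer(tab$name[i], tab$sequence[i],
                      orientation = tab$orientation[i], role = tab$role[i])
  })
  names(panel) <- tab$name
  panel
}

# coerce a panel-ish argument (single primer, list, data.frame) to a named
# list of degenerate_primer objects
.as_panel <- function(primers) {
  if (inherits(primers, "degenerate_primer")) {
    primers <- stats::setNames(list(primers), primers$name)
  } else if (is.data.frame(primers)) {
    primers <- stats::setNames(
      lapply(seq_len(nrow(primers)), function(i) {
        degenerate_primer(primers$name[i], primers$sequence[i],
                          orientation = primers$orientation[i],
                          role = if (is.null(primers$role)) "locus"
                                 else primers$role[i])
      }), primers$name)
  }
  stopifnot(is.list(primers), length(primers) > 0L,
            all(vapply(primers, inherits, logical(1), "degenerate_primer")))
  if (is.null(names(primers)) || any(!nzchar(names(primers)))) {
    names(primers) <- vapply(primers, `[[`, character(1), "name")
  }
  primers
}

#' Table-style view of a primer panel
#'
#' @param panel list of [degenerate_primer()] objects.
#' @return data.frame with one row per primer.
#' @export
panel_table <- function(panel) {
  panel <- .as_panel(panel)
  data.frame(
    name = vapply(panel, `[[`, character(1), "name"),
    sequence = vapply(panel, `[[`, character(1), "sequence"),
    orientation = vapply(panel, `[[`, character(1), "orientation"),
    role = vapply(panel, `[[`, character(1), "role"),
    length = vapply(panel, `[[`, integer(1), "length"),
    degeneracy = vapply(panel, `[[`, numeric(1), "degeneracy"),
    tail = vapply(panel, function(p) if (is.null(p$tail)) "" else p$tail,
                  character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
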