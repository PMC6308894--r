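# Shared fixtures and independent oracles used across the suite.

shipped_panel <- function() {
  read_primer_panel(system.file("extdata", "coi_primer_panel.tsv",
                                package = "primercov"))
}

locus_panel <- function() {
  panel <- shipped_panel()
  panel[vapply(panel, function(p) p$role == "locus", logical(1))]
}

SAURON <- "GGDRCWGGWTGAACWGTWTAYCCNCC"
MLCOIINTF <- "GGWACWGGWTGAACWGTWTAYCCYCC"
JGHCO <- "TAIACYTCIGGRTGICCRAARAAYCA"

random_plain <- function(n, L, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
}

# sites biased toward the primer: start from a random realization and
# mutate a few positions, so zoned counts exercise the 0..4 range
near_sites <- function(primer, n, seed) {
  set.seed(seed)
  exps <- iupac_expand(primer$sequence, cap = 4096)
  vapply(seq_len(n), function(i) {
    chars <- strsplit(sample(exps, 1), "", fixed = TRUE)[[1]]
    k <- sample(0:4, 1)
    if (k > 0) {
      pos <- sample(length(chars), k)
      chars[pos] <- vapply(chars[pos], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1)
      }, character(1))
    }
    s <- paste(chars, collapse = "")
    if (primer$orientation == "reverse") revcomp(s) else s
  }, character(1))
}

# Brute-force zoned-mismatch oracle: minimum, over all plain realizations
# of the degenerate primer, of the literal mismatch counts in the 3' zone
# (last 4 primer bases) and the remainder. Per-position mismatch columns
# are cached per base so many sites stay cheap; the comparison itself is
# plain character equality, fully independent of the package's mask
# algebra.
oracle_profiler <- function(primer, zone3 = 4L) {
  exps <- iupac_expand(primer$sequence, cap = 4096)
  E <- do.call(rbind, strsplit(exps, "", fixed = TRUE))
  L <- ncol(E)
  zone <- (L - zone3 + 1L):L
  cache <- lapply(seq_len(L), function(j) {
    m <- vapply(c("A", "C", "G", "T"), function(b) E[, j] != b,
                logical(nrow(E)))
    matrix(m, nrow = nrow(E), dimnames = list(NULL, c("A", "C", "G", "T")))
  })
  function(site_seq) {
    target <- if (primer$orientation == "reverse") revcomp(site_seq)
              else site_seq
    tc <- strsplit(target, "", fixed = TRUE)[[1]]
    m3 <- 0L
    m5 <- 0L
    m3v <- rep(0L, nrow(E))
    m5v <- rep(0L, nrow(E))
    for (j in seq_len(L)) {
      col <- cache[[j]][, tc[j]]
      if (j %in% zone) m3v <- m3v + col else m5v <- m5v + col
    }
    list(m3 = min(m3v), m5 = min(m5v))
  }
}

# small hand-built aligned refset: `plant` maps primer name -> 0-based
# offset; every row gets a fresh realization unless `site_strings` fixes
# them
plant_alignment <- function(primers, offsets, n = 10, width = 120,
                            seed = 1, classes = NULL) {
  spec <- fixture_spec(primers, offsets, n_classes = 1L, n_per_class = n,
                       seq_length = width, rules = NULL, seed = seed)
  fx <- generate_fixture(spec)
  if (!is.null(classes)) {
    fx$taxonomy$class <- classes
    fx$refset$records$class <- classes
  }
  fx
}

write_temp_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  path
}

write_temp_taxonomy <- function(tax, path = tempfile(fileext = ".tsv")) {
  write.table(tax, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
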