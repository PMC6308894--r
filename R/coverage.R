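# Zoned mismatch profiling and the nested mismatch-criteria coverage grid.
#
# A primer/site comparison is split into two zones: the four bases closest
# to the primer 3' end (where a mismatch tends to block extension) and the
# 5' remainder. Per-position set logic gives, for each zone, the number of
# positions where the template symbol fails the match predicate; for plain
# templates this equals the minimum zoned mismatch count over all plain
# realizations of the degenerate primer.

# zoned mismatch counts for many site strings at once.
# site strings are plus-strand; reverse primers are compared through their
# reverse complement, which maps the primer 3' zone onto the first zone3
# template positions.
.profile_masks <- function(primer, site_matrix, mode, zone3 = 4L) {
  L <- primer$length
  stopifnot(nrow(site_matrix) == L)
  pm <- iupac_masks(primer$sequence)
  if (primer$orientation == "reverse") {
    pm <- rev(.MASK_COMPLEMENT[pm])
    zone_idx <- seq_len(zone3)
  } else {
    zone_idx <- (L - zone3 + 1L):L
  }
  mism <- !.match_masks(pm, site_matrix, mode)
  mism <- matrix(mism, nrow = L)
  list(m3 = colSums(mism[zone_idx, , drop = FALSE]),
       m5 = colSums(mism[-zone_idx, , drop = FALSE]))
}

.site_matrix <- function(site_seqs, L, what = "site") {
  if (any(nchar(site_seqs) != L)) {
    stop(sprintf("%s length differs from primer length %d", what, L),
         call. = FALSE)
  }
  chars <- vapply(strsplit(toupper(site_seqs), "", fixed = TRUE), identity,
                  character(L))
  if (is.null(dim(chars))) chars <- matrix(chars, nrow = L)
  m <- matrix(unname(.IUPAC_MASK[chars]), nrow = L)
  if (anyNA(m)) stop(sprintf("invalid character in %s", what), call. = FALSE)
  m
}

#' Zoned mismatch profile of a primer against one site sequence
#'
#' Counts mismatching positions in the primer's 3'-terminal zone (`m3`,
#' last `zone3` bases of the primer as written 5' to 3') and in the
#' remainder (`m5`). The site is given in template plus-strand orientation;
#' reverse primers are compared against its reverse complement. A position
#' mismatches when [symbols_match()] is `FALSE` under `mode`.
#'
#' @param primer a [degenerate_primer()].
#' @param site_seq site string of exactly the primer's length, plus-strand.
#' @param mode match semantics (see [symbols_match()]).
#' @param zone3 width of the 3' zone (default 4).
#' @return list with integer `m3` (0..zone3) and `m5` (0..L-zone3).
#' @export
mismatch_profile <- function(primer, site_seq,
                             mode = c("intersection", "subset"),
                             zone3 = 4L) {
  mode <- match.arg(mode)
  stopifnot(inherits(primer, "degenerate_primer"))
  p <- .profile_masks(primer, .site_matrix(site_seq, primer$length), mode,
                      zone3)
  list(m3 = as.integer(p$m3), m5 = as.integer(p$m5))
}

#' Evaluate a primer panel against a reference alignment
#'
#' For each primer independently: locate its priming site (unless supplied
#' in `sites`), extract per-record site strings, and profile every covered
#' record. Per-primer denominators are independent, so primers whose sites
#' are covered by different subsets of records each get their own
#' denominator.
#'
#' @param refset an aligned `reference_set`.
#' @param primers a primer panel (list of [degenerate_primer()],
#'   data.frame, or single primer).
#' @param mode match semantics (see [symbols_match()]).
#' @param sites optional named list of `site_spec`s keyed by primer name;
#'   missing entries are located with [locate_site()].
#' @param zone3 width of the 3' zone.
#' @param ... passed to [locate_site()].
#' @return data.frame of profiles: `primer`, `seq_id`, `covered`, `reason`,
#'   `m3`, `m5`; attributes `sites` (list of `site_spec`), `mode`, `zone3`.
#' @export
evaluate_panel <- function(refset, primers,
                           mode = c("intersection", "subset"),
                           sites = NULL, zone3 = 4L, ...) {
  mode <- match.arg(mode)
  primers <- .as_panel(primers)
  out <- vector("list", length(primers))
  used_sites <- vector("list", length(primers))
  names(used_sites) <- names(primers)
  for (i in seq_along(primers)) {
    p <- primers[[i]]
    site <- sites[[p$name]] %||% locate_site(refset, p, mode = mode, ...)
    used_sites[[p$name]] <- site
    ext <- extract_site(refset, site, primer_length = p$length)
    m3 <- rep(NA_integer_, nrow(ext))
    m5 <- rep(NA_integer_, nrow(ext))
    if (any(ext$covered)) {
      prof <- .profile_masks(
        p, .site_matrix(ext$site_seq[ext$covered], p$length), mode, zone3)
      m3[ext$covered] <- as.integer(prof$m3)
      m5[ext$covered] <- as.integer(prof$m5)
    }
    out[[i]] <- data.frame(primer = p$name, seq_id = ext$seq_id,
                           covered = ext$covered, reason = ext$reason,
                           m3 = m3, m5 = m5,
                           row.names = NULL, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "sites") <- used_sites
  attr(res, "mode") <- mode
  attr(res, "zone3") <- zone3
  res
}

#' Nested mismatch-criteria coverage grid
#'
#' For every primer and every criterion cell (maximum 3'-zone mismatches
#' `max_m3` in 0..3 crossed with maximum remainder mismatches `max_m5` in
#' 0..4), the proportion of site-covering sequences with `m3 <= max_m3`
#' and `m5 <= max_m5`. With zero covering sequences the proportion is
#' `NA`, never 0.
#'
#' @param profiles profile data.frame from [evaluate_panel()].
#' @param max_m3,max_m5 criterion axes (defaults `0:3` and `0:4`).
#' @return data.frame (`primer`, `max_m3`, `max_m5`, `group`,
#'   `n_covering`, `n_matching`, `proportion`, `mode`), `group` fixed at
#'   `"OVERALL"`.
#' @export
criteria_grid <- function(profiles, max_m3 = 0:3, max_m5 = 0:4) {
  stopifnot(nrow(profiles) > 0L)
  mode <- attr(profiles, "mode") %||% NA_character_
  out <- lapply(split(profiles, profiles$primer), function(pp) {
    cov <- pp[pp$covered, , drop = FALSE]
    n_cov <- nrow(cov)
    grid <- expand.grid(max_m3 = max_m3, max_m5 = max_m5,
                        KEEP.OUT.ATTRS = FALSE)
    n_match <- vapply(seq_len(nrow(grid)), function(i) {
      sum(cov$m3 <= grid$max_m3[i] & cov$m5 <= grid$max_m5[i])
    }, integer(1))
    data.frame(primer = pp$primer[1], grid, group = "OVERALL",
               n_covering = n_cov, n_matching = n_match,
               proportion = if (n_cov == 0) NA_real_ else n_match / n_cov,
               mode = mode, row.names = NULL, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res[order(match(res$primer, unique(profiles$primer))), , drop = FALSE]
}

#' Coverage by taxonomic group at one mismatch criterion
#'
#' One row per taxonomic class present among the covering sequences, plus
#' an `OVERALL` row; the weighted mean of class proportions (weights
#' `n_covering`) equals the overall proportion by construction.
#'
#' @param profiles profile data.frame from [evaluate_panel()].
#' @param taxonomy data.frame with `seq_id` and `class` (e.g.
#'   `refset$records`).
#' @param max_m3,max_m5 the single criterion to evaluate (defaults 0 and
#'   3: perfect 3' zone, up to three remainder mismatches).
#' @return data.frame (`primer`, `max_m3`, `max_m5`, `group`,
#'   `n_covering`, `n_matching`, `proportion`, `mode`).
#' @export
coverage_by_group <- function(profiles, taxonomy, max_m3 = 0L, max_m5 = 3L) {
  stopifnot(all(c("seq_id", "class") %in% names(taxonomy)))
  mode <- attr(profiles, "mode") %||% NA_character_
  cls <- taxonomy$class[match(profiles$seq_id, taxonomy$seq_id)]
  cls[is.na(cls) | !nzchar(cls)] <- "(unclassified)"
  profiles$group <- cls
  out <- lapply(split(profiles, profiles$primer), function(pp) {
    cov <- pp[pp$covered, , drop = FALSE]
    groups <- sort(unique(cov$group))
    rows <- lapply(c(groups, "OVERALL"), function(g) {
      sub <- if (g == "OVERALL") cov else cov[cov$group == g, , drop = FALSE]
      n_cov <- nrow(sub)
      n_match <- sum(sub$m3 <= max_m3 & sub$m5 <= max_m5)
      data.frame(primer = pp$primer[1], max_m3 = max_m3, max_m5 = max_m5,
                 group = g, n_covering = n_cov, n_matching = n_match,
                 proportion = if (n_cov == 0) NA_real_ else n_match / n_cov,
                 mode = mode, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res[order(match(res$primer, unique(profiles$primer))), , drop = FALSE]
}

#' Compare per-primer amplification/match success
#'
#' Fits a binomial-logit model of success on primer identity, reporting
#' per-primer proportions, coefficient contrasts against a reference
#' primer with Wald p-values, and Holm-adjusted p-values across the
#' pairwise contrasts. Complete separation (a primer with all successes or
#' all failures) is detected and reported, and an exact Fisher test
#' against the reference primer is supplied as the fallback p-value for
#' every contrast.
#'
#' @param outcomes named list of logical (or 0/1) vectors, one per primer,
#'   or a data.frame with columns `primer` and `success`.
#' @param reference reference primer name (default: the first).
#' @return object of class `primer_comparison`: list with `proportions`,
#'   `contrasts` (data.frame: `primer`, `estimate`, `se`, `p`, `p_holm`,
#'   `p_fisher`), `reference`, `separation`.
#' @export
compare_primer_success <- function(outcomes, reference = NULL) {
  if (is.data.frame(outcomes)) {
    stopifnot(all(c("primer", "success") %in% names(outcomes)))
    outcomes <- split(as.logical(outcomes$success), outcomes$primer)
  }
  stopifnot(is.list(outcomes), length(outcomes) >= 2L,
            all(lengths(outcomes) >= 1L))
  outcomes <- lapply(outcomes, as.logical)
  reference <- reference %||% names(outcomes)[1]
  stopifnot(reference %in% names(outcomes))
  props <- vapply(outcomes, mean, numeric(1))
  dat <- data.frame(
    primer = factor(rep(names(outcomes), lengths(outcomes)),
                    levels = c(reference,
                               setdiff(names(outcomes), reference))),
    success = unlist(outcomes, use.names = FALSE))
  separation <- stats::setNames(props %in% c(0, 1), names(props))
  fit <- suppressWarnings(
    stats::glm(success ~ primer, family = stats::binomial(), data = dat))
  co <- summary(fit)$coefficients
  others <- setdiff(names(outcomes), reference)
  rowname <- paste0("primer", others)
  est <- co[rowname, "Estimate"]
  se <- co[rowname, "Std. Error"]
  p <- co[rowname, "Pr(>|z|)"]
  p_fisher <- vapply(others, function(nm) {
    tab <- rbind(c(sum(outcomes[[reference]]), sum(!outcomes[[reference]])),
                 c(sum(outcomes[[nm]]), sum(!outcomes[[nm]])))
    stats::fisher.test(tab)$p.value
  }, numeric(1))
  structure(
    list(proportions = props,
         contrasts = data.frame(primer = others, estimate = unname(est),
                                se = unname(se), p = unname(p),
                                p_holm = unname(stats::p.adjust(p, "holm")),
                                p_fisher = unname(p_fisher),
                                stringsAsFactors = FALSE),
         reference = reference,
         separation = separation),
    class = "primer_comparison")
}

#' @export
print.primer_comparison <- function(x, ...) {
  cat("<primer_comparison> reference:", x$reference, "\n")
  cat("proportions:\n")
  print(round(x$proportions, 4))
  if (any(x$separation)) {
    cat("complete separation in:",
        paste(names(x$separation)[x$separation], collapse = ", "),
        "- use p_fisher\n")
  }
  print(x$contrasts, digits = 4)
  invisible(x)
}

#' Write a coverage table as tidy CSV
#'
#' Undefined proportions (zero denominators) are written as empty fields,
#' never 0.
#'
#' @param coverage data.frame from [criteria_grid()] or
#'   [coverage_by_group()].
#' @param path output CSV path.
#' @export
write_coverage_csv <- function(coverage, path) {
  utils::write.csv(coverage, path, row.names = FALSE, na = "")
  invisible(path)
}
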