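test_that("column profiles count base frequencies and tally ambiguity", {
  strings <- c(rep("AAAA", 5), rep("AGAA", 5))
  prof <- column_profiles(site_strings = strings)
  expect_equal(prof$A[1], 1.0)
  expect_equal(prof$n[1], 10L)
  expect_equal(prof$A[2], 0.5)
  expect_equal(prof$G[2], 0.5)
  # template N excluded from frequencies but tallied
  prof2 <- column_profiles(site_strings = c(strings, "ANAA"))
  expect_equal(prof2$n[2], 10L)
  expect_equal(prof2$n_excluded[2], 1L)
  expect_equal(prof2$A[2] + prof2$G[2], 1.0)
  expect_error(column_profiles(site_strings = character(0)), "covering")
})

test_that("threshold consensus emits minimal IUPAC symbols per column", {
  mk <- function(freqs) {
    do.call(rbind, lapply(seq_along(freqs), function(i) {
      f <- freqs[[i]]
      data.frame(position = i, A = f[1], C = f[2], G = f[3], T = f[4],
                 n = 100L, n_excluded = 0L)
    }))
  }
  prof <- mk(list(c(0.99, 0, 0.01, 0),       # -> A
                  c(0.5, 0, 0.5, 0),         # -> R
                  c(0.3, 0.2, 0.3, 0.2),     # -> N
                  c(0, 1, 0, 0),             # -> C
                  c(0.6, 0, 0, 0.4)))        # -> W
  p <- propose_degenerate_primer(prof, f_min = 0.05)
  expect_equal(p$sequence, "ARNCW")
  expect_error(propose_degenerate_primer(mk(list(c(0.25, 0.25, 0.25, 0.25))),
                                         f_min = 0.3),
               "column 1")
})

test_that("a vanishing threshold reproduces full coverage of the site alignment", {
  panel <- list(fwd = degenerate_primer("fwd", MLCOIINTF, "forward"))
  fx <- plant_alignment(panel, c(fwd = 10L), n = 30, width = 60, seed = 51)
  ext <- extract_site(fx$refset, fx$sites$fwd)
  prof <- column_profiles(site_strings = ext$site_seq[ext$covered])
  designed <- propose_degenerate_primer(prof, f_min = 1e-9,
                                        max_degeneracy = Inf)
  dp <- evaluate_panel(fx$refset, list(designed = designed),
                       sites = list(designed = fx$sites$fwd))
  g <- criteria_grid(dp)
  expect_equal(g$proportion[g$max_m3 == 0 & g$max_m5 == 0], 1.0)
})

test_that("lowering the threshold is monotone in degeneracy and coverage", {
  # deterministic mixture of three realizations with 70/20/10 weights, so
  # column frequencies take known intermediate values
  exps <- iupac_expand(MLCOIINTF)
  strings <- c(rep(exps[1], 70), rep(exps[40], 20), rep(exps[101], 10))
  prof <- column_profiles(site_strings = strings)
  ladder <- c(0.6, 0.25, 0.15, 0.05, 1e-6)
  degs <- numeric(0)
  covs <- numeric(0)
  for (f in ladder) {
    d <- propose_degenerate_primer(prof, f_min = f, max_degeneracy = Inf)
    pr <- mismatch_profile(d, strings)
    degs <- c(degs, d$degeneracy)
    covs <- c(covs, mean(pr$m3 == 0 & pr$m5 == 0))
  }
  expect_true(all(diff(degs) >= 0))
  expect_true(all(diff(covs) >= -1e-12))
  expect_equal(covs[length(covs)], 1.0)  # vanishing threshold: full coverage
})

test_that("the degeneracy cap is enforced greedily and deterministically", {
  prof <- do.call(rbind, lapply(1:6, function(i) {
    data.frame(position = i, A = 0.4, C = 0.3, G = 0.2, T = 0.1,
               n = 100L, n_excluded = 0L)
  }))
  unc <- propose_degenerate_primer(prof, f_min = 0.05,
                                   max_degeneracy = Inf)
  expect_equal(unc$sequence, "NNNNNN")
  capped <- propose_degenerate_primer(prof, f_min = 0.05,
                                      max_degeneracy = 64)
  expect_lte(capped$degeneracy, 64)
  # identical entropies: pruning works from the 5' end, dropping the
  # rarest base first
  log <- attr(capped, "cap_log")
  expect_equal(log[[1]]$position, 1L)
  expect_equal(log[[1]]$dropped, "T")
  capped2 <- propose_degenerate_primer(prof, f_min = 0.05,
                                       max_degeneracy = 64)
  expect_equal(capped$sequence, capped2$sequence)
  # the default cap admits high-degeneracy designs
  sauron_prof <- column_profiles(
    site_strings = iupac_expand(SAURON)[seq(1, 768, by = 7)])
  redesign <- propose_degenerate_primer(sauron_prof, f_min = 0.01)
  expect_lte(redesign$degeneracy, 1024)
})

test_that("coverage gain localizes rescued positions and is zero on itself", {
  old <- degenerate_primer("mlCOIintF", MLCOIINTF, "forward")
  new <- degenerate_primer("Sauron-S878", SAURON, "forward")

  # a template with G at the position where the old primer has Y (3rd
  # base from its 3' end) mismatches the old primer but matches the new
  # primer's N there
  site <- iupac_expand(MLCOIINTF)[1]
  chars <- strsplit(site, "")[[1]]
  expect_equal(substr(MLCOIINTF, 24, 24), "Y")
  expect_equal(substr(SAURON, 24, 24), "N")
  chars[24] <- "G"
  site_g <- paste(chars, collapse = "")
  expect_equal(mismatch_profile(old, site_g)$m3, 1L)
  expect_equal(mismatch_profile(new, site_g)$m3, 0L)

  # fixture where 25% of one class carries a planted 3'-zone variant
  panel <- list(old = old)
  spec <- fixture_spec(panel, c(old = 15L), n_classes = 2L,
                       n_per_class = 20L, seq_length = 60L,
                       rules = data.frame(class = "classA", primer = "old",
                                          zone = "3prime", fraction = 0.25,
                                          count = 1L),
                       seed = 53)
  fx <- generate_fixture(spec)
  # rescue: widen the old primer to N at every 3'-zone position
  rescue <- degenerate_primer(
    "rescue", paste0(substr(MLCOIINTF, 1, 22), "NNNN"), "forward")
  gain <- coverage_gain(old, rescue, fx$refset, site = fx$sites$old)
  ga <- gain$by_group[gain$by_group$group == "classA", ]
  expect_equal(ga$gain, 0.25)
  expect_equal(gain$by_group$gain[gain$by_group$group == "classB"], 0)
  # rescued positions all sit in the 3' zone
  resc <- gain$by_position[gain$by_position$n_rescued > 0, ]
  expect_true(all(resc$position >= 23))

  # no-op redesign
  zero <- coverage_gain(old, old, fx$refset, site = fx$sites$old)
  expect_true(all(zero$by_group$gain == 0))
  expect_error(coverage_gain(old, degenerate_primer("x", "ACGTA", "forward"),
                             fx$refset), "length")
})

test_that("tail poor-fit check scans both strands at every offset", {
  tail <- "cacctgcttctaaat"
  # a planted copy of the tail must fail with identity 1
  panel <- list(fwd = degenerate_primer("fwd", MLCOIINTF, "forward"))
  fx <- plant_alignment(panel, c(fwd = 5L), n = 20, width = 120, seed = 1)
  planted <- fx$refset
  seq1 <- planted$records$sequence[1]
  planted$records$sequence[1] <- paste0(substr(seq1, 1, 50), toupper(tail),
                                        substr(seq1, 66, nchar(seq1)))
  chk_fail <- check_tail(tail, planted)
  expect_equal(chk_fail$status, "FAIL")
  expect_equal(chk_fail$max_identity, 1.0)
  expect_equal(chk_fail$offset, 50L)
  # a minus-strand copy is found too
  planted2 <- fx$refset
  planted2$records$sequence[2] <- paste0(
    substr(seq1, 1, 50), revcomp(toupper(tail)),
    substr(seq1, 66, nchar(seq1)))
  chk2 <- check_tail(tail, planted2)
  expect_equal(chk2$status, "FAIL")
  expect_equal(chk2$strand, "minus")
  # on a random reference the tail fits poorly (seeded fixture)
  chk_pass <- check_tail(tail, fx$refset)
  expect_equal(chk_pass$status, "PASS")
  expect_lte(chk_pass$max_identity, 0.85)
  # independent oracle for the maximum: exhaustive character-level scan
  best <- 0
  tl <- toupper(tail)
  for (s in fx$refset$records$sequence) {
    for (target in c(s, revcomp(s))) {
      for (o in 0:(nchar(target) - nchar(tl))) {
        w <- substr(target, o + 1, o + nchar(tl))
        id <- mean(strsplit(w, "")[[1]] == strsplit(tl, "")[[1]])
        best <- max(best, id)
      }
    }
  }
  expect_equal(chk_pass$max_identity, best)
  # empty reference set passes with a warning
  empty <- reference_set(stats::setNames(character(0), character(0)))
  expect_warning(chk3 <- check_tail(tail, empty), "empty")
  expect_equal(chk3$status, "PASS")
})
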