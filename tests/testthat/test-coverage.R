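test_that("zoned mismatch counting splits the 3' zone from the remainder", {
  p <- degenerate_primer("p", MLCOIINTF, "forward")
  site <- iupac_expand(MLCOIINTF)[1]
  expect_equal(mismatch_profile(p, site), list(m3 = 0L, m5 = 0L))

  # substitution at the primer's 3'-terminal position -> (1, 0)
  chars <- strsplit(site, "")[[1]]
  chars[length(chars)] <- setdiff(c("A", "C", "G", "T"),
                                  nt_set(substr(MLCOIINTF, 26, 26)))[1]
  expect_equal(mismatch_profile(p, paste(chars, collapse = "")),
               list(m3 = 1L, m5 = 0L))

  # substitution at the 5'-most position -> (0, 1)
  chars <- strsplit(site, "")[[1]]
  chars[1] <- setdiff(c("A", "C", "G", "T"), nt_set("G"))[1]
  expect_equal(mismatch_profile(p, paste(chars, collapse = "")),
               list(m3 = 0L, m5 = 1L))

  expect_error(mismatch_profile(p, "ACGT"), "length")
})

test_that("reverse primers are profiled against the reverse complement", {
  p <- degenerate_primer("rev", JGHCO, "reverse")
  oracle <- oracle_profiler(p)
  # site constructed as revcomp(realization) with one substitution placed
  # in the primer's 3' zone
  set.seed(21)
  realization <- sample(iupac_expand(JGHCO, cap = 4096), 1)
  chars <- strsplit(realization, "")[[1]]
  k <- 25  # inside last 4 primer bases; symbol C, unambiguous
  chars[k] <- setdiff(c("A", "C", "G", "T"), nt_set(substr(JGHCO, k, k)))[1]
  site <- revcomp(paste(chars, collapse = ""))
  got <- mismatch_profile(p, site)
  expect_equal(got, list(m3 = 1L, m5 = 0L))
  expect_equal(got, lapply(oracle(site), as.integer))
})

test_that("zoned profiles equal the brute-force minimum over realizations", {
  for (nm in c("Sauron-S878", "jgHCO2198", "ZBJ-ArtR2c", "mLepR1")) {
    p <- locus_panel()[[nm]]
    oracle <- oracle_profiler(p)
    sites <- c(random_plain(60, p$length, seed = 100 + p$length),
               near_sites(p, 60, seed = 200 + p$length))
    for (s in sites) {
      expect_equal(mismatch_profile(p, s), lapply(oracle(s), as.integer),
                   info = paste(nm, s))
    }
  }
})

test_that("total mismatch counts agree with Biostrings ambiguity matching", {
  # independent route: neditAt(fixed = FALSE) counts positions whose base
  # sets do not intersect (inosine-free primers only)
  for (nm in c("Sauron-S878", "mlCOIintF", "Uni-MinibarF1-d")) {
    p <- locus_panel()[[nm]]
    sites <- near_sites(p, 25, seed = 300 + nchar(nm))
    for (s in sites) {
      prof <- mismatch_profile(p, s)
      target <- if (p$orientation == "reverse") revcomp(s) else s
      ed <- Biostrings::neditAt(Biostrings::DNAString(p$sequence),
                                Biostrings::DNAString(target),
                                at = 1, fixed = FALSE)
      expect_equal(prof$m3 + prof$m5, ed, info = paste(nm, s))
    }
  }
})

test_that("panel evaluation profiles covered records with per-primer denominators", {
  panel <- list(fwd = degenerate_primer("fwd", SAURON, "forward"),
                rev = degenerate_primer("rev", JGHCO, "reverse"))
  spec <- fixture_spec(panel, c(fwd = 30L, rev = 120L), n_classes = 1L,
                       n_per_class = 10L, seq_length = 200L,
                       rules = data.frame(class = "classA", primer = "fwd",
                                          zone = "3prime", fraction = 0.1,
                                          count = 1L),
                       seed = 31)
  fx <- generate_fixture(spec)
  prof <- evaluate_panel(fx$refset, panel, sites = fx$sites)
  pf <- prof[prof$primer == "fwd" & prof$covered, ]
  expect_equal(sum(pf$m3 == 0 & pf$m5 == 0), 9L)
  expect_equal(sum(pf$m3 == 1 & pf$m5 == 0), 1L)
  # record not spanning a site is excluded from profiles
  fx$refset$aligned[1] <- paste0(paste(rep("-", 60), collapse = ""),
                                 substr(fx$refset$aligned[1], 61, 200))
  prof2 <- evaluate_panel(fx$refset, panel, sites = fx$sites)
  p1 <- prof2[prof2$seq_id == fx$taxonomy$seq_id[1], ]
  expect_false(p1$covered[p1$primer == "fwd"])
  expect_true(is.na(p1$m3[p1$primer == "fwd"]))
  # per-primer denominators are independent
  grid <- criteria_grid(prof2)
  expect_equal(unique(grid$n_covering[grid$primer == "fwd"]), 9L)
  expect_equal(unique(grid$n_covering[grid$primer == "rev"]), 10L)
})

test_that("the criteria grid has 20 monotone cells per primer", {
  panel <- list(fwd = degenerate_primer("fwd", SAURON, "forward"))
  spec <- fixture_spec(panel, c(fwd = 30L), n_classes = 2L,
                       n_per_class = 10L, seq_length = 100L,
                       rules = data.frame(
                         class = c("classA", "classB"),
                         primer = "fwd", zone = c("3prime", "remainder"),
                         fraction = c(0.5, 0.3), count = c(1L, 2L)),
                       seed = 32)
  fx <- generate_fixture(spec)
  prof <- evaluate_panel(fx$refset, panel, sites = fx$sites)
  grid <- criteria_grid(prof)
  expect_equal(nrow(grid), 20L)
  # monotone non-decreasing along both axes
  for (b in 0:4) {
    pr <- grid$proportion[grid$max_m5 == b][order(grid$max_m3[grid$max_m5 == b])]
    expect_true(all(diff(pr) >= 0))
  }
  for (a in 0:3) {
    pr <- grid$proportion[grid$max_m3 == a][order(grid$max_m5[grid$max_m3 == a])]
    expect_true(all(diff(pr) >= 0))
  }
  # all-perfect profiles fill every cell with 1
  prof0 <- prof
  prof0$m3[prof0$covered] <- 0L
  prof0$m5[prof0$covered] <- 0L
  expect_true(all(criteria_grid(prof0)$proportion == 1))
  # a single (1,0) profile is excluded exactly from the max_m3 = 0 cells
  prof1 <- prof0
  prof1$m3[which(prof1$covered)[1]] <- 1L
  g1 <- criteria_grid(prof1)
  expect_true(all(g1$proportion[g1$max_m3 == 0] < 1))
  expect_true(all(g1$proportion[g1$max_m3 >= 1] == 1))
})

test_that("zero covering sequences give undefined proportions, not zero", {
  prof <- data.frame(primer = "p", seq_id = c("a", "b"), covered = FALSE,
                     reason = "terminal_gap", m3 = NA_integer_,
                     m5 = NA_integer_)
  g <- criteria_grid(prof)
  expect_true(all(is.na(g$proportion)))
  expect_true(all(g$n_covering == 0))
  csv <- tempfile(fileext = ".csv")
  write_coverage_csv(g, csv)
  expect_false(any(grepl(",0,$", readLines(csv)[-1])))
})

test_that("per-class coverage conserves the overall proportion", {
  prof <- data.frame(
    primer = "p",
    seq_id = sprintf("s%02d", 1:15),
    covered = TRUE, reason = NA_character_,
    m3 = c(rep(0L, 9), 1L, rep(0L, 5)),
    m5 = 0L)
  tax <- data.frame(seq_id = sprintf("s%02d", 1:15),
                    class = rep(c("A", "B"), c(10, 5)))
  cg <- coverage_by_group(prof, tax, max_m3 = 0L, max_m5 = 3L)
  expect_equal(cg$proportion[cg$group == "A"], 0.9)
  expect_equal(cg$proportion[cg$group == "B"], 1.0)
  expect_equal(cg$proportion[cg$group == "OVERALL"], 14 / 15)
  # weighted mean of class rows equals OVERALL
  cls <- cg[cg$group != "OVERALL", ]
  expect_equal(sum(cls$proportion * cls$n_covering) / sum(cls$n_covering),
               cg$proportion[cg$group == "OVERALL"])
  expect_equal(sum(cls$n_covering), cg$n_covering[cg$group == "OVERALL"])
  # class absent from the covering set gets no row
  prof$covered[tax$class == "B"] <- FALSE
  prof$m3[!prof$covered] <- NA_integer_
  cg2 <- coverage_by_group(prof, tax)
  expect_false("B" %in% cg2$group)
})

test_that("subset-mode coverage never exceeds intersection-mode coverage", {
  panel <- list(fwd = degenerate_primer("fwd", SAURON, "forward"))
  fx <- plant_alignment(panel, c(fwd = 20L), n = 15, width = 80, seed = 41)
  # ambiguity in the template: N runs in some records
  fx$refset$aligned[1:3] <- vapply(fx$refset$aligned[1:3], function(s) {
    paste0(substr(s, 1, 24), "NN", substr(s, 27, nchar(s)))
  }, character(1))
  g_int <- criteria_grid(evaluate_panel(fx$refset, panel, sites = fx$sites,
                                        mode = "intersection"))
  g_sub <- criteria_grid(evaluate_panel(fx$refset, panel, sites = fx$sites,
                                        mode = "subset"))
  expect_true(all(g_sub$proportion <= g_int$proportion + 1e-12))
  expect_true(any(g_sub$proportion < g_int$proportion))
})

test_that("a primer covers all of its own realizations perfectly", {
  for (s in c(SAURON, MLCOIINTF)) {
    p <- degenerate_primer("p", s, "forward")
    reals <- iupac_expand(s)
    M <- vapply(reals, function(r) unlist(mismatch_profile(p, r)),
                integer(2))
    expect_true(all(M == 0L))
  }
})

test_that("primer success comparison reports contrasts with exact fallback", {
  # identical outcomes: contrast ~ 0, p ~ 1
  same <- list(p1 = rep(c(TRUE, FALSE), 25), p2 = rep(c(TRUE, FALSE), 25))
  cmp <- compare_primer_success(same)
  expect_lt(abs(cmp$contrasts$estimate), 1e-8)
  expect_gt(cmp$contrasts$p, 0.99)

  # 98/100 vs 50/100: strong positive contrast; agreement with an
  # independent Fisher exact test on the 2x2 table
  out <- list(weak = rep(c(TRUE, FALSE), c(50, 50)),
              strong = rep(c(TRUE, FALSE), c(98, 2)))
  cmp2 <- compare_primer_success(out, reference = "weak")
  expect_gt(cmp2$contrasts$estimate, 0)
  expect_lt(cmp2$contrasts$p, 0.001)
  fisher_p <- fisher.test(rbind(c(50, 50), c(98, 2)))$p.value
  expect_equal(cmp2$contrasts$p_fisher, fisher_p)
  expect_true(all(cmp2$contrasts$p_holm >= cmp2$contrasts$p))

  # complete separation: flagged, fallback produced, no crash
  sep <- list(ref = rep(c(TRUE, FALSE), c(30, 10)), all = rep(TRUE, 40))
  cmp3 <- compare_primer_success(sep)
  expect_true(cmp3$separation[["all"]])
  expect_true(is.finite(cmp3$contrasts$p_fisher))
})
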