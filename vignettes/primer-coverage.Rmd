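---
title: "Zoned-mismatch primer coverage: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Zoned-mismatch primer coverage: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primercov)
```

## The matching model

A degenerate primer is a string over the IUPAC nucleotide alphabet; each
symbol denotes a base set (R = {A,G}, Y = {C,T}, ..., N = {A,C,G,T}).
Inosine (`I`) is accepted on input and modeled as a universal base,
{A,C,G,T}: inosine pairs with all four natural bases, and tailed variants
of inosine-containing primers are conventionally written with `N` in its
place. `U` is normalized to `T`. Because the canonical symbol for the set
{A,C,G,T} is `N`, the reverse complement of a string containing `I` comes
back with `N` after two applications — an involution at the base-set
level, exact at the symbol level for every other code.

A primer position *matches* a template position when the two base sets
intersect (`intersection` mode, the default). This is the behavior of
ambiguity-aware pattern matching with ambiguity honored on both sides —
the same convention as `Biostrings` matching with `fixed = FALSE`, which
the test suite uses as an independent cross-check. Intersection semantics
let a template `N` match every primer symbol, which inflates coverage for
records with undetermined stretches; a stricter `subset` mode (template
set must be contained in the primer set) is therefore also provided, and
every report records which mode was used. Public reference sequences do
contain `N` runs, and nothing in their provenance says which reading is
"right"; exposing both, rather than hard-coding one, keeps the choice
auditable. Subset-mode coverage is cell-wise less than or equal to
intersection-mode coverage by construction.

The **zoned mismatch profile** of a primer of length $L$ against a
site sequence of the same length counts mismatching positions in two
zones: $m_3$ within the `zone3` bases closest to the primer 3' end
(default 4 — the width at which terminal mismatches are known to
suppress extension; exposed as a parameter so the grid logic is testable
at other widths), and $m_5$ in the remaining $L - 4$ bases. Primers must
be at least 5 nt so both zones exist. Site sequences are handled in
template plus-strand orientation; reverse primers are compared through
their reverse complement, which maps the primer's 3' zone onto the first
four template positions. Comparison is strictly index-to-index: the
site-extraction contract (below) guarantees no indels inside a covered
site, appropriate for a protein-coding locus like COI where priming-site
indels are rare and length-disrupting.

For a plain (A/C/G/T) site sequence, the per-position set logic yields
exactly the minimum of $(m_3, m_5)$ over all plain realizations of the
degenerate primer, because positions are independent. The suite checks
this against a brute-force enumeration oracle over 1,000 seeded site
strings for every primer in the shipped panel (degeneracies 1 to 2048).

**Coverage** is reported on the nested criteria grid: all 20 cells
(max $m_3 \in \{0..3\}$) × (max $m_5 \in \{0..4\}$), per primer, overall
and per taxonomic class, with the proportion of site-covering sequences
meeting each cell's criterion. Proportions are non-decreasing along both
axes; a zero denominator yields an explicit `NA` (serialized as an empty
field), never 0, so absent data cannot masquerade as zero coverage.

## Reference handling

Dereplication keeps one record per species — the longest, with ties
broken by lexicographically smallest sequence id — so that taxa with
many database records do not dominate coverage denominators. The species
key is the whitespace-collapsed, case-folded species string;
indeterminate entries ("Genus sp.") are distinct keys by default, with a
flag to drop them.

Priming sites are located by sliding a window of the primer's length
along the alignment columns on both strands and scoring each window by
the mean fraction of matching positions over records whose window is
gap-free; ties go to the leftmost window and the plus strand. For large
alignments the mean is taken over a seeded random subsample (default
1,000 records; `exact = TRUE` disables the cap). The located window is a
column interval; *site coverage* of a record then requires its degapped
window to have exactly the primer's length with only IUPAC characters.
Everything else is excluded from the denominator with a reason code
(`terminal_gap`, `internal_indel`, `length_mismatch`,
`invalid_character`) rather than being silently dropped or force-aligned
— partial site overlaps tell you nothing about whether the primer would
anneal, and records with internal indels at the site have no canonical
position-to-position correspondence.

Coordinates are 0-based half-open internally and in BED output; all
human-readable reports print 1-based inclusive, and say so.

## Primer design

Degenerate consensus design works from per-column base frequencies over
covering site strings (ambiguous template characters are excluded from
the frequencies but tallied). Every base with relative frequency at
least `f_min` is included; the default `f_min = 0.05` includes any base
carried by at least one in twenty reference sequences — low enough to
capture recurrent lineage-specific variants, high enough to exclude
singleton noise and sequencing errors. The degeneracy cap (default
1,024) bounds the primer-pool size at a scale that synthesis vendors and
pooled-annealing kinetics tolerate, and comfortably admits pools of
several hundred. When the cap binds, the threshold is raised greedily on
the lowest-entropy multi-base column first (ties to the 5'-most
position), dropping that column's rarest included base; low-entropy
columns lose the least coverage per unit of degeneracy saved, and the
deterministic order is logged in the design's `cap_log` attribute.

The universal-tail check is sequence identity, not thermodynamics: the
tail is slid over every record on both strands and the maximum identity
fraction is reported, failing above a threshold (default 0.85, i.e. more
than ~2 matching-base excess over the ~0.25 random expectation per
position on a 15-mer would need justification). A tail that anneals to
template during the high-stringency first cycles would defeat its
purpose as a template-independent priming site for the indexing step.

## Amplicon prediction

Binding sites are found by exhaustive scan of both strands (naive
O(nL); at desk scale this is the reference implementation, and the
strand-symmetry and re-verification properties in the test suite guard
any later optimization). Amplicon length **includes both primer
footprints** — the convention under which the shipped forward/reverse
pair yields its ~313 bp fragment — and every report header states the
convention. The default length window is 50–2,000 bp.

## The detection simulator

The simulator reproduces the *structure* of a mock-community sequencing
experiment: extract sets × balance levels × replicates (3 × 2 × 3 = 18
libraries in the default design, 85 members per community), lognormal
extract concentrations, balancing by dilution to a cap (default 5.0,
carried in whatever units concentrations were configured in — only
relative concentrations matter to the model, since both the pooling
arithmetic and the detection model are scale-free), competitive
amplification, and multinomial read sampling at a given depth.

Two of its components are this package's own constructions, kept in one
parameter block (`efficiency_params()`):

- **Efficiency model** `e = e_max · δ3^m3 · δ5^m5`, defaults
  `e_max = 0.95`, `δ3 = 0.3`, `δ5 = 0.8`. A well-matched template gains
  slightly less than a full doubling per cycle; a single 3'-zone
  mismatch costs roughly a three-fold efficiency drop (the scale of
  suppression reported for terminal mismatches in quantitative-PCR
  work), a remainder mismatch a mild one; and effects multiply. The
  model is monotone in each count, with δ3 ≤ δ5 encoding that terminal
  mismatches dominate.
- **Sequencing abstraction**: a single multinomial draw of `depth` reads
  over post-PCR proportions. Detection is `count ≥ r_min` (default 1).

With equal efficiencies and proportions $p$, the marginal detection
probability has the closed form $1 - (1 - p)^D$ at depth $D$; the suite
checks the empirical frequency against it over 10,000 seeded replicates
at $p \in \{0.001, 0.01, 0.1\}$ and $D \in \{10^3, 10^4\}$, within
three Monte-Carlo standard errors.

Randomness is governed by one root seed; each library derives its own
31-bit seed by hashing its identifier with the root, so libraries are
independent, reproducible, and insensitive to evaluation order. All
outputs record their seed.

The default experiment for model fitting simulates 1,000 libraries of 85
members with depths log-uniform on $[10^3, 10^5]$ — spanning the
"few thousand reads per sample" regime of heavily multiplexed runs up to
depths where sampling loss is negligible — and concentrations lognormal
(meanlog 0.5, sdlog 1.5, roughly 0.1–30 in concentration units, the
spread across which balancing decisions become consequential).

## The detection model

`fit_detection_model()` fits
$\mathrm{logit}\, P(\text{detect}) = \beta_0 + \beta_1 \log c_{rel} +
\beta_2 \log D \,(+\, \beta_3 \log c_{rel} \log D)$
by `stats::glm`. The interaction is included by default: the true
sampling process ($1-(1-p)^D$, a complementary-log-log surface) is not
exactly additive on the logit scale, and the interaction absorbs most of
the discrepancy. Covariates are centered by default, with the centers
stored in the fit and undone at prediction: without centering the "main"
coefficient of log concentration is its slope at a depth of one read, an
extrapolation far outside any data, and its sign is not determined by
the design. With centering, main effects are average effects over the
observed ranges, which is what "detection improves with concentration
and with depth" means operationally. McFadden's pseudo-R² is
$1 - \ell/\ell_0$ against the intercept-only model.

Complete separation is detected (non-convergence, or fitted
probabilities equal to the outcomes) and a ridge-penalized IRLS fit
(fixed penalty $10^{-2}$ on non-intercept terms) is substituted and
labeled `penalized` in the output; primer-success comparisons
(`compare_primer_success()`) instead fall back to Fisher's exact test
per contrast, reported alongside Wald and Holm-adjusted p-values.

## What the fixture generator does and does not emulate

`generate_fixture()` emits an indel-free alignment with primer sites
planted at stated offsets, per-class mismatch injections of exact
fractions and zone placement, and a truth table of every planted
$(m_3, m_5)$. This makes coverage outputs checkable *exactly*, which is
the point. It does not emulate: alignment errors or gap columns at
priming sites, length variation and partial records (every synthetic
record spans every site), phylogenetically correlated substitution
patterns (injections are independent given class), base composition bias
or codon structure, or ambiguity characters (unless planted explicitly).
Passing tests therefore demonstrate correctness of the bookkeeping —
zone assignment, denominators, group aggregation, strand handling — not
that any particular real-world coverage number will be attained;
coverage on a real reference set depends on that set. The headline
coverage percentages reported for published COI primer sets would
require the full public COI corpus (~10^5 species-dereplicated
records), which this package is sized to process but does not ship.

## Problem sizes and numerical choices

The shipped tests run on fixtures of 40–120 sequences × 60–250 columns,
1,000-site oracle sweeps per panel primer, 10,000-replicate Monte-Carlo
checks, and 1,000-library model-recovery runs — sizes chosen so the
whole suite completes in well under a minute on a laptop core while
still estimating every stochastic quantity to within the tolerances it
is tested at. Other conventions: proportion sums are validated to 1e-9;
window-score ties in site location break leftmost-then-plus-strand;
dereplication ties break to the smallest sequence id; the expansion
operation refuses degeneracies above a cap (default 10^6) and points to
the counting operation instead; empty reference sets make the tail check
pass vacuously with a warning, and zero-denominator coverage cells are
`NA`, never 0.

## Known limitations

- No thermodynamics: melting temperature, dimers, and hairpins are out
  of scope; "fit" is set-algebraic identity only.
- Site coverage excludes records with internal indels at the site; for
  loci where priming-site indels are genuinely common the denominators
  will be conservative.
- The efficiency model's parameters are plausible-scale constructions,
  not fitted quantities; conclusions from the simulator are qualitative
  (orderings, monotonicity), not calibrated predictions.
- `locate_site` assumes the priming site is alignable as a fixed column
  window; heavily gapped alignments may score windows on few records.
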