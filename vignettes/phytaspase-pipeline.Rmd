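---
title: "Methods: screening and characterizing phytaspases with phytasp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening and characterizing phytaspases with phytasp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytasp)
library(dplyr)
```

`phytasp` implements the computational pipeline behind the identification
and characterization of phytaspases — plant subtilases with caspase-like
Asp-P1 cleavage specificity — from a proteome. This vignette is the
package's own account of the methods: the models, the tunable parameters
and their defaults, the numerical conventions, and what the synthetic
data generators do and do not emulate.

## Domain-architecture screening

A plant subtilase precursor carries a signal peptide, the I9 prodomain
(an intramolecular chaperone and inhibitor that is removed
autocatalytically), the S8 peptidase domain with the Asp/His/Asn/Ser
catalytic machinery, and usually a protease-associated (PA) insertion.
`annotate_architecture()` detects the I9 and S8 domains by local
alignment of reference anchor segments against every protein.

The aligner (`local_align()`) is an exact Smith–Waterman dynamic program
with affine gaps (Gotoh's three-state recursion, implemented in C++). A
gap of length $L$ costs $g_{open} + g_{ext} L$; defaults are BLOSUM62
with 11/1, the classic protein-search parameterization. Determinism is
part of the contract: among equal-scoring cells the smallest (row,
column) wins, and the traceback prefers diagonal over up (gap in target)
over left (gap in query). `X` residues are scored with the worst value
of the corresponding BLOSUM62 column so unknown residues can never
create signal. The test suite pins the DP to an exhaustive enumeration
over all monotone matchings on random 12-mers, which is feasible because
the number of local alignments of two 12-mers is only
$\binom{24}{12}-1$.

A domain counts as present when the anchor's alignment reaches 50% of
its gapless self-score and covers at least 60% of the anchor. These two
thresholds are exposed (`score_frac`, `min_coverage`); no published
cutoff exists for this screen, and on the synthetic data the margin
between planted anchors and background alignments is enormous, so the
defaults are not delicate. The four designated catalytic positions of
the S8 anchor are mapped through the alignment and counted only when the
protein has the identical residue; the diagnostic S1-pocket position
(residue 331 in tobacco phytaspase numbering) is mapped the same way.

`completeness_filter()` retains proteins with length 650–800 residues
(bounds read as inclusive — the conventional reading; both boundaries
are unit-tested), all four catalytic residues, and the I9 prodomain,
reporting the first failing criterion per protein. The filter is
idempotent and order-invariant. Manual curation of misannotated gene
models, which a real screen would add, is deliberately out of scope.

`find_tandem_arrays()` operationalizes "tandemly arranged" as maximal
same-chromosome runs with consecutive gene starts at most `max_gap_kb`
(default 100 kb) apart. No standard definition exists; the flag is
exposed.

## Junction calling and candidate classification

The prodomain junction is the enzyme's first self-cleavage site, so its
sequence reflects the enzyme's own specificity. How junctions are placed
on each family member is not derivable from first principles, and the
default here is reference-anchored: `call_junction()` aligns annotated
references (with known junction positions) to each query, takes the
highest-scoring reference whose alignment covers its own junction (ties
broken by reference id), and maps the first mature residue through the
matched positions. When that column falls in a query gap the nearest
aligned mature-side position is used and flagged rather than guessed
silently. A motif-scan alternative, `call_junction_pwm()`, calls the
highest-scoring bond under a position-weight model; it is non-default
because it is only as good as the motif model it is given.

Windows use Schechter–Berger numbering: P6…P1 upstream and P1′…P6′
downstream of the scissile bond, padded with `-` at sequence
boundaries (`extract_window()`). The invariant Thr-Thr at P1′/P2′ of
mature plant subtilases is checked as a warning only, never a filter —
it is an empirical observation, not a definition.

`classify_phytaspase()` applies the two diagnostic rules: Asp at P1
makes a candidate; the S1-pocket residue subtypes it (His — the true
phytaspase configuration, thought to bind the substrate's P1 Asp; Lys —
a plausible charge-compatible variant; Gly — a wider, apolar pocket).
An unmapped or other residue gives subtype "other"; non-candidates are
never subtyped.

## The enrichment statistic behind the logos

For windows aligned at the junction (or at reconstructed cleavage
sites), `positional_enrichment()` compares, per position and residue,
the sample frequency against a background proteome composition. The
effect size is the frequency difference in percentage points,
$100(\hat f - f_0)$, and the test is a two-sided exact binomial test of
the count at that position against $f_0$: the smaller tail (including
the observed count) is doubled and capped at 1. The published displays
this mirrors use a resampled reference-set z-score; the exact test was
chosen because it is deterministic, assumption-free at small $n$, and
testable to machine precision against an independently coded
log-binomial oracle (the suite requires agreement within $10^{-12}$ on
the full 240-cell grid). A `method = "zscore"` normal approximation is
provided for cross-checking. No multiple-testing correction is applied,
matching common practice for these displays; `alpha` is exposed.

Two conventions deserve note. Pad symbols at boundary positions reduce
that position's $n$ instead of counting as a 21st letter. And because
the capped two-sided p-value can equal exactly 1, `alpha = 1` is
interpreted as disabling the significance filter (every cell
significant) so that logo heights then equal the raw frequency
differences everywhere; with a strict `p < 1` rule, cells at their
expected count would be excluded even at `alpha = 1`, which is never
what a user asking for "no filter" means.

The type-I behavior is calibrated in the tests: windows drawn from the
background produce significant cells at a rate bounded by the nominal
5% (the exact test is conservative at small $n$), checked over 100
seeded trials.

## Phylogeny

`pairwise_distances()` computes p-distances with pairwise deletion
(sites with a gap or `X` in either row are excluded per pair) and
optionally the Kimura protein correction
$d = -\ln(1 - p - 0.2\,p^2)$, which is what ClustalX applies by
default; uncorrected p-distance is the package default, both are
documented, and the correction refuses $p \ge 0.8541$ (log of a
non-positive number) with an actionable error.

`neighbor_joining()` is the Saitou–Nei agglomeration on the Q
criterion, with two deterministic conventions: Q-ties are broken by the
smallest index pair, and negative branch lengths are clamped to zero
with the deficit moved to the sister edge (preserving their sum;
`clamp_negative = FALSE` disables this, e.g. for comparison against
other implementations). Two taxa return a midpoint-split single edge as
a documented special case. On additive matrices NJ is consistent — the
output tree's path lengths reproduce the input exactly — and the suite
asserts this within $10^{-9}$ over 20 random trees of 4–8 leaves,
alongside a cross-check against an independent NJ implementation.
Progressive multiple alignment is out of scope: the module consumes an
existing MSA, because re-implementing an aligner would dominate the
package without adding anything to the pipeline's substance. Rooting and
bootstrap support are likewise out of scope.

`assign_clades()` operationalizes subfamily membership as
nearest-labelled-leaf by patristic distance (ties to the
lexicographically first reference). Published subfamily boundaries
involve curatorial judgment; nearest-reference assignment is a
deterministic, testable stand-in.

## PICS in silico

The PICS (proteomic identification of cleavage sites) experiment is
simulated and inverted end to end. `digest()` cleaves after the rule
residues — trypsin K/R or chymotrypsin F/Y/W/L, both blocked before Pro
— with zero missed cleavages, keeping peptides of 8–30 residues (the
MS-observable range; no published bounds exist for this step). The
primary sources for this assay disagree on the library enzyme
(chymotrypsin in one place, trypsin in another), so both rule sets ship
and the choice is always explicit — `digestion_rules()` has no silent
default beyond requiring the `enzyme` argument.

`simulate_cleavage()` scores every internal bond under a 12×20
position-weight model (pads contribute 0, so boundary bonds are neither
favored nor excluded), cleaves deterministically at a score threshold or
stochastically through a logistic link, retains at most one cut per
peptide (highest score, leftmost on ties — mirroring single-event
detection per library peptide), and drops prime fragments shorter than
4 residues as unidentifiable. `reconstruct_sites()` then plays the role
of the database lookup: each prime fragment must be a proper suffix of
exactly one library peptide; zero or multiple hits go to the ambiguity
report rather than producing a guessed window. The round-trip guarantee
— every retained reconstructed window equals its event's true window —
is asserted on a 5000-peptide library. Chemical protection,
biotinylation efficiency, capture losses and MS identification error
are not modelled.

## Assay quantification

`initial_rate()` fits an ordinary least-squares slope. How plate-reader
curves were windowed in the original assays is unstated, so the default
policy is explicit and overridable: among contiguous prefixes covering
at least 30% of the points, take the best $r^2$ (longest on ties).
This recovers the early linear phase of saturating curves and is exact
on noiseless lines under every policy. Units (per minute vs per hour)
are carried on the estimate, never converted implicitly. No
Michaelis–Menten parameters are fit; the assays this reflects report
relative rates only.

`ph_profile()` normalizes to percent of the maximum rate and reports
the argmax pH without interpolation (lower pH on ties).
`panel_table()` reports raw and percent-of-max rates per enzyme with
the top substrate flagged. `score_peptide()` places an AFC panel
peptide's C-terminal residue at P1 (the fluorophore occupies the prime
side) and sums the available window weights, linking PICS-derived
profiles to panel substrates.

`necrotic_fraction()` converts to grayscale by channel mean, removes
the scanner background with `gray < white_threshold` (default 250 of
255), and thresholds dark pixels within the leaf mask — Otsu on the
masked histogram by default (computed here directly because the
within-mask variant is needed), or a fixed cutoff for exact,
reproducible counts. Whether the original quantification thresholded
per image or globally is unstated; both are possible here.
`unpaired_ttest()` is the pooled-variance Student t-test ("unpaired
t-test" without a Welch qualifier), with Welch available; zero pooled
variance with equal means returns p = 1 by convention, with different
means it is an error rather than an infinite statistic.

## The synthetic-data module

Every input class the pipeline consumes can be generated with known
ground truth: background proteomes with controlled composition
(uniform by default, an Arabidopsis-like preset available), planted
subtilases, peptide libraries, linear-plus-noise fluorescence traces,
and tri-modal leaf images with an exact planted dark-pixel count. All
generators are bit-reproducible under a fixed seed and emit only the 20
canonical residues.

A planted subtilase is laid out as: random filler, the I9 anchor ending
immediately before the junction window, the 12-residue window (Asp or
another residue at P1, Thr-Thr at P1′/P2′ by default), a fixed
24-residue conserved mature-N-terminus segment, and the S8 anchor
(carrying the four catalytic residues and the S1-pocket position, where
the planted His/Lys/Gly is substituted) starting 30 residues into the
mature enzyme. The conserved segment matters: real subtilase families
are homologous immediately downstream of the junction, and without that
conservation the junction region of a fixture is pure noise, through
which a local aligner can legitimately find gap-shifted paths that
displace the mapped junction by a few residues. The fixture anchors are
fixed synthetic segments, not real domain sequences — real references
(with their own catalytic positions and junction annotations) plug into
the same function arguments.

`simulate_sbt_family()` defaults encode the composition reported for
the tomato family — 82 complete subtilases, of which 12 carry Asp at P1
(5 His-, 1 Lys-, 6 Gly-type at the S1 pocket) — so the family-scale
tests and the acceptance script exercise the pipeline at the study's
scale. What the generators do *not* emulate: real domain sequences and
their divergence structure, signal peptides as recognizable motifs,
gene models and introns, MS noise, or image vignetting and staining
variation. Passing tests therefore demonstrate the correctness of the
algorithms and their determinism, not screening performance on real
proteomes, where anchor choice and curation dominate.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at deliberately desk
scale: a 292-protein screening set (82 planted family members, 10
incomplete family members, 200 decoys), 5000-peptide PICS libraries,
20-tree NJ panels, 100-seed logo calibrations, and 10⁴ t-test
null simulations — sizes at which every stage's ground truth is exact
and the whole suite runs in about a minute. Branch lengths are
serialized at 12 significant digits (path-length round trips are tested
to $10^{-9}$); the exact binomial oracle agreement is required to
$10^{-12}$; alignment scores are integers and compared exactly.

## Known limitations

* Screening quality on real data depends on the reference anchors; the
  synthetic anchors validate the machinery only.
* Reference-anchored junction calling inherits the references'
  annotation quality, and the reported counts on a real proteome may
  differ slightly from published figures wherever those relied on
  manual curation.
* BLAST bit-scores/E-values are not reproduced (the screen uses exact
  local alignment, which is the stronger guarantee but not
  numerically comparable), and HMM-based domain detection is not
  attempted.
* The PICS simulation's one-cut-per-peptide rule is a simplification;
  multiply-cleaved peptides in a real digest yield nested fragments
  that the ambiguity report would partially absorb.
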