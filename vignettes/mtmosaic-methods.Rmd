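---
title: "Detecting interspecific mitochondrial recombination with mtmosaic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting interspecific mitochondrial recombination with mtmosaic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtmosaic)
```

## The problem

Animal mitochondrial genomes are usually inherited clonally from the mother,
so conspecific mt genomes are expected to differ uniformly along their length
at a low intraspecific rate. When species hybridize, paternal leakage and
heteroplasmy can put two divergent mt genomes into one cytoplasm, and
recombination between them produces *mosaic* genomes: a conspecific backbone
carrying fragments whose closest relative is another species. Such fragments
are a sensitive footprint of (possibly very recent, human-mediated)
interspecific hybridization — the setting that motivates this package is
hybridization among invasive icefishes (Salangidae), where complete mt
genomes of one species carry fragments nearly identical to two related
species.

`mtmosaic` takes a multiple alignment of complete mt genomes — candidate
recombinants plus reference genomes from related species — and answers four
questions:

1. Where does divergence along the genome depart from the intraspecific
   background (high-divergence, HD, regions)?
2. Is there statistical evidence of recombination at all (PHI permutation
   test)?
3. Which genome received which fragment from which donor, and where are the
   breakpoints (triplet scanning, MaxChi, event calling)?
4. How recent is each transfer (post-transfer mismatch counting), and which
   fragments can serve as diagnostic markers for hybrid monitoring?

A calibrated simulator of mosaic genomes (`simulate_mosaic()`) generates
data with known truth so that every stage is testable without any external
download.

## Data model and conventions

The substrate is an `mt_alignment`: equal-length sequences over
`A,C,G,T,N,-`. IUPAC ambiguity codes other than `N` are mapped to `N` on
ingest; `N` is treated as missing data and `-` as an alignment gap, and both
are excluded from every distance (pairwise deletion: each pair of sequences
is compared over the columns where both carry an unambiguous base). All
coordinates are 1-based, inclusive, in alignment-column space; conversion to
ungapped per-sequence positions is available read-only
(`ungapped_position()`), and fragment lengths are additionally reported
"excluding alignment gaps" because the two differ in gapped alignments.

Distances are raw p-distances (proportion of differing comparable sites, no
multiple-hit correction); nucleotide diversity π is the mean p-distance over
all unordered pairs. Standard errors come from a site bootstrap (columns
resampled with replacement, 1000 replicates, seeded, default seed 1729) —
a method-agnostic choice that is directly testable, in contrast to the
various analytic variance formulas implemented by classical software.

## Sliding windows and HD regions

`sliding_profile()` moves a window of 100 columns in steps of 25 (both
configurable) along the alignment; the statistic (π or pairwise Dxy) is
computed on each full window and assigned to the window's midpoint column
`start + floor((window-1)/2)`. Gaps count toward the window span but not
toward the statistic; trailing partial windows are dropped; windows with no
comparable site are flagged and given value 0.

`detect_hd_regions()` codifies what a reader does with a sliding-window
plot: the background is the median window value; windows above
`max(fold_threshold × background, absolute_floor)` (defaults 5× and 0.02)
are candidates; candidate runs separated by at most `merge_gap`
non-candidate windows merge; runs with fewer than `min_windows` candidates
are dropped. Peak ties resolve to the smaller midpoint.

Two properties of overlapping windows shaped the pipeline-level defaults:

* a single cluster of 3 intraspecific mutations inside one window length
  elevates up to `window/step` consecutive windows, so a run-length filter
  of 2 cannot reject point clusters — the pipeline requires 4 candidate
  windows and bridges gaps up to `window/step`;
* a fragment carried by one genome out of *k* contributes only a fraction
  `(k-1)/binom(k,2)` of the pooled π signal; a 4.5%-divergent fragment in a
  five-genome panel sits near the detection floor of a pooled profile. The
  pipeline therefore reads HD regions off the *pairwise* profiles
  (`detect_hd_regions_pairwise()`, floor 0.03), where a fragment shows its
  full interspecific divergence against every non-carrier, and merges
  regions across pairs. This mirrors the practice of inspecting per-pair
  sliding-window plots.

## The PHI permutation test

Recombination leaves a spatial signature on *parsimony-informative* sites
(≥ 2 states each carried by ≥ 2 sequences): sites sharing one genealogy are
mutually compatible, while sites on opposite sides of a breakpoint can
violate the four-gamete condition. `phi_test()`:

* binarizes each informative column to its two most frequent states (rows
  carrying other states or gaps are missing for that column; ties broken
  deterministically);
* scores every pair of informative columns within `w` alignment columns
  (default 100) as incompatible when all four binary haplotypes occur among
  rows observed at both columns;
* takes the mean incompatibility over those nearby pairs as the statistic;
* permutes the site patterns across the informative-site positions
  (Fisher–Yates in compiled code, driven by R's seeded RNG) and recomputes.

Under clonal evolution, homoplasy is position-independent and the observed
statistic is exchangeable with the permuted ones. Under recombination,
nearby sites share genealogies and are *more* compatible than permuted
arrangements, so significance is the lower tail:
`p = (1 + #{perm ≤ observed}) / (n_permutations + 1)`. The default 100,000
permutations resolve p-values below 10⁻⁵; the permutation loop costs a few
seconds on a 16.5-kb alignment. When no pair of informative sites is
incompatible anywhere, the permutation distribution is a point mass and the
result is flagged `degenerate`: such a test carries no information in either
direction and is never allowed to veto an event (it still reports p = 1 as
the global answer "no evidence of recombination").

## Breakpoint localization: MaxChi

`maxchi_scan()` orders the comparable sites of a sequence pair along the
alignment, labels each match/mismatch, and at every cut with `k` sites on
each side (default 30) forms the 2×2 table (match, mismatch) × (left, right)
and its chi-square statistic without continuity correction. The maximizing
cut is the breakpoint estimate (ties to the smallest column); significance
comes from permuting the labels over sites and recomputing the maximum, so
the multiple testing over cuts is built into the null.

Two site-list conventions are provided. `sites = "all"` uses every
pair-comparable column — appropriate when the pair itself is the whole
context. `sites = "polymorphic"` restricts to columns polymorphic across the
supplied alignment, the classical MaxChi convention; this matters at
realistic divergences, where a half-window of 30 raw columns contains only
~2 mismatches at 8% divergence and the table has no power. The event caller
uses the polymorphic convention on the (candidate, reference, donor)
triplet, so that sites varying only in unrelated lineages do not dilute the
half-window contrast.

## Event calling

`call_events()` combines the pieces. For each candidate, each same-group
(conspecific) sequence can act as major parent and each other-group sequence
as minor (donor) parent.

1. **Proposal.** `triplet_scan()` calls each window for the parent the
   candidate is strictly closer to; maximal runs of donor-side calls are
   candidate segments. Runs are pooled per (candidate, minor) across majors,
   and kept only when a *majority* of majors propose them — a run seen
   against a single major says more about that major (for example its own
   recombinant fragment) than about the candidate.
2. **Refinement.** On trio-informative sites (candidate, detection
   reference, minor all unambiguous and reference ≠ minor), sites where the
   candidate sides with the minor are donor support, sites where it sides
   with the reference are backbone support. The fragment core is the
   maximal-scoring contiguous block (donor +1, backbone −1, Kadane's
   algorithm), which stops isolated chance matches from stretching the
   fragment. The detection reference is the same-group sequence most
   divergent from the candidate inside the run, because a fellow recombinant
   sharing the fragment carries no breakpoint contrast there.
3. **Breakpoints vs core.** `begin`/`end` delimit the core (first to last
   donor-support site) and are used for mismatch and identity accounting;
   `breakpoint_begin`/`breakpoint_end` estimate the true breakpoints as
   midpoints between the core and the nearest flanking backbone-support
   sites. The distinction is deliberate: the true breakpoint is only
   localizable to the gap between two informative sites (mean gap ≈ 1 /
   divergence columns), the midpoint minimizes the worst-case error, but an
   interval extended to midpoints would sweep flanking backbone sites into
   the "fragment" and corrupt the post-transfer mismatch counts.
4. **Evidence filters.** A test requires ≥ 3 donor-support sites and a core
   candidate–minor divergence below half the genome-wide candidate–minor
   divergence (the near-identity signature of a transferred fragment), and
   the candidate must be closer to the minor inside the core than to its
   closest conspecific without a run at that locus.
5. **Scoring.** Each test is scored by the most conservative of three
   p-values: MaxChi at the beginning flank, MaxChi at the ending flank, and
   PHI on the segment ± `flank` columns. The flank MaxChi runs on the
   (candidate, reference, donor) triplet's polymorphic sites, with the
   flank widened adaptively to hold at least 2k + 10 informative sites and
   the half-window k capped at the core's donor-support count — sites
   beyond the fragment's informative content can only dilute the 2×2
   table, and without the cap a 4.5%-divergent 400-bp fragment (≈ 17
   informative sites) cannot reach a stable chi-square. The PHI component
   is skipped as powerless for segments shorter than 10× the PHI pair
   window: nearby site pairs straddling a breakpoint carry the opposite
   signal to the within-genealogy pairs the statistic relies on, and their
   share is roughly w / span. Bonferroni correction uses the total number
   of distinct (candidate, locus) tests; events with corrected
   p < `alpha` (default 0.05) are kept.
6. **Attribution.** The reported major parent is the conspecific minimizing
   the whole-genome distance outside the candidate's segments; the minor
   parent is the other-group sequence minimizing the within-core distance;
   within-core candidate–minor mismatches are counted and their positions
   recorded.

`annotate_mosaic()` sorts a genome's events and resolves overlaps by keeping
the smaller corrected p (recording the discarded one in a note);
`count_fragment_mismatches()` issues the recency call — an exact-copy
fragment (`identical`) is compatible with a very recent transfer or a PCR
chimera, while accumulated mismatches (`diverged`) mark substitutions that
arose after the transfer and argue against a PCR artifact;
`extract_markers()` flags fragments with identity fraction 1 as
diagnostic-identical markers suitable for monitoring ongoing hybridization.
No molecular-clock dating is attempted: recency is reported as the mismatch
count and left to the user's interpretation.

`recombination_scan()` runs all stages and returns a classed object with
`print`, `summary` and `plot` methods; `run_pipeline()` additionally writes
TSV tables, a newick tree, a JSON report and a run log, byte-identically for
identical inputs, configuration and seed.

## The simulator

`simulate_mosaic()` emulates the statistical structure the detection stages
assume, nothing more:

* a uniform-random ancestral sequence; species references derived on a star
  phylogeny with per-branch substitution probabilities calibrated so the
  *expected* pairwise p-distances hit the configured targets exactly
  (closed form for two lineages, least-squares on the exact pair relation
  `d = q_i + q_j − (4/3) q_i q_j` for three or more; unsatisfiable targets
  are rejected);
* individuals derived from their species reference at per-site rate
  `intraspecific_divergence / 2`;
* recombinants made by splicing donor fragments over recipient columns and
  applying exactly the configured number of post-transfer substitutions at
  recorded positions;
* Jukes–Cantor-style substitution (uniform among the three alternatives),
  no rate heterogeneity, no indels — the alignment is gapless, so planted
  breakpoints are exact and recovery can be scored without ambiguity.

`reference_mosaic_config()` bundles the regime the package is validated
against: 16,500 columns; a focal species with five individuals and two donor
species with one reference each, at 8.5% / 4.5% interspecific divergence
(the donor–donor pair, for which no empirical estimate is available, is set
to 8.5%, the same order as the deeper split) and 0.3% intraspecific
divergence; planted fragments of 140, 1710, 359 bp (donor B, into one
recipient; 0/2/0 post-transfer mutations), 1710 bp (donor B, into a second
recipient, 2 mutations) and 425 bp (donor C, 4 mutations) at fixed
coordinates. Identical seeds give byte-identical FASTA output, and
`write_truth()`/`read_truth()` round-trip the planted-event record.

What the simulator deliberately does *not* model — rate heterogeneity along
the genome, indels and control-region repeat structure, within-species
phylogeographic clade structure, sequencing error — bounds what passing
tests show about real data. In real genomes the control region and the
fast-evolving genes show divergences well above the simulator's uniform
rate, which makes HD regions easier to see there than in the simulation;
conversely, alignment error around indel-rich regions can produce false
recombination signals that the gapless simulator cannot exercise. Distances
and π printed for real data also reflect clade structure among conspecifics
that the star-shaped intraspecific model flattens.

## Numerical and testing choices

* Permutation p-values are `(1 + #{extreme}) / (n + 1)`, never zero; all
  permutation loops run off R's seeded RNG, and per-test seeds are derived
  from the caller's seed, so the whole pipeline is reproducible
  bit-for-bit.
* All maxima (MaxChi cuts, HD peaks) break ties toward the smaller column;
  candidate and reference iteration follows ingest order.
* Negative neighbor-joining branch lengths are clamped to zero; tree
  inference is distance-based (`ape::nj`) — the package takes no position on
  substitution models, and likelihood phylogenetics is out of scope.
* Test problem sizes: unit tests run on 2–6-kb simulated alignments;
  whole-pipeline validation uses the 16.5-kb reference regime over 20
  seeded replicates, 100,000 PHI permutations for the headline test and
  199–1000 permutations inside per-event loops. These sizes make the full
  suite run in a few minutes while keeping every statistical property
  measurable.
* At 4.5% donor divergence, diagnostic sites are ~22 columns apart, so a
  breakpoint is localized no better than the surrounding informative-site
  gap; across many replicates a small fraction of boundaries will
  necessarily miss a ±50-column target even with the optimal midpoint
  estimator. The median breakpoint error under the reference regime is a
  few columns.

## Known limitations

* Detection requires at least one non-recombinant conspecific reference;
  a fragment shared identically by *every* conspecific (a fixed
  introgression) leaves no within-species contrast and is invisible.
* Fragments much shorter than the window (≲ 150 columns) are detectable but
  sit at the edge of the conservative max-p scoring; their recovery is not
  guaranteed under the bundled regime, mirroring the weak per-method
  support such short fragments receive in practice.
* The fragment-purity filter (core divergence < half the genome-wide donor
  divergence) targets recent transfers; ancient, heavily diverged fragments
  fall outside the package's intended scope.
* The PHI implementation uses the binary four-gamete incompatibility on the
  two most frequent states; the refined multi-state incompatibility score
  of the original formulation is not implemented.
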