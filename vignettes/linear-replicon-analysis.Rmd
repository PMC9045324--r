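---
title: "Validating and comparing linear replicon assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating and comparing linear replicon assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replicontools)
```

# The problem

Actinomycete genomes are unusual twice over: their chromosomes are linear,
and they often carry giant linear plasmids (GLPs) — extrachromosomal
replicons of hundreds of kilobases with protein-capped telomeric ends.
Assemblies of such replicons are awkward to validate and compare:

* long-read assemblies need an orthogonal check that total structure is
  right, classically a rare-cutter restriction digest separated on a
  pulsed-field gel (PFGE) and compared band-by-band with the *in silico*
  digest;
* GLPs can end in long terminal inverted repeats (TIRs) — one end is the
  reverse complement of the other. Assemblers collapse the two copies
  into one, so the reported contig is roughly half the true plasmid and
  the collapsed repeat shows twice the read depth;
* derivative industrial strains carry plasmids that differ from the
  parental plasmid by insertions, deletions, inversions, translocations
  and SNPs, frequently bordered by insertion-sequence (IS) transposase
  genes, whose density and spatial association with breakpoints is the
  signature of mobile-element-driven plasticity.

`replicontools` turns each of these formerly by-hand analyses into a
deterministic, testable operation, and ships a seeded simulator so the
whole pipeline can be exercised end-to-end with exact ground truth and no
external data.

# Models and procedures

## Virtual digestion and gel matching

A restriction enzyme is a (possibly IUPAC-ambiguous) recognition site with
a top-strand cut offset. `find_sites()` scans the top strand with
ambiguity-aware matching (`Biostrings::matchPattern`, sites expanded,
assembly bases literal, so an `N` in a draft assembly never matches);
non-palindromic sites are additionally scanned as their reverse complement
and the bottom-strand cut mapped back to top-strand coordinates.
Palindromic sites — all four built-ins (DraI, AseI, BfrI, XbaI) — are
counted once. Circular replicons are scanned across the origin. Cut
positions are *prefix lengths* (an integer in (0, L) says how many bases
lie left of the cut), the one place the package departs from 1-based
inclusive coordinates, because a cut falls between bases.

Digestion is then arithmetic: a linear molecule with *n* distinct interior
cuts yields *n* + 1 fragments, a circular one *n* (or one uncut
full-length fragment), and fragment lengths sum exactly to the replicon
length — an identity the test suite checks on every random digest.

The gel model keeps the two facts of a PFGE run that matter for
validation: fragments below `min_visible_bp` (default 30,000 bp, typical
of run conditions resolving 50 kb–1 Mb) leave no band, and migration is
linear in log10(size) within the resolvable range. `match_bands()` makes
the traditional by-eye gel comparison an algorithm: a dynamic programme
over the two size-sorted lists finds the maximum number of one-to-one
matches under a relative-error cap (default `rel_tol = 0.05`, reflecting
PFGE sizing error on large bands), breaking ties by minimal total relative
error. Because compatibility windows are intervals on sorted lists, a
non-crossing assignment attains maximum cardinality, which is what the
DP searches. Predicted fragments within `rel_tol` of each other
co-migrate: after the assignment, an unmatched fragment that sits within
tolerance of a matched fragment *and* of its band joins that band's
co-migration group instead of being reported missing — without this, a
17-fragment digest could never validate against fewer distinct visible
bands.

## Collapsed-repeat resolution

The coverage model of a collapsed TIR is a step function: depth 2*d* over
the single reported arm copy (it attracts the reads of both copies),
*d* over the unique central region. `segment_coverage()` smooths the
per-base track with a running median (window 1,000 bp — wide enough to
flatten per-base noise, narrow relative to the ≥ 5,000 bp segments being
sought) and applies binary segmentation with a within-segment
squared-deviation cost. A split is accepted when its cost reduction
exceeds a BIC-style penalty, 10·σ²·log n, with σ estimated robustly from
the raw track's first differences (`mad(diff(x))/sqrt(2)`); on a noiseless
track σ = 0 and segmentation is exact. Segments shorter than
`min_segment_bp` (default 5,000) merge into the neighbour with the closer
mean. The procedure has no random element: the same track always yields
the same segments.

`call_collapsed_repeat()` scans end-anchored segment runs from both contig
ends and computes the length-weighted mean depth of each candidate arm
against the remainder. Candidates whose ratio falls in `ratio_band`
(default [1.6, 2.4], an operational reading of "about twice the
coverage") are eligible; among them the ratio closest to the band centre
wins. This tie rule matters: once the candidate boundary overshoots into
the central region the ratio drifts only slowly, so "maximal run in band"
would systematically overshoot, while "closest to 2×" locks onto the true
boundary. The arm must touch a contig end because the biological model is
a *terminal* inverted duplication; an interior duplication would need a
different mechanism and is deliberately not expanded. Baseline depth is
the central-region mean, not the global mean, because the arm dominates
the contig length and would bias a global baseline.

Reconstruction is exact arithmetic: full length = 2R + C, and
`expand_collapsed_sequence()` emits arm + central + revcomp(arm), whose
first R bases equal the reverse complement of its last R bases by
construction — an identity the tests assert verbatim, along with the fact
that re-digesting the expansion reproduces the simulator's ground-truth
fragment multiset.

## Rearrangement and SNP mapping

Two near-identical replicons are compared through unique k-mer anchors:
k-mers occurring exactly once in the reference (top strand) and exactly
once in the query (either strand) are matched forward and against the
reverse complement, then merged into maximal exact matches along shared
diagonals. The default k = 21 makes a chance shared k-mer vanishingly
rare even in a 70% GC, 300-kb plasmid, and — usefully — repeated
transposase cassettes exclude themselves from anchoring because their
k-mers are not unique.

Anchors are chained greedily along the reference into collinear,
consistently oriented blocks with gaps at most `max_gap` (default
5,000 bp) on both sequences; blocks spanning less than `min_block`
(default 500 bp) are dropped. Block identity is computed exactly:
anchored bases count as matches and inter-anchor gaps are globally
aligned (`Biostrings::pairwiseAlignment`), except gaps above 2,000 bp,
which are counted as unaligned rather than aligned (at that size they are
events, not divergence).

Event classification reads the block layout. A longest increasing chain
(weighted by block span) of query positions defines the collinear
backbone; blocks falling outside it are translocations, reverse-oriented
backbone blocks are inversions, and backbone gaps become insertions (gap
only in the query), deletions (gap only in the reference) or a
deletion+insertion pair (both). Gap bases covered by a translocated
block are excluded from this arithmetic so a move is reported once, not
as a phantom deletion plus insertion. The same gap logic runs *within*
blocks, between consecutive anchors, because an indel smaller than
`max_gap` does not break a block. Differences below `min_event`
(default 50 bp) are left to `call_snps()`, which aligns the short
inter-anchor gaps and reports substitution columns and sub-50-bp indels
with 1-based coordinates on both sequences. Insertions are additionally
reported with the derived-replicon coordinate of the first inserted base,
the convention in which published insertion positions are quoted.

`classify_snp_effect()` rebuilds the affected codon from the annotated
CDS frame (strand-aware) and translates before/after: synonymous,
missense, nonsense, frameshift (indel length ∤ 3) or in-frame indel; a
call outside any CDS is intergenic.

**Resolution limits worth knowing.** Anchor boundaries extend while bases
happen to agree, so event loci are recovered within ±k bp, not exactly.
A translocation displaced by less than `max_gap` is bridged by the
chainer and surfaces as a local indel pair — below the method's
resolution scale, and the simulator's round-trip sampler therefore keeps
translocation destinations, like all event footprints, more than
`max_gap` apart. Duplications are detected only when their copies anchor
(i.e. for two-copy repeats the copies must diverge enough to carry unique
k-mers); heavily repeated regions are reported as unaligned territory.

## Transposase density and breakpoint association

Feature categories come from an ordered, case-insensitive substring rule
table over CDS product strings (first match wins; default rules:
"transposase" → transposase; "transcriptional regulator" or "regulator" →
regulator; "hypothetical protein" → hypothetical; anything else →
other). Published tables do not disclose their counting rule, so the
table is explicit and user-overridable rather than hard-coded.

Density is count per Mbp, reported unrounded with a 1-decimal display
value. The breakpoint association test is a Monte-Carlo permutation
test: observed statistic = mean distance from breakpoints to the nearest
feature of the category (0 inside a feature, otherwise the base-count
gap to the nearest edge); the null redraws equally many positions
uniformly over the replicon `n_perm` times (seeded, vectorised through
`IRanges::distanceToNearest`); p = (1 + #{null ≤ observed})/(n_perm + 1).
Feature intervals are irregular, so an analytic null would be awkward;
the +1 pseudo-count keeps p away from 0. In the degenerate case of a
feature covering the whole replicon every null statistic is also 0 and
p = 1 — the test honestly carries no evidence, rather than the spurious
minimum p a strict-inequality count would report.

Median CDS length uses the lower-middle convention for even counts, so
the reported value is always an actual CDS length.

# The simulator: what it emulates, and what it does not

`generate_replicon()` draws i.i.d. bases at a target GC (default 0.72,
the high-GC regime where AT-rich rare-cutter sites are scarce).
`plant_cassettes()` places non-overlapping CDS cassettes with
category-typical product strings, optionally confined to windows (e.g.
a transposase-dense 40-kb region). `apply_events()` plants typed
rearrangements with exact post-hoc coordinates in a truth table;
insertion material can be sampled, copied from the same replicon (leaving
a two-copy repeat, as a chromosomal duplication would), or supplied
verbatim from another replicon. `make_inverted_repeat_plasmid()` builds
the full TIR plasmid and its collapsed form; `simulate_coverage()`
realises the 2d/d step with multiplicative uniform noise (default
baseline 40×, ±15%); `simulate_gel_observation()` perturbs visible
fragment sizes with multiplicative Gaussian error (default 2%) and can
merge co-migrating bands. Every generator is a pure function of its
arguments and seed; identical calls are bit-identical.

What the simulator does *not* model — and what passing tests therefore do
not show about real data: dinucleotide/codon structure (real genomes are
not i.i.d., so real site densities differ from the binomial expectation),
read-level error profiles (coverage noise is multiplicative per-base, not
per-read), partial digestion or methylation sensitivity, telomere ends,
and assembly artefacts other than a single collapsed terminal repeat per
contig.

# Numerical choices and test conditions

Study-condition geometry used by the acceptance script and tests, stated
here as the package's own choices: a 189,563-bp collapsed contig with a
167,000-bp arm and 22,563-bp central region (reconstructing to
356,563 bp); a 292,604-bp plasmid receiving a 6,708-bp insertion after
position 204,852; a 9,365,899-bp chromosome-length replicon carrying 53
transposase CDS (5.66 → 5.7 per Mbp). Property-scale conditions: repeat
recovery over 100 seeded simulations with R ∈ [50, 200] kb,
C ∈ [10, 40] kb, 40× depth, ±15% noise, requiring R and 2R + C within
±2% in ≥ 95 runs; event round-trips over 100 seeded 30-kb references
with 600–2,000-bp events spaced > max_gap apart; permutation-test
calibration over 200 replicates of 10 uniform breakpoints at
n_perm = 199 (rejection rate at α = 0.05 within binomial error), planted
signal at n_perm = 1,000; gel round-trips at 2% sizing error matched at
tol = 3× the error. Site-scan equivalence against a position-by-position
IUPAC oracle runs on 1,000 random sequences up to 10 kb across the four
built-in enzymes and both topologies.

Coordinates are 1-based inclusive everywhere a base is named (the
GenBank/IRanges convention in which published coordinates are printed);
only cut positions are prefix lengths. Depth segmentation and all
matching/chaining are deterministic given their inputs; every stochastic
component takes an explicit seed.

# Limitations

* GenBank parsing is a minimal flat-file reader (LOCUS topology,
  CDS/product, ORIGIN); `join()` locations collapse to their envelope
  with a warning. GFF3 and bedGraph go through `rtracklayer`.
* One collapsed repeat per contig; interior duplications are reported,
  not expanded.
* The comparison engine targets near-identical replicon pairs
  (hundreds of kb); it is not a general whole-genome aligner and does not
  attempt multiple alignment.
* Keyword classification is only as good as the annotation's product
  strings; pseudogenes and domain-only annotations will count or not
  count depending on wording, which is why published per-Mbp densities
  from differently-counted tables may not reproduce.
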