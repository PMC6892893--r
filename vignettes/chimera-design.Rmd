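---
title: "Designing and quantifying chimeric Cas12a nuclease libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and quantifying chimeric Cas12a nuclease libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chimeracas)
```

## The problem

Chimeragenesis builds synthetic proteins by exchanging segments between
homologous parents at defined crossover points. For Cas12a-type CRISPR
nucleases the attraction is that the enzyme is modular — recognition
(REC1/REC2) and nuclease (WED, PI, RuvC, BH, Nuc) domains with reasonably
clean boundaries — so segments recombined across even distantly related
orthologs (pairwise identities in the mid-30%s) can yield folded, active
nucleases with new PAM preferences and specificity profiles. This package
implements the computational chain around such a library: choosing the
crossover points, enumerating and realizing the designs, and quantifying
the screens used to characterize the variants.

This vignette explains the models and procedures, the parameters that
matter, the numerical choices, and what the synthetic-data generators do
and do not emulate.

## Conservation profile and junction selection

Crossovers must land where the parents still resemble each other, so that
the exchanged segments splice without breaking local structure. We score
each alignment column by **mean pairwise identity**: over all
`choose(n, 2)` row pairs, the fraction in which both rows carry the same
residue. A gap against anything (including gap–gap) counts as a mismatch,
which penalizes indel-prone regions. The raw profile is smoothed by a
centered moving average (default `window = 11` columns, about the width of
the short conserved motifs in Cas12a-type families; truncated at the
edges). Mean pairwise identity was chosen over entropy-based scores
because it is parameter-free and does not require modeling alphabet
frequencies; all we need is a ranking of locally conserved columns.

`select_junctions()` then accepts gap-free columns greedily in descending
smoothed score (ties to the smaller column), subject to a spacing rule:
for **every** parent, the projected nucleotide position (`3 ×` the 0-based
residue index) must keep at least `min_segment_nt` (default 500 bp) to
every accepted junction and to both sequence ends. The constraint is
measured on each parent's CDS, not in alignment columns, because the
design constraint — segments long enough to carry whole functional
domains — is a base-pair constraint. Columns containing any gap are
ineligible so that every parent has a well-defined crossover coordinate.

Greedy selection is a heuristic: a highest-scoring column can exclude two
lower-scoring columns that would have been jointly feasible. The test
suite verifies greedy output against an exhaustive subset search on small
instances in the regimes where the two coincide (loose spacing, and
planted-block alignments where high scores cluster inside well-separated
blocks — the regime the method is actually used in). At tight spacing on
adversarial profiles the greedy answer can be sub-optimal in total score;
it never violates the spacing invariant, which is checked exhaustively on
every emitted set.

Coordinates follow one convention everywhere: alignment columns are
1-based (as alignment viewers number them), residue indices 0-based, and
nucleotide intervals half-open `[3i, 3i+3)`, so coordinate arithmetic is
gap-free and unambiguous. The crossover sits immediately *before* the
junction residue; the junction residue belongs to the downstream segment.

The alignment itself is consumed, not computed — any standard aligner's
output can be supplied. Identity-dependent quantities therefore shift
slightly with aligner choice, which is why the pairwise-identity checks
carry a tolerance of a few percentage points.

## Enumeration and assembly

Two explicit schemes cover the 1- and 2-crossover libraries:

* **sequential** (1 crossover): for each junction `j` and ordered parent
  pair `(A, B)`, `A` up to `j` and `B` from `j` on — `J·P·(P−1)` designs;
* **backbone-swap** (2 crossovers): for each junction pair `i < j`, a
  backbone parent with its `[i, j)` segment replaced by a donor's —
  `C(J,2)·P·(P−1)` designs, or `C(J,2)·(P−1)` with a fixed backbone.

For nine parents and six junctions that is 432 sequential designs plus 120
fixed-backbone swaps — 552 designs in total, the scale of a synthesizable
gBlock library. The schemes are named and config-driven rather than
hard-coded because a physical library's exact composition is a wet-lab
choice; the count formulas are verified exhaustively for all
`P ∈ {2..9}`, `J ∈ {1..6}`.

Design ids are deterministic and sortable (`S{j}_{A}-{B}`,
`D{i}.{j}_{backbone}+{donor}`). Realization concatenates donor CDS slices
between projected junction coordinates and translates the result; every
segment is verbatim donor sequence, and identical inputs always produce
byte-identical outputs. `deduplicate()` collapses designs that realize the
same protein (possible when parents agree around a junction), keeping the
first in enumeration order and reporting collision groups.

`design_gblocks()` splits a CDS into the fewest fragments that fit
`max_fragment_len` (default 3000 nt, gBlock scale) after extension, each
adjacent pair sharing exactly `homology_len` nt (default 40, matching
~40 bp Gibson homology arms), terminal fragments carrying homology into
the vector arms. Merging the overlaps once reconstructs
`vector_left + CDS + vector_right` exactly — a tested invariant — and
overlaps that recur elsewhere in the construct are flagged as assembly
ambiguities.

## Screen statistics

The bacterial screens reduce to count ratios:

* cutting efficiency `(1 − a/b) × 100` with `a` = colonies under the
  targeting gRNA and `b` under the non-targeting control. `a > b` is
  reported as 0% with a warning (negative killing is noise, not biology);
* colorimetric editing efficiency `white / (white + red) × 100` — the
  standard galK/lacZ reading; the denominator is exactly the supplied
  counts (no correction for colonies lost to cutting without repair, since
  plate counts cannot resolve them);
* transformation efficiency `cfu × dilution / µg`;
* T7E1 indel rate `100 × (1 − sqrt(1 − (b+c)/(a+b+c)))` from band
  intensities — the square root converts cleaved-heteroduplex fraction to
  allele-level editing under random re-annealing.

Wilson score intervals (via `prop.test(correct = FALSE)`, default 95%)
accompany the proportion-based statistics. They are additive plumbing —
the point estimates are exactly the formulas above — but useful because
plate counts are small; the suite checks 99% intervals cover the true
simulated efficiency in ≥ 97/100 replicates. A dCas12a-style repression
level, where needed, is the same survival-ratio computation applied to
antibiotic-selection counts; that mapping is an interpretation, not a
distinct formula.

## PAM-depletion screen

The reporter carries a randomized NNNN PAM next to a fixed protospacer;
cells whose PAM supports cleavage are killed in the targeting sample and
survive in the non-targeting control, so functional PAMs are *depleted*
from the targeting library. The pipeline:

1. **extraction** — the 4-mer between fixed flanking anchors, matched by
   Hamming distance only (default ≤ 1 mismatch per anchor; no indels, for
   speed and determinism). Reads with no valid placement, multiple valid
   placements, or non-ACGT bases in the PAM are rejected with categorized
   tallies; quality is not filtered by default (an optional mean-Phred
   filter exists);
2. **counting** over the complete 256-PAM space, zeros included;
3. **frequencies** with pseudocount 1 (configurable to 0), keeping logs
   finite;
4. **enrichment**. Two conventions are implemented because the field's
   descriptions disagree: the ratio-of-logs form `log2(Y_i)/log2(X_i)`,
   and the log2 frequency change `log2(Y_i/X_i)`. The latter is the
   default: it matches the "frequency change (log2)" semantics, gives
   functional (depleted) PAMs positive scores, and is symmetric (swapping
   samples negates it). The ratio-of-logs form is undefined at
   frequencies of 0 or 1 and is sign-blind to which sample is which; when
   selected, undefined PAMs are flagged rather than scored.

`logo_matrix()` exports per-position base frequencies over the top-k PAMs
weighted by `max(score, 0)` for any logo renderer.

## Off-target panel and read-count summaries

`generate_cassettes()` builds the nine-cassette single-edit panel: one
substitution, one deletion, one insertion at each of three positions
(defaults: `round(L·{1,3,5}/6)` — one per PAM-proximal, middle and distal
third). The exact positions and substitution identity are configurable
because panel design is a choice; the defaults use complement
substitutions (always transversions, maximally perturbing pairing) and
insert the partner base 5′ of the position. Every cassette is at edit
distance exactly 1, verified against `utils::adist`.

`annotate_mismatches()` aligns a site to its target end-to-end
(Needleman–Wunsch; match +1, mismatch −1, gap −2; ties resolved toward
leftmost gap placement by preferring diagonal moves in traceback) and
reports the highlighted positions. The scorer is hand-written because the
tie-break is part of the contract; its scores are verified against full
alignment-space enumeration on tiny pairs and against
`Biostrings::pairwiseAlignment` on 500 random pairs up to 12 nt.

`offtarget_fraction()` summarizes a site read-count table as
`100 × Σoff / (on + Σoff)` after dropping off-target sites with reads
≤ `min_reads` (default 10; the filter is strict — "higher than 10"). This
ratio convention is the one consistent with reporting 0% when no
off-target site passes and sub-percent values at low off-target read
counts. The on-target count is not filtered: the summary is conditional
on the assay having detected its intended site, and which sites passed is
always reported.

## Synthetic data: what it emulates, and what it does not

All generators are pure functions of their seed and emit artifacts that
pass the consuming module's validation.

* `simulate_parent_family()` — a star-topology family: each parent copies
  an ancestral residue with per-parent probability `q_i`, else draws
  uniformly from the 20 amino acids; planted blocks (default 6 × 15 aa,
  evenly spaced along 1300 aa) are identical in all parents. The `q_i`
  are spaced so the *expected* pairwise identity of the least- and
  most-related pairs spans the configured band (default 33.8–43.0%,
  matching a diverged Cas12a-type ortholog set). At length 1300 each
  realized pairwise identity has a binomial sd of ~1.4 percentage points,
  and the min/max over 36 pairs are biased outward by roughly one to two
  more, so realized ranges land within ~3 points of the band edges. CDSs
  are back-generated with uniform synonymous codons plus a TAA stop. Not
  emulated: indel evolution (the family is generated aligned, gap-free),
  phylogenetic correlation structure, codon-usage bias. Junction
  *selection* on real alignments additionally contends with gap columns,
  which the suite covers with hand-built gapped fixtures instead.
* `simulate_pam_screen()` — multinomial read sets over the 256 PAMs,
  uniform in the control, functional PAMs down-weighted by
  `depletion_factor` (default 0.01) in the targeting sample; reads are
  pad + anchor + PAM + anchor + pad with uniform substitution errors
  (default 0.2%/base). Not emulated: indel sequencing errors, quality
  variation, PCR amplification bias, biological escape dynamics (real
  depletion screens show weakest-PAM escape effects that a multinomial
  cannot produce).
* `simulate_colony_counts()` — plain binomial draws at a known
  efficiency; no plating variance beyond binomial.
* `simulate_offtarget_table()` — decoys at 1–4 substitutions with reads
  allocated by a nonincreasing propensity curve; no indel off-targets, no
  genome context.

Passing tests on these generators demonstrate that the *computations* are
correct and that the recovery properties hold under the stated statistical
structure — not that real screens are free of the artifacts listed above.

## Problem sizes and numerical choices

The recovery suites run 100 seeded replicates each: PAM screens at 10^5
reads per sample (planted TTTV PAMs required in the top 8 of 256 in ≥ 95
runs) and nine-parent, 1300-aa families (all six junctions required inside
planted blocks in ≥ 95 runs). These sizes keep a full run in minutes on
one core while leaving the binomial noise realistic for MiSeq-scale
amplicon counts and plate-scale colony numbers.

Smoothing sums each window directly rather than differencing a cumulative
sum, so columns with identical window contents tie *exactly* and
tie-breaks (smaller column first) are reproducible. Degenerate inputs are
contracts, not surprises: empty junction sets warn and return empty;
zero-count denominators error; `a > b` clamps with a warning; rejected
reads are tallied by reason, never dropped silently.

## Known limitations

* Junction selection reproduces the stated constraints (conservation
  maxima, ≥ 500 bp segments, domain-sized pieces); where a real design
  also folds in expert structural judgment, the expert's exact picks are
  not recoverable from constraints alone.
* The greedy selector is exact only in the regimes described above.
* Anchored PAM extraction does not model indels in the anchors; reads
  with indels there are rejected rather than rescued.
* The off-target summary is only as complete as the supplied site table;
  sites below the read filter are excluded by design, and the package
  does not discover sites genome-wide.
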