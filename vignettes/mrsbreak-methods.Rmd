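---
title: "Methods: MRS scanning, IPCR simulation and junction analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MRS scanning, IPCR simulation and junction analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsbreak)
```

## Scope and model

`mrsbreak` implements four connected analyses for a single gene-local
reference: (1) prediction of candidate matrix/scaffold attachment regions
(MAR/SAR) by the bipartite MRS motif criterion; (2) an in-silico model of
the nested inverse-PCR (IPCR) assay that detects apoptotic chromosome
breaks inside an XbaI-flanked region of study; (3) mapping of breakpoints
and shift-translocation junctions, including junction microhomology, from
amplicon read sequences; and (4) cleavage-frequency statistics over
replicate band counts. A synthetic-data generator stands in for the wet-lab
inputs, with recorded ground truth, so every stage is testable end to end.

All coordinates are 1-based and fully inclusive on the Watson strand. This
is forced by the motif coordinate arithmetic the package reproduces: a
16 bp element printed at 26,055–26,070 only spans 16 bases under the
inclusive convention.

## The MRS scanner

An MRS pairs an 8 bp element `AATAAYAA` (exact match required) with a 16 bp
element `AWWRTAANNWWGNNNC` (at most one mismatch), on either strand, in
either order, possibly overlapping. Scanner behaviour worth stating
precisely:

* **Mismatch counting.** A window position mismatches when the base is not
  in the IUPAC class of the pattern symbol. A reference `N` satisfies only
  an `N` pattern symbol: an undetermined base is never allowed to support a
  motif call at an informative position. This is the conservative choice;
  it can only suppress, never create, hits on ambiguous references.
* **Strand handling.** Crick-strand hits are found by scanning the reverse
  complement; they are reported with Watson coordinates and the matched
  sequence as read 5'→3' on the Crick strand (the orientation in which the
  motif text is recognisable). Output is sorted by start, Watson first on
  ties.
* **Gap convention.** The distance between the two elements is the number
  of bases *strictly between* the intervals, negative when the 8-mer is
  upstream. Intersecting elements are `Overlap`, a category, never a
  gap ≤ 0. This convention was chosen because it reproduces, for every
  published element-coordinate pair in the packaged ABL catalogue, the
  distance the catalogue reports (including +47, −40, −178, +248 and the
  overlap rows) — see `tests/testthat/test-acceptance.R`.
* **Merging and clustering.** Same-element motifs within 200 bp (interval
  gap) collapse into one merged element by single-linkage chaining; each
  merged-16mer × merged-8mer combination whose best member pair overlaps or
  lies within `max_gap` is one MRS; MRS spans within `proximity` of each
  other cluster into one candidate site. Within a merged pair the
  *representative* combination minimises the absolute gap, with overlap
  ranking best; all member combinations are still tabulated, because the
  reference catalogue reports them all (e.g. one 16-mer against three
  overlapping 8-mers at +153/+156/+159).

### Parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `max_gap` | 250 | bp | the widened pairing rule; 200 reproduces the original MRS rule (the packaged catalogue's SAR1-resident pair, at 248, exists only under the widened rule) |
| `merge_distance` | 200 | bp | same-element collapse distance; kept at 200 even when `max_gap` is 250 |
| `proximity` | 1000 | bp | site clustering. The quantity is not standardised anywhere we know of; 1000 bp is chosen because the reference catalogue merges MRS pairs ~440–675 bp apart into one site while keeping MRSs ~2.7 kb apart separate, so any value in roughly [700, 2600] reproduces it — 1 kb is the round number in that window |
| 16-mer mismatch budget | 1 | — | part of the MRS definition; the 8-mer budget is fixed at 0 |

Raising `max_gap` or the mismatch budget never removes a hit or pair
(monotonicity; property-tested).

## The IPCR assay model

The simulated protocol is: XbaI digestion → apoptotic blunt break
(optional) → Klenow fill-in → circularisation → secondary digestion (AgeI
alone, AgeI+EcoRI, or AgeI+BsaAI) → two nested rounds of exact-annealing
PCR. Enzymes use the standard REBASE definitions (XbaI `T^CTAGA`, AgeI
`A^CCGGT`, EcoRI `G^AATTC`, BsaAI `YAC^GTR` blunt); the assay names the
enzymes and the simulator supplies their recognition chemistry.

**Overhang arithmetic.** Fragments are represented as top-strand
cut-to-cut intervals. An upstream XbaI end already carries its
overhang-derived `CTAG` bases on the top strand, so fill-in completes the
bottom strand without changing the sequence; a downstream XbaI end gains
`CTAG` on fill-in. Consequently an intact XbaI fragment circularises to
length + 4 with junction `...TCTAG|CTAGA...` — a 4 bp duplication. Note
that this does **not** regenerate a `TCTAGA` site: blunt ligation of two
filled XbaI ends destroys the recognition sequence, which is standard
fill-in biochemistry, and the simulator and its tests assert the
duplication junction rather than a regenerated site. A fragment with an
upstream XbaI end and a downstream apoptotic blunt end circularises with
no added bases; its junction reads `<break base>|CTAGA...`.

**Breakpoint convention.** `apply_break()` splits a fragment so the left
child ends at the breakpoint: the reported breakpoint is the last retained
base of the primer-proximal fragment. With the primer cassette at the 5'
end of the region of study (the geometry the synthetic reference uses), the
retained circle is `[region_start, b]`, and the nested product size is a
strictly increasing linear function of `b` — so `size_to_breakpoint()` is
an exact inverse, and the intact size (~3 kb for the 3.7 kb region with the
default cassette geometry) is the "no break detectable" ceiling.

**Template selection.** A circle is amplifiable when AgeI linearises it
exactly once. The elimination modes drop any circle whose amplified arc
still contains the eliminator's recognition site: intact circles always do
(the site is planted 3' of the expected break window), sufficiently cleaved
circles have lost it. This reproduces the assay's purpose — removing
competition from the abundant intact fragments — and its directionality:
the eliminator's position bounds the detectable break window.

**Annealing model.** Primers anneal by exact string match only, and each
must anneal exactly once on the circle. The assay's interpretation needs
positional logic, not thermodynamics; a mismatch-tolerant annealing model
is deliberately out of scope.

## Read mapping and junctions

Reads are anchored by greedy maximal exact matching: a 20 nt seed (the
`min_anchor` default; amplicon reads derive from the same reference, so
exact matching is the appropriate model and scoring-matrix alignment is
out of scope) at each uncovered read position, extended maximally, longest
extension wins, Watson preferred on ties.

Exact matching makes ligation and translocation junctions *ambiguous*
whenever the two joined contexts share leading bases — which is exactly the
microhomology phenomenon the junction analysis quantifies. The package
resolves the ambiguity by fixed conventions rather than silently:

* **Ligation junctions (breakpoint calls).** If the reference continuation
  past a break shares `j` leading bases with the region-start arm, the
  upstream block overshoots by `j` and the downstream block starts `j`
  into the region; the call subtracts the downstream block's offset, so
  planted breaks are recovered at base precision for every `j`.
* **Translocation junctions.** The 5' shared bases belong to the
  *insert* (so the host-gene breakpoint precedes them); the 3' shared
  bases belong to the *host gene*. The 5' microhomology is the longest
  shared prefix of the host continuation and the insert (capped at
  `max_k = 25`), the 3' microhomology the suffix analogue. Insert read
  intervals are 1-based inclusive; donor intervals are stored in both the
  inclusive and the end-exclusive convention, because the two arithmetic
  styles differ by one and both appear in practice — the package keeps
  both explicit rather than "fixing" either.

Uncovered read stretches shorter than 4 nt between blocks are junction
noise, not inserts; an uncovered stretch at a read end is a simple break,
not a shift translocation. Donor placement searches user-supplied partner
references (both strands) for an exact full-length hit; with no hit the
donor is `"unknown"` and only the insert geometry is reported.

## Cleavage statistics

The cleavage frequency is the mean number of cleaved-gene bands per
replicate, averaged within experiments and then across experiments, with
SD across experiments; the expected design is three independent
experiments of four to seven IPCR replicates (replicate counts outside the
configured range warn, not error). Group comparison uses the two-sided
equal-variance Student's t test (`stats::t.test`, `var.equal = TRUE`;
Welch by flag), significance at p < 0.05. The null calibration test draws
equal-mean Poisson counts (mean 5, n = 6 per group, 10,000 replicates) and
checks the rejection rate at α = 0.05 within ±0.01 — a band covering
Monte-Carlo noise plus the mild discreteness of small Poisson samples.

## The synthetic-data generator

The generator defines the package's study conditions:

* `random_sequence()` draws i.i.d. bases at a requested AT fraction
  (default 0.5); in motif-free mode, windows matching either MRS element
  are re-randomised to a fixpoint so every later hit is a planted one.
* `build_synthetic_abl()` reconstructs the gene-scale input: a 173,795 bp
  motif-free background carrying the packaged ABL MRS catalogue at its
  published coordinates and strands, an 11-exon synthetic gene model
  consistent with the catalogue's intron placements (intron 1 ≈ 140 kb),
  and the assay's region of study — a 3.7 kb XbaI fragment at
  128,301–132,000 with the primer cassette at its 5' end, AgeI in the
  cassette, EcoRI at 131,400 (so every break in the packaged 27-breakpoint
  table is detectable in AgeI+EcoRI mode), BsaAI at 131,700, and a `TGCC`
  junction motif at 130,001–130,004 for the translocation example. The
  exon boundaries, the SAR1 interval (129,000–134,000, chosen so that both
  the break cluster and the catalogue's site 9 fall inside it) and the
  region placement are synthetic reconstructions: the real gene's
  annotation file and SAR1 coordinates are not available to the package,
  so these are configuration, not ground truth, and are labelled synthetic
  throughout.
* `simulate_cleavage_reads()` is fully deterministic: each read is the
  nested product of the digestion–break–ligation–selection chain.
* `simulate_translocation_read()` plants an exact 5'-junction
  microhomology of `k` bases by editing its copy of the partner reference
  (edits recorded and returned), and guards the junction boundaries so the
  planted `k` is recovered exactly rather than extended by chance matches.
  The default read geometry (184 bp arm, insert, 586 bp arm) mirrors the
  packaged translocation example.
* `simulate_band_counts()` draws Poisson replicate counts around planted
  per-sample means (three experiments of six replicates by default).

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: sequencing and PCR errors (reads are error-free
consensus), incomplete digestion beyond a per-site cut-probability knob,
gel mobility and band intensity, polymorphism between the subject and the
reference, and genome-scale repeat structure (backgrounds are i.i.d.;
real intron 1 contains repeats that could produce additional MRS hits and
ambiguous anchors).

## Problem sizes

The default test and acceptance runs use: the full 173,795 bp synthetic
gene for the site scan; 200 random sequences of 2–5 kb for the brute-force
oracle comparison; planted MRS recovery over gaps −250..250 (step 10) at
both mismatch budgets; the 27-breakpoint IPCR round trip on the 3.7 kb
region; translocation recovery for k = 0..10; and 10,000 null simulations
for the t-test calibration. These sizes were chosen to exercise every code
path at the scale the analyses actually run at while keeping a full suite
run within a coffee break.

## Known limitations

* The scanner is the MRS criterion only; thermodynamic or AT-richness
  MAR/SAR predictors are out of scope.
* Exact-match anchoring cannot map reads from diverged references; that is
  a deliberate modelling choice for same-reference amplicons, not a
  limitation to be patched with a scoring matrix.
* The assay geometry assumes the primer cassette at the 5' end of the
  region of study. The simulator itself is general (templates, selection
  and products are computed from the circle), but `size_to_breakpoint()`
  and `call_breakpoints()` use the cassette-at-5'-end inversion.
* Configuration files are YAML (`read_run_config()`); the structured
  config format is a package choice and documented as such.
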