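---
title: "Methods: comparative plastome architecture with plastarch"
author: "plastarch authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative plastome architecture with plastarch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastarch)
```

# Scope and data model

`plastarch` analyses annotated circular plastomes. Internally everything is
0-based half-open; GenBank's 1-based inclusive coordinates exist only at the
I/O boundary, so interval arithmetic uses a single convention and the
conversion is isolated in one place. A `plastome_record` holds an uppercase
sequence over A/C/G/T/N plus ordered `gene_feature`s (normalized symbol,
strand, one or more intervals in transcription order, kind, pseudogene
flag). Ambiguity codes other than N are mapped to N with a warning: the
downstream statistics define behaviour only for the five-letter alphabet,
and undefined composition should not silently enter G/C or codon counts.

Gene names from heterogeneous annotations are forced into one symbol space
(`normalize_gene_name()`): lowercase three-letter stem with uppercased
suffix (`psbA`, `rpoC1`, `ycf2`), ribosomal RNAs as `rrn` stems, tRNAs as
`trnX-ANT` with an RNA-alphabet anticodon, plus a small alias table for
known spelling variants. Cross-genome comparisons (gene content, junction
tables, gene orders) presuppose exactly this shared symbol space. IR
duplicates are kept as distinct features; de-duplication happens only in
gene-order extraction, because junction tables need both copies.

# Inverted-repeat detection

The detector (`detect_inverted_repeat()`) returns the maximal-length pair
of disjoint intervals on the circle whose sequences are **exact** reverse
complements, with a minimum length (default 1,000 bp). Design choices:

* **Exactness.** The two IR copies of a single sequenced molecule are
  identical by construction, and exact identity makes "the maximal pair"
  well defined; no mismatch tolerance parameter is needed or offered.
* **Tie-break.** Among equal-length maximal pairs, the pair whose smaller
  start coordinate is smallest (then the smaller partner start) is chosen,
  so the result is deterministic.
* **Naming.** The longer single-copy arc is the LSC — naming is purely by
  length, not gene content, so no marker genes are required. Labels are
  assigned so the circle always reads LSC → IRA → SSC → IRB; all junction
  tables use that canonical linearization.
* **Failure is a result.** A genome with no qualifying pair is reported as
  "IR not detected" (`NULL`), not forced into a quadripartite model; the
  default 1 kb floor avoids promoting incidental short repeats.

The implementation hashes k-mers (k = min(min_length, 24)) of the circular
sequence against the reverse complement, extends each seed match maximally
along its complement anti-diagonal, and examines each maximal run once. On
circles small enough to enumerate, the result is tested against a
brute-force scan over all interval pairs; on generated genomes the planted
interval must be recovered exactly, for every seed.

Per-region G/C (`region_stats()`) counts G+C over A+C+G+T with N excluded
from both numerator and denominator; the genome total counts both IR
copies, so `lsc + ssc + 2·ir = total` is an exact integer identity.

# Gene order comparison

Signed gene orders are circular sequences of oriented symbols. With
`collapse_ir = TRUE` the IRB copy of duplicated genes is dropped so symbols
are unique; duplicated symbols outside the IR are an error rather than a
guess. tRNAs are included by default because documented inversion endpoints
are tRNAs.

`breakpoint_distance()` counts signed adjacencies of one order absent from
the other, with `(x → y)` matching `(−y → −x)`; it is symmetric and zero
exactly on the equivalence class generated by rotation and whole-circle
flip. `synteny_blocks()` reports maximal runs of shared genes co-linear in
both genomes, labelled same-orientation or inverted; every inverted block
short of the whole circle is an inversion candidate with endpoint genes.
Blocks are maximal **on the circle** — a run is extendable across the
origin — which keeps the partition property exact (block sizes always sum
to the shared-gene count). Inversions are reported descriptively as
inverted blocks; minimal reversal scenarios (sorting by reversals) are out
of scope because comparative plastome work interprets individual shared
inversions, not rearrangement distances. Translocations are reported as
shared genes whose quadripartite region labels differ, with IR-partial
labels kept distinct — a gene whose 5' end has slipped into the IR is a
different observation from a gene wholly relocated.

# Indel coding and classification

Gap events enter the analysis by **simple indel coding**: each distinct gap
with identical start and end columns defines one binary character; taxa
with that exact gap score 0, taxa with nucleotides across the whole span
score 1, and taxa whose own gap strictly contains the span score `?`
(inapplicable — their sequence carries no evidence about this event).
Leading and trailing terminal gaps are missing data, never indels, and
excluded alignment columns yield no characters. The containment rule is the
standard resolution for nested gaps; plain presence/absence scoring leaves
them undefined.

Character fit to a reference tree is the minimum number of state changes,
computed by unit-cost Sankoff dynamic programming (exact for
multifurcations, root-invariant; `?` is free, taking whichever state
minimizes the count). Categories follow the step count: 0 = invariant, 1 on
a pendant edge = autapomorphic, 1 on an internal edge = synapomorphic,
2+ = homoplastic. With missing data, several edges can carry the single
step; the edge with the smallest clade is chosen, so a state confined to
one terminal is always autapomorphic regardless of where `?` taxa could be
placed. Autapomorphy is additionally computable tree-free (minority state
in exactly one taxon), and the two counts must agree for complete
characters — that identity is property-tested. The step count itself is
tested two independent ways: exhaustive enumeration of all internal
labelings (all topologies for up to 6 leaves times all binary labelings,
sampled topologies at 7–8 leaves — sizes chosen to keep the exhaustive
check exact yet quick), and phangorn's Fitch parsimony as an external
cross-check.

# Codon usage

ENc follows Wright's estimator: per amino-acid family of degree *k* with
*n* codons at frequencies *pᵢ*, homozygosity `F = (n·Σpᵢ² − 1)/(n − 1)`;
family averages `F̂k`; `ENc = n₁ + Σk Nk/F̂k` (universal code:
`2 + 9/F̂2 + 1/F̂3 + 5/F̂4 + 3/F̂6`), capped at the code's maximum of 61.
Families observed fewer than twice are dropped from their average; a
missing threefold average falls back to `(F̂2 + F̂4)/2` (the convention of
the classic CodonW implementation); any other missing or non-positive
average leaves ENc undefined (`NA`) rather than silently extrapolated. The
genetic code is the universal code by default and configurable (e.g. NCBI
code 11); changing it changes the family structure, so the code id is
carried in every profile. Per-taxon reports pool codon counts across genes
into one profile — one value per taxon, not an average of per-gene values —
after removing excluded columns and that taxon's gaps; a post-gap length
not divisible by 3 is a frame error by default (`frame = "trim"` drops the
remainder, for alignments whose partitions are not all in frame).

Two closed forms anchor the scale and are asserted exactly: uniform usage
within every family reaches the cap of 61 (finite-sample F̂k lies at or
below 1/k), and one codon per amino acid gives F = 1 everywhere, hence
2+9+1+5+3 = 20. The finite-sample behaviour of F is pinned by the
four-codon family with counts (2,2,0,0): F = (4·0.5 − 1)/3 = 1/3.

# Pseudogene and editing screens

`pairwise_screen()` aligns a candidate region to a reference CDS globally
with affine gaps (match +1, mismatch −1, gap open 5, extend 1 — alignment
parameters are conventional, configurable, and bypassed entirely when a
published alignment is supplied verbatim). Percent identity divides
identical columns by the **full** alignment length including gap columns;
this denominator is a stated, configurable choice since "percent
similarity" alone does not define one. Indel events are maximal gap runs in
either row. Stop-codon accounting translates the query in the frame
projected from the reference through the alignment — a decayed region has
no reliable frame of its own — counting stops before the final reference
codon and checking the first/last codons for start/stop. The accepted start
set defaults to the strict `{ATG}`; GTG/ACG acceptance is a flag, because
"undetermined start" as an editing hint presumes the strict test.
`edit_hint_scan()` applies the same codon tests to every annotated
non-pseudo CDS and reports undetermined starts, undetermined stops and
internal stops with positions; these are *hints* — confirming RNA editing
requires cDNA, which is out of scope. `find_orfs()` reports maximal
ATG-to-stop spans above a length floor in three or six frames.

# Synthetic data and what the tests show

Each generator takes an explicit integer seed (never global RNG state; the
global stream is saved and restored), and identical parameters + seed give
byte-identical output — determinism is itself a tested contract. The truth
logs are complete: they suffice to score the corresponding analysis
exactly, which is the acceptance mechanism for everything that cannot be
compared against published numbers.

* `gen_plastome()` assembles LSC + IRA + SSC + revcomp(IRA) from
  independent random sequence at a target G/C (met within one point, by
  rejection). Rejection also guarantees no incidental inverted repeat of
  50 bp or more outside the planted pair, which makes detector recovery
  tests exact rather than statistical. Genes are placed without overlap;
  IRA genes are mirrored into IRB.
* `gen_rearranged_pair()` applies non-overlapping signed block reversals
  and single-gene region relabelings to a random signed order, recording
  endpoint genes. Overlapping reversals are excluded by construction —
  detection of overlapping events is explicitly descriptive, not
  guaranteed.
* `gen_indel_alignment()` starts from substitution-free identical rows
  (substitution realism is irrelevant to gap coding and would only blur
  the truth) and plants Poisson-per-branch deletion/insertion events whose
  spans never share boundaries, never touch (adjacent gaps would merge
  into one run and shift character boundaries), start at codon boundaries,
  and in frame-preserving mode have lengths that are multiples of 3 —
  mirroring the 3-bp gene indels real alignments show. Events on pendant
  branches are autapomorphic truth, internal branches synapomorphic;
  deliberate homoplasy plants one span on two incompatible branches.
* `gen_codon_seq()` samples amino acids uniformly and codons from a
  bias-interpolated family distribution using common random numbers, so
  raising the bias parameter only switches positions toward the canonical
  codon and ENc responds monotonically; bias 1 collapses to one codon per
  family (ENc exactly 20).

What passing these tests does **not** show: the generators have uniform
base composition within regions, no substitutions, no rate heterogeneity,
no annotation errors, no nearly-identical (rather than identical) IR
copies, and no overlapping indel events. Results on real plastomes depend
on annotation quality and on the IR copies actually being identical in the
assembly; a genome whose submitted annotation disagrees with the detected
maximal exact repeat is a finding to report, not an error to suppress.

# Numerical and degenerate-input choices

* IR detection: seeds shorter than the requested minimum are never used
  (k = min(min_length, 24)); a circle shorter than twice the minimum
  cannot contain a disjoint pair and returns `NULL` immediately; runs that
  overlap on the circle are trimmed to the longest disjoint sub-pair on
  the same diagonal.
* Indel coding drops candidate spans with no observed 1 or no observed 0
  (they carry no comparative signal), and disambiguates duplicate labels
  (two events starting at one column in different taxa sets) with a
  numeric suffix.
* `enc()` requires at least one estimable family; an empty profile is an
  error, an unestimable one is `NA` with a warning. Reports round to 2
  decimals only at the table boundary.
* Breakpoint distance and synteny blocks require at least two shared
  genes; genome-specific genes are dropped with a logged message, never
  silently.
* The pipeline isolates stage failures: a failed stage is recorded in the
  JSON run log and later stages still run; report TSVs carry no
  timestamps, so identical inputs and seed reproduce identical bytes
  (timings live only in the run log).

# Problem sizes used by the test suite

Exhaustive oracles run where exhaustion is exact and cheap: all unrooted
topologies to 6 leaves × all binary labelings for parsimony, all-pairs
scans on circles of a few hundred bp for IR maximality. Statistical
recovery runs at 100 seeds for planted IRs (2.3 kb circles) and planted
reversals (30-gene circles), 20 seeds × 5 bias levels for ENc
monotonicity, and 10–20 seeds for end-to-end indel recovery on 5–7 taxon
trees. These sizes were chosen so each property is either exact or has
negligible sampling slack while the whole suite stays quick to run.

# Known limitations

* IR detection assumes the two copies are exactly identical; assemblies
  with a handful of within-IR differences will report the longest exact
  sub-repeat instead. Both the annotation-derived and the detected IR can
  be compared by the caller; the package does not decide which is "right".
* Simple indel coding cannot distinguish two independent events that
  happen to share both boundaries; they become one character (that is the
  standard convention's known blind spot, and the deliberate mechanism of
  the generator's homoplasy mode).
* Single-step characters with missing data can admit several placements;
  the smallest-clade rule is a convention, and classifications are always
  relative to the one supplied tree.
* ENc is undefined for very short sequences (most families unobserved);
  per-gene ENc on short genes should be interpreted accordingly.
* The label spelling shared between matrices and trees is the caller's
  responsibility via the explicit `label_map` hook; no fuzzy matching is
  attempted.
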