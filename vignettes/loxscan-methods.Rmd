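---
title: "Methods: detecting and quantifying loxPsym-mediated rearrangements"
author: "loxscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and quantifying loxPsym-mediated rearrangements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and the choices
behind them: what each stage computes, which parameters matter, what the
simulator does and does not emulate, and where the design was genuinely
open.

## The measurement model

A genome carries L distinct loxPsym loci. Each locus i contributes two
flank sequences: U_i, the `flank_len` bases ending immediately before the
34-bp motif, and D_i, the `flank_len` bases starting immediately after it
(tandem motif copies at one locus are collapsed — at flank resolution a
junction between two co-located copies is indistinguishable from the
parental configuration, so multi-copy loci are treated as one locus).
Cre recombination between loci i and j fuses two flank *ends*; since the
motif is palindromic, all four end pairings are possible. The junction
reference pool therefore holds:

* L parental entries `{u_i, d_i}` (sequence `U_i + lox + D_i`), and
* 4·C(L,2) novel entries, one per end pair `{u_i,u_j}`, `{u_i,d_j}`,
  `{d_i,u_j}`, `{d_i,d_j}` with i ≠ j.

Same-end self pairs (`{u_i,u_i}`) are excluded by default so that pair
accounting matches C(L,2); they arise transiently from inverted
duplications and excision circles and can be enabled with
`build_junction_pool(..., include_self = TRUE)`. An entry and its reverse
complement denote the same junction; the canonical sequence reads
left-flank + motif + right-flank with ends ordered by (locus, side), the
left flank being U_a for side u or revcomp(D_a) for side d.

Pool entries are *composed on demand*: the pool object stores the flank
library and the end-pair table, so building an 11,175-entry pool for 75
loci is bookkeeping, not string assembly.

## Read classification

Motif occurrences in reads are found with a Myers bit-parallel
edit-distance scan (`max_lox_edits`, default 4 on the 34-bp motif, ~12%
divergence). Occurrences are non-overlapping, best first; palindromy makes
a reverse-strand scan redundant. Each occurrence's left and right contexts
(up to `flank_len` per side) are then scored against the candidate flank
ends — 2L candidates per side: `U_i` and revcomp(`D_i`) on the left,
`D_j` and revcomp(`U_j`) on the right, which automatically covers both
read orientations. Scoring is a banded affine anchored-overlap alignment
(match +1, mismatch −1, gap open −2, extend −1; band 25% of `flank_len`),
anchored at the motif boundary with free outer overhangs.

Two implementation points matter:

* **Per-end decomposition.** A pool entry's score is the sum of its two
  end scores, so classification is linear in L instead of quadratic. A
  k-mer seed prefilter (13-mers, diagonal-binned) shortlists candidate
  ends before alignment; ends sharing no diagonal-consistent seeds with
  the context cannot produce a qualifying alignment at these lengths and
  are skipped. The zero-error acceptance test verifies that this equals
  exhaustive search of every composed pool entry in every read.
* **Calling filters.** The best entry is called only when (a) its margin
  over the runner-up entry is at least `min_score_margin` (default 20
  score units — the internal analogue of an external aligner's MapQ
  uniqueness filter), and (b) each flank is covered to `min_flank_cov`
  (default 0.5). Ties and thin contexts (occurrences closer than
  `min_flank_cov · flank_len` to a read end) are UNCLASSIFIED — never
  assigned arbitrarily. Each occurrence contributes at most one count; a
  read spanning several occurrences contributes one count per occurrence.

The published coverage rule for retained read-to-pool matches is ambiguous
(whole entry vs one flank); this package uses a per-flank coverage
fraction, which is stricter and symmetric. That choice is deliberate and
documented here rather than attributed to the source protocol.

## Rate statistics

With Nnorm_i and Nre_i the normal and rearranged counts at locus i and
Nre_ij the per-pair counts:

* RR_i = Nre_i / (2·Nnorm_i + Nre_i). A normal read certifies both flanks
  of a locus while a rearranged read certifies one, hence the factor 2;
  Nall_i = 2·Nnorm_i + Nre_i is the locus' effective depth.
* RW_ij = Nre_ij / sqrt(Nall_i · Nall_j), zero when either Nall is zero.
  RR, ARR and RW are all invariant under uniform scaling of counts — the
  sequencing-depth normalisation property the statistic exists for, and a
  tested invariant.
* ARR: the published definition ("normalised to the total number of
  rearranged sites") admits at least two readings. The default here is
  the *partner-count* reading: the class-restricted rate
  Nre_{i,class}/Nall_i divided by the number of possible partner loci of
  that class (n_chrom(i) − 1 for intra, L − n_chrom(i) for inter). This
  makes intra and inter activity comparable per recombination
  opportunity, consistent with the expected-proportion argument that
  under uniform recombination intra events should make up
  ΣC(n_c,2)/C(L,2) of the total. The global-constant reading is available
  via `normalization = "total_rearranged"`; with per-class partner counts
  the two differ by a constant within a class, so group comparisons are
  unaffected by the choice.
* Outliers: upper-tail Tukey fence (Q3 + 1.5·IQR, type-7 quartiles). The
  source protocol does not state its outlier rule; this is the package's
  choice.
* Distance regression: OLS of RW on 1/d over intra pairs whose loci lie
  strictly on the same chromosome arm (both fully on one side of the
  centromere interval; centromere-spanning pairs excluded). d is the
  coordinate distance on the post-insertion reference.
* Group tests: intra- vs inter-ARR by two-sided Mann–Whitney (normal
  approximation with tie correction — exact enumeration is cross-checked
  in the tests); open- vs closed-chromatin inter-ARR by unpaired
  two-tailed t-test, a locus being "open" when its motif start overlaps
  any supplied interval. Contact-map utilities: Spearman correlation of
  RW against binned contact values over inter-chromosomal pairs, and the
  median-centred log2 ratio of two positive contact maps.

## Copy number and LOH

Each locus contributes an "up" and a "down" region: the `cnv_window`
(default 2000 bp) flank on either side. Depth is mean covered bases per
position, estimated by matching globally unique 16-mers of the window
sequences in each read (both orientations, dominant orientation per
read-window pair) — robust to reads clipped at junctions, and split by
whether the read contains the motif.

The integer caller reconstructs the iterative idea the source protocol
cites but does not specify; the reconstruction is the package's own.
Ratios r = depth_sample/depth_parent are scaled by s, initialised at
median(r); copy numbers CN = round(ploidy·r/s) (ties round half away from
zero); s is re-estimated as the median ratio over regions currently at
the modal ploidy, and the loop stops when assignments stabilise or after
`cnv_max_iter` rounds. Ratios further than ±0.35 from an integer (in
CN units) are flagged low-confidence. The procedure is invariant to
uniform depth scaling.

Per-locus states then follow a precedence: **rearranged** (novel junction
calls touch the locus) > **absent** (CN 0) > **intact_lox** (parental
junction reads present) > **lox_lost** (parent carried the motif, zero
motif-supporting reads, flank depth persists — the LOH signature; "no
reads" is taken literally, i.e. zero classified motif calls at the locus)
> **wildtype_only**. SV hypotheses combine a supported novel junction
with the CN of the four involved flank regions: all at ploidy →
reciprocal translocation; gains and losses → non-reciprocal; gains only →
duplication insertion; intra-pair with lost interior flanks → deletion;
uniform chromosome-wide shifts → aneuploidy.

A note on precision: the sampling noise of mean depth over a 2-kb window
is ≈ 1/sqrt(coverage) *regardless of read length* (long reads make the
bases within a window almost perfectly correlated), and dividing by a
simulated parent multiplies the variance by 2. Reliable integer rounding
at a 0.5·(1/ploidy) step therefore needs deep sampling; the bundled
simulations use 200–300×. On real data the parent division instead
removes *systematic* mappability bias, which the simulator does not
model.

## Segment deconvolution

A parental chromosome with m loci defines m+1 segments, each with a head
(left end in parental orientation) and tail. Reads are first partitioned
by marker (PCRTag-style) content — approximate marker hits at
`max_edits`, strict majority wins, ties unassigned. Junction calls are
translated to segment-end observations (locus end u_k ↔ tail of segment
k; d_k ↔ head of segment k+1); occurrences where only one side matches a
segment flank (e.g. homology-mediated fusions to non-segment sequence)
go to an unassigned report instead of being dropped.

Reconstruction treats each segment copy as an edge between its two ends
and each observed junction as an edge between ends, and enumerates
alternating trails that place every copy exactly once and realise every
retained junction at least once — the Eulerian-path view. Topology is
decided by free end slots (copy number minus junction incidences): two
free slots give a linear arrangement whose termini are the free ends,
zero gives a circle. Enumeration is deterministic (sorted end order),
capped at `max_alternatives` (default 16) with an ambiguity flag; with
repeated segments the true arrangement is guaranteed to be among the
alternatives, which is the strongest claim the observation multiset
supports. Junction support below `min_support` (default 2 reads; 1 in
zero-error settings) is discarded as chimera noise. Global orientation is
anchored on a designated segment (the centromere-containing one if
given, else the lowest placed id) held in + orientation; a linear
arrangement and its reverse complement are the same molecule and are
reported once. Inconsistent inputs (incidences exceeding copy numbers,
odd free-slot counts) raise errors listing the offending ends rather
than guessing.

## The simulator, and what passing tests do (and do not) show

`make_toy_genome` draws i.i.d. bases at a target GC (default 0.38);
`insert_lox` splices motifs with coordinate bookkeeping; `apply_events`
applies deletions, inversions, tandem and inverted duplications,
reciprocal and non-reciprocal translocations, circularisations,
aneuploidies and LOH conversions sequentially, re-resolving sites against
the current genome so composed simulations stay consistent. Every event
records the junction end-pairs it creates; after all events the log also
records every junction realised in the final genome — later events can
destroy earlier junctions, and recovery is always scored against the
surviving set. Physical bookkeeping notes: a tandem duplication of the
interval (i, j) creates the junction `{d_i, u_j}` (also the excision
circle's junction); an inverted duplication creates a self pair
`{u_j, u_j}` plus `{d_i, d_j}`; a circularisation keeps the inter-site
segment as the circle and loses the distal parts.

Reads have lognormal lengths (default median 8 kb, min 500 bp), uniform
strand and start positions (circular chromosomes wrap), and i.i.d.
per-base substitution/insertion/deletion errors (defaults 3%/1%/1%).
Reads are emitted until the error-free base total reaches the requested
coverage. This emulates nanopore-like data for junction-detection stress
tests; it deliberately does **not** model homopolymer-dependent error,
chimeric reads, base-caller quality scores, mappability structure or
recombination-rate heterogeneity. Passing the bundled round trips
therefore demonstrates correctness of the junction logic, the counting,
the CNV arithmetic and the reconstruction under realistic error *rates* —
not robustness to every artefact of real flow cells.

The bundled strain layout (`sparlox_sites()`) is a synthetic stand-in for
the engineered 83-site strain: per-chromosome locus counts chosen so the
2775 locus pairs split 210 intra / 2565 inter, positions spread to a
145 kb mean adjacent spacing on the standard chromosome lengths, 83 total
sites over 75 distinct loci, at least two per chromosome. Its summary
statistics are the strain's; its coordinates are not.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: a 5-chromosome, 2.5 Mb
genome with 20 loci and 10 planted events (one of each kind plus repeats)
read at 20× with 5% total error for junction recovery; the same scenario
at zero error for flank-length robustness (500/1000/1500/2500 bp must
yield identical junction sets); a 3×150 kb hetero-diploid with planted
CN ∈ {0,1,2,3} and two LOH conversions at 200–300× for copy-number
recovery (see the noise argument above); exhaustive enumeration of all
signed arrangements of up to 6 segments (55,144 reconstructions) plus all
circular arrangements of up to 4; and 20,000 null recombination draws on
the 75-locus layout for the intra-fraction fixed point. Alignment
tolerances, the ±0.35 low-confidence band, the 20-unit score margin and
the 0.5 coverage fraction are stated above with their rationale; seeds
enter only through the documented `seed` arguments, and the acceptance
script derives every stream from its `--seed`.

## Known limitations

* The classifier's seed prefilter assumes flanks are locally unique; in
  genomes with near-identical flank pairs (segmental duplications) the
  margin filter will mark the affected occurrences UNCLASSIFIED rather
  than resolve them.
* LOH calling requires a lox-free homolog whose flanks match the
  lox-bearing haplotype; diverged homologs (real heterozygosity beyond
  the motif) are not modelled.
* Deconvolution reports incomplete junction coverage as an error instead
  of guessing; chromosomes whose rearrangement removed all anchoring
  junctions for a segment cannot be placed.
* The CLI wrapper is a convenience; the R functions are the interface.
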