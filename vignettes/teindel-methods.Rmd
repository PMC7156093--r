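---
title: "Methods: TE-anchored discovery and mechanistic classification of large indels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TE-anchored discovery and mechanistic classification of large indels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Allopolyploid wheats accumulate large structural differences — deletions up
to the megabase scale, segment replacements, tandem copy-number changes and
inversions — particularly on the differential B sub-genome. Because
gypsy-superfamily LTR retrotransposons such as *Fatima* are abundant and
dynamic there, an insertion present in one assembly (e.g. wild emmer) and
absent from another (e.g. bread wheat) is a cheap, high-yield anchor for
finding such rearrangements: the insertion's flanks locate the orthologous
locus, and the way the flanks rejoin in the other genome records how the
intervening DNA was lost. `teindel` implements that procedure end to end,
and classifies every junction by the DNA-repair mechanism its sequence
signature implies.

## Pipeline model

1. **Retrieval** (`retrieve_insertions`). Element copies are found by
   homology to a consensus, chained per locus, structurally classified
   (full length / truncated / solo LTR), and captured with 500 bp of flank
   on each side. The significance statistic is an ungapped
   Karlin–Altschul expectation on the best block score with a permissive
   cutoff (1e-3); end boundaries carry a 20-base tolerance.
2. **Cross-genome matching** (`match_insertions_across_genomes`).
   Full-length insertions are paired by best reciprocal flank similarity;
   the score is total matched bases across both flanks, and the default
   cutoff (300 of up to 1000) stands in for a stringent alignment e-value,
   which is tool-specific. Two donor insertions whose flanks both match one
   derived insertion flag a candidate tandem duplication rather than being
   dropped.
3. **Ortholocus location** (`chromosome_walk`). For unmatched (candidate
   species-specific) insertions, flanking sequence is grown geometrically
   (5, 10, 20 kb … up to 5 Mb — covering the multi-megabase class of
   indels) and aligned to the partner chromosome until significant anchors
   bracket the locus on both sides. Because solo LTRs and other repeats can
   anchor to the wrong copy, the anchor *pair* is chosen by gap-geometry
   consistency: a deletion may shrink the derived-side gap to nothing (or
   overlap it by a junction repeat), but may not enlarge it beyond a
   bounded insert.
4. **Polymorphism triage** (`classify_polymorphism`), cheapest and most
   exculpatory first: assembly artifact (an N run within 100 bp of a
   putative breakpoint — excluded from indel calling), empty site with a
   single TSD copy, internal/chimeric deletion of the element itself,
   replacement by a non-homologous insert of at least 1 kb, and finally
   long-indel candidate.
5. **Breakpoint calling** (`call_indel`). Breakpoints are the inner borders
   of the outermost similarity blocks flanking the locus, on both genomes;
   lengths follow the 1-based closed convention (`end - start + 1`,
   `interval_length`). Tandem copy number is read off the off-diagonal
   blocks of each locus against itself; inversions are maximal runs of
   reverse-orientation blocks collinear in reversed order, gated to lie
   between the anchors on *both* genomes so that a reverse-strand element
   that is simply deleted does not masquerade as an inversion.
6. **Junction classification** (`classify_mechanism`), with documented
   precedence: copy-number variation; replacement by a foreign insert
   (introgression when the insert has no similarity block against the
   donor or any supplied reference genome); flanking direct repeats of at
   least 100 bp at 95 % identity (unequal intra-strand recombination, or
   inter-element LTR recombination when both breakpoints lie in
   same-family, same-orientation LTR annotations); a templated net
   insertion explained by SD-MMEJ reconstruction; a 1–9 bp microhomology
   retained in a single copy (MMEJ); otherwise blunt/C-NHEJ-or-ambiguous.
   All evidence is retained regardless of the final label.

## The similarity-block primitive

Breakpoints are only as sharp as the dot-plot primitive underneath, so its
definition matters. A block is a gapless pairing of equal-length intervals
such that

* every 100-bp window inside it meets the identity threshold (0.95) — the
  "95 % identity at a word size of 100" criterion that defines
  high-similarity regions;
* the block as a whole meets the threshold, with N counting as a mismatch
  and identity's denominator being the block length;
* **ends are anchored**: every terminal sub-segment also meets the
  threshold, which at 0.95 forces roughly 19 exactly matching bases at
  each border.

The last rule is deliberate. Under a plain mean-identity criterion a long
high-identity block can absorb hundreds of random trailing bases before its
average dips below threshold, smearing every breakpoint; end anchoring pins
borders to the last clean stretch, at the cost of trimming up to ~a window
length from a ragged tail. The test suite checks the implementation against
an exhaustive window-pair scan under exactly these semantics: blocks lie
inside the window union and cover it up to a bounded per-end loss. Blocks
are seeded by exact k-mers (k = 12 by default; any qualifying 100-bp window
at 95 % contains an exact 15-mer, so the seed loses nothing at the default
thresholds) and extended with prefix-sum "farthest qualifying endpoint"
jumps. Overlapping maximal blocks are all kept; downstream code chooses.

When the two junction sides share a repeat, the flanking blocks overlap on
the derived genome. The overlap is reported as `ambiguity_width`,
breakpoints follow the leftmost-placement convention, and the donor bases
actually removed equal `a_length + ambiguity_width` — this normalization
makes deletion lengths exact even when the repeat copies are diverged,
because the border slack cancels between the two genomes.

## SD-MMEJ reconstruction

Synthesis-dependent MMEJ explains junction "filler" DNA: a short primer
repeat at a broken end anneals to a nearby template, limited synthesis
copies a tract, and the new end anneals to the other side via junction
microhomology. `reconstruct_sdmmej` enumerates every explanation with at
most two rounds: primer repeats are suffixes of the broken end (1–8 bp),
templates are searched within 35 bp of either breakpoint (the worked
distances in wheat junctions are 12–29 bp), in direct (loop-out) and
inverted (snap-back) orientation and from either broken end. A
reconstruction is valid only if flank + explained insertion + flank equals
the derived junction exactly; the tract must equal the net insertion plus
the junction microhomology. Primer-plus-tract templates shorter than 4
bases are not counted as evidence — below that, matches are chance.

Ranking is by fewest rounds, then **longest junction microhomology**, then
shortest synthesis, then smallest primer distance. Putting microhomology
before synthesis length is a deliberate choice: the annealing step is the
mechanistically selective one, and the shortest-synthesis alternative for a
junction like the worked one-round case (tract `AATT`, 1-bp microhomology)
explains the same junction with less evidence than the full
`AATTTG`/`TTG` reconstruction. Apparently blunt junctions are also searched
(net insertion empty); a valid reconstruction is reported as a note, but
the label stays `blunt_cnhej_or_ambiguous` because blunt C-NHEJ cannot be
excluded. The classifier tolerates the microhomology regime boundary
explicitly: 1–9 bp is MMEJ; 100 bp at 95 % is recombination; the 10–99 bp
gap gets an "intermediate homology" note and the ambiguous label.

## The simulator and what it does (not) show

`simulate_genome_pair` builds an ancestor of i.i.d. background at 46 % GC
(wheat-like) carrying TE copies of a synthetic consensus, then derives the
second genome by mechanism-explicit surgery with recorded ground truth.
Each deletion-class event contains a full element copy so that it is
discoverable from insertion polymorphism, exactly as in the real
procedure. Default desk-scale study conditions, chosen once:

* consensus 3 kb with 300-bp LTRs (a scaled stand-in for a ~10-kb gypsy
  element with ~473-bp LTRs); per-copy divergence 2 % (5 % in the
  retrieval stress test, the upper end of "recent" insertions);
* deletions of ~5 kb, tandem units of 6 kb, foreign inserts of 2.5 kb,
  inversions of 8 kb, N runs of 500 bp (artifacts are reported only
  qualitatively in real data); TSDs drawn uniformly from 4–6 bp, as no
  canonical TSD length exists for the anchor family;
* direct repeats for unequal recombination: 300 bp at 99 % identity
  (matching the reported 99 % repeat identity at characterized loci);
  microhomologies of 4 bp unless specified;
* junction guard bases: the background adjacent to each planted junction is
  forced to differ from the characters that would let the recorded leftmost
  placement slide or let a flanking block chance-extend across the
  junction. Truth is therefore exact, not approximate.
* the standard validation workload (`mechanism_suite_specs`) plants six
  events per mechanism across six 130-kb chromosomes; the retrieval test
  uses 100 copies on a 700-kb chromosome and a 1-Mb TE-free genome for the
  false-positive check. These sizes keep a full run in minutes while
  leaving every event's footprint isolated.

i.i.d. background makes 100-bp/95 % blocks statistically impossible by
chance, which is the property the block thresholds rely on. Real genomes
are not i.i.d.: nested and fragmented repeats, segmental duplications, and
assembly gaps all make anchoring harder than in simulation, so a diagonal
confusion matrix here demonstrates correctness of the machinery, not
expected field accuracy. Genome-scale counts (thousands of insertions,
species-specific fractions, per-locus TE percentages) depend on the actual
wheat assemblies and are out of scope.

## Numerical choices and degenerate inputs

* All internal coordinates are 1-based closed; BED input/output converts at
  the boundary (0-based half-open), and report headers state the
  convention.
* Identity denominators are block lengths; N never matches.
* A derived-side junction remnant of at most 100 bp separates "deletion"
  from "replacement", but homology comes first: a multi-kilobase remnant
  that is itself homologous to the donor flanks (the recombined repeat) is
  still a deletion.
* Calls whose breakpoints abut a run of Ns are demoted to likely assembly
  artifacts and flagged low-confidence rather than silently emitted;
  partial anchor support yields a flagged partial call.
* Percentages (TE content) are reported to two decimals.
* SNP tolerance near junctions is a known limitation: anchor matching in
  the SD-MMEJ search is exact, so a polymorphism inside a signature motif
  can hide a reconstruction that manual inspection would accept.
* `event_spec` placement is automatic and non-overlapping; colliding
  explicit placements and out-of-bounds events fail loudly with the event
  ids involved.

## Reproducing the validation

`scripts/acceptance.R --seed N --out results/acceptance.json` regenerates
everything the package claims: the 22 locus-length cells from printed
coordinates, the worked junction signatures, the 42-event end-to-end
mechanism recovery (with breakpoint and length accuracy), and TE-retrieval
recovery/false positives. The same checks run as `testthat` tests, with
brute-force oracles (window-pair scans, an independent SD-MMEJ enumerator,
a plain Smith–Waterman, direct string surgery) computed alongside.
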