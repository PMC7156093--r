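# teindel

Transposon-anchored discovery and mechanistic classification of
large-scale genomic rearrangements between two related genome assemblies.

## The problem and who this is for

Comparative genomics of closely related assemblies — the motivating case is
the B sub-genome of allopolyploid wheats (wild emmer vs bread wheat) —
turns up deletions, replacements, tandem copy-number changes and inversions
from kilobases up to megabases. Abundant, dynamic LTR retrotransposons
(gypsy families such as *Fatima*) make excellent anchors for finding them:
an element present in one genome and absent from the other marks a locus
worth inspecting, its 500-bp flanks locate the orthologous site, and the
sequence at the rejoined junction records *how* the DNA was lost.

`teindel` is for researchers who want that whole procedure as tested,
reusable code:

* **retrieve** element copies matching a consensus (with flanks, structure
  class, TSDs);
* **match** insertions across genomes by flank similarity and find
  species-specific ones;
* **locate** orthologous loci by chromosome walking (geometric steps up to
  5 Mb);
* **call breakpoints** at the borders of gapless similarity blocks
  (≥ 100 bp at ≥ 95 % identity, the dot-plot criterion), plus tandem
  copy-number variation from self dot plots and inversions from
  reverse-orientation block runs;
* **classify each junction** by its inferred DNA double-strand-break
  repair mechanism.

## The classification model

Junction signatures map to mechanisms with documented precedence:

| signature | inferred mechanism |
|---|---|
| flanking direct repeats ≥ 100 bp, ≥ 95 % id | unequal intra-strand recombination |
| …and both breakpoints in same-family, same-orientation LTRs | inter-element LTR recombination |
| templated net insertion reconstructible by limited fill-in synthesis | SD-MMEJ (synthesis-dependent microhomology-mediated end joining) |
| 1–9 bp microhomology retained in a single copy | MMEJ |
| long non-homologous replacement insert | introgression |
| junction overlap spanning a tandem unit | copy-number variation |
| none of the above | blunt / C-NHEJ or ambiguous |

The SD-MMEJ reconstructor enumerates every explanation with ≤ 2 synthesis
rounds: a primer repeat (suffix of a broken end) anneals to a template
within 35 bp of either breakpoint (direct loop-out or inverted snap-back),
synthesis copies a tract *t*, and the junction microhomology μ (a prefix of
the far flank) closes the break, so that `tract = net_insertion + μ` and
`flank + net_insertion + flank` reproduces the derived junction exactly.
Deletion lengths follow the 1-based closed convention
(`interval_length(start, end) = end − start + 1`), and junction-repeat
ambiguity is reported explicitly: donor bases removed equal
`a_length + ambiguity_width`.

A mechanism-explicit simulator (`simulate_genome_pair`) generates genome
pairs with recorded ground truth for all eleven event types (the seven
repair mechanisms above plus full/empty TE sites, internal deletions,
assembly artifacts and inversions), so every stage is validated against
truth at desk scale.

## Worked example

```r
library(teindel)

cfg <- sim_config(n_chromosomes = 2, chromosome_length = 120000,
                  event_specs = lapply(c("unequal_recombination", "mmej",
                                         "sdmmej", "blunt", "introgression",
                                         "tandem_duplication"), event_spec),
                  seed = 7)
pair <- simulate_genome_pair(cfg)
rep <- run_pipeline(pair$genome_a, pair$genome_b, cfg$te_library[[1]],
                    te_annotation = pair$te_annotation)
rep$summary[, c("locus_id", "chromosome", "a_start", "removed_length",
                "b_length", "rearrangement_type", "mechanism",
                "microhomology")]
```

```
locus_id      chromosome  a_start  removed_length  b_length  rearrangement_type     mechanism                 microhomology
cnv_ins_0015  chr2        34730    6000            0         copy_number_variation  cnv_duplication
ins_0001      chr1         9950    5300            0         deletion_in_b          unequal_recombination     CTAAACTCA
ins_0002      chr1        26093    5000            4         deletion_in_b          sdmmej
ins_0003      chr1        39073    5000            2500      replacement            introgression
ins_0012      chr2         6016    5004            0         deletion_in_b          mmej                      TCGC
ins_0013      chr2        16164    5000            0         deletion_in_b          blunt_cnhej_or_ambiguous
```

One row per characterized locus: every planted event is recovered with its
mechanism; `removed_length` is the ambiguity-normalized donor loss (e.g.
5004 = a 5000-bp core plus the 4-bp `TCGC` microhomology retained in a
single copy at the junction), and `b_length` the derived-side junction
remnant (4 = the SD-MMEJ filler insertion; 2500 = the foreign introgressed
segment).

The bundled worked junctions behave the same way on curated wheat loci:

```r
wx <- worked_junction_examples()
reconstruct_sdmmej(list(left = wx$`3B_2`$left, right = wx$`3B_2`$right),
                   "AAT")[1, ]
```

```
 rounds primer_repeat synthesis_tract junction_microhomology net_insertion
      1             A          AATTTG                    TTG           AAT
```

i.e. the `AAT` filler at that junction is explained by the terminal `A`
priming on the upstream `AAATTTG`, six bases of synthesis, and annealing
via the `TTG` microhomology.

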