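---
title: "Splice junction calling, PSI quantification and synthetic validation"
author: "splicecall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splice junction calling, PSI quantification and synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicecall)
```

## The problem

Clinical RNA-seq panels need to flag splicing events that diverge from the
reference transcriptome — exon skips, the use of alternative 5'/3' splice
sites, retained introns and gene fusions — in *individual* samples, without
the large cohorts that outlier-detection methods require. `splicecall`
implements the analytical core of such a caller: it consumes deduplicated
gapped alignments (SAM/BAM), a genome (FASTA) and a transcript annotation
(GTF), and emits classified, quantified junction tables at tunable
stringency. A synthetic fixture generator makes every stage testable
without any external data.

## Coordinates and data model

A junction is stored as the 1-based inclusive *intron* interval — first
intronic base to last intronic base — matching the `SJ.out.tab` convention
of the STAR aligner, which keeps the package interoperable with the most
common upstream tool. The junction's "left" site is its first intronic base
and its "right" site its last; donor versus acceptor identity depends on
the strand. Every annotated intron contributes a left and a right site to
the splice-site index and one entry to the annotated-junction catalog;
sites are indexed per strand (two genes overlapping on opposite strands do
not share sites — the annotation does not resolve this ambiguity, so we
commit to the strand-aware reading), and a junction whose strand could not
be determined matches sites on either strand.

## Evidence collection

Each `N` CIGAR operation of a retained alignment record contributes one
observation to the junction spanning the skipped reference bases. Records
flagged unmapped, duplicate (deduplication is assumed upstream; the check
is defensive) or — unless requested — secondary are skipped, as are records
below `min_mapq` (default 0, since MAPQ conventions for unique mappers vary
across aligners). A gap flanked by fewer than `min_anchor` (default 5)
reference-aligned bases on either side is not counted: aligner overhang
filtering normally happens upstream, but the fixtures need a defined rule.
By default the two mates of a pair count as two observations (consensus
deduplication happens before alignment); `count_fragments = TRUE` collapses
them, since it is not obvious which convention an upstream pipeline
expects, and the choice is exposed rather than hidden.

Read-pair orientation is inferred from the paired / first-in-pair / reverse
flag bits under the declared protocol (`unstranded`, `forward` = FR,
`reverse` = RF) and aggregated per junction; the majority orientation
assigns the strand, ties and unstranded data yield `.`, and `.` junctions
are rescued by the canonical intron motif (GT–AG implies `+`, CT–AC
implies `-`) when the genome is available.

## The no-splice alternative

Splicing competes with not splicing. For every annotated and discovered
splice site the package measures the sequencing depth at a probe base
`nosplice_offset` bases *inside* the putative intron (default 3, i.e. the
3rd intronic base: position + 2 for a left site, position − 2 for a right
site). Only reference-consuming match states (M/=/X) count — a read spliced
(N) or deleted (D) over the probe base is not read-through evidence. This
read-through count enters PSI denominators as one additional alternative
and is reported as a `NoSplice` record at annotated sites (intron
retention, exon elongation) or a `Trivial` record at de novo sites.
Zero-depth read-through rows are kept only at sites that junction evidence
touches; sites never seen by any read would be zero-information rows and
are suppressed.

## PSI

For a junction $j$ and one of its two sites $s$,

$$\mathrm{PSI}_{s,j} = \frac{\mathrm{reads}_j}{\sum_{a \in A(s)} \mathrm{reads}_a}$$

where $A(s)$ ranges over every junction using site $s$ plus the no-splice
alternative. Each junction therefore carries *two* PSI values, one per
site; they answer different questions when the two sites face different
competition. PSI is undefined (reported `.`) when a site's total is zero.
Within any site group the PSI values sum to 1 by construction — this is
enforced by a dedicated property test. Denominators are per sample and per
site; sites are never pooled across strands. Orientation counts are
reported alongside but do not weight PSI, since it is not established how
mate orientations should enter the quantity.

## Refining novel junctions

When the bases flanking an intron repeat, the same read alignment is
consistent with several gap placements, and an aligner's arbitrary choice
can displace a novel junction away from the annotated site it actually
uses. Shift equivalence is defined purely on the reference sequence, as in
indel left-alignment — sliding the gap by $k$ preserves the concatenated
flanking sequence — so all reads of a junction shift together. Among the
equivalent placements the package chooses the one maximizing, in order:
number of annotated sites hit, membership in the annotated catalog,
canonical GT–AG motif, smallest absolute shift, leftmost position. The
last two tie-breaks are a committed convention: the smallest shift is
preferred because the aligner's placement carries information, and
leftmost resolves exact symmetric ties deterministically. Junctions whose
two sites are already annotated are never moved. The scan is capped at 100
bp as a guard against pathological repeats. If shifting makes two junction
keys collide their evidence is summed. Realignment is idempotent, never
reduces the number of annotated sites hit, and is tested against an
exhaustive brute-force enumeration on 1,000 random genomes.

## Classification

Junctions are classified by the annotation status of their two sites:
`Annotated` (both sites annotated and some transcript holds the pairing),
`Plausible` (both annotated, pairing novel — e.g. an exon skip),
`Anchored` (exactly one annotated — e.g. an alternative 5'/3' site),
`Unknown` (neither). Read-through records are `NoSplice` at annotated
sites and `Trivial` at de novo ones. The six classes are exhaustive and
mutually exclusive.

## Fusion candidates

Two evidence routes exist. A junction whose two sites are annotated in
disjoint, non-empty gene sets is a gap-evidenced candidate (same
chromosome by construction). A STAR-style chimeric junction table, when
provided, contributes candidates for breakpoint pairs on different
chromosomes, on incompatible strands, or more than `max_intra_dist`
(default 1 Mb — the choice is a package default, configurable) apart.
Without chimeric input only same-chromosome gap-evidenced fusions are
callable; this is a documented limitation, not a silent one.

## Filter tiers

Four stringency tiers gate the reported table: a record survives when its
class is reportable, `split_reads ≥ min_reads` and
`max(psi_left, psi_right) ≥ min_psi`:

| tier         | min_reads | min_psi |
|--------------|-----------|---------|
| none         | 0         | 0       |
| sensitive    | 5         | 0.01    |
| intermediate | 10        | 0.05    |
| stringent    | 20        | 0.10    |

These thresholds are this package's own defaults, chosen so that the tiers
are strictly nested and span the range from "show me everything novel" to
"high-confidence only"; they can be overridden per call or from a YAML
config. Reportable classes default to `Plausible`, `Anchored`, `Unknown`
and `NoSplice` — `Annotated` and `Trivial` rows appear only in the
unfiltered table, which is always written alongside. Filtering is a pure,
idempotent function of the records and the tier.

## The synthetic fixture generator

`make_reference()` builds a random-base chromosome carrying regularly laid
out multi-exon genes on alternating strands, with canonical splice motifs
written at every intron boundary so motif-based strand rescue behaves as on
real data. `plant_events()` draws at most one event per gene — exon skip,
multi-exon skip, intron retention, alternative 5' or 3' site at 12.5%
each, or no event at 37.5% — mirroring the class frequencies used in
published splicing-simulator benchmarks, with a true PSI drawn uniformly
from 0.2–0.8 (a realistic heterozygous-to-dominant range) and
alternative-site offsets of 4–20 bp into the intron.
`simulate_alignments()` emits coordinate-sorted paired SAM records mixing
the canonical and event isoforms.

One numerical choice deserves emphasis: the isoform of each fragment is
drawn with probability weighted by the number of valid fragment start
positions, not by the raw PSI. With raw per-fragment draws, a shorter event
isoform would produce proportionally more junction-crossing reads and the
realized junction-evidence fraction would overshoot the planted PSI; the
weighting makes the planted PSI the expected PSI *as measured at the shared
splice site*, which is the quantity the caller estimates.

What the generator does **not** emulate: sequencing errors (off by default
— the caller's arithmetic is error-agnostic), indels, soft-clipping,
multi-mapping, expression-level variation between genes (uniform target
depth), UMI structure, and GC or positional coverage bias. Passing tests
therefore demonstrate the correctness of the junction arithmetic,
classification, PSI computation and filtering — not robustness to
alignment artifacts, which belongs to the upstream aligner. One geometric
consequence of honest simulation: with the default 250 bp fragments and
100 bp reads, a short event isoform can yield zero junction-crossing reads
(the fragment ends simply never straddle the junction). The generator
counts the reads that actually evidence each event into a `support` column,
and recall statements condition on `support ≥ 10`, so such events are
excluded transparently rather than miscounted.

`score_calls()` compares caller output to the planted truth: exact matches
agree at both intron ends, near matches are within 10 bp at the worst end
(the tolerance used in published benchmark figures), retention truths match
`NoSplice` records at either flanking site, and reportable calls matched by
no truth are spurious. Read-through rows within tolerance of a
junction-truth end are absorbed as consequences of that truth — an
alternative-site event genuinely produces read-through at the displaced
boundary — rather than counted as false positives.

## Problem sizes and tolerances

The test suite and the acceptance script run entirely on generated
fixtures: 1,000 random site-group tables for PSI normalization (tolerance
1e−9), 1,000 random genome/junction pairs for realignment brute-force
equivalence, a 50-gene / 60× coverage fixture for end-to-end recall at the
published class frequencies, and a single-gene fixture with ~2,000
informative reads for PSI recovery at a planted value of 0.3 (tolerance 3
binomial standard deviations). These sizes were chosen so the full suite
completes in a couple of minutes on one CPU while every stage is exercised
at non-trivial scale.

## A worked example

```{r example, eval = FALSE}
ref <- make_reference(seed = 1, n_genes = 6, exons_per_gene = 5)
truth <- plant_events(ref, seed = 2)
sim <- simulate_alignments(ref, truth, depth = 60, seed = 3)

calls <- call_junctions(sim$sam, ref$gtf, ref$fasta,
                        tier = "sensitive", verbose = TRUE)
calls$filtered
score_calls(calls$records, sim$truth)$recall

## per-gene arc plot for a gene with filtered evidence
rep <- gene_report(calls$filtered, ref$models,
                   calls$filtered$genes_left[1])
rep$plot
```

## Known limitations

- Junction strand for unstranded libraries relies on the canonical motif;
  non-canonical novel junctions stay unstranded and match annotation on
  either strand.
- Fusion calling from gap evidence requires both breakpoints to hit
  annotated sites of different genes; fusions into intergenic space need
  chimeric input.
- The caller does not assemble composite events (a skip plus a retained
  intron in one gene appear as separate records); this is deliberate — PSI
  here is per junction per site, not per predefined event model.
- Whether upstream pipelines count reads or fragments differs; the default
  counts reads and `count_fragments = TRUE` switches, but the two settings
  give different denominators at mate-overlapping junctions.
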