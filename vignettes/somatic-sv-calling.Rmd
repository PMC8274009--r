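---
title: "Somatic structural variant calling with svkit: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Somatic structural variant calling with svkit: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svkit)
library(data.table)
```

## The problem

Somatic genome rearrangements in cancer leave two complementary footprints
in short-read sequencing: novel adjacencies (breakpoints, each made of two
breakends) and copy-number changes. A breakpoint can only be reported when
*both* of its sides map uniquely. When one side falls in a repeat array
(a centromere, a LINE insertion target, a satellite), breakpoint-only
callers drop the variant entirely. svkit implements a caller built around
three ideas:

1. **Single breakend variants.** A junction whose far side cannot be placed
   uniquely is still reported, anchored on its unique side, carrying the
   assembled but unplaceable sequence. Every copy-number transition should
   be explained by either a breakpoint or a single breakend; the fraction
   explained by neither estimates the caller's false negative rate.
2. **Positional de Bruijn graph breakend assembly.** All SV-supporting
   reads at a locus are assembled into a breakend contig *before* calling.
   Kmers carry reference-position constraints: clipped and split reads pin
   their kmers to the positions implied by the anchoring alignment, while
   mates of discordant or unmapped-mate pairs float within the interval
   allowed by the fragment-size distribution until shared kmers pin them.
3. **SV phasing.** A contig whose compound realignment spans several
   junctions phases them cis; a contig crossing one junction while
   aligning to the reference across another phases them trans. Imprecise
   "transitive" calls — spurious adjacencies between the outer ends of a
   chain of nearby real junctions — are collapsed onto the precise chain.

## Breakend conventions

Internally a breakend is `(chromosome, position, direction)` with 1-based
inclusive coordinates. Direction `HEAD` means anchored bases lie at
coordinates at or below the breakend (novel sequence continues to the
right); `TAIL` is the mirror. The position is the last anchored base. VCF
bracket notation is produced only at the serialisation boundary
(`write_vcf()`): HEAD/TAIL partners map to `t[p[`, HEAD/HEAD to `t]p]`,
TAIL/TAIL to `[p[t`, TAIL/HEAD to `]p]t`, and single breakends to `t.`/`.t`.

## Evidence model

Reads are admitted as evidence under the preprocessing rules: soft or hard
clips of at least 5 bp, indels of at least 5 bp (smaller ones are
reference-consistent), split reads whose every segment has mapping quality
at least 20, discordant pairs (template length outside the central 99.5%
of the proper-pair fragment-size distribution, estimated by direct
sorting), and reads with unmapped or sub-mapq-20 mates. Reads below mapq
20 are themselves treated as unmapped and contribute only through their
mapped partner. Reads with base-composition Shannon entropy below 0.5 bits
(a configurable default; the admission rule excludes homopolymer and dimer
junk while keeping AT-rich sequence) and clips matching bundled
Illumina adapter prefixes (exact for 6-11 bp of overlap, up to 10%
mismatches from 12 bp) are suppressed, as is all evidence in regions above
50,000x coverage.

Each item receives a phred-scaled quality
`min(mapq cap, -10 log10(empirical rate of the evidence signature))`, with
split reads capped by the mapping quality on both sides. Clip signatures
use the empirical per-read rate of clip operators at least as long as the
observed clip; in-range discordant pairs use the fragment-size tail
probability; distal pairs the discordant mapping rate; unmapped mates the
unmapped-mate rate. Zero rates are floored at one per observed read count.
The exact arithmetic by which these components combine into a variant
QUAL is a design choice of this package: assembled fragments contribute
their item scores (capped at 60) through the assembly (ASQ), and only
fragments *not* incorporated in a supporting assembly contribute through
the direct categories (SRQ/RPQ/IQ), so no fragment is double-counted.

## Assembly

Assembly runs per (chromosome, direction) cluster, mirrored so the anchor
always lies left. Clusters spanning several same-direction junctions
(for example the two ends of an inversion bridged by discordant-pair
intervals) are subdivided by clip position. The kmer size defaults to 25
(configurable; it must exceed the homopolymer runs expected in the data)
and kmer weight is the number of contributing reads — with uniform
simulated base qualities this is proportional to the summed-quality
weighting used on real data. The maximal-weight path is extracted
greedily with deterministic tie-breaks (lexicographic kmer, then leftmost
position). Contigs keep at most 300 bp of anchoring reference sequence,
are discarded above 1.5x the maximum fragment size or when fully
reference-supporting, and track per-fragment support intervals so that a
fragment only counts for a breakpoint when its support spans at least one
base beyond the homology interval on both sides.

Floating (mate-derived) kmers are pinned to the *leftmost* placement
consistent with their fragment-size window that shares kmers with
positioned sequence. This is what truncates assembly at unresolved repeat
loops: mates lying at unknown depths inside a tandem array collapse onto
the junction-proximal copies instead of phasing the array deeper, so
breakend contigs into repeats stay short — mirroring the behaviour that
makes mobile-element and satellite breakends resolvable as single
breakends rather than misassembled breakpoints.

## Realignment and homology

The built-in aligner performs exact full-length search plus a seeded
Smith-Waterman fallback (match 1, mismatch -4, gap open 6, gap extend 1 —
the scoring also used for inexact homology), with no clipping penalty.
Effective mapping quality is `60 * (1 - second_best/best)` clamped to
[0, 60], comparing only hits that compete for the same query bases: two
hits covering disjoint parts of a multi-junction contig are partial
alignments, not ambiguity. Compound realignment feeds soft-clipped
remainders back until nothing aligns; segments under 30 bp stay unaligned
as insert sequence, chains that do not overlap their originating locus are
discarded, and split bounds are adjusted to minimise (mismatches +
unaligned insert length), ties leftmost — which also un-aligns 1 bp
over-aligned non-template inserts. A HEAD-to-TAIL junction joining
adjacent reference positions with no insert is the reference allele and is
dropped.

Exact homology enumerates all junction placements producing an identical
alternate sequence (bounded at ±2 kb), left-aligns the call on breakend 1
and reports CIPOS/CIRPOS/HOMLEN/HOMSEQ. Inexact homology (IHOMPOS)
Smith-Waterman-aligns the breakpoint sequence against each breakend's
reference context, extended 300 bp from the break with the reference 10 bp
further; the homology length is the contiguous extension of the alignment
past the junction. Because the 10 bp over-extension exists to tolerate
small indels only, the extension stops at the first alignment gap longer
than 10 bp — otherwise a local alignment would happily jump a deletion's
gap and report the far flank as homology. Alignments soft-clipped on the
common-sequence side are ignored.

## Calling

Both passes (breakpoints, then single breakends) compute all maximal
cliques of the evidence compatibility graph — two items are compatible
when their breakend intervals and directions overlap on both sides — and
then allocate every item uniquely: first to a candidate supported by an
assembly containing the item's fragment, then to the highest-scoring
clique, then leftmost. CQ preserves the pre-allocation clique score.
Calls need two unique supporting fragments; intrachromosomal events under
the minimum event size (default 10 bp; 32 bp is the cohort-style setting)
are dropped unless inversion-like, so short foldback inversions survive.
Candidate single breakends require an assembled contig whose breakend
sequence has no unique alignment; they are suppressed within 10 bp of an
emitted breakpoint breakend explaining the same clip cluster.

## Somatic filtering

The filter is a set of pure predicates over the per-sample support
breakdown; the thresholds are fixed package defaults (3% normal support,
1000 bp short-event boundary, 8 normal fragments, 0.5% tumour AF, 16 bp
poly-C/G, 0.95 strand bias, 50 bp homology, 6 bp inexact homology on
100-800 bp deletions, 40 bp/6 bp inversion rule, 5 bp pseudo-deletion
margin with the 0.5/0.2 per-base edit-distance exemption, 2 bp PON
window with 75/428 aggregation quality, 350/1000 quality filter).
"Breakend coverage" in the normal is VF + REF (+ REFPAIR for
breakpoints); the VAF denominator is VF/(VF+REF+REFPAIR) for
breakpoints and VF/(VF+REF) for single breakends, since REFPAIR is
undefined at an unpartnered break. Simple-event annotation tests
reciprocal translocation, then templated insertion, then simple inversion
(pairs of inversion-like calls), a fixed documented order. Quality-filter
rescue closes transitively over assembly/SC/transitive links; equivalence
links never rescue. Two output sets are emitted: high confidence (PASS
only) and the sensitive low-confidence set (everything except hard
failures).

Transitive-path search is budgeted (100,000 paths, 1,000 per start) and
bounded to 1,000 bp, at most 4 junctions per path and segments of at
least 20 bp; paths cannot revisit a junction, and traversal expands
deterministically by segment length.

## The simulator and what it does (not) show

`simulate_sv_reads()` generates truth-placed SAM records from derivative
haplotypes: junction-crossing reads carry the soft clips a correct aligner
would produce, reads wholly inside a repeat array are placed at a random
unit with mapq 0, tumour reads are drawn from the tumour haplotypes with
probability equal to purity, and everything is deterministic under the
seed. Default conditions: 100 bp pairs, 300 +/- 30 bp fragments, 60x
tumour / 40x normal, purity 1, error-free bases. The bundled scenarios fix
the study conditions: 20 mixed rearrangements (>= 50 bp) in unique
sequence, ten junctions into a 50-copy repeat array, the 32-100 bp
duplication band with 9 bp minimum-size boundary events, and a clustered
three-junction chain with 100 bp segments.

What passing these scenarios shows: the geometry of the whole pipeline —
evidence extraction, positional assembly, compound realignment, homology,
clique calling, filtering, phasing — is correct on clean data at
realistic coverage, and the estimators recover planted rates. What it
does not show: robustness to sequencing error profiles, GC and coverage
bias, alignment artefacts of a real aligner, germline heterozygosity, or
microsatellite instability. Genome sizes are hundreds of kilobases so a
full run takes minutes; fragment-count statistics at junctions are
nevertheless the same as at scale because coverage, not genome size,
determines them.

## Worked example

```{r example}
cfg <- sim_config(
  synth_genome(c(chr1 = 40000L), seed = 5),
  sv_table("DEL", "chr1", 20000L, size = 500L),
  cov_tumour = 30, cov_normal = 20, seed = 9)
sim <- simulate_sv_reads(cfg)
res <- somatic_sv_pipeline(sim$tumour, sim$normal, cfg$genome)
res$high[, .(svtype, chrom1, pos1, dir1, chrom2, pos2, dir2, size,
             qual = round(qual), t_vf, n_vf, filter_status)]
```

The deletion is recovered at base-pair resolution with its full support
breakdown; `match_calls(res$high, sim$truth)` scores the call set against
the truth table under the 100 bp matching margin.

## Known limitations

* The quality-combination arithmetic and the mapq model of the built-in
  aligner are documented stand-ins; absolute QUAL values are not
  comparable to other callers, only their ordering and thresholds within
  this package.
* At 60x, single breakends into repeats score BQ near the 1000 quality
  threshold; some are emitted in the low-confidence set only. The
  1000-QUAL threshold is the default for deeply sequenced (100x) tumours
  and is deliberately not adjusted to the simulated depth.
* Insertions longer than `read_length - 2 * 30` bp leave no read with 30
  uniquely alignable bases on both flanks; they are reported as a pair of
  single breakends flanking the inserted sequence rather than as one
  breakpoint. This is a geometric property of short-read libraries, not a
  caller setting.
* Assembly processes each breakend cluster independently; there is no
  genome-wide streaming window, which is adequate at desk scale.
* Tumour-only calling runs (pass `normal = NULL`) but the somatic filter
  is designed for matched pairs.
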