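---
title: "Methods: tiled-amplicon haplotype reconstruction and structural-variant screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tiled-amplicon haplotype reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ampliphase)
```

# The problem

CD36 deficiency genotyping by exon-targeted Sanger sequencing has a blind
spot: a large heterozygous deletion removes an allele's primer sites, so the
intact allele amplifies alone and the deletion is invisible. `ampliphase`
implements the alternative strategy of sequencing a whole ~77 kb gene as
four overlapping long-range PCR amplicons with long reads, reconstructing
both parental haplotypes end to end, and reading structural variation
directly off the amplification pattern and the read alignments.

The pipeline has five stages:

1. **Allele clustering.** Reads of each amplicon are aligned to the locus
   reference, heterozygous sites are detected, and reads are partitioned
   into at most two allele groups.
2. **Consensus.** Each group is collapsed to a reference-anchored consensus
   sequence.
3. **Phasing.** Per-amplicon consensuses are chained across the >= 3 kb
   amplicon overlaps into two full-length haplotypes, using heterozygous
   variants shared by both flanking amplicons as junction evidence.
4. **Variant calling.** Each haplotype is diffed against the reference;
   calls are filtered to the reportable set (exonic, UTR, or intronic
   within 10 bp of an exon boundary) and samples are classified as
   homozygous / compound heterozygous / single heterozygous / none.
5. **SV resolution and screening.** A haplotype that amplifies some
   amplicons while a contiguous internal run drops out is an SV candidate;
   whole-locus reads resolve the exact breakpoints, and an in-silico
   gap-PCR screens donor cohorts for carriers of the resolved deletion.

# The synthetic study design

Real amplicon FASTQ can be supplied, but the package ships a fully seeded
generator that reproduces the geometry of the study design it emulates, so
every stage can be validated against known truth.

**Locus.** A 77,400 bp sequence with 15 exons (12 coding; translation start
in exon 3, 150 bp into the exon). The exon/intron layout is fixed; the
background sequence is seeded-random. Reference bases required by the
variant catalogue are stamped in — for example the `TATTGTGCCTATT` repeat
context in exon 13 that makes `c.1227delTATTGTGCCTAT` and
`c.1228_1239delATTGTGCCTATT` descriptions of the same edit, which is
exactly the alias pair the reporting layer must canonicalize (we 3'-shift,
so the second form is canonical).

**Panel.** Four amplicons of exactly 20,600 / 22,000 / 20,600 / 23,000 bp
(targets stated as 20.6/22/20.6/23 kb; placement tolerance ±50 bp) with
overlaps of 3,100 / 3,000 / 3,100 bp, using the study's primer sequences.
Each primer is verified to occur exactly once in the locus at up to two
mismatches; a background draw that violates this is regenerated.

**Truth structural variant.** The deletion-insertion removes exactly
19,971 bp starting at the position whose upstream-offset descriptor is
`c.1-15966`, replacing them with `CCAATGCTAAGGTTGA` (16 bp). Note an
internal inconsistency in the printed source coordinates this package had
to resolve: a span written `c.1-15966` to `c.120+3887` covers 19,973
positions, which cannot hold 19,971 deleted bases exactly. We anchor the
deletion length (19,971, the quantity every downstream number depends on)
and the left breakpoint descriptor; the right breakpoint then renders as
`c.120+3885`. The flanking reference bases are constrained so the junction
has no microhomology and the breakpoints are unambiguous.

Coordinate conventions: positions 5' of the CDS-containing exon use the
linear-genomic-offset form `c.1-K` (standard intron offsets cannot express
a breakpoint two introns upstream); intronic positions use nearest-boundary
`N+k`/`N-k` with ties going to the upstream `+` form; positions past the
CDS use `*K` linearly. `g_to_c()`/`c_to_g()` are exact inverses over every
locus position, which the test suite asserts by enumeration.

**Cohort.** `study_genotypes()` encodes the 43 deficiency samples
(14 type I, 29 type II; 86 haplotypes) verbatim; `make_study_cohort()`
materializes them. Each haplotype additionally receives background
heterozygous SNVs at a mean rate of 1/1,500 bp placed in deep-intronic
positions (away from exon boundaries, primer sites and engineered motifs),
plus two guaranteed het SNVs per amplicon overlap. The rate is the realistic
order of human heterozygosity and serves the same role natural polymorphism
serves in the real assay: it provides the within-amplicon sites that
separate alleles and the overlap sites that phase junctions. Because these
SNVs are deep-intronic they are invisible to the reportable-variant layer,
so they never contaminate cohort-level results. The deleted interval is
kept variant-free on SV haplotypes only (a variant inside a deleted segment
is not representable); partner haplotypes may vary there.

**Reads.** The amplicon error model is nanopore-like (2% substitution,
1.5% insertion, 2.5% deletion; 8 kb ± 2 kb reads), the whole-locus model
HiFi-like (0.2% each; 12 kb ± 3 kb). Read count follows
`depth x L / mean_length`; fragment starts are drawn over the extended span
`[2 - len, L]` and clipped, which makes expected coverage uniform across
the entire molecule (no edge ramp). The realized per-base coverage is
therefore `depth x L/(L + mean_length)`, about 0.72x nominal for the
amplicon geometry — thresholds below are set against realized coverage.
Quality strings are flat; truth labels (sample, haplotype, amplicon) ride
in the FASTQ comment and are used only for scoring, never by the pipeline.

What the generator does *not* emulate: PCR chimeras and recombination
artifacts, homopolymer-biased error profiles, barcode cross-talk, coverage
biases from GC or secondary structure, and mapping ambiguity from genomic
repeats (the background is random, hence essentially repeat-free at k = 21).
Passing tests therefore demonstrate algorithmic correctness under the
stated noise model, not robustness to every artifact of real data.

# Stage parameters and numerical policy

**Alignment** is delegated to minimap2 (`map-ont` / `map-hifi`, secondary
alignments off, `-Y` so supplementary records keep full sequence); the
module contract is the alignment table, not the engine. Alignments spanning
< 1 kb are dropped at QC.

**Heterozygous sites** (defaults): minimum covering depth 20, minor-allele
fraction >= 0.20, minor count >= 5. Indel alleles shorter than 5 bp are
collapsed with the reference key; longer indels become biallelic
presence/absence keys clustered across reads by placement (±3 bp). At
nanopore error rates, a 2% error base never reaches 20% minor fraction at
depth >= 20, and a balanced het site essentially never misses it.

**Clustering** seeds two signatures from the most dissimilar read pair
(ties to input order, so the procedure is deterministic), assigns reads by
signed agreement, then iterates a refinement pass — recompute per-site
majority signatures from current members, reassign every read — to a fixed
point (at most 6 passes). Iteration matters because an 8 kb read sees only
part of a 20 kb amplicon: each pass extends the phased span by about one
read length, and when the seed pair sits at one end of the amplicon a
single pass would leave the far tail — which is exactly a phasing overlap —
permanently unassigned. Reads covering no informative site are left
unassigned rather than dumped into cluster 1: forcing them in would poison
cluster purity with coin-flip assignments. Clusters smaller than
`min_reads = 5` are flagged low-support.

Two hygiene rules deal with the amplicon overlaps. A read contained
entirely in a shared overlap is ambiguous between the two flanking
amplicons (assignment ties go to the left-most); a "cluster" whose members
all lie inside an overlap is therefore debris and is dropped — without this
rule such debris can resurrect an amplicon that in fact dropped out. And
when a single cluster survives in an amplicon, the unassigned reads are
folded back into it: with one allele present they all belong to it, and
excluding them would leave coverage holes at the amplicon ends that break
junction matching.

**Consensus** is a per-reference-column plurality over the members' layered
alignments, with two deliberate biases toward the reference: ties and
columns below 3 covering reads take the reference base (no-call rather than
false call). Indels are voted as *events*, not columns: in repeat context
individual reads place the same deletion at shifted offsets, and a
per-column majority would fragment a 12 bp deletion into pieces. Deletion
events >= 2 bp and insertions are clustered across reads by placement, and
an event is written into the consensus only when one exact placement key is
shared by more than half of the covering members — scattered single-read
errors never produce one majority key.

**Phasing** scores each junction by the heterozygous variants inside the
overlap at which both flanking amplicons' cluster pairs differ, counting
each shared variant once, unweighted. A pairing is chosen only when one
orientation strictly dominates; otherwise the default pairing is used and
the junction is flagged ambiguous (a homozygous span genuinely cannot be
phased by this design — it is a property of the sample, not an error).
A single cluster facing a cluster pair is matched by the same evidence;
when it matches exactly one side, the unmatched side's amplicon is recorded
as a DROPOUT on the other haplotype. This sequence-based rule is what lets
the pipeline distinguish a homozygous amplicon (shared by both haplotypes)
from a one-allele amplification failure without using depth heuristics.
The exhaustive `2^(k-1)` chaining oracle is implemented for testing and
must agree with the greedy junction rule at every unambiguous junction
(they coincide because junction scores depend only on the relative
orientation at that junction).

**Haplotype diffing** chains unique 21-mers shared with the reference into
a collinear skeleton (query k-mers sampled at stride 7), aligns small
divergent gaps at base level (equal-length gaps up to 60 bp by direct
column comparison; otherwise Biostrings global alignment up to 300 bp per
side) and reports larger divergent blocks as single delins events — which
is precisely how a 19,971 bp deletion-insertion should surface. Edited
columns within 3 bp merge into one event before normalization, so junction
edits are not fragmented. All variants are 3'-shifted to canonical form;
applying the returned variants to the reference reproduces the input
sequence byte-for-byte, and the suite asserts this.

**SV calling** takes junction observations from two paths — deletion runs
>= 50 bp inside single CIGARs (indel ops bridged across chance matches of
<= 30 bp, which arise when part of the inserted sequence happens to anchor
inside the deleted interval) and same-strand primary/supplementary splits
with a reference gap >= 50 bp (segments shorter than 100 bp or below
mapping quality 10 are ignored) — clusters them at ±10 bp, and resolves
breakpoints by majority vote with the inserted sequence by plurality.
Because the aligner may represent the same physical junction in slightly
different ways for a minority of reads, resolved calls whose breakpoints
fall within 100 bp of a better-supported call are consolidated into it.
The call is shifted to its left-most equivalent placement and the shift
freedom reported as microhomology length. 50 bp is the conventional SV
size floor and keeps the caller disjoint from the small-variant differ;
minimum support is 3 junction-spanning reads; zygosity is heterozygous
when at least 3 non-junction reads span the middle of the deleted interval.

**Gap-PCR screen.** In-silico PCR finds primer sites allowing <= 2
mismatches but none in the 3'-terminal 5 bases (a minimal model of
extension specificity; no thermodynamics). The screening PCR's product
budget is 2,000 bp (short extension step) versus 25,000 bp for the
long-range PCR — this single parameter reproduces the assay logic: the
wild-type deletion-pair product (20,787 bp) always fails while the
deletion allele yields the 832 bp junction product; the 333 bp control
amplifies from intron 7 on either allele. Flank geometry: the printed
571/261 flank distances are measured on the deletion allele with the
16 bp insert inside the left flank (555 reference bases + 16), the only
reading consistent with the printed 832 bp product. Candidate carriers are
confirmed by sequencing the junction product in silico and requiring exact
breakpoint identity with the reference SV call; mismatching candidates are
demoted. The carrier-frequency interval is Wilson (not Wald — the estimate
is a small proportion near the boundary, where Wald collapses); invalid
samples stay in the denominator by default, matching a screen that reports
carriers over all donors screened.

# Problem sizes used in the shipped validation

The test suite and acceptance script run at sizes chosen to exercise every
code path at full fidelity while staying desk-scale: per-product amplicon
depth 20 (about 29x realized per amplicon, 14x per allele), whole-locus
depth 30 for SV calling with 8 extra seeded replicates at depth 25, the
complete 43-sample cohort at the truth level (all 86 haplotypes diffed and
classified), read-level reconstruction for representative genotypes of
every variant class, whole-locus SV false-positive screening over all 28
SV-free type II samples, and the full 600-donor gap-PCR screen with 3
implanted carriers. Sequencing-throughput figures of the emulated study
(tens of gigabases per instrument run) are hardware characteristics, not
algorithmic claims, and are out of scope.

# Known limitations

- Two alleles maximum per amplicon; a third cluster signals contamination
  and raises an error rather than attempting a mixture model.
- Phasing across a junction without informative overlap variants is
  reported ambiguous; no population prior or statistical phasing rescues it.
- The reference-anchored consensus cannot represent variants inside a
  region the aligner could not anchor (irrelevant at this locus's repeat
  content, limiting for segmental duplications).
- The in-silico PCR models primer-site presence and product length only;
  real-world failure modes (dimers, inhibitors, allele-biased efficiency)
  are not modelled, so screen sensitivity on real samples will be bounded
  by assay chemistry, not by this implementation.
- Breakpoint reporting uses left-most placement; descriptors from
  right-aligned callers for the same junction differ by the microhomology
  length, which is reported alongside the call for reconciliation.
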