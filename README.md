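# ampliphase

Full-length diploid haplotype reconstruction of a ~77 kb gene locus from
four overlapping long-range PCR amplicons sequenced with long reads, with
structural-variant breakpoint resolution and an in-silico gap-PCR carrier
screen.

## The problem

CD36 deficiency genotyping by exon-targeted assays has a structural blind
spot: a large heterozygous deletion removes one allele's primer sites, the
intact allele amplifies alone, and the deletion is invisible. Tiling the
whole gene with overlapping long amplicons closes that blind spot twice
over — the deletion announces itself as an allele-specific *amplicon
dropout*, and whole-locus long reads resolve its exact breakpoints.

`ampliphase` implements the full computational side of that design:

- **Allele clustering** — reads of each amplicon are aligned to the locus
  (minimap2 behind a table contract), heterozygous sites detected
  (min depth 20, minor fraction >= 0.20, minor count >= 5; indel alleles
  < 5 bp collapse with the reference key), and reads partitioned into <= 2
  allele groups by a seeded two-signature assignment with one refinement
  pass.
- **Consensus** — per-reference-column plurality per allele group, ties and
  thin columns to the reference; indels vote as placement-clustered events
  so repeat context cannot fragment them.
- **Phasing** — per-amplicon consensuses are chained across the >= 3 kb
  amplicon overlaps using shared heterozygous variants as junction
  evidence; junctions without informative sites are flagged ambiguous. A
  haplotype whose provenance shows a contiguous run of dropouts while the
  other haplotype covers all four amplicons is an SV candidate.
- **Variant calling** — each haplotype is diffed against the reference
  (unique-k-mer anchor chaining + base-level gap alignment), calls are
  3'-normalized, named in HGVS `c.`/`g.` syntax, filtered to the
  reportable set (exonic/UTR, or intronic within 10 bp of a boundary), and
  samples classified homozygous / compound heterozygous / single
  heterozygous / none.
- **SV resolution** — split-read and gapped-CIGAR junction observations
  (>= 50 bp) are clustered, breakpoints resolved by majority vote with the
  inserted sequence by plurality, reported left-aligned with the
  microhomology length, as VCF-style records and HGVS delins strings.
- **Gap-PCR screen** — in-silico multiplex PCR (<= 2 primer mismatches,
  none in the 3'-terminal 5 bases; product-size budget 2 kb) classifies
  donors from the control/deletion band pattern, confirms candidates by
  sequencing the junction product, and reports the carrier frequency with
  a Wilson 95% interval.

A seeded synthetic-data module generates the entire study design — the
77.4 kb locus (15 exons, ATG in exon 3), the 20.6/22/20.6/23 kb amplicon
panel with the study's primer sequences, the 43-sample deficiency cohort
with its encoded per-haplotype genotypes (including a 19,971 bp
deletion-insertion, `c.1-15966_c.120+3885delinsCCAATGCTAAGGTTGA`),
nanopore-like amplicon reads, HiFi-like whole-locus reads, and a 600-donor
screening cohort with 3 heterozygous carriers — so every stage is
validated against known truth. See the methods vignette
(`vignettes/haplotype-reconstruction-methods.Rmd`) for models, parameters
and limitations.

## Worked example

```r
library(ampliphase)

locus <- build_reference_locus(seed = 1)
cohort <- make_study_cohort(locus, seed = 11)
names(cohort) <- vapply(cohort, function(s) s$sample_id, character(1))

## a compound heterozygote carrying the structural variant
s <- cohort[["I-12"]]
sim <- simulate_amplicon_reads(s, locus, depth = 20, seed = 112)
wgs <- simulate_wgs_reads(s, depth = 30, seed = 212)
rep <- cmd_run(sim$reads, locus, run_config(), "I-12", wgs_reads = wgs)

rep$dropout$flag          # "sv_candidate"
rep$dropout$amplicons     # "amp2" "amp3"
rep$sv[[1]]
#> <sv_call> c.1-15966_c.120+3885delinsCCAATGCTAAGGTTGA (del 19971 bp,
#>   ins 16 bp) support=15 wt=12 het
rep$calls$zygosity        # "compound_heterozygous"
```

The dropout flag says the SV haplotype failed to amplify amplicons 2 and 3
(its primer sites are deleted); the whole-locus reads then pin the
junction: 19,971 reference bases replaced by the 16-base insert, supported
by 15 junction-spanning reads, with the 12 wild-type-spanning reads
proving heterozygosity.

```r
## population screen: 600 donors, 3 implanted carriers
screen <- cmd_screen(make_cohort(locus, 600, 3, seed = 1), locus,
                     run_config())
screen
#> <screen_result> 3/600 carriers = 0.50% (95% CI 0.17-1.46%)
```

Carriers show both the 333 bp control band and the 832 bp junction band;
the wild-type deletion-pair product (20,787 bp) exceeds the screening
PCR's extension budget and never amplifies.

## Command line

A thin CLI over the same functions lives at `inst/cli/ampliphase.R`:

```sh
Rscript inst/cli/ampliphase.R simulate --seed 1 --outdir out/
Rscript inst/cli/ampliphase.R run --sample I-12 --outdir out/
Rscript inst/cli/ampliphase.R screen --outdir out/
```
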