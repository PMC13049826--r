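# Amplicon assignment, het-site detection, allele clustering and consensus.
# Reads are simulated from the fixture locus; truth labels are only consulted
# to score the result, never by the pipeline.

test_that("amplicon assignment follows maximal span overlap", {
  loc <- fixture_locus()
  panel <- loc$panel
  mk <- function(s, e) data.table::data.table(
    read_id = "r", flag = 0L, pos = s, mapq = 60L, cigar = "1M",
    seq = "A", nm = 0L, ref_start = s, ref_end = e, qstart = 1L, qend = 1L,
    qlen = 1L, strand = "+", supplementary = FALSE, identity = 1)
  # wholly inside amplicon 4
  expect_identical(assign_amplicon(mk(60000L, 68000L), panel), "amp4")
  # spanning the amplicon 1/2 overlap with 70% in amplicon 1
  a <- panel$start[2]            # overlap start
  expect_identical(assign_amplicon(mk(a - 7000L, a + 3000L), panel), "amp1")
  # and the reverse balance goes to amplicon 2
  expect_identical(assign_amplicon(mk(a - 2000L, a + 8000L), panel), "amp2")
  # outside every amplicon
  expect_identical(assign_amplicon(mk(77300L, 77380L), panel), "unassigned")
  # real reads: truth amplicon labels agree with the assignment except for
  # reads lying (nearly) wholly inside an overlap, where the two amplicons
  # are genuinely indistinguishable and ties go to the left-most
  fx <- amp_fixture()
  truth_amp <- fx$reads[match(fx$aln$read_id, fx$reads$read_id), amplicon]
  expect_gt(mean(truth_amp == fx$amp_of), 0.90)
})

test_that("het sites are found in het amplicons and absent in hom ones", {
  loc <- fixture_locus()
  fx <- amp_fixture()
  sub <- fx$aln[fx$amp_of == "amp4", ]
  region <- c(loc$panel$start[4], loc$panel$end[4])
  het <- detect_het_sites(sub, region, loc$reference)
  expect_gt(nrow(het$sites), 0L)
  # the 12-bp deletion registers as a long-indel het key in exon 13
  del_site <- het$sites[het$sites$type == "del", ]
  expect_gte(nrow(del_site), 1L)
  # the site is a clustering key: its placement may wobble with read-level
  # alignment in the repeat context, its width must not
  expect_true(any(abs(del_site$pos - c_to_g("1227", loc$transcript)) <= 10L &
                    abs(del_site$width - 12L) <= 3L))
  # error-only noise never reaches the 20% minor fraction: simulate a
  # homozygous amplicon and expect zero het sites
  hom <- fixture_cohort()[["II-23"]]
  p <- simulate_amplicon(hom$hap1, loc$panel$fwd[4], loc$panel$rev[4])
  reads <- rbind(
    simulate_reads(p$product, 15, error_model("nanopore"), seed = 21,
                   prefix = "h1"),
    simulate_reads(p$product, 15, error_model("nanopore"), seed = 22,
                   prefix = "h2"))
  aln <- align_reads(reads, loc$reference, "map-ont")
  aln <- aln[!aln$supplementary & (aln$ref_end - aln$ref_start + 1L) >= 1000L, ]
  het0 <- detect_het_sites(aln, region, loc$reference)
  expect_identical(nrow(het0$sites), 0L)
  # insufficient depth is a hard error
  expect_error(detect_het_sites(aln[1:5, ], region, loc$reference),
               "insufficient")
})

test_that("clustering splits het amplicons at >=99% truth purity and keeps hom ones whole", {
  loc <- fixture_locus()
  fx <- amp_fixture()
  purities <- c()
  for (an in loc$panel$name) {
    sub <- fx$aln[fx$amp_of == an, ]
    region <- c(loc$panel$start[match(an, loc$panel$name)],
                loc$panel$end[match(an, loc$panel$name)])
    het <- detect_het_sites(sub, region, loc$reference)
    cl <- cluster_alleles(het, sub)
    expect_lte(length(cl), 2L)
    for (c1 in cl) {
      labs <- fx$reads[match(sub$read_id[c1$members], read_id), hap]
      purities <- c(purities, max(table(labs)) / length(labs))
    }
  }
  expect_gte(mean(purities), 0.99)
  # homozygous input yields a single cluster
  hom <- fixture_cohort()[["II-23"]]
  p <- simulate_amplicon(hom$hap1, loc$panel$fwd[2], loc$panel$rev[2])
  reads <- simulate_reads(p$product, 30, error_model("nanopore"), seed = 23)
  aln <- align_reads(reads, loc$reference, "map-ont")
  aln <- aln[!aln$supplementary & (aln$ref_end - aln$ref_start + 1L) >= 1000L, ]
  het <- detect_het_sites(aln, c(loc$panel$start[2], loc$panel$end[2]),
                          loc$reference)
  cl <- cluster_alleles(het, aln)
  expect_length(cl, 1L)
  # low-support flag below min_reads
  small <- cl[[1]]
  cl_small <- cluster_alleles(het, aln, min_reads = nrow(aln) + 1L)
  expect_true(cl_small[[1]]$low_support)
})

test_that("consensus of error-free reads is byte-exact and errorful consensus stays within 1 edit per 10 kb", {
  loc <- fixture_locus()
  hom <- fixture_cohort()[["II-23"]]
  p <- simulate_amplicon(hom$hap1, loc$panel$fwd[3], loc$panel$rev[3])
  region <- c(loc$panel$start[3], loc$panel$end[3])
  truth <- substr(hom$hap1, p$start, p$end)   # hap == ref here except SNVs

  r0 <- simulate_reads(p$product, 25, error_model(sub = 0, ins = 0, del = 0),
                       seed = 31)
  aln0 <- align_reads(r0, loc$reference, "map-ont")
  aln0 <- aln0[!aln0$supplementary, ]
  cons0 <- call_consensus(aln0, region, loc$reference)
  expect_identical(consensus_sequence(cons0), p$product)

  r1 <- simulate_reads(p$product, 30, error_model("nanopore"), seed = 32)
  aln1 <- align_reads(r1, loc$reference, "map-ont")
  aln1 <- aln1[!aln1$supplementary &
                 (aln1$ref_end - aln1$ref_start + 1L) >= 1000L, ]
  cons1 <- call_consensus(aln1, region, loc$reference)
  d <- utils::adist(consensus_sequence(cons1), p$product)[1, 1]
  expect_lte(d, ceiling(nchar(p$product) / 10000))
  # single-read cluster: consensus flagged low-support
  cons_single <- call_consensus(aln1[1, ], region, loc$reference)
  expect_true(cons_single$low_support)
})
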