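# Structural-variant calling from whole-locus HiFi-like reads: coverage
# signatures, junction candidates, exact breakpoint and insert recovery.

sv_fixture <- function() {
  if (!is.null(the_fixture$sv)) return(the_fixture$sv)
  loc <- fixture_locus()
  s <- diploid_sample(loc, "carrier", list(loc$sv$variant), list(),
                      seed = 8L)
  reads <- simulate_wgs_reads(s, depth = 30, seed = 42L)
  aln <- align_reads(reads, loc$reference, "map-hifi")
  the_fixture$sv <- list(sample = s, reads = reads, aln = aln)
  the_fixture$sv
}

test_that("coverage is flat without an SV and halves over a heterozygous deletion", {
  loc <- fixture_locus()
  wt <- diploid_sample(loc, "wt", list(), list(), seed = 9L)
  aln_wt <- align_reads(simulate_wgs_reads(wt, depth = 35, seed = 43L),
                        loc$reference, "map-hifi")
  cov <- coverage_profile(aln_wt, loc$reference$length)
  inner <- cov$depth[cov$start > 2000 & cov$end < loc$reference$length - 2000]
  expect_lt(stats::sd(inner) / mean(inner), 0.2)

  fx <- sv_fixture()
  cov2 <- coverage_profile(fx$aln, loc$reference$length)
  del <- cov2$depth[cov2$start > loc$sv$left + 500 &
                      cov2$end < loc$sv$right - 500]
  flank <- cov2$depth[(cov2$end < loc$sv$left - 1000 & cov2$start > 2000) |
                        (cov2$start > loc$sv$right + 1000 &
                           cov2$end < loc$reference$length - 2000)]
  ratio <- mean(del) / mean(flank)
  expect_gt(ratio, 0.35); expect_lt(ratio, 0.65)
  expect_error(coverage_profile(fx$aln, loc$reference$length, window = 10L))
})

test_that("junction caller recovers the exact breakpoints, insert and zygosity", {
  loc <- fixture_locus()
  fx <- sv_fixture()
  clusters <- find_junctions(fx$aln)
  expect_length(clusters, 1L)
  expect_gte(nrow(clusters[[1]]), 5L)
  sv <- resolve_junction(clusters[[1]], fx$aln, loc)
  expect_identical(sv$left, loc$sv$left - 1L)     # last retained base
  expect_identical(sv$right, loc$sv$right + 1L)   # first retained base
  expect_identical(sv$del_len, 19971L)
  expect_identical(sv$insert, "CCAATGCTAAGGTTGA")
  expect_identical(sv$zygosity, "het")
  expect_true(sv$confident)
  # deleted length invariant and HGVS round trip through the parser
  expect_identical(sv$del_len, sv$right - sv$left - 1L)
  v <- parse_hgvs(sv$hgvs_c, loc$transcript, loc$reference)
  nv <- normalize_variant(v, loc$reference)
  expect_identical(variant_key(nv),
                   variant_key(normalize_variant(sv$variant, loc$reference)))
  # homozygous carrier: no wild-type spanning reads
  hom <- diploid_sample(loc, "hom", list(loc$sv$variant),
                        list(loc$sv$variant), seed = 10L)
  aln_h <- align_reads(simulate_wgs_reads(hom, depth = 30, seed = 44L),
                       loc$reference, "map-hifi")
  sv_h <- resolve_junction(find_junctions(aln_h)[[1]], aln_h, loc)
  expect_identical(sv_h$zygosity, "hom")
})

test_that("breakpoint recovery is exact across seeded replicates", {
  loc <- fixture_locus()
  s <- sv_fixture()$sample
  for (rep in 1:8) {
    reads <- simulate_wgs_reads(s, depth = 25, seed = 500L + rep)
    aln <- align_reads(reads, loc$reference, "map-hifi")
    svs <- call_sv(aln, loc)
    expect_length(svs, 1L)
    expect_identical(svs[[1]]$left, loc$sv$left - 1L)
    expect_identical(svs[[1]]$right, loc$sv$right + 1L)
    expect_identical(svs[[1]]$insert, loc$sv$insert)
  }
})

test_that("no junction is called without an SV and small deletions stay below the size floor", {
  loc <- fixture_locus()
  wt <- diploid_sample(loc, "wt2", list(), list(), seed = 11L)
  aln <- align_reads(simulate_wgs_reads(wt, depth = 30, seed = 45L),
                     loc$reference, "map-hifi")
  expect_length(find_junctions(aln), 0L)
  # a 20-base deletion is real but sub-structural: the caller must ignore it
  p <- 30000L
  v20 <- new_variant(p, ref_sub(loc$reference, p, p + 19L), "")
  sdel <- diploid_sample(loc, "d20", list(v20), list(v20), seed = 12L)
  aln2 <- align_reads(simulate_wgs_reads(sdel, depth = 30, seed = 46L),
                      loc$reference, "map-hifi")
  expect_length(find_junctions(aln2), 0L)
})
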