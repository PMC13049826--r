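# Locus generator, amplicon panel geometry, cohort encodings, in-silico PCR
# and read simulation.

test_that("generated locus satisfies the assay geometry invariants", {
  loc <- fixture_locus()
  expect_gte(loc$reference$length, 74000L)
  expect_lte(loc$reference$length, 80000L)
  expect_identical(loc$transcript$n_exons, 15L)
  # ATG in exon 3
  e3 <- loc$transcript$exons[3, ]
  expect_true(loc$transcript$cds_start >= e3$start &&
                loc$transcript$cds_start <= e3$end)
  expect_identical(ref_sub(loc$reference, loc$transcript$cds_start,
                           loc$transcript$cds_start + 2L), "ATG")
  # 12 coding exons
  expect_identical(nrow(loc$transcript$coding), 12L)
  # panel: 4 amplicons, sizes within 50 bp of the designed targets,
  # every consecutive overlap >= 3 kb
  expect_identical(nrow(loc$panel), 4L)
  expect_true(all(abs(loc$panel$length -
                        c(20600L, 22000L, 20600L, 23000L)) <= 50L))
  expect_true(all(loc$overlaps$width >= 3000L))
  expect_true(all(loc$panel$length >= 20000L & loc$panel$length <= 23500L))
})

test_that("each assay primer occurs exactly once in the locus", {
  loc <- fixture_locus()
  subj <- Biostrings::DNAString(loc$reference$sequence)
  count2 <- function(p) {
    Biostrings::countPattern(Biostrings::DNAString(p), subj, max.mismatch = 2) +
      Biostrings::countPattern(Biostrings::reverseComplement(
        Biostrings::DNAString(p)), subj, max.mismatch = 2)
  }
  primers <- c(loc$panel$fwd, loc$panel$rev,
               unlist(loc$gap_assay[c("del_fwd", "del_rev",
                                      "ctrl_fwd", "ctrl_rev")]))
  for (p in primers) expect_identical(count2(p), 1L)
  # the deletion-flanking forward primer sits on the forward strand
  expect_identical(
    Biostrings::countPattern(Biostrings::DNAString("GTGTCAAACTGTCATCGGGGTG"),
                             subj), 1L)
})

test_that("locus generation is deterministic and the truth SV matches its descriptor", {
  loc <- fixture_locus()
  loc2 <- build_reference_locus(1L)
  expect_identical(loc$reference$sequence, loc2$reference$sequence)
  loc3 <- build_reference_locus(2L)
  expect_false(identical(loc$reference$sequence, loc3$reference$sequence))
  expect_identical(loc$sv$del_len, 19971L)
  expect_identical(loc$sv$insert, "CCAATGCTAAGGTTGA")
  expect_match(loc$sv$hgvs_c, "^c\\.1-15966_c\\.")
  # round trip through the parser reproduces the same edit
  v <- parse_hgvs(loc$sv$hgvs_c, loc$transcript, loc$reference)
  expect_identical(apply_variants(loc$reference, list(v))$sequence,
                   apply_variants(loc$reference, list(loc$sv$variant))$sequence)
})

test_that("study cohort encodes 43 samples / 86 haplotypes with the expected genotypes", {
  gt <- study_genotypes()
  expect_identical(nrow(gt), 43L)
  expect_identical(sum(gt$type == "I"), 14L)
  expect_identical(sum(gt$type == "II"), 29L)
  cohort <- fixture_cohort()
  expect_length(cohort, 43L)
  expect_identical(sum(lengths(lapply(cohort, function(s) s$truth[[1]]))) +
                     sum(lengths(lapply(cohort, function(s) s$truth[[2]]))),
                   71L)  # total encoded variant entries over 86 haplotypes
  # homozygote: both haplotypes carry the identical 12-bp deletion
  i11 <- cohort[["I-11"]]
  expect_identical(truth_hgvs(i11, 1, fixture_locus()),
                   truth_hgvs(i11, 2, fixture_locus()))
  # reference/reference sample has no truth variants
  expect_length(cohort[["II-23"]]$truth[[1]], 0L)
  expect_length(cohort[["II-23"]]$truth[[2]], 0L)
  # haplotype sequences derive from the variant lists
  loc <- fixture_locus()
  s <- cohort[["I-07"]]
  expect_identical(
    s$hap1, apply_variants(loc$reference, s$variants[[1]])$sequence)
})

test_that("in-silico PCR amplifies wild type and drops deletion alleles by reason", {
  loc <- fixture_locus()
  ref_seq <- loc$reference$sequence
  sv_seq <- apply_variants(loc$reference, list(loc$sv$variant))$sequence
  # amplicon 2 on wild type: ~22 kb product
  p <- simulate_amplicon(ref_seq, loc$panel$fwd[2], loc$panel$rev[2])
  expect_identical(p$status, "ok")
  expect_identical(nchar(p$product), 22000L)
  # amplicon 2 and 3 on the SV haplotype: primer sites deleted
  for (i in 2:3) {
    d <- simulate_amplicon(sv_seq, loc$panel$fwd[i], loc$panel$rev[i])
    expect_identical(d$status, "dropout")
    expect_identical(d$reason, "missing_site")
  }
  # amplicons 1 and 4 survive on the SV haplotype
  for (i in c(1L, 4L)) {
    k <- simulate_amplicon(sv_seq, loc$panel$fwd[i], loc$panel$rev[i])
    expect_identical(k$status, "ok")
  }
  # gap-PCR on wild type: product exists but exceeds the 1-minute extension
  g <- simulate_amplicon(ref_seq, loc$gap_assay$del_fwd,
                         loc$gap_assay$del_rev, max_product = 2000L)
  expect_identical(g$reason, "oversize")
  # on the deletion allele it collapses to the 832-bp junction product
  g2 <- simulate_amplicon(sv_seq, loc$gap_assay$del_fwd,
                          loc$gap_assay$del_rev, max_product = 2000L)
  expect_identical(nchar(g2$product), 832L)
})

test_that("primer matching tolerates 2 internal mismatches but not 3' mismatches", {
  loc <- fixture_locus()
  primer <- loc$gap_assay$del_fwd
  seq <- loc$reference$sequence
  site <- as.integer(regexpr(primer, seq))
  flip_at <- function(s, p) {
    paste0(substr(s, 1L, p - 1L), other_base(substr(s, p, p)),
           substr(s, p + 1L, nchar(s)))
  }
  # two mismatches in the 5' half of the primer site still amplify
  mut <- flip_at(flip_at(seq, site + 1L), site + 4L)
  expect_length(find_primer_sites(mut, primer, "+"), 1L)
  # a single mismatch in the 3'-terminal 5 bases kills the site
  mut3 <- flip_at(seq, site + nchar(primer) - 1L)
  expect_length(find_primer_sites(mut3, primer, "+"), 0L)
  # three mismatches exceed the tolerance entirely
  mut4 <- flip_at(flip_at(flip_at(seq, site + 1L), site + 4L), site + 7L)
  expect_length(find_primer_sites(mut4, primer, "+"), 0L)
})

test_that("read simulator hits the configured error composition and count", {
  tpl <- random_dna(20000L)
  em0 <- error_model(sub = 0, ins = 0, del = 0)
  r0 <- simulate_reads(tpl, depth = 5, em = em0, seed = 3)
  # zero-error reads are exact substrings
  for (i in seq_len(nrow(r0)))
    expect_identical(r0$seq[i], substr(tpl, r0$tpl_start[i], r0$tpl_end[i]))
  # read count ~ depth * L / mean length
  em <- error_model("nanopore")
  r <- simulate_reads(tpl, depth = 30, em = em, seed = 4)
  expect_gt(nrow(r), 0.8 * 30 * 20000 / em$read_length_mean)
  expect_lt(nrow(r), 1.2 * 30 * 20000 / em$read_length_mean)
  # substitution-only model: observed mismatch fraction within binomial range
  em_sub <- error_model(sub = 0.02, ins = 0, del = 0)
  rs <- simulate_reads(tpl, depth = 10, em = em_sub, seed = 5)
  obs <- mapply(function(s, a, b) {
    truth <- substr(tpl, a, b)
    sum(utf8ToInt(s) != utf8ToInt(truth)) / nchar(truth)
  }, rs$seq, rs$tpl_start, rs$tpl_end)
  frac <- sum(obs * nchar(rs$seq)) / sum(nchar(rs$seq))
  expect_gt(frac, 0.015); expect_lt(frac, 0.025)
  # determinism: same seed, identical reads
  expect_identical(simulate_reads(tpl, depth = 5, em = em, seed = 9),
                   simulate_reads(tpl, depth = 5, em = em, seed = 9))
})

test_that("whole-locus reads draw from both haplotypes near balance", {
  loc <- fixture_locus()
  s <- fixture_cohort()[["I-09"]]
  reads <- simulate_wgs_reads(s, depth = 30, seed = 6)
  bal <- mean(reads$hap == "H1")
  expect_gt(bal, 0.4); expect_lt(bal, 0.6)
  # truth labels present on every read
  expect_true(all(c("sample_id", "hap") %in% names(reads)))
  expect_false(any(is.na(reads$hap)))
})

test_that("screening cohort implants exactly the configured carriers", {
  loc <- fixture_locus()
  co <- make_cohort(loc, n = 25L, n_carriers = 4L, seed = 5L)
  expect_identical(co$n, 25L)
  expect_length(co$carrier_ids, 4L)
  has_sv <- vapply(co$donors, function(d) {
    any(vapply(c(d$variants[[1]], d$variants[[2]]),
               function(v) nchar(v$ref) > 10000L, logical(1)))
  }, logical(1))
  expect_identical(sum(has_sv), 4L)
  ids <- vapply(co$donors, function(d) d$sample_id, character(1))
  expect_setequal(ids[has_sv], co$carrier_ids)
  # carriers are heterozygous: exactly one haplotype carries the SV
  for (d in co$donors[has_sv]) {
    n_sv <- vapply(d$variants, function(vs)
      sum(vapply(vs, function(v) nchar(v$ref) > 10000L, logical(1))),
      integer(1))
    expect_identical(sort(n_sv), c(0L, 1L))
  }
  expect_error(make_cohort(loc, n = 3L, n_carriers = 5L), "n_carriers")
})
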