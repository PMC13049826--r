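# Junction phasing: agreement with the exhaustive chaining oracle on fuzzed
# instances, switch-error-free reconstruction with informative overlaps, and
# the amplicon-dropout SV signature.

test_that("greedy phasing matches the exhaustive oracle at every unambiguous junction", {
  set.seed(77)
  n_checked <- 0L
  for (rep in 1:200) {
    k <- sample(2:5, 1)
    inst <- random_instance(k, n_sites = sample(1:4, 1),
                            p_informative = runif(1, 0.2, 1))
    core <- phase_core(inst)
    oracle <- brute_force_phase(inst)
    for (j in seq_len(k - 1L)) {
      if (core$flags[j]) next      # ambiguous: oracle tie, not compared
      rel_core <- core$tracks[1, j] == core$tracks[1, j + 1L]
      rel_oracle <- oracle$tracks[1, j] == oracle$tracks[1, j + 1L]
      expect_identical(rel_core, rel_oracle)
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 200L)
})

test_that("single-site and majority-vote junctions pair as the evidence dictates", {
  # one informative SNV decides the pairing
  inst <- list(
    list(list(left = NULL, right = c(s1 = "A")),
         list(left = NULL, right = c(s1 = "G"))),
    list(list(left = c(s1 = "G"), right = NULL),
         list(left = c(s1 = "A"), right = NULL)))
  core <- phase_core(inst)
  expect_false(core$flags[1])
  expect_identical(core$tracks[, 2], c(2L, 1L))     # crossed pairing
  # 3-vs-1 conflicting evidence: majority wins
  inst2 <- list(
    list(list(left = NULL, right = c(s1 = "A", s2 = "A", s3 = "A", s4 = "A")),
         list(left = NULL, right = c(s1 = "G", s2 = "G", s3 = "G", s4 = "G"))),
    list(list(left = c(s1 = "A", s2 = "A", s3 = "A", s4 = "G"), right = NULL),
         list(left = c(s1 = "G", s2 = "G", s3 = "G", s4 = "A"), right = NULL)))
  core2 <- phase_core(inst2)
  expect_false(core2$flags[1])
  expect_identical(core2$tracks[, 2], c(1L, 2L))
  # no informative site: default pairing plus ambiguity flag
  inst3 <- list(
    list(list(left = NULL, right = c(s1 = "A")),
         list(left = NULL, right = c(s1 = "A"))),
    list(list(left = c(s1 = "A"), right = NULL),
         list(left = c(s1 = "A"), right = NULL)))
  core3 <- phase_core(inst3)
  expect_true(core3$flags[1])
})

test_that("a het sample with informative overlaps reconstructs with zero switch errors", {
  loc <- fixture_locus(); ref <- loc$reference; tx <- loc$transcript
  s <- fixture_cohort()[["I-09"]]
  sim <- simulate_amplicon_reads(s, loc, depth = 20, seed = 101L)
  rec <- reconstruct_sample(sim$reads, loc, run_config(), s$sample_id)
  expect_false(any(rec$phased$junction_flags))
  expect_identical(rec$dropout$flag, "none")
  got <- lapply(rec$calls$hgvs, function(x) sort(as.character(x)))
  truth <- lapply(1:2, function(h) truth_hgvs(s, h, loc))
  direct <- identical(got[[1]], truth[[1]]) && identical(got[[2]], truth[[2]])
  flipped <- identical(got[[1]], truth[[2]]) && identical(got[[2]], truth[[1]])
  expect_true(direct || flipped)
})

test_that("the SV carrier shows the two-amplicon dropout signature; wild type does not", {
  loc <- fixture_locus()
  s <- fixture_cohort()[["I-12"]]              # SV / c.1006+2T>G
  sim <- simulate_amplicon_reads(s, loc, depth = 20, seed = 112L)
  # the SV haplotype loses amplicons 2 and 3 at the PCR stage
  st <- vapply(sim$products, function(p) p$status, character(1))
  expect_identical(unname(st[c("H1.amp2", "H1.amp3")]),
                   c("dropout", "dropout"))
  rec <- reconstruct_sample(sim$reads, loc, run_config(), s$sample_id)
  expect_identical(rec$dropout$flag, "sv_candidate")
  expect_identical(sort(rec$dropout$amplicons), c("amp2", "amp3"))
  expect_length(rec$dropout$amplicons, 2L)

  wt <- fixture_cohort()[["II-24"]]
  sim_wt <- simulate_amplicon_reads(wt, loc, depth = 20, seed = 113L)
  rec_wt <- reconstruct_sample(sim_wt$reads, loc, run_config(), wt$sample_id)
  expect_identical(rec_wt$dropout$flag, "none")
})

test_that("both haplotypes dropping one amplicon is an assay failure, not an SV", {
  fake <- structure(list(
    h1 = list(provenance = c(amp1 = "DROPOUT", amp2 = "amp2.c1",
                             amp3 = "amp3.c1", amp4 = "amp4.c1")),
    h2 = list(provenance = c(amp1 = "DROPOUT", amp2 = "amp2.c2",
                             amp3 = "amp3.c2", amp4 = "amp4.c2"))),
    class = "phased_haplotypes")
  res <- detect_dropout_pattern(fake)
  expect_identical(res$flag, "assay_failure")
  expect_identical(res$amplicons, "amp1")
  # all amplicons present on both: nothing flagged
  ok <- structure(list(
    h1 = list(provenance = c(amp1 = "a", amp2 = "b", amp3 = "c", amp4 = "d")),
    h2 = list(provenance = c(amp1 = "a", amp2 = "b", amp3 = "c", amp4 = "d"))),
    class = "phased_haplotypes")
  expect_identical(detect_dropout_pattern(ok)$flag, "none")
})
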