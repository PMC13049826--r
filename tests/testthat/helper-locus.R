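# Shared fixtures, built once per test run. The locus and truth cohort are
# deterministic functions of their seeds.

# internal helpers exercised directly by tests
variant_key <- ampliphase:::variant_key
new_variant <- ampliphase::new_variant
other_base <- ampliphase:::other_base
random_dna <- ampliphase:::random_dna
ref_sub <- ampliphase:::ref_sub
child_seed <- ampliphase:::child_seed
phase_core <- ampliphase:::phase_core
brute_force_phase <- ampliphase:::brute_force_phase
find_primer_sites <- ampliphase:::find_primer_sites
mutate_read <- ampliphase:::mutate_read
consensus_slice <- ampliphase:::consensus_slice

seeded_sample <- function(n, k, seed) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(n, k)
}

the_fixture <- new.env(parent = emptyenv())

fixture_locus <- function() {
  if (is.null(the_fixture$locus))
    the_fixture$locus <- build_reference_locus(1L)
  the_fixture$locus
}

# truth-level study cohort (sequences + labels; no reads)
fixture_cohort <- function() {
  if (is.null(the_fixture$cohort)) {
    cohort <- make_study_cohort(fixture_locus(), seed = 11L)
    names(cohort) <- vapply(cohort, function(s) s$sample_id, character(1))
    the_fixture$cohort <- cohort
  }
  the_fixture$cohort
}

# truth-level reportable calls for the whole cohort
fixture_truth_calls <- function() {
  if (is.null(the_fixture$calls)) {
    loc <- fixture_locus()
    the_fixture$calls <- lapply(fixture_cohort(), function(s)
      call_sample(s$hap1, s$hap2, loc, s$sample_id, s$type))
  }
  the_fixture$calls
}

normalized_hgvs <- function(variants, locus) {
  sort(vapply(variants, function(v)
    hgvs_name(normalize_variant(v, locus$reference), locus$transcript),
    character(1)))
}

# truth reportable names for a diploid_sample haplotype
truth_hgvs <- function(sample, hap, locus) {
  normalized_hgvs(sample$truth[[hap]], locus)
}


# random abstract phasing instance: k amplicons, 2 clusters each,
# allele vectors over shared overlap sites per junction
random_instance <- function(k = 4L, n_sites = 3L, p_informative = 0.7) {
  junction_sites <- lapply(seq_len(k - 1L), function(j)
    paste0("j", j, "s", seq_len(n_sites)))
  hap_alleles <- lapply(junction_sites, function(sites) {
    a <- setNames(sample(c("A", "C", "G", "T"), length(sites), TRUE), sites)
    b <- ifelse(runif(length(sites)) < p_informative,
                other_base(a), a)
    list(a, setNames(b, sites))
  })
  lapply(seq_len(k), function(i) {
    lapply(1:2, function(h) {
      left <- if (i > 1L) hap_alleles[[i - 1L]][[h]] else NULL
      right <- if (i < k) hap_alleles[[i]][[h]] else NULL
      list(left = left, right = right)
    })
  })
}

# seeded het-sample amplicon read set shared by clustering tests
amp_fixture <- function() {
  if (!is.null(the_fixture$amp)) return(the_fixture$amp)
  loc <- fixture_locus()
  s <- fixture_cohort()[["I-09"]]      # het: 12-bp deletion / c.1156C>T
  sim <- simulate_amplicon_reads(s, loc, depth = 20, seed = 101L)
  aln <- align_reads(sim$reads, loc$reference, "map-ont")
  aln <- aln[!aln$supplementary & (aln$ref_end - aln$ref_start + 1L) >= 1000L, ]
  amp <- assign_amplicon(aln, loc$panel)
  the_fixture$amp <- list(sample = s, reads = sim$reads, aln = aln,
                          amp_of = amp)
  the_fixture$amp
}
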