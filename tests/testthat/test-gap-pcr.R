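# In-silico gap-PCR: band prediction, classification, cohort screening,
# confirmation sequencing and the Wilson interval.

test_that("band patterns follow the assay design", {
  loc <- fixture_locus()
  wt <- diploid_sample(loc, "wt", list(), list(), seed = 61L)
  het <- diploid_sample(loc, "het", list(loc$sv$variant), list(), seed = 62L)
  hom <- diploid_sample(loc, "hom", list(loc$sv$variant),
                        list(loc$sv$variant), seed = 63L)
  b_wt <- run_gap_pcr(wt, loc)
  expect_true(b_wt$control$present)
  expect_identical(b_wt$control$size, 333L)
  expect_false(b_wt$deletion$present)
  # the wild-type deletion-pair product exists but exceeds the budget
  expect_identical(b_wt$detail$hap1$deletion_reason, "oversize")
  expect_identical(loc$gap_assay$wt_product, 20787L)

  b_het <- run_gap_pcr(het, loc)
  expect_true(b_het$control$present && b_het$deletion$present)
  expect_identical(b_het$deletion$size, 832L)

  b_hom <- run_gap_pcr(hom, loc)
  # control target (intron 7) lies outside the deletion: still present
  expect_true(b_hom$control$present)
  expect_true(b_hom$deletion$present)

  expect_identical(classify_band_pattern(b_wt), "wildtype")
  expect_identical(classify_band_pattern(b_het), "carrier")
})

test_that("classification is a pure function over all four band patterns", {
  mk <- function(ctrl, del) list(control = list(present = ctrl),
                                 deletion = list(present = del))
  expect_identical(classify_band_pattern(mk(TRUE, TRUE)), "carrier")
  expect_identical(classify_band_pattern(mk(TRUE, FALSE)), "wildtype")
  expect_identical(classify_band_pattern(mk(FALSE, TRUE)),
                   "homozygous_deletion")
  expect_identical(classify_band_pattern(mk(FALSE, FALSE)), "invalid")
})

test_that("screen classifies a seeded cohort with full sensitivity and specificity", {
  loc <- fixture_locus()
  co <- make_cohort(loc, n = 60L, n_carriers = 3L, seed = 6L)
  res <- screen_cohort(co, loc)
  called <- res$samples$sample_id[res$samples$class == "carrier"]
  expect_setequal(called, co$carrier_ids)
  expect_identical(res$carriers, 3L)
  expect_equal(res$frequency, 3 / 60)
  expect_true(all(res$samples$class[!(res$samples$sample_id %in%
                                        co$carrier_ids)] == "wildtype"))
  # carrier-free cohort reports zero carriers
  co0 <- make_cohort(loc, n = 10L, n_carriers = 0L, seed = 7L)
  res0 <- screen_cohort(co0, loc)
  expect_identical(res0$carriers, 0L)
  expect_equal(res0$ci[["lower"]], 0)
  # all-carrier cohort flags everyone
  co_all <- make_cohort(loc, n = 6L, n_carriers = 6L, seed = 8L)
  expect_identical(screen_cohort(co_all, loc)$carriers, 6L)
})

test_that("confirmation sequencing validates true carriers and demotes a decoy deletion", {
  loc <- fixture_locus()
  co <- make_cohort(loc, n = 12L, n_carriers = 2L, seed = 9L)
  # engineer a decoy: a slightly larger deletion between the same primers,
  # so a short product forms but with different breakpoints
  decoy_var <- new_variant(
    loc$sv$left - 100L,
    ref_sub(loc$reference, loc$sv$left - 100L, loc$sv$right + 100L),
    "", "DEL")
  decoy <- diploid_sample(loc, "decoy", list(decoy_var), list(), seed = 64L)
  donors <- c(co$donors, list(decoy))
  res <- screen_cohort(donors, loc)
  cand <- res$samples$sample_id[res$samples$class == "carrier"]
  expect_true("decoy" %in% cand)
  conf <- confirm_candidates(cand, donors, loc, seed = 10L)
  expect_true(all(conf$confirmed[conf$sample_id %in% co$carrier_ids]))
  expect_false(conf$confirmed[conf$sample_id == "decoy"])
  expect_identical(conf$reason[conf$sample_id == "decoy"],
                   "breakpoint_mismatch")
  # empty candidate set stays empty
  expect_identical(nrow(confirm_candidates(character(0), donors, loc)), 0L)
})

test_that("Wilson interval matches the closed form and brackets the estimate", {
  # expected values frozen from an independent Wilson implementation
  # (statsmodels proportion_confint, method = "wilson")
  ci <- wilson_ci(3L, 600L)
  expect_equal(unname(ci["lower"]), 0.001701877658278, tolerance = 1e-8)
  expect_equal(unname(ci["upper"]), 0.014596206345286, tolerance = 1e-8)
  est <- estimate_frequency(c(rep("wildtype", 597), rep("carrier", 3)))
  expect_equal(est$frequency, 0.005)
  expect_true(est$ci["lower"] < est$frequency &
                est$frequency < est$ci["upper"])
  expect_error(estimate_frequency(character(0)), "no samples")
  # invalid samples stay in the denominator by default, excluded on request
  cls <- c(rep("wildtype", 8), "carrier", "invalid")
  expect_equal(estimate_frequency(cls)$n, 10L)
  expect_equal(estimate_frequency(cls, count_invalid = FALSE)$n, 9L)
})
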