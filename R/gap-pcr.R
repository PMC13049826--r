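# In-silico multiplex gap-PCR carrier screen: band prediction per donor,
# pattern classification, sequencing-based confirmation of candidate
# carriers, and carrier-frequency estimation with a Wilson interval.

#' Run the multiplex gap-PCR on a diploid sample
#'
#' The control pair amplifies a short intron-7 product from either haplotype.
#' The deletion-flanking pair yields a product only when the intervening
#' segment is deleted: on the wild-type allele its product exceeds the
#' extension-time budget (`max_product`) and drops out, while on the deletion
#' allele the flanks collapse onto a short junction product.
#'
#' @param sample a [diploid_sample()] (or any list with `hap1`/`hap2`
#'   sequences).
#' @param locus the locus model (provides the assay primers).
#' @param max_product longest product the screening PCR can extend.
#' @return object of class `band_pattern`: `sample_id`, `control`
#'   (present/size), `deletion` (present/size), and per-haplotype detail.
#' @export
run_gap_pcr <- function(sample, locus, max_product = 2000L) {
  ga <- locus$gap_assay
  bands <- list(control = list(present = FALSE, size = NA_integer_),
                deletion = list(present = FALSE, size = NA_integer_))
  detail <- list()
  for (h in c("hap1", "hap2")) {
    ctrl <- simulate_amplicon(sample[[h]], ga$ctrl_fwd, ga$ctrl_rev,
                              max_product = max_product)
    del <- simulate_amplicon(sample[[h]], ga$del_fwd, ga$del_rev,
                             max_product = max_product)
    if (ctrl$status == "ok") {
      bands$control$present <- TRUE
      bands$control$size <- nchar(ctrl$product)
    }
    if (del$status == "ok") {
      bands$deletion$present <- TRUE
      bands$deletion$size <- nchar(del$product)
      bands$deletion$product <- del$product
    }
    detail[[h]] <- list(control = ctrl$status, deletion = del$status,
                        deletion_reason = del$reason)
  }
  structure(list(sample_id = sample$sample_id %||% "sample",
                 control = bands$control, deletion = bands$deletion,
                 detail = detail),
            class = "band_pattern")
}

#' Classify a gap-PCR band pattern
#'
#' Pure function of the two bands: control + deletion = `carrier`;
#' control only = `wildtype`; deletion only = `homozygous_deletion`;
#' neither = `invalid`.
#'
#' @param pattern a `band_pattern` (or list with `control$present`,
#'   `deletion$present`).
#' @return classification string.
#' @export
classify_band_pattern <- function(pattern) {
  ctrl <- isTRUE(pattern$control$present)
  del <- isTRUE(pattern$deletion$present)
  if (ctrl && del) "carrier"
  else if (ctrl) "wildtype"
  else if (del) "homozygous_deletion"
  else "invalid"
}

#' Wilson score confidence interval for a proportion
#'
#' @param k successes.
#' @param n trials (> 0).
#' @param conf confidence level.
#' @return named numeric vector `c(lower, upper)`.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  stopifnot(n >= 1L)
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, center - half), upper = min(1, center + half))
}

#' Estimate the carrier frequency from screen classifications
#'
#' @param classes character vector of per-donor classes.
#' @param count_invalid keep invalid samples in the denominator (default,
#'   matching a screen that reports carriers over all screened donors).
#' @return list with `carriers`, `n`, `frequency` and `ci` (Wilson 95%).
#' @export
estimate_frequency <- function(classes, count_invalid = TRUE) {
  if (length(classes) == 0L) stop("no samples screened")
  n <- if (count_invalid) length(classes)
       else sum(classes != "invalid")
  k <- sum(classes %in% c("carrier", "homozygous_deletion"))
  list(carriers = k, n = n, frequency = k / n, ci = wilson_ci(k, n))
}

#' Screen a donor cohort by in-silico gap-PCR
#'
#' Runs [run_gap_pcr()] + [classify_band_pattern()] on every donor.
#'
#' @param cohort a [make_cohort()] result (or list of diploid samples).
#' @param locus the locus model.
#' @param max_product screening-PCR product-size budget.
#' @return object of class `screen_result`: per-donor `data.frame`
#'   (`sample_id`, `control_band`, `deletion_band`, `class`), plus
#'   `carriers`, `n`, `frequency`, `ci`.
#' @export
screen_cohort <- function(cohort, locus, max_product = 2000L) {
  donors <- if (inherits(cohort, "screen_cohort")) cohort$donors else cohort
  rows <- lapply(donors, function(d) {
    bp <- run_gap_pcr(d, locus, max_product = max_product)
    data.frame(sample_id = bp$sample_id,
               control_band = ifelse(bp$control$present, bp$control$size, NA),
               deletion_band = ifelse(bp$deletion$present, bp$deletion$size, NA),
               class = classify_band_pattern(bp),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  est <- estimate_frequency(tab$class)
  structure(c(list(samples = tab), est), class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> %d/%d carriers = %.2f%% (95%% CI %.2f-%.2f%%)\n",
              x$carriers, x$n, 100 * x$frequency,
              100 * x$ci["lower"], 100 * x$ci["upper"]))
  invisible(x)
}

#' Confirm candidate carriers by sequencing the junction product
#'
#' For each flagged donor, the deletion-allele gap-PCR product is sequenced
#' in silico, aligned to the locus, and its junction is resolved; the
#' candidate is confirmed only when the breakpoints match the reference
#' structural-variant call exactly. Mismatching candidates are demoted with
#' the observed breakpoints as the reason.
#'
#' @param candidates character vector of candidate sample ids.
#' @param cohort the screened cohort (source of haplotype sequences).
#' @param locus the locus model.
#' @param depth sequencing depth over the junction product.
#' @param seed RNG seed.
#' @return `data.frame` with `sample_id`, `confirmed`, `left`, `right`,
#'   `reason`.
#' @export
confirm_candidates <- function(candidates, cohort, locus, depth = 300L,
                               seed = 1L) {
  if (length(candidates) == 0L)
    return(data.frame(sample_id = character(0), confirmed = logical(0),
                      left = integer(0), right = integer(0),
                      reason = character(0), stringsAsFactors = FALSE))
  donors <- if (inherits(cohort, "screen_cohort")) cohort$donors else cohort
  names(donors) <- vapply(donors, function(d) d$sample_id, character(1))
  truth_left <- locus$sv$left - 1L; truth_right <- locus$sv$right + 1L
  out <- lapply(candidates, function(id) {
    d <- donors[[id]]
    bp <- run_gap_pcr(d, locus)
    if (!bp$deletion$present)
      return(data.frame(sample_id = id, confirmed = FALSE,
                        left = NA_integer_, right = NA_integer_,
                        reason = "no_product", stringsAsFactors = FALSE))
    reads <- simulate_reads(bp$deletion$product, depth,
                            error_model("nanopore"),
                            seed = child_seed(seed, match(id, candidates)),
                            prefix = paste0(id, "_gap"))
    aln <- align_reads(reads, locus$reference, "map-ont")
    cl <- find_junctions(aln)
    if (!length(cl))
      return(data.frame(sample_id = id, confirmed = FALSE,
                        left = NA_integer_, right = NA_integer_,
                        reason = "no_junction", stringsAsFactors = FALSE))
    support <- vapply(cl, nrow, integer(1))
    sv <- resolve_junction(cl[[which.max(support)]], aln, locus)
    ok <- sv$left == truth_left && sv$right == truth_right
    data.frame(sample_id = id, confirmed = ok, left = sv$left,
               right = sv$right,
               reason = if (ok) "breakpoints_identical" else "breakpoint_mismatch",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
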