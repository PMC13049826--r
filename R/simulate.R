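# Read and cohort simulation. All randomness flows through explicit seeds so
# identical seeds give byte-identical output.

#' Sequencing error model
#'
#' Per-base substitution/insertion/deletion probabilities and the read-length
#' distribution. `"nanopore"` is the default amplicon profile (2% sub, 1.5%
#' ins, 2.5% del; 8 kb +/- 2 kb reads); `"hifi"` the whole-locus profile
#' (0.2% each; 12 kb +/- 3 kb reads).
#'
#' @param profile `"nanopore"` or `"hifi"`, or override fields directly.
#' @param sub,ins,del per-base error probabilities (each in \[0, 0.15\]).
#' @param read_length_mean,read_length_sd read length distribution in bases.
#' @return object of class `error_model`.
#' @export
error_model <- function(profile = c("nanopore", "hifi"),
                        sub = NULL, ins = NULL, del = NULL,
                        read_length_mean = NULL, read_length_sd = NULL) {
  profile <- match.arg(profile)
  def <- if (profile == "nanopore")
    list(sub = 0.02, ins = 0.015, del = 0.025,
         read_length_mean = 8000, read_length_sd = 2000)
  else
    list(sub = 0.002, ins = 0.002, del = 0.002,
         read_length_mean = 12000, read_length_sd = 3000)
  em <- list(profile = profile,
             sub = sub %||% def$sub, ins = ins %||% def$ins,
             del = del %||% def$del,
             read_length_mean = read_length_mean %||% def$read_length_mean,
             read_length_sd = read_length_sd %||% def$read_length_sd)
  stopifnot(em$sub >= 0, em$sub <= 0.15, em$ins >= 0, em$ins <= 0.15,
            em$del >= 0, em$del <= 0.15)
  structure(em, class = "error_model")
}

# Inject iid substitution/insertion/deletion errors into one read (byte level).
mutate_read <- function(seq, em) {
  if (em$sub == 0 && em$ins == 0 && em$del == 0) return(seq)
  raw4 <- charToRaw("ACGT")
  r <- charToRaw(seq)
  n <- length(r)
  ns <- rbinom(1L, n, em$sub)
  if (ns > 0L) {
    pos <- sample.int(n, ns)
    shift <- sample.int(3L, ns, replace = TRUE)
    idx <- match(r[pos], raw4)
    r[pos] <- raw4[((idx - 1L + shift) %% 4L) + 1L]
  }
  nd <- rbinom(1L, n, em$del)
  if (nd > 0L) r <- r[-sample.int(length(r), nd)]
  m <- length(r)
  ni <- rbinom(1L, m, em$ins)
  if (ni > 0L) {
    pos <- sort(sample.int(m, ni))
    out <- raw(m + ni)
    ins_idx <- pos + seq_len(ni)
    out[ins_idx] <- raw4[sample.int(4L, ni, replace = TRUE)]
    out[-ins_idx] <- r
    r <- out
  }
  rawToChar(r)
}

#' Simulate long reads from a template molecule
#'
#' Read count follows `depth * nchar(template) / read_length_mean`. Fragment
#' start positions are drawn uniformly over the extended span
#' `[2 - len, L]` and clipped to the template, which makes expected coverage
#' uniform across the whole molecule (including both ends); the realized
#' per-base coverage is therefore `depth * L / (L + read_length_mean)`.
#'
#' @param template DNA string (an amplicon product or haplotype sequence).
#' @param depth nominal sequencing depth.
#' @param em an [error_model()].
#' @param seed RNG seed.
#' @param prefix read-id prefix; truth metadata columns are attached verbatim.
#' @param meta named list of truth labels stored with every read.
#' @return `data.table` with columns `read_id`, `seq`, `tpl_start`, `tpl_end`
#'   plus one column per `meta` entry.
#' @export
simulate_reads <- function(template, depth, em = error_model(), seed = 1L,
                           prefix = "read", meta = list()) {
  L <- nchar(template)
  n <- max(1L, round(depth * L / em$read_length_mean))
  with_seed(seed, {
    lens <- pmax(200L, round(rnorm(n, em$read_length_mean, em$read_length_sd)))
    starts <- floor(runif(n, min = 2 - lens, max = L + 1))
    a <- pmax(1L, as.integer(starts))
    b <- pmin(L, as.integer(starts) + lens - 1L)
    keep <- which(b - a + 1L >= 100L)
    seqs <- character(length(keep))
    for (i in seq_along(keep)) {
      k <- keep[i]
      seqs[i] <- mutate_read(substr(template, a[k], b[k]), em)
    }
    dt <- data.table::data.table(
      read_id = sprintf("%s_r%04d", prefix, seq_along(keep)),
      seq = seqs, tpl_start = a[keep], tpl_end = b[keep])
    for (nm in names(meta)) dt[[nm]] <- meta[[nm]]
    dt[]
  })
}

# --- in-silico PCR ----------------------------------------------------------

# Primer-site search with PCR-like specificity: up to `max_mismatch`
# mismatches, none within the 3'-terminal `three_prime` bases.
find_primer_sites <- function(seqstr, primer, strand = c("+", "-"),
                              max_mismatch = 2L, three_prime = 5L) {
  strand <- match.arg(strand)
  subj <- Biostrings::DNAString(seqstr)
  pat <- Biostrings::DNAString(if (strand == "+") primer else revcomp(primer))
  # exact sites first (fast path); degraded sites only matter when none exist
  hits <- Biostrings::matchPattern(pat, subj, max.mismatch = 0L)
  if (length(hits) > 0L) return(BiocGenerics::start(hits))
  hits <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mismatch)
  if (length(hits) == 0L) return(integer(0))
  ok <- vapply(seq_along(hits), function(i) {
    site <- as.character(hits[[i]])
    p <- as.character(pat)
    # the primer's 3' end is the site's right edge on '+', left edge on '-'
    tail_site <- if (strand == "+") substr(site, nchar(site) - three_prime + 1L, nchar(site))
                 else substr(site, 1L, three_prime)
    tail_pat <- if (strand == "+") substr(p, nchar(p) - three_prime + 1L, nchar(p))
                else substr(p, 1L, three_prime)
    tail_site == tail_pat
  }, logical(1))
  BiocGenerics::start(hits)[ok]
}

#' Simulate a PCR amplification from one template molecule
#'
#' Returns the product between a matching forward-primer site and a matching
#' reverse-primer site on the same molecule when the product length does not
#' exceed `max_product` (the extension-time budget); otherwise a dropout with
#' a reason code. When several compatible site pairs exist the shortest
#' product wins.
#'
#' @param hap_seq template molecule (haplotype sequence).
#' @param fwd,rev primer sequences (5'->3'; `rev` anneals to the + strand's
#'   complement, i.e. its reverse complement must occur in `hap_seq`).
#' @param max_product longest amplifiable product in bases.
#' @param max_mismatch,three_prime primer-matching tolerance: at most
#'   `max_mismatch` mismatches, none in the 3'-terminal `three_prime` bases.
#' @return list with `status` (`"ok"` or `"dropout"`), `reason` (`NA`,
#'   `"missing_site"` or `"oversize"`), `start`, `end` (template coordinates)
#'   and `product` (sequence or `NA`).
#' @export
simulate_amplicon <- function(hap_seq, fwd, rev, max_product = 25000L,
                              max_mismatch = 2L, three_prime = 5L) {
  stopifnot(max_product > 0L)
  f <- find_primer_sites(hap_seq, fwd, "+", max_mismatch, three_prime)
  r <- find_primer_sites(hap_seq, rev, "-", max_mismatch, three_prime)
  if (length(f) == 0L || length(r) == 0L)
    return(list(status = "dropout", reason = "missing_site",
                start = NA_integer_, end = NA_integer_, product = NA_character_))
  r_end <- r + nchar(rev) - 1L
  combos <- expand.grid(f = f, e = r_end)
  combos$len <- combos$e - combos$f + 1L
  combos <- combos[combos$len >= nchar(fwd) + nchar(rev), , drop = FALSE]
  if (nrow(combos) == 0L)
    return(list(status = "dropout", reason = "missing_site",
                start = NA_integer_, end = NA_integer_, product = NA_character_))
  combos <- combos[combos$len <= max_product, , drop = FALSE]
  if (nrow(combos) == 0L)
    return(list(status = "dropout", reason = "oversize",
                start = NA_integer_, end = NA_integer_, product = NA_character_))
  best <- combos[which.min(combos$len), ]
  list(status = "ok", reason = NA_character_,
       start = as.integer(best$f), end = as.integer(best$e),
       product = substr(hap_seq, best$f, best$e))
}

# --- diploid samples and cohorts -------------------------------------------

expand_genotype_cell <- function(cell, locus) {
  out <- list()
  for (s in split_genotype(cell)) {
    if (identical(s, "SV")) out <- c(out, list(locus$sv$variant))
    else out <- c(out, list(parse_hgvs(s, locus$transcript, locus$reference)))
  }
  out
}

# sample background heterozygous SNVs for one haplotype
draw_benign_snvs <- function(locus, avoid, rate, guaranteed_overlap = 2L) {
  pool <- locus$benign_pool
  n_bg <- rpois(1L, length(pool) * rate)
  pos <- sample(pool, min(n_bg, length(pool)))
  for (j in seq_len(nrow(locus$overlaps))) {
    ov <- pool[pool >= locus$overlaps$start[j] & pool <= locus$overlaps$end[j]]
    if (length(ov)) pos <- c(pos, sample(ov, min(guaranteed_overlap, length(ov))))
  }
  pos <- setdiff(sort(unique(pos)), integer(0))
  if (length(avoid)) pos <- pos[!vapply(pos, function(p)
    any(p >= avoid[, 1] & p <= avoid[, 2]), logical(1))]
  lapply(pos, function(p) {
    rb <- ref_sub(locus$reference, p, p)
    new_variant(p, rb, other_base(rb), "SNV")
  })
}

avoid_intervals <- function(variants, margin = 15L) {
  if (length(variants) == 0L) return(matrix(numeric(0), ncol = 2))
  t(vapply(variants, function(v) {
    sp <- variant_span(v); c(sp[1] - margin, sp[2] + margin)
  }, numeric(2)))
}

#' Build a diploid sample from per-haplotype variant lists
#'
#' Applies the listed variants (plus optional background heterozygous SNVs
#' emulating natural polymorphism between the two parental haplotypes) to the
#' reference and retains full truth labels.
#'
#' @param locus a [build_reference_locus()] model.
#' @param sample_id sample identifier.
#' @param hap1,hap2 lists of `variant` records (the reportable truth).
#' @param seed RNG seed for the background SNVs.
#' @param het_snp_rate background heterozygous SNV rate per available
#'   intronic base (0 disables); each SNV lands on one haplotype.
#' @param type optional study-type label.
#' @return object of class `diploid_sample` with fields `sample_id`, `type`,
#'   `variants` (list of 2: truth + background, the applied edit lists),
#'   `truth` (list of 2: reportable truth variants only), `hap1`, `hap2`
#'   (sequences) and `map1`, `map2` (locus-to-haplotype coordinate maps).
#' @export
diploid_sample <- function(locus, sample_id, hap1, hap2, seed = 1L,
                           het_snp_rate = 1 / 1500, type = NA_character_) {
  benign <- with_seed(seed, {
    lapply(list(hap1, hap2), function(truth) {
      if (het_snp_rate <= 0) return(list())
      draw_benign_snvs(locus, avoid_intervals(truth), het_snp_rate)
    })
  })
  vars1 <- c(hap1, benign[[1]])
  vars2 <- c(hap2, benign[[2]])
  a1 <- apply_variants(locus$reference, vars1)
  a2 <- apply_variants(locus$reference, vars2)
  structure(list(sample_id = sample_id, type = type,
                 truth = list(hap1, hap2),
                 variants = list(vars1, vars2),
                 hap1 = a1$sequence, hap2 = a2$sequence,
                 map1 = a1$map, map2 = a2$map),
            class = "diploid_sample")
}

#' @export
print.diploid_sample <- function(x, ...) {
  cat(sprintf("<diploid_sample> %s: %d + %d truth variants (%d + %d applied)\n",
              x$sample_id, length(x$truth[[1]]), length(x$truth[[2]]),
              length(x$variants[[1]]), length(x$variants[[2]])))
  invisible(x)
}

#' Materialize the study's 43-sample deficiency cohort
#'
#' Expands [study_genotypes()] against the synthetic locus: 14 type I and 29
#' type II samples (86 haplotypes) carrying exactly the encoded variant
#' lists, with seeded background heterozygous SNVs.
#'
#' @param locus a [build_reference_locus()] model.
#' @param seed RNG seed.
#' @param het_snp_rate background heterozygous SNV rate (see
#'   [diploid_sample()]).
#' @return list of `diploid_sample` objects.
#' @export
make_study_cohort <- function(locus, seed = 1L, het_snp_rate = 1 / 1500) {
  gt <- study_genotypes()
  lapply(seq_len(nrow(gt)), function(i) {
    diploid_sample(locus, gt$sample_id[i],
                   expand_genotype_cell(gt$hap1[i], locus),
                   expand_genotype_cell(gt$hap2[i], locus),
                   seed = child_seed(seed, i),
                   het_snp_rate = het_snp_rate, type = gt$type[i])
  })
}

#' Simulate whole-locus long reads from a diploid sample
#'
#' Draws reads from both haplotypes with equal per-base probability using a
#' low-error (HiFi-like) profile by default.
#'
#' @param sample a [diploid_sample()].
#' @param depth total nominal depth (split evenly across the haplotypes).
#' @param em an [error_model()].
#' @param seed RNG seed.
#' @return `data.table` of reads with truth columns `sample_id` and `hap`.
#' @export
simulate_wgs_reads <- function(sample, depth = 30, em = error_model("hifi"),
                               seed = 1L) {
  stopifnot(depth >= 2)
  r1 <- simulate_reads(sample$hap1, depth / 2, em, child_seed(seed, 1L),
                       prefix = paste0(sample$sample_id, "_h1"),
                       meta = list(sample_id = sample$sample_id, hap = "H1"))
  r2 <- simulate_reads(sample$hap2, depth / 2, em, child_seed(seed, 2L),
                       prefix = paste0(sample$sample_id, "_h2"),
                       meta = list(sample_id = sample$sample_id, hap = "H2"))
  data.table::rbindlist(list(r1, r2))
}

#' Simulate the four-amplicon panel for a diploid sample
#'
#' Runs the in-silico long-range PCR of every panel amplicon on both
#' haplotypes and sequences each successful product. Dropouts (e.g. loss of a
#' primer site on a deletion haplotype) yield no reads, exactly like a failed
#' amplification.
#'
#' @param sample a [diploid_sample()].
#' @param locus the locus model.
#' @param depth per-product nominal depth.
#' @param em an [error_model()].
#' @param seed RNG seed.
#' @param max_product longest amplifiable product (long-range PCR budget).
#' @return list with `reads` (pooled `data.table`, truth labels retained) and
#'   `products` (per haplotype x amplicon PCR outcomes).
#' @export
simulate_amplicon_reads <- function(sample, locus, depth = 20,
                                    em = error_model("nanopore"), seed = 1L,
                                    max_product = 25000L) {
  panel <- locus$panel
  haps <- list(H1 = sample$hap1, H2 = sample$hap2)
  products <- list()
  reads <- list()
  k <- 0L
  for (h in names(haps)) {
    for (i in seq_len(nrow(panel))) {
      k <- k + 1L
      pcr <- simulate_amplicon(haps[[h]], panel$fwd[i], panel$rev[i],
                               max_product = max_product)
      products[[paste(h, panel$name[i], sep = ".")]] <- pcr
      if (pcr$status == "ok") {
        reads[[k]] <- simulate_reads(
          pcr$product, depth, em, child_seed(seed, k),
          prefix = paste(sample$sample_id, h, panel$name[i], sep = "_"),
          meta = list(sample_id = sample$sample_id, hap = h,
                      amplicon = panel$name[i]))
      }
      ap_log("simulate_amplicon", sample = sample$sample_id, hap = h,
             amplicon = panel$name[i], status = pcr$status,
             reason = pcr$reason)
    }
  }
  list(reads = data.table::rbindlist(reads), products = products)
}

#' Build a donor cohort for the gap-PCR population screen
#'
#' `n` donors, `n_carriers` of which are heterozygous for the locus's
#' structural variant; every donor additionally carries sparse background
#' heterozygous SNVs.
#'
#' @param locus the locus model.
#' @param n cohort size.
#' @param n_carriers number of heterozygous SV carriers to implant.
#' @param seed RNG seed.
#' @param het_snp_rate background SNV rate per haplotype.
#' @return object of class `screen_cohort`: list with `donors` (list of
#'   `diploid_sample`), `n`, and `carrier_ids` (truth).
#' @export
make_cohort <- function(locus, n = 600L, n_carriers = 3L, seed = 1L,
                        het_snp_rate = 1 / 4000) {
  stopifnot(n_carriers <= n)
  carrier_idx <- with_seed(child_seed(seed, 0L), sort(sample.int(n, n_carriers)))
  donors <- lapply(seq_len(n), function(i) {
    is_carrier <- i %in% carrier_idx
    sv_hap <- if (is_carrier)
      with_seed(child_seed(seed, 10L * i + 5L), sample(1:2, 1)) else 0L
    hap1 <- if (sv_hap == 1L) list(locus$sv$variant) else list()
    hap2 <- if (sv_hap == 2L) list(locus$sv$variant) else list()
    diploid_sample(locus, sprintf("donor%03d", i), hap1, hap2,
                   seed = child_seed(seed, i), het_snp_rate = het_snp_rate)
  })
  structure(list(donors = donors, n = n,
                 carrier_ids = sprintf("donor%03d", carrier_idx)),
            class = "screen_cohort")
}
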