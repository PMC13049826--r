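# End-to-end orchestration: simulate -> reconstruct -> call -> screen ->
# report, plus the run configuration record written beside every output set.

#' Pipeline run configuration
#'
#' Collects every tunable threshold with its default; serializable to JSON
#' and back without loss.
#'
#' @param seed master seed.
#' @param depth per-product amplicon sequencing depth.
#' @param wgs_depth whole-locus sequencing depth.
#' @param amplicon_error,wgs_error [error_model()] profiles.
#' @param min_depth,min_frac,min_count,min_indel heterozygous-site thresholds.
#' @param min_reads low-support cluster threshold.
#' @param min_span shortest aligned span kept for clustering.
#' @param min_sv_size,min_support structural-variant caller thresholds.
#' @param max_product long-range PCR size budget.
#' @param gap_max_product screening-PCR size budget.
#' @param cohort_n,cohort_carriers screening-cohort geometry.
#' @param het_snp_rate background heterozygous SNV rate for the study cohort.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, depth = 20, wgs_depth = 30,
                       amplicon_error = error_model("nanopore"),
                       wgs_error = error_model("hifi"),
                       min_depth = 20L, min_frac = 0.2, min_count = 5L,
                       min_indel = 5L, min_reads = 5L, min_span = 1000L,
                       min_sv_size = 50L, min_support = 3L,
                       max_product = 25000L, gap_max_product = 2000L,
                       cohort_n = 600L, cohort_carriers = 3L,
                       het_snp_rate = 1 / 1500) {
  cfg <- as.list(environment())
  if (cfg$cohort_carriers > cfg$cohort_n)
    stop("config: cohort_carriers exceeds cohort_n")
  structure(cfg, class = "run_config")
}

config_to_json <- function(cfg, path = NULL) {
  x <- lapply(unclass(cfg), function(v)
    if (inherits(v, "error_model")) unclass(v) else v)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) writeLines(js, path)
  js
}

config_from_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  for (f in c("amplicon_error", "wgs_error")) {
    em <- as.list(x[[f]])
    x[[f]] <- error_model(em$profile, sub = em$sub, ins = em$ins,
                          del = em$del,
                          read_length_mean = em$read_length_mean,
                          read_length_sd = em$read_length_sd)
  }
  do.call(run_config, x)
}

#' Reconstruct a sample's haplotypes from amplicon long reads
#'
#' Aligns the pooled reads to the locus, assigns them to panel amplicons,
#' detects heterozygous sites, clusters each amplicon's reads into allele
#' groups, calls per-allele consensus sequences, phases the clusters across
#' the amplicon overlaps, and screens the provenance for the
#' amplicon-dropout SV signature.
#'
#' @param reads `data.table` with `read_id`, `seq` (truth columns ignored).
#' @param locus the locus model.
#' @param cfg a [run_config()].
#' @param sample_id label carried through the reports.
#' @return object of class `sample_reconstruction`: `phased`
#'   (`phased_haplotypes`), `dropout` ([detect_dropout_pattern()] result),
#'   `clusters` (per amplicon: member read ids per cluster), `calls`
#'   (`sample_calls` over the reconstructed haplotypes) and `aln` statistics.
#' @export
reconstruct_sample <- function(reads, locus, cfg = run_config(),
                               sample_id = "sample") {
  ref <- locus$reference; panel <- locus$panel
  aln <- align_reads(reads, ref, "map-ont")
  aln <- aln[!aln$supplementary & (aln$ref_end - aln$ref_start + 1L) >=
               cfg$min_span, ]
  amp_of <- assign_amplicon(aln, panel)
  ap_log("align", sample = sample_id, reads = nrow(reads),
         aligned = nrow(aln), unassigned = sum(amp_of == "unassigned"))
  amp_clusters <- vector("list", nrow(panel))
  cluster_members <- vector("list", nrow(panel))
  names(amp_clusters) <- names(cluster_members) <- panel$name
  for (i in seq_len(nrow(panel))) {
    sub <- aln[amp_of == panel$name[i], ]
    region <- c(panel$start[i], panel$end[i])
    if (nrow(sub) == 0L) {
      amp_clusters[[i]] <- list(); cluster_members[[i]] <- list()
      next
    }
    clusters <- if (nrow(sub) >= cfg$min_depth) {
      het <- detect_het_sites(sub, region, ref, min_depth = cfg$min_depth,
                              min_frac = cfg$min_frac,
                              min_count = cfg$min_count,
                              min_indel = cfg$min_indel)
      cluster_alleles(het, sub, min_reads = cfg$min_reads)
    } else {
      list(list(members = seq_len(nrow(sub)), signature = integer(0),
                low_support = TRUE))
    }
    # a genuine allele cluster must reach the amplicon's exclusive core:
    # reads contained in a shared overlap are ambiguous between the two
    # flanking amplicons and can form debris clusters that would wrongly
    # resurrect a dropped amplicon
    core_lo <- if (i > 1L) panel$end[i - 1L] + 1L else panel$start[i]
    core_hi <- if (i < nrow(panel)) panel$start[i + 1L] - 1L else panel$end[i]
    unassigned <- attr(clusters, "unassigned") %||% integer(0)
    clusters <- Filter(function(cl) {
      any(sub$ref_start[cl$members] <= core_hi &
            sub$ref_end[cl$members] >= core_lo)
    }, clusters)
    # a single surviving cluster owns the whole amplicon: fold the reads
    # that covered no informative site back in, so its consensus has no
    # coverage holes at the amplicon ends
    if (length(clusters) == 1L && length(unassigned))
      clusters[[1L]]$members <- sort(unique(c(clusters[[1L]]$members,
                                              unassigned)))
    amp_clusters[[i]] <- lapply(clusters, function(cl)
      call_consensus(sub[cl$members, ], region, ref))
    cluster_members[[i]] <- lapply(clusters, function(cl)
      sub$read_id[cl$members])
    ap_log("cluster", sample = sample_id, amplicon = panel$name[i],
           reads = nrow(sub), clusters = length(clusters),
           unassigned = length(attr(clusters, "unassigned")))
  }
  phased <- phase_amplicons(amp_clusters, locus, sample_id)
  dropout <- detect_dropout_pattern(phased)
  ap_log("phase", sample = sample_id, dropout = dropout$flag,
         amplicons = dropout$amplicons)
  calls <- calls_from_phased(phased, locus, sample_id)
  structure(list(sample_id = sample_id, phased = phased, dropout = dropout,
                 clusters = cluster_members, calls = calls,
                 n_aligned = nrow(aln)),
            class = "sample_reconstruction")
}

# reportable calls from the phased segments' consensus columns
calls_from_phased <- function(phased, locus, sample_id,
                              type = NA_character_) {
  ref <- locus$reference; tx <- locus$transcript
  per_hap <- lapply(list(phased$h1, phased$h2), function(h) {
    vs <- list()
    for (seg in h$segments) vs <- c(vs, consensus_diff(seg, ref))
    vs[order(vapply(vs, function(v) v$pos, integer(1)))]
  })
  rep1 <- filter_reportable(per_hap[[1]], tx)
  rep2 <- filter_reportable(per_hap[[2]], tx)
  structure(list(sample_id = sample_id, type = type,
                 all = per_hap, reportable = list(rep1, rep2),
                 hgvs = list(vapply(rep1, hgvs_name, character(1), tx = tx),
                             vapply(rep2, hgvs_name, character(1), tx = tx)),
                 zygosity = classify_zygosity(rep1, rep2)),
            class = "sample_calls")
}

#' Simulate the full study data set to disk
#'
#' Writes the locus bundle (reference FASTA, exon/amplicon/SV BED, transcript
#' and panel TSV), the 43-sample deficiency-cohort manifest, the screening
#' cohort manifest, the exact run configuration, and a checksum manifest.
#' Per-sample FASTQ is written for `samples` (default: the SV compound
#' heterozygote) to keep the output volume proportionate; reads for any
#' sample are regenerable from the seed.
#'
#' @param cfg a [run_config()].
#' @param outdir output directory (created).
#' @param samples sample ids to write amplicon FASTQ for, or `"all"`.
#' @return invisible list with the locus, cohorts and file manifest.
#' @export
cmd_simulate <- function(cfg = run_config(), outdir, samples = "I-12") {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  locus <- build_reference_locus(cfg$seed)
  cohort <- make_study_cohort(locus, seed = cfg$seed,
                              het_snp_rate = cfg$het_snp_rate)
  screen <- make_cohort(locus, n = cfg$cohort_n,
                        n_carriers = cfg$cohort_carriers, seed = cfg$seed)
  files <- character(0)
  p <- function(f) file.path(outdir, f)
  write_fasta(c(locus = locus$reference$sequence), p("reference.fa"))
  write_bed(data.frame(start = locus$transcript$exons$start,
                       end = locus$transcript$exons$end,
                       name = paste0("exon", seq_len(locus$transcript$n_exons))),
            p("exons.bed"), chrom = locus$reference$name)
  write_bed(data.frame(start = locus$panel$start, end = locus$panel$end,
                       name = locus$panel$name),
            p("amplicons.bed"), chrom = locus$reference$name)
  write_bed(data.frame(start = locus$sv$left, end = locus$sv$right,
                       name = paste0("sv_truth_", locus$sv$hgvs_g)),
            p("sv_truth.bed"), chrom = locus$reference$name)
  write.table(locus$panel, p("panel.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  gt <- study_genotypes()
  write.table(gt, p("study_cohort.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  screen_manifest <- data.frame(
    sample_id = vapply(screen$donors, function(d) d$sample_id, character(1)),
    carrier = vapply(screen$donors, function(d)
      d$sample_id %in% screen$carrier_ids, logical(1)))
  write.table(screen_manifest, p("screen_cohort.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  config_to_json(cfg, p("config.json"))
  files <- c("reference.fa", "exons.bed", "amplicons.bed", "sv_truth.bed",
             "panel.tsv", "study_cohort.tsv", "screen_cohort.tsv",
             "config.json")
  if (identical(samples, "all"))
    samples <- vapply(cohort, function(s) s$sample_id, character(1))
  for (sid in samples) {
    s <- cohort[[match(sid, gt$sample_id)]]
    sim <- simulate_amplicon_reads(s, locus, depth = cfg$depth,
                                   em = cfg$amplicon_error,
                                   seed = child_seed(cfg$seed, match(sid, gt$sample_id)))
    f <- paste0(sid, ".amplicons.fastq")
    write_fastq(sim$reads, p(f))
    files <- c(files, f)
  }
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(outdir, files))))
  write.table(manifest, p("MANIFEST.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  ap_log("simulate", outdir = outdir, files = length(files))
  invisible(list(locus = locus, cohort = cohort, screen = screen,
                 manifest = manifest))
}

#' Run the reconstruction pipeline on one sample
#'
#' Amplicon reads are reconstructed into phased haplotypes and reportable
#' calls; when the dropout signature flags an SV candidate, whole-locus
#' reads (supplied or simulated from the truth sample) are used to resolve
#' the junction, and the confirmed SV joins the flagged haplotype's call
#' set before zygosity classification.
#'
#' @param reads amplicon read table (`read_id`, `seq`).
#' @param locus the locus model.
#' @param cfg a [run_config()].
#' @param sample_id label.
#' @param wgs_reads optional whole-locus read table for SV resolution.
#' @param outdir optional directory for per-sample outputs (phased FASTA,
#'   VCF, zygosity TSV).
#' @return object of class `sample_report`: the reconstruction plus `sv`
#'   (list of `sv_call`) and final `calls`.
#' @export
cmd_run <- function(reads, locus, cfg = run_config(), sample_id = "sample",
                    wgs_reads = NULL, outdir = NULL) {
  rec <- reconstruct_sample(reads, locus, cfg, sample_id)
  svs <- list()
  calls <- rec$calls
  if (rec$dropout$flag == "sv_candidate" && !is.null(wgs_reads)) {
    aln <- align_reads(wgs_reads, locus$reference, "map-hifi")
    svs <- call_sv(aln, locus, min_sv_size = cfg$min_sv_size,
                   min_support = cfg$min_support)
    if (length(svs)) {
      hap_idx <- if (rec$dropout$hap == "H1") 1L else 2L
      calls$reportable[[hap_idx]] <- c(calls$reportable[[hap_idx]],
                                       lapply(svs, `[[`, "variant"))
      calls$hgvs[[hap_idx] ] <- c(calls$hgvs[[hap_idx]],
                                  vapply(svs, `[[`, "", "hgvs_c"))
      calls$zygosity <- classify_zygosity(calls$reportable[[1]],
                                          calls$reportable[[2]])
    }
  }
  ap_log("run", sample = sample_id, zygosity = calls$zygosity,
         sv_calls = length(svs))
  rep <- structure(list(sample_id = sample_id, reconstruction = rec,
                        dropout = rec$dropout, sv = svs, calls = calls),
                   class = "sample_report")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(setNames(
      list(rec$phased$h1$sequence, rec$phased$h2$sequence),
      paste0(sample_id, c("_H1 ", "_H2 "),
             c(paste(rec$phased$h1$provenance, collapse = ","),
               paste(rec$phased$h2$provenance, collapse = ",")))),
      file.path(outdir, paste0(sample_id, ".phased.fa")))
    sv1 <- if (length(svs)) { s <- svs[[1]]; attr(s, "hap") <- rec$dropout$hap; s }
    write_vcf(calls, locus$reference,
              file.path(outdir, paste0(sample_id, ".vcf")), sv = sv1)
    write.table(
      data.frame(sample_id = sample_id, zygosity = calls$zygosity,
                 dropout = rec$dropout$flag,
                 dropout_amplicons = paste(rec$dropout$amplicons,
                                           collapse = ",")),
      file.path(outdir, paste0(sample_id, ".zygosity.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  rep
}

#' Screen a cohort and write the summary
#'
#' @param cohort a [make_cohort()] result.
#' @param locus the locus model.
#' @param cfg a [run_config()].
#' @param outdir optional output directory (band TSV + summary JSON).
#' @param confirm run sequencing confirmation on candidate carriers.
#' @param seed seed for the confirmation sequencing.
#' @return `screen_result` with a `confirmation` field when requested.
#' @export
cmd_screen <- function(cohort, locus, cfg = run_config(), outdir = NULL,
                       confirm = TRUE, seed = NULL) {
  res <- screen_cohort(cohort, locus, max_product = cfg$gap_max_product)
  if (confirm) {
    cand <- res$samples$sample_id[res$samples$class %in%
                                    c("carrier", "homozygous_deletion")]
    res$confirmation <- confirm_candidates(cand, cohort, locus,
                                           seed = seed %||% cfg$seed)
    res$n_demoted <- sum(!res$confirmation$confirmed)
  }
  ap_log("screen", n = res$n, carriers = res$carriers,
         demoted = res$n_demoted %||% 0L)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write.table(res$samples, file.path(outdir, "screen_bands.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    summary <- list(n = res$n, carriers = res$carriers,
                    frequency = res$frequency,
                    ci_lower = unname(res$ci["lower"]),
                    ci_upper = unname(res$ci["upper"]),
                    demoted = res$n_demoted %||% 0L)
    writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA),
               file.path(outdir, "screen_summary.json"))
  }
  res
}
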