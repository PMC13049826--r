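# Encoded per-haplotype genotypes of the 43-sample CD36-deficiency study
# cohort (14 type I, 29 type II). Entries are semicolon-separated HGVS c.
# strings; "-" marks a reference haplotype. "SV" expands to the locus's
# 19,971-bp deletion-insertion descriptor (see build_reference_locus()).

#' Study cohort genotype table
#'
#' Per-sample haplotype genotypes of the 43-donor deficiency cohort
#' (14 type I and 29 type II samples; 86 haplotypes). Variants are HGVS `c.`
#' strings; `"-"` denotes a reference haplotype and `"SV"` the recurrent
#' structural variant.
#'
#' @return data.frame with columns `sample_id`, `type`, `hap1`, `hap2`.
#' @export
study_genotypes <- function() {
  del12 <- "c.1228_1239delATTGTGCCTATT"
  pro <- "c.-132A>C"
  rows <- rbind(
    c("I-01",  "I",  pro,                              "c.430-1G>C; c.-132A>C"),
    c("I-02",  "I",  pro,                              del12),
    c("I-03",  "I",  pro,                              "c.1229T>C; c.-132A>C"),
    c("I-04",  "I",  "c.332_333delCA; c.-132A>C",      del12),
    c("I-05",  "I",  "c.332_333delCA; c.-132A>C",      del12),
    c("I-06",  "I",  "c.332_333delCA; c.-132A>C",      del12),
    c("I-07",  "I",  "c.380C>T",                       del12),
    c("I-08",  "I",  "c.430-2A>G",                     "c.609+7A>G; c.-132A>C"),
    c("I-09",  "I",  del12,                            "c.1156C>T"),
    c("I-10",  "I",  del12,                            "c.1156C>T; c.1409C>T"),
    c("I-11",  "I",  del12,                            del12),
    c("I-12",  "I",  "SV",                             "c.1006+2T>G"),
    c("I-13",  "I",  "SV",                             "c.1156C>T; c.1409C>T"),
    c("I-14",  "I",  "SV",                             "c.1163A>T"),
    c("II-01", "II", pro,                              "-"),
    c("II-02", "II", pro,                              "-"),
    c("II-03", "II", "c.220C>T; c.-132A>C",            pro),
    c("II-04", "II", "c.275C>T",                       "-"),
    c("II-05", "II", "c.332_333delCA",                 "-"),
    c("II-06", "II", "c.332_333delCA; c.-132A>C",      "-"),
    c("II-07", "II", "c.332_333delCA; c.-132A>C",      "-"),
    c("II-08", "II", "c.332_333delCA; c.-132A>C",      "-"),
    c("II-09", "II", "c.332_333delCA; c.-132A>C",      "-"),
    c("II-10", "II", "c.332_333delCA; c.-132A>C",      "-"),
    c("II-11", "II", "c.429+3insG",                    "-"),
    c("II-12", "II", "c.847G>A",                       "-"),
    c("II-13", "II", "c.1156C>T",                      "-"),
    c("II-14", "II", "c.1156C>T",                      "-"),
    c("II-15", "II", "c.1156C>T; c.1409C>T",           "-"),
    c("II-16", "II", del12,                            "-"),
    c("II-17", "II", del12,                            "-"),
    c("II-18", "II", del12,                            pro),
    c("II-19", "II", del12,                            "c.609+7A>G; c.-132A>C"),
    c("II-20", "II", paste0(del12, "; c.-132A>C"),     "-"),
    c("II-21", "II", "c.1340_1343dupTCTT",             "-"),
    c("II-22", "II", "SV",                             "c.681C>A"),
    c("II-23", "II", "-",                              "-"),
    c("II-24", "II", "-",                              "-"),
    c("II-25", "II", "-",                              "-"),
    c("II-26", "II", "-",                              "-"),
    c("II-27", "II", "-",                              "-"),
    c("II-28", "II", "-",                              "-"),
    c("II-29", "II", "-",                              "-")
  )
  data.frame(sample_id = rows[, 1], type = rows[, 2],
             hap1 = rows[, 3], hap2 = rows[, 4], stringsAsFactors = FALSE)
}

# split a genotype cell into individual HGVS strings ("" for reference)
split_genotype <- function(cell) {
  if (identical(trimws(cell), "-")) return(character(0))
  trimws(strsplit(cell, ";")[[1]])
}
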