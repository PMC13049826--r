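# Synthetic locus construction. The generated locus reproduces the study's
# assay geometry exactly: a ~77 kb gene with 15 exons (coding starts in
# exon 3), a four-amplicon long-range PCR tiling panel of 20.6/22/20.6/23 kb
# with >= 3 kb overlaps, a recurrent 19,971-bp deletion-insertion whose left
# breakpoint renders c.1-15966, and a gap-PCR assay with a 333-bp control
# product, an 832-bp deletion-allele product and a 20,787-bp (unamplifiable)
# wild-type product.

amplicon_primers <- function() {
  data.frame(
    name = paste0("amp", 1:4),
    fwd_name = paste0("CD36 ", 1:4, "F"),
    rev_name = paste0("CD36 ", 1:4, "R"),
    fwd = c("CTCCCTCACCACCTATCCCTATAAGCT",
            "CAAAGTGGCTACGGCGATTGTAAGGATC",
            "TCCAAATTCAGACTCGGATTCCATTCAT",
            "GGCTTAGACAGTAAATGCTATGAACCAAG"),
    rev = c("CTGCCACTGCTTCATCAACCAACTTTA",
            "ACAGTAGTGTCACCTCCCGTCATCTGG",
            "ACCTTACCATACACTTGCAGCAGAAAT",
            "CACCGTCTTACACTTTGCTACTTCTTACA"),
    start = c(201L, 17701L, 36701L, 54201L),
    end = c(20800L, 39700L, 57300L, 77200L),
    coverage = c("5'UTR~exon 1", "intron 1", "exon 2~3", "exon 4~14"),
    stringsAsFactors = FALSE
  )
}

gap_primers <- function() {
  list(del_fwd = "GTGTCAAACTGTCATCGGGGTG",    # CD36 5F
       del_rev = "GACCCTTTTCCACAGTGCTTTG",    # CD36 5R
       ctrl_fwd = "CAGAGAGATGTGGAGGGGAGTT",   # CD36 6F
       ctrl_rev = "TCTTGCCCCTTCCTCCCTTTA")    # CD36 6R
}

# fixed genomic layout (1-based inclusive)
locus_layout <- function() {
  exons <- data.frame(
    start = c(15000L, 45000L, 49404L, 58000L, 59000L, 60500L, 61500L,
              62500L, 63500L, 64500L, 66000L, 67500L, 69000L, 70500L, 72000L),
    end   = c(15200L, 45119L, 49673L, 58179L, 59128L, 60679L, 61590L,
              62559L, 63559L, 64685L, 66113L, 67579L, 69079L, 70632L, 72400L))
  list(length = 77400L, exons = exons, cds_start = 49554L, cds_end = 70632L,
       sv_left = 33588L, sv_right = 53558L,       # deleted interval, inclusive
       sv_insert = "CCAATGCTAAGGTTGA",
       gap_del_fwd_start = 33033L,                # 555 ref bases 5' of the cut
       gap_del_rev_end = 53819L,                  # 261 ref bases 3' of the cut
       gap_ctrl_fwd_start = 61700L, gap_ctrl_rev_end = 62032L)
}

# base stamps forcing reference alleles/motifs required by the study genotypes
locus_stamps <- function(lay) {
  g <- function(off) lay$cds_start + off     # offset from c.1 within exon 3/4+
  list(
    list(pos = 49554L, seq = "ATG"),         # translation initiation, exon 3
    list(pos = 49422L, seq = "A"),           # c.-132
    list(pos = 58099L, seq = "C"),           # c.220
    list(pos = 58154L, seq = "C"),           # c.275
    list(pos = 59031L, seq = "CA"),          # c.332_333
    list(pos = 59079L, seq = "C"),           # c.380
    list(pos = 59131L, seq = "CA"),          # c.429+3 context (blocks G shifts)
    list(pos = 60498L, seq = "AG"),          # c.430-2, c.430-1
    list(pos = 60686L, seq = "A"),           # c.609+7
    list(pos = 61571L, seq = "C"),           # c.681
    list(pos = 64526L, seq = "G"),           # c.847
    list(pos = 64687L, seq = "T"),           # c.1006+2
    list(pos = 67535L, seq = "C"),           # c.1156
    list(pos = 67542L, seq = "A"),           # c.1163
    list(pos = 69026L, seq = "TATTGTGCCTATTG"),  # c.1227..1240; repeat context
    list(pos = 70559L, seq = "TCTTA"),       # c.1340_1343 dup unit + stop base
    list(pos = 70628L, seq = "C"),           # c.1409
    list(pos = 33588L, seq = "T"),           # SV left: != insert's first base
    list(pos = 53558L, seq = "G")            # SV right: != insert's last base
  )
}

stamp_seq <- function(chars, stamps) {
  for (s in stamps) {
    idx <- s$pos + seq_len(nchar(s$seq)) - 1L
    chars[idx] <- strsplit(s$seq, "")[[1]]
  }
  chars
}

primer_site_table <- function(lay) {
  amps <- amplicon_primers(); gp <- gap_primers()
  fwd <- data.frame(name = c(amps$fwd_name, "CD36 5F", "CD36 6F"),
                    seq = c(amps$fwd, gp$del_fwd, gp$ctrl_fwd),
                    start = c(amps$start, lay$gap_del_fwd_start,
                              lay$gap_ctrl_fwd_start),
                    strand = "+", stringsAsFactors = FALSE)
  rev_seqs <- c(amps$rev, gp$del_rev, gp$ctrl_rev)
  rev_ends <- c(amps$end, lay$gap_del_rev_end, lay$gap_ctrl_rev_end)
  rev <- data.frame(name = c(amps$rev_name, "CD36 5R", "CD36 6R"),
                    seq = rev_seqs,
                    start = rev_ends - nchar(rev_seqs) + 1L,
                    strand = "-", stringsAsFactors = FALSE)
  rbind(fwd, rev)
}

#' Build the synthetic reference locus
#'
#' Generates a 77.4 kb locus with the study's fixed assay geometry on a
#' seeded random background: 15 exons (12 coding, ATG in exon 3), the four
#' tiling-amplicon primer pairs at positions giving products of exactly
#' 20,600 / 22,000 / 20,600 / 23,000 bp with 3.0-3.1 kb overlaps, the gap-PCR
#' primer pairs, and all reference bases required by the study's variant
#' catalogue (e.g. the `TATTGTGCCTATT` repeat context that makes the
#' 12-bp exon 13 deletion's two printed spellings aliases). Each primer is
#' verified to occur exactly once (allowing up to 2 mismatches); if the random
#' background happens to create a spurious site, it is regenerated.
#'
#' @param seed integer RNG seed; the same seed yields a byte-identical locus.
#' @return object of class `locus_model`: list with `reference`
#'   ([locus_reference()]), `transcript` ([transcript_model()]), `panel`
#'   (amplicon table with primer sequences and expected coordinates),
#'   `overlaps` (junction intervals), `sv` (truth structural variant:
#'   `variant`, breakpoints, HGVS names), `gap_assay` (primer sequences and
#'   expected product sizes) and `benign_pool` (intronic positions available
#'   to the background-polymorphism generator).
#' @export
build_reference_locus <- function(seed = 1L) {
  lay <- locus_layout()
  stamps <- locus_stamps(lay)
  sites <- primer_site_table(lay)
  site_seq <- ifelse(sites$strand == "+", sites$seq,
                     vapply(sites$seq, revcomp, character(1)))
  site_end <- sites$start + nchar(site_seq) - 1L

  for (attempt in 0:4) {
    chars <- with_seed(child_seed(seed, attempt), {
      sample(DNA_BASES, lay$length, replace = TRUE)
    })
    chars <- stamp_seq(chars, stamps)
    for (i in seq_len(nrow(sites)))
      chars[sites$start[i]:site_end[i]] <- strsplit(site_seq[i], "")[[1]]
    seqstr <- paste(chars, collapse = "")
    if (all_primers_unique(seqstr, sites$seq)) break
    if (attempt == 4L) stop("could not place primers uniquely")
  }

  reference <- locus_reference("locus", seqstr)
  tx <- transcript_model(lay$exons, lay$cds_start, lay$cds_end,
                         locus_length = lay$length)

  panel <- amplicon_primers()
  panel$length <- panel$end - panel$start + 1L
  overlaps <- data.frame(
    junction = 1:3,
    start = panel$start[2:4],
    end = panel$end[1:3])
  overlaps$width <- overlaps$end - overlaps$start + 1L

  sv_var <- new_variant(lay$sv_left,
                        ref_sub(reference, lay$sv_left, lay$sv_right),
                        lay$sv_insert, "DELINS")
  sv <- list(variant = sv_var, left = lay$sv_left, right = lay$sv_right,
             del_len = lay$sv_right - lay$sv_left + 1L,
             insert = lay$sv_insert,
             hgvs_c = hgvs_name(sv_var, tx, "c"),
             hgvs_g = hgvs_name(sv_var, tx, "g"))

  gp <- gap_primers()
  gap_assay <- list(
    del_fwd = gp$del_fwd, del_rev = gp$del_rev,
    ctrl_fwd = gp$ctrl_fwd, ctrl_rev = gp$ctrl_rev,
    del_product = (lay$sv_left - lay$gap_del_fwd_start) +       # 555 left
      nchar(lay$sv_insert) +                                    # 16 insert
      (lay$gap_del_rev_end - lay$sv_right),                     # 261 right
    wt_product = lay$gap_del_rev_end - lay$gap_del_fwd_start + 1L,
    ctrl_product = lay$gap_ctrl_rev_end - lay$gap_ctrl_fwd_start + 1L)

  structure(list(reference = reference, transcript = tx, panel = panel,
                 overlaps = overlaps, sv = sv, gap_assay = gap_assay,
                 benign_pool = benign_pool(lay, sites, site_end),
                 layout = lay, seed = seed),
            class = "locus_model")
}

all_primers_unique <- function(seqstr, primers) {
  subj <- Biostrings::DNAString(seqstr)
  for (p in primers) {
    n <- Biostrings::countPattern(Biostrings::DNAString(p), subj,
                                  max.mismatch = 2) +
      Biostrings::countPattern(
        Biostrings::reverseComplement(Biostrings::DNAString(p)), subj,
        max.mismatch = 2)
    if (n != 1L) return(FALSE)
  }
  TRUE
}

# intronic positions safe for background het SNVs: away from exon boundaries
# (reportability filter), primer sites and stamped motifs
benign_pool <- function(lay, sites, site_end) {
  ok <- rep(TRUE, lay$length)
  ok[seq_len(300L)] <- FALSE
  ok[(lay$length - 300L):lay$length] <- FALSE
  for (i in seq_len(nrow(lay$exons)))
    ok[max(1L, lay$exons$start[i] - 20L):min(lay$length, lay$exons$end[i] + 20L)] <- FALSE
  for (i in seq_len(nrow(sites)))
    ok[(sites$start[i] - 5L):(site_end[i] + 5L)] <- FALSE
  for (s in locus_stamps(lay))
    ok[(s$pos - 5L):(s$pos + nchar(s$seq) + 4L)] <- FALSE
  which(ok)
}

#' @export
print.locus_model <- function(x, ...) {
  cat(sprintf("<locus_model> %d bp, %d exons, %d amplicons; SV del %d bp + ins %d bp (%s)\n",
              x$reference$length, x$transcript$n_exons, nrow(x$panel),
              x$sv$del_len, nchar(x$sv$insert), x$sv$hgvs_c))
  invisible(x)
}
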