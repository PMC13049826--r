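# Plain-text interchange: FASTA/FASTQ/BED/TSV/VCF writers for pipeline
# outputs. VCF rows follow VCF 4.2 with explicit REF/ALT sequences
# (no symbolic alleles).

#' Write sequences to FASTA
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(seqs)), path)
  invisible(path)
}

#' Write reads to FASTQ (flat quality profile, truth labels in the comment)
#' @param reads `data.table` from [simulate_reads()].
#' @param path output file.
#' @param qual_char quality character applied to every base.
#' @export
write_fastq <- function(reads, path, qual_char = "I") {
  meta_cols <- setdiff(names(reads), c("read_id", "seq"))
  comment <- if (length(meta_cols)) {
    parts <- lapply(meta_cols, function(cn) paste0(cn, "=", reads[[cn]]))
    paste0(" ", do.call(paste, parts))
  } else ""
  lines <- paste0("@", reads$read_id, comment, "\n", reads$seq, "\n+\n",
                  strrep(qual_char, nchar(reads$seq)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file into the read-table format
#' @param path FASTQ file; comment key=value pairs are restored as columns.
#' @return `data.table` with `read_id`, `seq` and any comment columns.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  stopifnot(length(lines) %% 4L == 0L)
  hdr <- sub("^@", "", lines[seq(1L, length(lines), by = 4L)])
  seqs <- lines[seq(2L, length(lines), by = 4L)]
  ids <- sub(" .*$", "", hdr)
  dt <- data.table::data.table(read_id = ids, seq = seqs)
  comment <- sub("^[^ ]+ ?", "", hdr)
  if (any(nzchar(comment))) {
    kv <- strsplit(comment, " ", fixed = TRUE)
    keys <- unique(unlist(lapply(kv, function(x) sub("=.*$", "", x))))
    keys <- keys[nzchar(keys)]
    for (k in keys) {
      dt[[k]] <- vapply(kv, function(x) {
        hit <- grep(paste0("^", k, "="), x, value = TRUE)
        if (length(hit)) sub("^[^=]+=", "", hit[1]) else NA_character_
      }, character(1))
    }
  }
  dt
}

#' Write intervals to BED (0-based half-open)
#' @param df data.frame with `start`, `end` (1-based inclusive) and `name`.
#' @param path output file.
#' @param chrom chromosome/locus name.
#' @export
write_bed <- function(df, path, chrom = "locus") {
  out <- data.frame(chrom = chrom, start = df$start - 1L, end = df$end,
                    name = df$name)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

variant_to_vcf_row <- function(v, reference) {
  if (v$kind == "SNV")
    return(list(pos = v$pos, ref = v$ref, alt = v$alt))
  if (!nzchar(v$alt) || !nzchar(v$ref)) {
    # anchored representation for pure indels
    anchor <- if (!nzchar(v$ref)) v$pos else v$pos - 1L
    base <- ref_sub(reference, anchor, anchor)
    if (!nzchar(v$ref))
      return(list(pos = anchor, ref = base, alt = paste0(base, v$alt)))
    return(list(pos = anchor, ref = paste0(base, v$ref), alt = base))
  }
  list(pos = v$pos, ref = v$ref, alt = v$alt)
}

#' Write phased per-haplotype variant calls as VCF 4.2
#'
#' One row per distinct variant with a phased genotype (`GT:PS`); the phase
#' set is the locus itself (one set per sample). Structural rows carry
#' `SVLEN`, `INSLEN`, `SUPPORT` and `HOMLEN` INFO fields when provided.
#'
#' @param calls a `sample_calls` object (reportable variants are written).
#' @param reference the [locus_reference()].
#' @param path output file.
#' @param sv optional `sv_call` to include.
#' @export
write_vcf <- function(calls, reference, path, sv = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", reference$name,
                   reference$length),
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Deleted length\">",
           "##INFO=<ID=INSLEN,Number=1,Type=Integer,Description=\"Inserted length\">",
           "##INFO=<ID=SUPPORT,Number=1,Type=Integer,Description=\"Junction-spanning reads\">",
           "##INFO=<ID=HOMLEN,Number=1,Type=Integer,Description=\"Junction microhomology\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", calls$sample_id, sep = "\t"))
  keys1 <- vapply(calls$reportable[[1]], variant_key, character(1))
  keys2 <- vapply(calls$reportable[[2]], variant_key, character(1))
  vars <- c(calls$reportable[[1]],
            calls$reportable[[2]][!(keys2 %in% keys1)])
  if (!is.null(sv) && !(variant_key(sv$variant) %in% c(keys1, keys2)))
    vars <- c(vars, list(sv$variant))
  rows <- character(0)
  for (v in vars) {
    k <- variant_key(v)
    gt <- paste0(as.integer(k %in% keys1 ||
                              (!is.null(sv) && identical(k, variant_key(sv$variant)) &&
                                 identical(attr(sv, "hap"), "H1"))),
                 "|",
                 as.integer(k %in% keys2 ||
                              (!is.null(sv) && identical(k, variant_key(sv$variant)) &&
                                 identical(attr(sv, "hap"), "H2"))))
    info <- "."
    if (!is.null(sv) && identical(k, variant_key(sv$variant)))
      info <- sprintf("SVLEN=-%d;INSLEN=%d;SUPPORT=%d;HOMLEN=%d",
                      sv$del_len, nchar(sv$insert), sv$support, sv$homlen)
    r <- variant_to_vcf_row(v, reference)
    rows <- c(rows, paste(reference$name, r$pos, ".", r$ref, r$alt, ".",
                          "PASS", info, "GT:PS", paste0(gt, ":1"), sep = "\t"))
  }
  ord <- order(as.integer(vapply(strsplit(rows, "\t"), `[`, "", 2L)))
  writeLines(c(hdr, rows[ord]), path)
  invisible(path)
}

#' Write a coverage track as bedGraph
#' @param cov result of [coverage_profile()].
#' @param path output file.
#' @param chrom locus name.
#' @export
write_bedgraph <- function(cov, path, chrom = "locus") {
  out <- data.frame(chrom = chrom, start = cov$start - 1L, end = cov$end,
                    depth = round(cov$depth, 3))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
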