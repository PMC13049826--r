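# Long-read alignment against the locus reference. The engine is minimap2
# (driven through temp files); the module contract is the alignment table
# returned by align_reads(), on which all downstream computation operates.

ap_cache <- new.env(parent = emptyenv())

reference_fasta <- function(reference) {
  key <- paste0(reference$name, "_", reference$length, "_",
                substr(reference$sequence, 1, 50))
  hit <- ap_cache[[key]]
  if (!is.null(hit) && file.exists(hit)) return(hit)
  path <- tempfile(fileext = ".fa")
  writeLines(c(paste0(">", reference$name), reference$sequence), path)
  ap_cache[[key]] <- path
  path
}

#' Align reads to the locus reference
#'
#' Runs minimap2 (`map-ont` for amplicon reads, `map-hifi` for whole-locus
#' reads) with supplementary alignments kept and soft clipping everywhere
#' (`-Y`), then parses the SAM into an alignment table. Secondary alignments
#' are suppressed; unmapped reads are dropped (their ids are recorded in the
#' `unaligned` attribute).
#'
#' @param reads `data.table` with `read_id` and `seq` columns (as produced by
#'   [simulate_reads()]), or a named character vector.
#' @param reference a [locus_reference()].
#' @param preset minimap2 preset.
#' @return `data.table` with one row per alignment record: `read_id`, `flag`,
#'   `pos`, `mapq`, `cigar`, `seq`, `ref_start`, `ref_end`, `qstart`, `qend`,
#'   `qlen` (query coordinates in SAM orientation), `strand`, `supplementary`,
#'   `nm` and `identity`.
#' @export
align_reads <- function(reads, reference, preset = c("map-ont", "map-hifi")) {
  preset <- match.arg(preset)
  if (is.character(reads))
    reads <- data.table::data.table(read_id = names(reads), seq = unname(reads))
  stopifnot(all(c("read_id", "seq") %in% names(reads)))
  if (Sys.which("minimap2") == "")
    stop("minimap2 not found on PATH; align_reads() requires it")

  fq <- tempfile(fileext = ".fa")
  on.exit(unlink(fq), add = TRUE)
  writeLines(paste0(">", reads$read_id, "\n", reads$seq), fq)
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam), add = TRUE)
  status <- system2("minimap2",
                    c("-a", "-x", preset, "--secondary=no", "-Y", "-t", "1",
                      reference_fasta(reference), fq),
                    stdout = sam, stderr = FALSE)
  if (status != 0L) stop("minimap2 failed with status ", status)

  lines <- readLines(sam)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L)
    return(empty_alignment_table(reads$read_id))
  f <- strsplit(lines, "\t", fixed = TRUE)
  dt <- data.table::data.table(
    read_id = vapply(f, `[`, "", 1L),
    flag = as.integer(vapply(f, `[`, "", 2L)),
    pos = as.integer(vapply(f, `[`, "", 4L)),
    mapq = as.integer(vapply(f, `[`, "", 5L)),
    cigar = vapply(f, `[`, "", 6L),
    seq = vapply(f, `[`, "", 10L),
    nm = vapply(f, function(x) {
      hit <- grep("^NM:i:", x, value = TRUE)
      if (length(hit)) as.integer(sub("^NM:i:", "", hit[1])) else NA_integer_
    }, integer(1)))
  dt <- dt[bitwAnd(flag, 4L) == 0L & cigar != "*"]
  dt <- dt[bitwAnd(flag, 256L) == 0L]          # drop secondary
  if (nrow(dt) == 0L) return(empty_alignment_table(reads$read_id))

  ref_w <- GenomicAlignments::cigarWidthAlongReferenceSpace(dt$cigar)
  dt[, ref_start := pos]
  dt[, ref_end := pos + ref_w - 1L]
  clips <- cigar_clips(dt$cigar)
  qaln <- GenomicAlignments::cigarWidthAlongQuerySpace(dt$cigar,
                                                       after.soft.clipping = TRUE)
  dt[, qstart := clips$lead + 1L]
  dt[, qend := clips$lead + qaln]
  dt[, qlen := nchar(seq)]
  dt[, strand := ifelse(bitwAnd(flag, 16L) > 0L, "-", "+")]
  dt[, supplementary := bitwAnd(flag, 2048L) > 0L]
  dt[, identity := 1 - nm / pmax(1L, qaln)]
  data.table::setattr(dt, "unaligned", setdiff(reads$read_id, dt$read_id))
  dt[]
}

empty_alignment_table <- function(ids) {
  dt <- data.table::data.table(
    read_id = character(0), flag = integer(0), pos = integer(0),
    mapq = integer(0), cigar = character(0), seq = character(0),
    nm = integer(0), ref_start = integer(0), ref_end = integer(0),
    qstart = integer(0), qend = integer(0), qlen = integer(0),
    strand = character(0), supplementary = logical(0), identity = numeric(0))
  data.table::setattr(dt, "unaligned", ids)
  dt
}

cigar_clips <- function(cigar) {
  lead <- integer(length(cigar)); trail <- integer(length(cigar))
  m <- regmatches(cigar, regexec("^(\\d+)[SH]", cigar))
  has <- lengths(m) > 0
  lead[has] <- as.integer(vapply(m[has], `[`, "", 2L))
  m <- regmatches(cigar, regexec("(\\d+)[SH]$", cigar))
  has <- lengths(m) > 0
  trail[has] <- as.integer(vapply(m[has], `[`, "", 2L))
  list(lead = lead, trail = trail)
}

# Lay read sequences onto reference space over [from, to]; rows align to the
# input order of `aln`. Returns a DNAStringSet of equal-width strings where
# '-' marks deleted bases and '+' pads beyond each read's aligned span.
stack_alignments <- function(aln, from, to) {
  layered <- GenomicAlignments::sequenceLayer(
    Biostrings::DNAStringSet(aln$seq), aln$cigar,
    from = "query", to = "reference")
  Biostrings::stackStrings(layered, from, to, shift = aln$pos - 1L,
                           Lpadding.letter = "+", Rpadding.letter = "+")
}
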