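# Whole-haplotype vs reference diffing via unique-k-mer anchor chaining.
# Collinear anchors partition the two sequences into exactly matching blocks
# and small divergent gaps; gaps are aligned base-level (Biostrings global
# alignment) when small, or reported as single delins events when large
# (e.g. a multi-kb structural deletion-insertion).

ref_kmer_index <- function(reference, k) {
  key <- paste0("kidx_", reference$name, "_", reference$length, "_", k)
  hit <- ap_cache[[key]]
  if (!is.null(hit)) return(hit)
  n <- reference$length - k + 1L
  km <- substring(reference$sequence, seq_len(n), seq_len(n) + k - 1L)
  dup <- duplicated(km) | duplicated(km, fromLast = TRUE)
  idx <- list(kmers = km, unique = !dup)
  ap_cache[[key]] <- idx
  idx
}

# collinear anchor table between query and reference (k-mer start positions)
diff_anchors <- function(query, reference, k = 21L, stride = 7L) {
  ridx <- ref_kmer_index(reference, k)
  nq <- nchar(query) - k + 1L
  if (nq < 1L) return(data.frame(q = integer(0), r = integer(0)))
  qpos <- unique(c(seq(1L, nq, by = stride), nq))
  qk <- substring(query, qpos, qpos + k - 1L)
  hit <- match(qk, ridx$kmers)
  ok <- !is.na(hit) & ridx$unique[pmax(hit, 1L)]
  # query-side uniqueness: drop duplicated query k-mers
  ok[ok] <- !(duplicated(qk[ok]) | duplicated(qk[ok], fromLast = TRUE))
  q <- qpos[ok]; r <- hit[ok]
  # greedy monotone chain in reference coordinate
  keep <- logical(length(q)); last <- 0L
  for (i in seq_along(q)) if (r[i] > last) { keep[i] <- TRUE; last <- r[i] }
  data.frame(q = q[keep], r = r[keep])
}

# base-level edits from a pair of gapped aligned strings (characters incl '-');
# edited columns within 3 reference bases merge into one event
edits_from_gapped <- function(qa, ra, r_offset) {
  qc <- strsplit(qa, "")[[1]]; rc <- strsplit(ra, "")[[1]]
  rpos <- cumsum(rc != "-") + r_offset      # reference position per column
  bad <- which(qc != rc)
  if (!length(bad)) return(list())
  grp <- cumsum(c(1L, as.integer(diff(rpos[bad]) > 3L)))
  edits <- list()
  for (g in unique(grp)) {
    cols <- bad[grp == g]
    ci <- min(cols); cj <- max(cols)
    ref_piece <- paste(rc[ci:cj][rc[ci:cj] != "-"], collapse = "")
    alt_piece <- paste(qc[ci:cj][qc[ci:cj] != "-"], collapse = "")
    if (!nzchar(ref_piece)) {
      edits[[length(edits) + 1L]] <-
        list(pos = rpos[ci] + 1L, ref = "", alt = alt_piece,
             ins_after = rpos[ci])
    } else {
      p1 <- rpos[ci] + as.integer(rc[ci] == "-")
      edits[[length(edits) + 1L]] <- list(pos = p1, ref = ref_piece,
                                          alt = alt_piece)
    }
  }
  edits
}

gap_edits <- function(qpiece, rpiece, r_start, reference, max_align = 300L) {
  if (!nzchar(qpiece) && !nzchar(rpiece)) return(list())
  if (!nzchar(qpiece))            # pure deletion
    return(list(list(pos = r_start, ref = rpiece, alt = "")))
  if (!nzchar(rpiece))            # pure insertion after r_start - 1
    return(list(list(pos = r_start, ref = "", alt = qpiece, ins_after = r_start - 1L)))
  if (nchar(qpiece) == nchar(rpiece) && nchar(qpiece) <= 60L)
    return(edits_from_gapped(qpiece, rpiece, r_start - 1L))
  if (nchar(qpiece) <= max_align && nchar(rpiece) <= max_align) {
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(qpiece), Biostrings::DNAString(rpiece),
      type = "global", substitutionMatrix =
        Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2),
      gapOpening = 4, gapExtension = 1)
    qa <- as.character(Biostrings::alignedPattern(al))
    ra <- as.character(Biostrings::alignedSubject(al))
    return(edits_from_gapped(qa, ra, r_start - 1L))
  }
  # large divergent block: one deletion-insertion event
  list(list(pos = r_start, ref = rpiece, alt = qpiece))
}

#' Diff a haplotype sequence against the reference
#'
#' Chains unique shared k-mers into a collinear alignment skeleton, aligns
#' the divergent gaps between anchors at base level, and returns normalized
#' variants whose application to the reference reproduces the haplotype
#' exactly. Divergent blocks longer than `max_align` bases on both sides are
#' reported as a single delins (the path a multi-kb deletion-insertion
#' takes).
#'
#' @param hap_seq haplotype (or consensus) sequence.
#' @param reference a [locus_reference()].
#' @param k anchor k-mer length.
#' @param max_align largest gap piece aligned base-by-base.
#' @return list of normalized `variant` records, sorted by position.
#' @export
diff_haplotype <- function(hap_seq, reference, k = 21L, max_align = 300L) {
  stopifnot(nzchar(hap_seq))
  anc <- diff_anchors(hap_seq, reference, k = k)
  if (nrow(anc) < 2L)
    stop("diff failed: sequence shares too few anchors with the reference")
  # collapse anchors on the same diagonal runs into gap list
  edits <- list()
  # head pieces before the first anchor
  a0q <- anc$q[1]; a0r <- anc$r[1]
  if (a0q > 1L || a0r > 1L) {
    edits <- c(edits, gap_edits(substr(hap_seq, 1L, a0q - 1L),
                                substr(reference$sequence, 1L, a0r - 1L),
                                1L, reference, max_align))
  }
  for (i in seq_len(nrow(anc) - 1L)) {
    q1 <- anc$q[i]; r1 <- anc$r[i]; q2 <- anc$q[i + 1L]; r2 <- anc$r[i + 1L]
    if (q2 - q1 == r2 - r1 &&
        substr(hap_seq, q1, q2 - 1L) ==
        substr(reference$sequence, r1, r2 - 1L)) next
    qpiece <- substr(hap_seq, q1 + k, q2 - 1L)
    rpiece <- substr(reference$sequence, r1 + k, r2 - 1L)
    edits <- c(edits, gap_edits(qpiece, rpiece, r1 + k, reference, max_align))
  }
  # tail pieces past the last anchor
  qn <- anc$q[nrow(anc)]; rn <- anc$r[nrow(anc)]
  qtail <- substr(hap_seq, qn + k, nchar(hap_seq))
  rtail <- substr(reference$sequence, rn + k, reference$length)
  if (nzchar(qtail) || nzchar(rtail))
    edits <- c(edits, gap_edits(qtail, rtail, rn + k, reference, max_align))

  out <- lapply(edits, function(e) {
    v <- if (!nzchar(e$ref))
      new_variant(e$ins_after %||% (e$pos - 1L), "", e$alt, "INS")
    else new_variant(e$pos, e$ref, e$alt)
    normalize_variant(v, reference)
  })
  out[order(vapply(out, function(v) v$pos, integer(1)))]
}
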