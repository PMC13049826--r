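# Structural-variant detection from whole-locus long reads: windowed
# coverage, junction candidates from split/gapped alignments, and a
# junction-consensus resolver producing an exact delins call.

#' Windowed coverage track
#'
#' Mean aligned-base depth per fixed-width window tiling the locus.
#'
#' @param aln alignment table ([align_reads()]).
#' @param locus_length total reference length.
#' @param window window width in bases (>= 50).
#' @return `data.frame` with `start`, `end`, `depth`.
#' @export
coverage_profile <- function(aln, locus_length, window = 500L) {
  stopifnot(window >= 50L)
  cov <- IRanges::coverage(IRanges::IRanges(aln$ref_start, aln$ref_end),
                           width = locus_length)
  starts <- seq(1L, locus_length, by = window)
  ends <- pmin(starts + window - 1L, locus_length)
  v <- IRanges::Views(cov, start = starts, end = ends)
  data.frame(start = starts, end = ends, depth = IRanges::viewMeans(v))
}

#' Junction candidates from split and gapped alignments
#'
#' Two observation paths feed the caller: (i) deletion runs of at least
#' `min_sv_size` bases inside a single alignment's CIGAR (adjacent insertion
#' ops contribute the inserted-sequence observation), and (ii) read pairs of
#' primary + supplementary alignments on the same strand whose reference
#' intervals are separated by at least `min_sv_size` bases, with the
#' unaligned query middle as the inserted sequence. Candidates agreeing
#' within 10 bases on both breakpoints are clustered.
#'
#' @param aln alignment table ([align_reads()]).
#' @param min_sv_size smallest event size considered structural.
#' @return list of clusters; each is a `data.table` of per-read observations
#'   (`read_id`, `left` = last retained reference base, `right` = first
#'   retained reference base, `insert`).
#' @export
find_junctions <- function(aln, min_sv_size = 50L) {
  obs <- rbind(cigar_junctions(aln, min_sv_size),
               split_junctions(aln, min_sv_size))
  if (is.null(obs) || nrow(obs) == 0L) return(list())
  data.table::setorder(obs, left, right)
  grp <- cumsum(c(1L, as.integer(
    abs(diff(obs$left)) > 10L | abs(diff(obs$right)) > 10L)))
  lapply(split(obs, grp), function(x) x)
}

# deletion (+ adjacent insertion) runs inside single CIGARs. Indel ops
# separated by short matched stretches (<= `bridge` bases — chance anchors
# of the inserted sequence inside the deleted interval) are merged into one
# junction observation, with the bridging query bases joining the insert.
cigar_junctions <- function(aln, min_sv_size, bridge = 30L) {
  out <- list()
  ops_all <- GenomicAlignments::explodeCigarOps(aln$cigar)
  lens_all <- GenomicAlignments::explodeCigarOpLengths(aln$cigar)
  for (i in seq_len(nrow(aln))) {
    ops <- ops_all[[i]]; lens <- lens_all[[i]]
    if (sum(lens[ops == "D"]) < min_sv_size) next
    rpos <- aln$pos[i]; qpos <- 1L
    n <- length(ops)
    j <- 1L
    while (j <= n) {
      if (ops[j] %in% c("D", "I")) {
        # extend over consecutive D/I ops and short bridging matches
        j2 <- j
        repeat {
          nxt <- j2 + 1L
          if (nxt <= n && ops[nxt] %in% c("D", "I")) { j2 <- nxt; next }
          if (nxt < n && ops[nxt] %in% c("M", "=", "X") &&
              lens[nxt] <= bridge && ops[nxt + 1L] %in% c("D", "I")) {
            j2 <- nxt + 1L; next
          }
          break
        }
        run <- j:j2
        d_only <- sum(lens[run][ops[run] == "D"])
        dlen <- d_only + sum(lens[run][ops[run] %in% c("M", "=", "X")])
        if (d_only >= min_sv_size) {
          qoff <- qpos; pieces <- character(0)
          for (t in run) {
            if (ops[t] %in% c("I", "M", "=", "X")) {
              pieces <- c(pieces, substr(aln$seq[i], qoff, qoff + lens[t] - 1L))
              qoff <- qoff + lens[t]
            }
          }
          out[[length(out) + 1L]] <- data.table::data.table(
            read_id = aln$read_id[i], left = rpos - 1L,
            right = rpos + dlen, insert = paste(pieces, collapse = ""))
        }
        for (t in run) {
          if (ops[t] == "D") rpos <- rpos + lens[t]
          else if (ops[t] == "I") qpos <- qpos + lens[t]
          else { rpos <- rpos + lens[t]; qpos <- qpos + lens[t] }
        }
        j <- j2 + 1L
        next
      }
      op <- ops[j]; len <- lens[j]
      if (op %in% c("M", "=", "X")) { rpos <- rpos + len; qpos <- qpos + len }
      else if (op == "N") rpos <- rpos + len
      else if (op == "S") qpos <- qpos + len
      j <- j + 1L
    }
  }
  data.table::rbindlist(out)
}

# supplementary-split observations
split_junctions <- function(aln, min_sv_size) {
  out <- list()
  # short or unreliably placed segments (e.g. a spurious anchor inside the
  # deleted interval) must not fabricate sub-junctions
  aln <- aln[(aln$ref_end - aln$ref_start + 1L) >= 100L & aln$mapq >= 10L, ]
  if (nrow(aln) == 0L) return(data.table::rbindlist(out))
  multi <- aln[, .N, by = read_id][N >= 2L, read_id]
  for (id in multi) {
    segs <- aln[read_id == id]
    if (length(unique(segs$strand)) != 1L) next
    data.table::setorder(segs, qstart)
    for (i in seq_len(nrow(segs) - 1L)) {
      a <- segs[i]; b <- segs[i + 1L]
      if (b$ref_start <= a$ref_end) next
      gap <- b$ref_start - a$ref_end - 1L
      if (gap < min_sv_size) next
      ins <- if (b$qstart > a$qend + 1L)
        substr(a$seq, a$qend + 1L, b$qstart - 1L) else ""
      # query overlap between segments: trim the right segment's start
      left <- a$ref_end; right <- b$ref_start
      if (b$qstart <= a$qend) {
        trim <- a$qend - b$qstart + 1L
        right <- right + trim
        if (right - left - 1L < min_sv_size) next
      }
      out[[length(out) + 1L]] <- data.table::data.table(
        read_id = id, left = left, right = right, insert = ins)
    }
  }
  data.table::rbindlist(out)
}

#' Resolve a junction cluster into a structural-variant call
#'
#' Breakpoints are taken by majority vote over the supporting reads and the
#' inserted sequence by plurality over the per-read insert observations; the
#' resulting delins is shifted to its left-most equivalent placement (the
#' shift range is reported as the junctional microhomology length).
#' Zygosity is heterozygous when wild-type reads spanning the deleted
#' interval remain.
#'
#' @param cluster one element of [find_junctions()]'s result.
#' @param aln the full alignment table (for wild-type spanning support).
#' @param locus the locus model (reference + transcript for HGVS naming).
#' @param min_support minimum junction-spanning reads for a confident call.
#' @return object of class `sv_call`: breakpoints (`left` = last retained
#'   base, `right` = first retained base), `del_len`, `insert`, `variant`,
#'   `hgvs_c`, `hgvs_g`, `support`, `wt_support`, `zygosity`, `homlen`,
#'   `confident`.
#' @export
resolve_junction <- function(cluster, aln, locus, min_support = 3L) {
  ref <- locus$reference; tx <- locus$transcript
  vote <- function(x) {
    tb <- sort(table(x), decreasing = TRUE)
    nm <- names(tb)[tb == tb[1]]
    sort(nm)[1]
  }
  left <- as.integer(vote(cluster$left))
  right <- as.integer(vote(cluster$right))
  insert <- vote(cluster$insert)
  support <- length(unique(cluster$read_id))

  # canonical left-most placement; count the shift freedom as microhomology
  homlen <- 0L
  repeat {
    can_shift <- left >= 1L && nzchar(insert) &&
      substr(insert, nchar(insert), nchar(insert)) ==
        ref_sub(ref, right - 1L, right - 1L)
    can_shift_del <- left >= 1L && !nzchar(insert) &&
      ref_sub(ref, left, left) == ref_sub(ref, right - 1L, right - 1L)
    if (can_shift) {
      insert <- paste0(ref_sub(ref, left, left),
                       substr(insert, 1L, nchar(insert) - 1L))
      left <- left - 1L; right <- right - 1L; homlen <- homlen + 1L
    } else if (can_shift_del) {
      left <- left - 1L; right <- right - 1L; homlen <- homlen + 1L
    } else break
    if (homlen > 500L) break
  }
  del_len <- right - left - 1L
  v <- new_variant(left + 1L, ref_sub(ref, left + 1L, right - 1L), insert,
                   if (nzchar(insert)) "DELINS" else "DEL")
  mid <- as.integer((left + right) / 2)
  wt <- sum(!aln$supplementary & aln$ref_start <= mid - 200L &
              aln$ref_end >= mid + 200L &
              !(aln$read_id %in% cluster$read_id))
  structure(list(left = left, right = right, del_len = del_len,
                 insert = insert, variant = v,
                 hgvs_c = hgvs_name(v, tx, "c"),
                 hgvs_g = hgvs_name(v, tx, "g"),
                 support = support, wt_support = wt,
                 zygosity = if (wt >= min_support) "het" else "hom",
                 homlen = homlen,
                 confident = support >= min_support),
            class = "sv_call")
}

#' @export
print.sv_call <- function(x, ...) {
  cat(sprintf("<sv_call> %s (del %d bp, ins %d bp) support=%d wt=%d %s%s\n",
              x$hgvs_c, x$del_len, nchar(x$insert), x$support, x$wt_support,
              x$zygosity, if (x$confident) "" else " [low-confidence]"))
  invisible(x)
}

#' Call structural variants from whole-locus long-read alignments
#'
#' Convenience wrapper: [find_junctions()] then [resolve_junction()] on every
#' cluster, returning confident calls only (low-support clusters are kept in
#' the `"low_confidence"` attribute).
#'
#' @param aln alignment table.
#' @param locus the locus model.
#' @param min_sv_size,min_support caller thresholds.
#' @return list of `sv_call` objects.
#' @export
call_sv <- function(aln, locus, min_sv_size = 50L, min_support = 3L) {
  clusters <- find_junctions(aln, min_sv_size)
  calls <- lapply(clusters, resolve_junction, aln = aln, locus = locus,
                  min_support = min_support)
  ok <- vapply(calls, function(x) x$confident, logical(1))
  out <- consolidate_sv_calls(calls[ok])
  attr(out, "low_confidence") <- calls[!ok]
  out
}

# The same physical junction can surface under slightly different alignment
# representations (a few reads absorb part of the insert into the flank,
# shifting a breakpoint by more than the cluster tolerance). Calls whose
# breakpoints lie within 100 bases of a better-supported call are treated
# as representation variants of it and dropped.
consolidate_sv_calls <- function(calls) {
  if (length(calls) <= 1L) return(calls)
  ord <- order(-vapply(calls, function(x) x$support, integer(1)))
  kept <- list()
  for (x in calls[ord]) {
    dup <- any(vapply(kept, function(k)
      abs(k$left - x$left) <= 100L && abs(k$right - x$right) <= 100L,
      logical(1)))
    if (!dup) kept[[length(kept) + 1L]] <- x
  }
  kept[order(vapply(kept, function(x) x$left, integer(1)))]
}
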