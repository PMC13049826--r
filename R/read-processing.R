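# Per-amplicon read processing: amplicon assignment, heterozygous-site
# detection, two-allele clustering and per-allele consensus.

#' Assign alignments to panel amplicons
#'
#' Each alignment goes to the amplicon whose interval overlaps the largest
#' fraction of its aligned span (ties to the left-most amplicon); alignments
#' overlapping no amplicon are `"unassigned"`.
#'
#' @param aln alignment table from [align_reads()].
#' @param panel amplicon table (`locus$panel`).
#' @return character vector of amplicon names, parallel to `aln` rows.
#' @export
assign_amplicon <- function(aln, panel) {
  if (nrow(aln) == 0L) return(character(0))
  ov <- sapply(seq_len(nrow(panel)), function(i) {
    pmax(0L, pmin(aln$ref_end, panel$end[i]) - pmax(aln$ref_start, panel$start[i]) + 1L)
  })
  if (is.null(dim(ov))) ov <- matrix(ov, nrow = 1L)
  best <- max.col(ov, ties.method = "first")
  out <- panel$name[best]
  out[apply(ov, 1L, max) == 0L] <- "unassigned"
  out
}

#' Detect heterozygous sites within one amplicon's alignments
#'
#' Substitution sites are columns where the two most frequent base alleles
#' each reach the minor-allele thresholds. Indel alleles shorter than
#' `min_indel` bases are collapsed with the reference key (deleted bases
#' count toward the reference base); longer insertions/deletions are treated
#' as biallelic presence/absence keys at their start column.
#'
#' @param aln alignment table rows for one amplicon (primary alignments).
#' @param region `c(start, end)` reference interval of the amplicon.
#' @param reference a [locus_reference()].
#' @param min_depth minimum covering reads for a site to be considered.
#' @param min_frac minimum minor-allele fraction.
#' @param min_count minimum minor-allele read count.
#' @param min_indel indel length below which the allele merges with the
#'   reference key.
#' @return list with `sites` (data.frame: `pos`, `type`, `allele_a`,
#'   `allele_b`, `count_a`, `count_b`, `width`), `carriers` (list of member
#'   row indices for indel sites), and `stack` (the reference-space read
#'   stack, reused by clustering/consensus).
#' @export
detect_het_sites <- function(aln, region, reference, min_depth = 20L,
                             min_frac = 0.2, min_count = 5L, min_indel = 5L) {
  if (nrow(aln) < min_depth)
    stop("insufficient coverage: ", nrow(aln), " reads < min_depth ", min_depth)
  from <- region[1]; to <- region[2]
  stk <- stack_alignments(aln, from, to)
  cm <- Biostrings::consensusMatrix(stk)
  need <- c(DNA_BASES, "-", "+")
  for (r in setdiff(need, rownames(cm)))
    cm <- rbind(cm, matrix(0L, 1, ncol(cm), dimnames = list(r)))
  B <- cm[DNA_BASES, , drop = FALSE]
  dash <- cm["-", ]
  refchars <- strsplit(ref_sub(reference, from, to), "")[[1]]
  refrow <- match(refchars, DNA_BASES)
  cov <- colSums(B) + dash
  # small deletions collapse into the reference key
  Badj <- B
  Badj[cbind(refrow, seq_along(refchars))] <-
    Badj[cbind(refrow, seq_along(refchars))] + dash

  ord <- apply(Badj, 2L, order, decreasing = TRUE)
  a_idx <- ord[1L, ]; b_idx <- ord[2L, ]
  ccol <- seq_len(ncol(Badj))
  count_a <- Badj[cbind(a_idx, ccol)]
  count_b <- Badj[cbind(b_idx, ccol)]
  is_het <- cov >= min_depth & count_b >= min_count & count_a >= min_count &
    count_b / pmax(1, cov) >= min_frac & count_a / pmax(1, cov) >= min_frac
  sub_sites <- data.frame(
    pos = from + which(is_het) - 1L,
    type = rep("sub", sum(is_het)),
    allele_a = DNA_BASES[a_idx[is_het]], allele_b = DNA_BASES[b_idx[is_het]],
    count_a = count_a[is_het], count_b = count_b[is_het],
    width = rep(1L, sum(is_het)), stringsAsFactors = FALSE)

  indels <- long_indel_sites(aln, from, to, cov, min_depth, min_frac,
                             min_count, min_indel)
  sites <- rbind(sub_sites, indels$sites)
  if (nrow(sites)) sites <- sites[order(sites$pos), , drop = FALSE]
  list(sites = sites, carriers = indels$carriers[order(indels$sites$pos)],
       stack = stk, from = from, to = to)
}

# biallelic presence/absence sites from indel ops >= min_indel
long_indel_sites <- function(aln, from, to, cov, min_depth, min_frac,
                             min_count, min_indel) {
  recs <- list()
  for (op in c("D", "I")) {
    rng <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      aln$cigar, pos = aln$pos, ops = op)
    n_per <- lengths(rng)
    if (sum(n_per) == 0L) next
    u <- unlist(rng)
    w <- if (op == "D") BiocGenerics::width(u) else indel_ins_widths(aln, n_per)
    recs[[op]] <- data.table::data.table(
      row = rep(seq_along(n_per), n_per),
      start = BiocGenerics::start(u), width = w, op = op)[width >= min_indel]
  }
  recs <- data.table::rbindlist(recs)
  sites <- data.frame(pos = integer(0), type = character(0),
                      allele_a = character(0), allele_b = character(0),
                      count_a = integer(0), count_b = integer(0),
                      width = integer(0), stringsAsFactors = FALSE)
  carriers <- list()
  if (is.null(recs) || nrow(recs) == 0L)
    return(list(sites = sites, carriers = carriers))
  data.table::setorder(recs, op, start, width)
  # single-link clustering: same op, start/width within 3 bases
  nr <- nrow(recs)
  brk <- if (nr > 1L)
    recs$op[-1L] != recs$op[-nr] | recs$start[-1L] - recs$start[-nr] > 3L |
      abs(recs$width[-1L] - recs$width[-nr]) > 3L
  else logical(0)
  grp <- cumsum(c(1L, as.integer(brk)))
  recs[, cluster := grp]
  for (g in unique(grp)) {
    sub <- recs[cluster == g]
    p <- as.integer(round(stats::median(sub$start)))
    if (p < from || p > to) next
    n_car <- length(unique(sub$row))
    covp <- cov[p - from + 1L]
    n_ref <- covp - n_car
    if (covp >= min_depth && n_car >= min_count && n_ref >= min_count &&
        n_car / covp >= min_frac && n_ref / covp >= min_frac) {
      key <- paste0(sub$op[1], round(stats::median(sub$width)))
      sites <- rbind(sites, data.frame(
        pos = p, type = if (sub$op[1] == "D") "del" else "ins",
        allele_a = "ref", allele_b = key,
        count_a = n_ref, count_b = n_car,
        width = as.integer(round(stats::median(sub$width))),
        stringsAsFactors = FALSE))
      carriers[[length(carriers) + 1L]] <- unique(sub$row)
    }
  }
  list(sites = sites, carriers = carriers)
}

indel_ins_widths <- function(aln, n_per) {
  qr <- GenomicAlignments::cigarRangesAlongQuerySpace(aln$cigar, ops = "I")
  BiocGenerics::width(unlist(qr))
}

# reads x sites allele matrix: 1 = allele_a, 2 = allele_b, NA = uninformative
read_allele_matrix <- function(het, aln) {
  sites <- het$sites
  n <- length(het$stack)
  if (nrow(sites) == 0L)
    return(matrix(NA_integer_, nrow = n, ncol = 0L))
  M <- matrix(NA_integer_, nrow = n, ncol = nrow(sites))
  chars <- NULL
  sub_idx <- which(sites$type == "sub")
  if (length(sub_idx)) {
    cols <- sites$pos[sub_idx] - het$from + 1L
    chars <- as.matrix(het$stack)[, cols, drop = FALSE]
    for (k in seq_along(sub_idx)) {
      s <- sub_idx[k]
      M[chars[, k] == sites$allele_a[s], s] <- 1L
      M[chars[, k] == sites$allele_b[s], s] <- 2L
    }
  }
  ind_idx <- which(sites$type != "sub")
  if (length(ind_idx)) {
    carried <- het$carriers
    for (k in seq_along(ind_idx)) {
      s <- ind_idx[k]
      covering <- aln$ref_start <= sites$pos[s] - 5L &
        aln$ref_end >= sites$pos[s] + 5L
      M[covering, s] <- 1L
      M[carried[[k]], s] <- 2L
    }
  }
  M
}

#' Cluster one amplicon's reads into allele groups
#'
#' With no heterozygous site all reads form a single cluster. Otherwise two
#' signature vectors are seeded from the most dissimilar read pair, reads are
#' assigned by allele agreement, and one refinement pass recomputes the
#' per-site majority signatures and reassigns every read (which also reaches
#' reads sharing no site with the seeds). Reads covering no informative site
#' remain unassigned rather than being forced into a cluster. Deterministic
#' given input order.
#'
#' @param het result of [detect_het_sites()].
#' @param aln the same alignment rows.
#' @param min_reads clusters with fewer members are flagged low-support.
#' @return list of clusters, each `list(members, signature, low_support)`;
#'   attribute `"unassigned"` holds row indices of unassignable reads.
#' @export
cluster_alleles <- function(het, aln, min_reads = 5L) {
  n <- nrow(aln)
  M <- read_allele_matrix(het, aln)
  if (ncol(M) == 0L) {
    cl <- list(list(members = seq_len(n), signature = integer(0),
                    low_support = n < min_reads))
    attr(cl, "unassigned") <- integer(0)
    return(cl)
  }
  A1 <- !is.na(M) & M == 1L
  A2 <- !is.na(M) & M == 2L
  D <- tcrossprod(A1, A2); D <- D + t(D)
  S <- tcrossprod(A1, A1) + tcrossprod(A2, A2)
  shared <- D + S
  frac <- ifelse(shared > 0, D / shared, -1)
  # most dissimilar pair, ties to smallest indices
  best <- which(frac == max(frac), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  if (max(frac) <= 0) {      # no read pair shares a site with disagreement
    cl <- list(list(members = seq_len(n), signature = integer(0),
                    low_support = n < min_reads))
    attr(cl, "unassigned") <- integer(0)
    return(cl)
  }
  sig <- list(M[best[1], ], M[best[2], ])
  assign_pass <- function(sig) {
    s1 <- matrix(sig[[1]], nrow = n, ncol = ncol(M), byrow = TRUE)
    s2 <- matrix(sig[[2]], nrow = n, ncol = ncol(M), byrow = TRUE)
    a1 <- rowSums(!is.na(M) & !is.na(s1) & M == s1)
    d1 <- rowSums(!is.na(M) & !is.na(s1) & M != s1)
    a2 <- rowSums(!is.na(M) & !is.na(s2) & M == s2)
    d2 <- rowSums(!is.na(M) & !is.na(s2) & M != s2)
    score1 <- a1 - d1; score2 <- a2 - d2
    out <- rep(NA_integer_, n)
    out[score1 > score2] <- 1L
    out[score2 > score1] <- 2L
    out
  }
  memb <- assign_pass(sig)
  # refinement: per-site majority signatures from current members, reassign;
  # iterate to a fixed point so the linkage propagates across the whole
  # amplicon (each pass extends the phased span by about one read length,
  # and the seed pair may sit at one end of a 20 kb amplicon)
  for (pass in 1:6) {
    sig <- lapply(1:2, function(k) {
      rows <- which(memb == k)
      if (!length(rows)) return(rep(NA_integer_, ncol(M)))
      apply(M[rows, , drop = FALSE], 2L, function(col) {
        t1 <- sum(col == 1L, na.rm = TRUE); t2 <- sum(col == 2L, na.rm = TRUE)
        if (t1 > t2) 1L else if (t2 > t1) 2L else NA_integer_
      })
    })
    memb2 <- assign_pass(sig)
    converged <- identical(memb2, memb)
    memb <- memb2
    if (converged) break
  }
  clusters <- lapply(1:2, function(k) {
    rows <- which(memb == k)
    list(members = rows, signature = sig[[k]],
         low_support = length(rows) < min_reads)
  })
  clusters <- clusters[vapply(clusters, function(c) length(c$members) > 0,
                              logical(1))]
  attr(clusters, "unassigned") <- which(is.na(memb))
  clusters
}

#' Call a per-allele consensus over one amplicon
#'
#' Reference-anchored per-column plurality over the member reads' layered
#' alignments; ties (and zero-coverage columns) resolve toward the reference
#' base, biasing toward no-call rather than a false variant. Insertions are
#' retained when more than half of the covering members share one at the same
#' anchor (the per-anchor plurality sequence is used), which keeps genuine
#' insertion alleles of any length while discarding scattered single-read
#' insertion errors.
#'
#' @param aln alignment rows of the cluster members.
#' @param region `c(start, end)` amplicon interval.
#' @param reference a [locus_reference()].
#' @return object of class `allele_consensus`: `start`, `end`, `bases`
#'   (character per reference column, `""` = deleted), `ins` (data.table
#'   `anchor`, `seq`), `support`, `depth`, `n_reads`.
#' @export
call_consensus <- function(aln, region, reference, min_cov = 3L) {
  stopifnot(nrow(aln) >= 1L)
  from <- region[1]; to <- region[2]
  stk <- stack_alignments(aln, from, to)
  cm <- Biostrings::consensusMatrix(stk)
  for (r in setdiff(c(DNA_BASES, "-", "+"), rownames(cm)))
    cm <- rbind(cm, matrix(0L, 1, ncol(cm), dimnames = list(r)))
  V <- cm[c(DNA_BASES, "-"), , drop = FALSE]
  refchars <- strsplit(ref_sub(reference, from, to), "")[[1]]
  cov <- colSums(V)
  top <- apply(V, 2L, max)
  # plurality with ties (and zero coverage) to the reference base
  winner <- character(ncol(V))
  for (j in seq_len(ncol(V))) {
    if (cov[j] < min_cov) { winner[j] <- refchars[j]; next }
    cand <- rownames(V)[V[, j] == top[j]]
    winner[j] <- if (refchars[j] %in% cand) refchars[j] else cand[1]
  }
  bases <- ifelse(winner == "-", "", winner)

  # deletions of >= 2 bases vote as events, not per column: in repeat context
  # individual reads place the same deletion at shifted offsets, and a
  # per-column majority would otherwise fragment it. The modal placement of
  # each majority-supported event overrides the affected columns (flanking
  # columns inside the event window revert to the reference).
  ev <- consensus_events(aln, from, to, op = "D", min_width = 2L)
  for (e in ev) {
    win <- max(from, e$win_lo):min(to, e$win_hi)
    bases[win - from + 1L] <- refchars[win - from + 1L]
    delcols <- max(from, e$start):min(to, e$start + e$width - 1L)
    bases[delcols - from + 1L] <- ""
  }

  ins <- consensus_insertions(aln, from, to)
  structure(list(start = from, end = to, bases = bases, ins = ins,
                 support = as.integer(top), depth = as.integer(cov),
                 n_reads = nrow(aln), low_support = nrow(aln) < 2L),
            class = "allele_consensus")
}

# majority-supported indel events of one op type, clustered across reads by
# placement (|delta start| <= 5, |delta width| <= 3); each event reports its
# modal (start, width) placement and the full window its observations span
consensus_events <- function(aln, from, to, op = "D", min_width = 2L) {
  rr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    aln$cigar, pos = aln$pos, ops = op)
  n_per <- lengths(rr)
  if (sum(n_per) == 0L) return(list())
  u <- unlist(rr)
  dt <- data.table::data.table(row = rep(seq_along(n_per), n_per),
                               start = BiocGenerics::start(u),
                               width = BiocGenerics::width(u))
  dt <- dt[width >= min_width & start >= from & start <= to]
  if (nrow(dt) == 0L) return(list())
  data.table::setorder(dt, start, width)
  nr <- nrow(dt)
  brk <- if (nr > 1L)
    dt$start[-1L] - dt$start[-nr] > 5L | abs(dt$width[-1L] - dt$width[-nr]) > 3L
  else logical(0)
  dt[, cluster := cumsum(c(1L, as.integer(brk)))]
  out <- list()
  for (g in unique(dt$cluster)) {
    sub <- dt[cluster == g]
    p <- as.integer(round(stats::median(sub$start)))
    covering <- sum(aln$ref_start <= p - 1L & aln$ref_end >= p + 1L)
    carriers <- length(unique(sub$row))
    if (covering < 3L || carriers * 2L <= covering) next
    key <- paste(sub$start, sub$width)
    modal <- names(sort(table(key), decreasing = TRUE))[1]
    mk <- as.integer(strsplit(modal, " ")[[1]])
    out[[length(out) + 1L]] <- list(
      start = mk[1], width = mk[2],
      win_lo = min(sub$start), win_hi = max(sub$start + sub$width - 1L),
      carriers = carriers)
  }
  out
}

consensus_insertions <- function(aln, from, to) {
  rr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    aln$cigar, pos = aln$pos, ops = "I")
  qr <- GenomicAlignments::cigarRangesAlongQuerySpace(aln$cigar, ops = "I")
  n_per <- lengths(rr)
  empty <- data.table::data.table(anchor = integer(0), seq = character(0))
  if (sum(n_per) == 0L) return(empty)
  rstart <- BiocGenerics::start(unlist(rr))
  qs <- BiocGenerics::start(unlist(qr)); qe <- BiocGenerics::end(unlist(qr))
  row <- rep(seq_along(n_per), n_per)
  seqs <- substr(rep(aln$seq, n_per), qs, qe)
  dt <- data.table::data.table(row = row, anchor = rstart - 1L, seq = seqs)
  dt <- dt[anchor >= from & anchor <= to]
  if (nrow(dt) == 0L) return(empty)
  # cluster anchors within 5 bases so placement jitter in repeat context does
  # not split one insertion allele's support
  data.table::setorder(dt, anchor)
  nr <- nrow(dt)
  brk <- if (nr > 1L) dt$anchor[-1L] - dt$anchor[-nr] > 5L else logical(0)
  dt[, cluster := cumsum(c(1L, as.integer(brk)))]
  out <- list()
  for (g in unique(dt$cluster)) {
    sub <- dt[cluster == g]
    a <- as.integer(round(stats::median(sub$anchor)))
    covering <- sum(aln$ref_start <= a & aln$ref_end >= a + 1L)
    # a genuine insertion allele aligns to one (anchor, sequence) key in
    # nearly every member read; scattered single-read errors never give one
    # exact key majority support
    key <- paste(sub$anchor, sub$seq)
    tab <- sort(table(key), decreasing = TRUE)
    if (covering < 3L || tab[1] * 2L <= covering) next
    sp <- regmatches(names(tab)[1], regexec("^(\\d+) (.*)$", names(tab)[1]))[[1]]
    out[[length(out) + 1L]] <- data.table::data.table(
      anchor = as.integer(sp[2]), seq = sp[3])
  }
  if (!length(out)) return(empty)
  res <- data.table::rbindlist(out)
  data.table::setorder(res, anchor)
  res
}

#' Sequence of a consensus object
#' @param cons an `allele_consensus` (or a slice of one).
#' @return DNA string with insertions woven in after their anchors.
#' @export
consensus_sequence <- function(cons) {
  bases <- cons$bases
  if (nrow(cons$ins)) {
    idx <- cons$ins$anchor - cons$start + 1L
    ok <- idx >= 1L & idx <= length(bases)
    bases[idx[ok]] <- paste0(bases[idx[ok]], cons$ins$seq[ok])
  }
  paste(bases, collapse = "")
}

# restrict a consensus to reference columns [from, to]
consensus_slice <- function(cons, from, to) {
  stopifnot(from >= cons$start, to <= cons$end)
  idx <- (from - cons$start + 1L):(to - cons$start + 1L)
  structure(list(start = from, end = to, bases = cons$bases[idx],
                 ins = cons$ins[cons$ins$anchor >= from & cons$ins$anchor < to],
                 support = cons$support[idx], depth = cons$depth[idx],
                 n_reads = cons$n_reads, low_support = cons$low_support),
            class = "allele_consensus")
}

#' Variants implied by a consensus relative to the reference
#'
#' Collects per-column substitutions/deletions and consensus insertions,
#' merges edited positions separated by at most `merge_gap` reference bases
#' into single delins events (so a junction edit is not fragmented), and
#' normalizes each resulting variant.
#'
#' @param cons an `allele_consensus`.
#' @param reference a [locus_reference()].
#' @param merge_gap maximum unedited gap merged into one event.
#' @return list of normalized `variant` records.
#' @export
consensus_diff <- function(cons, reference, merge_gap = 3L) {
  from <- cons$start
  refchars <- strsplit(ref_sub(reference, cons$start, cons$end), "")[[1]]
  edited <- which(cons$bases != refchars)          # subs and deletions
  pos_ed <- from + edited - 1L
  # represent each edit by its reference interval; insertions by [a+1, a]
  iv <- rbind(
    if (length(pos_ed)) cbind(pos_ed, pos_ed),
    if (nrow(cons$ins)) cbind(cons$ins$anchor + 1L, cons$ins$anchor))
  if (is.null(iv) || nrow(iv) == 0L) return(list())
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  grp <- cumsum(c(1L, as.integer(
    iv[-1, 1] - pmax(iv[-nrow(iv), 2], iv[-nrow(iv), 1] - 1L) > merge_gap + 1L)))
  out <- list()
  for (g in unique(grp)) {
    rows <- iv[grp == g, , drop = FALSE]
    p1 <- min(rows[, 1]); p2 <- max(rows[, 1], rows[, 2])
    p1 <- max(p1, cons$start); p2 <- min(p2, cons$end)
    cols <- (p1 - from + 1L):(p2 - from + 1L)
    alt_bases <- cons$bases[cols]
    ins_here <- cons$ins[cons$ins$anchor >= p1 & cons$ins$anchor <= p2]
    if (nrow(ins_here)) {
      idx <- ins_here$anchor - p1 + 1L
      alt_bases[idx] <- paste0(alt_bases[idx], ins_here$seq)
    }
    lead_ins <- cons$ins[cons$ins$anchor == p1 - 1L]
    alt <- paste0(if (nrow(lead_ins)) lead_ins$seq[1] else "",
                  paste(alt_bases, collapse = ""))
    rs <- ref_sub(reference, p1, p2)
    if (identical(alt, rs)) next
    out[[length(out) + 1L]] <-
      normalize_variant(new_variant(p1, rs, alt, "DELINS"), reference)
  }
  out
}
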