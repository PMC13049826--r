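#' Reference locus sequence
#'
#' Container for the genomic reference sequence of the target locus. The
#' sequence is stored as a single uppercase DNA string; all locus ("g.")
#' coordinates used across the package are 1-based positions into it.
#'
#' @param name identifier for the locus.
#' @param sequence DNA string (A/C/G/T only), at least 60 kb.
#' @return An object of class `locus_reference` with fields `name`,
#'   `sequence` and `length`.
#' @export
locus_reference <- function(name, sequence) {
  sequence <- toupper(as.character(sequence))
  if (grepl("[^ACGT]", sequence))
    stop("locus sequence must contain only A, C, G, T")
  if (nchar(sequence) < 60000L)
    stop("locus sequence shorter than 60 kb: got ", nchar(sequence))
  structure(list(name = name, sequence = sequence, length = nchar(sequence)),
            class = "locus_reference")
}

#' @export
print.locus_reference <- function(x, ...) {
  cat(sprintf("<locus_reference> %s: %d bp\n", x$name, x$length))
  invisible(x)
}

ref_sub <- function(ref, start, end) {
  if (start < 1L || end > ref$length) stop("coordinates outside locus")
  substr(ref$sequence, start, end)
}

#' Transcript model for the locus
#'
#' Exon structure plus the CDS span on the forward strand. Exons are 1-based
#' inclusive locus intervals, sorted and non-overlapping. `cds_start` is the
#' locus position of c.1 (first base of the ATG) and must fall inside an exon;
#' `cds_end` is the last coding base.
#'
#' @param exons data.frame with columns `start`, `end` (one row per exon).
#' @param cds_start,cds_end locus positions of the CDS boundaries.
#' @param locus_length total locus length (used for coordinate validation).
#' @return Object of class `transcript_model`; carries a precomputed map of
#'   coding-exon segments to CDS ("c.") coordinates.
#' @export
transcript_model <- function(exons, cds_start, cds_end, locus_length = NA_integer_) {
  exons <- as.data.frame(exons)[, c("start", "end")]
  stopifnot(all(exons$start <= exons$end))
  if (is.unsorted(exons$start, strictly = TRUE))
    stop("exons must be sorted in ascending order")
  if (any(exons$start[-1] <= exons$end[-nrow(exons)]))
    stop("exons must not overlap")
  in_exon <- function(p) any(p >= exons$start & p <= exons$end)
  if (!in_exon(cds_start) || !in_exon(cds_end))
    stop("cds_start/cds_end must lie inside exons")

  # coding segments with cumulative c. coordinates
  seg <- exons[exons$end >= cds_start & exons$start <= cds_end, ]
  seg$g_start <- pmax(seg$start, cds_start)
  seg$g_end <- pmin(seg$end, cds_end)
  w <- seg$g_end - seg$g_start + 1L
  seg$c_start <- cumsum(c(0L, w[-length(w)])) + 1L
  seg$c_end <- cumsum(w)
  seg$exon <- match(seg$start, exons$start)

  structure(list(exons = exons, n_exons = nrow(exons),
                 cds_start = cds_start, cds_end = cds_end,
                 coding = seg, locus_length = locus_length),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %d exons, CDS %d..%d (c.1..c.%d)\n",
              x$n_exons, x$cds_start, x$cds_end, max(x$coding$c_end)))
  invisible(x)
}

# index of the exon whose 5'UTR hosts c.- coordinates (exon containing cds_start)
cds_exon_index <- function(tx) {
  with(tx, which(exons$start <= cds_start & exons$end >= cds_start))
}

#' Convert a locus position to a CDS-space coordinate string
#'
#' Coding positions map to plain `N`; 5'UTR positions inside the
#' CDS-containing exon map to `-K`; intronic positions between coding exons
#' map to the nearest-exon offset form `N+k` / `N-k` (ties broken toward the
#' upstream `+` form). Positions 5' of the CDS-containing exon use the
#' linear-genomic-offset convention `1-K`, where K is the genomic distance to
#' c.1 — this reproduces breakpoint strings such as `c.1-15966` that standard
#' intron offsets cannot express. Positions 3' of the CDS use `*K` with K the
#' linear genomic distance past the last coding base.
#'
#' @param pos integer vector of locus positions.
#' @param tx a [transcript_model()].
#' @return character vector of c. coordinate bodies (without the `"c."`
#'   prefix), e.g. `"120+3885"`, `"-132"`, `"1-15966"`.
#' @export
g_to_c <- function(pos, tx) {
  vapply(as.integer(pos), g_to_c1, character(1), tx = tx)
}

g_to_c1 <- function(pos, tx) {
  if (is.na(pos) || pos < 1L ||
      (!is.na(tx$locus_length) && pos > tx$locus_length))
    stop("position outside locus: ", pos)
  cod <- tx$coding
  hit <- which(pos >= cod$g_start & pos <= cod$g_end)
  if (length(hit) == 1L)
    return(as.character(cod$c_start[hit] + (pos - cod$g_start[hit])))
  utr_exon <- cds_exon_index(tx)
  utr_start <- tx$exons$start[utr_exon]
  if (pos < tx$cds_start) {
    if (pos >= utr_start) return(paste0("-", tx$cds_start - pos))
    return(paste0("1-", tx$cds_start - pos))      # upstream linear offset
  }
  if (pos > tx$cds_end) {
    last_seg <- nrow(cod)
    # within the last coding exon's 3' extension this cannot happen (cds_end
    # ends the exon in this model); use linear distance past the CDS.
    return(paste0("*", pos - tx$cds_end))
  }
  # intronic between coding exons
  up <- max(which(cod$g_end < pos))
  dn <- up + 1L
  d_up <- pos - cod$g_end[up]
  d_dn <- cod$g_start[dn] - pos
  if (d_up <= d_dn) paste0(cod$c_end[up], "+", d_up)
  else paste0(cod$c_start[dn], "-", d_dn)
}

#' Convert a CDS-space coordinate string to a locus position
#'
#' Inverse of [g_to_c()]. Accepts bodies with or without the `"c."` prefix:
#' `N`, `-K`, `*K`, `N+k`, `N-k` (the latter covering both intronic offsets
#' and the upstream linear convention `1-K`).
#'
#' @param cstr character vector of c. coordinates.
#' @param tx a [transcript_model()].
#' @return integer vector of locus positions.
#' @export
c_to_g <- function(cstr, tx) {
  vapply(as.character(cstr), c_to_g1, integer(1), tx = tx, USE.NAMES = FALSE)
}

c_to_g1 <- function(cstr, tx) {
  s <- sub("^c\\.", "", trimws(cstr))
  m <- regmatches(s, regexec("^(\\*?-?\\d+)([+-]\\d+)?$", s))[[1]]
  if (length(m) == 0L) stop("malformed c. coordinate: ", cstr)
  base <- m[2]; off <- m[3]
  g <- if (startsWith(base, "-")) {
    tx$cds_start - as.integer(sub("^-", "", base))
  } else if (startsWith(base, "*")) {
    tx$cds_end + as.integer(sub("^\\*", "", base))
  } else {
    n <- as.integer(base)
    cod <- tx$coding
    hit <- which(n >= cod$c_start & n <= cod$c_end)
    if (length(hit) != 1L) stop("c. position outside CDS: ", cstr)
    cod$g_start[hit] + (n - cod$c_start[hit])
  }
  if (!is.na(off) && nzchar(off)) g <- g + as.integer(off)
  as.integer(g)
}

#' Create a variant record
#'
#' Internal edit representation in locus space: `pos` is the 1-based first
#' affected base (for insertions, the base *after* which the new sequence is
#' inserted), `ref` the replaced reference bases (empty for pure insertions),
#' `alt` the inserted bases (empty for pure deletions).
#'
#' @param pos locus position.
#' @param ref,alt replaced / inserted sequence (possibly empty strings).
#' @param kind one of `"SNV"`, `"DEL"`, `"INS"`, `"DUP"`, `"DELINS"`; inferred
#'   from `ref`/`alt` when missing.
#' @return Object of class `variant`.
#' @export
new_variant <- function(pos, ref, alt, kind = NULL) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (!nzchar(ref) && !nzchar(alt)) stop("variant with empty ref and alt")
  if (is.null(kind)) {
    kind <- if (nchar(ref) == 1L && nchar(alt) == 1L) "SNV"
    else if (!nzchar(alt)) "DEL"
    else if (!nzchar(ref)) "INS"
    else "DELINS"
  }
  structure(list(pos = as.integer(pos), ref = ref, alt = alt, kind = kind),
            class = "variant")
}

#' @export
print.variant <- function(x, ...) {
  cat(sprintf("<variant> %s @%d %s>%s\n", x$kind, x$pos,
              if (nzchar(x$ref)) x$ref else "-",
              if (nzchar(x$alt)) x$alt else "-"))
  invisible(x)
}

variant_span <- function(v) {
  # occupied reference interval; insertions occupy nothing (anchor after pos)
  if (!nzchar(v$ref)) c(v$pos + 0.5, v$pos + 0.5)
  else c(v$pos, v$pos + nchar(v$ref) - 1L)
}

validate_variant <- function(v, ref) {
  if (nzchar(v$ref)) {
    have <- ref_sub(ref, v$pos, v$pos + nchar(v$ref) - 1L)
    if (have != v$ref)
      stop(sprintf("variant ref mismatch at %d: expected %s, reference has %s",
                   v$pos, v$ref, have))
  } else if (v$pos < 0L || v$pos > ref$length) {
    stop("insertion anchor outside locus")
  }
  invisible(v)
}

variant_key <- function(v) paste(v$pos, v$ref, v$alt, sep = ":")

#' Canonical 3'-shifted form of a variant
#'
#' Trims shared ref/alt affixes, then shifts pure deletions and insertions to
#' their 3'-most (right-most) placement within repeat context; insertions that
#' exactly duplicate the immediately preceding reference segment are
#' reclassified as `DUP`. SNVs are fixed points. Idempotent: two descriptors
#' of the same edit normalize to the identical record.
#'
#' @param v a [new_variant()].
#' @param ref a [locus_reference()].
#' @return a normalized `variant`.
#' @export
normalize_variant <- function(v, ref) {
  validate_variant(v, ref)
  r <- v$ref; a <- v$alt; pos <- v$pos
  # trim common prefix
  np <- 0L
  while (np < nchar(r) && np < nchar(a) &&
         substr(r, np + 1L, np + 1L) == substr(a, np + 1L, np + 1L)) np <- np + 1L
  if (np > 0L) {
    r <- substr(r, np + 1L, nchar(r)); a <- substr(a, np + 1L, nchar(a))
    pos <- pos + np
  }
  # trim common suffix
  ns <- 0L
  while (ns < nchar(r) && ns < nchar(a) &&
         substr(r, nchar(r) - ns, nchar(r) - ns) ==
         substr(a, nchar(a) - ns, nchar(a) - ns)) ns <- ns + 1L
  if (ns > 0L) { r <- substr(r, 1L, nchar(r) - ns); a <- substr(a, 1L, nchar(a) - ns) }

  if (!nzchar(r) && !nzchar(a)) stop("variant is a no-op after trimming")

  if (nzchar(r) && nzchar(a)) {          # substitution or delins: fixed
    kind <- if (nchar(r) == 1L && nchar(a) == 1L) "SNV" else "DELINS"
    return(new_variant(pos, r, a, kind))
  }
  if (!nzchar(a)) {                      # pure deletion: 3' shift
    len <- nchar(r)
    while (pos + len <= ref$length &&
           substr(ref$sequence, pos, pos) == substr(ref$sequence, pos + len, pos + len)) {
      pos <- pos + 1L
    }
    return(new_variant(pos, ref_sub(ref, pos, pos + len - 1L), "", "DEL"))
  }
  # pure insertion after `anchor`. Insertion records already use anchor-after
  # semantics; a delins reduced to an insertion by trimming has pos at the
  # first divergent base, one past the anchor.
  anchor <- if (!nzchar(v$ref)) pos else pos - 1L
  ins <- a
  while (anchor + 1L <= ref$length &&
         substr(ins, 1L, 1L) == substr(ref$sequence, anchor + 1L, anchor + 1L)) {
    anchor <- anchor + 1L
    ins <- paste0(substr(ins, 2L, nchar(ins)), substr(ins, 1L, 1L))
  }
  len <- nchar(ins)
  kind <- if (anchor >= len &&
              ref_sub(ref, anchor - len + 1L, anchor) == ins) "DUP" else "INS"
  new_variant(anchor, "", ins, kind)
}

#' Apply variants to the reference to build a haplotype sequence
#'
#' Variants must be non-overlapping after normalization. Returns the edited
#' sequence together with a locus-to-haplotype coordinate map.
#'
#' @param ref a [locus_reference()].
#' @param variants list of `variant` records (any order).
#' @return list with `sequence` (character scalar) and `map` (integer vector
#'   of length `ref$length`: haplotype position of each reference base, `NA`
#'   for deleted bases). The map is monotone over unedited positions.
#' @export
apply_variants <- function(ref, variants) {
  if (length(variants) == 0L)
    return(list(sequence = ref$sequence, map = seq_len(ref$length)))
  variants <- lapply(variants, validate_variant, ref = ref)
  ord <- order(vapply(variants, function(v) v$pos + if (nzchar(v$ref)) 0 else 0.5,
                      numeric(1)))
  variants <- variants[ord]
  spans <- t(vapply(variants, variant_span, numeric(2)))
  if (nrow(spans) > 1L) {
    bad <- which(spans[-1L, 1L] <= spans[-nrow(spans), 2L])
    if (length(bad))
      stop(sprintf("overlapping variants: #%d (%s) and #%d (%s)",
                   bad[1], variant_key(variants[[bad[1]]]),
                   bad[1] + 1L, variant_key(variants[[bad[1] + 1L]])))
  }
  pieces <- character(0)
  map <- rep(NA_integer_, ref$length)
  cursor <- 1L      # next unconsumed reference base
  out_len <- 0L
  for (v in variants) {
    keep_end <- if (nzchar(v$ref)) v$pos - 1L else v$pos
    if (keep_end >= cursor) {
      n <- keep_end - cursor + 1L
      pieces <- c(pieces, substr(ref$sequence, cursor, keep_end))
      map[cursor:keep_end] <- out_len + seq_len(n)
      out_len <- out_len + n
    }
    if (v$kind == "SNV") {
      pieces <- c(pieces, v$alt)
      map[v$pos] <- out_len + 1L
      out_len <- out_len + 1L
      cursor <- v$pos + 1L
    } else {
      if (nzchar(v$alt)) { pieces <- c(pieces, v$alt); out_len <- out_len + nchar(v$alt) }
      cursor <- keep_end + 1L + nchar(v$ref)
    }
  }
  if (cursor <= ref$length) {
    n <- ref$length - cursor + 1L
    pieces <- c(pieces, substr(ref$sequence, cursor, ref$length))
    map[cursor:ref$length] <- out_len + seq_len(n)
  }
  list(sequence = paste(pieces, collapse = ""), map = map)
}
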