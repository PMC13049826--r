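# HGVS-style descriptor support, restricted to the forms used in this locus's
# reporting: substitutions, deletions (with or without the deleted sequence,
# including the single-start form "c.1227delTATTGTGCCTAT"), duplications,
# insertions, and deletion-insertions. Coordinates may be in c. space
# (transcript required) or g. space.

strip_hgvs_ws <- function(text) {
  # printed tables use thin/nonbreaking spaces and en-dashes around tokens
  s <- gsub("[\\s\u00a0\u2009\u2008\u202f]+", "", text, perl = TRUE)
  gsub("[\u2013\u2212]", "-", s)
}

#' Parse an HGVS descriptor into a variant
#'
#' Supported bodies (in `c.` or `g.` space): `N ref>alt`, `N_M del[SEQ]`,
#' `N delSEQ`, `N_M dupSEQ`, `N insSEQ`, `N_M insSEQ`, `N_M delinsSEQ`.
#' Whitespace (including typographic spaces) is ignored and en-dashes are
#' treated as hyphens, so strings lifted from printed tables parse as-is.
#' The second coordinate of a range may repeat the space prefix
#' (`g.33588_g.53560delins...`).
#'
#' @param text HGVS string, e.g. `"c.-132A>C"` or
#'   `"c.1-15966_c.120+3885delinsCCAATGCTAAGGTTGA"`.
#' @param tx [transcript_model()]; required for `c.` space.
#' @param ref optional [locus_reference()]; when supplied, deletion/dup
#'   sequences are validated and deletions written without a sequence are
#'   resolved against it.
#' @return a `variant` in locus (g.) space.
#' @export
parse_hgvs <- function(text, tx = NULL, ref = NULL) {
  s <- strip_hgvs_ws(text)
  space <- if (startsWith(s, "c.")) "c" else if (startsWith(s, "g.")) "g" else
    stop("HGVS string must start with 'c.' or 'g.': ", text)
  if (space == "c" && is.null(tx)) stop("c.-space HGVS requires a transcript")
  body <- substr(s, 3L, nchar(s))

  coord <- function(tok) {
    tok <- sub(paste0("^", space, "\\."), "", tok)
    if (space == "g") {
      if (!grepl("^\\d+$", tok)) stop("malformed g. coordinate: ", tok)
      as.integer(tok)
    } else c_to_g1(tok, tx)
  }
  ctok <- "[*-]?\\d+(?:[+-]\\d+)?"
  ctok2 <- paste0("(?:", space, "\\.)?", ctok)

  # N_M delinsSEQ
  m <- regmatches(body, regexec(
    paste0("^(", ctok, ")_(", ctok2, ")delins([ACGTacgt]+)$"), body))[[1]]
  if (length(m)) {
    p1 <- coord(m[2]); p2 <- coord(m[3])
    if (p2 <= p1) stop("delins range reversed: ", text)
    rseq <- if (!is.null(ref)) ref_sub(ref, p1, p2) else
      strrep("N", p2 - p1 + 1L)
    return(new_variant(p1, rseq, toupper(m[4]), "DELINS"))
  }
  # N_M dupSEQ / dup
  m <- regmatches(body, regexec(
    paste0("^(", ctok, ")_(", ctok2, ")dup([ACGTacgt]*)$"), body))[[1]]
  if (length(m)) {
    p1 <- coord(m[2]); p2 <- coord(m[3])
    dseq <- toupper(m[4])
    if (!nzchar(dseq)) {
      if (is.null(ref)) stop("dup without sequence requires the reference")
      dseq <- ref_sub(ref, p1, p2)
    }
    if (nchar(dseq) != p2 - p1 + 1L) stop("dup length mismatch: ", text)
    if (!is.null(ref) && ref_sub(ref, p1, p2) != dseq)
      stop("dup sequence does not match reference: ", text)
    return(new_variant(p2, "", dseq, "DUP"))
  }
  # N dupSEQ (single-base or anchored duplication)
  m <- regmatches(body, regexec(
    paste0("^(", ctok, ")dup([ACGTacgt]+)$"), body))[[1]]
  if (length(m)) {
    p1 <- coord(m[2]); dseq <- toupper(m[3])
    if (!is.null(ref) && ref_sub(ref, p1 - nchar(dseq) + 1L, p1) != dseq)
      stop("dup sequence does not match reference: ", text)
    return(new_variant(p1, "", dseq, "DUP"))
  }
  # N_M del[SEQ]
  m <- regmatches(body, regexec(
    paste0("^(", ctok, ")_(", ctok2, ")del([ACGTacgt]*)$"), body))[[1]]
  if (length(m)) {
    p1 <- coord(m[2]); p2 <- coord(m[3])
    dseq <- toupper(m[4])
    if (nzchar(dseq) && nchar(dseq) != p2 - p1 + 1L)
      stop("del length mismatch: ", text)
    if (!nzchar(dseq)) {
      if (is.null(ref)) stop("del without sequence requires the reference")
      dseq <- ref_sub(ref, p1, p2)
    }
    return(new_variant(p1, dseq, "", "DEL"))
  }
  # N delSEQ (single start coordinate, deletion length from the sequence)
  m <- regmatches(body, regexec(
    paste0("^(", ctok, ")del([ACGTacgt]+)$"), body))[[1]]
  if (length(m)) {
    p1 <- coord(m[2])
    return(new_variant(p1, toupper(m[3]), "", "DEL"))
  }
  # N insSEQ / N_M insSEQ (insertion after the first coordinate)
  m <- regmatches(body, regexec(
    paste0("^(", ctok, ")(?:_(", ctok2, "))?ins([ACGTacgt]+)$"), body))[[1]]
  if (length(m)) {
    p1 <- coord(m[2])
    if (nzchar(m[3]) && coord(m[3]) != p1 + 1L)
      stop("insertion range must be adjacent positions: ", text)
    return(new_variant(p1, "", toupper(m[4]), "INS"))
  }
  # N ref>alt
  m <- regmatches(body, regexec(
    paste0("^(", ctok, ")([ACGTacgt])>([ACGTacgt])$"), body))[[1]]
  if (length(m)) {
    return(new_variant(coord(m[2]), toupper(m[3]), toupper(m[4]), "SNV"))
  }
  stop("unsupported HGVS syntax: '", text, "'")
}

#' Name a variant in HGVS style
#'
#' Produces the descriptor in `g.` or `c.` space. Deleted sequences longer
#' than `max_seq` bases are omitted (plain `del`); the inserted sequence of a
#' delins is always printed. In `c.` space, when a range endpoint carries an
#' offset the second endpoint repeats the `c.` prefix, matching the style of
#' breakpoint descriptors such as `c.1-15966_c.120+3885delinsCCAATGCTAAGGTTGA`.
#'
#' @param v a `variant`.
#' @param tx [transcript_model()] (required for `space = "c"`).
#' @param space `"c"` or `"g"`.
#' @param max_seq longest deleted sequence to spell out.
#' @return HGVS string.
#' @export
hgvs_name <- function(v, tx = NULL, space = c("c", "g"), max_seq = 30L) {
  space <- match.arg(space)
  cc <- function(pos) {
    if (space == "g") as.character(pos) else g_to_c1(pos, tx)
  }
  pre <- paste0(space, ".")
  rng <- function(p1, p2) {
    a <- cc(p1); b <- cc(p2)
    b_pref <- if (space == "c" && grepl("[+*-]", paste0(a, b))) pre else ""
    paste0(a, "_", b_pref, b)
  }
  body <- switch(v$kind,
    SNV = paste0(cc(v$pos), v$ref, ">", v$alt),
    DEL = {
      p2 <- v$pos + nchar(v$ref) - 1L
      seqpart <- if (nchar(v$ref) <= max_seq) v$ref else ""
      if (nchar(v$ref) == 1L) paste0(cc(v$pos), "del", seqpart)
      else paste0(rng(v$pos, p2), "del", seqpart)
    },
    INS = paste0(cc(v$pos), "ins", v$alt),
    DUP = {
      len <- nchar(v$alt)
      if (len == 1L) paste0(cc(v$pos), "dup", v$alt)
      else paste0(rng(v$pos - len + 1L, v$pos), "dup", v$alt)
    },
    DELINS = paste0(rng(v$pos, v$pos + nchar(v$ref) - 1L), "delins", v$alt),
    stop("unknown variant kind: ", v$kind)
  )
  paste0(pre, body)
}
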