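# Coordinate system, HGVS descriptors, normalization and variant application.

test_that("CDS coordinate conversion handles coding, UTR, intronic and upstream positions", {
  loc <- fixture_locus()
  tx <- loc$transcript
  cds <- tx$cds_start
  expect_identical(g_to_c(cds, tx), "1")
  # 5'UTR inside the CDS-containing exon
  expect_identical(g_to_c(cds - 132L, tx), "-132")
  # far upstream of exon 3: linear genomic offset from c.1
  expect_identical(g_to_c(cds - 15966L, tx), "1-15966")
  # intron offsets on both sides of a boundary
  expect_identical(g_to_c(c_to_g("430", tx) - 1L, tx), "430-1")
  expect_identical(g_to_c(c_to_g("609", tx) + 7L, tx), "609+7")
  expect_error(g_to_c(0L, tx), "outside")
  expect_error(g_to_c(loc$reference$length + 1L, tx), "outside")
})

test_that("g_to_c and c_to_g are mutual inverses over the whole locus", {
  loc <- fixture_locus()
  tx <- loc$transcript
  pos <- seeded_sample(loc$reference$length, 4000L, seed = 2L)
  expect_identical(c_to_g(g_to_c(pos, tx), tx), pos)
  # and the specific breakpoint coordinates
  expect_identical(c_to_g("c.1", tx), tx$cds_start)
  expect_identical(c_to_g("c.120+3887", tx),
                   c_to_g("120", tx) + 3887L)
  expect_identical(c_to_g("c.-132", tx), tx$cds_start - 132L)
})

test_that("HGVS parser covers the study's descriptor forms", {
  loc <- fixture_locus()
  tx <- loc$transcript; ref <- loc$reference
  v <- parse_hgvs("c.-132A>C", tx, ref)
  expect_identical(v$kind, "SNV")
  expect_identical(v$pos, tx$cds_start - 132L)
  expect_identical(v$ref, "A"); expect_identical(v$alt, "C")

  # typographic spacing and dashes as printed in tables
  v2 <- parse_hgvs("c.430–2 A > G", tx, ref)
  expect_identical(v2$pos, c_to_g("430", tx) - 2L)

  v3 <- parse_hgvs("c.1340_1343dupTCTT", tx, ref)
  expect_identical(v3$kind, "DUP")
  expect_identical(nchar(v3$alt), 4L)

  # g-space delins with repeated prefix; 16-base insert
  v4 <- parse_hgvs(sprintf("g.%d_g.%ddelinsCCAATGCTAAGGTTGA",
                           loc$sv$left, loc$sv$right), tx, ref)
  expect_identical(nchar(v4$alt), 16L)
  expect_identical(nchar(v4$ref), loc$sv$del_len)

  expect_error(parse_hgvs("c.10inv", tx, ref), "unsupported")
  expect_error(parse_hgvs("x.10A>C", tx, ref), "must start")
})

test_that("the two printed spellings of the exon 13 deletion are the same edit", {
  loc <- fixture_locus()
  ref <- loc$reference; tx <- loc$transcript
  v1 <- parse_hgvs("c.1227delTATTGTGCCTAT", tx, ref)
  v2 <- parse_hgvs("c.1228_1239delATTGTGCCTATT", tx, ref)
  s1 <- apply_variants(ref, list(v1))$sequence
  s2 <- apply_variants(ref, list(v2))$sequence
  expect_identical(s1, s2)
  n1 <- normalize_variant(v1, ref); n2 <- normalize_variant(v2, ref)
  expect_identical(variant_key(n1), variant_key(n2))
  expect_identical(hgvs_name(n1, tx), "c.1228_1239delATTGTGCCTATT")
})

test_that("normalization 3'-shifts deletions through repeat runs (exhaustive)", {
  loc <- fixture_locus()
  ref <- loc$reference
  # build a 5-base homopolymer run and enumerate all placements of a 1-base
  # deletion within it: all must produce one edited string and one canonical
  run <- regexpr("AAAAA", ref$sequence)
  skip_if(run < 0, "no homopolymer run in fixture")
  p0 <- as.integer(run)
  edited <- unique(vapply(0:4, function(o)
    apply_variants(ref, list(new_variant(p0 + o, "A", "")))$sequence,
    character(1)))
  expect_length(edited, 1L)
  canon <- unique(vapply(0:4, function(o)
    variant_key(normalize_variant(new_variant(p0 + o, "A", ""), ref)),
    character(1)))
  expect_length(canon, 1L)
  # the canonical placement is the 3'-most one in the run
  v <- normalize_variant(new_variant(p0, "A", ""), ref)
  expect_identical(v$pos, p0 + 4L)
})

test_that("normalization is idempotent and HGVS round-trips on fuzzed variants", {
  loc <- fixture_locus()
  ref <- loc$reference; tx <- loc$transcript
  set.seed(31)
  for (i in 1:150) {
    p <- sample(1000:76000, 1)
    kind <- sample(c("SNV", "DEL", "INS"), 1)
    v <- switch(kind,
      SNV = new_variant(p, ref_sub(ref, p, p),
                        other_base(ref_sub(ref, p, p))),
      DEL = new_variant(p, ref_sub(ref, p, p + sample(0:11, 1)), ""),
      INS = new_variant(p, "", random_dna(sample(1:8, 1))))
    nv <- normalize_variant(v, ref)
    expect_identical(variant_key(normalize_variant(nv, ref)),
                     variant_key(nv))
    for (space in c("c", "g")) {
      back <- parse_hgvs(hgvs_name(nv, tx, space), tx, ref)
      expect_identical(apply_variants(ref, list(back))$sequence,
                       apply_variants(ref, list(v))$sequence)
    }
  }
})

test_that("apply_variants obeys the length-conservation formula and rejects overlaps", {
  loc <- fixture_locus()
  ref <- loc$reference
  expect_identical(apply_variants(ref, list())$sequence, ref$sequence)
  v_snv <- new_variant(5000L, ref_sub(ref, 5000L, 5000L), "A")
  if (v_snv$ref == "A") v_snv <- new_variant(5000L, "A", "G")
  one <- apply_variants(ref, list(v_snv))
  expect_identical(nchar(one$sequence), ref$length)

  sv <- loc$sv$variant
  res <- apply_variants(ref, list(sv))
  expect_identical(ref$length - nchar(res$sequence), 19971L - 16L)
  # coordinate map: monotone over retained positions, NA over deleted ones
  expect_true(all(is.na(res$map[loc$sv$left:loc$sv$right])))
  kept <- res$map[!is.na(res$map)]
  expect_true(all(diff(kept) > 0))

  v1 <- new_variant(10000L, ref_sub(ref, 10000L, 10010L), "")
  v2 <- new_variant(10005L, ref_sub(ref, 10005L, 10005L), "T")
  expect_error(apply_variants(ref, list(v1, v2)), "overlapping")
})
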