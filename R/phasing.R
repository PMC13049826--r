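# Chaining per-amplicon allele clusters into two full-length haplotypes via
# shared heterozygous variants inside the >= 3 kb amplicon overlaps, plus
# detection of the contiguous-dropout signature of cryptic deletions.

# --- junction evidence (pure functions on allele vectors) -------------------

# alleles of a cluster over an overlap: consensus column characters plus
# insertion keys, as one named character vector
overlap_alleles <- function(cons, from, to) {
  sl <- consensus_slice(cons, from, to)
  v <- sl$bases
  names(v) <- paste0("p", seq(from, to))
  if (nrow(sl$ins)) {
    iv <- sl$ins$seq
    names(iv) <- paste0("i", sl$ins$anchor)
    v <- c(v, iv)
  }
  v
}

# align two allele vectors on the union of their site names
allele_pair <- function(a, b) {
  keys <- union(names(a), names(b))
  av <- a[keys]; bv <- b[keys]
  av[is.na(av)] <- ""; bv[is.na(bv)] <- ""
  list(a = unname(av), b = unname(bv), keys = keys)
}

count_diff <- function(a, b) {
  p <- allele_pair(a, b)
  sum(p$a != p$b)
}

# evidence for pairing two upstream clusters with two downstream clusters:
# informative sites are those where both pairs differ
junction_evidence <- function(up, down) {
  stopifnot(length(up) == 2L, length(down) == 2L)
  keys <- Reduce(union, c(lapply(up, names), lapply(down, names)))
  get <- function(v) { x <- v[keys]; x[is.na(x)] <- ""; unname(x) }
  u1 <- get(up[[1]]); u2 <- get(up[[2]])
  d1 <- get(down[[1]]); d2 <- get(down[[2]])
  informative <- u1 != u2 & d1 != d2
  parallel <- sum(informative & u1 == d1 & u2 == d2)
  cross <- sum(informative & u1 == d2 & u2 == d1)
  list(n_informative = sum(informative), parallel = parallel, cross = cross)
}

# match one allele vector against two alternatives at their informative sites
match_single <- function(x, alt) {
  keys <- Reduce(union, c(list(names(x)), lapply(alt, names)))
  get <- function(v) { y <- v[keys]; y[is.na(y)] <- ""; unname(y) }
  xv <- get(x); a1 <- get(alt[[1]]); a2 <- get(alt[[2]])
  informative <- a1 != a2
  c(sum(informative & xv == a1), sum(informative & xv == a2))
}

# --- core chaining ----------------------------------------------------------

# instance: list per amplicon of clusters, each cluster a list with elements
# `left` and `right` (allele vectors over the flanking overlaps; NULL at the
# outer ends). Returns per-amplicon track assignment.
phase_core <- function(instance) {
  k <- length(instance)
  n_cl <- vapply(instance, length, integer(1))
  if (any(n_cl > 2L))
    stop("contamination: amplicon with ", max(n_cl), " allele clusters")
  # track state: cluster index per amplicon (NA = dropout), per track
  tr <- matrix(NA_integer_, nrow = 2L, ncol = k)
  flags <- rep(FALSE, k - 1L)      # ambiguous-junction flags
  init <- which(n_cl > 0L)[1]
  if (is.na(init)) stop("no amplified amplicon")
  tr[, init] <- if (n_cl[init] == 2L) c(1L, 2L) else c(1L, 1L)
  if (init > 1L && k >= 2L) flags[seq_len(init - 1L)] <- TRUE
  j <- init
  while (j < k) {
    up_idx <- tr[, j]
    down <- instance[[j + 1L]]
    nd <- length(down)
    if (nd == 0L) {
      tr[, j + 1L] <- NA_integer_
      flags[j] <- TRUE
    } else if (all(is.na(up_idx))) {
      tr[, j + 1L] <- if (nd == 2L) c(1L, 2L) else c(1L, 1L)
      flags[j] <- TRUE
    } else if (nd == 2L) {
      dn <- list(down[[1]]$left, down[[2]]$left)
      if (!is.na(up_idx[1]) && !is.na(up_idx[2]) && up_idx[1] != up_idx[2]) {
        ev <- junction_evidence(
          list(instance[[j]][[up_idx[1]]]$right, instance[[j]][[up_idx[2]]]$right),
          dn)
        if (ev$parallel > ev$cross) tr[, j + 1L] <- c(1L, 2L)
        else if (ev$cross > ev$parallel) tr[, j + 1L] <- c(2L, 1L)
        else { tr[, j + 1L] <- c(1L, 2L); flags[j] <- TRUE }
      } else {
        # upstream single (shared or one-track); match it to the downstream pair
        live <- which(!is.na(up_idx))[1]
        u <- instance[[j]][[up_idx[live]]]$right
        sc <- match_single(u, dn)
        if (sc[1] > sc[2] || sc[2] > sc[1]) {
          w <- if (sc[1] > sc[2]) 1L else 2L
          if (all(!is.na(up_idx))) {
            # both tracks shared one cluster yet downstream splits: the
            # unmatched allele's upstream amplicon did not amplify
            tr[1L, j + 1L] <- w; tr[2L, j + 1L] <- 3L - w
            tr[2L, j] <- NA_integer_
            tr[1L, j] <- up_idx[live]
          } else {
            tr[live, j + 1L] <- w
            tr[3L - live, j + 1L] <- 3L - w
          }
        } else {
          tr[, j + 1L] <- c(1L, 2L); flags[j] <- TRUE
        }
      }
    } else {                      # single downstream cluster
      d <- down[[1]]$left
      if (!is.na(up_idx[1]) && !is.na(up_idx[2]) && up_idx[1] != up_idx[2]) {
        sc <- match_single(d, list(instance[[j]][[up_idx[1]]]$right,
                                   instance[[j]][[up_idx[2]]]$right))
        if (sc[1] > sc[2]) { tr[1L, j + 1L] <- 1L; tr[2L, j + 1L] <- NA_integer_ }
        else if (sc[2] > sc[1]) { tr[2L, j + 1L] <- 1L; tr[1L, j + 1L] <- NA_integer_ }
        else { tr[, j + 1L] <- 1L; flags[j] <- TRUE }
      } else {
        live <- which(!is.na(up_idx))
        u <- instance[[j]][[up_idx[live[1]]]]$right
        nd_diff <- count_diff(u, d)
        if (length(live) == 2L) {
          tr[, j + 1L] <- 1L                      # shared stays shared
        } else if (nd_diff <= 2L) {
          tr[live, j + 1L] <- 1L                  # continues the live track
        } else {
          tr[3L - live, j + 1L] <- 1L             # resumes the other track
          flags[j] <- TRUE
        }
      }
    }
    j <- j + 1L
  }
  list(tracks = tr, flags = flags)
}

# exhaustive 2^(k-1) chaining oracle over amplicons that all have 2 clusters
brute_force_phase <- function(instance) {
  k <- length(instance)
  stopifnot(k <= 6L, all(vapply(instance, length, integer(1)) == 2L))
  junction_score <- function(j, rel_flip) {
    up <- lapply(instance[[j]], `[[`, "right")
    down <- lapply(instance[[j + 1L]], `[[`, "left")
    if (rel_flip) down <- down[c(2L, 1L)]
    ev <- junction_evidence(up, down)
    ev$parallel
  }
  if (k == 1L) return(list(tracks = matrix(c(1L, 2L), 2L, 1L), score = 0))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k - 1L))
  best <- NULL; best_score <- -Inf
  for (i in seq_len(nrow(combos))) {
    flips_rel <- as.logical(combos[i, ])
    score <- sum(vapply(seq_len(k - 1L), function(j)
      junction_score(j, flips_rel[j]), numeric(1)))
    if (score > best_score) { best_score <- score; best <- flips_rel }
  }
  # absolute orientation: cumulative XOR of relative flips
  tr <- matrix(NA_integer_, 2L, k)
  flip_abs <- cumsum(c(FALSE, best)) %% 2L == 1L
  for (j in seq_len(k)) tr[, j] <- if (flip_abs[j]) c(2L, 1L) else c(1L, 2L)
  list(tracks = tr, score = best_score, rel_flips = best)
}

# --- public phasing over consensus clusters ---------------------------------

#' Phase per-amplicon allele clusters into two full-length haplotypes
#'
#' At each junction the pairing of upstream and downstream clusters is chosen
#' by agreement of shared heterozygous variants within the amplicon overlap;
#' junctions with no informative site receive the default pairing plus an
#' ambiguity flag. A single cluster facing a cluster pair is matched by the
#' same evidence, which distinguishes a homozygous amplicon (shared by both
#' haplotypes) from a one-allele amplification failure and records the
#' missing allele as a DROPOUT. The merged haplotype keeps the upstream copy
#' of every overlap.
#'
#' @param amp_clusters list (one entry per panel amplicon, in order) of lists
#'   of `allele_consensus` objects (0, 1 or 2 clusters per amplicon).
#' @param locus the locus model (panel and overlap geometry).
#' @param sample_id label stored on the result.
#' @return object of class `phased_haplotypes`: list with `h1`, `h2` (each
#'   with `provenance`, `segments`, `sequence`), `junctions` (evidence and
#'   ambiguity flags) and `sample_id`.
#' @export
phase_amplicons <- function(amp_clusters, locus, sample_id = "sample") {
  panel <- locus$panel
  k <- nrow(panel)
  stopifnot(length(amp_clusters) == k)
  ovl <- locus$overlaps
  inst <- lapply(seq_len(k), function(i) {
    lapply(amp_clusters[[i]], function(cons) {
      left <- if (i > 1L)
        overlap_alleles(cons, ovl$start[i - 1L], ovl$end[i - 1L]) else NULL
      right <- if (i < k)
        overlap_alleles(cons, ovl$start[i], ovl$end[i]) else NULL
      list(left = left, right = right)
    })
  })
  core <- phase_core(inst)
  haps <- lapply(1:2, function(t) {
    idx <- core$tracks[t, ]
    provenance <- ifelse(is.na(idx), "DROPOUT",
                         paste0(panel$name, ".c", idx))
    names(provenance) <- panel$name
    segments <- list()
    run_start <- NULL
    for (i in seq_len(k)) {
      if (is.na(idx[i])) { run_start <- NULL; next }
      cons <- amp_clusters[[i]][[idx[i]]]
      from <- if (!is.null(run_start)) segments[[length(segments)]]$end + 1L
              else panel$start[i]
      segments[[length(segments) + 1L]] <-
        consensus_slice(cons, max(from, cons$start), cons$end)
      run_start <- run_start %||% i
    }
    sequence <- paste(vapply(segments, consensus_sequence, character(1)),
                      collapse = "")
    list(provenance = provenance, segments = segments, sequence = sequence)
  })
  structure(list(sample_id = sample_id, h1 = haps[[1]], h2 = haps[[2]],
                 junction_flags = core$flags, tracks = core$tracks),
            class = "phased_haplotypes")
}

#' Detect the amplicon-dropout signature of a structural variant
#'
#' A haplotype whose provenance shows DROPOUT for a contiguous run of
#' amplicons while the other haplotype amplified all of them is flagged as an
#' SV candidate with that amplicon list. If both haplotypes drop the same
#' amplicon the assay failed for that amplicon (no SV call).
#'
#' @param phased a `phased_haplotypes` object.
#' @return list with `flag` (`"sv_candidate"`, `"assay_failure"` or
#'   `"none"`), `hap` (`"H1"`/`"H2"` or `NA`) and `amplicons` (names).
#' @export
detect_dropout_pattern <- function(phased) {
  d1 <- phased$h1$provenance == "DROPOUT"
  d2 <- phased$h2$provenance == "DROPOUT"
  amps <- names(phased$h1$provenance)
  if (any(d1 & d2))
    return(list(flag = "assay_failure", hap = NA_character_,
                amplicons = amps[d1 & d2]))
  for (t in 1:2) {
    dt_ <- if (t == 1L) d1 else d2
    other <- if (t == 1L) d2 else d1
    if (any(dt_) && !any(other)) {
      runs <- rle(dt_)
      if (sum(runs$values) == 1L)        # one contiguous run
        return(list(flag = "sv_candidate", hap = paste0("H", t),
                    amplicons = amps[dt_]))
    }
  }
  list(flag = "none", hap = NA_character_, amplicons = character(0))
}
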