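# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a child seed from a base seed and a stream index; keeps values < 2^31.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(stream)) %% 2147483629 + 1
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Substitute each base for a uniformly chosen different base (vectorized).
other_base <- function(bases) {
  idx <- match(bases, DNA_BASES)
  DNA_BASES[((idx - 1L + sample.int(3L, length(bases), replace = TRUE)) %% 4L) + 1L]
}

ap_verbose <- function() isTRUE(getOption("ampliphase.verbose", FALSE))

# Structured one-line-per-stage log record; silent unless
# options(ampliphase.verbose = TRUE).
ap_log <- function(stage, ...) {
  if (!ap_verbose()) return(invisible(NULL))
  kv <- list(...)
  msg <- paste0(names(kv), "=", vapply(kv, function(x) paste(x, collapse = ","),
                                       character(1)), collapse = " ")
  message(sprintf("[ampliphase] %s %s", stage, msg))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
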