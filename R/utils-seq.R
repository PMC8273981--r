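# Byte-level sequence helpers. Sequences live as plain character strings at
# the API surface and as raw vectors (one byte per base) internally, which
# keeps whole-chromosome edits cheap.

.BASE_RAW <- charToRaw("ACGT")

.BASE_LUT <- local({
  lut <- rep(NA_integer_, 256L)
  lut[as.integer(charToRaw("ACGT")) + 1L] <- 0:3
  lut[as.integer(charToRaw("acgt")) + 1L] <- 0:3
  lut
})

.COMP_LUT <- local({
  lut <- as.raw(rep(utf8ToInt("N"), 256L))
  lut[as.integer(charToRaw("ACGTN")) + 1L] <- charToRaw("TGCAN")
  lut
})

.random_seq_raw <- function(n) .BASE_RAW[sample.int(4L, n, replace = TRUE)]

#' Generate a random DNA sequence
#'
#' Uniform i.i.d. bases over A/C/G/T. Used by the synthetic-genome generator
#' for chromosome backbones and satellite monomers.
#'
#' @param n Sequence length in bp.
#' @param seed Optional integer seed applied before sampling.
#' @return A single character string of length `n`.
#' @export
random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 1)
  rawToChar(.random_seq_raw(n))
}

#' Reverse complement of a DNA string
#'
#' @param x A character string over A/C/G/T/N (case-insensitive input is
#'   uppercased).
#' @return The reverse complement as an upper-case string.
#' @export
revcomp <- function(x) {
  r <- charToRaw(toupper(x))
  rawToChar(rev(.COMP_LUT[as.integer(r) + 1L]))
}

# Substitute bases at `pos` (1-based) in raw vector `r`, always to a
# different base. Returns the mutated raw vector.
.substitute_at <- function(r, pos) {
  if (length(pos) == 0L) return(r)
  old <- .BASE_LUT[as.integer(r[pos]) + 1L]
  new <- (old + sample.int(3L, length(pos), replace = TRUE)) %% 4L
  r[pos] <- .BASE_RAW[new + 1L]
  r
}

# Per-base i.i.d. substitution at `rate`; returns list(seq = raw, pos = 1-based
# substituted positions).
.mutate_raw <- function(r, rate) {
  n <- length(r)
  k <- stats::rbinom(1L, n, rate)
  pos <- if (k > 0L) sort(sample.int(n, k)) else integer(0)
  list(seq = .substitute_at(r, pos), pos = pos)
}

#' Build a tandem satellite array from a monomer
#'
#' Concatenates `copies` copies of `monomer` and applies independent per-base
#' substitutions at `mutation_rate`, emulating monomer turnover within an
#' array.
#'
#' @param monomer Monomer sequence (character string).
#' @param copies Number of tandem copies.
#' @param mutation_rate Per-base substitution probability applied across the
#'   whole array (default 0).
#' @param seed Optional integer seed.
#' @return The array as a character string.
#' @export
tandem_array_seq <- function(monomer, copies, mutation_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(copies >= 1, mutation_rate >= 0, mutation_rate <= 1)
  r <- charToRaw(strrep(toupper(monomer), copies))
  if (mutation_rate > 0) r <- .mutate_raw(r, mutation_rate)$seq
  rawToChar(r)
}

# Telomeric terminus: (TTAGGG)n on the forward strand at the right end and its
# reverse complement at the left end of a chromosome.
.telomere_motif <- function(copies, left = FALSE) {
  m <- strrep("TTAGGG", copies)
  if (left) revcomp(m) else m
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
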