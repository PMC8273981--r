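# Long-read simulation for the k-mer profiling module: uniform sampling from
# the haploid (X) assembly with i.i.d. substitution errors, emulating HiFi
# circular-consensus reads (no quality strings, no indels).

#' Simulate long reads with substitution errors
#'
#' Reads are drawn uniformly over valid start positions across the genome
#' (forward strand; canonical k-mer counting is strand-symmetric) so that the
#' total read bases approximate `coverage` times the genome size.
#'
#' @param x A `genome_bundle` with sequences, or a character vector of
#'   sequences (named or not).
#' @param coverage Target fold coverage.
#' @param read_len Read length in bp.
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @return Character vector of reads with attribute `source` (data.frame
#'   chrom, start of each read, 1-based).
#' @export
gen_kmer_reads <- function(x, coverage, read_len, error_rate = 0, seed = 1L) {
  seqs <- if (inherits(x, "genome_bundle")) {
    if (is.null(x$sequences)) stop("bundle has no sequences (track_only mode)", call. = FALSE)
    vapply(x$sequences, function(s) s[["X"]], character(1))
  } else as.character(x)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  lens <- nchar(seqs)
  if (read_len > min(lens))
    stop("read_len (", read_len, ") exceeds the shortest chromosome (", min(lens), ")",
         call. = FALSE)
  stopifnot(coverage > 0, error_rate >= 0, error_rate < 1)
  set.seed(seed)
  G <- sum(lens)
  n_reads <- ceiling(coverage * G / read_len)
  nvalid <- lens - read_len + 1
  ci <- sample.int(length(seqs), n_reads, replace = TRUE, prob = nvalid)
  starts <- floor(stats::runif(n_reads) * nvalid[ci]) + 1
  reads <- unname(substring(seqs[ci], starts, starts + read_len - 1))
  if (error_rate > 0) {
    big <- charToRaw(paste0(reads, collapse = ""))
    n_err <- stats::rbinom(1L, length(big), error_rate)
    if (n_err > 0) {
      idx <- sample.int(length(big), n_err)
      big <- .substitute_at(big, idx)
      allstr <- rawToChar(big)
      ends <- seq_len(n_reads) * read_len
      reads <- substring(allstr, ends - read_len + 1, ends)
    }
  }
  attr(reads, "source") <- data.frame(chrom = names(seqs)[ci], start = starts)
  reads
}
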