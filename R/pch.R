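# Pericentromeric heterochromatin (PCH): windowed repeat content, block
# calling, H3K9me3 peak enrichment and the PCH-size vs chromosome-size
# correlation.

#' Windowed repeat content
#'
#' Per window, the fraction of bases covered by at least one repeat interval
#' (overlapping annotations are collapsed first).
#'
#' @param repeats data.frame with chrom, start, end (0-based half-open), e.g.
#'   a bundle's `repeat_track` or an imported BED.
#' @param chrom_meta data.frame with chrom and length.
#' @param window Window size in bp (default 50 kb).
#' @return Window track data.frame with `value` = covered fraction.
#' @export
repeat_content_track <- function(repeats, chrom_meta, window = 5e4) {
  win <- tile_windows(chrom_meta, window)
  win$value <- 0
  for (i in seq_len(nrow(chrom_meta))) {
    chrom <- chrom_meta$chrom[i]
    L <- chrom_meta$length[i]
    wi <- which(win$chrom == chrom)
    rp <- repeats[repeats$chrom == chrom, , drop = FALSE]
    if (nrow(rp) == 0L) next
    if (any(rp$start < 0 | rp$end > L))
      stop("repeat interval outside chromosome ", chrom, call. = FALSE)
    ir <- IRanges::reduce(IRanges::IRanges(rp$start + 1, rp$end))
    cov <- IRanges::coverage(ir, width = L)
    v <- IRanges::Views(cov, win$start[wi] + 1, win$end[wi])
    win$value[wi] <- IRanges::viewSums(v) / (win$end[wi] - win$start[wi])
  }
  win
}

#' Call PCH blocks from a repeat-content track
#'
#' Windows with repeat content above `threshold` are merged across gaps of at
#' most `max_gap_windows` windows into blocks; each block is annotated with
#' centromere containment when centromere intervals are supplied.
#'
#' @param track Window track from [repeat_content_track()].
#' @param centromeres Optional data.frame with chrom, cen_start, cen_end.
#' @param threshold Repeat-content threshold, strict (default 0.40, the
#'   per-window highlighting rule).
#' @param max_gap_windows Bridgeable gap in windows (default 5).
#' @return data.frame (class `pch_blocks`) chrom, start, end,
#'   mean_repeat_frac, contains_centromere; attribute `summary` reports total
#'   PCH bp, genome fraction and per-chromosome proportions.
#' @export
call_pch <- function(track, centromeres = NULL, threshold = 0.40,
                     max_gap_windows = 5L) {
  blocks <- list()
  for (chrom in unique(track$chrom)) {
    tw <- track[track$chrom == chrom, , drop = FALSE]
    runs <- .merge_marked_runs(!is.na(tw$value) & tw$value > threshold,
                               max_gap_windows)
    if (nrow(runs) == 0L) next
    for (j in seq_len(nrow(runs))) {
      sel <- runs$first[j]:runs$last[j]
      blocks[[length(blocks) + 1L]] <- data.frame(
        chrom = chrom, start = tw$start[runs$first[j]], end = tw$end[runs$last[j]],
        mean_repeat_frac = stats::weighted.mean(tw$value[sel],
                                                tw$end[sel] - tw$start[sel]))
    }
  }
  res <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               mean_repeat_frac = numeric(0))
  res$contains_centromere <- logical(nrow(res))
  if (!is.null(centromeres) && nrow(res)) {
    for (i in seq_len(nrow(res))) {
      cc <- centromeres[centromeres$chrom == res$chrom[i], , drop = FALSE]
      res$contains_centromere[i] <- nrow(cc) > 0 && !is.na(cc$cen_start[1]) &&
        cc$cen_start[1] < res$end[i] && cc$cen_end[1] > res$start[i]
    }
  }
  rownames(res) <- NULL
  genome_bp <- sum(tapply(track$end, track$chrom, max))
  pch_bp <- sum(res$end - res$start)
  per_chrom <- tapply(res$end - res$start, res$chrom, sum)
  attr(res, "summary") <- list(
    pch_bp = pch_bp, genome_bp = genome_bp, genome_fraction = pch_bp / genome_bp,
    per_chromosome = per_chrom)
  class(res) <- c("pch_blocks", "data.frame")
  res
}

#' H3K9me3 peak enrichment in PCH
#'
#' Peaks with a -log10 p score strictly above `score_min` are kept; the
#' report contrasts the fraction of surviving peaks whose midpoint lies in a
#' PCH block with the PCH fraction of the genome.
#'
#' @param peaks data.frame with chrom, start, end, score (-log10 p).
#' @param pch_blocks Blocks from [call_pch()] (or truth).
#' @param chrom_meta data.frame with chrom and length.
#' @param score_min Score filter, strict inequality (default 8).
#' @return List with n_peaks, peak_fraction_in_pch, genome_fraction_pch,
#'   ratio (NA with a `note` when no peak survives).
#' @export
peak_enrichment <- function(peaks, pch_blocks, chrom_meta, score_min = 8) {
  keep <- peaks[peaks$score > score_min, , drop = FALSE]
  genome_bp <- sum(chrom_meta$length)
  gfrac <- sum(pch_blocks$end - pch_blocks$start) / genome_bp
  if (nrow(keep) == 0L)
    return(list(n_peaks = 0L, peak_fraction_in_pch = NA_real_,
                genome_fraction_pch = gfrac, ratio = NA_real_,
                note = "no peak passes the score filter"))
  mid <- (keep$start + keep$end) / 2
  inp <- vapply(seq_len(nrow(keep)), function(i) {
    b <- pch_blocks[pch_blocks$chrom == keep$chrom[i], , drop = FALSE]
    nrow(b) > 0 && any(mid[i] >= b$start & mid[i] < b$end)
  }, logical(1))
  pfrac <- mean(inp)
  list(n_peaks = nrow(keep), peak_fraction_in_pch = pfrac,
       genome_fraction_pch = gfrac, ratio = pfrac / gfrac, note = NULL)
}

#' Correlation between per-chromosome PCH size and chromosome size
#'
#' Pearson correlation with a two-sided t-test, over all chromosomes in
#' `chrom_meta` (chromosomes without called PCH contribute zero).
#'
#' @param pch_blocks Blocks from [call_pch()].
#' @param chrom_meta data.frame with chrom and length.
#' @return List with r, p, n; r is NA (flagged in `note`) under zero
#'   variance.
#' @export
pch_size_correlation <- function(pch_blocks, chrom_meta) {
  bp <- tapply(pch_blocks$end - pch_blocks$start, pch_blocks$chrom, sum)
  x <- chrom_meta$length
  y <- as.numeric(bp[chrom_meta$chrom])
  y[is.na(y)] <- 0
  if (sum(y > 0) < 3L) stop("need PCH on at least 3 chromosomes", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(x),
                note = "zero variance"))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x), note = NULL)
}
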