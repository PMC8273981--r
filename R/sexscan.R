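# Sex-linkage scanning: sex-specific variant calling, windowed density,
# between-sex Hudson FST, exact allele-count association, SLR demarcation,
# windowed X-Y intronic similarity and evolutionary-strata segmentation.

#' Tile chromosomes into fixed-size windows
#'
#' @param chrom_meta data.frame with chrom and length.
#' @param window Window size in bp; the ragged last window is kept.
#' @return data.frame chrom, start, end (0-based half-open).
#' @export
tile_windows <- function(chrom_meta, window = 5e4) {
  out <- lapply(seq_len(nrow(chrom_meta)), function(i) {
    L <- chrom_meta$length[i]
    st <- seq(0, L - 1, by = window)
    data.frame(chrom = chrom_meta$chrom[i], start = st, end = pmin(st + window, L))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call sex-specific SNPs
#'
#' A site is male-specific when every non-missing male is heterozygous and
#' every non-missing female is homozygous (all for the same allele); the
#' `"female"` mode is symmetric. Sites with more than `max_missing`
#' missingness, or with either sex entirely missing, are excluded.
#'
#' @param vt A `variant_table`.
#' @param specific_to `"male"` (default) or `"female"`.
#' @param max_missing Maximum tolerated fraction of missing genotypes per
#'   site (default 0.2).
#' @return The subset of `vt$sites` that passes, with attribute `idx` giving
#'   the row indices into `vt$sites`.
#' @export
call_sex_specific_snps <- function(vt, specific_to = c("male", "female"),
                                   max_missing = 0.2) {
  specific_to <- match.arg(specific_to)
  if (!all(c("male", "female") %in% vt$sex))
    stop("need at least one sample of each sex", call. = FALSE)
  het_sex <- specific_to
  hom_sex <- setdiff(c("male", "female"), specific_to)
  gh <- vt$geno[, vt$sex == het_sex, drop = FALSE]
  gm <- vt$geno[, vt$sex == hom_sex, drop = FALSE]
  miss <- rowMeans(is.na(vt$geno))
  n_h <- rowSums(!is.na(gh))
  n_m <- rowSums(!is.na(gm))
  all_het <- rowSums(gh == 1L, na.rm = TRUE) == n_h & n_h > 0L
  hom <- gm == 0L | gm == 2L
  all_hom <- rowSums(hom, na.rm = TRUE) == n_m & n_m > 0L
  gmin <- do.call(pmin, c(lapply(seq_len(ncol(gm)), function(j) gm[, j]), na.rm = TRUE))
  gmax <- do.call(pmax, c(lapply(seq_len(ncol(gm)), function(j) gm[, j]), na.rm = TRUE))
  same <- !is.na(gmin) & !is.na(gmax) & gmin == gmax
  keep <- as.integer(which(miss <= max_missing & all_het & all_hom & same))
  out <- vt$sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "idx") <- keep
  out
}

#' Windowed site counts
#'
#' @param sites data.frame with chrom and pos (1-based), e.g. from
#'   [call_sex_specific_snps()].
#' @param chrom_meta data.frame with chrom and length.
#' @param window Window size in bp (default 50 kb).
#' @return A window track data.frame: chrom, start, end, value (count),
#'   n_variants.
#' @export
window_counts <- function(sites, chrom_meta, window = 5e4) {
  win <- tile_windows(chrom_meta, window)
  win$value <- 0
  for (chrom in unique(win$chrom)) {
    wi <- which(win$chrom == chrom)
    pos <- sites$pos[sites$chrom == chrom]
    if (length(pos) == 0L) next
    bin <- findInterval(pos - 1L, win$start[wi])
    tb <- tabulate(bin, length(wi))
    win$value[wi] <- tb
  }
  win$n_variants <- win$value
  win
}

#' Windowed Hudson-type FST between the sexes
#'
#' Per site, within-sex expected heterozygosities are sample-size-corrected
#' (`2pq * 2n/(2n-1)`) and averaged over the two sexes; the between-sex
#' heterozygosity is `p_m(1-p_f) + p_f(1-p_m)`. Each window reports a
#' ratio-of-averages `FST = 1 - mean(H_within)/mean(H_between)`. Windows with
#' fewer than `min_variants` informative sites, and monomorphic windows, are
#' missing.
#'
#' @param vt A `variant_table`.
#' @param chrom_meta data.frame with chrom and length.
#' @param window Window size (default 50 kb).
#' @param min_variants Minimum variants per window (default 40).
#' @return Window track data.frame with `value` = FST and `n_variants`.
#' @export
window_fst <- function(vt, chrom_meta, window = 5e4, min_variants = 40L) {
  if (!all(c("male", "female") %in% vt$sex))
    stop("need both sexes", call. = FALSE)
  gM <- vt$geno[, vt$sex == "male", drop = FALSE]
  gF <- vt$geno[, vt$sex == "female", drop = FALSE]
  nM <- 2 * rowSums(!is.na(gM)); nF <- 2 * rowSums(!is.na(gF))
  pM <- rowSums(gM, na.rm = TRUE) / nM
  pF <- rowSums(gF, na.rm = TRUE) / nF
  ok <- nM >= 2 & nF >= 2
  hwM <- 2 * pM * (1 - pM) * nM / (nM - 1)
  hwF <- 2 * pF * (1 - pF) * nF / (nF - 1)
  hw <- (hwM + hwF) / 2
  hb <- pM * (1 - pF) + pF * (1 - pM)
  win <- tile_windows(chrom_meta, window)
  win$value <- NA_real_
  win$n_variants <- 0L
  for (chrom in unique(win$chrom)) {
    wi <- which(win$chrom == chrom)
    si <- which(vt$sites$chrom == chrom & ok)
    if (length(si) == 0L) next
    bin <- findInterval(vt$sites$pos[si] - 1L, win$start[wi])
    win$n_variants[wi] <- tabulate(bin, length(wi))
    shw <- tapply(hw[si], bin, sum)
    shb <- tapply(hb[si], bin, sum)
    b <- as.integer(names(shw))
    val <- 1 - shw / shb
    val[shb == 0] <- NA_real_
    win$value[wi[b]] <- val
  }
  win$value[win$n_variants < min_variants] <- NA_real_
  win
}

# Two-sided exact hypergeometric p for one 2x2 allele table
# (altM, refM | altF, refF): sum of all table probabilities not exceeding the
# observed one, at fixed margins.
.exact_assoc_p <- function(altM, refM, altF, refF) {
  K <- altM + altF            # total alt alleles
  nM <- altM + refM           # male alleles
  tot <- nM + altF + refF
  if (K == 0 || K == tot) return(1)
  supp <- max(0, K - (tot - nM)):min(nM, K)
  pr <- stats::dhyper(supp, K, tot - K, nM)
  p0 <- stats::dhyper(altM, K, tot - K, nM)
  min(1, sum(pr[pr <= p0 * (1 + 1e-7)]))
}

#' Exact per-site association scan for sex
#'
#' For every site the 2x2 allele-count table (alt/ref by male/female) is
#' tested with a two-sided exact hypergeometric test; the scan replaces
#' mixed-model machinery, which adds nothing when population structure is
#' absent and the signal is full penetrance.
#'
#' @param vt A `variant_table`.
#' @return `vt$sites` with columns `p` and `neglog10p` appended.
#' @export
assoc_scan <- function(vt) {
  if (!all(c("male", "female") %in% vt$sex))
    stop("need both sexes", call. = FALSE)
  gM <- vt$geno[, vt$sex == "male", drop = FALSE]
  gF <- vt$geno[, vt$sex == "female", drop = FALSE]
  altM <- rowSums(gM, na.rm = TRUE); refM <- 2 * rowSums(!is.na(gM)) - altM
  altF <- rowSums(gF, na.rm = TRUE); refF <- 2 * rowSums(!is.na(gF)) - altF
  p <- vapply(seq_len(nrow(vt$sites)), function(i)
    .exact_assoc_p(altM[i], refM[i], altF[i], refF[i]), numeric(1))
  out <- vt$sites
  out$p <- p
  out$neglog10p <- -log10(p)
  out
}

# Merge marked windows into runs bridging gaps of at most max_gap unmarked
# windows; returns a data.frame of blocks (window-index ranges).
.merge_marked_runs <- function(marked, max_gap) {
  idx <- which(marked)
  if (length(idx) == 0L) return(data.frame(first = integer(0), last = integer(0)))
  brk <- c(TRUE, diff(idx) > max_gap + 1L)
  grp <- cumsum(brk)
  data.frame(first = tapply(idx, grp, min), last = tapply(idx, grp, max))
}

#' Demarcate the sex-linked region from a density track
#'
#' Windows with at least `min_count` sex-specific SNPs are marked; marked
#' runs are merged across gaps of at most `max_gap_windows` windows, and the
#' longest merged run (in bp) becomes the SLR. The chromosome complement of
#' the SLR is reported as pseudoautosomal.
#'
#' @param track A window track from [window_counts()].
#' @param min_count Minimum SNPs per window to mark it (default 3).
#' @param max_gap_windows Bridgeable gap in windows (default 5).
#' @return An `slr_call`: list with chrom, start, end, `pars` (data.frame of
#'   pseudoautosomal intervals) and `n_marked`; `chrom` is `NA` when no
#'   window passes.
#' @export
demarcate_slr <- function(track, min_count = 3L, max_gap_windows = 5L) {
  best <- NULL
  for (chrom in unique(track$chrom)) {
    tw <- track[track$chrom == chrom, , drop = FALSE]
    runs <- .merge_marked_runs(tw$value >= min_count, max_gap_windows)
    if (nrow(runs) == 0L) next
    runs$start <- tw$start[runs$first]
    runs$end <- tw$end[runs$last]
    runs$len <- runs$end - runs$start
    top <- runs[which.max(runs$len), ]
    if (is.null(best) || top$len > best$len) {
      best <- top; best$chrom <- chrom
      best$chrom_len <- max(tw$end)
      best$n_marked <- sum(tw$value >= min_count)
    }
  }
  if (is.null(best))
    return(structure(list(chrom = NA_character_, start = NA_real_, end = NA_real_,
                          pars = NULL, n_marked = 0L), class = "slr_call"))
  pars <- data.frame(chrom = best$chrom,
                     start = c(0, best$end), end = c(best$start, best$chrom_len))
  pars <- pars[pars$end > pars$start, , drop = FALSE]
  structure(list(chrom = best$chrom, start = best$start, end = best$end,
                 pars = pars, n_marked = best$n_marked), class = "slr_call")
}

#' @export
print.slr_call <- function(x, ...) {
  if (is.na(x$chrom)) cat("slr_call: empty (no window passed)\n")
  else cat(sprintf("slr_call: %s %.2f-%.2f Mb (%.2f Mb, %d marked windows)\n",
                   x$chrom, x$start / 1e6, x$end / 1e6, (x$end - x$start) / 1e6,
                   x$n_marked))
  invisible(x)
}

#' Windowed X-Y sequence similarity over introns
#'
#' Haplotypes must be coordinate-matched (collinear, no indel handling).
#' Similarity per window is one minus the mismatch fraction among compared
#' positions, where comparison is restricted to intron intervals (divergence
#' in coding sequence is shaped by selection, and intergenic repeats
#' complicate alignment in real data). Windows with fewer than `min_bases`
#' compared bases are missing (gene deserts).
#'
#' @param x_seq,y_seq The two haplotype sequences (equal-length strings).
#' @param introns data.frame of intron intervals (start, end; 0-based
#'   half-open) or `NULL` to compare every position.
#' @param window Window size in bp (default 100 kb).
#' @param min_bases Minimum compared bases per window (default 1 kb).
#' @param chrom Chromosome name for the output track.
#' @return Window track data.frame with `value` = similarity and `n_compared`.
#' @export
xy_window_similarity <- function(x_seq, y_seq, introns = NULL, window = 1e5,
                                 min_bases = 1000, chrom = "chr") {
  xr <- charToRaw(x_seq); yr <- charToRaw(y_seq)
  if (length(xr) != length(yr))
    stop("haplotype lengths differ (", length(xr), " vs ", length(yr),
         "); indels are not handled", call. = FALSE)
  L <- length(xr)
  mask <- if (is.null(introns)) rep(TRUE, L) else {
    m <- logical(L)
    for (i in seq_len(nrow(introns))) {
      s <- max(0, introns$start[i]); e <- min(L, introns$end[i])
      if (e > s) m[(s + 1):e] <- TRUE
    }
    m
  }
  mm <- (xr != yr) & mask
  cmm <- c(0, cumsum(mm)); cmk <- c(0, cumsum(mask))
  st <- seq(0, L - 1, by = window)
  en <- pmin(st + window, L)
  n_cmp <- cmk[en + 1] - cmk[st + 1]
  n_mm <- cmm[en + 1] - cmm[st + 1]
  val <- ifelse(n_cmp >= min_bases, 1 - n_mm / n_cmp, NA_real_)
  data.frame(chrom = chrom, start = st, end = en, value = val, n_compared = n_cmp)
}

#' Segment the SLR into evolutionary strata
#'
#' Exhaustive single-changepoint search over the SLR's similarity windows,
#' minimizing the pooled within-segment sum of squared deviations of
#' divergence (1 - similarity); both segments must span at least two windows.
#' The segments are compared with a two-sided Wilcoxon rank-sum test (exact
#' for small samples without ties, normal approximation with tie correction
#' otherwise, as implemented in [stats::wilcox.test()]). Because the
#' changepoint is chosen to maximize the contrast, the raw Wilcoxon p is
#' anti-conservative under a constant-divergence null; a permutation
#' calibration therefore re-runs the search on `n_perm` permutations of the
#' window values and reports `selection_p`, the fraction of permutations
#' whose optimized Wilcoxon p is at least as small. Two strata are reported
#' only when both the raw Wilcoxon p and `selection_p` fall below `alpha`.
#'
#' @param similarity Window track from [xy_window_similarity()].
#' @param slr_interval `(start, end)` of the SLR in bp.
#' @param alpha Significance level for the two-strata call (default 0.05).
#' @param min_windows Minimum non-missing windows required (default 6).
#' @param n_perm Permutations for the selection calibration (default 500).
#' @return An `slr_strata`: list with `strata` (data.frame name, start, end,
#'   mean_divergence, n_windows), `two_strata`, `wilcoxon_p`, `selection_p`,
#'   `boundary`.
#' @export
segment_strata <- function(similarity, slr_interval, alpha = 0.05,
                           min_windows = 6L, n_perm = 500L) {
  midp <- (similarity$start + similarity$end) / 2
  w <- similarity[midp >= slr_interval[1] & midp < slr_interval[2] &
                  !is.na(similarity$value), , drop = FALSE]
  d <- 1 - w$value
  n <- length(d)
  one <- function(p, psel = NA_real_) structure(list(
    strata = data.frame(name = "R1", start = slr_interval[1], end = slr_interval[2],
                        mean_divergence = mean(d), n_windows = n),
    two_strata = FALSE, wilcoxon_p = p, selection_p = psel,
    boundary = NA_real_), class = "slr_strata")
  if (n < min_windows) return(one(NA_real_))
  best_split <- function(x) {
    s1 <- cumsum(x); s2 <- cumsum(x^2)
    sse <- function(a, b) {
      su <- s1[b] - if (a > 1) s1[a - 1] else 0
      sq <- s2[b] - if (a > 1) s2[a - 1] else 0
      sq - su^2 / (b - a + 1)
    }
    cand <- 2:(length(x) - 2)
    tot <- vapply(cand, function(c) sse(1, c) + sse(c + 1, length(x)), numeric(1))
    cand[which.min(tot)]
  }
  wp <- function(x, c) suppressWarnings(
    stats::wilcox.test(x[1:c], x[(c + 1):length(x)])$p.value)
  cp <- best_split(d)
  pw <- wp(d, cp)
  # calibration of the changepoint selection under the constant null
  psel <- .with_seed(104729L, {
    hits <- 0L
    for (bperm in seq_len(n_perm)) {
      dp <- d[sample.int(n)]
      if (wp(dp, best_split(dp)) <= pw) hits <- hits + 1L
    }
    (hits + 1) / (n_perm + 1)
  })
  if (is.na(pw) || pw >= alpha || psel >= alpha) return(one(pw, psel))
  boundary <- w$end[cp]
  strata <- data.frame(
    name = c("R1", "R2"),
    start = c(slr_interval[1], boundary),
    end = c(boundary, slr_interval[2]),
    mean_divergence = c(mean(d[1:cp]), mean(d[(cp + 1):n])),
    n_windows = c(cp, n - cp))
  structure(list(strata = strata, two_strata = TRUE, wilcoxon_p = pw,
                 selection_p = psel, boundary = boundary),
            class = "slr_strata")
}

#' @export
print.slr_strata <- function(x, ...) {
  cat("slr_strata:", if (x$two_strata) "two strata" else "single stratum",
      sprintf("(Wilcoxon p = %.3g)\n", x$wilcoxon_p))
  for (i in seq_len(nrow(x$strata)))
    cat(sprintf("  %s %.2f-%.2f Mb: divergence %.3f%% (%d windows)\n",
                x$strata$name[i], x$strata$start[i] / 1e6, x$strata$end[i] / 1e6,
                100 * x$strata$mean_divergence[i], x$strata$n_windows[i]))
  invisible(x)
}
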