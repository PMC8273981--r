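# Epigenome emulation: H3K9me3-like scored peaks with elevated density inside
# planted PCH, and per-chromosome Hi-C contact matrices with a power-law
# distance decay, a multiplicative contact elevation within PCH and an
# alternating A/B checkerboard outside it.

#' Simulate H3K9me3 peaks and Hi-C contact matrices
#'
#' Peaks are placed by a Poisson process whose density inside planted PCH
#' blocks is `pch_peak_ratio` times the background density; every peak carries
#' a -log10 p score. Contact counts follow
#' `base_count * (|i-j|+1)^(-decay_exponent)` with a multiplicative
#' `pch_boost` when both bins lie in PCH and a two-compartment checkerboard
#' (same-compartment pairs up-weighted by `1 + compartment_strength`,
#' cross-compartment down-weighted) outside PCH, plus Poisson noise unless
#' `noise = "none"`.
#'
#' @param bundle A `genome_bundle` with PCH truth.
#' @param config Generator config (defaults to the bundle's).
#' @param bin_size Hi-C bin size in bp (default 50 kb).
#' @param peak_rate Background peak density per bp (default 1 per 50 kb).
#' @param pch_peak_ratio Peak density ratio inside vs outside PCH (default 4).
#' @param decay_exponent Power-law contact decay exponent (default 1).
#' @param pch_boost Multiplicative contact elevation within PCH (default 2).
#' @param compartment_block Compartment block size in bp; must be a multiple
#'   of the 250-kb eigenvector resolution for clean aggregation (default
#'   1.5 Mb).
#' @param compartment_strength Checkerboard contrast in (0, 1) (default 0.3).
#' @param base_count Expected count at distance 0 before modulation.
#' @param noise `"poisson"` (default) or `"none"` for the deterministic
#'   expectation.
#' @param chroms Chromosomes to build matrices for (default: all).
#' @return List with `peaks` (data.frame chrom, start, end, score),
#'   `matrices` (named list of `contact_matrix`) and `truth` (per-chromosome
#'   compartment labels and the parameters used).
#' @export
gen_epigenome <- function(bundle, config = bundle$truth$config,
                          bin_size = 5e4, peak_rate = 1 / 5e4,
                          pch_peak_ratio = 4, decay_exponent = 1,
                          pch_boost = 2, compartment_block = 1.5e6,
                          compartment_strength = 0.3, base_count = 300,
                          noise = c("poisson", "none"),
                          chroms = bundle$meta$chrom) {
  noise <- match.arg(noise)
  if (is.null(bundle$truth$pch)) stop("bundle lacks PCH truth", call. = FALSE)
  if (any(bundle$meta$length <= 0)) stop("zero-length chromosome", call. = FALSE)
  set.seed(config$seed + 23L)
  pch <- bundle$truth$pch
  peaks_l <- list(); mats <- list(); comp_truth <- list()
  for (chrom in chroms) {
    L <- bundle$meta$length[bundle$meta$chrom == chrom]
    p <- pch[pch$chrom == chrom, , drop = FALSE]
    # peaks: piecewise-constant Poisson process
    segs <- data.frame(start = 0, end = L, rate = peak_rate)
    if (nrow(p)) {
      brk <- sort(unique(c(0, p$start, p$end, L)))
      segs <- data.frame(start = brk[-length(brk)], end = brk[-1])
      inp <- vapply(segs$start, function(s) any(s >= p$start & s < p$end), logical(1))
      segs$rate <- ifelse(inp, peak_rate * pch_peak_ratio, peak_rate)
    }
    pk <- lapply(seq_len(nrow(segs)), function(j) {
      np <- stats::rpois(1L, segs$rate[j] * (segs$end[j] - segs$start[j]))
      if (np == 0L) return(NULL)
      st <- sort(round(stats::runif(np, segs$start[j], segs$end[j])))
      w <- sample(500:2000, np, replace = TRUE)
      data.frame(chrom = chrom, start = st, end = pmin(st + w, L),
                 score = round(2 + stats::rexp(np, 1 / 6), 3))
    })
    peaks_l[[chrom]] <- do.call(rbind, pk)

    # contact matrix
    nb <- ceiling(L / bin_size)
    mid <- (seq_len(nb) - 0.5) * bin_size
    in_pch <- vapply(mid, function(m) nrow(p) > 0 && any(m >= p$start & m < p$end),
                     logical(1))
    comp <- ifelse((floor(mid / compartment_block)) %% 2 == 0, "A", "B")
    comp[in_pch] <- "B"  # PCH is inactive chromatin
    d <- abs(outer(seq_len(nb), seq_len(nb), "-"))
    E <- base_count * (d + 1)^(-decay_exponent)
    both_pch <- outer(in_pch, in_pch, "&")
    neither <- outer(!in_pch, !in_pch, "&")
    same <- outer(comp, comp, "==")
    mod <- matrix(1, nb, nb)
    mod[both_pch] <- pch_boost
    mod[neither & same] <- mod[neither & same] * (1 + compartment_strength)
    mod[neither & !same] <- mod[neither & !same] * (1 - compartment_strength)
    E <- E * mod
    if (noise == "poisson") {
      up <- upper.tri(E, diag = TRUE)
      cnt <- matrix(0, nb, nb)
      cnt[up] <- stats::rpois(sum(up), E[up])
      cnt <- cnt + t(cnt) - diag(diag(cnt))
    } else cnt <- E
    mats[[chrom]] <- contact_matrix(chrom, bin_size, cnt)
    comp_truth[[chrom]] <- data.frame(chrom = chrom,
                                      start = (seq_len(nb) - 1) * bin_size,
                                      end = pmin(seq_len(nb) * bin_size, L),
                                      compartment = comp, in_pch = in_pch)
  }
  peaks <- do.call(rbind, peaks_l)
  rownames(peaks) <- NULL
  list(peaks = peaks, matrices = mats,
       truth = list(compartments = do.call(rbind, comp_truth),
                    pch_peak_ratio = pch_peak_ratio, pch_boost = pch_boost,
                    decay_exponent = decay_exponent, base_count = base_count))
}
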