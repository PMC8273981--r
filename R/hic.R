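# Hi-C contact matrix analysis: symmetric iterative proportional balancing,
# observed/expected Pearson PC1 compartments at 250-kb resolution, and the
# distance-stratified PCH vs non-PCH contact comparison.

#' Construct a contact matrix
#'
#' @param chrom Chromosome name.
#' @param bin_size Bin size in bp.
#' @param counts Symmetric non-negative numeric matrix of binned
#'   intra-chromosomal contact counts.
#' @return A `contact_matrix` (list with chrom, bin_size, counts).
#' @export
contact_matrix <- function(chrom, bin_size, counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("counts must be square", call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative", call. = FALSE)
  if (max(abs(counts - t(counts))) > 1e-8 * max(1, max(counts)))
    stop("counts must be symmetric", call. = FALSE)
  structure(list(chrom = chrom, bin_size = bin_size, counts = counts),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("contact_matrix:", x$chrom, "|", nrow(x$counts), "bins of",
      x$bin_size, "bp\n")
  invisible(x)
}

#' Balance a contact matrix by symmetric iterative proportional scaling
#'
#' Rows/columns with zero sum are masked; the remaining submatrix is scaled
#' as `D A D` with `d_i = sqrt(target/rowsum_i)` until every unmasked row sum
#' is within `tol` (relative) of the common mean. For positive matrices this
#' shares its fixed point with Knight-Ruiz balancing.
#'
#' @param cm A `contact_matrix`.
#' @param tol Relative row-sum tolerance (default 1e-6).
#' @param max_iter Iteration cap (default 1000); non-convergence raises a
#'   warning and flags the result.
#' @return The balanced `contact_matrix`, with attributes `masked` (logical
#'   per bin) and `converged`.
#' @export
balance_matrix <- function(cm, tol = 1e-6, max_iter = 1000L) {
  A <- cm$counts
  masked <- rowSums(A) == 0
  act <- which(!masked)
  if (length(act) == 0L) stop("all bins empty", call. = FALSE)
  B <- A[act, act, drop = FALSE]
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    r <- rowSums(B)
    tgt <- mean(r)
    if (max(abs(r / tgt - 1)) <= tol) { converged <- TRUE; break }
    s <- sqrt(tgt / r)
    B <- B * outer(s, s)
  }
  if (!converged)
    warning("balancing did not converge in ", max_iter, " iterations")
  out <- matrix(0, nrow(A), ncol(A))
  out[act, act] <- B
  res <- contact_matrix(cm$chrom, cm$bin_size, out)
  attr(res, "masked") <- masked
  attr(res, "converged") <- converged
  res
}

# Aggregate a contact matrix to a coarser bin size (integer factor).
.aggregate_cm <- function(cm, bin_size_out) {
  f <- bin_size_out / cm$bin_size
  if (abs(f - round(f)) > 1e-9 || f < 1)
    stop("output bin size must be an integer multiple of the matrix bin size",
         call. = FALSE)
  f <- as.integer(round(f))
  if (f == 1L) return(cm)
  n <- nrow(cm$counts)
  grp <- (seq_len(n) - 1L) %/% f
  M <- rowsum(cm$counts, grp)
  M <- t(rowsum(t(M), grp))
  contact_matrix(cm$chrom, bin_size_out, M)
}

# Observed/expected transform: each entry divided by the mean of its
# (unmasked) diagonal.
.oe_matrix <- function(A, active) {
  n <- nrow(A)
  d <- abs(.row(dim(A)) - .col(dim(A)))
  both <- outer(active, active, "&")
  em <- tapply(A[both], d[both], mean)
  E <- matrix(NA_real_, n, n)
  E[both] <- em[as.character(d[both])]
  E[E == 0] <- NA
  OE <- A / E
  OE[!both] <- NA
  OE
}

#' A/B compartments: first principal component of the O/E correlation matrix
#'
#' The balanced matrix is aggregated to `bin_size_out` (250 kb by default),
#' transformed to observed/expected by dividing each entry by its diagonal
#' mean, and the Pearson correlation matrix of the O/E columns is computed.
#' PC1 is the leading eigenvector of the column-centered correlation matrix,
#' obtained by power iteration (tolerance 1e-8), with its sign oriented so
#' that PC1 correlates positively with gene density: positive values are
#' active A compartments, negative values silenced B compartments.
#'
#' @param cm A balanced `contact_matrix`.
#' @param gene_density Numeric vector of gene counts per output bin, or a
#'   window track whose windows tile the chromosome at `bin_size_out`.
#' @param bin_size_out Output resolution in bp (default 250 kb).
#' @return A data.frame (class `compartment_track`): chrom, start, end, pc1,
#'   label ("A"/"B"/NA).
#' @export
oe_pearson_pc1 <- function(cm, gene_density = NULL, bin_size_out = 2.5e5) {
  cma <- .aggregate_cm(cm, bin_size_out)
  A <- cma$counts
  n <- nrow(A)
  active <- rowSums(A) > 0
  OE <- .oe_matrix(A, active)
  usable <- active
  for (i in which(active)) {
    v <- OE[active, i]
    if (all(is.na(v)) || stats::sd(v, na.rm = TRUE) == 0) usable[i] <- FALSE
  }
  idx <- which(usable)
  pc1 <- rep(NA_real_, n)
  if (length(idx) >= 3L) {
    C <- stats::cor(OE[idx, idx], use = "pairwise.complete.obs")
    C[is.na(C)] <- 0
    Cc <- scale(C, center = TRUE, scale = FALSE)
    v <- .power_pc1(Cc)
    # scale the unit eigenvector by the PC1 standard deviation so that
    # structureless matrices yield near-zero entries
    lam <- attr(v, "lambda")
    pc1[idx] <- as.numeric(v) * sqrt(max(lam, 0) / max(1, length(idx) - 1))
  }
  gd <- NULL
  if (!is.null(gene_density)) {
    gd <- if (is.data.frame(gene_density)) gene_density$value else as.numeric(gene_density)
    if (length(gd) != n)
      stop("gene_density must have one value per output bin (", n, ")", call. = FALSE)
    cc <- suppressWarnings(stats::cor(pc1, gd, use = "complete.obs"))
    if (!is.na(cc) && cc < 0) pc1 <- -pc1
  }
  st <- (seq_len(n) - 1) * bin_size_out
  data.frame(chrom = cma$chrom, start = st, end = st + bin_size_out,
             pc1 = pc1,
             label = ifelse(is.na(pc1), NA_character_,
                            ifelse(pc1 > 0, "A", "B"))) |>
    structure(class = c("compartment_track", "data.frame"))
}

# Leading right-singular direction of a column-centered matrix via power
# iteration on the covariance; deterministic ramp start avoids the (measure
# zero) orthogonal stall.
.power_pc1 <- function(Mc, tol = 1e-8, max_iter = 10000L) {
  S <- crossprod(Mc)
  m <- ncol(S)
  v <- seq_len(m) / sqrt(sum(seq_len(m)^2))
  lam <- 0
  for (it in seq_len(max_iter)) {
    w <- S %*% v
    lam <- sqrt(sum(w^2))
    if (lam == 0) return(structure(rep(0, m), lambda = 0))
    w <- as.numeric(w) / lam
    if (sum(abs(w - v * sign(sum(w * v) + 1e-300))) < tol) { v <- w; break }
    v <- w
  }
  structure(v, lambda = lam)
}

#' Distance-stratified PCH vs non-PCH contact comparison
#'
#' Bin pairs with balanced counts strictly above `min_count` are classified
#' PCH-PCH (both bin midpoints in a PCH block) or nonPCH-nonPCH (neither);
#' mixed pairs are dropped. Mean normalized contact is reported per log2
#' distance stratum and class, and a pooled two-sided Wilcoxon rank-sum test
#' compares the classes over distance strata where both are populated
#' (distance-matched pooling).
#'
#' @param cm A balanced `contact_matrix` (50-kb bins in the standard
#'   pipeline).
#' @param pch_blocks Blocks from [call_pch()] or planted truth.
#' @param min_count Count filter, strict inequality (default 10).
#' @return List with `p`, `strata` (data.frame stratum, distance_bins, class
#'   means and pair counts) and `note` (set when a class is empty and the
#'   comparison is skipped).
#' @export
distance_stratified_contacts <- function(cm, pch_blocks, min_count = 10) {
  A <- cm$counts
  n <- nrow(A)
  mid <- (seq_len(n) - 0.5) * cm$bin_size
  b <- pch_blocks[pch_blocks$chrom == cm$chrom, , drop = FALSE]
  in_pch <- vapply(mid, function(m) nrow(b) > 0 && any(m >= b$start & m < b$end),
                   logical(1))
  ut <- which(upper.tri(A), arr.ind = TRUE)
  val <- A[ut]
  keep <- val > min_count
  if (!any(keep))
    return(list(p = NA_real_, strata = NULL,
                note = "no pair passes the count filter"))
  i <- ut[keep, 1]; j <- ut[keep, 2]; val <- val[keep]
  cls <- ifelse(in_pch[i] & in_pch[j], "PCH",
                ifelse(!in_pch[i] & !in_pch[j], "nonPCH", NA))
  ok <- !is.na(cls)
  if (!any(cls[ok] == "PCH") || !any(cls[ok] == "nonPCH"))
    return(list(p = NA_real_, strata = NULL,
                note = "a class is empty; comparison skipped"))
  d <- (j - i)[ok]; val <- val[ok]; cls <- cls[ok]
  stratum <- floor(log2(d))
  tab <- stats::aggregate(val, list(stratum = stratum, class = cls),
                          function(x) c(mean = mean(x), n = length(x)))
  strata <- data.frame(stratum = tab$stratum, class = tab$class,
                       mean = tab$x[, "mean"], n = tab$x[, "n"])
  both <- intersect(strata$stratum[strata$class == "PCH"],
                    strata$stratum[strata$class == "nonPCH"])
  sel <- stratum %in% both
  p <- if (any(sel))
    suppressWarnings(stats::wilcox.test(val[sel][cls[sel] == "PCH"],
                                        val[sel][cls[sel] == "nonPCH"])$p.value)
  else NA_real_
  list(p = p, strata = strata[order(strata$stratum, strata$class), ], note = NULL)
}
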