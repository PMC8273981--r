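# Expression quantification and screening: TPM, the tau tissue-specificity
# index, the sex-determining-candidate screen on SLR genes, and the PCH vs
# non-PCH expression contrast.

#' Transcripts per million
#'
#' `TPM_g = 1e6 * (c_g / l_g) / sum_i(c_i / l_i)` per sample; columns sum to
#' one million exactly.
#'
#' @param counts Genes x samples numeric matrix of read counts.
#' @param lengths Gene (exonic) lengths in bp, recycled along rows.
#' @return TPM matrix with the same dimnames; all-zero samples stay all-zero
#'   and are listed in the `zero_samples` attribute.
#' @export
tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (any(lengths <= 0)) stop("gene lengths must be > 0", call. = FALSE)
  if (length(lengths) != nrow(counts))
    stop("need one length per gene", call. = FALSE)
  rate <- counts / lengths
  cs <- colSums(rate)
  zero <- cs == 0
  cs[zero] <- 1
  out <- sweep(rate, 2, cs, "/") * 1e6
  attr(out, "zero_samples") <- colnames(counts)[zero]
  out
}

#' Tissue-specificity index tau
#'
#' Per gene, group means `x_i` of `log2(TPM + 1)` are computed and
#' `tau = sum_i (1 - x_i / max(x)) / (n_groups - 1)`: 0 for uniform
#' expression, 1 for single-group expression. Genes with zero expression in
#' every group are missing.
#'
#' @param expr TPM matrix (genes x samples).
#' @param groups Character/factor of group labels, one per sample.
#' @return Named numeric vector of tau values in `[0, 1]` (NA for silent
#'   genes).
#' @export
tau <- function(expr, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("tau needs at least 2 groups", call. = FALSE)
  if (length(groups) != ncol(expr)) stop("one group label per sample", call. = FALSE)
  lg <- log2(expr + 1)
  gm <- t(rowsum(t(lg), groups) / as.vector(table(groups)))
  mx <- apply(gm, 1, max)
  val <- rowSums(1 - gm / mx) / (ncol(gm) - 1)
  val[mx == 0] <- NA_real_
  stats::setNames(val, rownames(expr))
}

#' Screen for sex-determining candidate expression patterns
#'
#' A gene is *expressed* in a group when its group-mean TPM exceeds
#' `expressed_min`. Two patterns are called: `testis_exclusive` (expressed in
#' testis and in no other group) and `testis_plus_early_intersex` (expressed
#' in testis and early intersex, both at least `fold` times the ovary mean,
#' and testis/early-intersex means within 2-fold of each other). Early
#' intersex is stages I1-I3 when stage labels are present, otherwise the
#' whole intersex group.
#'
#' @param expr TPM matrix (genes x samples).
#' @param samples data.frame with sample, group and optional stage columns.
#' @param slr_genes Optional character vector restricting the report to SLR
#'   genes (others get `in_slr = FALSE` and are dropped).
#' @param fold Ovary-depletion fold (default 4).
#' @param expressed_min Expressed threshold in TPM (default 1).
#' @return data.frame (class `candidate_report`): gene, pattern, the group
#'   means (testis, ovary, early_intersex, other_max), in_slr.
#' @export
screen_candidates <- function(expr, samples, slr_genes = NULL, fold = 4,
                              expressed_min = 1) {
  for (g in c("testis", "ovary", "intersex"))
    if (!g %in% samples$group)
      stop("missing required group: ", g, call. = FALSE)
  grp <- samples$group
  stage <- if ("stage" %in% names(samples)) samples$stage else rep(NA, nrow(samples))
  early <- grp == "intersex" &
    (if (all(is.na(stage[grp == "intersex"]))) TRUE else stage %in% c("I1", "I2", "I3"))
  late <- grp == "intersex" & !early
  mean_of <- function(sel) if (any(sel)) rowMeans(expr[, sel, drop = FALSE]) else
    rep(NA_real_, nrow(expr))
  m_testis <- mean_of(grp == "testis")
  m_ovary <- mean_of(grp == "ovary")
  m_early <- mean_of(early)
  other_groups <- setdiff(unique(grp), "testis")
  m_other <- do.call(cbind, lapply(other_groups, function(g) mean_of(grp == g)))
  other_max <- apply(m_other, 1, max, na.rm = TRUE)
  excl <- m_testis > expressed_min & other_max <= expressed_min
  conc <- pmax(m_testis, m_early) <= 2 * pmin(m_testis, m_early)
  tpei <- m_testis > expressed_min & m_early > expressed_min &
    m_testis >= fold * m_ovary & m_early >= fold * m_ovary & conc
  pattern <- ifelse(excl, "testis_exclusive",
                    ifelse(tpei, "testis_plus_early_intersex", "none"))
  out <- data.frame(gene = rownames(expr), pattern = pattern,
                    testis = m_testis, ovary = m_ovary,
                    early_intersex = m_early, other_max = other_max,
                    in_slr = if (is.null(slr_genes)) NA else
                      rownames(expr) %in% slr_genes)
  if (!is.null(slr_genes)) out <- out[out$in_slr, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_report", "data.frame")
  out
}

#' Compare expression between PCH and non-PCH genes
#'
#' Genes are split by midpoint containment in PCH blocks; per class the
#' report gives the proportion expressed (mean TPM > 1), the median mean-TPM
#' and the median tau, with two-sided Wilcoxon rank-sum tests on per-gene
#' mean TPM and on tau.
#'
#' @param expr TPM matrix (genes x samples).
#' @param pch_blocks Blocks from [call_pch()] or truth.
#' @param gene_positions data.frame with gene_id, chrom, start, end.
#' @param groups Group labels per sample (for tau); omit to skip the tau
#'   comparison.
#' @return List with per-class summaries and `p_tpm`, `p_tau`; `note` is set
#'   (and p values NA) when a class is empty.
#' @export
pch_expression_compare <- function(expr, pch_blocks, gene_positions,
                                   groups = NULL) {
  if (nrow(pch_blocks) == 0L)
    return(list(note = "no PCH blocks; comparison skipped",
                p_tpm = NA_real_, p_tau = NA_real_))
  gp <- gene_positions[match(rownames(expr), gene_positions$gene_id), ]
  mid <- (gp$start + gp$end) / 2
  in_pch <- vapply(seq_len(nrow(gp)), function(i) {
    b <- pch_blocks[pch_blocks$chrom == gp$chrom[i], , drop = FALSE]
    nrow(b) > 0 && any(mid[i] >= b$start & mid[i] < b$end)
  }, logical(1))
  if (!any(in_pch) || all(in_pch))
    return(list(note = "a class is empty; comparison skipped",
                p_tpm = NA_real_, p_tau = NA_real_))
  mtpm <- rowMeans(expr)
  tv <- if (is.null(groups)) rep(NA_real_, nrow(expr)) else tau(expr, groups)
  summ <- function(sel) list(
    n = sum(sel), prop_expressed = mean(mtpm[sel] > 1),
    median_tpm = stats::median(mtpm[sel]),
    median_tau = stats::median(tv[sel], na.rm = TRUE))
  p_tpm <- suppressWarnings(stats::wilcox.test(mtpm[in_pch], mtpm[!in_pch])$p.value)
  p_tau <- if (is.null(groups)) NA_real_ else
    suppressWarnings(stats::wilcox.test(tv[in_pch], tv[!in_pch])$p.value)
  list(pch = summ(in_pch), non_pch = summ(!in_pch),
       p_tpm = p_tpm, p_tau = p_tau, note = NULL)
}
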