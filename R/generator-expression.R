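# Gonadal expression emulation: negative-binomial counts for the study's
# sampling design (five testes, five ovaries, five intersex gonads staged
# I1-I5, plus single-replicate somatic tissues for tissue-specificity), with
# two planted candidate patterns among SLR genes and, optionally, elevated
# expression of PCH genes.

#' Simulate gonadal (and somatic) expression counts
#'
#' Baseline expression levels are log-normal with a fraction of silent genes;
#' expected counts scale with gene (exon) length so that TPM recovers the
#' planted levels. One SLR gene is planted as testis-exclusive and one as
#' testis-plus-early-intersex with ovary depletion. When `pch_boost > 1`,
#' genes inside planted PCH blocks get `pch_boost`-fold higher baseline
#' levels and a smaller silent fraction; at `pch_boost = 1` PCH and non-PCH
#' genes are exchangeable (the null).
#'
#' @param bundle A `genome_bundle` with gene models.
#' @param config Generator config (defaults to the bundle's).
#' @param n_replicates Gonad replicates per group (default 5).
#' @param somatic_tissues Names of single-replicate somatic tissues.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2); at 0
#'   counts equal their expectations exactly.
#' @param pch_boost Expression elevation of PCH genes (default 2; 1 = null).
#' @return List with `counts` (genes x samples integer-ish matrix), `lengths`
#'   (exonic gene lengths, bp), `samples` (data.frame sample, group, stage)
#'   and `truth` (planted candidate gene ids and expression means).
#' @export
gen_expression <- function(bundle, config = bundle$truth$config,
                           n_replicates = 5L,
                           somatic_tissues = c("brain", "liver", "muscle",
                                               "gill", "kidney", "skin"),
                           dispersion = 0.1, pch_boost = 2) {
  genes <- bundle$genes$genes
  if (is.null(genes) || nrow(genes) == 0L) stop("bundle has no genes", call. = FALSE)
  set.seed(config$seed + 37L)
  ex <- bundle$genes$exons
  glen <- tapply(ex$end - ex$start, ex$gene_id, sum)[genes$gene_id]
  ng <- nrow(genes)

  samples <- data.frame(
    sample = c(paste0("M", seq_len(n_replicates)), paste0("F", seq_len(n_replicates)),
               paste0("I", seq_len(n_replicates)), somatic_tissues),
    group = c(rep("testis", n_replicates), rep("ovary", n_replicates),
              rep("intersex", n_replicates), somatic_tissues),
    stage = c(rep(NA, 2 * n_replicates), paste0("I", seq_len(n_replicates)),
              rep(NA, length(somatic_tissues))))
  nsamp <- nrow(samples)

  mid <- (genes$start + genes$end) / 2
  pch <- bundle$truth$pch
  in_pch <- vapply(seq_len(ng), function(i) {
    p <- pch[pch$chrom == genes$chrom[i], , drop = FALSE]
    nrow(p) > 0 && any(mid[i] >= p$start & mid[i] < p$end)
  }, logical(1))

  silent_p <- if (pch_boost > 1) ifelse(in_pch, 0.15, 0.35) else rep(0.3, ng)
  base <- stats::rlnorm(ng, meanlog = 3, sdlog = 1.3)
  base[stats::runif(ng) < silent_p] <- 0
  if (pch_boost != 1) base[in_pch] <- base[in_pch] * pch_boost

  # per-gene x per-sample expression level with mild group-level wobble
  x <- matrix(rep(base, nsamp), nrow = ng)
  x <- x * matrix(stats::rlnorm(ng * nsamp, 0, 0.2), nrow = ng)

  # planted SLR candidates
  slr <- bundle$truth$slr
  cand <- data.frame(gene_id = character(0), pattern = character(0))
  if (!is.null(slr)) {
    slr_genes <- genes$gene_id[genes$chrom == slr$chrom &
                               mid >= slr$start & mid < slr$end]
    if (length(slr_genes) >= 2L) {
      pick <- sample(slr_genes, 2L)
      early <- samples$stage %in% c("I1", "I2", "I3")
      # testis + early-intersex, depleted in ovary (HMGN6-like pattern)
      i1 <- match(pick[1], genes$gene_id)
      x[i1, ] <- 2
      x[i1, samples$group == "testis"] <- 50
      x[i1, early] <- 40
      x[i1, samples$group == "ovary"] <- 0.5
      # testis-exclusive (SYCE3-like pattern)
      i2 <- match(pick[2], genes$gene_id)
      x[i2, ] <- 0
      x[i2, samples$group == "testis"] <- 80
      cand <- data.frame(gene_id = pick,
                         pattern = c("testis_plus_early_intersex", "testis_exclusive"))
    }
  }

  mu <- x * matrix(rep(glen / 1e3, nsamp), nrow = ng)
  counts <- if (dispersion == 0) mu else
    matrix(stats::rnbinom(ng * nsamp, mu = mu, size = 1 / dispersion), nrow = ng)
  dimnames(counts) <- list(genes$gene_id, samples$sample)
  list(counts = counts, lengths = stats::setNames(as.numeric(glen), genes$gene_id),
       samples = samples,
       truth = list(candidates = cand, in_pch = stats::setNames(in_pch, genes$gene_id),
                    base = stats::setNames(base, genes$gene_id), mu = mu))
}
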