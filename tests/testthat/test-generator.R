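# Synthetic genome generator: planted structure, determinism, invariants.

test_that("zero divergence gives identical X and Y haplotypes", {
  cfg <- small_config(seed = 5, divergence_r1 = 0, divergence_r2 = 0)
  b <- gen_genome(cfg)
  s <- b$sequences[[1]]
  expect_identical(s[["X"]], s[["Y"]])
  expect_length(b$truth$xy_diffs, 0)
})

test_that("same seed reproduces the bundle byte-identically, different seeds differ", {
  cfg <- small_config(seed = 11)
  b1 <- gen_genome(cfg)
  b2 <- gen_genome(cfg)
  expect_identical(b1, b2)
  b3 <- gen_genome(small_config(seed = 12))
  expect_false(identical(b1$truth$xy_diffs, b3$truth$xy_diffs))
})

test_that("the 24-chromosome preset plants the study's structures", {
  cfg <- zigzag_config(seed = 1, track_only = TRUE)
  expect_equal(cfg$n_chromosomes, 24L)
  expect_equal(cfg$chrom_lengths[cfg$sex_chrom_index], 27.9e6)
  expect_equal(cfg$slr_interval, c(17e6, 24e6))
  expect_equal(cfg$strata_boundary, 20e6)
  expect_equal(nchar(cfg$cen_monomer), 524L)
  expect_equal(nchar(cfg$tel_monomer), 190L)
  expect_equal(cfg$hifi_error_rate, 0.00086)
  b <- gen_genome(cfg)
  expect_null(b$sequences)                       # track-only
  expect_equal(nrow(b$truth$pch), 24L)
  # morphology plan: 5 metacentric / 3 submetacentric / 16 telocentric
  expect_equal(as.vector(table(b$meta$class)[c("metacentric", "submetacentric",
                                               "telocentric")]),
               c(5L, 3L, 16L))
  # SLR spans the centromere; PARs flank it on both sides
  cen <- b$meta[cfg$sex_chrom_index, ]
  expect_true(cen$cen_start >= 17e6 && cen$cen_end <= 24e6)
})

test_that("centromeric satellite arrays carry the preset monomers", {
  b <- small_bundle()
  cfg <- b$truth$config
  cen <- b$meta[2, ]                   # autosome, interior centromere
  s <- substr(b$sequences[[2]][["X"]], cen$cen_start + 1,
              cen$cen_start + 2 * cfg$cen_monomer_len)
  # first two copies differ from the monomer only by the 1% array mutation
  mono2 <- strrep(cfg$cen_monomer, 2)
  mism <- mean(charToRaw(s) != charToRaw(mono2))
  expect_lt(mism, 0.05)
  # telomeric termini carry the conserved motif
  expect_match(substr(b$sequences[[1]][["X"]], 2e6 - 17, 2e6), "TTAGGG")
})

test_that("config invariants are enforced with the field named", {
  expect_error(generator_config(chrom_lengths = c(1e6, -5)), "chrom_lengths")
  expect_error(generator_config(chrom_lengths = 1e6, slr_interval = c(5e5, 2e6)),
               "slr_interval")
  expect_error(generator_config(chrom_lengths = 1e6, slr_interval = c(2e5, 8e5),
                                strata_boundary = 9e5), "strata_boundary")
  expect_error(generator_config(chrom_lengths = 1e6, divergence_r1 = 1.5),
               "divergence_r1")
  expect_error(generator_config(chrom_lengths = 2e5, pch_min_len = 1e6),
               "pch_min_len")
})

test_that("repeat track hits its target coverage inside and outside PCH", {
  cfg <- generator_config(seed = 7, chrom_lengths = c(2e7, 1.5e7),
                          sex_chrom_index = 1, track_only = TRUE)
  b <- gen_genome(cfg)
  rc <- repeat_content_track(b$repeat_track, b$meta)
  mid <- (rc$start + rc$end) / 2
  in_pch <- vapply(seq_len(nrow(rc)), function(i) {
    p <- b$truth$pch[b$truth$pch$chrom == rc$chrom[i], ]
    any(mid[i] >= p$start & mid[i] < p$end)
  }, logical(1))
  expect_gte(mean(rc$value[in_pch]), cfg$pch_repeat_frac - 0.05)
  expect_lte(mean(rc$value[!in_pch]), cfg$background_repeat_frac + 0.05)
})

test_that("gene models are internally consistent", {
  b <- small_bundle()
  g <- b$genes$genes; e <- b$genes$exons
  expect_true(all(e$start >= g$start[match(e$gene_id, g$gene_id)]))
  expect_true(all(e$end <= g$end[match(e$gene_id, g$gene_id)]))
  # exons within a gene do not overlap
  by_gene <- split(e, e$gene_id)
  ok <- vapply(by_gene, function(x) {
    x <- x[order(x$start), ]
    nrow(x) < 2 || all(x$start[-1] >= x$end[-nrow(x)])
  }, logical(1))
  expect_true(all(ok))
  intr <- intron_intervals(b$genes)
  expect_true(all(intr$end > intr$start))
})

test_that("SLR genotypes are fully sex-linked and background sites follow HWE", {
  b <- small_bundle()
  vt <- small_vt()
  expect_equal(ncol(vt$geno), 20L)
  slr <- b$truth$slr
  in_slr <- vt$sites$chrom == slr$chrom & vt$sites$pos > slr$start &
    vt$sites$pos <= slr$end
  expect_equal(sum(in_slr), length(b$truth$xy_sites))
  gm <- vt$geno[in_slr, vt$sex == "male", drop = FALSE]
  gf <- vt$geno[in_slr, vt$sex == "female", drop = FALSE]
  expect_true(all(gm == 1L))
  expect_true(all(gf == 0L))
  # background het fraction matches E[2p(1-p)] for p ~ U(0.05, 0.95):
  # E p = 0.5, E p^2 = 0.9^2/12 + 0.25, so P(het) = 0.365
  gb <- vt$geno[!in_slr, , drop = FALSE]
  p_het <- mean(gb == 1L)
  se <- sqrt(0.365 * 0.635 / length(gb))   # upper bound ignoring site grouping
  expect_lt(abs(p_het - 0.365), 0.02)
  expect_error(gen_population_genotypes(b, generator_config(
    seed = 1, chrom_lengths = 5e6, n_males = 0, n_females = 0)), "zero samples")
})

test_that("simulated reads cover uniformly and carry the requested error rate", {
  b <- small_bundle()
  reads0 <- gen_kmer_reads(b, coverage = 2, read_len = 2000, error_rate = 0,
                           seed = 5)
  src <- attr(reads0, "source")
  seqs <- vapply(b$sequences, function(s) s[["X"]], character(1))
  idx <- sample(length(reads0), 50)
  for (i in idx)
    expect_identical(reads0[i], substr(seqs[[src$chrom[i]]], src$start[i],
                                       src$start[i] + 1999))
  expect_equal(length(reads0), ceiling(2 * sum(b$meta$length) / 2000))
  # substitution errors at the configured rate, within 3 binomial SD
  rate <- 0.002
  reads1 <- gen_kmer_reads(b, coverage = 2, read_len = 2000, error_rate = rate,
                           seed = 5)
  src1 <- attr(reads1, "source")
  nb <- length(reads1) * 2000
  mism <- sum(vapply(seq_along(reads1), function(i) {
    truth <- substr(seqs[[src1$chrom[i]]], src1$start[i], src1$start[i] + 1999)
    sum(charToRaw(truth) != charToRaw(reads1[i]))
  }, numeric(1)))
  expect_lt(abs(mism / nb - rate), 3 * sqrt(rate * (1 - rate) / nb))
  expect_error(gen_kmer_reads(b, coverage = 1, read_len = 2e6), "read_len")
})

test_that("epigenome generator obeys its closed-form contracts", {
  b <- small_bundle()
  # deterministic decay mode: count at distance 2d vs d follows the power law
  epi0 <- gen_epigenome(b, noise = "none", pch_boost = 1,
                        compartment_strength = 0, decay_exponent = 1,
                        chroms = "chr2")
  A <- epi0$matrices[["chr2"]]$counts
  expect_equal(A[1, 11] / A[1, 21], 21 / 11, tolerance = 1e-12)
  expect_equal(A[1, 2], 300 / 2, tolerance = 1e-12)
  # PCH elevation: within-PCH counts are exactly boost x matched-distance
  # background in noise-free mode
  epi2 <- gen_epigenome(b, noise = "none", pch_boost = 2,
                        compartment_strength = 0, chroms = "chr2")
  A2 <- epi2$matrices[["chr2"]]$counts
  ct <- epi2$truth$compartments
  inp <- ct$in_pch[ct$chrom == "chr2"]
  i_in <- which(inp); i_out <- which(!inp)
  if (length(i_in) >= 2 && length(i_out) >= 2) {
    d_in <- abs(i_in[1] - i_in[2]); pair_out <- i_out[abs(outer(i_out, i_out, "-")) == d_in]
    expect_equal(A2[i_in[1], i_in[2]],
                 2 * 300 * (d_in + 1)^(-1), tolerance = 1e-12)
  }
  # peaks under a 4:1 density ratio are enriched in PCH
  epi <- gen_epigenome(b, pch_peak_ratio = 4)
  enr <- peak_enrichment(epi$peaks, b$truth$pch, b$meta, score_min = 0)
  expect_gt(enr$ratio, 2)
  # a uniform peak field gives ratio ~ 1
  epi1 <- gen_epigenome(b, pch_peak_ratio = 1)
  enr1 <- peak_enrichment(epi1$peaks, b$truth$pch, b$meta, score_min = 0)
  expect_lt(abs(enr1$ratio - 1), 0.5)
})

test_that("expression generator plants the candidate patterns and NB limits", {
  b <- small_bundle()
  ge <- gen_expression(b)
  expect_equal(sum(ge$samples$group %in% c("testis", "ovary", "intersex")), 15L)
  expect_equal(as.vector(table(ge$samples$group)[c("testis", "ovary", "intersex")]),
               c(5L, 5L, 5L))
  tp <- tpm(ge$counts, ge$lengths)
  cand <- ge$truth$candidates
  excl <- cand$gene_id[cand$pattern == "testis_exclusive"]
  testis <- ge$samples$group == "testis"
  expect_gt(mean(tp[excl, testis]), 1)
  expect_lt(mean(tp[excl, !testis]), 1)
  # dispersion 0: counts equal their expectations exactly
  ge0 <- gen_expression(b, dispersion = 0)
  expect_equal(unname(ge0$counts), unname(ge0$truth$mu))
  expect_error(gen_expression(structure(list(genes = list(genes = NULL)),
                                        class = "genome_bundle"),
                              b$truth$config), "genes")
})
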