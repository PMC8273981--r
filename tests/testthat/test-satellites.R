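# Tandem satellite detection, monomer canonicalization, family building and
# karyotype classification.

test_that("perfect and mutated tandem arrays are detected at the true period", {
  ta <- find_tandem_arrays(strrep("ACGT", 100), min_period = 2)
  expect_equal(nrow(ta), 1L)
  expect_equal(ta$period, 4L)
  expect_equal(ta$copy_number, 100)
  expect_equal(ta$start, 0)
  expect_equal(ta$end, 400)
  # a 524-bp monomer with 1% per-base mutation over 50 copies
  mono <- random_seq(524, seed = 77)
  arr <- tandem_array_seq(mono, 50, 0.01, seed = 78)
  ta2 <- find_tandem_arrays(arr)
  expect_equal(ta2$period[1], 524L)
  expect_equal(canonical_monomer(ta2$consensus[1]), canonical_monomer(mono))
})

test_that("uniform random sequence yields no arrays", {
  expect_equal(nrow(find_tandem_arrays(random_seq(1e4, seed = 5))), 0L)
})

test_that("detection matches a brute-force all-period scan on short sequences", {
  set.seed(41)
  sq <- paste0(random_seq(600), tandem_array_seq(random_seq(7), 30, 0.05),
               random_seq(600))
  ta <- find_tandem_arrays(sq, min_period = 2, max_period = 50)
  bf <- brute_tandem_scan(sq, 2, 50, 0.2)
  expect_gt(nrow(ta), 0)
  expect_true(ta$period[1] %in% bf$period)
  # the detector's array coincides with a brute-force hit of the same period
  bfp <- bf[bf$period == ta$period[1], ]
  ov <- pmin(ta$end[1], bfp$end) - pmax(ta$start[1], bfp$start)
  expect_gt(max(ov) / (ta$end[1] - ta$start[1]), 0.9)
  # and every brute-force period hit is explained by a detected array
  # (possibly at a smaller fundamental period)
  for (j in seq_len(nrow(bf))) {
    ov <- pmin(ta$end, bf$end[j]) - pmax(ta$start, bf$start[j])
    expect_gt(max(ov / (bf$end[j] - bf$start[j])), 0.5)
  }
})

test_that("monomer canonicalization is rotation- and strand-invariant", {
  expect_equal(canonical_monomer("GTAC"), "ACGT")
  expect_equal(canonical_monomer("AAAA"), canonical_monomer("TTTT"))
  set.seed(9)
  for (i in 1:20) {
    m <- random_seq(sample(5:40, 1))
    cm <- canonical_monomer(m)
    expect_equal(canonical_monomer(cm), cm)                 # idempotent
    off <- sample(nchar(m), 1)
    rot <- paste0(substr(m, off, nchar(m)), substr(m, 1, off - 1))
    expect_equal(canonical_monomer(rot), cm)                # rotation
    expect_equal(canonical_monomer(revcomp(m)), cm)         # strand
  }
  expect_error(canonical_monomer("ACGX"), "non-ACGTN")
})

test_that("families merge rotated monomers and rank by total span", {
  mono <- random_seq(40, seed = 13)
  rot <- paste0(substr(mono, 11, 40), substr(mono, 1, 10))
  arrays <- data.frame(
    chrom = c("chr1", "chr2", "chr1"),
    start = c(0, 0, 5000), end = c(4000, 2000, 5800),
    period = c(40L, 40L, 20L), copy_number = c(100, 50, 40),
    mismatch_frac = 0, consensus = c(mono, rot, random_seq(20, seed = 14)))
  fam <- build_families(arrays)
  expect_equal(nrow(fam), 2L)
  expect_equal(fam$total_bp, c(6000, 800))        # sorted descending
  expect_equal(fam$n_loci, c(2L, 1L))
})

test_that("planted families are recovered with the planted rank order", {
  set.seed(21)
  lens <- c(90, 60, 45, 30, 21)
  sizes <- c(9000, 6000, 3600, 1800, 840)
  arrays <- do.call(rbind, lapply(seq_along(lens), function(i) {
    data.frame(chrom = "chr1", start = i * 2e4, end = i * 2e4 + sizes[i],
               period = lens[i], copy_number = sizes[i] / lens[i],
               mismatch_frac = 0, consensus = random_seq(lens[i]))
  }))
  fam <- build_families(arrays[sample(nrow(arrays)), ])
  expect_equal(nrow(fam), 5L)
  expect_equal(fam$total_bp, sort(sizes, decreasing = TRUE))
  expect_equal(fam$monomer_len, lens)
})

test_that("distribution-based labels separate centromeric from telomeric", {
  meta <- data.frame(chrom = paste0("chr", 1:6), length = rep(1e7, 6),
                     class = c("metacentric", "submetacentric",
                               rep("telocentric", 4)))
  mk <- function(chrom, start, end, mono)
    data.frame(chrom = chrom, start = start, end = end,
               period = nchar(mono), copy_number = (end - start) / nchar(mono),
               mismatch_frac = 0, consensus = mono)
  cen_m <- random_seq(50, seed = 31); tel_m <- random_seq(30, seed = 32)
  oth_m <- random_seq(40, seed = 33)
  arrays <- rbind(
    do.call(rbind, lapply(1:6, function(i)           # one interior locus each
      mk(paste0("chr", i), 5e6, 5e6 + 5e4, cen_m))),
    do.call(rbind, lapply(1:6, function(i)           # terminal loci
      mk(paste0("chr", i), 1e7 - 3e4, 1e7, tel_m))),
    mk("chr1", 1e4, 4e4, tel_m),                     # second end on chr1
    do.call(rbind, lapply(c(1e6, 3e6, 5e6, 7e6, 9e6 - 3e5), function(s)
      mk("chr2", s, s + 2e4, oth_m))))               # scattered interior
  fam <- classify_families(build_families(arrays), meta)
  lab <- stats::setNames(fam$label, fam$canonical_monomer)
  expect_equal(unname(lab[canonical_monomer(cen_m)]), "centromeric")
  expect_equal(unname(lab[canonical_monomer(tel_m)]), "telomere-associated")
  expect_equal(unname(lab[canonical_monomer(oth_m)]), "other")

  cen <- locate_centromeres(fam, meta)
  expect_true(all(cen$resolved))
  expect_true(all(abs(cen$cen_start - 5e6) < 1))
  # missing cluster on an extra chromosome -> unresolved
  meta7 <- rbind(meta, data.frame(chrom = "chr7", length = 1e7,
                                  class = "telocentric"))
  cen7 <- locate_centromeres(fam, meta7)
  expect_false(cen7$resolved[cen7$chrom == "chr7"])
})

test_that("terminal centromeric clusters put centromeres at chromosome ends", {
  meta <- data.frame(chrom = c("chr1", "chr2"), length = c(1e7, 8e6),
                     class = c("submetacentric", "telocentric"))
  mono <- random_seq(50, seed = 51)
  mk <- function(chrom, start, end)
    data.frame(chrom = chrom, start = start, end = end, period = 50L,
               copy_number = (end - start) / 50, mismatch_frac = 0,
               consensus = mono)
  arrays <- rbind(mk("chr1", 4e6, 4.05e6), mk("chr2", 0, 5e4))
  fam <- classify_families(build_families(arrays), meta)
  expect_equal(fam$label, "centromeric")
  cen <- locate_centromeres(fam, meta)
  expect_equal(cen$cen_start[cen$chrom == "chr2"], 0)
})

test_that("arm-ratio thresholds classify morphology with the boundary inclusive", {
  meta <- data.frame(chrom = paste0("chr", 1:4), length = rep(1e7, 4))
  cen <- data.frame(chrom = paste0("chr", 1:4),
                    cen_start = c(5e6, 2.5e6, 0, NA) - c(5e3, 5e3, 0, NA),
                    cen_end = c(5e6, 2.5e6, 0, NA) + c(5e3, 5e3, 1e4, NA))
  m <- classify_morphology(cen, meta)
  expect_equal(m$class[1], "metacentric")       # midpoint, ratio 1
  expect_equal(m$class[2], "submetacentric")    # 25%, ratio 3, boundary
  expect_equal(m$arm_ratio[2], 3, tolerance = 1e-2)
  expect_equal(m$class[3], "telocentric")       # terminal, ratio -> large
  expect_true(is.na(m$class[4]))                # unresolved
})

test_that("family assignment is invariant to strand and array phase", {
  mono <- random_seq(60, seed = 61)
  arr <- tandem_array_seq(mono, 40)
  sq1 <- paste0(random_seq(500, seed = 62), arr, random_seq(500, seed = 63))
  ta1 <- find_tandem_arrays(sq1, max_period = 100)
  ta2 <- find_tandem_arrays(revcomp(sq1), max_period = 100)
  expect_equal(ta1$period, ta2$period)
  expect_equal(canonical_monomer(ta1$consensus[1]),
               canonical_monomer(ta2$consensus[1]))
  # phase shift: start the array mid-monomer
  sq3 <- paste0(random_seq(500, seed = 64), substr(arr, 31, nchar(arr)),
                random_seq(500, seed = 65))
  ta3 <- find_tandem_arrays(sq3, max_period = 100)
  expect_equal(canonical_monomer(ta3$consensus[1]),
               canonical_monomer(ta1$consensus[1]))
})
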