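# Sex-linkage scan: sex-specific calls, windowed density/FST, exact
# association, SLR demarcation, X-Y similarity, strata segmentation.

test_that("sex-specific calling applies the all-male-het / all-female-hom rule", {
  sex <- std_sex()
  g_yes <- matrix(c(rep(1L, 10), rep(0L, 10)), nrow = 1)         # male-specific
  g_no <- matrix(c(rep(1L, 9), 0L, rep(0L, 10)), nrow = 1)       # one male hom
  g_fhet <- matrix(c(rep(1L, 10), rep(0L, 9), 1L), nrow = 1)     # one female het
  g_mixf <- matrix(c(rep(1L, 10), rep(0L, 5), rep(2L, 5)), nrow = 1)  # females differ
  vt <- make_vt(rbind(g_yes, g_no, g_fhet, g_mixf), sex)
  out <- call_sex_specific_snps(vt)
  expect_equal(attr(out, "idx"), 1L)
  # symmetric female-specific mode
  vtf <- make_vt(rbind(matrix(c(rep(0L, 10), rep(1L, 10)), nrow = 1)), sex)
  expect_equal(attr(call_sex_specific_snps(vtf, "female"), "idx"), 1L)
  # missingness above 20% excludes the site; all-missing sites are skipped
  g_miss <- g_yes; g_miss[1, 1:5] <- NA
  vtm <- make_vt(rbind(g_yes, g_miss, matrix(NA_integer_, 1, 20)), sex)
  expect_equal(attr(call_sex_specific_snps(vtm), "idx"), 1L)
})

test_that("acceptance probability of a random HWE site matches the exact product", {
  p <- 0.3; n_sites <- 10000
  # rule probability: all 10 males het, all 10 females hom for the same allele
  p_rule <- (2 * p * (1 - p))^10 * (((1 - p)^2)^10 + (p^2)^10)
  set.seed(71)
  g <- matrix(rbinom(n_sites * 20, 2, p), nrow = n_sites)
  vt <- make_vt(g, std_sex())
  acc <- length(attr(call_sex_specific_snps(vt), "idx")) / n_sites
  expect_lt(abs(acc - p_rule), 3 * sqrt(p_rule * (1 - p_rule) / n_sites))
})

test_that("window counts tile, count and conserve totals", {
  meta <- data.frame(chrom = "chr1", length = 220000)
  empty <- data.frame(chrom = character(0), pos = integer(0))
  w0 <- window_counts(empty, meta)
  expect_equal(w0$value, rep(0, 5))
  expect_equal(w0$end[5], 220000)               # ragged last window kept
  sites <- data.frame(chrom = "chr1",
                      pos = c(seq(1000, 49000, length.out = 7), 60000, 210001))
  w <- window_counts(sites, meta)
  expect_equal(w$value[1], 7)
  expect_equal(sum(w$value), nrow(sites))
})

test_that("windowed FST hits the fixed-difference and null anchors", {
  sex <- std_sex()
  meta <- data.frame(chrom = "chr1", length = 5e4)
  fixed <- matrix(rep(c(2L, 0L), c(10, 10)), nrow = 50, ncol = 20, byrow = TRUE)
  vt <- make_vt(fixed, sex, pos = seq(100, 49000, length.out = 50))
  w <- window_fst(vt, meta, min_variants = 40)
  expect_equal(w$value[1], 1)
  # equal allele frequencies in both sexes: FST ~ 0
  set.seed(5)
  g <- matrix(rbinom(50 * 20, 2, 0.5), nrow = 50)
  vt2 <- make_vt(g, sex, pos = seq(100, 49000, length.out = 50))
  w2 <- window_fst(vt2, meta, min_variants = 40)
  expect_lt(abs(w2$value[1]), 0.1)
  expect_true(w2$value[1] >= -0.1 && w2$value[1] <= 1)
  # allele-label swap leaves FST unchanged
  vt3 <- make_vt(2L - g, sex, pos = seq(100, 49000, length.out = 50))
  expect_equal(window_fst(vt3, meta, min_variants = 40)$value[1], w2$value[1])
  # the min-variant filter: 39 variants -> missing
  vt4 <- make_vt(fixed[1:39, ], sex, pos = seq(100, 49000, length.out = 39))
  expect_true(is.na(window_fst(vt4, meta, min_variants = 40)$value[1]))
  # monomorphic window -> missing
  vt5 <- make_vt(matrix(0L, 45, 20), sex, pos = seq(100, 49000, length.out = 45))
  expect_true(is.na(window_fst(vt5, meta, min_variants = 40)$value[1]))
})

test_that("association p values match the exact enumeration oracle", {
  sex <- std_sex()
  g <- rbind(
    matrix(c(rep(1L, 10), rep(0L, 10)), nrow = 1),   # fully sex-linked
    matrix(c(rep(1L, 5), rep(0L, 5), rep(1L, 5), rep(0L, 5)), nrow = 1),
    matrix(0L, 1, 20))                               # monomorphic
  vt <- make_vt(g, sex)
  sc <- assoc_scan(vt)
  # independent oracle: two-sided Fisher's exact test on the allele table
  oracle <- fisher.test(matrix(c(10, 10, 0, 20), 2, byrow = TRUE))$p.value
  expect_equal(sc$p[1], oracle, tolerance = 1e-9)
  expect_equal(sc$p[2], 1)                 # identical counts in both sexes
  expect_equal(sc$neglog10p[2], 0)
  expect_equal(sc$p[3], 1)                 # monomorphic
  # swapping sex labels leaves p unchanged
  sex_sw <- stats::setNames(rev(sex), names(sex))
  vt_sw <- vt; vt_sw$sex <- stats::setNames(
    ifelse(sex == "male", "female", "male"), names(sex))
  expect_equal(assoc_scan(vt_sw)$p, sc$p)
})

test_that("fully sex-specific sites attain the design's maximal significance", {
  b <- small_bundle()
  vt <- small_vt()
  sc <- assoc_scan(vt)
  sss <- call_sex_specific_snps(vt)
  pmax_design <- fisher.test(matrix(c(10, 10, 0, 20), 2, byrow = TRUE))$p.value
  expect_true(all(abs(sc$p[attr(sss, "idx")] - pmax_design) < 1e-12))
  expect_true(all(sc$p >= pmax_design - 1e-12))
})

test_that("SLR demarcation merges runs and picks the longest", {
  meta <- data.frame(chrom = "chr1", length = 5e6)
  mk_track <- function(counts) data.frame(chrom = "chr1",
    start = (seq_along(counts) - 1) * 5e4, end = seq_along(counts) * 5e4,
    value = counts)
  # single isolated marked window
  v <- rep(0, 100); v[40] <- 5
  s1 <- demarcate_slr(mk_track(v))
  expect_equal(c(s1$start, s1$end), c(39 * 5e4, 40 * 5e4))
  # runs of 10 vs 40 marked windows: the long one wins
  v2 <- rep(0, 100); v2[5:14] <- 4; v2[41:80] <- 4
  s2 <- demarcate_slr(mk_track(v2))
  expect_equal(c(s2$start, s2$end), c(40 * 5e4, 80 * 5e4))
  expect_equal(s2$pars$start, c(0, 80 * 5e4))
  # gaps up to 5 windows are bridged, 6 are not
  v3 <- rep(0, 100); v3[10:15] <- 3; v3[21:30] <- 3   # gap of 5
  expect_equal(demarcate_slr(mk_track(v3))$start, 9 * 5e4)
  v4 <- rep(0, 100); v4[10:15] <- 3; v4[22:30] <- 3   # gap of 6
  expect_equal(demarcate_slr(mk_track(v4))$start, 21 * 5e4)
  # nothing marked -> empty call
  expect_true(is.na(demarcate_slr(mk_track(rep(0, 100)))$chrom))
})

test_that("X-Y similarity respects the intron mask and equal-length contract", {
  s <- random_seq(3e5, seed = 81)
  introns <- data.frame(start = seq(0, 2.9e5, by = 1e4), end = seq(0, 2.9e5, by = 1e4) + 5e3)
  w <- xy_window_similarity(s, s, introns, window = 1e5)
  expect_equal(w$value, rep(1, 3))
  # a window with no intronic bases is missing
  introns2 <- introns[introns$start >= 1e5, ]
  w2 <- xy_window_similarity(s, s, introns2, window = 1e5)
  expect_true(is.na(w2$value[1]))
  expect_equal(w2$value[2:3], rep(1, 2))
  expect_error(xy_window_similarity(s, substr(s, 1, 1000), introns), "lengths differ")
  # planted divergence is recovered on the masked positions
  r <- charToRaw(s); set.seed(82)
  pos <- which(stats::runif(length(r)) < 0.01)
  y <- slrscape:::.substitute_at(r, pos)
  w3 <- xy_window_similarity(s, rawToChar(y), introns, window = 1e5)
  expect_equal(mean(1 - w3$value), 0.01, tolerance = 0.15)
})

test_that("strata segmentation matches the exact Wilcoxon oracle and nulls", {
  # {1,2,3} vs {4,5,6}: exact p = 2 * 1/20 = 0.1, verified by enumerating all
  # 20 assignments of ranks to the first group
  d <- c(1, 2, 3, 4, 5, 6) / 100
  cmb <- utils::combn(6, 3)
  w_obs <- sum(rank(d)[1:3])
  w_all <- apply(cmb, 2, function(i) sum(rank(d)[i]))
  p_enum <- mean(w_all <= w_obs | w_all >= sum(rank(d)) / 2 + (sum(rank(d)) / 2 - w_obs))
  expect_equal(p_enum, 0.1)
  track <- data.frame(chrom = "chr", start = (0:5) * 1e5, end = (1:6) * 1e5,
                      value = 1 - d)
  st <- segment_strata(track, c(0, 6e5))
  expect_equal(st$wilcoxon_p, 0.1)
  expect_false(st$two_strata)        # 0.1 >= 0.05: single stratum reported
  expect_equal(nrow(st$strata), 1L)
  # a clear changepoint is found and located
  set.seed(83)
  dv <- c(rnorm(15, 0.012, 0.0008), rnorm(20, 0.008, 0.0008))
  tr2 <- data.frame(chrom = "chr", start = (0:34) * 1e5, end = (1:35) * 1e5,
                    value = 1 - dv)
  st2 <- segment_strata(tr2, c(0, 35e5))
  expect_true(st2$two_strata)
  expect_equal(st2$boundary, 15e5)
  expect_equal(st2$strata$name, c("R1", "R2"))
  expect_gt(st2$strata$mean_divergence[1], st2$strata$mean_divergence[2])
  # too few windows: single stratum, p missing
  st3 <- segment_strata(track[1:4, ], c(0, 4e5))
  expect_false(st3$two_strata)
  expect_true(is.na(st3$wilcoxon_p))
})

test_that("constant divergence rarely yields two strata (null calibration)", {
  n_two <- 0L
  for (s in 1:20) {
    set.seed(900 + s)
    dv <- rnorm(30, 0.01, 0.001)
    tr <- data.frame(chrom = "chr", start = (0:29) * 1e5, end = (1:30) * 1e5,
                     value = 1 - dv)
    if (segment_strata(tr, c(0, 30e5))$two_strata) n_two <- n_two + 1L
  }
  expect_lte(n_two / 20, 0.15)
})

test_that("planted sex linkage is recovered at the planted coordinates", {
  lens <- strata_r1 <- numeric(2)
  for (s in 1:2) {
    cfg <- generator_config(seed = 130 + s, chrom_lengths = 27.9e6,
                            sex_chrom_index = 1, slr_interval = c(17e6, 24e6),
                            strata_boundary = 20e6, track_only = TRUE)
    b <- gen_genome(cfg)
    vt <- gen_population_genotypes(b)
    slr <- demarcate_slr(window_counts(call_sex_specific_snps(vt), b$meta))
    lens[s] <- (slr$end - slr$start) / 1e6
    expect_lt(abs(slr$start - 17e6), 3e5)
    expect_lt(abs(slr$end - 24e6), 3e5)
  }
  expect_true(all(abs(lens - 7) <= 0.3))
})
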