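# Shared fixtures, built in code and cached per test run.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) assign(key, expr, envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# Small sequence-mode diploid genome: 2 chromosomes, SLR on chr1.
small_config <- function(seed = 3, ...) {
  generator_config(seed = seed, chrom_lengths = c(2e6, 1.5e6),
                   sex_chrom_index = 1, slr_interval = c(6e5, 1.4e6),
                   strata_boundary = 1e6, cen_copies = 40, tel_copies = 30,
                   pch_mean_len = 3e5, pch_sd_len = 5e4, pch_min_len = 1e5, ...)
}

small_bundle <- function() cached("small_bundle", gen_genome(small_config()))

small_vt <- function() cached("small_vt", gen_population_genotypes(small_bundle()))

# Full-scale sex chromosome with sequences (shared by strata/divergence tests).
sexchrom_bundle <- function() cached("sexchrom_bundle", {
  cfg <- generator_config(seed = 1, chrom_lengths = 27.9e6, sex_chrom_index = 1,
                          slr_interval = c(17e6, 24e6), strata_boundary = 20e6)
  gen_genome(cfg)
})

# Hand-built variant table: explicit genotype matrix, 1-based positions.
make_vt <- function(geno, sex, chrom = "chr1", pos = NULL) {
  n <- nrow(geno)
  if (is.null(pos)) pos <- seq_len(n) * 1000L
  sites <- data.frame(chrom = chrom, pos = pos,
                      ref = rep("A", n), alt = rep("G", n))
  colnames(geno) <- names(sex)
  structure(list(sites = sites, geno = geno, sex = sex),
            class = "variant_table")
}

std_sex <- function(n_m = 10, n_f = 10) {
  stats::setNames(rep(c("male", "female"), c(n_m, n_f)),
                  c(paste0("M", seq_len(n_m)), paste0("F", seq_len(n_f))))
}

# Brute-force all-period tandem scan (independent oracle, quadratic in L):
# for every period and window start, test the window mismatch fraction
# directly on the raw bytes.
brute_tandem_scan <- function(seq, min_period, max_period, max_mismatch,
                              min_len = 50L) {
  r <- charToRaw(seq)
  L <- length(r)
  hits <- list()
  for (p in min_period:min(max_period, floor(L / 2))) {
    need <- max(2L * p, min_len)
    good <- logical(L)
    for (s in seq_len(L - 2L * p + 1L)) {
      mm <- sum(r[s:(s + p - 1L)] != r[(s + p):(s + 2L * p - 1L)])
      if (mm / p <= max_mismatch) good[s:(s + 2L * p - 1L)] <- TRUE
    }
    rl <- rle(good)
    en <- cumsum(rl$lengths); st <- en - rl$lengths + 1L
    for (j in which(rl$values)) {
      if (en[j] - st[j] + 1L >= need)
        hits[[length(hits) + 1L]] <- data.frame(period = p, start = st[j] - 1L,
                                                end = en[j])
    }
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(period = integer(0), start = integer(0), end = integer(0))
}
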