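#' Configuration for the synthetic diploid genome generator
#'
#' Collects every knob of the generator: karyotype dimensions, the planted
#' sex-linked region (SLR) and its two divergence strata, satellite monomer
#' presets, pericentromeric heterochromatin (PCH) geometry, resequencing
#' design and the HiFi read error preset. Coordinates are 0-based half-open
#' throughout the package and converted only at I/O boundaries.
#'
#' @param seed Integer seed; the generator is fully deterministic given the
#'   config.
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_lengths Integer vector of chromosome lengths in bp.
#' @param sex_chrom_index Index of the XY pair among the chromosomes.
#' @param slr_interval Numeric `(start, end)` of the SLR on the sex
#'   chromosome, bp, 0-based half-open.
#' @param strata_boundary Changepoint between the two divergence strata, bp.
#' @param divergence_r1,divergence_r2 Per-base X-to-Y substitution
#'   probabilities in the first (older, higher-divergence) and second stratum.
#' @param cen_monomer_len,tel_monomer_len Monomer lengths (bp) of the
#'   centromeric and telomere-associated satellites.
#' @param cen_copies,tel_copies Tandem copies planted per array.
#' @param pch_mean_len,pch_sd_len,pch_min_len Normal mean/sd and truncation
#'   floor (bp) for planted PCH block lengths.
#' @param pch_repeat_frac,background_repeat_frac Target repeat coverage
#'   fraction inside PCH blocks and elsewhere.
#' @param snp_density Expected polymorphic sites per bp for the resequencing
#'   design (also the density of genotypable X-Y sites in `track_only` mode).
#' @param n_males,n_females Resequenced individuals per sex.
#' @param hifi_error_rate Per-base substitution probability of simulated HiFi
#'   reads.
#' @param track_only If `TRUE`, no base-level sequences are generated; all
#'   coordinate tracks (karyotype, repeats, PCH, genes, SLR truth) are still
#'   emitted, which keeps whole-genome scans fast.
#' @param cen_monomer,tel_monomer Optional explicit monomer sequences;
#'   defaults are random sequences derived deterministically from `seed`.
#' @return An object of class `generator_config` (a validated list).
#' @seealso [zigzag_config()] for the preset mirroring the study system,
#'   [gen_genome()].
#' @export
generator_config <- function(seed = 1L,
                             n_chromosomes = length(chrom_lengths),
                             chrom_lengths,
                             sex_chrom_index = 1L,
                             slr_interval = NULL,
                             strata_boundary = NULL,
                             divergence_r1 = 0.012,
                             divergence_r2 = 0.008,
                             cen_monomer_len = 524L,
                             tel_monomer_len = 190L,
                             cen_copies = 100L,
                             tel_copies = 50L,
                             pch_mean_len = 4.2e6,
                             pch_sd_len = 5e5,
                             pch_min_len = 1e6,
                             pch_repeat_frac = 0.55,
                             background_repeat_frac = 0.15,
                             snp_density = 1e-3,
                             n_males = 10L,
                             n_females = 10L,
                             hifi_error_rate = 0.00086,
                             track_only = FALSE,
                             cen_monomer = NULL,
                             tel_monomer = NULL) {
  cfg <- list(
    seed = as.integer(seed),
    n_chromosomes = as.integer(n_chromosomes),
    chrom_lengths = as.numeric(chrom_lengths),
    sex_chrom_index = as.integer(sex_chrom_index),
    slr_interval = if (is.null(slr_interval)) NULL else as.numeric(slr_interval),
    strata_boundary = if (is.null(strata_boundary)) NULL else as.numeric(strata_boundary),
    divergence_r1 = divergence_r1,
    divergence_r2 = divergence_r2,
    cen_monomer_len = as.integer(cen_monomer_len),
    tel_monomer_len = as.integer(tel_monomer_len),
    cen_copies = as.integer(cen_copies),
    tel_copies = as.integer(tel_copies),
    pch_mean_len = pch_mean_len,
    pch_sd_len = pch_sd_len,
    pch_min_len = pch_min_len,
    pch_repeat_frac = pch_repeat_frac,
    background_repeat_frac = background_repeat_frac,
    snp_density = snp_density,
    n_males = as.integer(n_males),
    n_females = as.integer(n_females),
    hifi_error_rate = hifi_error_rate,
    track_only = isTRUE(track_only)
  )
  cfg$cen_monomer <- if (is.null(cen_monomer))
    .with_seed(cfg$seed + 1000003L, random_seq(cfg$cen_monomer_len)) else toupper(cen_monomer)
  cfg$tel_monomer <- if (is.null(tel_monomer))
    .with_seed(cfg$seed + 2000003L, random_seq(cfg$tel_monomer_len)) else toupper(tel_monomer)
  class(cfg) <- "generator_config"
  validate_config(cfg)
  cfg
}

#' Validate a generator configuration
#'
#' Checks the structural invariants (positive lengths, SLR inside the sex
#' chromosome, strata boundary inside the SLR, probabilities in `[0, 1]`) and
#' errors naming the offending field.
#'
#' @param cfg A `generator_config`.
#' @return `cfg`, invisibly, if valid.
#' @export
validate_config <- function(cfg) {
  fail <- function(field, why) stop("invalid generator_config: field '", field, "' ", why, call. = FALSE)
  if (cfg$n_chromosomes < 1L) fail("n_chromosomes", "must be >= 1")
  if (length(cfg$chrom_lengths) != cfg$n_chromosomes)
    fail("chrom_lengths", "must have one entry per chromosome")
  if (any(cfg$chrom_lengths <= 0)) fail("chrom_lengths", "must be > 0")
  if (cfg$sex_chrom_index < 1L || cfg$sex_chrom_index > cfg$n_chromosomes)
    fail("sex_chrom_index", "out of range")
  sex_len <- cfg$chrom_lengths[cfg$sex_chrom_index]
  if (!is.null(cfg$slr_interval)) {
    if (length(cfg$slr_interval) != 2L || cfg$slr_interval[1] >= cfg$slr_interval[2])
      fail("slr_interval", "must be an increasing (start, end) pair")
    if (cfg$slr_interval[1] < 0 || cfg$slr_interval[2] > sex_len)
      fail("slr_interval", "must lie within the sex chromosome")
    if (!is.null(cfg$strata_boundary) &&
        (cfg$strata_boundary <= cfg$slr_interval[1] || cfg$strata_boundary >= cfg$slr_interval[2]))
      fail("strata_boundary", "must lie strictly inside slr_interval")
  }
  for (f in c("divergence_r1", "divergence_r2", "pch_repeat_frac",
              "background_repeat_frac", "hifi_error_rate")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) fail(f, "must be a probability in [0, 1]")
  }
  for (f in c("cen_monomer_len", "tel_monomer_len", "cen_copies", "tel_copies",
              "pch_mean_len", "pch_min_len"))
    if (cfg[[f]] <= 0) fail(f, "must be > 0")
  if (cfg$snp_density < 0 || cfg$snp_density > 1) fail("snp_density", "must be in [0, 1]")
  if (cfg$pch_min_len >= min(cfg$chrom_lengths))
    fail("pch_min_len", "PCH cannot be longer than the shortest chromosome")
  if (cfg$n_males < 0L || cfg$n_females < 0L) fail("n_males/n_females", "must be >= 0")
  if (nchar(cfg$cen_monomer) != cfg$cen_monomer_len)
    fail("cen_monomer", "length must equal cen_monomer_len")
  if (nchar(cfg$tel_monomer) != cfg$tel_monomer_len)
    fail("tel_monomer", "length must equal tel_monomer_len")
  invisible(cfg)
}

# Chromosome lengths (Mb) of the 24-chromosome preset. Total ~600 Mb with the
# submetacentric sex chromosome (index 6) fixed at 27.9 Mb.
.ZIGZAG_LENGTHS_MB <- c(
  46.5, 43.8, 41.2, 38.9, 36.7,        # metacentric
  27.9, 33.4, 31.2,                    # submetacentric (chr6 = XY)
  29.3, 27.6, 26.0, 24.5, 23.1, 21.8, 20.6, 19.5, 18.4, 17.4,
  16.5, 15.6, 14.8, 14.0, 13.3, 12.6   # telocentric
)

#' Preset emulating the zig-zag eel study system
#'
#' 24 chromosomes (~600 Mb total; 5 metacentric, 3 submetacentric, 16
#' telocentric), a 27.9-Mb submetacentric XY pair with the SLR planted over
#' 17-24 Mb spanning the centromere and PARs at both ends, strata boundary at
#' 20 Mb with per-base divergences 1.2% (R1) and 0.8% (R2) (~1% overall),
#' 524-bp centromeric and 190-bp telomere-associated satellite monomers,
#' PCH lengths ~ Normal(4.2 Mb, 0.5 Mb) truncated above 1 Mb with 55% repeat
#' coverage against a 15% background, 10 males + 10 females at ~1 SNP/kb, and
#' a 0.086% HiFi read error preset.
#'
#' @param seed Integer seed.
#' @param track_only Generate coordinate tracks only (no sequences); suitable
#'   for whole-genome scans.
#' @param ... Overrides passed through to [generator_config()].
#' @return A `generator_config`.
#' @export
zigzag_config <- function(seed = 1L, track_only = FALSE, ...) {
  args <- list(
    seed = seed,
    chrom_lengths = round(.ZIGZAG_LENGTHS_MB * 1e6),
    sex_chrom_index = 6L,
    slr_interval = c(17e6, 24e6),
    strata_boundary = 20e6,
    track_only = track_only
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(generator_config, args)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("generator_config:", x$n_chromosomes, "chromosomes,",
      sprintf("%.1f Mb total", sum(x$chrom_lengths) / 1e6),
      if (x$track_only) "(track-only)" else "", "\n")
  if (!is.null(x$slr_interval))
    cat(sprintf("  SLR: chr%d %.1f-%.1f Mb, strata boundary %.1f Mb (r1=%.3g, r2=%.3g)\n",
                x$sex_chrom_index, x$slr_interval[1] / 1e6, x$slr_interval[2] / 1e6,
                if (is.null(x$strata_boundary)) NA else x$strata_boundary / 1e6,
                x$divergence_r1, x$divergence_r2))
  cat(sprintf("  satellites: cen %d bp x %d, tel %d bp x %d; PCH ~%.1f Mb @ %d%% vs %d%%\n",
              x$cen_monomer_len, x$cen_copies, x$tel_monomer_len, x$tel_copies,
              x$pch_mean_len / 1e6, round(100 * x$pch_repeat_frac),
              round(100 * x$background_repeat_frac)))
  invisible(x)
}
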