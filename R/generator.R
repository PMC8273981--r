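# Synthetic diploid genome generator. Plants, with known ground truth, the
# structures the downstream modules are built to recover: a submetacentric XY
# pair whose SLR spans the centromere (PARs at both ends, two divergence
# strata), one centromeric satellite array per chromosome plus
# telomere-associated arrays and (TTAGGG)n termini, PCH blocks with elevated
# repeat coverage, and gene models. Interval coordinates are 0-based
# half-open; point positions (variant sites) are 1-based.

# Assign morphology classes in the study's 5:3:16 proportions, forcing the
# sex chromosome to be submetacentric.
.karyotype_classes <- function(n, sex_idx) {
  n_meta <- max(0L, round(n * 5 / 24))
  n_sub <- max(1L, round(n * 3 / 24))
  cls <- rep("telocentric", n)
  if (n_meta > 0L) cls[seq_len(min(n_meta, n))] <- "metacentric"
  sub_idx <- seq.int(n_meta + 1L, min(n_meta + n_sub, n))
  cls[sub_idx] <- "submetacentric"
  cls[sex_idx] <- "submetacentric"
  cls
}

# Alternating repeat/gap renewal process over [from, to); expected coverage
# equals `frac` exactly, so window-level repeat content concentrates tightly
# around the target.
.renewal_intervals <- function(from, to, frac, mean_len = 300, min_len = 50) {
  span <- to - from
  if (span <= 0 || frac <= 0) return(data.frame(start = numeric(0), end = numeric(0)))
  if (frac >= 1) return(data.frame(start = from, end = to))
  mean_gap <- mean_len * (1 - frac) / frac
  n <- ceiling(2 * span / (mean_len + mean_gap)) + 20L
  lens <- min_len + stats::rgeom(n, 1 / (mean_len - min_len + 1))
  gaps <- 1 + round(stats::rexp(n, 1 / mean_gap))
  starts <- from + cumsum(gaps) + c(0, cumsum(lens[-n]))
  ends <- starts + lens
  keep <- starts < to
  starts <- starts[keep]; ends <- pmin(ends[keep], to)
  data.frame(start = starts, end = ends)
}

# Sequential non-overlapping gene placement. Spacing is uniform along the
# chromosome (~one gene per 50 kb), matching the reported gene density of the
# gene-rich stratum; PCH gene-poverty is not emulated (see the methods
# vignette's limitations).
.place_genes <- function(chrom, L, pch, mean_gap = 4e4, mean_gap_pch = mean_gap) {
  genes <- list(); exons <- list()
  pos <- 3e4 + stats::rexp(1, 1 / mean_gap)
  i <- 0L
  in_pch <- function(p) nrow(pch) > 0 && any(p >= pch$start & p < pch$end)
  while (pos < L - 5e4) {
    n_ex <- sample(3:8, 1L)
    ex_len <- sample(120:400, n_ex, replace = TRUE)
    in_len <- if (n_ex > 1L) sample(500:3000, n_ex - 1L, replace = TRUE) else integer(0)
    glen <- sum(ex_len) + sum(in_len)
    if (pos + glen >= L - 3e4) break
    i <- i + 1L
    id <- sprintf("%s_g%04d", chrom, i)
    off <- cumsum(c(0, head(as.vector(rbind(ex_len, c(in_len, 0))), -1)))
    ex_start <- round(pos) + off[seq(1, by = 2, length.out = n_ex)]
    genes[[i]] <- data.frame(gene_id = id, chrom = chrom,
                             start = round(pos), end = round(pos) + glen,
                             strand = sample(c("+", "-"), 1L))
    exons[[i]] <- data.frame(gene_id = id, chrom = chrom,
                             start = ex_start, end = ex_start + ex_len)
    gap <- if (in_pch(pos + glen)) mean_gap_pch else mean_gap
    pos <- pos + glen + stats::rexp(1, 1 / gap)
  }
  list(genes = do.call(rbind, genes), exons = do.call(rbind, exons))
}

#' Generate a synthetic diploid genome with planted ground truth
#'
#' Builds the full input set for the pipeline: chromosome sequences (unless
#' `config$track_only`), per-chromosome metadata with centromere intervals and
#' morphology, a repeat annotation track, gene models, and a `truth` record
#' holding the realized coordinates of everything planted. On the sex
#' chromosome the Y haplotype is derived from the X by per-base substitution
#' inside the SLR at the two stratum rates; X and Y are identical outside the
#' SLR, so both chromosome ends are pseudoautosomal.
#'
#' @param config A [generator_config()].
#' @return A `genome_bundle`: list with elements `sequences` (per chromosome a
#'   named character vector `c(X=, Y=)`; autosomal haplotypes are identical;
#'   `NULL` in track-only mode), `meta` (data.frame: chrom, length, class,
#'   cen_start, cen_end), `repeat_track` (data.frame: chrom, start, end,
#'   class), `genes` (list of `genes` and `exons` data.frames) and `truth`.
#' @export
gen_genome <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  n <- config$n_chromosomes
  chroms <- paste0("chr", seq_len(n))
  lens <- config$chrom_lengths
  sex_idx <- config$sex_chrom_index
  classes <- .karyotype_classes(n, sex_idx)
  tel_motif_bp <- 300
  cen_w <- config$cen_copies * config$cen_monomer_len
  tel_w <- config$tel_copies * config$tel_monomer_len

  meta <- data.frame(chrom = chroms, length = lens, class = classes,
                     cen_start = NA_real_, cen_end = NA_real_)
  pch_truth <- list(); rep_track <- list(); gene_l <- list(); exon_l <- list()
  tel_sides <- vector("list", n)

  for (i in seq_len(n)) {
    L <- lens[i]
    if (cen_w + 2 * tel_w + 2 * tel_motif_bp >= L)
      stop("invalid generator_config: field 'chrom_lengths' chromosome ", i,
           " too short for planted satellite arrays", call. = FALSE)
    # centromere placement by morphology; on the sex chromosome inside the SLR
    if (i == sex_idx && !is.null(config$slr_interval)) {
      mid <- config$slr_interval[1] + 0.35 * diff(config$slr_interval)
      cs <- round(mid - cen_w / 2)
    } else if (classes[i] == "metacentric") {
      cs <- round(stats::runif(1, 0.42, 0.50) * L)
    } else if (classes[i] == "submetacentric") {
      cs <- round(stats::runif(1, 0.25, 0.35) * L)
    } else {
      cs <- tel_motif_bp
    }
    ce <- cs + cen_w
    meta$cen_start[i] <- cs; meta$cen_end[i] <- ce

    # PCH block around the centromere, shifted to fit inside the chromosome
    plen <- Inf
    for (try in 1:100) {
      plen <- stats::rnorm(1, config$pch_mean_len, config$pch_sd_len)
      if (plen > config$pch_min_len && plen < 0.8 * L) break
    }
    plen <- round(min(max(plen, config$pch_min_len), 0.8 * L))
    ps <- round((cs + ce) / 2 - plen / 2)
    ps <- min(max(ps, 0), L - plen)
    pch_i <- data.frame(chrom = chroms[i], start = ps, end = ps + plen)
    pch_truth[[i]] <- pch_i

    # telomere-associated arrays: both ends on metacentrics, otherwise the
    # end away from the centromere
    sides <- if (classes[i] == "metacentric") c("left", "right")
             else if (cs < L / 2) "right" else "left"
    tel_sides[[i]] <- sides
    sat <- data.frame(
      start = c(0, L - tel_motif_bp, cs,
                if ("left" %in% sides) tel_motif_bp,
                if ("right" %in% sides) L - tel_motif_bp - tel_w),
      end = c(tel_motif_bp, L, ce,
              if ("left" %in% sides) tel_motif_bp + tel_w,
              if ("right" %in% sides) L - tel_motif_bp),
      class = c("telomere", "telomere", "satellite_cen",
                rep("satellite_tel", length(sides))))
    # interspersed repeats: dense inside PCH, sparse background
    bg1 <- .renewal_intervals(0, ps, config$background_repeat_frac)
    inp <- .renewal_intervals(ps, ps + plen, config$pch_repeat_frac)
    bg2 <- .renewal_intervals(ps + plen, L, config$background_repeat_frac)
    isp <- rbind(bg1, inp, bg2)
    isp$class <- "interspersed"
    rt <- rbind(sat, isp)
    rt <- data.frame(chrom = chroms[i], rt[order(rt$start), ])
    rep_track[[i]] <- rt

    g <- .place_genes(chroms[i], L, pch_i)
    gene_l[[i]] <- g$genes; exon_l[[i]] <- g$exons
  }

  pch_truth <- do.call(rbind, pch_truth)
  repeat_track <- do.call(rbind, rep_track)
  rownames(repeat_track) <- NULL
  genes <- list(genes = do.call(rbind, gene_l), exons = do.call(rbind, exon_l))

  sequences <- NULL
  xy_diffs <- integer(0)
  if (!config$track_only) {
    sequences <- vector("list", n)
    names(sequences) <- chroms
    for (i in seq_len(n)) {
      L <- lens[i]
      r <- .random_seq_raw(L)
      r[1:tel_motif_bp] <- charToRaw(.telomere_motif(tel_motif_bp / 6, left = TRUE))
      r[(L - tel_motif_bp + 1):L] <- charToRaw(.telomere_motif(tel_motif_bp / 6))
      cen_seq <- tandem_array_seq(config$cen_monomer, config$cen_copies, 0.01)
      cs <- meta$cen_start[i]
      r[(cs + 1):(cs + cen_w)] <- charToRaw(cen_seq)
      for (side in tel_sides[[i]]) {
        ts <- tandem_array_seq(config$tel_monomer, config$tel_copies, 0.01)
        at <- if (side == "left") tel_motif_bp else L - tel_motif_bp - tel_w
        r[(at + 1):(at + tel_w)] <- charToRaw(ts)
      }
      x <- rawToChar(r)
      if (i == sex_idx && !is.null(config$slr_interval)) {
        sb <- if (is.null(config$strata_boundary)) config$slr_interval[1] else config$strata_boundary
        i1 <- (config$slr_interval[1] + 1):sb           # stratum R1, 1-based
        i2 <- (sb + 1):config$slr_interval[2]           # stratum R2
        y <- r
        m1 <- .mutate_raw(y[i1], config$divergence_r1)
        m2 <- .mutate_raw(y[i2], config$divergence_r2)
        y[i1] <- m1$seq; y[i2] <- m2$seq
        xy_diffs <- sort(c(m1$pos + config$slr_interval[1], m2$pos + sb))
        sequences[[i]] <- c(X = x, Y = rawToChar(y))
      } else {
        sequences[[i]] <- c(X = x, Y = x)
      }
    }
  }

  # genotypable X-Y sites: all realized differences in sequence mode, a
  # snp_density-thinned set in track-only mode
  xy_sites <- integer(0)
  if (!is.null(config$slr_interval)) {
    if (config$track_only) {
      slr_len <- diff(config$slr_interval)
      k <- stats::rbinom(1L, slr_len, config$snp_density)
      xy_sites <- sort(sample.int(slr_len, k)) + config$slr_interval[1]
    } else xy_sites <- xy_diffs
  }

  truth <- list(
    config = config,
    karyotype = meta,
    pch = pch_truth,
    slr = if (is.null(config$slr_interval)) NULL else
      list(chrom = chroms[sex_idx], start = config$slr_interval[1],
           end = config$slr_interval[2], strata_boundary = config$strata_boundary),
    xy_diffs = xy_diffs,
    xy_sites = xy_sites
  )

  structure(list(sequences = sequences, meta = meta,
                 repeat_track = repeat_track, genes = genes, truth = truth),
            class = "genome_bundle")
}

#' @export
print.genome_bundle <- function(x, ...) {
  cat("genome_bundle:", nrow(x$meta), "chromosomes,",
      sprintf("%.1f Mb", sum(x$meta$length) / 1e6),
      if (is.null(x$sequences)) "(track-only)" else "(with sequences)", "\n")
  if (!is.null(x$truth$slr))
    cat(sprintf("  SLR: %s %.1f-%.1f Mb (%d genotypable X-Y sites)\n",
                x$truth$slr$chrom, x$truth$slr$start / 1e6, x$truth$slr$end / 1e6,
                length(x$truth$xy_sites)))
  cat("  PCH blocks:", nrow(x$truth$pch),
      sprintf("(mean %.2f Mb); genes: %d\n",
              mean((x$truth$pch$end - x$truth$pch$start)) / 1e6,
              nrow(x$genes$genes)))
  invisible(x)
}

# Intron intervals (gene bodies minus exons), 0-based half-open.
#' Derive intron intervals from a bundle's gene models
#'
#' @param genes A list with `genes` and `exons` data.frames as produced by
#'   [gen_genome()].
#' @return data.frame with chrom, start, end of every intron.
#' @export
intron_intervals <- function(genes) {
  ex <- genes$exons
  ex <- ex[order(ex$gene_id, ex$start), ]
  sp <- split(ex, ex$gene_id)
  out <- lapply(sp, function(e) {
    if (nrow(e) < 2L) return(NULL)
    data.frame(chrom = e$chrom[1], start = e$end[-nrow(e)], end = e$start[-1])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[res$end > res$start, ]
}
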