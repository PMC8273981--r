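# Resequencing-design emulation: genotypes for n_males + n_females diploid
# individuals. Every planted X-Y difference in the SLR becomes a site that is
# heterozygous in all males and homozygous-reference in all females;
# background sites elsewhere follow Hardy-Weinberg at random allele
# frequencies.

#' Generate population genotypes with full sex linkage in the SLR
#'
#' @param bundle A `genome_bundle` with SLR truth.
#' @param config The generator config (defaults to the one inside `bundle`).
#' @param missing_rate Per-genotype missingness probability (default 0).
#' @return A `variant_table`: list with `sites` (data.frame chrom, pos
#'   (1-based), ref, alt), `geno` (sites x samples integer matrix, 0 = hom
#'   ref, 1 = het, 2 = hom alt, NA = missing) and `sex` (named character
#'   vector, "male"/"female").
#' @export
gen_population_genotypes <- function(bundle, config = bundle$truth$config,
                                     missing_rate = 0) {
  ns <- config$n_males + config$n_females
  if (ns < 1L) stop("zero samples: n_males + n_females must be >= 1", call. = FALSE)
  set.seed(config$seed + 11L)
  samples <- c(if (config$n_males > 0) paste0("M", seq_len(config$n_males)),
               if (config$n_females > 0) paste0("F", seq_len(config$n_females)))
  sex <- stats::setNames(rep(c("male", "female"), c(config$n_males, config$n_females)),
                         samples)
  slr <- bundle$truth$slr
  sites_l <- list(); geno_l <- list()
  for (i in seq_len(nrow(bundle$meta))) {
    chrom <- bundle$meta$chrom[i]
    L <- bundle$meta$length[i]
    k <- stats::rbinom(1L, L, config$snp_density)
    pos <- sort(sample.int(L, k))
    if (!is.null(slr) && chrom == slr$chrom)
      pos <- pos[pos <= slr$start | pos > slr$end]  # background outside the SLR
    if (length(pos)) {
      p <- stats::runif(length(pos), 0.05, 0.95)
      g <- matrix(stats::rbinom(length(pos) * ns, 2L, rep(p, ns)),
                  nrow = length(pos), ncol = ns)
      sites_l[[length(sites_l) + 1L]] <- data.frame(chrom = chrom, pos = pos)
      geno_l[[length(geno_l) + 1L]] <- g
    }
    if (!is.null(slr) && chrom == slr$chrom && length(bundle$truth$xy_sites)) {
      xp <- bundle$truth$xy_sites
      g <- matrix(rep(ifelse(sex == "male", 1L, 0L), each = length(xp)),
                  nrow = length(xp), ncol = ns)
      sites_l[[length(sites_l) + 1L]] <- data.frame(chrom = chrom, pos = xp)
      geno_l[[length(geno_l) + 1L]] <- g
    }
  }
  sites <- do.call(rbind, sites_l)
  geno <- do.call(rbind, geno_l)
  ord <- order(match(sites$chrom, bundle$meta$chrom), sites$pos)
  sites <- sites[ord, , drop = FALSE]
  geno <- geno[ord, , drop = FALSE]
  # ref from the assembled sequence where present, random otherwise
  bases <- c("A", "C", "G", "T")
  ref <- character(nrow(sites))
  if (!is.null(bundle$sequences)) {
    for (chrom in unique(sites$chrom)) {
      idx <- which(sites$chrom == chrom)
      r <- charToRaw(bundle$sequences[[chrom]][["X"]])
      ref[idx] <- strsplit(rawToChar(r[sites$pos[idx]]), "")[[1]]
    }
  } else ref <- sample(bases, nrow(sites), replace = TRUE)
  alt <- sample(bases, nrow(sites), replace = TRUE)
  clash <- alt == ref
  while (any(clash)) {
    alt[clash] <- sample(bases, sum(clash), replace = TRUE)
    clash <- alt == ref
  }
  sites$ref <- ref; sites$alt <- alt
  if (missing_rate > 0) {
    drop <- matrix(stats::runif(length(geno)) < missing_rate, nrow = nrow(geno))
    geno[drop] <- NA_integer_
  }
  colnames(geno) <- samples
  rownames(sites) <- NULL
  structure(list(sites = sites, geno = geno, sex = sex), class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat("variant_table:", nrow(x$sites), "biallelic sites x", ncol(x$geno),
      sprintf("samples (%d male, %d female)\n",
              sum(x$sex == "male"), sum(x$sex == "female")))
  invisible(x)
}
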