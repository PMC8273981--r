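# End-to-end orchestration: simulate -> k-mer profile -> satellites ->
# sex-linkage scan -> strata -> PCH/Hi-C -> expression, with a single
# structured report. Stages that need base-level sequences are skipped (with
# a note) on track-only bundles.

#' Run the full pipeline on a generator configuration
#'
#' Stages run in dependency order; every stage's summary lands in the report,
#' and rerunning with the same config reproduces it exactly. Module
#' thresholds can be overridden through `params` using module-qualified
#' names, e.g. `params = list(demarcate_slr = list(min_count = 5))`.
#'
#' @param config A `generator_config` (e.g. [zigzag_config()]), or a list
#'   with an element `generator` holding one plus optional `stages` /
#'   `params` / `outdir`.
#' @param stages Character vector of stages to run, a subset of
#'   `c("sexscan", "strata", "satellites", "kmer", "pch", "expr")`.
#' @param params Named list of per-operation argument overrides.
#' @param outdir Optional directory; when given, the standard files (FASTA,
#'   GFF3, BEDs, VCF, tracks, contact matrices, TSVs, report JSON) are
#'   written there.
#' @param kmer_coverage,kmer_read_len Read-simulation settings for the k-mer
#'   stage.
#' @return A `pipeline_report` list: config echo, per-stage summaries,
#'   package version.
#' @export
run_pipeline <- function(config,
                         stages = c("sexscan", "strata", "satellites",
                                    "kmer", "pch", "expr"),
                         params = list(), outdir = NULL,
                         kmer_coverage = 30, kmer_read_len = 5000) {
  if (!inherits(config, "generator_config")) {
    stages <- config$stages %||% stages
    params <- config$params %||% params
    outdir <- config$outdir %||% outdir
    config <- config$generator
  }
  stopifnot(inherits(config, "generator_config"))
  ov <- function(op, args) {
    extra <- params[[op]]
    if (!is.null(extra)) args[names(extra)] <- extra
    args
  }
  report <- list(config = config, stages = list(),
                 version = as.character(utils::packageVersion("slrscape")))
  bundle <- gen_genome(config)
  report$stages$simulate <- list(
    n_chromosomes = nrow(bundle$meta),
    genome_bp = sum(bundle$meta$length),
    track_only = is.null(bundle$sequences),
    pch_blocks = nrow(bundle$truth$pch))
  has_seq <- !is.null(bundle$sequences)
  slr_call <- NULL

  if ("sexscan" %in% stages) {
    vt <- gen_population_genotypes(bundle)
    sss <- do.call(call_sex_specific_snps, ov("call_sex_specific_snps", list(vt = vt)))
    dens <- do.call(window_counts, ov("window_counts",
                                      list(sites = sss, chrom_meta = bundle$meta)))
    slr_call <- do.call(demarcate_slr, ov("demarcate_slr", list(track = dens)))
    fst <- do.call(window_fst, ov("window_fst",
                                  list(vt = vt, chrom_meta = bundle$meta)))
    assoc <- do.call(assoc_scan, ov("assoc_scan", list(vt = vt)))
    report$stages$sexscan <- list(
      n_sites = nrow(vt$sites), n_sex_specific = nrow(sss),
      slr = list(chrom = slr_call$chrom, start = slr_call$start,
                 end = slr_call$end),
      max_fst = suppressWarnings(max(fst$value, na.rm = TRUE)),
      max_neglog10p = max(assoc$neglog10p))
    if (!is.null(outdir)) {
      write_variant_vcf(vt, file.path(outdir, "variants.vcf.gz"))
      write_bedgraph(dens, file.path(outdir, "male_specific_density.bedGraph"))
      write_bedgraph(fst, file.path(outdir, "fst.bedGraph"))
      data.table::fwrite(assoc, file.path(outdir, "association.tsv"), sep = "\t")
    }
  }

  if ("strata" %in% stages) {
    if (!has_seq || is.null(bundle$truth$slr)) {
      report$stages$strata <- list(note = "skipped: needs sequences and an SLR")
    } else {
      sx <- bundle$sequences[[bundle$truth$slr$chrom]]
      introns <- intron_intervals(bundle$genes)
      introns <- introns[introns$chrom == bundle$truth$slr$chrom, ]
      sim <- do.call(xy_window_similarity, ov("xy_window_similarity", list(
        x_seq = sx[["X"]], y_seq = sx[["Y"]], introns = introns,
        chrom = bundle$truth$slr$chrom)))
      iv <- if (!is.null(slr_call) && !is.na(slr_call$chrom))
        c(slr_call$start, slr_call$end)
      else c(bundle$truth$slr$start, bundle$truth$slr$end)
      st <- do.call(segment_strata, ov("segment_strata",
                                       list(similarity = sim, slr_interval = iv)))
      report$stages$strata <- list(
        two_strata = st$two_strata, wilcoxon_p = st$wilcoxon_p,
        selection_p = st$selection_p, boundary = st$boundary,
        strata = st$strata)
      if (!is.null(outdir)) {
        write_bedgraph(sim, file.path(outdir, "xy_similarity.bedGraph"))
        sdf <- st$strata; sdf$chrom <- bundle$truth$slr$chrom
        sdf$name <- sdf$name
        write_bed(sdf[, c("chrom", "start", "end", "name")],
                  file.path(outdir, "strata.bed"))
      }
    }
  }

  if ("satellites" %in% stages) {
    if (!has_seq) {
      report$stages$satellites <- list(note = "skipped: needs sequences")
    } else {
      seqs <- vapply(bundle$sequences, function(s) s[["X"]], character(1))
      arrays <- do.call(find_tandem_arrays,
                        ov("find_tandem_arrays", list(seqs = seqs)))
      fams <- build_families(arrays)
      fams <- do.call(classify_families, ov("classify_families", list(
        families = fams, chrom_meta = bundle$meta)))
      cens <- tryCatch(locate_centromeres(fams, bundle$meta),
                       error = function(e) NULL)
      morph <- if (!is.null(cens)) classify_morphology(cens, bundle$meta)
      report$stages$satellites <- list(
        n_arrays = nrow(arrays), n_families = nrow(fams),
        families = fams[, c("family", "monomer_len", "total_bp", "label")],
        morphology_counts = if (!is.null(morph)) as.list(attr(morph, "counts")))
      if (!is.null(outdir)) {
        data.table::fwrite(as.data.frame(fams),
                           file.path(outdir, "satellite_families.tsv"), sep = "\t")
        write_bed(arrays[, c("chrom", "start", "end")],
                  file.path(outdir, "tandem_arrays.bed"))
        if (!is.null(morph))
          data.table::fwrite(morph, file.path(outdir, "karyotype.tsv"), sep = "\t")
      }
    }
  }

  if ("kmer" %in% stages) {
    if (!has_seq) {
      report$stages$kmer <- list(note = "skipped: needs sequences")
    } else {
      reads <- gen_kmer_reads(bundle, coverage = kmer_coverage,
                              read_len = kmer_read_len,
                              error_rate = config$hifi_error_rate,
                              seed = config$seed + 101L)
      spec <- do.call(count_kmers, ov("count_kmers", list(reads = reads, k = 21L)))
      fit <- fit_spectrum(spec)
      report$stages$kmer <- list(
        genome_size_bp = fit$genome_size_bp, error_rate = fit$error_rate,
        valley = fit$valley, hom_coverage = fit$hom_coverage)
      if (!is.null(outdir))
        data.table::fwrite(spec$histogram, file.path(outdir, "kmer_spectrum.tsv"),
                           sep = "\t")
    }
  }

  pch_blocks <- NULL
  if ("pch" %in% stages) {
    rc <- do.call(repeat_content_track, ov("repeat_content_track", list(
      repeats = bundle$repeat_track, chrom_meta = bundle$meta)))
    cen <- data.frame(chrom = bundle$meta$chrom,
                      cen_start = bundle$meta$cen_start,
                      cen_end = bundle$meta$cen_end)
    pch_blocks <- do.call(call_pch, ov("call_pch", list(
      track = rc, centromeres = cen)))
    epi <- gen_epigenome(bundle, chroms = bundle$meta$chrom[
      min(nrow(bundle$meta), bundle$truth$config$sex_chrom_index)])
    enr <- do.call(peak_enrichment, ov("peak_enrichment", list(
      peaks = epi$peaks, pch_blocks = pch_blocks, chrom_meta = bundle$meta)))
    cmname <- names(epi$matrices)[1]
    bal <- balance_matrix(epi$matrices[[cmname]])
    gw <- bundle$genes$genes[bundle$genes$genes$chrom == cmname, ]
    nb <- ceiling(bundle$meta$length[bundle$meta$chrom == cmname] / 2.5e5)
    gd <- tabulate(pmin(floor((gw$start + gw$end) / 2 / 2.5e5) + 1L, nb), nb)
    comp <- do.call(oe_pearson_pc1, ov("oe_pearson_pc1", list(
      cm = bal, gene_density = gd)))
    dsc <- do.call(distance_stratified_contacts, ov(
      "distance_stratified_contacts", list(cm = bal, pch_blocks = pch_blocks)))
    corr <- tryCatch(pch_size_correlation(pch_blocks, bundle$meta),
                     error = function(e) list(r = NA, p = NA, note = conditionMessage(e)))
    report$stages$pch <- list(
      n_blocks = nrow(pch_blocks),
      mean_block_mb = mean(pch_blocks$end - pch_blocks$start) / 1e6,
      genome_fraction = attr(pch_blocks, "summary")$genome_fraction,
      peak_enrichment = enr, contact_p = dsc$p,
      size_correlation = corr[c("r", "p")],
      n_compartment_A = sum(comp$label == "A", na.rm = TRUE))
    if (!is.null(outdir)) {
      write_bed(pch_blocks[, c("chrom", "start", "end")],
                file.path(outdir, "pch_blocks.bed"))
      pk <- epi$peaks; pk$score <- pk$score
      write_bed(pk, file.path(outdir, "h3k9me3_peaks.bed"))
      write_contact_matrix(bal, file.path(outdir, paste0(cmname, "_balanced.txt")))
      write_bedgraph(stats::setNames(comp[, c("chrom", "start", "end", "pc1")],
                                     c("chrom", "start", "end", "value")),
                     file.path(outdir, "pc1.bedGraph"))
    }
  }

  if ("expr" %in% stages) {
    ge <- gen_expression(bundle)
    tp <- tpm(ge$counts, ge$lengths)
    gonly <- ge$samples$group %in% c("testis", "ovary", "intersex")
    tauv <- tau(tp, ge$samples$group)
    slr <- bundle$truth$slr
    slr_genes <- if (!is.null(slr)) {
      g <- bundle$genes$genes
      g$gene_id[g$chrom == slr$chrom &
                (g$start + g$end) / 2 >= slr$start &
                (g$start + g$end) / 2 < slr$end]
    }
    cand <- screen_candidates(tp[, gonly, drop = FALSE],
                              ge$samples[gonly, ], slr_genes = slr_genes)
    pchcmp <- if (!is.null(pch_blocks))
      pch_expression_compare(tp, pch_blocks, bundle$genes$genes,
                             groups = ge$samples$group)
    report$stages$expr <- list(
      n_genes = nrow(tp), n_samples = ncol(tp),
      n_candidates = sum(cand$pattern != "none"),
      candidates = cand[cand$pattern != "none", c("gene", "pattern")],
      median_tau = stats::median(tauv, na.rm = TRUE),
      pch_comparison = if (!is.null(pchcmp)) pchcmp[c("p_tpm", "p_tau", "note")])
    if (!is.null(outdir)) {
      data.table::fwrite(data.frame(gene = rownames(tp), tp),
                         file.path(outdir, "tpm.tsv"), sep = "\t")
      data.table::fwrite(data.frame(gene = names(tauv), tau = tauv),
                         file.path(outdir, "tau.tsv"), sep = "\t")
      jsonlite::write_json(cand, file.path(outdir, "candidates.json"),
                           dataframe = "rows", auto_unbox = TRUE, digits = NA)
      write_sample_sheet(ge$samples, file.path(outdir, "samples.tsv"))
    }
  }

  if (!is.null(outdir))
    jsonlite::write_json(.report_jsonable(report),
                         file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  class(report) <- "pipeline_report"
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# strip non-serializable bits (the config class is fine; data.frames become
# row-wise records)
.report_jsonable <- function(report) {
  report$config <- unclass(report$config)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report (slrscape", x$version, ")\n")
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    cat(" -", nm, ": ")
    if (!is.null(s$note)) cat(s$note, "\n")
    else if (nm == "sexscan" && !is.null(s$slr$chrom) && !is.na(s$slr$chrom))
      cat(sprintf("SLR %s %.2f-%.2f Mb, %d sex-specific sites\n",
                  s$slr$chrom, s$slr$start / 1e6, s$slr$end / 1e6, s$n_sex_specific))
    else cat(length(s), "summary fields\n")
  }
  invisible(x)
}
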