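# I/O boundaries. Internal coordinates are 0-based half-open intervals and
# 1-based point positions; conversions to the 1-based closed conventions of
# FASTA/GFF3/VCF happen here. Standard formats go through Biostrings,
# rtracklayer and vcfR.

#' Write bundle haplotype sequences as FASTA
#'
#' Both haplotypes of every chromosome are written, named `chrN_X` /
#' `chrN_Y`.
#'
#' @param bundle A `genome_bundle` with sequences.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(bundle, path) {
  if (is.null(bundle$sequences)) stop("bundle has no sequences", call. = FALSE)
  seqs <- unlist(lapply(names(bundle$sequences), function(ch) {
    s <- bundle$sequences[[ch]]
    stats::setNames(as.character(s), paste0(ch, "_", names(s)))
  }))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

# data.frame (0-based half-open) -> GRanges (1-based closed)
.df_to_gr <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1, df$end))
}

#' Write intervals as BED
#'
#' @param df data.frame with chrom, start, end (0-based half-open), optional
#'   `name` and `score` columns (the peak writer puts -log10 p in score).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  gr <- .df_to_gr(df)
  if (!is.null(df$name)) names(gr) <- df$name
  if (!is.null(df$score)) gr$score <- df$score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED file into a 0-based half-open data.frame
#'
#' @param path BED path.
#' @return data.frame chrom, start, end (+ name/score when present).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr))
  if (!is.null(gr$name)) df$name <- gr$name
  if (!is.null(gr$score)) df$score <- gr$score
  df
}

#' Write a window track as bedGraph
#'
#' @param track Window track data.frame (chrom, start, end, value).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  t2 <- track[!is.na(track$value), , drop = FALSE]
  gr <- .df_to_gr(t2)
  gr$score <- t2$value
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write gene models as GFF3
#'
#' @param genes List with `genes` and `exons` data.frames (a bundle's
#'   `genes`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genes_gff3 <- function(genes, path) {
  g <- genes$genes; e <- genes$exons
  gr_g <- .df_to_gr(g)
  gr_g$type <- "gene"; gr_g$ID <- g$gene_id
  S4Vectors::mcols(gr_g)$source <- "slrscape"
  gr_e <- .df_to_gr(e)
  gr_e$type <- "exon"; gr_e$Parent <- e$gene_id
  S4Vectors::mcols(gr_e)$source <- "slrscape"
  gr <- c(gr_g, gr_e)
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' Write a variant table as VCF v4.2 (GT only)
#'
#' @param vt A `variant_table`.
#' @param path Output path (`.vcf.gz` is produced by vcfR).
#' @return The path written, invisibly.
#' @export
write_variant_vcf <- function(vt, path) {
  n <- nrow(vt$sites)
  fix <- cbind(CHROM = vt$sites$chrom, POS = as.character(vt$sites$pos),
               ID = rep(".", n), REF = vt$sites$ref, ALT = vt$sites$alt,
               QUAL = rep(".", n), FILTER = rep("PASS", n), INFO = rep(".", n))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[vt$geno + 1L], nrow = n)
  gt_str[is.na(vt$geno)] <- "./."
  gt <- cbind(FORMAT = rep("GT", n), gt_str)
  colnames(gt) <- c("FORMAT", colnames(vt$geno))
  obj <- suppressMessages(methods::new(methods::getClassDef("vcfR", package = "vcfR"),
                      meta = c("##fileformat=VCFv4.2",
                               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
                      fix = fix, gt = gt))
  vcfR::write.vcf(obj, file = path)
  invisible(path)
}

#' Read a VCF into a variant table
#'
#' Keeps biallelic SNPs only; genotypes are coded by alt-allele dosage.
#'
#' @param path VCF path.
#' @param sex Named character vector ("male"/"female") for the sample
#'   columns.
#' @return A `variant_table`.
#' @export
read_variant_vcf <- function(path, sex) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  fix <- vcfR::getFIX(v)[bi, , drop = FALSE]
  gt <- vcfR::extract.gt(v)[bi, , drop = FALSE]
  code <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  code[gt %in% c("0/0", "0|0")] <- 0L
  code[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  code[gt %in% c("1/1", "1|1")] <- 2L
  sites <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"])
  rownames(sites) <- NULL
  structure(list(sites = sites, geno = code, sex = sex[colnames(code)]),
            class = "variant_table")
}

#' Write a contact matrix as 3-column text plus a JSON sidecar
#'
#' Upper-triangle entries (including the diagonal) with nonzero counts are
#' written as `bin_i bin_j count` (0-based bins); `<path>.json` records the
#' chromosome, bin size and bin count.
#'
#' @param cm A `contact_matrix`.
#' @param path Output path for the matrix text.
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(cm, path) {
  ut <- which(upper.tri(cm$counts, diag = TRUE) & cm$counts != 0, arr.ind = TRUE)
  dt <- data.table::data.table(bin_i = ut[, 1] - 1L, bin_j = ut[, 2] - 1L,
                               count = cm$counts[ut])
  data.table::fwrite(dt, path, sep = "\t")
  jsonlite::write_json(list(chrom = cm$chrom, bin_size = cm$bin_size,
                            n_bins = nrow(cm$counts)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a contact matrix written by [write_contact_matrix()]
#'
#' @param path Matrix text path (expects `<path>.json` alongside).
#' @return A `contact_matrix`.
#' @export
read_contact_matrix <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  dt <- data.table::fread(path)
  n <- meta$n_bins
  A <- matrix(0, n, n)
  A[cbind(dt$bin_i + 1L, dt$bin_j + 1L)] <- dt$count
  A[cbind(dt$bin_j + 1L, dt$bin_i + 1L)] <- dt$count
  contact_matrix(meta$chrom, meta$bin_size, A)
}

#' Write (and read) a sample sheet TSV
#'
#' @param samples data.frame (sample, group, stage, or sample, sex).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(samples, path) {
  data.table::fwrite(samples, path, sep = "\t")
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  as.data.frame(data.table::fread(path))
}
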