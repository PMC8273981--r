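# Tandem satellite detection and karyotype classification.
#
# The detector is self-contained (no external tandem-repeat finder): for each
# candidate period p it compares the sequence with itself shifted by p and
# reports maximal stretches whose mismatch fraction stays within tolerance,
# assigning each stretch the smallest period that explains it. Families are
# built by grouping rotation/strand-canonicalized monomers, then labeled
# centromeric or telomere-associated from their chromosomal distribution.

#' Detect tandem repeat arrays
#'
#' For each period `p` in `[min_period, max_period]` (ascending, so the
#' smallest explaining period wins) the sequence is compared against itself
#' shifted by `p`; positions are marked where a `p`-wide window of the
#' shift-mismatch indicator has mismatch fraction at most `max_mismatch`, and
#' maximal marked stretches become arrays. Arrays shorter than two periods
#' are suppressed, as are arrays mostly covered by an already accepted
#' smaller-period array (harmonic suppression).
#'
#' @param seqs Character vector of sequences (names become chromosome ids).
#' @param min_period,max_period Period search range in bp.
#' @param max_mismatch Maximum tolerated mismatch fraction between copies.
#' @param min_len Minimum array length in bp (default 50): a significance
#'   floor below which short-period two-copy matches arise by chance in
#'   random sequence.
#' @return A data.frame (class `tandem_arrays`) with chrom, start, end
#'   (0-based half-open), period, copy_number, mismatch_frac, consensus (the
#'   per-column majority monomer).
#' @export
find_tandem_arrays <- function(seqs, min_period = 10L, max_period = 2000L,
                               max_mismatch = 0.2, min_len = 50L) {
  stopifnot(min_period >= 2L, min_period <= max_period)
  nm <- names(seqs)
  seqs <- as.character(seqs)
  names(seqs) <- if (is.null(nm)) paste0("seq", seq_along(seqs)) else nm
  out <- list()
  for (chrom in names(seqs)) {
    r <- charToRaw(toupper(seqs[[chrom]]))
    L <- length(r)
    covered <- logical(L)
    for (p in min_period:min(max_period, floor(L / 2))) {
      d <- r[seq_len(L - p)] != r[(p + 1L):L]
      nw <- L - 2L * p + 1L           # window starts: comparisons i..i+p-1
      if (nw < 1L) break
      cm <- c(0, cumsum(d))
      wf <- (cm[(p + 1L):(L - p + 1L)] - cm[seq_len(nw)]) / p
      good <- which(wf <= max_mismatch)
      if (length(good) == 0L) next
      # group good window starts whose 2p-wide spans overlap
      grp <- cumsum(c(1L, diff(good) > 2L * p))
      for (j in unique(grp)) {
        i1 <- min(good[grp == j]); i2 <- max(good[grp == j])
        # trim until the overall mismatch fraction meets the tolerance
        while (i2 > i1 && (cm[i2 + p] - cm[i1]) / (i2 + p - i1) > max_mismatch) {
          if (d[i1]) i1 <- i1 + 1L else i2 <- i2 - 1L
        }
        b1 <- i1; b2 <- i2 + 2L * p - 1L
        len <- b2 - b1 + 1L
        if (len < max(2L * p, min_len)) next
        if (mean(covered[b1:b2]) > 0.5) next
        covered[b1:b2] <- TRUE
        ncop <- floor(len / p)
        cons <- .majority_consensus(r[b1:(b1 + ncop * p - 1L)], p, ncop)
        mmf <- (cm[i2 + p] - cm[i1]) / (i2 + p - i1)
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = b1 - 1L, end = b2, period = p,
          copy_number = len / p, mismatch_frac = mmf, consensus = cons)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               period = integer(0), copy_number = numeric(0),
               mismatch_frac = numeric(0), consensus = character(0))
  res <- res[order(match(res$chrom, names(seqs)), res$start), ]
  rownames(res) <- NULL
  class(res) <- c("tandem_arrays", "data.frame")
  res
}

# Per-column majority over the stacked copies of an array.
.majority_consensus <- function(r, p, ncop) {
  m <- matrix(as.integer(r), nrow = p)
  cons <- vapply(seq_len(p), function(i) {
    tb <- tabulate(.BASE_LUT[m[i, ] + 1L] + 1L, 4L)
    which.max(tb)
  }, integer(1))
  rawToChar(.BASE_RAW[cons])
}

#' Canonical form of a satellite monomer
#'
#' The lexicographically smallest string among all rotations of the monomer
#' and all rotations of its reverse complement; invariant to array phase and
#' strand, and idempotent.
#'
#' @param monomer A non-empty string over A/C/G/T/N.
#' @return The canonical monomer string.
#' @export
canonical_monomer <- function(monomer) {
  m <- toupper(monomer)
  if (nchar(m) == 0L) stop("empty monomer", call. = FALSE)
  if (grepl("[^ACGTN]", m)) stop("monomer contains non-ACGTN characters", call. = FALSE)
  n <- nchar(m)
  rots <- function(s) {
    d <- paste0(s, s)
    vapply(seq_len(n), function(i) substr(d, i, i + n - 1L), character(1))
  }
  min(c(rots(m), rots(revcomp(m))))
}

# Best identity between two monomers over all rotations of the shorter one,
# compared over min-length prefixes.
.rotation_identity <- function(m1, m2) {
  if (nchar(m1) < nchar(m2)) { tmp <- m1; m1 <- m2; m2 <- tmp }
  r1 <- charToRaw(m1); r2 <- charToRaw(m2)
  n2 <- length(r2)
  d2 <- c(r2, r2)
  best <- 0
  for (off in 0:(n2 - 1L)) {
    id <- mean(r1[seq_len(n2)] == d2[(off + 1L):(off + n2)])
    if (id > best) best <- id
    if (best >= 0.999) break
  }
  best
}

#' Group tandem arrays into satellite families
#'
#' Arrays are merged into a family when their canonical monomers have lengths
#' within `len_tol` of each other and sequence identity of at least
#' `min_identity` (computed over rotations). Families are ranked by total
#' genomic span.
#'
#' @param arrays A `tandem_arrays` data.frame carrying consensus monomers.
#' @param min_identity Minimum monomer identity to merge (default 0.8).
#' @param len_tol Maximum relative monomer length difference (default 0.1).
#' @param top_n Report only the `top_n` largest families (default all).
#' @return A data.frame (class `satellite_families`) with family, monomer_len,
#'   total_bp, copy_number, n_loci, label (`NA` until
#'   [classify_families()]), canonical_monomer; attribute `loci` holds the
#'   member arrays per family.
#' @export
build_families <- function(arrays, min_identity = 0.8, len_tol = 0.1, top_n = Inf) {
  if (nrow(arrays) == 0L) {
    fam <- data.frame(family = character(0), monomer_len = integer(0),
                      total_bp = numeric(0), copy_number = numeric(0),
                      n_loci = integer(0), label = character(0),
                      canonical_monomer = character(0))
    class(fam) <- c("satellite_families", "data.frame")
    return(fam)
  }
  ord <- order(arrays$end - arrays$start, decreasing = TRUE)
  canon <- vapply(arrays$consensus, canonical_monomer, character(1), USE.NAMES = FALSE)
  fam_of <- integer(nrow(arrays))
  reps <- character(0)   # representative canonical monomer per family
  for (i in ord) {
    assigned <- 0L
    for (f in seq_along(reps)) {
      n1 <- nchar(canon[i]); n2 <- nchar(reps[f])
      if (abs(n1 - n2) / max(n1, n2) > len_tol) next
      if (.rotation_identity(canon[i], reps[f]) >= min_identity) { assigned <- f; break }
    }
    if (assigned == 0L) { reps <- c(reps, canon[i]); assigned <- length(reps) }
    fam_of[i] <- assigned
  }
  tot <- tapply(arrays$end - arrays$start, fam_of, sum)
  rank_ord <- order(tot, decreasing = TRUE)
  loci <- list(); rows <- list()
  for (k in seq_along(rank_ord)) {
    f <- as.integer(names(tot))[rank_ord[k]]
    memb <- arrays[fam_of == f, , drop = FALSE]
    id <- paste0("S", k)
    loci[[id]] <- memb
    rows[[k]] <- data.frame(
      family = id, monomer_len = nchar(reps[f]),
      total_bp = sum(memb$end - memb$start),
      copy_number = sum(memb$copy_number), n_loci = nrow(memb),
      label = NA_character_, canonical_monomer = reps[f])
  }
  fam <- do.call(rbind, rows)
  keep <- seq_len(min(top_n, nrow(fam)))
  fam <- fam[keep, , drop = FALSE]
  rownames(fam) <- NULL
  attr(fam, "loci") <- loci[fam$family]
  class(fam) <- c("satellite_families", "data.frame")
  fam
}

# Merge a family's loci on one chromosome into clusters (gap <= cluster_gap).
.family_clusters <- function(loci, cluster_gap) {
  res <- list()
  for (chrom in unique(loci$chrom)) {
    l <- loci[loci$chrom == chrom, , drop = FALSE]
    l <- l[order(l$start), ]
    grp <- cumsum(c(1, l$start[-1] > cummax(l$end)[-nrow(l)] + cluster_gap))
    for (g in unique(grp)) {
      m <- l[grp == g, , drop = FALSE]
      res[[length(res) + 1L]] <- data.frame(
        chrom = chrom, start = min(m$start), end = max(m$end),
        bp = sum(m$end - m$start), n_loci = nrow(m))
    }
  }
  do.call(rbind, res)
}

#' Label satellite families as centromeric or telomere-associated
#'
#' Loci are merged into clusters per chromosome (gap at most `cluster_gap`).
#' A family is centromeric when, on at least 70% of the chromosomes carrying
#' it, it forms exactly one cluster, and on at least one
#' metacentric/submetacentric chromosome that single cluster is interior
#' (more than `end_margin` from both ends). A family is telomere-associated
#' when at least 90% of its clusters lie within `end_margin` of a chromosome
#' end. Everything else is `other`.
#'
#' @param families A `satellite_families` object.
#' @param chrom_meta data.frame with chrom, length and optionally a `class`
#'   morphology column (without it, every chromosome may satisfy the interior
#'   requirement).
#' @param end_margin Distance from a chromosome end defining "terminal"
#'   (default 200 kb).
#' @param cluster_gap Maximum gap between loci in one cluster (default 500 kb).
#' @return The families data.frame with `label` filled in; attribute
#'   `clusters` holds per-family cluster tables.
#' @export
classify_families <- function(families, chrom_meta, end_margin = 2e5,
                              cluster_gap = 5e5) {
  loci_all <- attr(families, "loci")
  clusters <- list()
  for (i in seq_len(nrow(families))) {
    id <- families$family[i]
    cl <- .family_clusters(loci_all[[id]], cluster_gap)
    cl$chrom_len <- chrom_meta$length[match(cl$chrom, chrom_meta$chrom)]
    if (anyNA(cl$chrom_len))
      stop("array chromosomes not found in chrom_meta: ",
           paste(unique(cl$chrom[is.na(cl$chrom_len)]), collapse = ", "),
           call. = FALSE)
    cl$terminal <- cl$start < end_margin | cl$end > cl$chrom_len - end_margin
    clusters[[id]] <- cl
    per_chrom <- table(cl$chrom)
    frac_single <- mean(per_chrom == 1L)
    single_chroms <- names(per_chrom)[per_chrom == 1L]
    eligible <- if ("class" %in% names(chrom_meta))
      chrom_meta$chrom[chrom_meta$class %in% c("metacentric", "submetacentric")]
    else chrom_meta$chrom
    interior_ok <- any(vapply(single_chroms, function(ch) {
      row <- cl[cl$chrom == ch, , drop = FALSE]
      ch %in% eligible && !row$terminal[1]
    }, logical(1)))
    if (frac_single >= 0.7 && interior_ok) {
      families$label[i] <- "centromeric"
    } else if (mean(cl$terminal) >= 0.9) {
      families$label[i] <- "telomere-associated"
    } else families$label[i] <- "other"
  }
  attr(families, "clusters") <- clusters
  families
}

#' Locate centromeres from the centromeric satellite family
#'
#' The centromere of each chromosome is the span of the single cluster of the
#' centromeric family on it. Chromosomes without a cluster are flagged
#' unresolved (incomplete assembly); with several clusters the one with the
#' largest total satellite span is chosen and a tie flag is raised when the
#' runner-up is equal.
#'
#' @param families Labeled families from [classify_families()].
#' @param chrom_meta data.frame with chrom and length.
#' @return data.frame chrom, cen_start, cen_end, resolved, tie.
#' @export
locate_centromeres <- function(families, chrom_meta) {
  idx <- which(families$label == "centromeric")
  if (length(idx) == 0L) stop("no centromeric-labeled family", call. = FALSE)
  cl <- attr(families, "clusters")[[families$family[idx[1]]]]
  out <- data.frame(chrom = chrom_meta$chrom, cen_start = NA_real_,
                    cen_end = NA_real_, resolved = FALSE, tie = FALSE)
  for (i in seq_len(nrow(out))) {
    cc <- cl[cl$chrom == out$chrom[i], , drop = FALSE]
    if (nrow(cc) == 0L) next
    best <- which.max(cc$bp)
    out$tie[i] <- sum(cc$bp == cc$bp[best]) > 1L
    out$cen_start[i] <- cc$start[best]
    out$cen_end[i] <- cc$end[best]
    out$resolved[i] <- TRUE
  }
  out
}

#' Classify chromosome morphology from centromere position
#'
#' Arm ratio (long over short arm, short arm floored at 1 bp) thresholds
#' following the Levan convention collapsed to three classes: metacentric
#' (ratio <= 1.7), submetacentric (1.7 < ratio <= 3), telocentric (> 3).
#' Chromosomes with an unresolved centromere get `NA`.
#'
#' @param centromeres data.frame from [locate_centromeres()] (or any with
#'   chrom, cen_start, cen_end).
#' @param chrom_meta data.frame with chrom and length.
#' @return data.frame chrom, length, cen_mid, arm_ratio, class; attribute
#'   `counts` tabulates the classes.
#' @export
classify_morphology <- function(centromeres, chrom_meta) {
  m <- merge(chrom_meta[, c("chrom", "length")], centromeres, by = "chrom",
             sort = FALSE)
  mid <- (m$cen_start + m$cen_end) / 2
  short <- pmax(pmin(mid, m$length - mid), 1)
  long <- pmax(mid, m$length - mid)
  ratio <- long / short
  cls <- ifelse(ratio <= 1.7, "metacentric",
                ifelse(ratio <= 3, "submetacentric", "telocentric"))
  cls[is.na(mid)] <- NA_character_
  out <- data.frame(chrom = m$chrom, length = m$length, cen_mid = mid,
                    arm_ratio = ratio, class = cls)
  attr(out, "counts") <- table(factor(cls, c("metacentric", "submetacentric",
                                             "telocentric")))
  out
}
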