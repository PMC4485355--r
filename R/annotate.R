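#' Genomic categories
#'
#' Each site anchor is assigned exactly one category relative to the gene
#' models, by precedence:
#' `TSS_region > Promoter > Downstream > UTR5 > CodingExon > Intron >
#' Intergenic`.
#'
#' Definitions (all on the anchor point, `tss_window` defaults to 200 bp,
#' `flank` to 2000 bp):
#' * `TSS_region`: within `tss_window` bp of any TSS, either side.
#' * `Promoter`: within `flank` bp upstream (strand-aware) of the TSS region.
#' * `Downstream`: within `flank` bp past the TTS (strand-aware).
#' * `UTR5`: exonic and 5' of the first CDS base (genes with CDS only).
#' * `CodingExon`: any other exonic anchor (CDS, or exon of a non-coding
#'   gene; 3' untranslated exonic sequence also falls here).
#' * `Intron`: inside the gene span but not exonic.
#' * `Intergenic`: none of the above, for every gene.
#'
#' @name genomic_categories
#' @keywords internal
NULL

.GENOMIC_CATEGORIES <- c("TSS_region", "Promoter", "Downstream", "UTR5",
                         "CodingExon", "Intron", "Intergenic")

# Per-gene category regions as 0-based closed position ranges [lo, hi]
# (positions, not intervals: an anchor is a single base). Returns a
# data.table(chrom, lo, hi, rank).
.category_regions <- function(genes, tss_window, flank) {
  n <- nrow(genes)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    st <- genes$strand[i]; tss <- genes$tss[i]; tts <- genes$tts[i]
    ex <- genes$exons[[i]]; cd <- genes$cds[[i]]
    reg <- list()
    reg[[length(reg) + 1L]] <- c(tss - tss_window, tss + tss_window, 1)
    if (st == "+") {
      reg[[length(reg) + 1L]] <- c(tss - tss_window - flank,
                                   tss - tss_window - 1, 2)
      reg[[length(reg) + 1L]] <- c(tts + 1, tts + flank, 3)
    } else {
      reg[[length(reg) + 1L]] <- c(tss + tss_window + 1,
                                   tss + tss_window + flank, 2)
      reg[[length(reg) + 1L]] <- c(tts - flank, tts - 1, 3)
    }
    # exonic categories; half-open exon [s,e) -> closed positions [s, e-1]
    if (!is.null(cd) && nrow(cd)) {
      cds_lo <- min(cd[, 1L]); cds_hi <- max(cd[, 2L]) - 1
      for (j in seq_len(nrow(ex))) {
        s <- ex[j, 1L]; e <- ex[j, 2L] - 1
        if (st == "+") {
          if (s < cds_lo)
            reg[[length(reg) + 1L]] <- c(s, min(e, cds_lo - 1), 4)
          if (e >= cds_lo)
            reg[[length(reg) + 1L]] <- c(max(s, cds_lo), e, 5)
        } else {
          if (e > cds_hi)
            reg[[length(reg) + 1L]] <- c(max(s, cds_hi + 1), e, 4)
          if (s <= cds_hi)
            reg[[length(reg) + 1L]] <- c(s, min(e, cds_hi), 5)
        }
      }
    } else {
      for (j in seq_len(nrow(ex)))
        reg[[length(reg) + 1L]] <- c(ex[j, 1L], ex[j, 2L] - 1, 5)
    }
    # introns: gene span minus exons
    gaps_lo <- ex[-nrow(ex), 2L]
    gaps_hi <- ex[-1L, 1L] - 1
    keep <- gaps_lo <= gaps_hi
    if (any(keep))
      for (j in which(keep))
        reg[[length(reg) + 1L]] <- c(gaps_lo[j], gaps_hi[j], 6)
    m <- do.call(rbind, reg)
    rows[[i]] <- data.table::data.table(chrom = genes$chrom[i],
                                        lo = m[, 1L], hi = m[, 2L],
                                        rank = as.integer(m[, 3L]))
  }
  out <- data.table::rbindlist(rows)
  out[out$lo <= out$hi]
}

#' Assign genomic categories to site anchors
#'
#' @param sites a peak set (anchors follow the summit/midpoint rule).
#' @param genes a [gene_models()] object.
#' @param tss_window half-width of the TSS region in bp (default 200).
#' @param flank promoter/downstream extent in bp (default 2000).
#' @return factor of categories, one per site, levels in precedence order.
#' @export
assign_category <- function(sites, genes, tss_window = 200, flank = 2000) {
  stopifnot(inherits(genes, "gene_models"))
  if (nrow(genes) == 0L) stop("assign_category: no genes loaded")
  reg <- .category_regions(genes, tss_window, flank)
  a <- anchor_positions(sites)
  chrom <- as.character(GenomicRanges::seqnames(sites))
  best <- rep(7L, length(sites))
  for (ch in unique(chrom)) {
    r <- reg[reg$chrom == ch]
    si <- which(chrom == ch)
    if (nrow(r) == 0L || !length(si)) next
    q <- IRanges::IRanges(start = a[si] + 1, width = 1L)
    s <- IRanges::IRanges(start = r$lo + 1, end = r$hi + 1)
    hits <- IRanges::findOverlaps(q, s)
    if (length(hits)) {
      agg <- tapply(r$rank[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits), min)
      best[si[as.integer(names(agg))]] <- as.integer(agg)
    }
  }
  factor(.GENOMIC_CATEGORIES[best], levels = .GENOMIC_CATEGORIES)
}

#' Per-class genomic category distribution
#'
#' @param c a `classified_sites` object.
#' @param genes a [gene_models()] object.
#' @inheritParams assign_category
#' @return data.table with one row per (class, category): count and
#'   within-class fraction (`NA` fractions for an empty class).
#' @export
category_distribution <- function(c, genes, tss_window = 200, flank = 2000) {
  stopifnot(inherits(c, "classified_sites"))
  rows <- lapply(c("IM", "IO", "MO"), function(cl) {
    p <- .class_peaks(c, cl)
    if (length(p) == 0L)
      return(data.table::data.table(class = cl,
                                    category = .GENOMIC_CATEGORIES,
                                    count = 0L, fraction = NA_real_))
    cat <- assign_category(p, genes, tss_window, flank)
    n <- table(cat)
    data.table::data.table(class = cl, category = names(n),
                           count = as.integer(n),
                           fraction = as.numeric(n) / length(p))
  })
  data.table::rbindlist(rows)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value from the hypergeometric distribution: the sum of
#' the probabilities of all tables (with the observed margins) whose
#' probability does not exceed that of the observed table. A relative
#' tolerance of 1e-7 absorbs floating-point ties, as is conventional.
#'
#' @param a,b,c,d cell counts, rows = groups, columns = in/out:
#'   `[[a, b], [c, d]]`.
#' @return p-value in (0, 1].
#' @export
fisher_exact2x2 <- function(a, b, c, d) {
  x <- c(a, b, c, d)
  if (any(x < 0) || any(x != floor(x)))
    stop("fisher_exact2x2: counts must be nonnegative integers")
  m <- a + c; n <- b + d; k <- a + b
  support <- max(0, k - n):min(k, m)
  pr <- stats::dhyper(support, m, n, k)
  pobs <- stats::dhyper(a, m, n, k)
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
}

#' Compare a category fraction between two site classes
#'
#' Fisher's exact test on the 2x2 table of in-category / out-of-category
#' counts for two classes (e.g. IM sites within 200 bp of a TSS versus IO
#' sites).
#'
#' @param k1,k2 length-2 integer vectors `(count in category, count not in
#'   category)` for the two classes.
#' @return list with the two fractions, the table and the two-sided p-value.
#' @export
compare_class_fractions <- function(k1, k2) {
  stopifnot(length(k1) == 2L, length(k2) == 2L)
  if (sum(k1) == 0 || sum(k2) == 0)
    stop("compare_class_fractions: empty class")
  p <- fisher_exact2x2(k1[1L], k1[2L], k2[1L], k2[2L])
  list(fraction1 = k1[1L] / sum(k1), fraction2 = k2[1L] / sum(k2),
       table = matrix(c(k1, k2), nrow = 2L, byrow = TRUE), p_value = p)
}

#' GC content around site anchors
#'
#' Fraction (G + C) / (A + C + G + T) in a window of `window` bp either side
#' of each anchor (window clipped at chromosome ends); case-insensitive, N
#' excluded from the denominator. All-N windows give `NA`.
#'
#' @param sites a peak set.
#' @param sequences a [Biostrings::DNAStringSet] named by chromosome.
#' @param window half-width in bp (default 100).
#' @return numeric vector of fractions in `[0, 1]`, `NA` where undefined.
#' @export
gc_content <- function(sites, sequences, window = 100) {
  a <- anchor_positions(sites)
  chrom <- as.character(GenomicRanges::seqnames(sites))
  miss <- setdiff(unique(chrom), names(sequences))
  if (length(miss))
    stop("gc_content: no sequence for chromosome ", miss[1L])
  len <- Biostrings::width(sequences)[match(chrom, names(sequences))]
  lo <- pmax(a - window, 0)
  hi <- pmin(a + window + 1, len)  # half-open window end
  out <- rep(NA_real_, length(sites))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    vw <- Biostrings::Views(sequences[[ch]], start = lo[i] + 1, end = hi[i])
    f <- Biostrings::letterFrequency(vw, c("A", "C", "G", "T"))
    tot <- rowSums(f)
    out[i] <- ifelse(tot > 0, (f[, "C"] + f[, "G"]) / tot, NA_real_)
  }
  out
}
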