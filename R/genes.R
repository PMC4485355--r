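#' Gene models
#'
#' A gene model records the gene span, strand, transcription start (TSS) and
#' termination (TTS) positions, exon structure and optional coding sequence
#' (CDS) intervals. Coordinates are 0-based half-open; `tss` and `tts` are
#' single 0-based positions (on the minus strand `tss > tts`).
#'
#' @param id character gene identifiers.
#' @param chrom chromosome names.
#' @param strand `+` or `-` per gene.
#' @param start,end gene span, 0-based half-open.
#' @param exons list of two-column matrices (`start`, `end`) per gene.
#' @param cds list of two-column matrices or `NULL` entries.
#' @return an object of class `gene_models` (a data.table).
#' @export
gene_models <- function(id, chrom, strand, start, end, exons, cds = NULL) {
  n <- length(id)
  if (is.null(cds)) cds <- vector("list", n)
  stopifnot(length(chrom) == n, length(strand) == n,
            length(start) == n, length(end) == n, length(exons) == n,
            length(cds) == n, all(strand %in% c("+", "-")))
  if (any(start < 0 | start >= end)) stop("gene_models: invalid gene span")
  for (i in seq_len(n)) {
    ex <- exons[[i]]
    if (is.null(ex) || nrow(ex) == 0L)
      exons[[i]] <- ex <- cbind(start[i], end[i])
    o <- order(ex[, 1L])
    ex <- ex[o, , drop = FALSE]
    if (any(ex[, 1L] >= ex[, 2L]) || any(ex[, 1L] < start[i]) ||
        any(ex[, 2L] > end[i]))
      stop("gene_models: exon outside span for gene ", id[i])
    if (nrow(ex) > 1L && any(ex[-1L, 1L] < ex[-nrow(ex), 2L]))
      stop("gene_models: overlapping exons for gene ", id[i])
    exons[[i]] <- ex
  }
  dt <- data.table::data.table(
    id = as.character(id), chrom = as.character(chrom), strand = strand,
    start = as.numeric(start), end = as.numeric(end),
    tss = ifelse(strand == "+", as.numeric(start), as.numeric(end) - 1),
    tts = ifelse(strand == "+", as.numeric(end) - 1, as.numeric(start)),
    exons = exons, cds = cds)
  data.table::setattr(dt, "class", c("gene_models", class(dt)))
  dt[]
}

#' Read gene models from GFF3
#'
#' Parses `gene`, `exon` and `CDS` features; exons and CDS are attached to
#' their gene through the `Parent` (or `ID` prefix) attribute. GFF 1-based
#' closed coordinates are converted to 0-based half-open on read.
#'
#' @param path GFF3 file.
#' @return a [gene_models()] object.
#' @export
read_gff_genes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t", skip = "#",
                          colClasses = list(character = c(1, 9)),
                          col.names = c("seqid", "source", "type", "start",
                                        "end", "score", "strand", "phase",
                                        "attr"))
  att <- function(x, key) {
    hit <- regexpr(paste0("(^|;)", key, "=[^;]+"), x)
    out <- rep(NA_character_, length(x))
    out[hit > 0] <- sub(paste0("^;?", key, "="), "", regmatches(x, hit))
    out
  }
  g <- dt[dt$type == "gene"]
  if (nrow(g) == 0L) stop("GFF '", path, "': no gene features")
  gid <- att(g$attr, "ID")
  ex <- dt[dt$type == "exon"]
  cd <- dt[dt$type == "CDS"]
  exp_ <- att(ex$attr, "Parent")
  cdp <- att(cd$attr, "Parent")
  exl <- lapply(gid, function(i) {
    r <- ex[which(exp_ == i)]
    if (nrow(r) == 0L) NULL else cbind(r$start - 1, r$end)
  })
  cdl <- lapply(gid, function(i) {
    r <- cd[which(cdp == i)]
    if (nrow(r) == 0L) NULL else {
      m <- cbind(r$start - 1, r$end)
      m[order(m[, 1L]), , drop = FALSE]
    }
  })
  gene_models(id = gid, chrom = g$seqid, strand = g$strand,
              start = g$start - 1, end = g$end, exons = exl, cds = cdl)
}

#' Read gene models from BED12
#'
#' Blocks become exons; the `thickStart`/`thickEnd` region intersected with
#' the blocks becomes the CDS (no CDS when thickStart == thickEnd).
#'
#' @param path BED12 file.
#' @return a [gene_models()] object.
#' @export
read_bed12_genes <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = c(1, 4, 6, 9, 11, 12)))
  if (ncol(dt) < 12L) stop("BED12 '", path, "': expected 12 columns")
  data.table::setnames(dt, c("chrom", "start", "end", "name", "score",
                             "strand", "thickStart", "thickEnd", "rgb",
                             "blockCount", "blockSizes", "blockStarts"))
  splitnum <- function(s) as.numeric(strsplit(sub(",$", "", s), ",")[[1L]])
  exl <- vector("list", nrow(dt))
  cdl <- vector("list", nrow(dt))
  for (i in seq_len(nrow(dt))) {
    sz <- splitnum(dt$blockSizes[i])
    st <- splitnum(dt$blockStarts[i]) + dt$start[i]
    ex <- cbind(st, st + sz)
    exl[[i]] <- ex
    if (dt$thickEnd[i] > dt$thickStart[i]) {
      cs <- pmax(ex[, 1L], dt$thickStart[i])
      ce <- pmin(ex[, 2L], dt$thickEnd[i])
      keep <- cs < ce
      if (any(keep)) cdl[[i]] <- cbind(cs[keep], ce[keep])
    }
  }
  gene_models(id = dt$name, chrom = dt$chrom, strand = dt$strand,
              start = dt$start, end = dt$end, exons = exl, cds = cdl)
}

#' Write gene models as GFF3
#'
#' @param genes a [gene_models()] object.
#' @param path output file.
#' @export
write_gff_genes <- function(genes, path) {
  stopifnot(inherits(genes, "gene_models"))
  lines <- c("##gff-version 3")
  fmt <- function(chrom, type, s0, e0, strand, attr)
    sprintf("%s\tctcfCycle\t%s\t%.0f\t%.0f\t.\t%s\t.\t%s",
            chrom, type, s0 + 1, e0, strand, attr)
  for (i in seq_len(nrow(genes))) {
    lines <- c(lines, fmt(genes$chrom[i], "gene", genes$start[i],
                          genes$end[i], genes$strand[i],
                          paste0("ID=", genes$id[i])))
    ex <- genes$exons[[i]]
    for (j in seq_len(nrow(ex)))
      lines <- c(lines, fmt(genes$chrom[i], "exon", ex[j, 1L], ex[j, 2L],
                            genes$strand[i], paste0("Parent=", genes$id[i])))
    cd <- genes$cds[[i]]
    if (!is.null(cd))
      for (j in seq_len(nrow(cd)))
        lines <- c(lines, fmt(genes$chrom[i], "CDS", cd[j, 1L], cd[j, 2L],
                              genes$strand[i], paste0("Parent=", genes$id[i])))
  }
  writeLines(lines, path)
  invisible(path)
}
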