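#' Genome table
#'
#' A genome table maps chromosome names to lengths in base pairs and acts as
#' the coordinate reference every interval container is validated against.
#' Analyses are typically restricted to a chromosome whitelist (for
#' D. melanogaster: 2L, 2R, 3L, 3R, 4, X); intervals on other chromosomes are
#' rejected on load.
#'
#' @param lengths named numeric vector of strictly positive chromosome
#'   lengths in bp.
#' @return an object of class `genome_table` (a named integer-valued numeric
#'   vector).
#' @export
genome_table <- function(lengths) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
    stop("genome_table: all chromosomes must be named")
  if (anyDuplicated(names(lengths)))
    stop("genome_table: duplicated chromosome names")
  nm <- names(lengths)
  lengths <- stats::setNames(as.numeric(lengths), nm)
  if (any(!is.finite(lengths)) || any(lengths <= 0) ||
      any(lengths != floor(lengths)))
    stop("genome_table: lengths must be positive integers")
  structure(lengths, class = "genome_table")
}

#' @export
print.genome_table <- function(x, ...) {
  cat("genome_table with", length(x), "chromosomes,",
      format(sum(x), big.mark = ","), "bp total\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Read a chrom.sizes file
#'
#' Two-column TSV: chromosome name, length. Lines failing validation are
#' reported with their line number.
#'
#' @param path file path.
#' @param whitelist optional character vector; chromosomes not listed are
#'   dropped (all must then be present in the file).
#' @return a [genome_table()].
#' @export
read_chrom_sizes <- function(path, whitelist = NULL) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (ncol(dt) < 2L)
    stop("chrom.sizes '", path, "': expected 2 tab-separated columns")
  len <- suppressWarnings(as.numeric(dt[[2L]]))
  bad <- which(is.na(len) | len <= 0 | len != floor(len))
  if (length(bad))
    stop("chrom.sizes '", path, "': invalid length at line ", bad[1L])
  g <- stats::setNames(len, dt[[1L]])
  if (!is.null(whitelist)) {
    missing <- setdiff(whitelist, names(g))
    if (length(missing))
      stop("chrom.sizes '", path, "': whitelisted chromosomes absent: ",
           paste(missing, collapse = ", "))
    g <- g[whitelist]
  }
  genome_table(g)
}

#' @rdname read_chrom_sizes
#' @param genome a [genome_table()].
#' @export
write_chrom_sizes <- function(genome, path) {
  stopifnot(inherits(genome, "genome_table"))
  data.table::fwrite(
    data.table::data.table(chrom = names(genome),
                           length = format(as.numeric(genome), scientific = FALSE,
                                           trim = TRUE)),
    path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

# Seqinfo built from a genome table (used to attach lengths to GRanges).
.genome_seqinfo <- function(genome) {
  GenomeInfoDb::Seqinfo(seqnames = names(genome),
                        seqlengths = as.integer(genome))
}

# TRUE when two containers were validated against the same genome.
.same_genome <- function(a, b) {
  identical(GenomeInfoDb::seqlengths(a), GenomeInfoDb::seqlengths(b))
}
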