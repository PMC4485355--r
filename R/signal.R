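#' Signal tracks
#'
#' A per-chromosome step function: sorted non-overlapping 0-based half-open
#' intervals with real values; regions without data are 0. Read and written
#' as 4-column bedGraph.
#'
#' @param chrom,start,end interval coordinates (0-based half-open).
#' @param value real values.
#' @param genome optional [genome_table()]; when supplied, intervals are
#'   validated against chromosome bounds.
#' @return an object of class `signal_track` (a data.table).
#' @export
signal_track <- function(chrom, start, end, value, genome = NULL) {
  dt <- data.table::data.table(chrom = as.character(chrom),
                               start = as.numeric(start),
                               end = as.numeric(end),
                               value = as.numeric(value))
  if (any(dt$start < 0 | dt$start >= dt$end))
    stop("signal_track: invalid interval")
  if (!is.null(genome)) {
    bad <- !(dt$chrom %in% names(genome)) |
      dt$end > as.numeric(genome)[match(dt$chrom, names(genome))]
    if (any(bad, na.rm = TRUE))
      stop("signal_track: interval outside genome at record ", which(bad)[1L])
  }
  data.table::setorder(dt, chrom, start)
  ov <- dt[, any(start[-1L] < end[-.N]), by = chrom]$V1
  if (any(ov, na.rm = TRUE))
    stop("signal_track: overlapping intervals")
  data.table::setattr(dt, "class", c("signal_track", class(dt)))
  dt[]
}

#' Read/write bedGraph signal tracks
#'
#' @param path file path.
#' @inheritParams signal_track
#' @export
read_bedgraph <- function(path, genome = NULL) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (ncol(dt) != 4L)
    stop("bedGraph '", path, "': expected 4 columns")
  signal_track(dt[[1L]], dt[[2L]], dt[[3L]], dt[[4L]], genome = genome)
}

#' @rdname read_bedgraph
#' @param track a `signal_track`.
#' @export
write_bedgraph <- function(track, path) {
  out <- data.table::copy(data.table::as.data.table(track))
  out[, start := format(start, scientific = FALSE, trim = TRUE)]
  out[, end := format(end, scientific = FALSE, trim = TRUE)]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Signal meta-profile around site anchors
#'
#' For each site the window `[anchor - flank, anchor + flank)` is cut into
#' bins of `bin` bp; the bin value is the length-weighted mean of the track
#' over the bin (0 where the track has no data). The profile is the
#' unweighted mean over sites; windows clipped at chromosome ends contribute
#' only their fully covered bins, and each bin's denominator counts only the
#' sites covering it.
#'
#' @param sites a non-empty peak set.
#' @param track a `signal_track`.
#' @param flank half-width of the window in bp; must be divisible by `bin`.
#' @param bin bin width in bp.
#' @return object of class `meta_profile`: data.table (offset = bin center
#'   relative to the anchor, mean, n).
#' @export
aggregate_profile <- function(sites, track, flank = 1000, bin = 50) {
  if (length(sites) == 0L) stop("aggregate_profile: empty site set")
  if (flank %% bin != 0) stop("aggregate_profile: flank must be divisible by bin")
  a <- anchor_positions(sites)
  chrom <- as.character(GenomicRanges::seqnames(sites))
  genome <- .peak_genome(sites)
  clen <- as.numeric(genome)[match(chrom, names(genome))]
  nb <- 2L * flank / bin
  offs <- seq(-flank, flank - bin, by = bin)  # bin left edges
  # one row per (site, bin), keeping bins fully inside the chromosome
  site_id <- rep(seq_along(a), each = nb)
  bs <- rep(a, each = nb) + rep(offs, times = length(a))
  be <- bs + bin
  keep <- bs >= 0 & be <= rep(clen, each = nb)
  bins <- data.table::data.table(chrom = rep(chrom, each = nb)[keep],
                                 start = bs[keep], end = be[keep],
                                 site = site_id[keep],
                                 off = rep(offs, times = length(a))[keep])
  tr <- data.table::as.data.table(track)
  val <- numeric(nrow(bins))
  if (nrow(tr)) {
    q <- GenomicRanges::GRanges(bins$chrom,
                                IRanges::IRanges(bins$start + 1, bins$end))
    s <- GenomicRanges::GRanges(tr$chrom, IRanges::IRanges(tr$start + 1, tr$end))
    hits <- GenomicRanges::findOverlaps(q, s)
    if (length(hits)) {
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      w <- pmin(bins$end[qh], tr$end[sh]) - pmax(bins$start[qh], tr$start[sh])
      contrib <- w * tr$value[sh]
      agg <- rowsum(contrib, qh)
      val[as.integer(rownames(agg))] <- agg[, 1L]
    }
  }
  bins[, binval := val / bin]
  prof <- bins[, .(mean = mean(binval), n = .N), by = off]
  data.table::setorder(prof, off)
  out <- data.table::data.table(offset = prof$off + bin / 2,
                                mean = prof$mean, n = prof$n)
  data.table::setattr(out, "class", c("meta_profile", class(out)))
  out[]
}

#' @export
print.meta_profile <- function(x, ...) {
  cat("meta_profile with", nrow(x), "bins; peak mean",
      signif(max(x$mean), 4), "at offset", x$offset[which.max(x$mean)], "\n")
  invisible(x)
}

#' Write a meta-profile as TSV
#'
#' @param profile a `meta_profile`.
#' @param path output file.
#' @export
write_profile <- function(profile, path) {
  data.table::fwrite(data.table::as.data.table(profile), path, sep = "\t")
  invisible(path)
}
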