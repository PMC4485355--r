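#' Peak sets
#'
#' Peaks ("binding sites") are stored as a [GenomicRanges::GRanges] with
#' metadata columns `name`, `score` and `summit` and the genome's chromosome
#' lengths attached as seqinfo. All user-facing coordinates follow the BED
#' convention (0-based, half-open); the constructor takes BED coordinates and
#' converts them internally. `summit` is the offset of the point of maximal
#' enrichment from the interval start (0-based within the interval), or `NA`
#' when unknown.
#'
#' Normalization sorts intervals by (chromosome, start) and validates every
#' record: `0 <= start < end <= chromosome length`, `0 <= summit < width`.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end 0-based half-open interval coordinates.
#' @param name free-text labels (defaults to `site_1 ...`).
#' @param score nonnegative real scores (default 0).
#' @param strand one of `+`, `-`, `.` per interval (default `.`).
#' @param summit optional integer offsets from `start`, `NA` allowed.
#' @param genome a [genome_table()].
#' @return a `GRanges` peak set.
#' @export
peak_set <- function(chrom, start, end, name = NULL, score = 0,
                     strand = ".", summit = NA_integer_, genome) {
  stopifnot(inherits(genome, "genome_table"))
  n <- length(chrom)
  if (is.null(name)) name <- paste0("site_", seq_len(n))
  score <- rep_len(as.numeric(score), n)
  strand <- rep_len(as.character(strand), n)
  summit <- rep_len(suppressWarnings(as.integer(summit)), n)
  start <- as.numeric(start); end <- as.numeric(end)
  bad <- which(!(start >= 0 & start < end))
  if (length(bad))
    stop("peak_set: invalid interval at record ", bad[1L],
         " (need 0 <= start < end)")
  unknown <- which(!(chrom %in% names(genome)))
  if (length(unknown))
    stop("peak_set: unknown chromosome '", chrom[unknown[1L]],
         "' at record ", unknown[1L])
  over <- which(end > as.numeric(genome)[match(chrom, names(genome))])
  if (length(over))
    stop("peak_set: interval beyond chromosome end at record ", over[1L])
  badsum <- which(!is.na(summit) & (summit < 0 | summit >= end - start))
  if (length(badsum))
    stop("peak_set: summit outside interval at record ", badsum[1L])
  if (any(score < 0, na.rm = TRUE)) stop("peak_set: negative score")
  strand[strand == "."] <- "*"
  if (n == 0L) {
    gr <- GenomicRanges::GRanges(seqinfo = .genome_seqinfo(genome))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      name = character(0), score = numeric(0), summit = integer(0))
    return(gr)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = names(genome)),
    ranges = IRanges::IRanges(start = start + 1, end = end),
    strand = strand,
    name = as.character(name), score = score, summit = summit,
    seqinfo = .genome_seqinfo(genome))
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

# 0-based coordinates of a peak GRanges, as a data.table.
.bed_coords <- function(gr) {
  data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    name = S4Vectors::mcols(gr)$name,
    score = S4Vectors::mcols(gr)$score,
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))),
    summit = S4Vectors::mcols(gr)$summit)
}

.peak_genome <- function(gr) {
  genome_table(GenomeInfoDb::seqlengths(gr))
}

# Identity key used when excluding a bait from its own target set.
.peak_key <- function(gr) {
  paste(as.character(GenomicRanges::seqnames(gr)),
        GenomicRanges::start(gr), GenomicRanges::end(gr),
        S4Vectors::mcols(gr)$name, sep = "\r")
}

#' Anchor positions of a peak set
#'
#' The anchor of a site is the summit when one is recorded, otherwise the
#' interval midpoint `floor((start + end) / 2)` in 0-based coordinates. All
#' distance and category computations act on anchors.
#'
#' @param peaks a peak set.
#' @param use_summit set `FALSE` to force midpoints even when summits exist.
#' @return numeric vector of 0-based anchor positions.
#' @export
anchor_positions <- function(peaks, use_summit = TRUE) {
  s0 <- GenomicRanges::start(peaks) - 1
  e0 <- as.numeric(GenomicRanges::end(peaks))
  summit <- S4Vectors::mcols(peaks)$summit
  a <- floor((s0 + e0) / 2)
  if (use_summit && !is.null(summit)) {
    k <- !is.na(summit)
    a[k] <- s0[k] + summit[k]
  }
  a
}

#' Read and write BED peak files
#'
#' `read_peaks_bed()` accepts BED3 and BED6, plus an optional 7th column with
#' the summit offset from the interval start (-1 or "." for unknown).
#' Malformed lines are reported with their line number. `write_peaks_bed()`
#' emits BED6+summit when any summit is present, BED6 otherwise.
#'
#' @param path file path.
#' @param genome a [genome_table()]; intervals are validated against it and
#'   chromosomes outside it rejected.
#' @return `read_peaks_bed()`: a peak set `GRanges`.
#' @export
read_peaks_bed <- function(path, genome) {
  if (file.exists(path) && file.size(path) == 0)
    return(peak_set(character(), numeric(), numeric(), genome = genome))
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE,
                          colClasses = list(character = 1))
  if (nrow(dt) == 0L)
    return(peak_set(character(), numeric(), numeric(), genome = genome))
  if (ncol(dt) < 3L)
    stop("BED '", path, "': expected at least 3 columns")
  start <- suppressWarnings(as.numeric(dt[[2L]]))
  end <- suppressWarnings(as.numeric(dt[[3L]]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("BED '", path, "': non-numeric coordinate at line ", bad[1L])
  name <- if (ncol(dt) >= 4L) as.character(dt[[4L]]) else NULL
  score <- if (ncol(dt) >= 5L) suppressWarnings(as.numeric(dt[[5L]])) else 0
  score[is.na(score)] <- 0
  strand <- if (ncol(dt) >= 6L) as.character(dt[[6L]]) else "."
  summit <- if (ncol(dt) >= 7L) {
    s <- suppressWarnings(as.integer(dt[[7L]]))
    s[!is.na(s) & s < 0] <- NA_integer_
    s
  } else NA_integer_
  tryCatch(
    peak_set(dt[[1L]], start, end, name = name, score = score,
             strand = strand, summit = summit, genome = genome),
    error = function(e) stop("BED '", path, "': ", conditionMessage(e)))
}

#' @rdname read_peaks_bed
#' @param peaks a peak set.
#' @export
write_peaks_bed <- function(peaks, path) {
  dt <- .bed_coords(peaks)
  dt[, start := format(start, scientific = FALSE, trim = TRUE)]
  dt[, end := format(end, scientific = FALSE, trim = TRUE)]
  if (all(is.na(dt$summit))) dt[, summit := NULL]
  else dt[, summit := data.table::fifelse(is.na(summit), -1L, summit)]
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE,
                     na = "-1")
  invisible(path)
}

#' Nearest same-chromosome distance
#'
#' Distance from a bait site to the nearest target site on the same
#' chromosome, measured between anchors (summit when present, midpoint
#' otherwise). A target identical to the bait (same chromosome, start, end
#' and name) is excluded. Returns `NA` when no same-chromosome target
#' remains.
#'
#' @param bait a peak set of length 1 (the bait site).
#' @param targets a peak set.
#' @return nonnegative number, or `NA` when no same-chromosome target exists.
#' @seealso [nearest_distances()] for the vectorized version.
#' @export
nearest_same_chrom_distance <- function(bait, targets) {
  stopifnot(length(bait) == 1L)
  nearest_distances(bait, targets)
}

#' Nearest same-chromosome distances for every bait
#'
#' Vectorized [nearest_same_chrom_distance()]: for each bait, the distance to
#' the nearest target anchor on the same chromosome, excluding any target
#' identical to the bait.
#'
#' @param baits,targets peak sets.
#' @param exclude_identity exclude targets identical to the bait (default).
#' @return numeric vector, `NA` where no target exists.
#' @export
nearest_distances <- function(baits, targets, exclude_identity = TRUE) {
  ab <- anchor_positions(baits)
  at <- anchor_positions(targets)
  bc <- as.character(GenomicRanges::seqnames(baits))
  tc <- as.character(GenomicRanges::seqnames(targets))
  excl <- if (exclude_identity && length(targets))
    match(.peak_key(baits), .peak_key(targets))
  else rep(NA_integer_, length(baits))
  .nn_dist(ab, bc, at, tc, excl)
}

# Core nearest-distance kernel on plain vectors. For each bait anchor, the
# candidate nearest targets lie at sorted positions k-1..k+2 around the
# findInterval insertion point; a window of 4 is sufficient even when one
# candidate is removed by identity exclusion.
.nn_dist <- function(ab, bc, at, tc, excl) {
  out <- rep(NA_real_, length(ab))
  for (ch in unique(bc)) {
    bi <- which(bc == ch)
    ti <- which(tc == ch)
    if (!length(ti)) next
    o <- order(at[ti])
    ts <- at[ti][o]
    tid <- ti[o]
    k <- findInterval(ab[bi], ts)
    cand <- cbind(k - 1L, k, k + 1L, k + 2L)
    d <- abs(matrix(ts[pmax(pmin(cand, length(ts)), 1L)], ncol = 4L) - ab[bi])
    d[cand < 1L | cand > length(ts)] <- Inf
    ex <- excl[bi]
    if (any(!is.na(ex))) {
      exm <- matrix(tid[pmax(pmin(cand, length(ts)), 1L)], ncol = 4L)
      d[!is.na(ex) & exm == ex] <- Inf
    }
    m <- do.call(pmin, as.data.frame(d))
    out[bi] <- ifelse(is.finite(m), m, NA_real_)
  }
  out
}

# Same-set nearest-other distances from per-chromosome anchor vectors:
# after sorting, each element's nearest other element is an adjacent one.
# Used in permutation loops where building GRanges would dominate runtime.
.nn_self_from_anchors <- function(anchors, chrom) {
  out <- rep(NA_real_, length(anchors))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    if (length(i) < 2L) next
    o <- order(anchors[i])
    a <- anchors[i][o]
    dl <- c(Inf, diff(a))
    dr <- c(diff(a), Inf)
    out[i[o]] <- pmin(dl, dr)
  }
  out
}

# Bait-vs-target nearest distances from anchor vectors (no identity issue).
.nn_cross_from_anchors <- function(ab, bc, at, tc) {
  .nn_dist(ab, bc, at, tc, rep(NA_integer_, length(ab)))
}

#' Shuffle peak locations along chromosomes
#'
#' The permutation null used throughout: every interval keeps its length,
#' chromosome, name, score, strand and summit offset, while its start is
#' redrawn uniformly from `[0, chromLen - length]`. Shuffled intervals may
#' overlap each other. With the same `seed` the output is identical.
#'
#' @param peaks a peak set.
#' @param genome optional [genome_table()]; defaults to the genome attached
#'   to `peaks`.
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used (and advanced).
#' @return a peak set with the same per-chromosome interval multiset of
#'   lengths.
#' @export
shuffle_peaks <- function(peaks, genome = NULL, seed = NULL) {
  if (is.null(genome)) genome <- .peak_genome(peaks)
  w <- GenomicRanges::width(peaks)
  len <- as.numeric(genome)[match(as.character(GenomicRanges::seqnames(peaks)),
                                  names(genome))]
  over <- which(w > len)
  if (length(over))
    stop("shuffle_peaks: interval '", S4Vectors::mcols(peaks)$name[over[1L]],
         "' is longer than its chromosome")
  draw <- function() {
    s0 <- floor(stats::runif(length(peaks)) * (len - w + 1))
    s0 <- pmin(s0, len - w)  # guard against runif() returning values ~1
    out <- peaks
    IRanges::ranges(out) <- IRanges::IRanges(start = s0 + 1, width = w)
    GenomicRanges::sort(out, ignore.strand = TRUE)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
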