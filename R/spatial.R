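#' Domain sets
#'
#' Ordered non-overlapping domain intervals per chromosome (TADs or syntenic
#' blocks), with a kind tag. Boundaries are the domain edges.
#'
#' @param chrom,start,end domain coordinates (0-based half-open).
#' @param kind one of `TAD`, `synteny12D`, `syntenyHD` (free-form accepted).
#' @param genome a [genome_table()].
#' @return a `GRanges` of class attribute kind, sorted, validated
#'   non-overlapping.
#' @export
domain_set <- function(chrom, start, end, kind = "TAD", genome) {
  gr <- peak_set(chrom, start, end,
                 name = paste0(kind, "_", seq_along(chrom)), genome = genome)
  red <- GenomicRanges::reduce(gr, ignore.strand = TRUE, min.gapwidth = 0L)
  if (length(red) != length(gr))
    stop("domain_set: overlapping domains")
  S4Vectors::metadata(gr)$kind <- kind
  gr
}

#' Read a domain BED file
#'
#' @param path BED3+ file of domain intervals.
#' @inheritParams domain_set
#' @export
read_domains_bed <- function(path, kind = "TAD", genome) {
  p <- read_peaks_bed(path, genome)
  domain_set(as.character(GenomicRanges::seqnames(p)),
             GenomicRanges::start(p) - 1, GenomicRanges::end(p),
             kind = kind, genome = genome)
}

#' Domain boundaries
#'
#' Every domain edge is a boundary; a position shared by two adjacent
#' domains is a single boundary. Boundaries are indexed 0..B-1 per
#' chromosome in coordinate order. With `width > 0` each boundary is the
#' interval `[pos - width/2, pos + width/2)`; otherwise a zero-width point.
#'
#' @param domains a [domain_set()].
#' @param width boundary interval width in bp (default 0 = point).
#' @return data.table (chrom, pos, index, start, end).
#' @export
domain_boundaries <- function(domains, width = 0) {
  dt <- data.table::data.table(
    chrom = rep(as.character(GenomicRanges::seqnames(domains)), 2L),
    pos = c(GenomicRanges::start(domains) - 1,
            as.numeric(GenomicRanges::end(domains))))
  dt <- unique(dt)
  data.table::setorder(dt, chrom, pos)
  dt[, index := seq_len(.N) - 1L, by = chrom]
  dt[, `:=`(start = pos - width / 2, end = pos + width / 2)]
  dt[]
}

#' Site enrichment profile around domain boundaries
#'
#' For every domain edge, site anchors within `flank` bp are binned by
#' signed distance: negative when the anchor lies on the domain-interior
#' side of the edge, positive outside; both edges of each domain are used
#' with the orientation flipped so the convention holds at left and right
#' edges. The profile is the site count per bin divided by the number of
#' edges.
#'
#' @param sites a peak set.
#' @param domains a [domain_set()].
#' @param flank half-width of the window in bp; divisible by `bin`.
#' @param bin bin width in bp.
#' @return a `meta_profile` data.table (offset = bin center of signed
#'   distance, mean = sites per boundary, n = raw count).
#' @export
boundary_enrichment_profile <- function(sites, domains, flank = 10000,
                                        bin = 500) {
  if (length(domains) == 0L)
    stop("boundary_enrichment_profile: empty domain set")
  if (flank %% bin != 0)
    stop("boundary_enrichment_profile: flank must be divisible by bin")
  edges <- data.table::data.table(
    chrom = rep(as.character(GenomicRanges::seqnames(domains)), 2L),
    pos = c(GenomicRanges::start(domains) - 1,
            as.numeric(GenomicRanges::end(domains))),
    orient = rep(c(-1, 1), each = length(domains)))  # left, right edge
  a <- anchor_positions(sites)
  chrom <- as.character(GenomicRanges::seqnames(sites))
  nb <- 2L * flank / bin
  counts <- integer(nb)
  for (ch in unique(edges$chrom)) {
    ai <- sort(a[chrom == ch])
    e <- edges[edges$chrom == ch]
    if (!length(ai)) next
    for (j in seq_len(nrow(e))) {
      lo <- findInterval(e$pos[j] - flank - 1, ai) + 1L
      hi <- findInterval(e$pos[j] + flank, ai)
      if (lo > hi) next
      signed <- e$orient[j] * (ai[lo:hi] - e$pos[j])
      bidx <- floor(signed / bin) + flank / bin + 1L
      ok <- bidx >= 1L & bidx <= nb
      counts <- counts + tabulate(bidx[ok], nbins = nb)
    }
  }
  out <- data.table::data.table(
    offset = seq(-flank, flank - bin, by = bin) + bin / 2,
    mean = counts / nrow(edges), n = counts)
  data.table::setattr(out, "class", c("meta_profile", class(out)))
  out[]
}

#' Label boundaries by the site classes they contain
#'
#' A boundary gets label `IM`/`IO`/`MO` when at least one site of that class
#' overlaps the boundary interval by >= 1 bp. Point boundaries (width 0) use
#' a containment window of `containment` bp either side. Labels may overlap;
#' unlabeled boundaries are retained.
#'
#' @param domains a [domain_set()].
#' @param c a `classified_sites` object.
#' @param containment half-width in bp of the containment window used for
#'   point boundaries (default 500).
#' @param boundary_width explicit boundary interval width (default 0 =
#'   points with containment window).
#' @return object of class `labeled_boundaries`: data.table (chrom, pos,
#'   index, start, end, IM, IO, MO).
#' @export
label_boundaries <- function(domains, c, containment = 500,
                             boundary_width = 0) {
  stopifnot(inherits(c, "classified_sites"))
  b <- domain_boundaries(domains, width = boundary_width)
  if (boundary_width == 0)
    b[, `:=`(start = pos - containment, end = pos + containment)]
  bir <- GenomicRanges::GRanges(b$chrom,
                                IRanges::IRanges(b$start + 1, b$end))
  for (cl in c("IM", "IO", "MO")) {
    p <- .class_peaks(c, cl)
    b[[cl]] <- if (length(p))
      IRanges::overlapsAny(bir, GenomicRanges::granges(p)) else FALSE
  }
  data.table::setattr(b, "class", c("labeled_boundaries", class(b)))
  b[]
}

#' Write labeled boundaries as BED
#'
#' Labels go in the name field, comma-separated (`.` when unlabeled).
#'
#' @param boundaries a `labeled_boundaries` object.
#' @param path output file.
#' @export
write_labeled_boundaries <- function(boundaries, path) {
  lab <- apply(as.matrix(boundaries[, c("IM", "IO", "MO")]), 1L, function(x)
    if (any(x)) paste(c("IM", "IO", "MO")[x], collapse = ",") else ".")
  dt <- data.table::data.table(
    chrom = boundaries$chrom,
    start = format(boundaries$start, scientific = FALSE, trim = TRUE),
    end = format(pmax(boundaries$end, boundaries$start + 1),
                 scientific = FALSE, trim = TRUE),
    name = lab)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

# Number of domains entirely within [p1, p2] (p1 <= p2), given sorted
# domain starts/ends of one chromosome. Adjacent boundaries of one domain
# are therefore 1 domain apart.
.domains_between <- function(p1, p2, dstart, dend) {
  findInterval(p2, dend) - findInterval(p1 - 0.5, dstart)
}

# Per labeled boundary: minimum domain count to the nearest other boundary
# with the same label on the same chromosome. The count is monotone in the
# position span, so only adjacent labeled boundaries need checking.
# Returns NA for boundaries with no same-chromosome partner.
.min_domain_spacing <- function(positions, chroms, domains) {
  dchrom <- as.character(GenomicRanges::seqnames(domains))
  out <- rep(NA_real_, length(positions))
  for (ch in unique(chroms)) {
    i <- which(chroms == ch)
    if (length(i) < 2L) next
    di <- which(dchrom == ch)
    ds <- sort(GenomicRanges::start(domains)[di] - 1)
    de <- sort(as.numeric(GenomicRanges::end(domains)[di]))
    o <- order(positions[i])
    p <- positions[i][o]
    k <- length(p)
    dn <- .domains_between(p[-k], p[-1L], ds, de)  # adjacent pairs
    left <- c(Inf, dn)
    right <- c(dn, Inf)
    out[i[o]] <- pmin(left, right)
  }
  out
}

#' Permutation test result
#'
#' Common container for the spatial permutation tests: the observed
#' statistic distribution, the pooled null over permutations (equal weight
#' per permutation), per-permutation medians, the permutation count and
#' seed, and a two-sided Wilcoxon rank-sum p-value of observed versus pooled
#' null. Direction is reported through the medians.
#'
#' @name perm_test_result
#' @keywords internal
NULL

.perm_test_result <- function(statistic, observed, null, perm_medians,
                              n_perm, seed) {
  p <- stats::wilcox.test(observed, null, exact = FALSE)$p.value
  structure(list(statistic = statistic,
                 observed = observed, null = null,
                 perm_medians = perm_medians,
                 n_perm = n_perm, seed = seed,
                 observed_median = stats::median(observed),
                 null_median = stats::median(null),
                 p_value = p),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Permutation test:", x$statistic, "\n")
  cat(sprintf("  observed: n = %d, median = %.4g\n",
              length(x$observed), x$observed_median))
  cat(sprintf("  null:     n = %d (pooled over %d permutations), median = %.4g\n",
              length(x$null), x$n_perm, x$null_median))
  cat(sprintf("  two-sided Wilcoxon p = %.4g (seed %d)\n", x$p_value, x$seed))
  invisible(x)
}

#' Nearest-neighbor distance permutation test
#'
#' For each bait site the distance to the nearest target site on the same
#' chromosome is computed (anchor to anchor); the null distribution pools
#' the same statistic over `n_perm` chromosome-preserving uniform shuffles
#' of the targets. When baits and targets are the same set (detected
#' automatically, or forced with `same_set`), the bait is excluded from its
#' own targets and each permutation shuffles the single set, so baits and
#' targets move together. Significance is a two-sided Wilcoxon rank-sum test
#' of observed versus pooled null distances.
#'
#' @param baits,targets peak sets on the same genome.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed; the same seed reproduces the result exactly.
#' @param same_set `NULL` to auto-detect, or logical.
#' @return a `perm_test` object.
#' @export
nearest_neighbor_permutation_test <- function(baits, targets, n_perm = 1000,
                                              seed = 1L, same_set = NULL) {
  if (!.same_genome(baits, targets))
    stop("nearest_neighbor_permutation_test: different genomes")
  if (is.null(same_set))
    same_set <- length(baits) == length(targets) &&
      setequal(.peak_key(baits), .peak_key(targets))
  observed <- nearest_distances(baits, targets)
  observed <- observed[!is.na(observed)]
  if (length(observed) < 2L)
    stop("nearest_neighbor_permutation_test: insufficient sites")
  genome <- .peak_genome(targets)
  tw <- GenomicRanges::width(targets)
  tc <- as.character(GenomicRanges::seqnames(targets))
  tlen <- as.numeric(genome)[match(tc, names(genome))]
  tsum <- S4Vectors::mcols(targets)$summit
  taoff <- ifelse(is.na(tsum), tw %/% 2L, tsum)
  if (any(tw > tlen))
    stop("nearest_neighbor_permutation_test: interval longer than chromosome")
  ba <- anchor_positions(baits)
  bc <- as.character(GenomicRanges::seqnames(baits))
  nulls <- vector("list", n_perm)
  medians <- numeric(n_perm)
  withr::with_seed(seed, {
    for (k in seq_len(n_perm)) {
      st <- floor(stats::runif(length(targets)) * (tlen - tw + 1))
      anch <- pmin(st, tlen - tw) + taoff
      d <- if (same_set) .nn_self_from_anchors(anch, tc)
      else .nn_cross_from_anchors(ba, bc, anch, tc)
      d <- d[!is.na(d)]
      nulls[[k]] <- d
      medians[k] <- stats::median(d)
    }
  })
  .perm_test_result("nearest_same_chrom_distance", observed,
                    unlist(nulls), medians, n_perm, as.integer(seed))
}

#' Boundary-spacing permutation test (minimum domain numbers)
#'
#' The statistic for each boundary carrying the class label is the minimum
#' number of domains separating it from the nearest other same-label
#' boundary on the same chromosome (adjacent boundaries of one domain are 1
#' domain apart; cross-chromosome pairs never contribute). The null permutes
#' the label assignment uniformly over all boundaries of each chromosome,
#' preserving the per-chromosome label count, pooled over `n_perm`
#' permutations. Two-sided Wilcoxon rank-sum p-value.
#'
#' @param boundaries a `labeled_boundaries` object (see
#'   [label_boundaries()]).
#' @param domains the [domain_set()] the boundaries derive from.
#' @param class one of `"IM"`, `"IO"`, `"MO"`.
#' @inheritParams nearest_neighbor_permutation_test
#' @return a `perm_test` object.
#' @export
boundary_spacing_permutation_test <- function(boundaries, domains, class,
                                              n_perm = 1000, seed = 1L) {
  stopifnot(inherits(boundaries, "labeled_boundaries"),
            class %in% c("IM", "IO", "MO"))
  lab <- boundaries[[class]]
  bch <- boundaries$chrom
  usable <- names(which(table(bch[lab]) >= 2L))
  if (!length(usable))
    stop("boundary_spacing_permutation_test: fewer than 2 '", class,
         "' boundaries on every chromosome")
  obs <- .min_domain_spacing(boundaries$pos[lab], bch[lab], domains)
  obs <- obs[!is.na(obs)]
  nulls <- vector("list", n_perm)
  medians <- numeric(n_perm)
  chroms <- unique(bch)
  idx_by_chrom <- lapply(chroms, function(ch) which(bch == ch))
  names(idx_by_chrom) <- chroms
  k_by_chrom <- vapply(chroms, function(ch) sum(lab[bch == ch]), integer(1))
  withr::with_seed(seed, {
    for (k in seq_len(n_perm)) {
      sel <- unlist(lapply(chroms, function(ch) {
        i <- idx_by_chrom[[ch]]
        kk <- k_by_chrom[[ch]]
        if (kk == 0L) integer(0) else i[sample.int(length(i), kk)]
      }))
      d <- .min_domain_spacing(boundaries$pos[sel], bch[sel], domains)
      d <- d[!is.na(d)]
      nulls[[k]] <- d
      medians[k] <- if (length(d)) stats::median(d) else NA_real_
    }
  })
  .perm_test_result(paste0("min_domain_spacing_", class), obs,
                    unlist(nulls), medians, n_perm, as.integer(seed))
}
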