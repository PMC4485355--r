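#' Read and write UCSC chain files
#'
#' A chain is a pairwise genome alignment: a header
#' `chain score tName tSize tStrand tStart tEnd qName qSize qStrand qStart
#' qEnd id` followed by alignment block lines `size dt dq` and a final bare
#' `size`. The target strand is always `+`; minus-strand chains give query
#' coordinates on the reverse strand. Block sizes and gaps must sum to the
#' header spans; a mismatch is a parse error naming the chain id.
#'
#' @param path chain file.
#' @return `read_chain()`: a list of class `chain_set`; each element has the
#'   header fields and a numeric `blocks` matrix with columns `size`, `dt`,
#'   `dq` (`dt`/`dq` are 0 for the last block).
#' @export
read_chain <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^chain\\b", lines)
  if (!length(hdr)) stop("chain '", path, "': no chain headers")
  ends <- c(hdr[-1L] - 1L, length(lines))
  chains <- vector("list", length(hdr))
  for (i in seq_along(hdr)) {
    h <- strsplit(trimws(lines[hdr[i]]), "\\s+")[[1L]]
    if (length(h) < 13L)
      stop("chain '", path, "': malformed header at line ", hdr[i])
    ch <- list(score = as.numeric(h[2L]),
               t_name = h[3L], t_size = as.numeric(h[4L]), t_strand = h[5L],
               t_start = as.numeric(h[6L]), t_end = as.numeric(h[7L]),
               q_name = h[8L], q_size = as.numeric(h[9L]), q_strand = h[10L],
               q_start = as.numeric(h[11L]), q_end = as.numeric(h[12L]),
               id = as.integer(h[13L]))
    body <- lines[(hdr[i] + 1L):ends[i]]
    parts <- lapply(strsplit(trimws(body), "\\s+"), as.numeric)
    nb <- length(parts)
    blocks <- matrix(0, nrow = nb, ncol = 3L,
                     dimnames = list(NULL, c("size", "dt", "dq")))
    for (j in seq_len(nb)) {
      p <- parts[[j]]
      if (j < nb && length(p) != 3L || j == nb && !length(p) %in% c(1L, 3L))
        stop("chain '", path, "': malformed block in chain ", ch$id)
      blocks[j, seq_along(p)] <- p
    }
    if (any(blocks[, "size"] <= 0))
      stop("chain '", path, "': nonpositive block size in chain ", ch$id)
    tspan <- sum(blocks[, "size"]) + sum(blocks[, "dt"])
    qspan <- sum(blocks[, "size"]) + sum(blocks[, "dq"])
    if (tspan != ch$t_end - ch$t_start || qspan != ch$q_end - ch$q_start)
      stop("chain '", path, "': block sizes do not sum to span in chain ",
           ch$id)
    ch$blocks <- blocks
    chains[[i]] <- ch
  }
  structure(chains, class = "chain_set")
}

#' @rdname read_chain
#' @param chains a `chain_set`.
#' @export
write_chain <- function(chains, path) {
  out <- character(0)
  for (ch in chains) {
    out <- c(out, sprintf("chain %.0f %s %.0f %s %.0f %.0f %s %.0f %s %.0f %.0f %d",
                          ch$score, ch$t_name, ch$t_size, ch$t_strand,
                          ch$t_start, ch$t_end, ch$q_name, ch$q_size,
                          ch$q_strand, ch$q_start, ch$q_end, ch$id))
    b <- ch$blocks
    n <- nrow(b)
    if (n > 1L)
      out <- c(out, sprintf("%.0f %.0f %.0f", b[-n, 1L], b[-n, 2L], b[-n, 3L]))
    out <- c(out, sprintf("%.0f", b[n, 1L]), "")
  }
  writeLines(out, path)
  invisible(path)
}

# Absolute block start coordinates of one chain on target and query
# (query in query-strand coordinates, as in the file).
.chain_block_starts <- function(ch) {
  b <- ch$blocks
  sz <- b[, "size"]; dt <- b[, "dt"]; dq <- b[, "dq"]
  ts <- ch$t_start + c(0, cumsum(sz + dt))[seq_along(sz)]
  qs <- ch$q_start + c(0, cumsum(sz + dq))[seq_along(sz)]
  list(ts = ts, qs = qs, sz = sz)
}

# Map 0-based target positions through one chain. Returns forward-strand
# query positions, NA where the position falls in a gap or outside the chain.
.map_positions <- function(pos, ch) {
  bs <- .chain_block_starts(ch)
  j <- findInterval(pos, bs$ts)
  ok <- j >= 1L & pos < bs$ts[pmax(j, 1L)] + bs$sz[pmax(j, 1L)]
  q <- rep(NA_real_, length(pos))
  jj <- pmax(j, 1L)
  q[ok] <- bs$qs[jj[ok]] + (pos[ok] - bs$ts[jj[ok]])
  if (ch$q_strand == "-") q[ok] <- ch$q_size - 1 - q[ok]
  q
}

#' Map an interval to another genome through chain alignments
#'
#' Every base of the interval is mapped through the aligned blocks of the
#' best-scoring chain whose target span overlaps the interval (score ties
#' broken by lowest chain id). When the fraction of mapped bases is at least
#' `min_match` (default 0.5, the lift-over remap threshold), the minimal
#' query interval spanning all mapped bases is returned; otherwise the
#' interval is reported unmapped. Minus-strand chains yield forward-strand
#' query coordinates.
#'
#' @param interval a peak set of length 1, on the chains' target genome.
#' @param chains a `chain_set`.
#' @param min_match minimum mapped-base fraction (default 0.5).
#' @return a one-row data.table (`chrom`, `start`, `end`, `mapped_fraction`)
#'   or `NULL` when unmapped.
#' @export
map_through_chain <- function(interval, chains, min_match = 0.5) {
  stopifnot(length(interval) == 1L)
  res <- map_intervals(interval, chains, min_match)
  if (is.na(res$chrom[1L])) NULL else res
}

#' @rdname map_through_chain
#' @param intervals a peak set (vectorized form; one output row per input,
#'   `NA` rows for unmapped intervals).
#' @export
map_intervals <- function(intervals, chains, min_match = 0.5) {
  n <- length(intervals)
  chrom <- as.character(GenomicRanges::seqnames(intervals))
  s0 <- GenomicRanges::start(intervals) - 1
  e0 <- as.numeric(GenomicRanges::end(intervals))
  out <- data.table::data.table(chrom = rep(NA_character_, n),
                                start = NA_real_, end = NA_real_,
                                mapped_fraction = 0)
  for (i in seq_len(n)) {
    cand <- Filter(function(ch) ch$t_name == chrom[i] &&
                     ch$t_start < e0[i] && ch$t_end > s0[i], chains)
    if (!length(cand)) next
    sc <- vapply(cand, `[[`, numeric(1), "score")
    id <- vapply(cand, `[[`, integer(1), "id")
    ch <- cand[[order(-sc, id)[1L]]]
    q <- .map_positions(s0[i]:(e0[i] - 1), ch)
    frac <- mean(!is.na(q))
    if (frac >= min_match && frac > 0) {
      out$chrom[i] <- ch$q_name
      out$start[i] <- min(q, na.rm = TRUE)
      out$end[i] <- max(q, na.rm = TRUE) + 1
      out$mapped_fraction[i] <- frac
    } else out$mapped_fraction[i] <- frac
  }
  out
}

#' Cross-species conservation table
#'
#' Mirrors the lift-over-based conservation analysis: binding sites of each
#' other species are mapped into the reference genome through that species'
#' chains (minimum match 0.5 by default), and a reference site is flagged
#' conserved in a species when it overlaps a mapped site by at least 1 bp.
#' The reference species itself always counts as one supporting species, so
#' "conserved in at least N species" means flagged in at least N - 1 other
#' species.
#'
#' @param sites the reference-species peak set (all classified sites).
#' @param species_peaks named list of peak sets in the other species'
#'   coordinates.
#' @param species_chains named list (same names) of `chain_set`s mapping each
#'   species' genome to the reference genome.
#' @param min_match lift-over minimum match fraction.
#' @param ref_genome [genome_table()] of the reference genome, used to clip
#'   mapped intervals.
#' @return object of class `conservation_table`: a data.table with one row
#'   per reference site, one logical column per species, and columns
#'   `conserved_in_at_least_2` .. `_4` (monotone non-increasing).
#' @export
conservation_table <- function(sites, species_peaks, species_chains,
                               min_match = 0.5, ref_genome = NULL) {
  stopifnot(identical(names(species_peaks), names(species_chains)))
  if (is.null(ref_genome)) ref_genome <- .peak_genome(sites)
  tab <- data.table::data.table(site = S4Vectors::mcols(sites)$name)
  site_ir <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(sites),
    ranges = IRanges::ranges(sites))
  for (sp in names(species_peaks)) {
    mp <- map_intervals(species_peaks[[sp]], species_chains[[sp]], min_match)
    mp <- mp[!is.na(mp$chrom) & mp$chrom %in% names(ref_genome)]
    flag <- rep(FALSE, length(sites))
    if (nrow(mp)) {
      lenr <- as.numeric(ref_genome)[match(mp$chrom, names(ref_genome))]
      mp[, `:=`(start = pmax(start, 0), end = pmin(end, lenr))]
      mp <- mp[mp$start < mp$end]
      gr <- GenomicRanges::GRanges(mp$chrom,
                                   IRanges::IRanges(mp$start + 1, mp$end))
      flag <- IRanges::overlapsAny(site_ir, gr)
    }
    tab[[sp]] <- flag
  }
  nsp <- rowSums(as.matrix(tab[, -1L])) + 1L  # + reference species itself
  for (N in 2:4) tab[[paste0("conserved_in_at_least_", N)]] <- nsp >= N
  data.table::setattr(tab, "class",
                      c("conservation_table", class(tab)))
  tab[]
}

#' Observed/expected conservation per site class
#'
#' For a class, the observed count is the number of its sites conserved in at
#' least `N` species; the expected count allocates the total number of
#' conserved sites proportionally to class size. The ratio is accompanied by
#' a two-sided Fisher's exact p-value of the class against the pooled other
#' classes. Note MO-site conservation is usually not assessable with real
#' data (no mitotic ChIP exists for the other species); the computation is
#' still performed when a table is supplied.
#'
#' @param c a `classified_sites` object.
#' @param table a [conservation_table()] whose rows cover, in order, the
#'   concatenated IM, IO, MO sites of `c`.
#' @param N minimum number of supporting species, 2..4.
#' @return data.table (class, n, observed, expected, oe_ratio, p_value).
#' @export
observed_expected_conservation <- function(c, table, N = 2) {
  stopifnot(inherits(c, "classified_sites"), N >= 2, N <= 4)
  n <- site_class_counts(c)
  if (nrow(table) != sum(n))
    stop("observed_expected_conservation: table rows do not match sites")
  cons <- table[[paste0("conserved_in_at_least_", N)]]
  cls <- rep(c("IM", "IO", "MO"), times = n)
  total_cons <- sum(cons)
  total <- sum(n)
  rows <- lapply(c("IM", "IO", "MO"), function(cl) {
    obs <- sum(cons[cls == cl])
    exp_ <- total_cons * n[[cl]] / total
    p <- fisher_exact2x2(obs, n[[cl]] - obs,
                         total_cons - obs, (total - n[[cl]]) - (total_cons - obs))
    data.table::data.table(class = cl, n = n[[cl]], observed = obs,
                           expected = exp_,
                           oe_ratio = if (exp_ > 0) obs / exp_ else NA_real_,
                           p_value = p)
  })
  data.table::rbindlist(rows)
}
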