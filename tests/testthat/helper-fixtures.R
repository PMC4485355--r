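# Shared fixtures and independent oracles. Oracles are deliberately written
# as plain loops, independent of the vectorized implementation paths they
# check.

CATEGORIES <- c("TSS_region", "Promoter", "Downstream", "UTR5",
                "CodingExon", "Intron", "Intergenic")

tiny_genome <- function(lengths = c(chr2L = 1e6, chrX = 5e5)) {
  genome_table(lengths)
}

mk_peaks <- function(chrom, start, end, genome, summit = NA_integer_, ...) {
  peak_set(chrom, start, end, summit = summit, genome = genome, ...)
}

random_peaks <- function(n, genome, width = 200) {
  L <- as.numeric(genome)
  ci <- sample.int(length(L), n, replace = TRUE, prob = L)
  s <- floor(runif(n) * (L[ci] - width))
  peak_set(names(genome)[ci], s, s + width, genome = genome)
}

# all-pairs nearest-distance oracle
oracle_nearest <- function(baits, targets) {
  ab <- anchor_positions(baits)
  at <- anchor_positions(targets)
  bc <- as.character(GenomicRanges::seqnames(baits))
  tc <- as.character(GenomicRanges::seqnames(targets))
  key <- function(p) paste(as.character(GenomicRanges::seqnames(p)),
                           GenomicRanges::start(p), GenomicRanges::end(p),
                           S4Vectors::mcols(p)$name)
  bk <- key(baits); tk <- key(targets)
  out <- rep(NA_real_, length(baits))
  for (i in seq_along(baits)) {
    best <- Inf
    excluded <- FALSE
    for (j in seq_along(targets)) {
      if (tc[j] != bc[i]) next
      if (!excluded && tk[j] == bk[i]) { excluded <- TRUE; next }
      best <- min(best, abs(ab[i] - at[j]))
    }
    if (is.finite(best)) out[i] <- best
  }
  out
}

# per-base brute-force chain mapping oracle
oracle_map_chain <- function(s0, e0, ch, min_match = 0.5) {
  mapped <- numeric(0)
  for (pos in s0:(e0 - 1)) {
    t <- ch$t_start
    q <- ch$q_start
    hit <- NA
    for (j in seq_len(nrow(ch$blocks))) {
      sz <- ch$blocks[j, "size"]
      if (pos >= t && pos < t + sz) { hit <- q + (pos - t); break }
      t <- t + sz + ch$blocks[j, "dt"]
      q <- q + sz + ch$blocks[j, "dq"]
    }
    if (!is.na(hit)) {
      if (ch$q_strand == "-") hit <- ch$q_size - 1 - hit
      mapped <- c(mapped, hit)
    }
  }
  frac <- length(mapped) / (e0 - s0)
  if (frac >= min_match && frac > 0)
    list(chrom = ch$q_name, start = min(mapped), end = max(mapped) + 1,
         frac = frac)
  else NULL
}

# random chain over one chromosome (constructed directly, not via the
# package generator)
random_chain <- function(t_name = "chr2L", t_size = 1e5, q_strand = "+",
                        n_blocks = NULL, id = 1L, score = 1000) {
  if (is.null(n_blocks)) n_blocks <- sample(1:8, 1)
  sz <- sample(20:400, n_blocks, replace = TRUE)
  dt <- c(sample(0:300, n_blocks - 1, replace = TRUE), 0)
  dq <- c(sample(0:300, n_blocks - 1, replace = TRUE), 0)
  t_start <- sample(0:2000, 1)
  t_end <- t_start + sum(sz) + sum(dt)
  stopifnot(t_end <= t_size)
  q_span <- sum(sz) + sum(dq)
  q_start <- sample(0:2000, 1)
  q_size <- q_start + q_span + sample(0:2000, 1)
  structure(list(list(
    score = score, t_name = t_name, t_size = t_size, t_strand = "+",
    t_start = t_start, t_end = t_end, q_name = "q1", q_size = q_size,
    q_strand = q_strand, q_start = q_start, q_end = q_start + q_span,
    id = id,
    blocks = cbind(size = sz, dt = dt, dq = dq))), class = "chain_set")
}

# exhaustive hypergeometric enumeration oracle for the two-sided Fisher test
oracle_fisher <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  support <- max(0, k - n):min(k, m)
  pr <- exp(lchoose(m, support) + lchoose(n, k - support) -
              lchoose(m + n, k))
  pobs <- pr[match(a, support)]
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
}

# per-gene region-membership oracle for genomic categories
oracle_category <- function(a, chrom, genes, tss_window = 200, flank = 2000) {
  best <- 7L
  for (i in seq_len(nrow(genes))) {
    if (genes$chrom[i] != chrom) next
    st <- genes$strand[i]; tss <- genes$tss[i]; tts <- genes$tts[i]
    ex <- genes$exons[[i]]; cd <- genes$cds[[i]]
    in_exon <- any(a >= ex[, 1] & a < ex[, 2])
    r <- if (abs(a - tss) <= tss_window) 1L
    else if (st == "+" && a < tss - tss_window &&
             a >= tss - tss_window - flank) 2L
    else if (st == "-" && a > tss + tss_window &&
             a <= tss + tss_window + flank) 2L
    else if (st == "+" && a > tts && a <= tts + flank) 3L
    else if (st == "-" && a < tts && a >= tts - flank) 3L
    else if (in_exon && !is.null(cd) && st == "+" && a < min(cd[, 1])) 4L
    else if (in_exon && !is.null(cd) && st == "-" && a >= max(cd[, 2])) 4L
    else if (in_exon) 5L
    else if (a >= genes$start[i] && a < genes$end[i]) 6L
    else 7L
    best <- min(best, r)
  }
  CATEGORIES[best]
}

# exhaustive pairwise minimum-domain-spacing oracle
oracle_min_spacing <- function(positions, chroms, dom_chrom, dom_start,
                               dom_end) {
  out <- rep(NA_real_, length(positions))
  for (i in seq_along(positions)) {
    best <- Inf
    for (j in seq_along(positions)) {
      if (i == j || chroms[i] != chroms[j]) next
      lo <- min(positions[i], positions[j])
      hi <- max(positions[i], positions[j])
      cnt <- sum(dom_chrom == chroms[i] & dom_start >= lo & dom_end <= hi)
      best <- min(best, cnt)
    }
    if (is.finite(best)) out[i] <- best
  }
  out
}

small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config(
        seed = 101L, chromosomes = c(chr1 = 2e6, chr2 = 1e6),
        n_genes = 80L, n_im = 60L, n_io = 120L, n_mo = 80L,
        n_species = 2L, species_noise_peaks = 30L)
      cache <<- simulate_dataset(cfg)
    }
    cache
  }
})
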