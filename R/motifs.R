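#' Position weight matrices
#'
#' A PWM holds per-position base probabilities (4 rows A, C, G, T by L
#' columns), a pseudocount and background base frequencies. Scores are
#' log2 odds: `sum_i log2(p'_ib / q_b)` where `p'` is the pseudocount-smoothed
#' probability `(p + pc) / (1 + 4 pc)`.
#'
#' @param mat 4 x L matrix of probabilities (rows A, C, G, T; columns sum to
#'   1) or of counts (normalized on construction).
#' @param background base frequencies, length 4 summing to 1.
#' @param pseudocount added to every cell before renormalization
#'   (default 0.001).
#' @return an object of class `pwm` with elements `prob` (smoothed
#'   probabilities), `score` (log2-odds matrix), `max_score`, `length`.
#' @export
pwm <- function(mat, background = rep(0.25, 4), pseudocount = 0.001) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L) stop("pwm: matrix must have 4 rows (A, C, G, T)")
  if (any(mat < 0)) stop("pwm: negative entries")
  if (abs(sum(background) - 1) > 1e-9 || length(background) != 4L)
    stop("pwm: background must be 4 frequencies summing to 1")
  cs <- colSums(mat)
  if (any(cs == 0)) stop("pwm: empty column")
  mat <- sweep(mat, 2L, cs, "/")
  p <- sweep(mat + pseudocount, 2L, 1 + 4 * pseudocount, "/")
  rownames(p) <- c("A", "C", "G", "T")
  s <- log2(p / background)
  structure(list(prob = p, score = s, background = background,
                 pseudocount = pseudocount,
                 max_score = sum(apply(s, 2L, max)),
                 length = ncol(p)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm of length", x$length, "- max score",
      round(x$max_score, 2), "bits; consensus",
      paste(rownames(x$prob)[apply(x$prob, 2L, which.max)], collapse = ""),
      "\n")
  invisible(x)
}

#' Build a near-deterministic PWM from a consensus string
#'
#' @param consensus string over A/C/G/T.
#' @param match_prob probability of the consensus base at each position
#'   (default 0.94, remainder split over the other bases).
#' @inheritParams pwm
#' @export
pwm_from_consensus <- function(consensus, match_prob = 0.94,
                               background = rep(0.25, 4),
                               pseudocount = 0.001) {
  b <- strsplit(toupper(consensus), "")[[1L]]
  if (!all(b %in% c("A", "C", "G", "T")))
    stop("pwm_from_consensus: consensus must be over A/C/G/T")
  m <- matrix((1 - match_prob) / 3, nrow = 4L, ncol = length(b),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  m[cbind(match(b, rownames(m)), seq_along(b))] <- match_prob
  pwm(m, background = background, pseudocount = pseudocount)
}

#' Read PWMs in JASPAR or MEME minimal format
#'
#' JASPAR: `>ID name` header then four lines `A [ 1 2 ... ]` etc.
#' MEME minimal: the first `letter-probability matrix` block (rows are
#' positions, columns A C G T).
#'
#' @param path file path.
#' @inheritParams pwm
#' @return a [pwm()] (JASPAR: the first matrix in the file).
#' @export
read_jaspar <- function(path, background = rep(0.25, 4),
                        pseudocount = 0.001) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("JASPAR '", path, "': no '>' header")
  rows <- lines[(hdr[1L] + 1L):min(hdr[1L] + 4L, length(lines))]
  getrow <- function(l) {
    x <- sub("^\\s*[ACGTacgt]", "", l)
    as.numeric(regmatches(x, gregexpr("[0-9.eE+-]+", x))[[1L]])
  }
  base <- toupper(substr(trimws(rows), 1L, 1L))
  m <- do.call(rbind, lapply(rows, getrow))
  if (!setequal(base, c("A", "C", "G", "T")))
    stop("JASPAR '", path, "': expected rows A, C, G, T")
  m <- m[match(c("A", "C", "G", "T"), base), , drop = FALSE]
  pwm(m, background = background, pseudocount = pseudocount)
}

#' @rdname read_jaspar
#' @export
read_meme_minimal <- function(path, background = rep(0.25, 4),
                              pseudocount = 0.001) {
  lines <- readLines(path)
  i <- grep("letter-probability matrix", lines)
  if (!length(i)) stop("MEME '", path, "': no letter-probability matrix")
  rows <- list()
  j <- i[1L] + 1L
  while (j <= length(lines)) {
    nums <- suppressWarnings(as.numeric(strsplit(trimws(lines[j]), "\\s+")[[1L]]))
    if (length(nums) != 4L || anyNA(nums)) break
    rows[[length(rows) + 1L]] <- nums
    j <- j + 1L
  }
  if (!length(rows)) stop("MEME '", path, "': empty matrix")
  pwm(t(do.call(rbind, rows)), background = background,
      pseudocount = pseudocount)
}

.BASE_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L)

.encode_seq <- function(s) {
  unname(.BASE_CODE[strsplit(toupper(as.character(s)), "")[[1L]]])
}

# Score every offset of an encoded sequence against a score matrix.
# Positions with non-ACGT bases score -Inf.
.scan_scores <- function(code, S) {
  L <- ncol(S)
  n <- length(code)
  if (n < L) return(numeric(0))
  nw <- n - L + 1L
  sc <- numeric(nw)
  for (i in seq_len(L)) {
    v <- S[, i][code[i:(i + nw - 1L)]]
    v[is.na(v)] <- -Inf
    sc <- sc + v
  }
  sc
}

# Reverse-complement a score (or probability) matrix.
.rc_matrix <- function(S) S[4:1, rev(seq_len(ncol(S))), drop = FALSE]

#' Scan a sequence with a PWM
#'
#' Log2-odds scanning of both strands; a minus-strand hit at (0-based)
#' offset `o` means the reverse complement of `seq[o .. o+L)` matches the
#' motif. Hits with score >= `threshold_bits` are returned sorted by offset.
#'
#' @param sequence character scalar or `DNAString`.
#' @param pwm a [pwm()].
#' @param threshold_bits minimum score in bits.
#' @return data.table (offset, strand, score), 0-based offsets.
#' @export
scan_pwm <- function(sequence, pwm, threshold_bits) {
  stopifnot(inherits(pwm, "pwm"), is.finite(threshold_bits))
  code <- .encode_seq(sequence)
  fw <- .scan_scores(code, pwm$score)
  rv <- .scan_scores(code, .rc_matrix(pwm$score))
  hits <- data.table::data.table(
    offset = c(which(fw >= threshold_bits), which(rv >= threshold_bits)) - 1L,
    strand = rep(c("+", "-"),
                 c(sum(fw >= threshold_bits), sum(rv >= threshold_bits))),
    score = c(fw[fw >= threshold_bits], rv[rv >= threshold_bits]))
  data.table::setorder(hits, offset, strand)
  hits[]
}

#' Two-part motif
#'
#' The bipartite recognition sequence: a canonical ~20 bp core (module A)
#' and a shorter downstream module B, separated by a bounded gap. A site is
#' two-part-positive when a module A hit and a module B hit occur on the same
#' strand with A 5' of B and a gap (in bp between the end of A and the start
#' of B, reading 5'->3') within `[min_gap, max_gap]`.
#'
#' Default per-module thresholds are 60% of each module's maximum attainable
#' score in bits.
#'
#' @param module_a,module_b [pwm()] objects.
#' @param min_gap,max_gap allowed gap range in bp (defaults 0 and 15).
#' @param threshold_a,threshold_b per-module score thresholds in bits;
#'   `NULL` means 0.6 x max score.
#' @return an object of class `two_part_motif`.
#' @export
two_part_motif <- function(module_a, module_b, min_gap = 0, max_gap = 15,
                           threshold_a = NULL, threshold_b = NULL) {
  stopifnot(inherits(module_a, "pwm"), inherits(module_b, "pwm"),
            min_gap >= 0, min_gap <= max_gap)
  if (is.null(threshold_a)) threshold_a <- 0.6 * module_a$max_score
  if (is.null(threshold_b)) threshold_b <- 0.6 * module_b$max_score
  structure(list(module_a = module_a, module_b = module_b,
                 min_gap = min_gap, max_gap = max_gap,
                 threshold_a = threshold_a, threshold_b = threshold_b),
            class = "two_part_motif")
}

#' Default two-part motif used by the synthetic generator
#'
#' Synthetic stand-ins for the discovered motif pair: module A resembles the
#' canonical 20 bp CTCF core, module B a short downstream module, both as
#' near-deterministic PWMs built from a consensus. They are NOT database
#' matrices; real analyses should load matrices with [read_jaspar()] or
#' [read_meme_minimal()].
#'
#' @inheritParams two_part_motif
#' @export
default_two_part_motif <- function(min_gap = 0, max_gap = 15) {
  two_part_motif(
    module_a = pwm_from_consensus("TGGCCACCAGGGGGCGCTAC"),
    module_b = pwm_from_consensus("CTGCAGTGGC"),
    min_gap = min_gap, max_gap = max_gap)
}

# TRUE when one sequence contains a valid A..gap..B arrangement.
.two_part_positive_seq <- function(sequence, motif) {
  ha <- scan_pwm(sequence, motif$module_a, motif$threshold_a)
  if (nrow(ha) == 0L) return(FALSE)
  hb <- scan_pwm(sequence, motif$module_b, motif$threshold_b)
  if (nrow(hb) == 0L) return(FALSE)
  La <- motif$module_a$length
  Lb <- motif$module_b$length
  for (st in c("+", "-")) {
    a <- ha$offset[ha$strand == st]
    b <- hb$offset[hb$strand == st]
    if (!length(a) || !length(b)) next
    gap <- if (st == "+") outer(b, a + La, "-") else outer(a, b + Lb, "-")
    if (any(gap >= motif$min_gap & gap <= motif$max_gap)) return(TRUE)
  }
  FALSE
}

#' Per-site two-part motif calls
#'
#' @param sites a peak set.
#' @param sequences a named [Biostrings::DNAStringSet].
#' @param motif a [two_part_motif()].
#' @param window half-width of the scanned window in bp.
#' @return logical vector, one entry per site.
#' @export
two_part_positive <- function(sites, sequences,
                              motif = default_two_part_motif(),
                              window = 100) {
  seqs <- site_sequences(sites, sequences, window = window)
  vapply(seqs, .two_part_positive_seq, logical(1), motif = motif,
         USE.NAMES = FALSE)
}

#' Two-part motif occurrence fraction per site class
#'
#' Extracts a window of `window` bp either side of each site anchor and
#' reports, per class, the fraction of sites containing the two-part motif.
#'
#' @param c a `classified_sites` object.
#' @param sequences a [Biostrings::DNAStringSet] named by chromosome.
#' @param motif a [two_part_motif()] (default [default_two_part_motif()]).
#' @param window half-width of the scanned window in bp (default 100).
#' @return data.table (class, n, positives, fraction); `NA` fraction for an
#'   empty class.
#' @export
two_part_fraction <- function(c, sequences, motif = default_two_part_motif(),
                              window = 100) {
  stopifnot(inherits(c, "classified_sites"), inherits(motif, "two_part_motif"))
  rows <- lapply(c("IM", "IO", "MO"), function(cl) {
    p <- .class_peaks(c, cl)
    if (length(p) == 0L)
      return(data.table::data.table(class = cl, n = 0L, positives = 0L,
                                    fraction = NA_real_))
    pos <- two_part_positive(p, sequences, motif = motif, window = window)
    data.table::data.table(class = cl, n = length(p),
                           positives = sum(pos),
                           fraction = mean(pos))
  })
  data.table::rbindlist(rows)
}

#' Extract anchor-centered sequences
#'
#' @param sites a peak set.
#' @param sequences a named [Biostrings::DNAStringSet].
#' @param window half-width in bp; windows are clipped at chromosome ends.
#' @return character vector of sequences, one per site.
#' @export
site_sequences <- function(sites, sequences, window = 100) {
  a <- anchor_positions(sites)
  chrom <- as.character(GenomicRanges::seqnames(sites))
  len <- Biostrings::width(sequences)[match(chrom, names(sequences))]
  lo <- pmax(a - window, 0)
  hi <- pmin(a + window + 1, len)
  out <- character(length(sites))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    vw <- Biostrings::Views(sequences[[ch]], start = lo[i] + 1, end = hi[i])
    out[i] <- as.character(vw)
  }
  out
}
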