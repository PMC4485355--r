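#' Classify binding sites by cell-cycle occupancy
#'
#' Partitions an interphase peak set and a mitosis peak set for one factor
#' into the three occupancy classes: interphase-mitosis-common (IM) sites are
#' interphase peaks overlapping at least one mitosis peak by at least
#' `min_overlap` bp (coordinates taken from the interphase record);
#' interphase-only (IO) sites are the remaining interphase peaks;
#' mitosis-only (MO) sites are mitosis peaks with no qualifying overlap with
#' any interphase peak. The partition conserves the interphase count:
#' `|IM| + |IO|` equals the number of interphase peaks.
#'
#' @param interphase,mitosis peak sets normalized against the same genome.
#' @param min_overlap minimum overlap in bp to call two peaks the same site
#'   (default 1).
#' @return an object of class `classified_sites`: a list with peak sets
#'   `im`, `io`, `mo`, the source counts and `min_overlap`.
#' @export
classify_sites <- function(interphase, mitosis, min_overlap = 1L) {
  if (!.same_genome(interphase, mitosis))
    stop("classify_sites: interphase and mitosis sets use different genomes")
  if (!is.numeric(min_overlap) || min_overlap < 1)
    stop("classify_sites: min_overlap must be >= 1")
  hits <- GenomicRanges::findOverlaps(interphase, mitosis,
                                      minoverlap = as.integer(min_overlap),
                                      ignore.strand = TRUE)
  im_idx <- unique(S4Vectors::queryHits(hits))
  mo_idx <- setdiff(seq_along(mitosis), S4Vectors::subjectHits(hits))
  out <- list(
    im = interphase[sort(im_idx)],
    io = interphase[setdiff(seq_along(interphase), im_idx)],
    mo = mitosis[sort(mo_idx)],
    source_interphase_count = length(interphase),
    source_mitosis_count = length(mitosis),
    min_overlap = as.integer(min_overlap))
  class(out) <- "classified_sites"
  out
}

#' @export
print.classified_sites <- function(x, ...) {
  n <- site_class_counts(x)
  cat("classified_sites:", sum(n), "sites\n")
  p <- class_proportions(x)
  for (cl in names(n))
    cat(sprintf("  %s: %6d (%.3f)\n", cl, n[[cl]], p[[cl]]))
  invisible(x)
}

#' Per-class site counts and proportions
#'
#' @param c a `classified_sites` object.
#' @return `site_class_counts()`: named integer vector (IM, IO, MO).
#'   `class_proportions()`: named numeric vector summing to 1.
#' @export
site_class_counts <- function(c) {
  stopifnot(inherits(c, "classified_sites"))
  c(IM = length(c$im), IO = length(c$io), MO = length(c$mo))
}

#' @rdname site_class_counts
#' @param digits optional rounding of the reported fractions.
#' @export
class_proportions <- function(c, digits = NULL) {
  n <- site_class_counts(c)
  if (sum(n) == 0L) stop("class_proportions: empty classification")
  p <- n / sum(n)
  if (!is.null(digits)) p <- round(p, digits)
  p
}

# Peak set for one class label.
.class_peaks <- function(c, class) {
  stopifnot(inherits(c, "classified_sites"))
  switch(class, IM = c$im, IO = c$io, MO = c$mo,
         stop("unknown site class '", class, "'"))
}

#' Write classification outputs
#'
#' Emits one BED file per class (`<prefix>_IM.bed`, ...) and a TSV summary
#' with counts and fractions.
#'
#' @param c a `classified_sites` object.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix, e.g. the factor name.
#' @return invisibly, the summary table.
#' @export
write_classified_sites <- function(c, dir, prefix = "sites") {
  stopifnot(inherits(c, "classified_sites"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cl in c("IM", "IO", "MO"))
    write_peaks_bed(.class_peaks(c, cl),
                    file.path(dir, paste0(prefix, "_", cl, ".bed")))
  n <- site_class_counts(c)
  sm <- data.table::data.table(factor = prefix, class = names(n),
                               count = as.integer(n),
                               fraction = round(n / sum(n), 6))
  data.table::fwrite(sm, file.path(dir, paste0(prefix, "_summary.tsv")),
                     sep = "\t")
  invisible(sm)
}
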