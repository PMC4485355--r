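test_that("generated genome honors GC and determinism", {
  cfg <- synthetic_config(seed = 5L, chromosomes = c(c1 = 1e6))
  g <- generate_genome(cfg)
  f <- Biostrings::letterFrequency(g$sequences, c("A", "C", "G", "T"))
  gc <- sum(f[, c("C", "G")]) / sum(f)
  expect_lt(abs(gc - 0.42), 0.01)
  g2 <- generate_genome(cfg)
  expect_identical(as.character(g$sequences), as.character(g2$sequences))
  cfg2 <- synthetic_config(seed = 5L, chromosomes = c(c1 = 2e4),
                           background_gc = 1.0)
  s <- as.character(generate_genome(cfg2)$sequences[[1]])
  expect_equal(Biostrings::letterFrequency(
    Biostrings::DNAString(s), "GC"), c(`G|C` = 2e4))
  expect_error(synthetic_config(chromosomes = numeric(0)), "chromosome")
})

test_that("domains are sorted, non-overlapping; genes are packed validly", {
  sim <- small_sim()
  d <- sim$tads
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(d)),
    start = GenomicRanges::start(d) - 1, end = as.numeric(GenomicRanges::end(d)))
  bychrom <- split(dt, dt$chrom)
  for (x in bychrom) {
    expect_true(all(diff(x$start) > 0))
    expect_true(all(x$start[-1] >= x$end[-nrow(x)]))
  }
  genes <- sim$genes
  for (ch in unique(genes$chrom)) {
    x <- genes[genes$chrom == ch]
    o <- order(x$start)
    if (nrow(x) > 1L)
      expect_true(all(x$start[o][-1] >= x$end[o][-nrow(x)]))
  }
  # gene models written to GFF3 and read back are identical in structure
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff_genes(genes, f)
  back <- read_gff_genes(f)
  expect_equal(back$start, genes$start)
  expect_equal(back$tss, genes$tss)
  expect_equal(lapply(back$exons, unname), lapply(genes$exons, unname))
})

test_that("chain mappable fraction interacts with min_match as stated", {
  g <- list(genome = genome_table(c(c1 = 5e5)))
  mkcfg <- function(f) synthetic_config(
    seed = 9L, chromosomes = c(c1 = 5e5), mappable_fraction = f,
    n_species = 1L, minus_strand_prob = 0, n_genes = 20L)
  # fraction 1.0: every interval maps through the identity-like chain
  ann1 <- generate_annotations_and_domains(mkcfg(1.0), g)
  gt <- g$genome
  iv <- peak_set("c1", 2e5, 2e5 + 500, genome = gt)
  res <- map_through_chain(iv, ann1$chains_from_ref$sp1, min_match = 0.5)
  expect_false(is.null(res))
  expect_equal(res$mapped_fraction, 1)
  # fraction 0.4 with min_match 0.5: a full-length interval cannot map
  ann04 <- generate_annotations_and_domains(mkcfg(0.4), g)
  full <- peak_set("c1", 0, 5e5, genome = gt)
  mp <- map_intervals(full, ann04$chains_from_ref$sp1, min_match = 0.5)
  expect_true(is.na(mp$chrom))
  expect_lt(abs(mp$mapped_fraction - 0.4), 0.1)
})

test_that("generated chain files are valid and invert each other", {
  sim <- small_sim()
  f <- withr::local_tempfile(fileext = ".chain")
  write_chain(sim$chains_to_ref$sp1, f)
  back <- read_chain(f)  # span validation happens on read
  expect_length(back, length(sim$chains_to_ref$sp1))
  # map a reference interval out and back through the two directions
  gt <- sim$genome
  iv <- peak_set("chr1", 1e6, 1e6 + 300, genome = gt)
  out <- map_through_chain(iv, sim$chains_from_ref$sp1, min_match = 0.9)
  if (!is.null(out)) {
    g2 <- sim$species_genomes$sp1
    iv2 <- peak_set(out$chrom, out$start, out$end, genome = g2)
    home <- map_through_chain(iv2, sim$chains_to_ref$sp1, min_match = 0.9)
    expect_false(is.null(home))
    expect_equal(home$chrom, "chr1")
    expect_lte(abs(home$start - 1e6), out$end - out$start)
  }
})

test_that("full-fidelity round trip recovers the planted truth", {
  sim <- small_sim()
  cls <- classify_sites(sim$interphase, sim$mitosis)
  truth_counts <- table(sim$truth$class)
  expect_equal(unname(site_class_counts(cls)),
               as.integer(truth_counts[c("IM", "IO", "MO")]))
  # IM coordinates come from the interphase record
  expect_equal(sort(ctcfCycle:::.peak_key(cls$im)),
               sort(with(sim$truth[sim$truth$class == "IM"],
                         paste(chrom, start + 1, end, name, sep = "\r"))))
  # planted TSS fraction is recovered within binomial error
  imt <- sim$truth[sim$truth$class == "IM"]
  expect_equal(mean(imt$placement == "tss"), 0.33, tolerance = 0.02)
  cats <- assign_category(cls$im, sim$genes)
  planted <- mean(imt$placement == "tss")
  expect_gt(mean(cats == "TSS_region"), planted - 0.05)
})

test_that("all generator outputs are re-readable (write -> read identity)", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(seed = 19L, chromosomes = c(c1 = 3e5, c2 = 2e5),
                          n_genes = 20L, n_im = 15L, n_io = 25L, n_mo = 20L,
                          n_species = 1L, species_noise_peaks = 10L)
  sim <- simulate_dataset(cfg, dir = dir)
  gt <- read_chrom_sizes(sim$paths$chrom_sizes)
  expect_equal(unclass(gt), unclass(sim$genome))
  ip <- read_peaks_bed(sim$paths$interphase, gt)
  expect_equal(ctcfCycle:::.bed_coords(ip),
               ctcfCycle:::.bed_coords(sim$interphase))
  seqs <- Biostrings::readDNAStringSet(sim$paths$fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  expect_identical(as.character(seqs), as.character(sim$sequences))
  tr <- read_bedgraph(sim$paths$track_interphase, genome = gt)
  expect_equal(tr$value, sim$tracks$interphase$value)
  ch <- read_chain(sim$paths$chains[["sp1"]])
  expect_equal(length(ch), length(sim$chains_to_ref$sp1))
  # rerunning the same config reproduces the files byte for byte
  dir2 <- withr::local_tempdir()
  simulate_dataset(cfg, dir = dir2)
  for (f in c("interphase_peaks.bed", "genes.gff3", "truth.tsv",
              "sp1_to_ref.chain"))
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)))
})
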