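# single-gene fixtures for category assignment
plus_gene <- function() {
  gene_models(id = "gA", chrom = "chr2L", strand = "+",
              start = 5000, end = 12000,
              exons = list(rbind(c(5000, 7000), c(9000, 12000))),
              cds = list(rbind(c(5500, 7000), c(9000, 11000))))
}
minus_gene <- function() {
  gene_models(id = "gB", chrom = "chr2L", strand = "-",
              start = 2000, end = 8000,
              exons = list(rbind(c(2000, 4000), c(6000, 8000))),
              cds = list(rbind(c(2500, 4000), c(6000, 7500))))
}

anchor_site <- function(a, g) mk_peaks("chr2L", a, a + 1, g, summit = 0L)

test_that("assign_category follows the stated examples", {
  g <- tiny_genome()
  genes <- plus_gene()
  cat_at <- function(a, gn = genes) as.character(
    assign_category(anchor_site(a, g), gn))
  expect_equal(cat_at(4900), "TSS_region")
  expect_equal(cat_at(3500), "Promoter")
  expect_equal(cat_at(900000), "Intergenic")
  # minus-strand gene occupying [2000, 8000): TSS at 7999
  expect_equal(cat_at(8100, minus_gene()), "TSS_region")
  # gene-body categories on the plus-strand gene
  expect_equal(cat_at(5300), "UTR5")        # exonic, 5' of CDS start
  expect_equal(cat_at(6000), "CodingExon")
  expect_equal(cat_at(8000), "Intron")
  expect_equal(cat_at(12500), "Downstream")
  expect_error(assign_category(anchor_site(1, g), plus_gene()[0]), "genes")
})

test_that("assign_category matches the per-gene oracle on random inputs", {
  g <- tiny_genome(c(chr2L = 2e5, chrX = 1e5))
  withr::with_seed(17, {
    for (rep in 1:5) {
      cfg <- synthetic_config(seed = 1000L + rep,
                              chromosomes = c(chr2L = 2e5, chrX = 1e5),
                              n_genes = 12L, gene_length_range = c(1500, 6000))
      genes <- generate_annotations_and_domains(
        cfg, list(genome = tiny_genome(c(chr2L = 2e5, chrX = 1e5))))$genes
      n <- 200
      ci <- sample(c("chr2L", "chrX"), n, replace = TRUE)
      a <- ifelse(ci == "chr2L", sample.int(2e5, n) - 1, sample.int(1e5, n) - 1)
      sites <- peak_set(ci, a, a + 1, summit = 0L, genome = g)
      got <- as.character(assign_category(sites, genes))
      # sites were sorted by coordinate on construction
      a_sorted <- anchor_positions(sites)
      c_sorted <- as.character(GenomicRanges::seqnames(sites))
      want <- vapply(seq_len(n), function(i)
        oracle_category(a_sorted[i], c_sorted[i], genes), character(1))
      expect_equal(got, want)
    }
  })
})

test_that("category fractions per class sum to one", {
  sim <- small_sim()
  cls <- classify_sites(sim$interphase, sim$mitosis)
  cd <- category_distribution(cls, sim$genes)
  sums <- tapply(cd$fraction, cd$class, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_equal(nrow(cd), 21L)
})

test_that("fisher exact matches enumeration and the stated examples", {
  expect_equal(fisher_exact2x2(8, 2, 2, 8), oracle_fisher(8, 2, 2, 8))
  expect_equal(round(fisher_exact2x2(8, 2, 2, 8), 3), 0.023)
  expect_equal(fisher_exact2x2(5, 5, 5, 5), 1)
  # smallest attainable two-sided p for fixed margins
  expect_equal(fisher_exact2x2(10, 0, 0, 10), oracle_fisher(10, 0, 0, 10))
  expect_equal(fisher_exact2x2(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_error(fisher_exact2x2(-1, 2, 3, 4), "nonnegative")
  res <- compare_class_fractions(c(33, 67), c(25, 75))
  expect_equal(res$fraction1, 0.33)
  expect_equal(res$p_value, oracle_fisher(33, 67, 25, 75))
  expect_error(compare_class_fractions(c(0, 0), c(1, 1)), "empty")
})

test_that("gc_content counts G+C over ACGT, excluding N", {
  g <- genome_table(c(c1 = 12))
  seqs <- Biostrings::DNAStringSet(c(c1 = "GCGCATATGCAT"))
  site <- function(a, w) {
    p <- peak_set("c1", max(a - 1, 0), min(a + 2, 12), genome = g,
                  summit = a - max(a - 1, 0))
    gc_content(p, seqs, window = w)
  }
  expect_equal(gc_content(peak_set("c1", 0, 4, genome = g, summit = 1L),
                          seqs, window = 1), 1.0)   # "GCG"
  expect_equal(gc_content(peak_set("c1", 4, 8, genome = g, summit = 1L),
                          seqs, window = 1), 0.0)   # "TAT"
  expect_equal(gc_content(peak_set("c1", 7, 11, genome = g, summit = 2L),
                          seqs, window = 1), 2 / 3) # "GCA"
  nseq <- Biostrings::DNAStringSet(c(c1 = "NNNNNNNNNNNN"))
  expect_true(is.na(gc_content(peak_set("c1", 0, 4, genome = g, summit = 1L),
                               nseq, window = 1)))
})

test_that("gc_content is complement-balanced", {
  # swapping A<->G and T<->C complements the GC fraction
  g <- genome_table(c(c1 = 400))
  withr::with_seed(9, {
    s <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
               collapse = "")
  })
  swapped <- chartr("AGTC", "GACT", s)
  p <- peak_set("c1", 100, 300, genome = g)
  v1 <- gc_content(p, Biostrings::DNAStringSet(c(c1 = s)), window = 80)
  v2 <- gc_content(p, Biostrings::DNAStringSet(c(c1 = swapped)), window = 80)
  expect_equal(v1, 1 - v2)
})

test_that("BED12 gene models match their GFF3 equivalent", {
  f <- withr::local_tempfile(fileext = ".bed")
  # two-exon gene on -, CDS trimmed inside the blocks
  writeLines(paste(c("chr2L", 2000, 8000, "gB", 0, "-", 2500, 7500, "0",
                     2, "2000,2000", "0,4000"), collapse = "\t"), f)
  gm <- read_bed12_genes(f)
  expect_equal(gm$strand, "-")
  expect_equal(gm$tss, 7999)
  expect_equal(gm$tts, 2000)
  expect_equal(unname(gm$exons[[1]]), cbind(c(2000, 6000), c(4000, 8000)))
  expect_equal(unname(gm$cds[[1]]), cbind(c(2500, 6000), c(4000, 7500)))
  # same structure through the GFF3 writer/reader
  f2 <- withr::local_tempfile(fileext = ".gff3")
  write_gff_genes(gm, f2)
  gm2 <- read_gff_genes(f2)
  expect_equal(unname(gm2$cds[[1]]), unname(gm$cds[[1]]))
  g <- tiny_genome()
  a <- peak_set("chr2L", 3000, 3001, summit = 0L, genome = g)
  expect_equal(as.character(assign_category(a, gm)),
               as.character(assign_category(a, gm2)))
})
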