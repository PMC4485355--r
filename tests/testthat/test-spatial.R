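mk_domains <- function(g, starts, ends, chrom = "chr1") {
  domain_set(rep(chrom, length(starts)), starts, ends, genome = g)
}

simple_classified <- function(im, io = NULL, mo = NULL, g) {
  mk <- function(x) if (is.null(x)) peak_set(character(), numeric(),
                                             numeric(), genome = g) else x
  structure(list(im = mk(im), io = mk(io), mo = mk(mo),
                 source_interphase_count = length(mk(im)) + length(mk(io)),
                 source_mitosis_count = length(mk(im)) + length(mk(mo)),
                 min_overlap = 1L), class = "classified_sites")
}

test_that("boundary derivation dedupes shared edges and indexes in order", {
  g <- genome_table(c(chr1 = 1e6))
  d <- mk_domains(g, c(1000, 3000, 10000), c(3000, 6000, 20000))
  b <- domain_boundaries(d)
  expect_equal(b$pos, c(1000, 3000, 6000, 10000, 20000))
  expect_equal(b$index, 0:4)
})

test_that("boundary enrichment profile: planted and empty cases", {
  g <- genome_table(c(chr1 = 1e6))
  d <- mk_domains(g, seq(10000, 910000, by = 100000) - 10000 + 10000,
                  seq(10000, 910000, by = 100000) + 40000)
  b <- domain_boundaries(d)
  # sites exactly at every boundary -> all mass in the bins next to 0
  sites <- peak_set(rep("chr1", nrow(b)), b$pos - 50, b$pos + 50,
                    summit = 50L, genome = g)
  pr <- boundary_enrichment_profile(sites, d, flank = 10000, bin = 500)
  expect_equal(sum(pr$n[abs(pr$offset) > 500]), 0)
  expect_gt(sum(pr$n[abs(pr$offset) < 500]), 0)
  # sites at domain centers with a small flank -> empty profile
  centers <- floor((GenomicRanges::start(d) - 1 +
                      GenomicRanges::end(d)) / 2)
  csites <- peak_set(rep("chr1", length(centers)), centers - 50,
                     centers + 50, summit = 50L, genome = g)
  pr2 <- boundary_enrichment_profile(csites, d, flank = 10000, bin = 500)
  expect_equal(sum(pr2$n), 0)
  expect_error(boundary_enrichment_profile(sites, d[0], flank = 1000,
                                           bin = 100), "empty")
})

test_that("label_boundaries follows the containment rule", {
  g <- genome_table(c(chr1 = 1e6))
  d <- mk_domains(g, c(1000, 5000), c(3000, 9000))
  im <- peak_set("chr1", 1500, 1600, genome = g)          # inside [1000,3000)
  io <- peak_set("chr1", 2900, 3100, genome = g)          # spans boundary 3000
  cl <- simple_classified(im, io, NULL, g)
  lb <- label_boundaries(d, cl, containment = 500)
  # boundary at 1000: IM site [1500,1600) is within +-500? no (starts 1500)
  expect_false(lb$IM[lb$pos == 1000])
  # boundary at 3000 gets IO (overlap) and IM is 1400 away -> no
  expect_true(lb$IO[lb$pos == 3000])
  expect_false(lb$IM[lb$pos == 3000])
  # widen containment so the IM site reaches boundary 1000
  lb2 <- label_boundaries(d, cl, containment = 600)
  expect_true(lb2$IM[lb2$pos == 1000])
  # unlabeled boundaries are retained
  expect_true(all(c(5000, 9000) %in% lb$pos))
  expect_false(any(lb$MO))
})

test_that("minimum domain spacing matches the stated examples", {
  g <- genome_table(c(chr1 = 1e6))
  # five tiled domains D1..D5 -> boundaries B0..B5
  edges <- seq(0, 500000, by = 100000) + 1000
  d <- mk_domains(g, edges[-6], edges[-1])
  b <- domain_boundaries(d)
  expect_equal(nrow(b), 6L)
  ms <- ctcfCycle:::.min_domain_spacing(b$pos[c(2, 5)], rep("chr1", 2), d)
  expect_equal(ms, c(3, 3))  # labels at B1 and B4
  ms2 <- ctcfCycle:::.min_domain_spacing(b$pos[c(3, 4)], rep("chr1", 2), d)
  expect_equal(ms2, c(1, 1))  # adjacent boundaries B2, B3
})

test_that("spacing statistic equals the exhaustive oracle", {
  g <- genome_table(c(chr1 = 5e6, chr2 = 3e6))
  withr::with_seed(41, {
    for (rep in 1:30) {
      d1 <- ctcfCycle:::.tile_intervals(5e6, c(50000, 200000), c(5000, 20000))
      d2 <- ctcfCycle:::.tile_intervals(3e6, c(50000, 200000), c(5000, 20000))
      d <- domain_set(c(rep("chr1", nrow(d1)), rep("chr2", nrow(d2))),
                      c(d1[, 1], d2[, 1]), c(d1[, 2], d2[, 2]), genome = g)
      b <- domain_boundaries(d)
      k <- sample(2:min(10, nrow(b)), 1)
      sel <- sort(sample.int(nrow(b), k))
      got <- ctcfCycle:::.min_domain_spacing(b$pos[sel], b$chrom[sel], d)
      want <- oracle_min_spacing(
        b$pos[sel], b$chrom[sel],
        as.character(GenomicRanges::seqnames(d)),
        GenomicRanges::start(d) - 1, as.numeric(GenomicRanges::end(d)))
      expect_equal(got, want)
    }
  })
})

test_that("clustered sites are detected against the shuffled null", {
  g <- genome_table(c(chr1 = 2e7))
  withr::with_seed(77, {
    centers <- runif(10, 1e6, 1.9e7)
    a <- rep(centers, each = 50) + runif(500, -5000, 5000)
    p <- peak_set(rep("chr1", 500), a - 100, a + 100, genome = g)
  })
  res <- nearest_neighbor_permutation_test(p, p, n_perm = 200, seed = 5)
  expect_lt(res$p_value, 1e-4)
  expect_lt(res$observed_median, res$null_median)
})

test_that("permutation tests are deterministic under a fixed seed", {
  g <- genome_table(c(chr1 = 1e6))
  p <- peak_set(rep("chr1", 2), c(100000, 500000), c(100200, 500200),
                genome = g)
  r1 <- nearest_neighbor_permutation_test(p, p, n_perm = 50, seed = 13)
  r2 <- nearest_neighbor_permutation_test(p, p, n_perm = 50, seed = 13)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$null, r2$null)
  expect_equal(r1$observed, rep(400000, 2))
  expect_error(nearest_neighbor_permutation_test(p[1], p[1], n_perm = 5,
                                                 seed = 1),
               "insufficient")
})

test_that("the test is invariant to chromosome relabeling and global shift", {
  g1 <- genome_table(c(chrA = 2e6))
  g2 <- genome_table(c(chrB = 2e6))
  withr::with_seed(55, {
    s <- sort(floor(runif(40) * (2e6 - 200)))
  })
  p1 <- peak_set(rep("chrA", 40), s, s + 200, genome = g1)
  p2 <- peak_set(rep("chrB", 40), s, s + 200, genome = g2)
  r1 <- nearest_neighbor_permutation_test(p1, p1, n_perm = 30, seed = 2)
  r2 <- nearest_neighbor_permutation_test(p2, p2, n_perm = 30, seed = 2)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$observed, r2$observed)
})

test_that("label permutation conserves per-chromosome label counts", {
  g <- genome_table(c(chr1 = 5e6))
  dm <- ctcfCycle:::.tile_intervals
  withr::with_seed(61, {
    m <- dm(5e6, c(50000, 150000), c(5000, 20000))
  })
  d <- domain_set(rep("chr1", nrow(m)), m[, 1], m[, 2], genome = g)
  b <- domain_boundaries(d)
  lb <- data.table::copy(b)
  lab <- rep(FALSE, nrow(b))
  lab[seq(1, nrow(b), by = 3)] <- TRUE
  lb[, `:=`(IM = lab, IO = FALSE, MO = FALSE)]
  data.table::setattr(lb, "class", c("labeled_boundaries", class(lb)))
  res <- boundary_spacing_permutation_test(lb, d, "IM", n_perm = 100,
                                           seed = 4)
  # every permutation contributes the same number of spacing values as the
  # observed labeling (all labels on one chromosome, all with partners)
  expect_equal(length(res$null), 100 * sum(lab))
  expect_equal(length(res$observed), sum(lab))
})

test_that("clustered boundary labels are closer than the permuted null", {
  g <- genome_table(c(chr1 = 2e7))
  withr::with_seed(71, {
    m <- ctcfCycle:::.tile_intervals(2e7, c(80000, 120000), c(5000, 10000))
  })
  d <- domain_set(rep("chr1", nrow(m)), m[, 1], m[, 2], genome = g)
  b <- domain_boundaries(d)
  expect_gte(nrow(b), 100)
  lb <- data.table::copy(b)
  lab <- rep(FALSE, nrow(b))
  withr::with_seed(72, {
    runs <- sort(sample.int(nrow(b) - 5, 5))  # 5 runs of 4 adjacent labels
  })
  for (r in runs) lab[r:(r + 3)] <- TRUE
  lb[, `:=`(IM = lab, IO = FALSE, MO = FALSE)]
  data.table::setattr(lb, "class", c("labeled_boundaries", class(lb)))
  res <- boundary_spacing_permutation_test(lb, d, "IM", n_perm = 200,
                                           seed = 6)
  expect_lt(res$p_value, 0.05)
  expect_lt(res$observed_median, res$null_median)
})

test_that("cross-set tests shuffle targets only and stay deterministic", {
  g <- genome_table(c(chr1 = 5e6))
  withr::with_seed(91, {
    sb <- sort(floor(runif(30) * (5e6 - 200)))
    st <- sort(floor(runif(50) * (5e6 - 200)))
  })
  baits <- peak_set(rep("chr1", 30), sb, sb + 200, genome = g)
  targets <- peak_set(rep("chr1", 50), st, st + 200, genome = g)
  r1 <- nearest_neighbor_permutation_test(baits, targets, n_perm = 40,
                                          seed = 3)
  r2 <- nearest_neighbor_permutation_test(baits, targets, n_perm = 40,
                                          seed = 3)
  expect_identical(r1$p_value, r2$p_value)
  expect_equal(sort(r1$observed),
               sort(nearest_distances(baits, targets)))
  expect_true(r1$p_value >= 0 && r1$p_value <= 1)
  expect_equal(length(r1$null), 40L * 30L)  # one distance per bait, pooled
})
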