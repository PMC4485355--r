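test_that("chain parser validates spans and round-trips", {
  f <- withr::local_tempfile(fileext = ".chain")
  writeLines(c("chain 1000 chr2L 100000 + 100 700 q1 5000 + 50 580 1",
               "200 100 30", "300", ""), f)
  ch <- read_chain(f)
  expect_length(ch, 1L)
  expect_equal(ch[[1]]$blocks[, "size"], c(200, 300))
  f2 <- withr::local_tempfile(fileext = ".chain")
  write_chain(ch, f2)
  expect_equal(read_chain(f2), ch, ignore_attr = TRUE)
  bad <- withr::local_tempfile()
  writeLines(c("chain 1000 chr2L 100000 + 100 700 q1 5000 + 50 681 7",
               "200 100 30", "300"), bad)
  expect_error(read_chain(bad), "chain 7")
})

test_that("identity chains map intervals to themselves", {
  g <- tiny_genome(c(chr2L = 1e5))
  ch <- structure(list(list(
    score = 10, t_name = "chr2L", t_size = 1e5, t_strand = "+",
    t_start = 0, t_end = 1e5, q_name = "chr2L", q_size = 1e5,
    q_strand = "+", q_start = 0, q_end = 1e5, id = 1L,
    blocks = cbind(size = 1e5, dt = 0, dq = 0))), class = "chain_set")
  res <- map_through_chain(mk_peaks("chr2L", 4000, 4300, g), ch)
  expect_equal(res$start, 4000)
  expect_equal(res$end, 4300)
  expect_equal(res$mapped_fraction, 1)
})

test_that("min_match threshold controls mapping", {
  g <- tiny_genome(c(chr2L = 1e5))
  # chain covering only 40% of a 1000 bp interval
  ch <- structure(list(list(
    score = 10, t_name = "chr2L", t_size = 1e5, t_strand = "+",
    t_start = 1000, t_end = 1400, q_name = "q1", q_size = 5000,
    q_strand = "+", q_start = 0, q_end = 400, id = 1L,
    blocks = cbind(size = 400, dt = 0, dq = 0))), class = "chain_set")
  iv <- mk_peaks("chr2L", 1000, 2000, g)
  expect_null(map_through_chain(iv, ch, min_match = 0.5))
  res <- map_through_chain(iv, ch, min_match = 0.4)
  expect_equal(res$mapped_fraction, 0.4)
})

test_that("interval mapping equals the per-base oracle on random chains", {
  g <- tiny_genome(c(chr2L = 1e5))
  withr::with_seed(23, {
    for (rep in 1:100) {
      strand <- if (rep %% 2 == 0) "-" else "+"
      ch <- random_chain(q_strand = strand)
      s0 <- sample(0:(99000), 1)
      w <- sample(30:600, 1)
      iv <- mk_peaks("chr2L", s0, s0 + w, g)
      got <- map_through_chain(iv, ch, min_match = 0.5)
      want <- oracle_map_chain(s0, s0 + w, ch[[1]], min_match = 0.5)
      if (is.null(want)) expect_null(got)
      else {
        expect_equal(got$start, want$start)
        expect_equal(got$end, want$end)
        expect_equal(got$mapped_fraction, want$frac)
      }
    }
  })
})

test_that("best-scoring covering chain wins, ties broken by lowest id", {
  g <- tiny_genome(c(chr2L = 1e5))
  mk_chain <- function(score, id, q_off) list(
    score = score, t_name = "chr2L", t_size = 1e5, t_strand = "+",
    t_start = 0, t_end = 1e4, q_name = "q1", q_size = 1e5,
    q_strand = "+", q_start = q_off, q_end = q_off + 1e4, id = id,
    blocks = cbind(size = 1e4, dt = 0, dq = 0))
  chains <- structure(list(mk_chain(5, 2L, 0), mk_chain(9, 1L, 500),
                           mk_chain(9, 3L, 900)), class = "chain_set")
  res <- map_through_chain(mk_peaks("chr2L", 100, 200, g), chains)
  expect_equal(res$start, 600)  # id 1 among the two score-9 chains
})

test_that("conservation table flags overlap and is monotone in N", {
  sim <- small_sim()
  cls <- classify_sites(sim$interphase, sim$mitosis)
  all_sites <- c(cls$im, cls$io, cls$mo)
  ct <- conservation_table(all_sites, sim$species_peaks, sim$chains_to_ref)
  n2 <- sum(ct$conserved_in_at_least_2)
  n3 <- sum(ct$conserved_in_at_least_3)
  n4 <- sum(ct$conserved_in_at_least_4)
  expect_true(n2 >= n3 && n3 >= n4)
  # with 2 synthetic species, at-least-4 (= 3 others) is unattainable
  expect_equal(n4, 0L)
  # planted conservation is class-dependent: IM flagged more than MO
  cl <- rep(c("IM", "IO", "MO"), times = site_class_counts(cls))
  rate <- tapply(ct$conserved_in_at_least_2, cl, mean)
  expect_gt(rate[["IM"]], rate[["MO"]])
})

test_that("observed/expected follows the worked example and sums close", {
  # 100 sites, 20 conserved; class of 50 with 15 conserved -> O/E 1.5
  g <- tiny_genome(c(chr2L = 1e6))
  mkcl <- function(n_im, n_io, n_mo) {
    s <- seq(0, by = 1000, length.out = n_im + n_io + n_mo)
    structure(list(
      im = peak_set(rep("chr2L", n_im), s[1:n_im], s[1:n_im] + 100,
                    genome = g),
      io = peak_set(rep("chr2L", n_io), s[n_im + 1:n_io],
                    s[n_im + 1:n_io] + 100, genome = g),
      mo = peak_set(rep("chr2L", n_mo), s[n_im + n_io + 1:n_mo],
                    s[n_im + n_io + 1:n_mo] + 100, genome = g),
      source_interphase_count = n_im + n_io,
      source_mitosis_count = n_im + n_mo, min_overlap = 1L),
      class = "classified_sites")
  }
  cl <- mkcl(50, 30, 20)
  flags <- c(rep(TRUE, 15), rep(FALSE, 35),  # IM: 15/50
             rep(TRUE, 4), rep(FALSE, 26),   # IO: 4/30
             rep(TRUE, 1), rep(FALSE, 19))   # MO: 1/20
  tab <- data.table::data.table(site = paste0("s", 1:100), spX = flags)
  tab$conserved_in_at_least_2 <- flags
  tab$conserved_in_at_least_3 <- FALSE
  tab$conserved_in_at_least_4 <- FALSE
  oe <- observed_expected_conservation(cl, tab, N = 2)
  im <- oe[oe$class == "IM"]
  expect_equal(im$expected, 20 * 50 / 100)
  expect_equal(im$oe_ratio, 1.5)
  expect_equal(im$p_value, oracle_fisher(15, 35, 5, 45))
  # invariants: observed sums to total conserved; size-weighted mean O/E = 1
  expect_equal(sum(oe$observed), 20)
  expect_equal(sum(oe$oe_ratio * oe$expected) / 20, 1, tolerance = 1e-12)
  # every site conserved -> all O/E 1, p 1
  tab2 <- data.table::copy(tab)
  tab2$conserved_in_at_least_2 <- TRUE
  oe2 <- observed_expected_conservation(cl, tab2, N = 2)
  expect_equal(oe2$oe_ratio, rep(1, 3))
  expect_equal(oe2$p_value, rep(1, 3))
})
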