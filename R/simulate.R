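#' Synthetic dataset configuration
#'
#' One configuration object drives every synthetic input the pipeline
#' consumes. Defaults emulate the analyzed Drosophila world at reduced
#' scale: the six whitelisted chromosome arms (total ~21 Mb instead of the
#' full genome), 4,145 binding sites split 21/49/30% into IM/IO/MO,
#' class-specific TSS-proximal fractions of 33%/25%/10%, two-part motif
#' planting at 60%/51%/29% and a GC-rich mitosis-only class (0.55 versus a
#' 0.42 background). All fractions are in `[0, 1]`; the same configuration
#' and seed reproduce every output byte-identically.
#'
#' @param seed integer seed.
#' @param chromosomes named vector of chromosome lengths in bp (>= 10 kb).
#' @param background_gc background GC fraction of the generated sequence.
#' @param n_genes number of gene models (placed without overlap).
#' @param gene_length_range,exons_per_gene gene structure parameters.
#' @param noncoding_fraction fraction of genes without CDS.
#' @param n_im,n_io,n_mo per-class site counts.
#' @param peak_width_range peak width range in bp.
#' @param im_jitter maximum |offset| between the interphase and mitosis
#'   record of an IM site; must stay below the minimum peak width so the
#'   pair always overlaps and classification recovers the truth exactly.
#' @param tss_fraction,boundary_fraction,cluster_fraction named per-class
#'   fractions of sites placed near TSSs, near TAD boundaries, or in
#'   clusters (the rest is uniform).
#' @param cluster_count,cluster_radius cluster structure (centers per class,
#'   radius in bp).
#' @param motif_fraction per-class fraction of sites with a planted
#'   two-part motif.
#' @param motif_gap gap in bp between the planted modules.
#' @param gc_target per-class GC content planted across the site interval
#'   (`NA` = background).
#' @param domain_width_range,domain_gap_range TAD geometry in bp.
#' @param synteny_width_range,synteny_gap_range syntenic-block geometry.
#' @param n_species number of other species for conservation (max 3 used by
#'   the at-least-N summary).
#' @param mappable_fraction fraction of aligned bases per chain.
#' @param minus_strand_prob probability that a species chromosome aligns on
#'   the minus strand.
#' @param conserved_fraction named per-class probability that a site has a
#'   counterpart peak in each other species.
#' @param species_noise_peaks species-specific (non-conserved) peaks per
#'   species.
#' @param signal_amplitude,signal_background,signal_halfwidth signal-track
#'   shape: plateau height per class over `[summit - hw, summit + hw)`, on a
#'   background of 0.
#' @param tss_window TSS planting half-width (matches the 200 bp category).
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    seed = 1L,
    chromosomes = c("2L" = 4e6, "2R" = 4e6, "3L" = 4e6, "3R" = 4e6,
                    "4" = 1e6, "X" = 4e6),
    background_gc = 0.42,
    n_genes = 1800,
    gene_length_range = c(1500, 8000),
    exons_per_gene = c(1L, 5L),
    noncoding_fraction = 0.1,
    n_im = 870L, n_io = 2031L, n_mo = 1244L,
    peak_width_range = c(200, 400),
    im_jitter = 50,
    tss_fraction = c(IM = 0.33, IO = 0.25, MO = 0.10),
    boundary_fraction = c(IM = 0.15, IO = 0.10, MO = 0.10),
    cluster_fraction = c(IM = 0, IO = 0, MO = 0),
    cluster_count = c(IM = 10L, IO = 10L, MO = 10L),
    cluster_radius = 5000,
    motif_fraction = c(IM = 0.60, IO = 0.51, MO = 0.29),
    motif_gap = 5,
    gc_target = c(IM = NA, IO = NA, MO = 0.55),
    domain_width_range = c(50000, 200000),
    domain_gap_range = c(5000, 20000),
    synteny_width_range = c(200000, 500000),
    synteny_gap_range = c(10000, 50000),
    n_species = 3L,
    mappable_fraction = 0.7,
    minus_strand_prob = 0.3,
    conserved_fraction = c(IM = 0.8, IO = 0.4, MO = 0.05),
    species_noise_peaks = 200L,
    signal_amplitude = c(IM = 10, IO = 6, MO = 6),
    signal_background = 0,
    signal_halfwidth = 100,
    tss_window = 200) {
  cfg <- as.list(environment())
  frac <- c(cfg$tss_fraction, cfg$boundary_fraction, cfg$cluster_fraction,
            cfg$motif_fraction, cfg$mappable_fraction,
            cfg$conserved_fraction, cfg$background_gc)
  if (any(frac < 0 | frac > 1, na.rm = TRUE))
    stop("synthetic_config: fractions must lie in [0, 1]")
  if (any(cfg$chromosomes < 1e4))
    stop("synthetic_config: chromosome lengths must be >= 10 kb")
  if (length(cfg$chromosomes) == 0L)
    stop("synthetic_config: at least one chromosome required")
  if (cfg$im_jitter >= cfg$peak_width_range[1L])
    stop("synthetic_config: im_jitter must be below the minimum peak width")
  structure(cfg, class = "synthetic_config")
}

#' Generate the synthetic genome
#'
#' i.i.d. bases at the configured background GC.
#'
#' @param config a [synthetic_config()].
#' @return list with `genome` (a [genome_table()]) and `sequences`
#'   (a `DNAStringSet` named by chromosome).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  genome <- genome_table(config$chromosomes)
  gc <- config$background_gc
  pr <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  base_utf8 <- utf8ToInt("ACGT")
  seqs <- withr::with_seed(config$seed + 1L, {
    lapply(as.numeric(genome), function(L)
      intToUtf8(base_utf8[sample.int(4L, L, replace = TRUE, prob = pr)]))
  })
  sequences <- Biostrings::DNAStringSet(unlist(seqs))
  names(sequences) <- names(genome)
  list(genome = genome, sequences = sequences)
}

# Draw integer uniformly in [lo, hi].
.runifi <- function(n, lo, hi) lo + floor(stats::runif(n) * (hi - lo + 1))

# Tile one chromosome with non-overlapping intervals.
.tile_intervals <- function(L, width_range, gap_range) {
  out <- list()
  pos <- .runifi(1L, gap_range[1L], gap_range[2L])
  repeat {
    w <- .runifi(1L, width_range[1L], width_range[2L])
    if (pos + w > L) break
    out[[length(out) + 1L]] <- c(pos, pos + w)
    pos <- pos + w + .runifi(1L, gap_range[1L], gap_range[2L])
  }
  if (length(out)) do.call(rbind, out) else matrix(numeric(0), ncol = 2L)
}

#' Generate gene models, domains, syntenic blocks and chains
#'
#' Genes are slotted without overlap, with random strand, exon count and
#' (for coding genes) CDS obtained by trimming untranslated ends in
#' transcript order. TADs and syntenic blocks tile a fraction of each
#' chromosome set by the width/gap ranges. For each other species, one
#' chain per chromosome aligns a `mappable_fraction` of bases, with random
#' internal gaps on both sides and minus-strand alignments at the
#' configured probability; chains are emitted in both directions
#' (reference -> species and species -> reference).
#'
#' @param config a [synthetic_config()].
#' @param genome output of [generate_genome()] (the `genome` element is
#'   required; sequences are not used here).
#' @return list: `genes`, `tads`, `synteny` (domain sets), `alignments`
#'   (internal block lists), `chains_to_ref` (named list of `chain_set`,
#'   species -> reference, as used by the conservation stage),
#'   `chains_from_ref`, `species_genomes`.
#' @export
generate_annotations_and_domains <- function(config, genome) {
  stopifnot(inherits(config, "synthetic_config"))
  gt <- genome$genome
  withr::with_seed(config$seed + 2L, {
    genes <- .gen_genes(config, gt)
    tads <- .gen_domains(config$domain_width_range, config$domain_gap_range,
                         "TAD", gt)
    synteny <- .gen_domains(config$synteny_width_range,
                            config$synteny_gap_range, "synteny12D", gt)
    al <- .gen_alignments(config, gt)
    list(genes = genes, tads = tads, synteny = synteny,
         alignments = al$alignments,
         chains_to_ref = al$chains_to_ref,
         chains_from_ref = al$chains_from_ref,
         species_genomes = al$species_genomes)
  })
}

.gen_genes <- function(config, gt) {
  L <- as.numeric(gt)
  slot <- config$gene_length_range[2L] + 500
  nslot <- floor(L / slot)
  ng <- round(config$n_genes * L / sum(L))
  if (any(ng > nslot))
    stop("generate_annotations_and_domains: too many genes for chromosome ",
         names(gt)[which(ng > nslot)[1L]])
  rows <- list()
  for (ci in seq_along(L)) {
    if (ng[ci] == 0L) next
    slots <- sort(sample.int(nslot[ci], ng[ci])) - 1L
    glen <- .runifi(ng[ci], config$gene_length_range[1L],
                    config$gene_length_range[2L])
    gstart <- slots * slot + .runifi(ng[ci], 0, slot - glen - 1)
    strand <- sample(c("+", "-"), ng[ci], replace = TRUE)
    for (k in seq_len(ng[ci])) {
      nex <- .runifi(1L, config$exons_per_gene[1L], config$exons_per_gene[2L])
      ex <- .split_exons(gstart[k], gstart[k] + glen[k], nex)
      coding <- stats::runif(1) > config$noncoding_fraction
      cds <- if (coding) .trim_cds(ex, strand[k]) else NULL
      rows[[length(rows) + 1L]] <- list(
        chrom = names(gt)[ci], strand = strand[k],
        start = gstart[k], end = gstart[k] + glen[k], exons = ex, cds = cds)
    }
  }
  gene_models(id = sprintf("gene%04d", seq_along(rows)),
              chrom = vapply(rows, `[[`, character(1), "chrom"),
              strand = vapply(rows, `[[`, character(1), "strand"),
              start = vapply(rows, `[[`, numeric(1), "start"),
              end = vapply(rows, `[[`, numeric(1), "end"),
              exons = lapply(rows, `[[`, "exons"),
              cds = lapply(rows, function(r) r$cds))
}

# Cut [s, e) into n exons separated by introns, all segments >= 50 bp;
# falls back to a single exon when the gene is too short.
.split_exons <- function(s, e, n) {
  len <- e - s
  nseg <- 2L * n - 1L
  if (n == 1L || len < 50 * nseg) return(cbind(s, e))
  cuts <- sort(sample.int(len - nseg * 50 + nseg - 1, nseg - 1L))
  w <- diff(c(0, cuts, len - nseg * 50 + nseg - 1)) - 1 + 50
  edges <- s + cumsum(c(0, w))
  idx <- seq(1L, nseg, by = 2L)
  cbind(edges[idx], edges[idx + 1L])
}

# CDS = exons with untranslated ends trimmed in transcript order.
.trim_cds <- function(ex, strand) {
  total <- sum(ex[, 2L] - ex[, 1L])
  u5 <- .runifi(1L, 50, 300)
  u3 <- .runifi(1L, 50, 300)
  if (total < u5 + u3 + 30) return(NULL)
  trim_l <- if (strand == "+") u5 else u3
  trim_r <- if (strand == "+") u3 else u5
  out <- list()
  for (j in seq_len(nrow(ex))) {
    s <- ex[j, 1L]; e <- ex[j, 2L]; w <- e - s
    dl <- min(trim_l, w); trim_l <- trim_l - dl; s <- s + dl
    out[[j]] <- c(s, e)
  }
  for (j in rev(seq_along(out))) {
    s <- out[[j]][1L]; e <- out[[j]][2L]; w <- max(e - s, 0)
    dr <- min(trim_r, w); trim_r <- trim_r - dr
    out[[j]][2L] <- e - dr
  }
  m <- do.call(rbind, out)
  m <- m[m[, 1L] < m[, 2L], , drop = FALSE]
  if (nrow(m)) m else NULL
}

.gen_domains <- function(width_range, gap_range, kind, gt) {
  rows <- lapply(seq_along(gt), function(ci) {
    m <- .tile_intervals(as.numeric(gt)[ci], width_range, gap_range)
    if (nrow(m)) data.table::data.table(chrom = names(gt)[ci],
                                        start = m[, 1L], end = m[, 2L])
  })
  dt <- data.table::rbindlist(Filter(Negate(is.null), rows))
  domain_set(dt$chrom, dt$start, dt$end, kind = kind, genome = gt)
}

# Neutral alignment for one (species, chromosome): blocks in reference
# order with reference starts m, sizes sz, species-strand-frame starts r,
# species strand and chromosome size.
.gen_alignments <- function(config, gt) {
  f <- config$mappable_fraction
  species <- paste0("sp", seq_len(config$n_species))
  alignments <- list()
  species_genomes <- list()
  chains_to_ref <- list()
  chains_from_ref <- list()
  id <- 0L
  for (sp in species) {
    sp_lens <- numeric(0)
    al_sp <- list()
    ch_to <- list()
    ch_from <- list()
    for (ci in seq_along(gt)) {
      L <- as.numeric(gt)[ci]
      chrom <- names(gt)[ci]
      m <- list(); sz <- list()
      pos <- .runifi(1L, 0, 3000)
      repeat {
        s <- .runifi(1L, 5000, 20000)
        if (f >= 1) gap <- 0
        else gap <- max(0, round(s * (1 - f) / f * stats::runif(1, 0.5, 1.5)))
        if (pos + s > L) {
          if (L - pos > 1000 && length(m) == 0L) s <- L - pos else break
        }
        m[[length(m) + 1L]] <- pos
        sz[[length(sz) + 1L]] <- s
        pos <- pos + s + max(gap, if (f >= 1) 0 else 1)
        if (pos >= L) break
      }
      m <- unlist(m); sz <- unlist(sz)
      k <- length(m)
      sp_gap <- if (k > 1L) .runifi(k - 1L, 0, 500) else numeric(0)
      if (f >= 1) sp_gap <- rep(0, max(k - 1L, 0))
      pad <- .runifi(1L, 0, 5000)
      r <- pad + c(0, cumsum(sz[-k] + sp_gap))
      strand <- if (stats::runif(1) < config$minus_strand_prob) "-" else "+"
      sp_chrom <- paste0(sp, "_", chrom)
      sp_size <- r[k] + sz[k] + .runifi(1L, 0, 5000)
      al <- list(chrom = chrom, sp_chrom = sp_chrom, m = m, sz = sz, r = r,
                 strand = strand, sp_size = sp_size, ref_size = L)
      al_sp[[chrom]] <- al
      sp_lens[sp_chrom] <- sp_size
      id <- id + 1L
      score <- .runifi(1L, 1e4, 1e6)
      ch_from[[length(ch_from) + 1L]] <-
        .alignment_chain(al, direction = "from_ref", score = score, id = id)
      id <- id + 1L
      ch_to[[length(ch_to) + 1L]] <-
        .alignment_chain(al, direction = "to_ref", score = score, id = id)
    }
    alignments[[sp]] <- al_sp
    species_genomes[[sp]] <- genome_table(sp_lens)
    chains_to_ref[[sp]] <- structure(ch_to, class = "chain_set")
    chains_from_ref[[sp]] <- structure(ch_from, class = "chain_set")
  }
  list(alignments = alignments, species_genomes = species_genomes,
       chains_to_ref = chains_to_ref, chains_from_ref = chains_from_ref)
}

# Emit one UCSC chain from a neutral alignment, in either direction.
.alignment_chain <- function(al, direction, score, id) {
  k <- length(al$m)
  if (direction == "from_ref") {
    # target = reference (+), query = species (species-strand frame)
    TT <- al$m; SS <- al$sz; QQ <- al$r
    hdr <- list(t_name = al$chrom, t_size = al$ref_size,
                q_name = al$sp_chrom, q_size = al$sp_size,
                q_strand = al$strand)
  } else {
    # target = species forward strand, query = reference
    if (al$strand == "+") {
      TT <- al$r; SS <- al$sz; QQ <- al$m
      hdr <- list(t_name = al$sp_chrom, t_size = al$sp_size,
                  q_name = al$chrom, q_size = al$ref_size, q_strand = "+")
    } else {
      # species forward order reverses the block list; reference coords go
      # to the reference minus-strand frame
      ord <- rev(seq_len(k))
      TT <- (al$sp_size - (al$r + al$sz))[ord]
      SS <- al$sz[ord]
      QQ <- (al$ref_size - (al$m + al$sz))[ord]
      hdr <- list(t_name = al$sp_chrom, t_size = al$sp_size,
                  q_name = al$chrom, q_size = al$ref_size, q_strand = "-")
    }
  }
  blocks <- matrix(0, nrow = k, ncol = 3L,
                   dimnames = list(NULL, c("size", "dt", "dq")))
  blocks[, "size"] <- SS
  if (k > 1L) {
    blocks[-k, "dt"] <- TT[-1L] - (TT[-k] + SS[-k])
    blocks[-k, "dq"] <- QQ[-1L] - (QQ[-k] + SS[-k])
  }
  c(list(score = score, t_strand = "+",
         t_start = TT[1L], t_end = TT[k] + SS[k],
         q_start = QQ[1L], q_end = QQ[k] + SS[k], id = id,
         blocks = blocks), hdr)
}

# Map reference positions to species forward-strand coordinates through a
# neutral alignment; NA in gaps.
.alignment_map <- function(pos, al) {
  j <- findInterval(pos, al$m)
  jj <- pmax(j, 1L)
  ok <- j >= 1L & pos < al$m[jj] + al$sz[jj]
  q <- rep(NA_real_, length(pos))
  q[ok] <- al$r[jj[ok]] + (pos[ok] - al$m[jj[ok]])
  if (al$strand == "-") q[ok] <- al$sp_size - 1 - q[ok]
  q
}

#' Generate peak sets, species peaks, signal tracks and the truth table
#'
#' Sites are planted class by class (TSS-proximal, boundary-proximal,
#' clustered, uniform), IM sites are written into both peak sets with a
#' bounded jitter so the pair always overlaps, and accidental cross-class
#' overlaps between the interphase and mitosis sets are re-placed so the
#' classification recovers the planted truth exactly. When sequences are
#' supplied, class GC targets are written across the site intervals and the
#' two-part motif consensus is planted at the configured per-class
#' fractions. Species peak sets contain the class-dependent conserved
#' counterparts of reference sites (mapped through the synthetic
#' alignments) plus species-specific noise peaks.
#'
#' @param config a [synthetic_config()].
#' @param genome output of [generate_genome()]; its `sequences` element is
#'   modified (GC/motif planting) and returned.
#' @param annotations output of [generate_annotations_and_domains()].
#' @return list: `interphase`, `mitosis` (peak sets), `truth` (data.table),
#'   `sequences` (with planted features), `tracks` (list of two
#'   `signal_track`s), `species_peaks` (named list of peak sets in species
#'   coordinates).
#' @export
generate_peak_data <- function(config, genome, annotations) {
  stopifnot(inherits(config, "synthetic_config"))
  gt <- genome$genome
  withr::with_seed(config$seed + 3L, {
    truth <- .place_sites(config, gt, annotations)
    sequences <- genome$sequences
    if (!is.null(sequences))
      sequences <- .plant_sequences(config, sequences, truth)
    ip <- truth[truth$class %in% c("IM", "IO")]
    interphase <- peak_set(ip$chrom, ip$start, ip$end, name = ip$name,
                           summit = ip$summit, genome = gt)
    mt <- truth[truth$class %in% c("IM", "MO")]
    mitosis <- peak_set(mt$chrom, mt$start_m, mt$end_m, name = mt$name,
                        summit = mt$summit_m, genome = gt)
    tracks <- .gen_tracks(config, truth, gt)
    species_peaks <- .gen_species_peaks(config, truth, annotations)
    list(interphase = interphase, mitosis = mitosis, truth = truth,
         sequences = sequences, tracks = tracks,
         species_peaks = species_peaks)
  })
}

# Draw k anchors of one placement type. Cluster centers are drawn once per
# class and reused (so re-placements stay within the class's clusters).
.draw_of_type <- function(k, type, cls, config, gt, annotations, centers) {
  L <- as.numeric(gt)
  draw_uniform <- function(k) {
    ci <- sample.int(length(L), k, replace = TRUE, prob = L)
    list(chrom = names(gt)[ci], anchor = .runifi(k, 500, L[ci] - 500))
  }
  out <- switch(
    type,
    tss = {
      genes <- annotations$genes
      gi <- sample.int(nrow(genes), k, replace = TRUE)
      list(chrom = genes$chrom[gi],
           anchor = genes$tss[gi] + .runifi(k, -0.9 * config$tss_window,
                                            0.9 * config$tss_window))
    },
    boundary = {
      bnd <- domain_boundaries(annotations$tads)
      bi <- sample.int(nrow(bnd), k, replace = TRUE)
      list(chrom = bnd$chrom[bi],
           anchor = bnd$pos[bi] + .runifi(k, -400, 400))
    },
    cluster = {
      ki <- sample.int(length(centers$chrom), k, replace = TRUE)
      list(chrom = centers$chrom[ki],
           anchor = centers$anchor[ki] +
             .runifi(k, -config$cluster_radius, config$cluster_radius))
    },
    uniform = draw_uniform(k))
  out$anchor <- pmin(pmax(out$anchor, 500),
                     L[match(out$chrom, names(gt))] - 500)
  out$placement <- rep(type, k)
  out
}

# Cluster centers for one class (uniform over the genome, length-weighted).
.class_centers <- function(cls, config, gt) {
  L <- as.numeric(gt)
  nc <- max(1L, config$cluster_count[[cls]])
  ci <- sample.int(length(L), nc, replace = TRUE, prob = L)
  list(chrom = names(gt)[ci], anchor = .runifi(nc, 500, L[ci] - 500))
}

# Draw anchors for one class following its placement mix.
.draw_anchors <- function(n, cls, config, gt, annotations, centers) {
  n_tss <- round(config$tss_fraction[[cls]] * n)
  n_bnd <- round(config$boundary_fraction[[cls]] * n)
  n_clu <- round(config$cluster_fraction[[cls]] * n)
  n_uni <- n - n_tss - n_bnd - n_clu
  if (n_uni < 0) stop("generate_peak_data: placement fractions for ", cls,
                      " exceed 1")
  if (nrow(domain_boundaries(annotations$tads)) == 0L) n_bnd <- 0L
  if (nrow(annotations$genes) == 0L) n_tss <- 0L
  n_uni <- n - n_tss - n_bnd - n_clu
  parts <- list()
  for (spec in list(c("tss", n_tss), c("boundary", n_bnd),
                    c("cluster", n_clu), c("uniform", n_uni))) {
    k <- as.integer(spec[2L])
    if (k > 0)
      parts[[spec[1L]]] <- .draw_of_type(k, spec[1L], cls, config, gt,
                                         annotations, centers)
  }
  list(chrom = unlist(lapply(parts, `[[`, "chrom"), use.names = FALSE),
       anchor = unlist(lapply(parts, `[[`, "anchor"), use.names = FALSE),
       placement = unlist(lapply(parts, `[[`, "placement"),
                          use.names = FALSE))
}

# Build the truth table and resolve accidental interphase/mitosis overlaps
# so that only IM pairs overlap across the two sets.
.place_sites <- function(config, gt, annotations) {
  L <- as.numeric(gt)
  rows <- list()
  centers <- list()
  for (cls in c("IM", "IO", "MO")) {
    n <- config[[paste0("n_", tolower(cls))]]
    if (n == 0L) next
    centers[[cls]] <- .class_centers(cls, config, gt)
    a <- .draw_anchors(n, cls, config, gt, annotations, centers[[cls]])
    w <- .runifi(n, config$peak_width_range[1L], config$peak_width_range[2L])
    clen <- L[match(a$chrom, names(gt))]
    start <- pmin(pmax(a$anchor - w %/% 2L, 0), clen - w)
    summit <- a$anchor - start
    summit <- pmin(pmax(summit, 0L), w - 1L)
    dt <- data.table::data.table(
      class = cls, chrom = a$chrom, start = start, end = start + w,
      summit = as.integer(summit), placement = a$placement, width = w)
    if (cls == "IM") {
      jit <- .runifi(n, -config$im_jitter, config$im_jitter)
      sm <- pmin(pmax(start + jit, 0), clen - w)
      dt[, `:=`(start_m = sm, end_m = sm + w,
                summit_m = as.integer(pmin(pmax(a$anchor - sm, 0L), w - 1L)))]
    } else if (cls == "MO") {
      dt[, `:=`(start_m = start, end_m = start + w,
                summit_m = as.integer(summit))]
    } else {
      dt[, `:=`(start_m = NA_real_, end_m = NA_real_, summit_m = NA_integer_)]
    }
    rows[[cls]] <- dt
  }
  truth <- data.table::rbindlist(rows)
  truth[, name := paste0(tolower(class), "_", seq_len(.N)), by = class]
  # motif / GC truth columns
  truth[, motif := FALSE]
  truth[, gc := NA_real_]
  for (cls in c("IM", "IO", "MO")) {
    i <- which(truth$class == cls)
    k <- round(config$motif_fraction[[cls]] * length(i))
    if (k > 0) truth$motif[i[sample.int(length(i), k)]] <- TRUE
    truth$gc[i] <- config$gc_target[[cls]]
  }
  .resolve_collisions(config, truth, gt, annotations, centers)
}

.resolve_collisions <- function(config, truth, gt, annotations, centers,
                                max_iter = 60L) {
  L <- as.numeric(gt)
  for (iter in seq_len(max_iter)) {
    ip <- which(truth$class %in% c("IM", "IO"))
    mt <- which(truth$class %in% c("IM", "MO"))
    gi <- GenomicRanges::GRanges(truth$chrom[ip],
                                 IRanges::IRanges(truth$start[ip] + 1,
                                                  truth$end[ip]))
    gm <- GenomicRanges::GRanges(truth$chrom[mt],
                                 IRanges::IRanges(truth$start_m[mt] + 1,
                                                  truth$end_m[mt]))
    hits <- GenomicRanges::findOverlaps(gi, gm)
    qi <- ip[S4Vectors::queryHits(hits)]
    sj <- mt[S4Vectors::subjectHits(hits)]
    # offending pairs: any overlap where either member is IO or MO
    bad <- truth$class[qi] == "IO" | truth$class[sj] == "MO"
    redo <- unique(c(qi[bad & truth$class[qi] == "IO" &
                          truth$class[sj] != "MO"],
                     sj[bad & truth$class[sj] == "MO"]))
    if (!length(redo)) return(truth[])
    # re-place each offender with a fresh draw of its own placement rule
    for (t in seq_along(redo)) {
      i <- redo[t]
      one <- .draw_of_type(1L, truth$placement[i], truth$class[i], config,
                           gt, annotations, centers[[truth$class[i]]])
      w <- truth$width[i]
      clen <- L[match(one$chrom, names(gt))]
      s <- min(max(one$anchor - w %/% 2L, 0), clen - w)
      truth$chrom[i] <- one$chrom
      truth$start[i] <- s
      truth$end[i] <- s + w
      truth$summit[i] <- as.integer(min(max(one$anchor - s, 0), w - 1))
      truth$placement[i] <- one$placement
      if (truth$class[i] %in% c("MO", "IM")) {
        truth$start_m[i] <- s
        truth$end_m[i] <- s + w
        truth$summit_m[i] <- truth$summit[i]
      }
    }
  }
  stop("generate_peak_data: could not resolve peak collisions; ",
       "reduce site counts or widths")
}

# GC rewriting then motif planting, sequentially per site (on plain R
# strings; converting back to a DNAStringSet once at the end).
.plant_sequences <- function(config, sequences, truth) {
  motif <- default_two_part_motif()
  consA <- paste(rownames(motif$module_a$prob)[
    apply(motif$module_a$prob, 2L, which.max)], collapse = "")
  consB <- paste(rownames(motif$module_b$prob)[
    apply(motif$module_b$prob, 2L, which.max)], collapse = "")
  insert <- paste0(consA, paste(rep("A", config$motif_gap), collapse = ""),
                   consB)
  raws <- lapply(stats::setNames(names(sequences), names(sequences)),
                 function(ch) charToRaw(as.character(sequences[[ch]])))
  base_raw <- charToRaw("ACGT")
  ins_raw <- charToRaw(insert)
  ins_len <- length(ins_raw)
  for (i in which(!is.na(truth$gc))) {
    w <- truth$end[i] - truth$start[i]
    gc <- truth$gc[i]
    pr <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    raws[[truth$chrom[i]]][(truth$start[i] + 1):truth$end[i]] <-
      base_raw[sample.int(4L, w, replace = TRUE, prob = pr)]
  }
  for (i in which(truth$motif)) {
    anchor <- truth$start[i] + truth$summit[i]
    s0 <- anchor - ins_len %/% 2L
    s0 <- max(0, min(s0, length(raws[[truth$chrom[i]]]) - ins_len))
    raws[[truth$chrom[i]]][(s0 + 1):(s0 + ins_len)] <- ins_raw
  }
  out <- Biostrings::DNAStringSet(vapply(raws, rawToChar, character(1)))
  names(out) <- names(raws)
  out
}

# Plateau-shaped signal tracks; interphase covers IM + IO, mitosis IM + MO.
.gen_tracks <- function(config, truth, gt) {
  hw <- config$signal_halfwidth
  amp <- config$signal_amplitude
  mk <- function(classes, use_m) {
    t <- truth[truth$class %in% classes]
    anchor <- if (use_m) t$start_m + t$summit_m else t$start + t$summit
    clen <- as.numeric(gt)[match(t$chrom, names(gt))]
    gr <- GenomicRanges::GRanges(
      factor(t$chrom, levels = names(gt)),
      IRanges::IRanges(pmax(anchor - hw, 0) + 1, pmin(anchor + hw, clen)),
      seqinfo = .genome_seqinfo(gt))
    cov <- GenomicRanges::coverage(gr, weight = amp[t$class])
    rows <- lapply(names(cov), function(ch) {
      r <- cov[[ch]]
      v <- S4Vectors::runValue(r) + config$signal_background
      s <- c(0, cumsum(S4Vectors::runLength(r)))
      keep <- v != 0
      data.table::data.table(chrom = ch, start = s[-length(s)][keep],
                             end = s[-1L][keep], value = v[keep])
    })
    dt <- data.table::rbindlist(rows)
    signal_track(dt$chrom, dt$start, dt$end, dt$value, genome = gt)
  }
  list(interphase = mk(c("IM", "IO"), use_m = FALSE),
       mitosis = mk(c("IM", "MO"), use_m = TRUE))
}

# Conserved counterparts of reference sites in each species, plus noise.
.gen_species_peaks <- function(config, truth, annotations) {
  out <- list()
  for (sp in names(annotations$alignments)) {
    al_sp <- annotations$alignments[[sp]]
    gt_sp <- annotations$species_genomes[[sp]]
    keep <- stats::runif(nrow(truth)) <
      config$conserved_fraction[truth$class]
    rows <- list()
    for (i in which(keep)) {
      al <- al_sp[[truth$chrom[i]]]
      if (is.null(al)) next
      q <- .alignment_map(truth$start[i]:(truth$end[i] - 1), al)
      if (mean(!is.na(q)) < 0.8) next
      rows[[length(rows) + 1L]] <-
        c(min(q, na.rm = TRUE), max(q, na.rm = TRUE) + 1,
          match(al$sp_chrom, names(gt_sp)))
    }
    nnoise <- config$species_noise_peaks
    if (nnoise > 0) {
      Ls <- as.numeric(gt_sp)
      ci <- sample.int(length(Ls), nnoise, replace = TRUE, prob = Ls)
      w <- .runifi(nnoise, config$peak_width_range[1L],
                   config$peak_width_range[2L])
      s <- .runifi(nnoise, 0, pmax(Ls[ci] - w, 1))
      for (k in seq_len(nnoise))
        rows[[length(rows) + 1L]] <- c(s[k], s[k] + w[k], ci[k])
    }
    m <- do.call(rbind, rows)
    out[[sp]] <- peak_set(names(gt_sp)[m[, 3L]], m[, 1L], m[, 2L],
                          genome = gt_sp)
  }
  out
}

#' Generate the full synthetic dataset
#'
#' Runs [generate_genome()], [generate_annotations_and_domains()] and
#' [generate_peak_data()] and, when `dir` is given, writes every output in
#' its standard text format: FASTA, chrom.sizes, peak BEDs (with summit
#' column), GFF3 gene models, TAD and syntenic-block BEDs, species peak
#' BEDs, UCSC chains (species to reference), bedGraph tracks and the truth
#' TSV, plus the configuration as JSON.
#'
#' @param config a [synthetic_config()].
#' @param dir optional output directory.
#' @param with_sequences set `FALSE` to skip sequence generation and
#'   GC/motif planting (faster, for interval-only studies).
#' @return list with all in-memory objects (`genome`, `sequences`, `genes`,
#'   `tads`, `synteny`, `chains_to_ref`, `species_genomes`, `interphase`,
#'   `mitosis`, `truth`, `tracks`, `species_peaks`, `config`, `paths`).
#' @export
simulate_dataset <- function(config = synthetic_config(), dir = NULL,
                             with_sequences = TRUE) {
  stopifnot(inherits(config, "synthetic_config"))
  g <- if (with_sequences) generate_genome(config)
  else list(genome = genome_table(config$chromosomes), sequences = NULL)
  ann <- generate_annotations_and_domains(config, g)
  pk <- generate_peak_data(config, g, ann)
  res <- list(genome = g$genome, sequences = pk$sequences,
              genes = ann$genes, tads = ann$tads, synteny = ann$synteny,
              chains_to_ref = ann$chains_to_ref,
              chains_from_ref = ann$chains_from_ref,
              species_genomes = ann$species_genomes,
              interphase = pk$interphase, mitosis = pk$mitosis,
              truth = pk$truth, tracks = pk$tracks,
              species_peaks = pk$species_peaks, config = config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    p <- list()
    p$chrom_sizes <- file.path(dir, "genome.chrom.sizes")
    write_chrom_sizes(res$genome, p$chrom_sizes)
    if (!is.null(res$sequences)) {
      p$fasta <- file.path(dir, "genome.fa")
      Biostrings::writeXStringSet(res$sequences, p$fasta)
    }
    p$interphase <- file.path(dir, "interphase_peaks.bed")
    write_peaks_bed(res$interphase, p$interphase)
    p$mitosis <- file.path(dir, "mitosis_peaks.bed")
    write_peaks_bed(res$mitosis, p$mitosis)
    p$genes <- file.path(dir, "genes.gff3")
    write_gff_genes(res$genes, p$genes)
    p$tads <- file.path(dir, "tads.bed")
    write_peaks_bed(res$tads, p$tads)
    p$synteny <- file.path(dir, "synteny.bed")
    write_peaks_bed(res$synteny, p$synteny)
    p$truth <- file.path(dir, "truth.tsv")
    data.table::fwrite(res$truth, p$truth, sep = "\t")
    p$track_interphase <- file.path(dir, "interphase_signal.bedgraph")
    write_bedgraph(res$tracks$interphase, p$track_interphase)
    p$track_mitosis <- file.path(dir, "mitosis_signal.bedgraph")
    write_bedgraph(res$tracks$mitosis, p$track_mitosis)
    p$chains <- character(0)
    p$species_peaks <- character(0)
    p$species_sizes <- character(0)
    for (sp in names(res$chains_to_ref)) {
      f <- file.path(dir, paste0(sp, "_to_ref.chain"))
      write_chain(res$chains_to_ref[[sp]], f)
      p$chains[sp] <- f
      f2 <- file.path(dir, paste0(sp, "_peaks.bed"))
      write_peaks_bed(res$species_peaks[[sp]], f2)
      p$species_peaks[sp] <- f2
      f3 <- file.path(dir, paste0(sp, ".chrom.sizes"))
      write_chrom_sizes(res$species_genomes[[sp]], f3)
      p$species_sizes[sp] <- f3
    }
    p$config <- file.path(dir, "config.json")
    .write_config_json(config, p$config)
    res$paths <- p
  }
  res
}

.write_config_json <- function(config, path) {
  x <- unclass(config)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}
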