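#' Pipeline configuration
#'
#' A pipeline run is driven by one configuration (an R list, or a JSON file
#' read with [read_pipeline_config()]) holding either a `synthetic` block
#' (overrides for [synthetic_config()]; inputs are then generated into
#' `<outdir>/inputs`) or an `inputs` block of file paths:
#' `chrom_sizes`, `interphase`, `mitosis` (required for every run), and
#' optionally `genes` (GFF3), `fasta`, `tads`, `synteny` (BED),
#' `chains`/`species_peaks`/`species_sizes` (named per species) and
#' `tracks` (`interphase`, `mitosis` bedGraphs).
#'
#' `stages` toggles `classify`, `annotate`, `conserve`, `motif`, `profile`
#' and `spatial` (all on by default; a stage missing its inputs fails fast
#' before anything runs). `params` holds the analysis parameters with the
#' study defaults: `min_overlap` 1 bp, `tss_window` 200 bp, `flank` 2000 bp,
#' `min_match` 0.5, `n_perm` 1000, `motif_window` 100 bp, `profile_flank`
#' 1000 bp, `profile_bin` 50 bp, `boundary_flank` 10000 bp, `boundary_bin`
#' 500 bp, `boundary_containment` 500 bp. `seed` seeds every stochastic
#' stage; identical configuration and seed give byte-identical reports.
#'
#' @param path JSON configuration file.
#' @return a named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("pipeline config not found: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

.default_params <- function() {
  list(min_overlap = 1, tss_window = 200, flank = 2000, min_match = 0.5,
       n_perm = 1000, motif_window = 100, profile_flank = 1000,
       profile_bin = 50, boundary_flank = 10000, boundary_bin = 500,
       boundary_containment = 500)
}

.default_stages <- function() {
  list(classify = TRUE, annotate = TRUE, conserve = TRUE, motif = TRUE,
       profile = TRUE, spatial = TRUE)
}

# Fill defaults and check that every enabled stage's inputs are resolvable.
.validate_config <- function(config, outdir) {
  cfg <- config
  cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  cfg$params <- utils::modifyList(.default_params(),
                                  as.list(cfg$params %||% list()))
  cfg$stages <- utils::modifyList(.default_stages(),
                                  as.list(cfg$stages %||% list()))
  if (is.null(cfg$synthetic) && is.null(cfg$inputs))
    stop("pipeline config needs either a 'synthetic' or an 'inputs' block")
  if (!is.null(cfg$inputs)) {
    req <- c("chrom_sizes", "interphase", "mitosis")
    need <- req
    if (isTRUE(cfg$stages$annotate)) need <- c(need, "genes")
    if (isTRUE(cfg$stages$conserve))
      need <- c(need, "chains", "species_peaks", "species_sizes")
    if (isTRUE(cfg$stages$motif)) need <- c(need, "fasta")
    if (isTRUE(cfg$stages$profile)) need <- c(need, "tracks")
    if (isTRUE(cfg$stages$spatial)) need <- c(need, "tads")
    miss <- setdiff(unique(need), names(cfg$inputs))
    if (length(miss))
      stop("pipeline config: missing input(s) for enabled stages: ",
           paste(miss, collapse = ", "))
    flat <- unlist(cfg$inputs, use.names = TRUE)
    absent <- flat[!file.exists(flat)]
    if (length(absent))
      stop("pipeline input file not found: ", absent[1L])
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Load all inputs named in the config into memory.
.load_inputs <- function(inputs) {
  genome <- read_chrom_sizes(inputs$chrom_sizes)
  d <- list(genome = genome,
            interphase = read_peaks_bed(inputs$interphase, genome),
            mitosis = read_peaks_bed(inputs$mitosis, genome))
  if (!is.null(inputs$genes)) d$genes <- read_gff_genes(inputs$genes)
  if (!is.null(inputs$fasta))
    d$sequences <- Biostrings::readDNAStringSet(inputs$fasta)
  if (!is.null(d$sequences))
    names(d$sequences) <- sub("\\s.*$", "", names(d$sequences))
  if (!is.null(inputs$tads))
    d$tads <- read_domains_bed(inputs$tads, kind = "TAD", genome = genome)
  if (!is.null(inputs$synteny))
    d$synteny <- read_domains_bed(inputs$synteny, kind = "synteny12D",
                                  genome = genome)
  if (!is.null(inputs$chains)) {
    d$chains <- lapply(inputs$chains, read_chain)
    spg <- lapply(inputs$species_sizes, read_chrom_sizes)
    d$species_peaks <- lapply(names(inputs$species_peaks), function(sp)
      read_peaks_bed(inputs$species_peaks[[sp]], spg[[sp]]))
    names(d$species_peaks) <- names(inputs$species_peaks)
  }
  if (!is.null(inputs$tracks))
    d$tracks <- lapply(inputs$tracks, read_bedgraph, genome = genome)
  d
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order (classify, then annotate,
#' conserve, motif, profile, spatial as enabled), writes per-stage TSV/BED
#' outputs plus a consolidated report (`report.json` and `report.txt`) into
#' `outdir`, and returns the report invisibly. Identical configuration and
#' seed produce byte-identical reports; disabled stages leave their report
#' sections absent.
#'
#' @param config a configuration list (see [read_pipeline_config()]) or a
#'   path to a JSON configuration.
#' @param outdir output directory, created if needed (defaults to
#'   `config$outdir`).
#' @return invisibly, the report list.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  outdir <- outdir %||% config$outdir
  if (is.null(outdir)) stop("run_pipeline: no output directory given")
  cfg <- .validate_config(config, outdir)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  prm <- cfg$params
  logfile <- file.path(outdir, "pipeline.log")
  unlink(logfile)
  log <- function(...) {
    msg <- paste0(...)
    message(msg)
    cat(msg, "\n", file = logfile, append = TRUE, sep = "")
  }
  # parameter provenance: study default vs user override
  defaults <- .default_params()
  for (nm in names(prm)) {
    src <- if (identical(prm[[nm]], defaults[[nm]])) "default" else "override"
    log("param ", nm, " = ", prm[[nm]], " (", src, ")")
  }
  if (!is.null(cfg$synthetic)) {
    sargs <- as.list(cfg$synthetic)
    if (!is.null(sargs$chromosomes))
      sargs$chromosomes <- unlist(sargs$chromosomes)
    for (nm in c("tss_fraction", "boundary_fraction", "cluster_fraction",
                 "motif_fraction", "gc_target", "signal_amplitude",
                 "conserved_fraction", "cluster_count"))
      if (!is.null(sargs[[nm]])) sargs[[nm]] <- unlist(sargs[[nm]])
    if (is.null(sargs$seed)) sargs$seed <- cfg$seed
    scfg <- do.call(synthetic_config, sargs)
    sim <- simulate_dataset(scfg, dir = file.path(outdir, "inputs"))
    d <- list(genome = sim$genome, interphase = sim$interphase,
              mitosis = sim$mitosis, genes = sim$genes,
              sequences = sim$sequences, tads = sim$tads,
              synteny = sim$synteny, chains = sim$chains_to_ref,
              species_peaks = sim$species_peaks, tracks = sim$tracks)
  } else {
    d <- .load_inputs(cfg$inputs)
  }
  report <- list(parameters = prm, seed = cfg$seed)

  log("stage: classify")
  cls <- classify_sites(d$interphase, d$mitosis,
                        min_overlap = prm$min_overlap)
  sm <- write_classified_sites(cls, outdir, prefix = "sites")
  report$classification <- list(
    counts = as.list(site_class_counts(cls)),
    proportions = as.list(round(class_proportions(cls), 6)),
    source_interphase = cls$source_interphase_count,
    source_mitosis = cls$source_mitosis_count,
    min_overlap = cls$min_overlap)

  if (isTRUE(cfg$stages$annotate) && !is.null(d$genes)) {
    log("stage: annotate")
    cd <- category_distribution(cls, d$genes, tss_window = prm$tss_window,
                                flank = prm$flank)
    data.table::fwrite(cd, file.path(outdir, "category_distribution.tsv"),
                       sep = "\t")
    tssrow <- function(cl) {
      x <- cd[cd$class == cl]
      k <- x$count[x$category == "TSS_region"]
      c(k, sum(x$count) - k)
    }
    cmp <- compare_class_fractions(tssrow("IM"), tssrow("IO"))
    report$annotation <- list(
      categories = split(cd$fraction, cd$class) |>
        lapply(stats::setNames, .GENOMIC_CATEGORIES),
      tss_im_vs_io = list(fraction_im = cmp$fraction1,
                          fraction_io = cmp$fraction2,
                          fisher_p = cmp$p_value))
    if (!is.null(d$sequences)) {
      gcv <- lapply(c("IM", "IO", "MO"), function(cl) {
        p <- .class_peaks(cls, cl)
        if (!length(p)) return(NA_real_)
        mean(gc_content(p, d$sequences, window = prm$motif_window),
             na.rm = TRUE)
      })
      report$annotation$mean_gc <- stats::setNames(gcv, c("IM", "IO", "MO"))
    }
  }

  if (isTRUE(cfg$stages$conserve) && !is.null(d$chains)) {
    log("stage: conserve")
    all_sites <- c(cls$im, cls$io, cls$mo)
    ct <- conservation_table(all_sites, d$species_peaks, d$chains,
                             min_match = prm$min_match,
                             ref_genome = d$genome)
    for (sp in names(d$species_peaks)) {
      mp <- map_intervals(d$species_peaks[[sp]], d$chains[[sp]],
                          min_match = prm$min_match)
      mp <- mp[!is.na(mp$chrom)]
      mp$name <- sprintf("%s_map_%d", sp, seq_len(nrow(mp)))
      data.table::fwrite(
        mp[, c("chrom", "start", "end", "name", "mapped_fraction")],
        file.path(outdir, paste0(sp, "_mapped.bed")),
        sep = "\t", col.names = FALSE)
    }
    oe <- data.table::rbindlist(lapply(2:4, function(N)
      cbind(N = N, observed_expected_conservation(cls, ct, N = N))))
    data.table::fwrite(oe, file.path(outdir, "conservation_oe.tsv"),
                       sep = "\t")
    report$conservation <- list(
      note = paste("MO-site conservation is rarely assessable with real",
                   "data (no mitotic ChIP in other species); interpret MO",
                   "rows with caution."),
      table = lapply(split(oe, oe$N), function(x)
        lapply(split(x, x$class), function(r)
          list(observed = r$observed, expected = r$expected,
               oe_ratio = r$oe_ratio, p_value = r$p_value))))
  }

  if (isTRUE(cfg$stages$motif) && !is.null(d$sequences)) {
    log("stage: motif")
    mf <- two_part_fraction(cls, d$sequences, window = prm$motif_window)
    hits <- data.table::rbindlist(lapply(c("IM", "IO", "MO"), function(cl) {
      p <- .class_peaks(cls, cl)
      if (!length(p)) return(NULL)
      data.table::data.table(
        class = cl, site = S4Vectors::mcols(p)$name,
        two_part = two_part_positive(p, d$sequences,
                                     window = prm$motif_window))
    }))
    data.table::fwrite(hits, file.path(outdir, "motif_sites.tsv"),
                       sep = "\t")
    data.table::fwrite(mf, file.path(outdir, "motif_fractions.tsv"),
                       sep = "\t")
    report$motifs <- list(two_part_fraction =
                            stats::setNames(as.list(mf$fraction), mf$class))
  }

  if (isTRUE(cfg$stages$profile) && !is.null(d$tracks)) {
    log("stage: profile")
    sec <- list()
    for (tn in names(d$tracks)) {
      for (cl in c("IM", "IO", "MO")) {
        p <- .class_peaks(cls, cl)
        if (!length(p)) next
        pr <- aggregate_profile(p, d$tracks[[tn]],
                                flank = prm$profile_flank,
                                bin = prm$profile_bin)
        write_profile(pr, file.path(outdir,
                                    paste0("profile_", tn, "_", cl, ".tsv")))
        sec[[paste0(tn, "_", cl)]] <-
          list(center_mean = pr$mean[which.min(abs(pr$offset))],
               edge_mean = mean(pr$mean[c(1L, nrow(pr))]))
      }
    }
    report$signal <- sec
  }

  if (isTRUE(cfg$stages$spatial) && !is.null(d$tads)) {
    log("stage: spatial")
    sec <- list(nearest_neighbor = list(), boundary_spacing = list())
    for (cl in c("IM", "IO", "MO")) {
      p <- .class_peaks(cls, cl)
      if (length(p) < 2L) next
      tst <- nearest_neighbor_permutation_test(
        p, p, n_perm = prm$n_perm, seed = cfg$seed + match(cl, c("IM", "IO", "MO")))
      sec$nearest_neighbor[[cl]] <- list(
        observed_median = tst$observed_median,
        null_median = tst$null_median,
        n_perm = tst$n_perm, seed = tst$seed, p_value = tst$p_value)
    }
    doms <- list(TAD = d$tads)
    if (!is.null(d$synteny)) doms$synteny12D <- d$synteny
    for (dn in names(doms)) {
      lb <- label_boundaries(doms[[dn]], cls,
                             containment = prm$boundary_containment)
      write_labeled_boundaries(lb, file.path(outdir,
                                             paste0("boundaries_", dn, ".bed")))
      for (cl in c("IM", "IO", "MO")) {
        pr <- boundary_enrichment_profile(.class_peaks(cls, cl), doms[[dn]],
                                          flank = prm$boundary_flank,
                                          bin = prm$boundary_bin)
        write_profile(pr, file.path(outdir,
                                    paste0("boundary_profile_", dn, "_",
                                           cl, ".tsv")))
        res <- tryCatch(
          boundary_spacing_permutation_test(
            lb, doms[[dn]], cl, n_perm = prm$n_perm,
            seed = cfg$seed + 10L + match(cl, c("IM", "IO", "MO"))),
          error = function(e) NULL)
        if (!is.null(res))
          sec$boundary_spacing[[paste0(dn, "_", cl)]] <- list(
            observed_median = res$observed_median,
            null_median = res$null_median,
            n_perm = res$n_perm, seed = res$seed, p_value = res$p_value)
      }
    }
    report$spatial <- sec
  }

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       na = "null")
  writeLines(.report_text(report), file.path(outdir, "report.txt"))
  invisible(report)
}

# Human-readable rendering of the report list.
.report_text <- function(report) {
  out <- c("ctcfCycle pipeline report", "=========================", "")
  fmt <- function(x) if (is.numeric(x)) signif(x, 6) else x
  walk <- function(x, indent = "") {
    res <- character(0)
    for (nm in names(x)) {
      v <- x[[nm]]
      if (is.list(v)) {
        res <- c(res, paste0(indent, nm, ":"),
                 walk(v, paste0(indent, "  ")))
      } else {
        res <- c(res, paste0(indent, nm, ": ",
                             paste(fmt(v), collapse = ", ")))
      }
    }
    res
  }
  c(out, walk(report))
}
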