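# End-to-end orchestration: simulate (or read inputs), scan tandem repeats,
# call telomeres and centromeres, detect gene clusters, scan heterozygosity,
# and write a combined report with truth-recovery metrics when truth is
# available. All stages are deterministic given the config seed.

#' Build or load a run configuration
#'
#' Every parameter carries the pipeline default: 150-kb terminal windows and
#' 5-12 bp units for telomeres, 30-500 bp periods with copies >= 2 for the
#' tandem scan, e-value < 1e-5 / identity > 30% for similarity filtering,
#' 3-gene seeds extended 30 genes for clusters, GQ >= 30 / MAF >= 0.01 for
#' SNP filtering, 100-kb windows and top 5% for hotspots.
#'
#' @param path optional YAML file; fields override the defaults.
#' @param ... named overrides applied after the file.
#' @return list of class `run_config`.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- list(
    seed = 1L,
    out_dir = NULL,
    # inputs: either simulate = TRUE or explicit paths
    simulate = TRUE,
    fasta = NULL, gff3 = NULL, domains = NULL, hits = NULL, vcf = NULL,
    sim = list(),                  # overrides for simulation_spec()
    telomere = list(terminal_window = 150000L, min_unit = 5L,
                    max_unit = 12L, min_copies = 50),
    tandem = list(min_period = 30L, max_period = 500L, min_copies = 2,
                  min_identity = 0.80),
    centromere = list(window = 100000L, min_array_bp = 50000L,
                      max_gap = 500000L, factor = 2),
    clusters = list(seed_run = 3L, extend = 30L, max_evalue = 1e-5,
                    min_identity = 30),
    hetscan = list(window = 100000L, top_fraction = 0.05,
                   max_bridge_windows = 1L, min_windows = 2L,
                   min_gq = 30, min_maf = 0.01)
  )
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path)
    cfg <- utils::modifyList(cfg, yaml::read_yaml(path))
  }
  cfg <- utils::modifyList(cfg, list(...))
  structure(cfg, class = "run_config")
}

#' Run the full annotation pipeline
#'
#' Runs simulate (or load) -> tandem scan -> telomere and centromere calls ->
#' gene clusters -> heterozygosity scan, writes per-stage TSV/BED outputs and
#' a JSON + text report to `config$out_dir` (when set), and computes
#' truth-recovery metrics when simulated truth is available.
#'
#' @param config a [run_config()].
#' @return list of class `pipeline_report` with per-stage results and
#'   `recovery` metrics (NULL without truth).
#' @export
run_all <- function(config = run_config()) {
  cfg <- config
  truth <- NULL
  snps <- NULL
  if (isTRUE(cfg$simulate)) {
    spec <- do.call(simulation_spec,
                    utils::modifyList(list(seed = cfg$seed), cfg$sim))
    sim <- simulate_genome(spec)
    genome <- sim$genome
    features <- sim$features
    domains <- sim$domains
    truth <- sim$truth
    hs <- scale_hotspots(truth$chrom_lengths)
    snps <- simulate_snp_samples(truth$chrom_lengths, spec = spec,
                                 hotspots = hs)
    variants <- snps$variants
    hits <- NULL
  } else {
    if (is.null(cfg$fasta) || !file.exists(cfg$fasta))
      stop("config error: fasta input missing")
    genome <- read_fasta(cfg$fasta)
    features <- if (!is.null(cfg$gff3)) read_gff3(cfg$gff3) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 kind = character(), subtype = character(), id = character(),
                 strand = character())
    domains <- if (!is.null(cfg$domains))
      utils::read.table(cfg$domains, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE) else NULL
    hits <- if (!is.null(cfg$hits))
      utils::read.table(cfg$hits, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE) else NULL
    variants <- if (!is.null(cfg$vcf)) read_vcf(cfg$vcf) else NULL
  }
  chrom_lengths <- vapply(genome, nchar, 0L)

  # telomeres
  tl <- cfg$telomere
  unit_res <- find_telomere_unit(genome, tl$terminal_window, tl$min_unit,
                                 tl$max_unit)
  telomeres <- if (!is.na(unit_res$unit))
    call_telomeres(genome, unit_res$unit, tl$terminal_window,
                   tl$min_copies) else NULL

  # tandem arrays, families, centromeres
  td <- cfg$tandem
  arrays <- scan_tandem_arrays(genome, td$min_period, td$max_period,
                               td$min_copies, td$min_identity)
  grouped <- group_harmonics(arrays, genome_length = sum(chrom_lengths))
  units <- summarize_repeat_units(arrays, sum(chrom_lengths))
  cn <- cfg$centromere
  cens <- call_centromeres(grouped, features, chrom_lengths,
                           window = cn$window,
                           min_array_bp = cn$min_array_bp,
                           max_gap = cn$max_gap, factor = cn$factor)
  genes <- features[features$kind == "gene", , drop = FALSE]
  captured <- captured_genes(cens$calls, genes)

  # gene clusters
  cl <- cfg$clusters
  recs <- gene_records(genes, domains)
  kept_hits <- if (!is.null(hits))
    filter_similarity_hits(hits, recs, cl$max_evalue, cl$min_identity)
    else NULL
  clusters <- find_domain_clusters(recs, cl$seed_run, cl$extend,
                                   hits = kept_hits)
  rg <- classify_r_genes(recs)

  # heterozygosity
  het <- NULL
  if (!is.null(variants)) {
    hc <- cfg$hetscan
    filt <- filter_variants(variants,
                            filter_config(min_gq = hc$min_gq,
                                          min_maf = hc$min_maf))
    sharing <- partition_sharing(filt$variants)
    profile <- window_heterozygosity(filt$variants, chrom_lengths,
                                     hc$window)
    hotspots <- call_hotspots(profile, hc$top_fraction,
                              hc$max_bridge_windows, hc$min_windows)
    het <- list(filter_tally = filt$tally, sharing = sharing,
                profile = profile, hotspots = hotspots)
  }

  recovery <- if (!is.null(truth))
    recovery_metrics(telomeres, cens$calls, grouped, het, truth,
                     if (!is.null(snps)) snps$truth else NULL) else NULL

  report <- structure(list(
    config = unclass(cfg),
    chrom_lengths = chrom_lengths,
    telomere_unit = unit_res$unit,
    telomeres = telomeres,
    arrays = arrays,
    families = grouped$families,
    units = units,
    centromeres = cens$calls,
    centromere_diagnostics = cens$diagnostics,
    captured = captured,
    clusters = clusters,
    r_genes = rg$count,
    het = het,
    recovery = recovery
  ), class = "pipeline_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir,
                                          grouped = grouped)
  report
}

# Hotspot intervals used by the simulated end-to-end run: one elevated
# interval on each of a few chromosomes, together ~4% of the genome so the
# top-5% window quantile can cover them.
scale_hotspots <- function(chrom_lengths, n = 3L) {
  n <- min(n, length(chrom_lengths))
  ch <- names(chrom_lengths)[seq_len(n)]
  frac <- 0.04 * sum(chrom_lengths) / n
  do.call(rbind, lapply(ch, function(c1) {
    L <- chrom_lengths[[c1]]
    len <- min(round(frac), round(0.25 * L))
    data.frame(chrom = c1, start = round(L * 0.3),
               end = round(L * 0.3) + len,
               stringsAsFactors = FALSE)
  }))
}

# Compare pipeline calls with simulated truth.
recovery_metrics <- function(telomeres, cen_calls, grouped, het, truth,
                             snp_truth = NULL) {
  out <- list()
  if (!is.null(telomeres) && !is.null(truth$telomeres)) {
    called <- telomeres[telomeres$present, , drop = FALSE]
    key_called <- paste(called$chrom, called$arm)
    key_truth <- paste(truth$telomeres$chrom, truth$telomeres$arm)
    out$telomere <- list(
      n_truth = length(key_truth), n_called = length(key_called),
      recall = mean(key_truth %in% key_called),
      precision = if (length(key_called))
        mean(key_called %in% key_truth) else NA_real_)
  }
  if (!is.null(cen_calls) && !is.null(truth$centromeres)) {
    jac <- vapply(seq_len(nrow(truth$centromeres)), function(i) {
      tr <- truth$centromeres[i, ]
      c1 <- cen_calls[cen_calls$chrom == tr$chrom, , drop = FALSE]
      if (nrow(c1) == 0L) return(0)
      interval_jaccard(c1$start[1L], c1$end[1L], tr$start, tr$end)
    }, 0)
    out$centromere <- list(n_truth = nrow(truth$centromeres),
                           n_called = nrow(cen_calls),
                           mean_jaccard = mean(jac),
                           frac_jaccard_08 = mean(jac >= 0.8))
  }
  if (!is.null(het) && !is.null(snp_truth) &&
      !is.null(snp_truth$hotspots) && nrow(het$hotspots)) {
    hs <- snp_truth$hotspots
    jac <- vapply(seq_len(nrow(hs)), function(i) {
      f <- het$hotspots[het$hotspots$chrom == hs$chrom[i], , drop = FALSE]
      if (nrow(f) == 0L) return(0)
      max(vapply(seq_len(nrow(f)), function(j)
        interval_jaccard(f$start[j], f$end[j], hs$start[i], hs$end[i]), 0))
    }, 0)
    out$hotspots <- list(n_truth = nrow(hs),
                         n_called = nrow(het$hotspots),
                         mean_jaccard = mean(jac))
  }
  out
}

# Write per-stage files plus report.json / report.txt.
write_report <- function(report, dir, grouped = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$telomeres))
    write_tsv(report$telomeres, file.path(dir, "telomeres.tsv"))
  if (nrow(report$arrays))
    write_tsv(report$arrays, file.path(dir, "arrays.tsv"))
  write_tsv(report$units, file.path(dir, "repeat_units.tsv"))
  if (!is.null(report$centromeres)) {
    write_bed(report$centromeres[, c("chrom", "start", "end")],
              file.path(dir, "centromeres.bed"))
    write_tsv(report$centromeres, file.path(dir, "centromeres.tsv"))
  }
  if (!is.null(report$centromere_diagnostics))
    write_tsv(report$centromere_diagnostics,
              file.path(dir, "centromere_candidates.tsv"))
  write_tsv(report$captured, file.path(dir, "captured_genes.tsv"))
  write_tsv(report$clusters, file.path(dir, "clusters.tsv"))
  if (!is.null(report$het)) {
    write_tsv(report$het$profile, file.path(dir, "het_windows.tsv"))
    if (nrow(report$het$hotspots))
      write_bed(report$het$hotspots[, c("chrom", "start", "end")],
                file.path(dir, "hotspots.bed"))
  }
  summary_json <- list(
    provenance = list(package = "t2tscan",
                      version = as.character(utils::packageVersion("t2tscan")),
                      seed = report$config$seed,
                      parameters = report$config[c("telomere", "tandem",
                                                   "centromere", "clusters",
                                                   "hetscan")]),
    n_chromosomes = length(report$chrom_lengths),
    genome_bp = sum(report$chrom_lengths),
    telomere_unit = report$telomere_unit,
    telomeres_present = if (!is.null(report$telomeres))
      sum(report$telomeres$present) else 0L,
    telomere_arms = if (!is.null(report$telomeres))
      nrow(report$telomeres) else 0L,
    n_centromeres = if (!is.null(report$centromeres))
      nrow(report$centromeres) else 0L,
    n_clusters = nrow(report$clusters),
    n_r_genes = report$r_genes,
    n_captured_genes = nrow(report$captured),
    sharing = if (!is.null(report$het))
      report$het$sharing[c("shared_all", "partial", "total",
                           "percentage_shared")] else NULL,
    n_hotspots = if (!is.null(report$het)) nrow(report$het$hotspots)
      else NULL,
    recovery = report$recovery)
  jsonlite::write_json(summary_json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("t2tscan pipeline report\n")
  cat("  genome: ", length(x$chrom_lengths), " chromosomes, ",
      sum(x$chrom_lengths), " bp\n", sep = "")
  if (!is.null(x$telomeres)) {
    cat("  telomeres: unit ", x$telomere_unit, "; ",
        sum(x$telomeres$present), " of ", nrow(x$telomeres),
        " arms present\n", sep = "")
  }
  cat("  tandem arrays: ", nrow(x$arrays), " (",
      nrow(x$families), " families)\n", sep = "")
  if (nrow(x$units)) {
    top <- utils::head(x$units, 3L)
    cat("  top repeat units (period: % genome): ",
        paste(sprintf("%d: %.2f%%", top$period,
                      100 * top$genome_fraction), collapse = ", "),
        "\n", sep = "")
  }
  cat("  centromeres called: ",
      if (!is.null(x$centromeres)) nrow(x$centromeres) else 0L,
      "; captured genes: ", nrow(x$captured), "\n", sep = "")
  cat("  gene clusters: ", nrow(x$clusters), "; R genes: ", x$r_genes,
      "\n", sep = "")
  if (!is.null(x$het)) {
    s <- x$het$sharing
    cat("  heterozygosity: ", s$total, " sites, ", s$percentage_shared,
        "% shared in all samples; ", nrow(x$het$hotspots),
        " hotspot fragments\n", sep = "")
  }
  if (!is.null(x$recovery) && length(x$recovery)) {
    cat("  truth recovery:\n")
    if (!is.null(x$recovery$telomere))
      cat(sprintf("    telomeres: recall %.2f precision %.2f\n",
                  x$recovery$telomere$recall,
                  x$recovery$telomere$precision))
    if (!is.null(x$recovery$centromere))
      cat(sprintf("    centromeres: %d/%d called, mean Jaccard %.2f\n",
                  x$recovery$centromere$n_called,
                  x$recovery$centromere$n_truth,
                  x$recovery$centromere$mean_jaccard))
    if (!is.null(x$recovery$hotspots))
      cat(sprintf("    hotspots: %d called / %d truth, mean Jaccard %.2f\n",
                  x$recovery$hotspots$n_called,
                  x$recovery$hotspots$n_truth,
                  x$recovery$hotspots$mean_jaccard))
  }
  invisible(x)
}
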