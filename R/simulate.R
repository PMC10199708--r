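# Seeded synthetic-genome simulator with machine-readable truth.
#
# Emulates the statistical structure the annotation stages assume:
#   (i)  7-bp telomeric tandem arrays (TTTAGGG/CCCTAAA) at chromosome ends,
#   (ii) centromeric satellite arrays built from a monomer (default 107 bp)
#        with a fraction emitted as dimer/trimer (2x/3x) concatemer blocks,
#   (iii) TE-like annotation features with density depletion at centromeres,
#   (iv) ordered gene models carrying domain accessions with planted
#        tandem-like clusters, and
#   (v)  multi-sample heterozygous SNP sets with localized hotspots and a
#        controlled all-sample sharing fraction.
# Background sequence is i.i.d. uniform ACGT; gene and TE tracks are emitted
# as annotation features (the sequence substrate under them stays background).
# All outputs are deterministic given the spec seed.

#' Build a simulation specification
#'
#' Defaults describe a 19-chromosome genome with 1-2 Mb chromosomes,
#' telomeres on every arm (200-2000 copies of TTTAGGG), one centromeric
#' array of a 107-bp monomer family per chromosome (100-500 kb, 2% per-copy
#' substitution, part of it emitted as literal dimer/trimer concatemer
#' blocks), TE features 5-fold depleted inside centromeres, and gene models
#' with planted domain clusters.
#'
#' @param seed integer seed (mandatory).
#' @param n_chroms number of chromosomes.
#' @param chrom_lengths optional vector of lengths (bp); sampled from
#'   `chrom_length_range` when NULL.
#' @param chrom_length_range sampling range for chromosome lengths.
#' @param telomere_plan list: unit, copies_range, mutation_rate, and
#'   `absent` — character vector of "chrN:left"/"chrN:right" arms to skip.
#' @param centromere_plan list: period, monomer (random per seed when NULL),
#'   array_length_range, dimer_fraction, trimer_fraction, mutation_rate,
#'   concatemer_divergence, present flag.
#' @param te_plan list: density_per_mb, families (named weights),
#'   length_range, centromere_depletion.
#' @param gene_plan list: count_per_mb, length_range, domain_vocab,
#'   max_domains_per_gene, clusters — list of planted cluster specs
#'   (accession, chrom index, n_seed, n_extra).
#' @param snp_plan list: n_samples, background_rate (het sites per bp),
#'   hotspot_multiplier, hotspots (data.frame chrom/start/end or NULL),
#'   shared_fraction, gq_fail_fraction.
#' @return list of class `simulation_spec`.
#' @export
simulation_spec <- function(seed,
                            n_chroms = 19L,
                            chrom_lengths = NULL,
                            chrom_length_range = c(1e6, 2e6),
                            telomere_plan = list(),
                            centromere_plan = list(),
                            te_plan = list(),
                            gene_plan = list(),
                            snp_plan = list()) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  tp <- utils::modifyList(list(unit = "TTTAGGG",
                               copies_range = c(200L, 2000L),
                               mutation_rate = 0,
                               absent = character()), telomere_plan)
  cp <- utils::modifyList(list(period = 107L, monomer = NULL,
                               array_length_range = c(1e5, 5e5),
                               dimer_fraction = 0.2, trimer_fraction = 0.1,
                               mutation_rate = 0.02,
                               concatemer_divergence = 0,
                               present = TRUE,
                               overrides = list()), centromere_plan)
  te <- utils::modifyList(list(density_per_mb = 80,
                               families = c(Gypsy = 0.35, Copia = 0.35,
                                            `MULE-MuDR` = 0.15,
                                            Helitron = 0.15),
                               length_range = c(500, 5000),
                               centromere_depletion = 5), te_plan)
  gp <- utils::modifyList(list(count_per_mb = 25,
                               length_range = c(1000, 4000),
                               domain_vocab = c("PPR", "WAK", "ABC_tran",
                                                "Peptidase", "RVT",
                                                "Integrase", "Multicopper",
                                                "TPS"),
                               max_domains_per_gene = 3L,
                               clusters = list(
                                 list(accession = "NB-ARC", chrom = 1L,
                                      n_seed = 4L, n_extra = 3L),
                                 list(accession = "LRR", chrom = 2L,
                                      n_seed = 3L, n_extra = 2L))),
                          gene_plan)
  sp <- utils::modifyList(list(n_samples = 4L,
                               background_rate = 2e-4,
                               hotspot_multiplier = 10,
                               hotspots = NULL,
                               shared_fraction = 0.853,
                               gq_fail_fraction = 0.05), snp_plan)
  stopifnot(sp$shared_fraction >= 0, sp$shared_fraction <= 1,
            cp$mutation_rate >= 0, cp$mutation_rate <= 1,
            tp$mutation_rate >= 0, tp$mutation_rate <= 1)
  structure(list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
                 chrom_lengths = chrom_lengths,
                 chrom_length_range = chrom_length_range,
                 telomere_plan = tp, centromere_plan = cp, te_plan = te,
                 gene_plan = gp, snp_plan = sp),
            class = "simulation_spec")
}

# Tandem-array string from a monomer: `copies` may be fractional; length is
# round(copies * |monomer|); per-copy substitutions at `rate`.
tandem_string <- function(monomer, copies, rate = 0) {
  p <- nchar(monomer)
  total <- round(copies * p)
  ncop <- ceiling(total / p)
  mutate_dna(substr(strrep(monomer, ncop), 1L, total), rate)
}

#' Plant a tandem array into a background sequence
#'
#' Inserts `round(copies * |monomer|)` bp of tandem repeat at `position`
#' (0-based), replacing the background. Substitutions are drawn per position
#' per copy at `per_copy_mutation_rate` from the current RNG stream.
#'
#' @param background_seq background chromosome string.
#' @param monomer repeat unit.
#' @param copies fractional copy number (>= 1).
#' @param per_copy_mutation_rate substitution probability per position.
#' @param position 0-based insertion offset.
#' @return list with `seq` (modified string) and `truth`
#'   (start, end, period, copies, monomer).
#' @export
plant_tandem_array <- function(background_seq, monomer, copies,
                               per_copy_mutation_rate = 0, position) {
  stopifnot(copies >= 1)
  arr <- tandem_string(monomer, copies, per_copy_mutation_rate)
  n <- nchar(background_seq)
  if (position < 0L || position + nchar(arr) > n)
    stop("array exceeds chromosome bounds: [", position, ", ",
         position + nchar(arr), ") on length ", n)
  substr(background_seq, position + 1L, position + nchar(arr)) <- arr
  list(seq = background_seq,
       truth = data.frame(start = position, end = position + nchar(arr),
                          period = nchar(monomer), copies = copies,
                          monomer = monomer, stringsAsFactors = FALSE))
}

# Centromeric satellite block: monomer / dimer / trimer sections whose bp
# budget follows the spec fractions. Dimer/trimer units are concatenations of
# the monomer; `divergence` optionally substitutes that fraction of positions
# in the 2nd (and 3rd) copy of the concatemer unit so the higher-order period
# becomes the scanner-level period.
satellite_array <- function(monomer, total_len, dimer_fraction,
                            trimer_fraction, rate, divergence = 0) {
  p <- nchar(monomer)
  make_unit <- function(k) {
    pieces <- c(monomer,
                replicate(k - 1L, mutate_dna(monomer, divergence)))
    paste(pieces, collapse = "")
  }
  budgets <- c(mono = 1 - dimer_fraction - trimer_fraction,
               di = dimer_fraction, tri = trimer_fraction) * total_len
  parts <- list(); truths <- list()
  offset <- 0
  ks <- c(mono = 1L, di = 2L, tri = 3L)
  for (b in names(budgets)) {
    if (budgets[[b]] < p * ks[[b]] * 2) next
    unit <- make_unit(ks[[b]])
    # whole copies per block keep the monomer phase continuous across blocks
    copies <- floor(budgets[[b]] / nchar(unit))
    s <- tandem_string(unit, copies, rate)
    parts[[b]] <- s
    truths[[b]] <- data.frame(start = offset, end = offset + nchar(s),
                              period = nchar(unit),
                              copies = round(copies, 1L),
                              stringsAsFactors = FALSE)
    offset <- offset + nchar(s)
  }
  list(seq = paste(unlist(parts), collapse = ""),
       blocks = do.call(rbind, truths))
}

#' Simulate a genome with planted truth
#'
#' Generates chromosome sequences with planted telomeres and centromeric
#' satellite arrays, gene and TE annotation features (TEs depleted inside
#' centromeres, genes never overlapping satellite arrays), per-gene domain
#' tables with planted clusters, and a machine-readable truth set.
#'
#' @param spec a [simulation_spec()].
#' @return list of class `genome_sim`: `genome` (named character vector),
#'   `features` (data.frame), `domains` (data.frame gene_id, ordinal,
#'   domains), `truth` (list of telomeres, centromeres, arrays, clusters),
#'   `spec`.
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$seed, {
    n <- spec$n_chroms
    lens <- spec$chrom_lengths
    if (is.null(lens)) {
      lens <- round(stats::runif(n, spec$chrom_length_range[1L],
                                 spec$chrom_length_range[2L]))
    }
    lens <- as.integer(lens)
    chroms <- paste0("chr", seq_len(n))
    names(lens) <- chroms
    cp <- spec$centromere_plan
    tp <- spec$telomere_plan
    monomer <- cp$monomer
    if (is.null(monomer)) monomer <- random_dna(cp$period)
    genome <- character(n)
    names(genome) <- chroms
    tel_truth <- list(); cen_truth <- list(); arr_truth <- list()
    u <- nchar(tp$unit)
    for (i in seq_len(n)) {
      ch <- chroms[i]
      L <- lens[i]
      s <- random_dna(L)
      # centromere
      if (isTRUE(cp$present)) {
        ov <- cp$overrides[[ch]]
        mono_i <- if (!is.null(ov$monomer)) ov$monomer
                  else if (!is.null(ov$period)) random_dna(ov$period)
                  else monomer
        alen <- round(stats::runif(1L, cp$array_length_range[1L],
                                   cp$array_length_range[2L]))
        margin <- 160000L
        avail <- L - 2L * margin
        if (avail < alen) alen <- max(avail, 0L)
        if (alen < 4L * nchar(mono_i))
          stop("infeasible packing: centromere array does not fit on ", ch)
        sat <- satellite_array(mono_i, alen, cp$dimer_fraction,
                               cp$trimer_fraction, cp$mutation_rate,
                               cp$concatemer_divergence)
        alen <- nchar(sat$seq)
        cstart <- margin + (avail - alen) %/% 2L
        substr(s, cstart + 1L, cstart + alen) <- sat$seq
        cen_truth[[ch]] <- data.frame(chrom = ch, start = cstart,
                                      end = cstart + alen,
                                      period = nchar(mono_i),
                                      monomer = mono_i,
                                      stringsAsFactors = FALSE)
        blk <- sat$blocks
        blk$start <- blk$start + cstart
        blk$end <- blk$end + cstart
        blk$chrom <- ch
        arr_truth[[ch]] <- blk
      }
      # telomeres: CCCTAAA-strand at the left end, TTTAGGG at the right end
      for (arm in c("left", "right")) {
        if (paste0(ch, ":", arm) %in% tp$absent) next
        copies <- sample(tp$copies_range[1L]:tp$copies_range[2L], 1L)
        unit <- if (arm == "left") revcomp(tp$unit) else tp$unit
        tlen <- copies * u
        pos <- if (arm == "left") 0L else L - tlen
        res <- plant_tandem_array(s, unit, copies, tp$mutation_rate, pos)
        s <- res$seq
        tel_truth[[paste0(ch, ":", arm)]] <- data.frame(
          chrom = ch, arm = arm, start = pos, end = pos + tlen,
          copies = copies, stringsAsFactors = FALSE)
      }
      genome[ch] <- s
    }
    cen_df <- if (length(cen_truth)) do.call(rbind, c(cen_truth, make.row.names = FALSE)) else NULL
    tel_df <- if (length(tel_truth)) do.call(rbind, c(tel_truth, make.row.names = FALSE)) else NULL
    arr_df <- if (length(arr_truth)) do.call(rbind, c(arr_truth, make.row.names = FALSE)) else NULL
    feat <- simulate_features(lens, cen_df, spec)
    gd <- simulate_gene_domains(feat$genes, spec)
    features <- rbind(feat$genes, feat$tes)
    features <- features[order(features$chrom, features$start), , drop = FALSE]
    rownames(features) <- NULL
    structure(list(genome = genome,
                   features = features,
                   domains = gd$domains,
                   truth = list(telomeres = tel_df, centromeres = cen_df,
                                arrays = arr_df, clusters = gd$clusters,
                                chrom_lengths = lens),
                   spec = spec),
              class = "genome_sim")
  })
}

# Gene and TE annotation features. Genes avoid satellite/telomere intervals;
# TE density is divided by the depletion factor inside centromeres.
simulate_features <- function(lens, cen_df, spec) {
  gp <- spec$gene_plan
  te <- spec$te_plan
  tp <- spec$telomere_plan
  genes <- list(); tes <- list()
  gene_n0 <- 0L
  for (ch in names(lens)) {
    L <- lens[[ch]]
    cen <- if (!is.null(cen_df)) cen_df[cen_df$chrom == ch, , drop = FALSE]
           else cen_df
    forbid <- data.frame(start = c(0L, L - 20000L),
                         end = c(20000L, L))  # telomeric margins
    if (!is.null(cen) && nrow(cen))
      forbid <- rbind(forbid, cen[, c("start", "end")])
    # genes
    ng <- max(0L, round(L / 1e6 * gp$count_per_mb))
    glen <- round(stats::runif(ng, gp$length_range[1L], gp$length_range[2L]))
    gstart <- if (ng) sort(sample.int(L - max(glen), ng)) else integer()
    keep <- rep(TRUE, ng)
    last_end <- -1
    for (i in seq_len(ng)) {
      e <- gstart[i] + glen[i]
      if (gstart[i] <= last_end ||
          any(e > forbid$start & gstart[i] < forbid$end)) {
        keep[i] <- FALSE
      } else last_end <- e
    }
    gstart <- gstart[keep]; glen <- glen[keep]
    ng <- length(gstart)
    if (ng) {
      ids <- sprintf("%s_g%04d", ch, seq_len(ng))
      genes[[ch]] <- data.frame(chrom = ch, start = gstart,
                                end = gstart + glen, kind = "gene",
                                subtype = NA_character_, id = ids,
                                strand = sample(c("+", "-"), ng, TRUE),
                                stringsAsFactors = FALSE)
      gene_n0 <- gene_n0 + ng
    }
    # TEs
    nt <- max(0L, round(L / 1e6 * te$density_per_mb))
    tlen <- round(stats::runif(nt, te$length_range[1L], te$length_range[2L]))
    tstart <- if (nt) sample.int(L - max(tlen), nt) else integer()
    if (!is.null(cen) && nrow(cen)) {
      inside <- tstart >= cen$start[1L] & tstart < cen$end[1L]
      drop <- inside & stats::runif(nt) > 1 / te$centromere_depletion
      tstart <- tstart[!drop]; tlen <- tlen[!drop]
    }
    nt <- length(tstart)
    if (nt) {
      fam <- sample(names(te$families), nt, replace = TRUE,
                    prob = te$families)
      tes[[ch]] <- data.frame(chrom = ch, start = tstart,
                              end = tstart + tlen, kind = "TE",
                              subtype = fam,
                              id = sprintf("%s_te%05d", ch, seq_len(nt)),
                              strand = sample(c("+", "-"), nt, TRUE),
                              stringsAsFactors = FALSE)
    }
  }
  list(genes = do.call(rbind, c(genes, make.row.names = FALSE)),
       tes = do.call(rbind, c(tes, make.row.names = FALSE)))
}

# Assign domain accessions; plant clusters (accessions reserved for planting
# never occur at random, so planted clusters are exactly recoverable).
simulate_gene_domains <- function(genes, spec) {
  gp <- spec$gene_plan
  recs <- gene_records(genes)
  ndom <- sample.int(gp$max_domains_per_gene, nrow(recs), replace = TRUE)
  doms <- lapply(ndom, function(k)
    sample(gp$domain_vocab, min(k, length(gp$domain_vocab))))
  chroms <- unique(recs$chrom)
  cl_truth <- list()
  for (cl in gp$clusters) {
    ch <- if (is.numeric(cl$chrom)) chroms[cl$chrom] else cl$chrom
    if (is.na(ch) || !(ch %in% recs$chrom)) next
    idx <- which(recs$chrom == ch)
    need <- cl$n_seed + cl$n_extra
    if (length(idx) < need + 10L) next
    anchor <- sample(seq_len(length(idx) - need - 6L), 1L) + 3L
    seed_idx <- idx[anchor:(anchor + cl$n_seed - 1L)]
    extra_pool <- setdiff(idx[max(1L, anchor - 30L):
                                min(length(idx), anchor + cl$n_seed - 1L + 30L)],
                          seed_idx)
    extra_idx <- sort(sample(extra_pool, min(cl$n_extra, length(extra_pool))))
    for (i in c(seed_idx, extra_idx))
      doms[[i]] <- unique(c(doms[[i]], cl$accession))
    cl_truth[[length(cl_truth) + 1L]] <- data.frame(
      accession = cl$accession, chrom = ch,
      members = paste(recs$gene_id[sort(c(seed_idx, extra_idx))],
                      collapse = ","),
      stringsAsFactors = FALSE)
  }
  domstr <- vapply(doms, paste, "", collapse = ",")
  list(domains = data.frame(gene_id = recs$gene_id, ordinal = recs$ordinal,
                            domains = domstr, stringsAsFactors = FALSE),
       clusters = if (length(cl_truth)) do.call(rbind, cl_truth) else NULL)
}

#' Simulate multi-sample heterozygous SNPs with hotspots
#'
#' Places heterozygous sites at a background density with elevated density
#' inside hotspot intervals, assigns each site a sharing class (heterozygous
#' in all samples with probability `shared_fraction`, otherwise in 1..n-1
#' samples), and draws genotype qualities so a configurable fraction fails
#' GQ < 30 for filter testing. Overlapping hotspot intervals on one
#' chromosome are merged with a warning.
#'
#' @param chrom_lengths named vector of chromosome lengths.
#' @param spec a [simulation_spec()] (its `snp_plan` and seed are used), or
#'   NULL to pass the plan fields directly.
#' @param seed overrides the spec seed when given.
#' @param ... plan fields overriding the spec's snp_plan (background_rate,
#'   hotspots, hotspot_multiplier, shared_fraction, gq_fail_fraction,
#'   n_samples).
#' @return list with `variants` (a `variant_set`) and `truth` (list:
#'   `sharing` per-site class, `hotspots` merged intervals).
#' @export
simulate_snp_samples <- function(chrom_lengths, spec = NULL, seed = NULL,
                                 ...) {
  plan <- if (!is.null(spec)) spec$snp_plan
          else simulation_spec(seed = 1L)$snp_plan
  plan <- utils::modifyList(plan, list(...))
  if (is.null(seed)) {
    if (is.null(spec)) stop("either spec or seed must be given")
    seed <- derive_seed(spec$seed, "snp")
  }
  hs <- plan$hotspots
  if (!is.null(hs) && nrow(hs)) {
    merged <- list()
    for (ch in unique(hs$chrom)) {
      sub <- hs[hs$chrom == ch, , drop = FALSE]
      m <- merge_intervals(sub[, c("start", "end")])
      if (nrow(m) < nrow(sub)) warning("overlapping hotspots merged on ", ch)
      if ("rate" %in% names(sub)) {
        m$rate <- vapply(seq_len(nrow(m)), function(i)
          max(sub$rate[sub$end > m$start[i] & sub$start < m$end[i]]), 0)
      }
      m$chrom <- ch
      merged[[ch]] <- m
    }
    hs <- do.call(rbind, c(merged, make.row.names = FALSE))
    bad <- hs$end > chrom_lengths[hs$chrom] | hs$start < 0
    if (any(bad)) stop("hotspot interval outside chromosome")
  }
  with_seed(seed, {
    ns <- plan$n_samples
    sites <- list(); classes <- list()
    for (ch in names(chrom_lengths)) {
      L <- chrom_lengths[[ch]]
      pos <- sample.int(L, min(stats::rpois(1L, L * plan$background_rate), L))
      if (!is.null(hs)) {
        sub <- hs[hs$chrom == ch, , drop = FALSE]
        for (i in seq_len(nrow(sub))) {
          hlen <- sub$end[i] - sub$start[i]
          # hotspots carry either an absolute per-bp rate or the multiplier
          target <- if ("rate" %in% names(sub)) sub$rate[i]
                    else plan$background_rate * plan$hotspot_multiplier
          extra_rate <- max(target - plan$background_rate, 0)
          extra <- stats::rpois(1L, hlen * extra_rate)
          pos <- c(pos, sub$start[i] + sample.int(hlen, min(extra, hlen)))
        }
      }
      pos <- sort(unique(pos)) - 1L   # 0-based
      if (!length(pos)) next
      sites[[ch]] <- data.frame(chrom = ch, pos = pos,
                                stringsAsFactors = FALSE)
    }
    if (!length(sites)) {
      empty_m <- matrix(character(), 0L, ns,
                        dimnames = list(NULL, paste0("S", seq_len(ns))))
      vs <- structure(list(
        sites = data.frame(chrom = character(), pos = integer(),
                           ref = character(), alt = character(),
                           n_alleles = integer(), stringsAsFactors = FALSE),
        gt = empty_m,
        gq = matrix(numeric(), 0L, ns, dimnames = dimnames(empty_m)),
        samples = colnames(empty_m)), class = "variant_set")
      return(list(variants = vs,
                  truth = list(sharing = character(), hotspots = hs)))
    }
    sdf <- do.call(rbind, c(sites, make.row.names = FALSE))
    nsite <- nrow(sdf)
    ref <- DNA_BASES[sample.int(4L, nsite, TRUE)]
    alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1L), "",
                  USE.NAMES = FALSE)
    shared <- stats::runif(nsite) < plan$shared_fraction
    gt <- matrix("0/0", nrow = nsite, ncol = ns,
                 dimnames = list(NULL, paste0("S", seq_len(ns))))
    for (i in seq_len(nsite)) {
      who <- if (shared[i]) seq_len(ns)
             else sample(seq_len(ns), sample.int(ns - 1L, 1L))
      gt[i, who] <- "0/1"
    }
    gq <- matrix(as.numeric(
      ifelse(stats::runif(nsite * ns) < plan$gq_fail_fraction,
             sample(10:29, nsite * ns, TRUE),
             sample(30:99, nsite * ns, TRUE))),
      nrow = nsite, dimnames = dimnames(gt))
    vs <- structure(list(
      sites = data.frame(chrom = sdf$chrom, pos = sdf$pos, ref = ref,
                         alt = alt, n_alleles = 2L,
                         stringsAsFactors = FALSE),
      gt = gt, gq = gq, samples = colnames(gt)), class = "variant_set")
    list(variants = vs,
         truth = list(sharing = ifelse(shared, "all", "partial"),
                      hotspots = hs))
  })
}

#' Benchmark layout for heterozygosity hotspot recovery
#'
#' A 19-chromosome layout emulating the heterozygosity geography of a nearly
#' homozygous grapevine reference clone: nine multi-Mb hotspot fragments
#' (two of them on one chromosome) at the positions reported for that
#' genotype, on chromosomes scaled by `scale`. Used with
#' [simulate_snp_samples()] to benchmark the top-quantile hotspot caller.
#'
#' @param scale linear scale factor applied to chromosome lengths and
#'   interval coordinates (default 0.1; windows should be scaled alike).
#' @return list with `chrom_lengths` (named, bp) and `hotspots`
#'   (data.frame chrom, start, end).
#' @export
het_benchmark_layout <- function(scale = 0.1) {
  lens_mb <- c(chr1 = 26, chr2 = 20, chr3 = 22, chr4 = 26, chr5 = 26,
               chr6 = 24, chr7 = 30, chr8 = 23, chr9 = 25, chr10 = 26,
               chr11 = 21, chr12 = 25, chr13 = 27, chr14 = 31, chr15 = 22,
               chr16 = 24, chr17 = 19, chr18 = 36, chr19 = 26)
  hs <- data.frame(
    chrom = c("chr1", "chr2", "chr3", "chr4", "chr7", "chr10", "chr10",
              "chr11", "chr16"),
    start = c(1.1, 4.2, 9.4, 21.8, 15.3, 0.7, 17.6, 7.1, 13.0) * 1e6,
    end = c(1.3, 7.2, 9.9, 22.9, 26.2, 6.5, 18.3, 7.8, 13.5) * 1e6,
    stringsAsFactors = FALSE)
  list(chrom_lengths = round(lens_mb * 1e6 * scale),
       hotspots = data.frame(chrom = hs$chrom,
                             start = round(hs$start * scale),
                             end = round(hs$end * scale),
                             stringsAsFactors = FALSE))
}

#' Write simulator outputs to a directory
#'
#' Emits genome.fasta, features.gff3, domains.tsv, samples.vcf (when SNPs
#' were simulated), truth.json and truth BED files.
#'
#' @param sim a `genome_sim` from [simulate_genome()].
#' @param dir output directory (created if needed).
#' @param snps optional result of [simulate_snp_samples()].
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, snps = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$genome, file.path(dir, "genome.fasta"))
  write_gff3(sim$features, file.path(dir, "features.gff3"))
  write_tsv(sim$domains, file.path(dir, "domains.tsv"))
  tr <- sim$truth
  if (!is.null(tr$telomeres))
    write_bed(cbind(tr$telomeres[, c("chrom", "start", "end")],
                    name = paste0(tr$telomeres$chrom, ":",
                                  tr$telomeres$arm)),
              file.path(dir, "truth_telomeres.bed"))
  if (!is.null(tr$centromeres))
    write_bed(tr$centromeres[, c("chrom", "start", "end")],
              file.path(dir, "truth_centromeres.bed"))
  truth_json <- list(
    chrom_lengths = as.list(tr$chrom_lengths),
    telomeres = tr$telomeres, centromeres = tr$centromeres,
    arrays = tr$arrays, clusters = tr$clusters)
  if (!is.null(snps)) {
    write_vcf(snps$variants, file.path(dir, "samples.vcf"),
              chrom_lengths = tr$chrom_lengths)
    truth_json$snp_sharing <- snps$truth$sharing
    truth_json$snp_hotspots <- snps$truth$hotspots
  }
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @export
print.genome_sim <- function(x, ...) {
  cat("genome_sim:", length(x$genome), "chromosomes,",
      sum(nchar(x$genome)), "bp;",
      nrow(x$features), "features;",
      nrow(x$domains), "gene domain records\n")
  invisible(x)
}
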