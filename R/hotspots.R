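# Multi-sample heterozygosity: strict variant filtering, sharing partition
# across clones, non-overlapping windowed heterozygous-site counts, and
# top-quantile hotspot fragments.
#
# Filtering criteria (applied in order, first failing rule attributed):
# exactly two alleles; no missing genotypes; all genotype qualities >= min_gq;
# minor allele frequency >= min_maf over the samples' genotypes.

#' Filter configuration for multi-sample SNP sets
#'
#' @param biallelic_only drop sites with more than two alleles.
#' @param min_gq minimum per-sample genotype quality.
#' @param max_missing_fraction maximum fraction of missing genotypes
#'   (default 0: no missing allowed).
#' @param min_maf minimum minor allele frequency.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(biallelic_only = TRUE, min_gq = 30,
                          max_missing_fraction = 0, min_maf = 0.01) {
  stopifnot(min_gq >= 0, max_missing_fraction >= 0,
            max_missing_fraction <= 1, min_maf >= 0, min_maf <= 0.5)
  structure(list(biallelic_only = biallelic_only, min_gq = min_gq,
                 max_missing_fraction = max_missing_fraction,
                 min_maf = min_maf),
            class = "filter_config")
}

# Split "0/1"-style genotypes into an allele-code matrix (2 columns).
gt_alleles <- function(gt) {
  parts <- strsplit(gt, "[/|]")
  a1 <- suppressWarnings(as.integer(vapply(parts, function(p)
    if (length(p) >= 1L) p[1L] else NA_character_, "")))
  a2 <- suppressWarnings(as.integer(vapply(parts, function(p)
    if (length(p) >= 2L) p[2L] else NA_character_, "")))
  cbind(a1, a2)
}

# Heterozygosity matrix (site x sample): TRUE when the two alleles differ.
het_matrix <- function(vs) {
  al <- gt_alleles(as.vector(vs$gt))
  m <- matrix(al[, 1L] != al[, 2L], nrow = nrow(vs$sites),
              ncol = length(vs$samples))
  colnames(m) <- vs$samples
  m
}

#' Filter a multi-sample variant set
#'
#' Applies the strict SNP filters: biallelic sites only, no missing
#' genotypes (up to `max_missing_fraction`), all genotype qualities at least
#' `min_gq`, and minor allele frequency at least `min_maf` computed over the
#' samples' genotypes. Removal is attributed to the first failing rule.
#'
#' @param vs a `variant_set` from [read_vcf()] or the simulator.
#' @param config a [filter_config()].
#' @return list with `variants` (filtered `variant_set`), `kept` (logical
#'   index into the input sites) and `tally` (named removal counts per rule).
#' @export
filter_variants <- function(vs, config = filter_config()) {
  n <- nrow(vs$sites)
  ns <- length(vs$samples)
  stopifnot(ns >= 1L)
  if (n == 0L) {
    return(list(variants = vs, kept = logical(0),
                tally = c(alleles = 0L, missing = 0L, gq = 0L, maf = 0L)))
  }
  fail <- rep(NA_character_, n)
  if (config$biallelic_only) {
    bad <- vs$sites$n_alleles != 2L
    fail[is.na(fail) & bad] <- "alleles"
  }
  missing_frac <- rowMeans(is.na(vs$gt))
  fail[is.na(fail) & missing_frac > config$max_missing_fraction] <- "missing"
  gq_bad <- rowSums(is.na(vs$gq) | vs$gq < config$min_gq) > 0L
  fail[is.na(fail) & gq_bad] <- "gq"
  # MAF over all genotyped alleles at the site
  al <- gt_alleles(as.vector(vs$gt))
  alt_cnt <- rowSums(matrix(al[, 1L] > 0L, nrow = n), na.rm = TRUE) +
    rowSums(matrix(al[, 2L] > 0L, nrow = n), na.rm = TRUE)
  tot <- rowSums(matrix(!is.na(al[, 1L]), nrow = n)) +
    rowSums(matrix(!is.na(al[, 2L]), nrow = n))
  maf <- pmin(alt_cnt / tot, 1 - alt_cnt / tot)
  fail[is.na(fail) & (is.na(maf) | maf < config$min_maf)] <- "maf"
  kept <- is.na(fail)
  tally <- c(alleles = sum(fail == "alleles", na.rm = TRUE),
             missing = sum(fail == "missing", na.rm = TRUE),
             gq = sum(fail == "gq", na.rm = TRUE),
             maf = sum(fail == "maf", na.rm = TRUE))
  out <- vs
  out$sites <- vs$sites[kept, , drop = FALSE]
  rownames(out$sites) <- NULL
  out$gt <- vs$gt[kept, , drop = FALSE]
  out$gq <- vs$gq[kept, , drop = FALSE]
  list(variants = out, kept = kept, tally = tally)
}

#' Partition heterozygous sites by sharing across samples
#'
#' Splits filtered sites into those heterozygous in every sample
#' (`shared_all`) versus heterozygous in 1..n-1 samples (`partial`). Sites
#' heterozygous in no sample are excluded with a warning (they should not
#' survive the MAF filter).
#'
#' @param vs a filtered `variant_set`.
#' @return list with `shared_all`, `partial`, `total`, `percentage_shared`
#'   (1 decimal) and `class` (per-site factor: "all"/"partial").
#' @export
partition_sharing <- function(vs) {
  het <- het_matrix(vs)
  nhet <- rowSums(het, na.rm = TRUE)
  if (any(nhet == 0L)) {
    warning(sum(nhet == 0L), " sites heterozygous in no sample excluded")
  }
  use <- nhet > 0L
  ns <- length(vs$samples)
  shared <- sum(nhet[use] == ns)
  partial <- sum(nhet[use] < ns)
  total <- sum(use)
  list(shared_all = shared, partial = partial, total = total,
       percentage_shared = round(100 * shared / total, 1L),
       class = ifelse(nhet == ns, "all",
                      ifelse(nhet > 0L, "partial", "none")))
}

#' Pooled heterozygous-site counts in non-overlapping windows
#'
#' A site at 0-based position p on a chromosome belongs to window
#' `floor(p / window)`. Counts pool the samples' union: a site shared by
#' several samples is counted once. Per-sample profiles are also returned.
#'
#' @param vs a filtered `variant_set`.
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param window window size in bp (non-overlapping).
#' @return data.frame chrom, win_start, win_end, count, plus one
#'   `count_<sample>` column per sample.
#' @export
window_heterozygosity <- function(vs, chrom_lengths, window = 100000L) {
  bad <- setdiff(unique(vs$sites$chrom), names(chrom_lengths))
  if (length(bad)) stop("site on unknown chromosome: ", bad[1L])
  if (any(vs$sites$pos >= chrom_lengths[vs$sites$chrom]))
    stop("site beyond chromosome length")
  het <- het_matrix(vs)
  out <- list()
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    nw <- as.integer(ceiling(len / window))
    starts <- (seq_len(nw) - 1L) * window
    idx <- which(vs$sites$chrom == ch)
    wi <- vs$sites$pos[idx] %/% window + 1L
    df <- data.frame(chrom = ch, win_start = starts,
                     win_end = pmin(starts + window, len),
                     count = as.integer(tabulate(wi, nbins = nw)),
                     stringsAsFactors = FALSE)
    for (s in vs$samples) {
      df[[paste0("count_", s)]] <-
        as.integer(tabulate(wi[het[idx, s]], nbins = nw))
    }
    out[[ch]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call heterozygosity hotspot fragments
#'
#' The qualification threshold is the empirical `1 - top_fraction` quantile
#' (inverse-ECDF, type 1) of genome-wide window counts restricted to windows
#' with a nonzero count. Qualifying windows (count >= threshold) are merged
#' into fragments, bridging up to `max_bridge_windows` non-qualifying windows;
#' fragments with fewer than `min_windows` qualifying windows are discarded.
#' Fragment coordinates run from the first window start to the last window
#' end.
#'
#' @param profile window profile from [window_heterozygosity()].
#' @param top_fraction tail fraction defining hotspots.
#' @param max_bridge_windows non-qualifying windows bridged inside a fragment.
#' @param min_windows minimum qualifying windows per fragment.
#' @return data.frame chrom, start, end, n_windows, mean_count; attribute
#'   `threshold` carries the qualification threshold.
#' @export
call_hotspots <- function(profile, top_fraction = 0.05,
                          max_bridge_windows = 1L, min_windows = 2L) {
  counts <- profile$count
  if (length(counts) < 20L)
    stop("need >= 20 windows genome-wide for a top-", top_fraction,
         " quantile")
  nz <- counts[counts > 0L]
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_windows = integer(),
                      mean_count = numeric(), stringsAsFactors = FALSE)
  if (!length(nz)) return(structure(empty, threshold = NA_real_))
  thr <- stats::quantile(nz, probs = 1 - top_fraction, type = 1L,
                         names = FALSE)
  out <- list()
  for (ch in unique(profile$chrom)) {
    sub <- profile[profile$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$win_start), , drop = FALSE]
    q <- sub$count >= thr
    r <- rle(q)
    if (length(r$lengths) > 2L) {
      inner <- 2L:(length(r$lengths) - 1L)
      flip <- inner[!r$values[inner] & r$lengths[inner] <= max_bridge_windows]
      if (length(flip)) {
        g <- rep(r$values, r$lengths)
        ends0 <- cumsum(r$lengths)
        starts0 <- ends0 - r$lengths + 1L
        for (i in flip) g[starts0[i]:ends0[i]] <- TRUE
        r <- rle(g)
      }
    }
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      wset <- starts[i]:ends[i]
      qual <- wset[q[wset]]
      if (length(qual) < min_windows) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch,
        start = sub$win_start[min(qual)],
        end = sub$win_end[max(qual)],
        n_windows = length(qual),
        mean_count = mean(sub$count[qual]),
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty
  rownames(res) <- NULL
  structure(res, threshold = thr)
}
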