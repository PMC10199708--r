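# Centromere localization: windowed density profiles of satellite arrays,
# genes and TEs; per-chromosome selection of the centromeric monomer family;
# and the call itself — the bp-maximal run of satellite-bearing windows whose
# gene+TE density is depleted relative to the rest of the chromosome. Genes
# captured inside calls are extracted for downstream annotation.
#
# The depletion test formalizes what is usually done by eye in a genome
# browser: a candidate region only becomes the centromere call when mean
# gene+TE covered bp per window inside the region is lower than outside.

#' Windowed coverage profile of features or arrays
#'
#' Computes bp covered per non-overlapping window by the union of the input
#' intervals (overlapping features count once per bp). Windows tile the
#' chromosome from 0.
#'
#' @param features data.frame with chrom, start, end (0-based half-open),
#'   restricted to one chromosome (a chrom column is optional for empty input).
#' @param chrom_length chromosome length in bp.
#' @param window window size in bp.
#' @return data.frame win_start, win_end, bp with `ceiling(len / window)` rows.
#' @export
density_profile <- function(features, chrom_length, window = 100000L) {
  nw <- as.integer(ceiling(chrom_length / window))
  starts <- (seq_len(nw) - 1L) * window
  ends <- pmin(starts + window, chrom_length)
  bp <- numeric(nw)
  if (!is.null(features) && nrow(features) > 0L) {
    if (any(features$end > chrom_length))
      stop("feature beyond chromosome end")
    if (any(features$start < 0L)) stop("negative feature coordinate")
    cov <- IRanges::coverage(
      IRanges::IRanges(start = features$start + 1L, end = features$end),
      width = chrom_length)
    covered <- S4Vectors::runValue(cov) > 0L
    flat <- S4Vectors::Rle(covered, S4Vectors::runLength(cov))
    v <- IRanges::Views(flat, start = starts + 1L, end = ends)
    bp <- IRanges::viewSums(v)
  }
  data.frame(win_start = starts, win_end = ends, bp = as.numeric(bp))
}

#' Select the centromeric monomer family per chromosome
#'
#' The genome-wide most-abundant family (by total bp) is the default target on
#' every chromosome. A chromosome switches to its locally most-abundant family
#' when that family's bp there exceeds the default family's bp by at least
#' `factor` (chromosome-specific satellites, e.g. distinct monomers on
#' individual chromosomes of an otherwise uniform genome).
#'
#' @param grouped result of [group_harmonics()] (families + assigned arrays).
#' @param chroms chromosome names to report (defaults to those with arrays).
#' @param factor local-dominance factor for an override.
#' @return data.frame chrom, family_id, base_period (NA rows for chromosomes
#'   with no arrays).
#' @export
select_centromeric_family <- function(grouped, chroms = NULL, factor = 2) {
  arrays <- grouped$arrays
  fams <- grouped$families
  if (is.null(chroms)) chroms <- unique(arrays$chrom)
  if (nrow(fams) == 0L) {
    return(data.frame(chrom = chroms, family_id = NA_character_,
                      base_period = NA_integer_, stringsAsFactors = FALSE))
  }
  default_fam <- fams$family_id[which.max(fams$total_bp)]
  res <- lapply(chroms, function(ch) {
    sub <- arrays[arrays$chrom == ch, , drop = FALSE]
    if (nrow(sub) == 0L) {
      message("no repeat family on chromosome ", ch)
      return(data.frame(chrom = ch, family_id = NA_character_,
                        base_period = NA_integer_, stringsAsFactors = FALSE))
    }
    bp_by_fam <- tapply(sub$end - sub$start, sub$family_id, sum)
    local_best <- names(bp_by_fam)[which.max(bp_by_fam)]
    def_bp <- if (default_fam %in% names(bp_by_fam))
      bp_by_fam[[default_fam]] else 0
    fam <- default_fam
    if (local_best != default_fam && bp_by_fam[[local_best]] >= factor * def_bp)
      fam <- local_best
    data.frame(chrom = ch, family_id = fam,
               base_period = fams$base_period[match(fam, fams$family_id)],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Call the centromere of one chromosome
#'
#' Candidate regions are maximal runs of windows containing target-family
#' array bp, bridging array-free gaps up to `max_gap`. Candidates below
#' `min_array_bp` of array coverage are dropped. Among the rest, candidates
#' are visited in decreasing array-bp order and the first whose mean gene+TE
#' covered bp per window inside is lower than outside becomes the call;
#' boundaries are snapped to the outermost contributing arrays.
#'
#' @param arrays target-family arrays on this chromosome (chrom/start/end).
#' @param genes,tes feature data.frames for this chromosome (may be empty).
#' @param chrom_length chromosome length in bp.
#' @param window profile window in bp.
#' @param min_array_bp minimum target-family bp inside a candidate.
#' @param max_gap maximum bridged array-free gap in bp.
#' @return list with `call` (one-row data.frame chrom, start, end, array_bp,
#'   gene_te_inside, gene_te_outside, or NULL) and `candidates` (diagnostics
#'   data.frame of all candidate regions).
#' @export
call_centromere <- function(arrays, genes, tes, chrom_length,
                            window = 100000L, min_array_bp = 50000L,
                            max_gap = 500000L) {
  chrom <- if (nrow(arrays)) arrays$chrom[1L] else NA_character_
  empty <- data.frame(start = integer(), end = integer(),
                      array_bp = numeric())
  if (nrow(arrays) == 0L) return(list(call = NULL, candidates = empty))
  feat <- rbind(genes[, c("start", "end"), drop = FALSE],
                tes[, c("start", "end"), drop = FALSE])
  prof_d <- density_profile(feat, chrom_length, window)
  nw <- nrow(prof_d)
  # candidate regions: arrays merged across gaps up to max_gap (bp),
  # boundaries thereby snapped to the outermost contributing arrays
  cand <- merge_intervals(arrays[, c("start", "end")], gap = max_gap)
  cand$array_bp <- vapply(seq_len(nrow(cand)), function(i) {
    inb <- arrays$start >= cand$start[i] & arrays$end <= cand$end[i]
    m <- merge_intervals(arrays[inb, c("start", "end")])
    sum(m$end - m$start)
  }, 0)
  cand <- cand[order(-cand$array_bp), , drop = FALSE]
  candidates <- cand
  cand <- cand[cand$array_bp >= min_array_bp, , drop = FALSE]
  if (nrow(cand) == 0L) {
    warning("no candidate centromere region reaches min_array_bp on ",
            chrom)
    return(list(call = NULL, candidates = candidates))
  }
  for (i in seq_len(nrow(cand))) {
    wset <- which(prof_d$win_start < cand$end[i] &
                    prof_d$win_end > cand$start[i])
    inside <- mean(prof_d$bp[wset])
    outside <- if (length(wset) < nw) mean(prof_d$bp[-wset]) else Inf
    if (inside < outside) {
      call <- data.frame(chrom = chrom, start = cand$start[i],
                         end = cand$end[i],
                         array_bp = cand$array_bp[i],
                         gene_te_inside = inside,
                         gene_te_outside = outside,
                         stringsAsFactors = FALSE)
      return(list(call = call, candidates = candidates))
    }
  }
  warning("no candidate passes the gene/TE depletion test on ", chrom)
  list(call = NULL, candidates = candidates)
}

#' Call centromeres genome-wide
#'
#' Runs [select_centromeric_family()] and [call_centromere()] on every
#' chromosome: at most one call per chromosome.
#'
#' @param grouped result of [group_harmonics()].
#' @param features feature data.frame (genes + TEs) for the whole genome.
#' @param chrom_lengths named vector of chromosome lengths.
#' @inheritParams call_centromere
#' @param factor local-dominance factor passed to [select_centromeric_family()].
#' @return list with `calls` (data.frame, one row per called chromosome),
#'   `selection` (per-chromosome family), `diagnostics` (all candidates).
#' @export
call_centromeres <- function(grouped, features, chrom_lengths,
                             window = 100000L, min_array_bp = 50000L,
                             max_gap = 500000L, factor = 2) {
  sel <- select_centromeric_family(grouped, chroms = names(chrom_lengths),
                                   factor = factor)
  arrays <- grouped$arrays
  calls <- list(); diags <- list()
  for (ch in names(chrom_lengths)) {
    fam <- sel$family_id[sel$chrom == ch]
    if (length(fam) == 0L || is.na(fam)) next
    a <- arrays[arrays$chrom == ch & arrays$family_id == fam, , drop = FALSE]
    g <- features[features$chrom == ch & features$kind == "gene", , drop = FALSE]
    t <- features[features$chrom == ch & features$kind == "TE", , drop = FALSE]
    res <- call_centromere(a, g, t, chrom_lengths[[ch]], window = window,
                           min_array_bp = min_array_bp, max_gap = max_gap)
    if (!is.null(res$call)) {
      res$call$family_id <- fam
      res$call$base_period <- sel$base_period[sel$chrom == ch]
      calls[[ch]] <- res$call
    }
    if (nrow(res$candidates)) {
      res$candidates$chrom <- ch
      diags[[ch]] <- res$candidates
    }
  }
  list(calls = if (length(calls)) do.call(rbind, c(calls, make.row.names = FALSE))
       else NULL,
       selection = sel,
       diagnostics = if (length(diags)) do.call(rbind, c(diags, make.row.names = FALSE))
       else NULL)
}

#' Genes captured inside centromere calls
#'
#' A gene is captured when its interval overlaps a call by at least 1 bp.
#'
#' @param calls data.frame of centromere calls (chrom, start, end).
#' @param genes gene feature data.frame (chrom, start, end, id).
#' @return data.frame chrom, gene id, start, end, call_start, call_end,
#'   sorted by position; zero rows when nothing is captured.
#' @export
captured_genes <- function(calls, genes) {
  out <- list()
  if (is.null(calls) || nrow(calls) == 0L || nrow(genes) == 0L) {
    return(data.frame(chrom = character(), id = character(),
                      start = integer(), end = integer(),
                      call_start = integer(), call_end = integer()))
  }
  for (i in seq_len(nrow(calls))) {
    g <- genes[genes$chrom == calls$chrom[i] &
                 genes$end > calls$start[i] &
                 genes$start < calls$end[i], , drop = FALSE]
    if (nrow(g) == 0L) next
    g <- g[order(g$start), , drop = FALSE]
    out[[i]] <- data.frame(chrom = g$chrom, id = g$id,
                           start = g$start, end = g$end,
                           call_start = calls$start[i],
                           call_end = calls$end[i],
                           stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), id = character(),
                      start = integer(), end = integer(),
                      call_start = integer(), call_end = integer()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
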