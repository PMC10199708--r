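# Telomere unit discovery and per-arm telomere calling.
#
# Telomeres are searched only inside terminal windows (default 150 kb) at each
# chromosome end; interstitial telomeric repeats elsewhere are deliberately
# ignored. Candidate unit lengths span 5-12 bp; runs explainable by a
# fundamental period below the minimum unit length (e.g. mono- or
# dinucleotide tracts) are excluded.

# Terminal windows of one chromosome: list of (arm, start, end) in 0-based
# half-open genome coordinates. Windows longer than the chromosome are
# truncated with a warning.
terminal_windows <- function(chrom_len, terminal_window) {
  w <- terminal_window
  if (w > chrom_len) {
    warning("terminal window truncated to chromosome length")
    w <- chrom_len
  }
  list(left = c(0L, w), right = c(chrom_len - w, chrom_len))
}

# Exact tandem runs of unit length u inside a window sequence. Returns spans
# (0-based half-open, window-local) with their repeating unit, skipping
# non-primitive units (fundamental period != u).
unit_runs <- function(wseq, u, min_copies, min_identity = 0.95) {
  x <- encode_dna(wseq)
  sp <- verify_period(x, u, min_identity, min_copies, bridge = u)
  if (is.null(sp)) return(NULL)
  sp$unit <- substring(wseq, sp$start + 1L, sp$start + u)
  fp <- vapply(sp$unit, fundamental_period, 0L)
  sp[fp == u & !grepl("[^ACGT]", sp$unit), , drop = FALSE]
}

#' Discover the telomeric repeat unit
#'
#' Scans the terminal windows of every chromosome for tandem runs of units of
#' length `min_unit`..`max_unit` and returns the canonical unit covering the
#' most bp summed over all windows, together with per-chromosome coverage as
#' supporting evidence. Units whose fundamental period is below `min_unit`
#' (e.g. dinucleotide tracts) are excluded.
#'
#' @param genome named character vector of chromosome sequences.
#' @param terminal_window bp searched at each chromosome end.
#' @param min_unit,max_unit unit length range in bp.
#' @param min_copies minimum tandem copies for a run to count as evidence.
#' @return list with `unit` (canonical string, or `NA` if none found),
#'   `total_bp`, and `evidence` (data.frame chrom, arm, unit, bp).
#' @export
find_telomere_unit <- function(genome, terminal_window = 150000L,
                               min_unit = 5L, max_unit = 12L,
                               min_copies = 10L) {
  check_genome(genome)
  ev <- list()
  for (chrom in names(genome)) {
    len <- nchar(genome[[chrom]])
    wins <- suppressWarnings(terminal_windows(len, terminal_window))
    for (arm in names(wins)) {
      wseq <- substr(genome[[chrom]], wins[[arm]][1L] + 1L, wins[[arm]][2L])
      for (u in min_unit:max_unit) {
        runs <- unit_runs(wseq, u, min_copies)
        if (is.null(runs) || nrow(runs) == 0L) next
        ev[[length(ev) + 1L]] <- data.frame(
          chrom = chrom, arm = arm,
          unit = vapply(runs$unit, canonical_monomer, "", USE.NAMES = FALSE),
          bp = runs$end - runs$start, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(ev)) {
    message("no telomeric unit found")
    return(list(unit = NA_character_, total_bp = 0,
                evidence = data.frame(chrom = character(), arm = character(),
                                      unit = character(), bp = numeric())))
  }
  ev <- do.call(rbind, ev)
  totals <- tapply(ev$bp, ev$unit, sum)
  best <- names(totals)[which.max(totals)]
  evidence <- stats::aggregate(bp ~ chrom + arm + unit, data = ev, FUN = sum)
  list(unit = best, total_bp = unname(totals[best]), evidence = evidence)
}

#' Call telomeres at every chromosome arm
#'
#' For each arm, finds the maximal tandem array of `unit` (any rotation,
#' either strand) inside the terminal window. Runs broken by at most one
#' unit length of non-matching sequence are bridged; longer breaks end the
#' array. An arm is called present when the array reaches `min_copies`.
#'
#' @param genome named character vector of chromosome sequences.
#' @param unit telomere repeat unit (any rotation/strand; canonicalized
#'   internally), e.g. from [find_telomere_unit()].
#' @param terminal_window bp searched at each chromosome end.
#' @param min_copies presence threshold in copies.
#' @return data.frame with one row per arm: chrom, arm (left/right), present,
#'   unit (canonical), copies (1 decimal), start, end (0-based half-open
#'   genome coordinates; NA when absent), length.
#' @export
call_telomeres <- function(genome, unit, terminal_window = 150000L,
                           min_copies = 50) {
  check_genome(genome)
  if (is.na(unit)) stop("unit is NA; run find_telomere_unit() first")
  u <- nchar(unit)
  canon <- canonical_monomer(unit)
  valid <- unique(c(rotations(unit), rotations(revcomp(unit))))
  out <- list()
  for (chrom in names(genome)) {
    len <- nchar(genome[[chrom]])
    wins <- terminal_windows(len, terminal_window)
    for (arm in names(wins)) {
      ws <- wins[[arm]][1L]; we <- wins[[arm]][2L]
      wseq <- substr(genome[[chrom]], ws + 1L, we)
      wn <- nchar(wseq)
      hit <- rep(FALSE, max(wn - u + 1L, 0L))
      for (v in valid) {
        mm <- gregexpr(v, wseq, fixed = TRUE)[[1L]]
        if (mm[1L] != -1L) hit[mm] <- TRUE
      }
      best <- best_run(hit, bridge = u, min_block = u)
      if (is.null(best)) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, arm = arm, present = FALSE, unit = canon,
          copies = 0, start = NA_integer_, end = NA_integer_, length = 0L,
          stringsAsFactors = FALSE)
        next
      }
      span <- best[2L] - best[1L] + u          # hit positions -> bp span
      copies <- round(span / u, 1L)
      s0 <- ws + best[1L] - 1L
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, arm = arm, present = copies >= min_copies,
        unit = canon, copies = copies,
        start = s0, end = s0 + span, length = span,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Longest TRUE run in a logical vector, bridging FALSE gaps <= bridge.
# Terminal TRUE-blocks shorter than min_block are trimmed back off: they are
# chance boundary matches into background, not array continuation (a genuine
# tandem continuation is hit at every consecutive position). Returns
# c(first, last) 1-based indices or NULL.
best_run <- function(hit, bridge = 0L, min_block = 1L) {
  if (!length(hit) || !any(hit)) return(NULL)
  r <- rle(hit)
  if (length(r$lengths) > 2L) {
    inner <- 2L:(length(r$lengths) - 1L)
    flip <- inner[!r$values[inner] & r$lengths[inner] <= bridge]
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
  runs <- which(r$values)
  i <- runs[which.max(r$lengths[runs])]
  s <- starts[i]; e <- ends[i]
  if (min_block > 1L) {
    ro <- rle(hit[s:e])
    oe <- cumsum(ro$lengths)
    os <- oe - ro$lengths + 1L
    tb <- which(ro$values & ro$lengths >= min_block)
    if (!length(tb)) {
      tb <- which(ro$values)[which.max(ro$lengths[which(ro$values)])]
    }
    s2 <- s + os[tb[1L]] - 1L
    e2 <- s + oe[tb[length(tb)]] - 1L
    s <- s2; e <- e2
  }
  c(s, e)
}
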