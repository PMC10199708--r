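# Tandem-repeat (satellite) array detection, monomer canonicalization,
# harmonic grouping into monomer families, and genome-wide unit summaries.
#
# Detection strategy: candidate periods are seeded from exact k-mer recurrence
# distances, then verified by shifted self-identity — the fraction of
# positions i with seq[i] == seq[i + p] over the candidate span. Consensus
# monomers are per-column majority votes over full copies. An exact tandem of
# period p is also a tandem of 2p; the scanner reports the smallest period
# that clears the identity threshold, and group_harmonics() re-attaches
# deliberate higher-order (concatemer) units to their base family.

#' Canonical form of a tandem-repeat monomer
#'
#' Both strand representations and all rotational phases of a tandem unit
#' denote the same monomer (e.g. the plant telomere unit TTTAGGG/CCCTAAA).
#' The canonical form is the lexicographically smallest string among all
#' rotations of the unit and all rotations of its reverse complement; it is
#' idempotent and strand/rotation invariant.
#'
#' @param unit non-empty ACGT string.
#' @return canonical monomer string.
#' @examples
#' canonical_monomer("TTTAGGG")  # "AAACCCT"
#' canonical_monomer("CCCTAAA")  # same
#' @export
canonical_monomer <- function(unit) {
  if (!is.character(unit) || length(unit) != 1L || nchar(unit) == 0L)
    stop("unit must be a single non-empty string")
  if (grepl("[^ACGT]", unit)) stop("non-ACGT character in unit: ", unit)
  min(c(rotations(unit), rotations(revcomp(unit))))
}

# k-mer recurrence seeding: distances between consecutive occurrences of each
# exact k-mer. Returns a data.frame(period, votes) for distances inside
# [min_period, max_period] seen at least min_votes times.
candidate_periods <- function(x, min_period, max_period, kmer = 12L,
                              min_votes = 5L) {
  n <- length(x)
  m <- n - kmer + 1L
  if (m < 2L) return(integer())
  code <- numeric(m)
  for (j in seq_len(kmer) - 1L) {
    code <- code * 4 + as.numeric(x[(1L + j):(m + j)])
  }
  keep <- which(!is.na(code))
  if (length(keep) < 2L) return(integer())
  o <- keep[order(code[keep], keep)]
  d <- diff(o)
  same <- diff(code[o]) == 0
  d <- d[same & d >= min_period & d <= max_period]
  if (!length(d)) return(integer())
  tab <- table(d)
  sort(as.integer(names(tab)[tab >= min_votes]))
}

# Verify one candidate period on an encoded sequence: find maximal spans whose
# per-period shifted identity clears min_identity. Returns data.frame of
# 0-based half-open spans.
verify_period <- function(x, p, min_identity, min_copies, bridge = NULL) {
  n <- length(x)
  if (n < 2L * p) return(NULL)
  if (is.null(bridge)) bridge <- p
  e <- x[seq_len(n - p)] == x[(p + 1L):n]
  e[is.na(e)] <- FALSE
  nw <- n - 2L * p + 1L
  cs <- c(0, cumsum(e))
  W <- cs[(seq_len(nw)) + p] - cs[seq_len(nw)]
  good <- W >= min_identity * p
  r <- rle(good)
  # bridge short bad runs flanked by good runs
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
  out <- NULL
  for (i in which(r$values)) {
    a <- starts[i]; b <- ends[i]
    span <- (b - a) + 2L * p
    copies <- span / p
    if (copies >= min_copies) {
      out <- rbind(out, data.frame(start = a - 1L, end = a - 1L + span))
    }
  }
  out
}

# Trim array boundaries to the consensus: the array must begin and end with
# an uninterrupted run of `anchor` positions matching the phase-aligned
# consensus. Counters the sub-period overhang into background that the
# windowed shifted-identity rule allows (random background matches ~25% of
# positions, so a 10-position exact run pins the true edge).
refine_boundaries <- function(x, start, end, p, cons, anchor = 10L) {
  span <- end - start
  if (span < 2L * p + 2L * anchor) return(c(start, end))
  cvec <- encode_dna(cons)
  expected <- cvec[((seq_len(span) - 1L) %% p) + 1L]
  obs <- x[(start + 1L):end]
  M <- !is.na(obs) & !is.na(expected) & obs == expected
  cs <- c(0, cumsum(M))
  lim <- min(span - anchor, 2L * p)
  wsum <- cs[(seq_len(lim)) + anchor] - cs[seq_len(lim)]
  a <- which(wsum == anchor)[1L]            # first clean anchor run
  a <- if (is.na(a)) 0L else a - 1L
  # tail: last j with M[(j-anchor+1)..j] all true, searched in the tail 2p
  lo <- max(a + 2L * p, span - 2L * p)
  js <- span:max(lo, anchor)
  b <- NA_integer_
  for (j in js) {
    if (cs[j + 1L] - cs[j - anchor + 1L] == anchor) { b <- j; break }
  }
  if (is.na(b)) b <- span
  c(start + a, start + b)
}

# Majority-vote consensus and mean copy-to-consensus identity for an array.
array_consensus <- function(seq, start, end, p) {
  span <- end - start
  ncop <- span %/% p
  if (ncop < 1L) return(list(consensus = substr(seq, start + 1L, start + p),
                             identity = 1))
  starts <- start + (seq_len(ncop) - 1L) * p
  rows <- substring(seq, starts + 1L, starts + p)
  mat <- matrix(unlist(strsplit(rows, "", fixed = TRUE)),
                nrow = ncop, byrow = TRUE)
  cons <- apply(mat, 2L, function(col) {
    tb <- table(col)
    names(tb)[which.max(tb)]  # ties: alphabetical first (table is sorted)
  })
  idn <- mean(t(mat) == cons)
  list(consensus = paste(cons, collapse = ""), identity = idn)
}

#' Scan a genome for tandem-repeat arrays
#'
#' Detects maximal tandem arrays with monomer periods in
#' `[min_period, max_period]`, at least `min_copies` (fractional) copies and
#' shifted self-identity at least `min_identity`. Candidate periods are seeded
#' by exact k-mer recurrence and verified by shifted identity; overlapping
#' explanations are resolved by reporting the smallest period that clears the
#' threshold (harmonics) and otherwise the higher identity x span score.
#'
#' @param genome named character vector of chromosome sequences (a single
#'   unnamed string is accepted).
#' @param min_period,max_period monomer length range in bp.
#' @param min_copies minimum fractional copy number of a reported array.
#' @param min_identity minimum shifted self-identity within the array.
#' @param kmer seed k-mer length.
#' @param min_votes minimum k-mer recurrence count for a candidate period.
#' @return data.frame with chrom, start, end (0-based half-open), period,
#'   copies (1 decimal), identity, consensus, canonical.
#' @export
scan_tandem_arrays <- function(genome, min_period = 30L, max_period = 500L,
                               min_copies = 2, min_identity = 0.80,
                               kmer = 12L, min_votes = 5L) {
  if (is.null(names(genome))) {
    names(genome) <- paste0("seq", seq_along(genome))
  }
  check_genome(genome)
  res <- list()
  for (chrom in names(genome)) {
    seq <- genome[[chrom]]
    n <- nchar(seq)
    if (n < 2L * min_period) next
    x <- encode_dna(seq)
    cands <- candidate_periods(x, min_period, max_period, kmer, min_votes)
    hits <- NULL
    for (p in cands) {
      sp <- verify_period(x, p, min_identity, min_copies)
      if (is.null(sp)) next
      sp$period <- p
      hits <- rbind(hits, sp)
    }
    if (is.null(hits) || nrow(hits) == 0L) next
    for (i in seq_len(nrow(hits))) {
      cons0 <- array_consensus(seq, hits$start[i], hits$end[i],
                               hits$period[i])$consensus
      se <- refine_boundaries(x, hits$start[i], hits$end[i],
                              hits$period[i], cons0)
      hits$start[i] <- se[1L]
      hits$end[i] <- se[2L]
    }
    cons <- lapply(seq_len(nrow(hits)), function(i)
      array_consensus(seq, hits$start[i], hits$end[i], hits$period[i]))
    hits$identity <- vapply(cons, `[[`, 0, "identity")
    hits$consensus <- vapply(cons, `[[`, "", "consensus")
    # a consensus that is exactly k-periodic means the true monomer is the
    # k-mer: relabel to the fundamental period, or drop the array when that
    # period falls below the scan range (e.g. telomeric 7-mers surfacing as
    # long pseudo-periods)
    drop <- rep(FALSE, nrow(hits))
    for (i in seq_len(nrow(hits))) {
      fp <- fundamental_period(hits$consensus[i])
      if (fp < hits$period[i]) {
        if (fp < min_period) { drop[i] <- TRUE; next }
        hits$period[i] <- fp
        cc <- array_consensus(seq, hits$start[i], hits$end[i], fp)
        hits$consensus[i] <- cc$consensus
        hits$identity[i] <- cc$identity
      }
    }
    hits <- hits[!drop, , drop = FALSE]
    if (nrow(hits) == 0L) next
    # overlapping detections of the same period describe one array: take the
    # union and recompute its consensus
    merged <- list()
    for (p in unique(hits$period)) {
      sub <- merge_intervals(hits[hits$period == p, c("start", "end")])
      sub$period <- p
      merged[[as.character(p)]] <- sub
    }
    hits <- do.call(rbind, merged)
    cons <- lapply(seq_len(nrow(hits)), function(i)
      array_consensus(seq, hits$start[i], hits$end[i], hits$period[i]))
    hits$identity <- vapply(cons, `[[`, 0, "identity")
    hits$consensus <- vapply(cons, `[[`, "", "consensus")
    hits <- resolve_overlaps(hits)
    hits$copies <- round((hits$end - hits$start) / hits$period, 1L)
    hits$canonical <- vapply(hits$consensus, canonical_monomer, "",
                             USE.NAMES = FALSE)
    hits$chrom <- chrom
    res[[chrom]] <- hits[, c("chrom", "start", "end", "period", "copies",
                             "identity", "consensus", "canonical")]
  }
  if (!length(res)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      period = integer(), copies = numeric(),
                      identity = numeric(), consensus = character(),
                      canonical = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Resolve overlapping candidate arrays of different periods on one chromosome.
# Exact duplicates collapse first; harmonically related overlapping arrays
# (one period an integer multiple of the other, overlap >= half the shorter
# span) collapse to the smallest period; remaining >= 50% overlaps keep the
# higher identity x span score. Overlaps below half the shorter span between
# non-harmonic periods are co-located distinct units and both are kept.
resolve_overlaps <- function(hits) {
  hits <- hits[!duplicated(hits[, c("start", "end", "period")]), ,
               drop = FALSE]
  if (nrow(hits) <= 1L) return(hits)
  hits$score <- hits$identity * (hits$end - hits$start)
  # pass 1: harmonic suppression, smallest period wins
  hits <- hits[order(hits$period, -hits$score, hits$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits) - 1L)) {
    if (!keep[i]) next
    for (j in (i + 1L):nrow(hits)) {
      if (!keep[j]) next
      ov <- min(hits$end[i], hits$end[j]) - max(hits$start[i], hits$start[j])
      if (ov <= 0) next
      shorter <- min(hits$end[i] - hits$start[i], hits$end[j] - hits$start[j])
      if (ov >= 0.5 * shorter && hits$period[j] %% hits$period[i] == 0L)
        keep[j] <- FALSE
    }
  }
  hits <- hits[keep, , drop = FALSE]
  # pass 2: remaining heavy overlaps keep the higher score
  hits <- hits[order(-hits$score, hits$period, hits$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  for (j in seq_len(nrow(hits))[-1L]) {
    for (i in seq_len(j - 1L)) {
      if (!keep[i]) next
      ov <- min(hits$end[i], hits$end[j]) - max(hits$start[i], hits$start[j])
      if (ov <= 0) next
      shorter <- min(hits$end[i] - hits$start[i], hits$end[j] - hits$start[j])
      if (ov >= 0.5 * shorter) { keep[j] <- FALSE; break }
    }
  }
  hits <- hits[keep, , drop = FALSE]
  hits$score <- NULL
  hits
}

# Best rotation/strand identity between a probe and a base monomer of the
# same length.
rotation_identity <- function(probe, base) {
  cands <- c(rotations(base), rotations(revcomp(base)))
  max(vapply(cands, function(r) string_identity(probe, r), 0))
}

#' Group integer-multiple (harmonic) units into monomer families
#'
#' An array of period k*p joins a family with base period p when its consensus,
#' cut into k pieces of length p, matches the base monomer at a mean identity
#' of at least `identity_min` under rotation and strand. Each array joins at
#' most one family; the smallest qualifying base period wins. Arrays that
#' qualify for no existing family found a new one.
#'
#' @param arrays data.frame from [scan_tandem_arrays()].
#' @param length_tolerance allowed |period - k * base| slack in bp.
#' @param identity_min minimum mean piece-to-base identity.
#' @param genome_length optional total genome length for family fractions.
#' @return list with `families` (data.frame family_id, base_period,
#'   base_consensus, member_periods, n_arrays, total_bp, genome_fraction) and
#'   `arrays` (input plus family_id, family_base columns).
#' @export
group_harmonics <- function(arrays, length_tolerance = 0L,
                            identity_min = 0.80, genome_length = NA_real_) {
  arrays <- arrays[order(arrays$period, -(arrays$end - arrays$start)), ,
                   drop = FALSE]
  fam_base <- integer()      # base periods
  fam_cons <- character()    # base consensus monomers
  assignment <- integer(nrow(arrays))
  for (i in seq_len(nrow(arrays))) {
    p <- arrays$period[i]
    cons <- arrays$consensus[i]
    hit <- 0L
    for (f in order(fam_base)) {
      bp <- fam_base[f]
      k <- round(p / bp)
      if (k < 1L || abs(p - k * bp) > length_tolerance) next
      pieces <- substring(cons, (seq_len(k) - 1L) * bp + 1L, seq_len(k) * bp)
      pieces <- pieces[nchar(pieces) == bp]
      if (!length(pieces)) next
      idn <- mean(vapply(pieces, rotation_identity, 0, base = fam_cons[f]))
      if (idn >= identity_min) { hit <- f; break }
    }
    if (hit == 0L) {
      fam_base <- c(fam_base, p)
      fam_cons <- c(fam_cons, cons)
      hit <- length(fam_base)
    }
    assignment[i] <- hit
  }
  arrays$family_id <- paste0("fam", assignment)
  arrays$family_base <- fam_base[assignment]
  fams <- lapply(seq_along(fam_base), function(f) {
    sub <- arrays[assignment == f, , drop = FALSE]
    data.frame(
      family_id = paste0("fam", f),
      base_period = fam_base[f],
      base_consensus = fam_cons[f],
      member_periods = paste(sort(unique(sub$period)), collapse = ","),
      n_arrays = nrow(sub),
      total_bp = sum(sub$end - sub$start),
      genome_fraction = sum(sub$end - sub$start) / genome_length,
      stringsAsFactors = FALSE
    )
  })
  families <- do.call(rbind, fams)
  if (is.null(families)) {
    families <- data.frame(family_id = character(), base_period = integer(),
                           base_consensus = character(),
                           member_periods = character(), n_arrays = integer(),
                           total_bp = numeric(), genome_fraction = numeric())
  } else {
    families <- families[order(-families$total_bp, families$base_period), ,
                         drop = FALSE]
    rownames(families) <- NULL
  }
  list(families = families, arrays = arrays)
}

#' Genome-wide summary of repeat unit lengths
#'
#' Per-period totals over a set of arrays, ranked by genome bp covered
#' (descending; ties broken by ascending period). Counting is per distinct
#' period; arrays of a harmonic family with different scanned periods appear
#' as separate rows (see [group_harmonics()] for family-level totals).
#'
#' @param arrays data.frame from [scan_tandem_arrays()].
#' @param genome_length total genome length in bp.
#' @return data.frame period, n_arrays, total_copies, total_bp,
#'   genome_fraction, ranked.
#' @export
summarize_repeat_units <- function(arrays, genome_length) {
  stopifnot(genome_length > 0)
  if (nrow(arrays) == 0L) {
    return(data.frame(period = integer(), n_arrays = integer(),
                      total_copies = numeric(), total_bp = numeric(),
                      genome_fraction = numeric()))
  }
  sp <- split(arrays, arrays$period)
  out <- do.call(rbind, lapply(sp, function(a) data.frame(
    period = a$period[1L],
    n_arrays = nrow(a),
    total_copies = round(sum(a$copies), 1L),
    total_bp = sum(a$end - a$start),
    genome_fraction = sum(a$end - a$start) / genome_length
  )))
  out <- out[order(-out$total_bp, out$period), , drop = FALSE]
  rownames(out) <- NULL
  out
}
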