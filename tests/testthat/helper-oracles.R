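# Brute-force oracles, written independently of the package's detection
# paths: naive enumeration and exhaustive scans on small inputs.

oracle_rc <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# canonical monomer by naive enumeration of all rotations of both strands
oracle_canonical <- function(s) {
  n <- nchar(s)
  cands <- character(0)
  for (str in c(s, oracle_rc(s))) {
    ch <- strsplit(str, "")[[1]]
    for (k in 0:(n - 1L)) {
      cands <- c(cands, paste(c(ch[seq_len(n) > k], ch[seq_len(k)]),
                              collapse = ""))
    }
  }
  sort(cands)[1L]
}

# Exhaustive all-period tandem scan on short sequences: for every period,
# positions where the 2p-length window of the shifted match vector reaches
# min_identity; merged into intervals. Detects arrays of >= 3 copies.
oracle_scan <- function(seq, min_period = 30L, max_period = 500L,
                        min_identity = 0.8) {
  x <- strsplit(seq, "")[[1]]
  n <- length(x)
  out <- list()
  for (p in min_period:min(max_period, floor((n - 1) / 3))) {
    m <- x[seq_len(n - p)] == x[(p + 1):n]
    L <- 2L * p
    nw <- length(m) - L + 1L
    if (nw < 1L) next
    cs <- c(0, cumsum(m))
    frac <- (cs[(seq_len(nw)) + L] - cs[seq_len(nw)]) / L
    good <- frac >= min_identity
    if (!any(good)) next
    r <- rle(good)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      out[[length(out) + 1L]] <- data.frame(
        period = p,
        start = starts[i] - 1L,
        end = ends[i] - 1L + 3L * p)  # 0-based half-open
    }
  }
  if (!length(out)) {
    return(data.frame(period = integer(), start = integer(),
                      end = integer()))
  }
  do.call(rbind, out)
}

# Exhaustive domain-cluster enumeration: every window of `seed_run`
# consecutive carrier ordinals seeds a member set; member sets of one
# accession are merged while their ordinal ranges overlap.
oracle_clusters <- function(ords, domsets, seed_run = 3L, extend = 30L) {
  accs <- unique(unlist(domsets))
  res <- list()
  for (acc in sort(accs)) {
    carriers <- sort(ords[vapply(domsets, function(d) acc %in% d, TRUE)])
    seeds <- Filter(function(o) all((o:(o + seed_run - 1L)) %in% carriers),
                    carriers)
    if (!length(seeds)) next
    msets <- lapply(seeds, function(o)
      carriers[carriers >= o - extend &
                 carriers <= o + seed_run - 1L + extend])
    repeat {
      merged <- FALSE
      for (i in seq_along(msets)) {
        for (j in seq_along(msets)) {
          if (j <= i) next
          if (min(msets[[i]]) <= max(msets[[j]]) &&
              min(msets[[j]]) <= max(msets[[i]])) {
            msets[[i]] <- sort(unique(c(msets[[i]], msets[[j]])))
            msets <- msets[-j]
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
      if (!merged) break
    }
    msets <- unique(msets)
    for (m in msets) {
      res[[length(res) + 1L]] <- list(accession = acc, members = m)
    }
  }
  res
}

# deterministic random DNA for fixtures
rand_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

truth_jaccard <- function(call_start, call_end, tr_start, tr_end) {
  inter <- max(0, min(call_end, tr_end) - max(call_start, tr_start))
  uni <- (call_end - call_start) + (tr_end - tr_start) - inter
  inter / uni
}
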