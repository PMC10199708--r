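# Domain-seeded gene-cluster detection and resistance-gene classification.
#
# Genes are ordered along each chromosome (ordinal index by start coordinate)
# and carry a set of protein-domain accessions. A run of >= 3 consecutive
# genes sharing an accession seeds a cluster; the cluster then collects every
# gene carrying that accession within +/- 30 gene ordinals of the seed run.
# Distances are measured in gene ordinals, not bp. Pairwise similarity hits
# (BLAST-like, e-value < 1e-5, identity > 30%, sharing a domain) describe the
# duplication landscape; optionally cluster members may be required to have a
# kept hit to another member.

split_domains <- function(x) {
  lapply(strsplit(ifelse(is.na(x) | x == "", " ", x), ",", fixed = TRUE),
         function(d) setdiff(trimws(d), ""))
}

#' Build ordered gene records
#'
#' Assigns 0-based ordinal indices along each chromosome by start coordinate
#' and attaches comma-separated domain accessions.
#'
#' @param genes gene feature data.frame (chrom, start, end, id).
#' @param domains data.frame with gene_id and comma-separated accessions
#'   column `domains` (as in the simulator's domains.tsv).
#' @return data.frame gene_id, chrom, ordinal, start, end, domains (string).
#' @export
gene_records <- function(genes, domains = NULL) {
  g <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  ord <- unlist(lapply(split(seq_len(nrow(g)), g$chrom),
                       function(i) seq_along(i) - 1L), use.names = FALSE)
  # split() reorders by chrom factor levels; realign
  g$ordinal <- NA_integer_
  for (ch in unique(g$chrom)) {
    idx <- which(g$chrom == ch)
    g$ordinal[idx] <- seq_along(idx) - 1L
  }
  dom <- rep("", nrow(g))
  if (!is.null(domains)) {
    m <- match(g$id, domains$gene_id)
    dom <- ifelse(is.na(m), "", domains$domains[m])
  }
  data.frame(gene_id = g$id, chrom = g$chrom, ordinal = g$ordinal,
             start = g$start, end = g$end, domains = dom,
             stringsAsFactors = FALSE)
}

#' Filter all-vs-all protein similarity hits
#'
#' Keeps a hit when e-value < `max_evalue`, identity > `min_identity`
#' (strict inequalities) and query and subject share at least one domain
#' accession; then applies symmetric closure (if A-B is kept, B-A is kept).
#'
#' @param hits data.frame query, subject, pident, evalue (outfmt-6 subset).
#' @param genes gene records from [gene_records()] (domain source).
#' @param max_evalue e-value threshold (exclusive).
#' @param min_identity percent-identity threshold (exclusive).
#' @return filtered, symmetric data.frame of hits.
#' @export
filter_similarity_hits <- function(hits, genes, max_evalue = 1e-5,
                                   min_identity = 30) {
  unknown <- setdiff(unique(c(hits$query, hits$subject)), genes$gene_id)
  if (length(unknown))
    stop("hit references unknown gene: ", unknown[1L])
  hits <- hits[hits$query != hits$subject, , drop = FALSE]
  keep <- hits$evalue < max_evalue & hits$pident > min_identity
  hits <- hits[keep, , drop = FALSE]
  doms <- split_domains(genes$domains)
  names(doms) <- genes$gene_id
  shared <- vapply(seq_len(nrow(hits)), function(i) {
    length(intersect(doms[[hits$query[i]]], doms[[hits$subject[i]]])) > 0L
  }, TRUE)
  hits <- hits[shared, , drop = FALSE]
  if (nrow(hits) == 0L) return(hits)
  # symmetric closure
  key <- paste(hits$query, hits$subject)
  rev_missing <- !(paste(hits$subject, hits$query) %in% key)
  if (any(rev_missing)) {
    add <- hits[rev_missing, , drop = FALSE]
    tmp <- add$query; add$query <- add$subject; add$subject <- tmp
    hits <- rbind(hits, add)
  }
  hits <- hits[order(hits$query, hits$subject), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Find domain-seeded gene clusters
#'
#' For each accession on each chromosome, every maximal run of at least
#' `seed_run` consecutive ordinals all carrying the accession seeds a
#' cluster. The cluster collects all genes carrying the accession within
#' `[run_start - extend, run_end + extend]` ordinals; clusters of the same
#' accession whose collected ordinal ranges overlap are merged. With
#' `require_hits = TRUE`, non-seed members must additionally have a kept
#' similarity hit to another member.
#'
#' @param genes gene records from [gene_records()].
#' @param seed_run seed length in consecutive genes.
#' @param extend extension window in gene ordinals.
#' @param hits optional filtered hits (see [filter_similarity_hits()]).
#' @param require_hits require members to be linked by a kept hit.
#' @return data.frame cluster_id, accession, chrom, n_genes, members
#'   (comma-separated gene_ids), span_start, span_end.
#' @export
find_domain_clusters <- function(genes, seed_run = 3L, extend = 30L,
                                 hits = NULL, require_hits = FALSE) {
  doms <- split_domains(genes$domains)
  out <- list()
  for (ch in unique(genes$chrom)) {
    idx <- which(genes$chrom == ch)
    idx <- idx[order(genes$ordinal[idx])]
    ords <- genes$ordinal[idx]
    accs <- unique(unlist(doms[idx]))
    for (acc in accs) {
      has <- vapply(doms[idx], function(d) acc %in% d, TRUE)
      carriers <- ords[has]
      runs <- consecutive_runs(carriers)
      runs <- runs[runs$len >= seed_run, , drop = FALSE]
      if (nrow(runs) == 0L) next
      members_per_run <- lapply(seq_len(nrow(runs)), function(i) {
        lo <- runs$first[i] - extend
        hi <- runs$last[i] + extend
        carriers[carriers >= lo & carriers <= hi]
      })
      merged <- merge_member_sets(members_per_run)
      for (mem in merged) {
        gidx <- idx[match(mem, ords)]
        gid <- genes$gene_id[gidx]
        if (require_hits && !is.null(hits) && length(mem) > 1L) {
          linked <- gid %in% c(hits$query[hits$subject %in% gid],
                               hits$subject[hits$query %in% gid])
          seed_set <- seed_members(mem, seed_run)
          keepm <- linked | mem %in% seed_set
          gidx <- gidx[keepm]; gid <- gid[keepm]; mem <- mem[keepm]
        }
        out[[length(out) + 1L]] <- data.frame(
          accession = acc, chrom = ch,
          leftmost = min(mem), n_genes = length(mem),
          members = paste(gid, collapse = ","),
          span_start = min(genes$start[gidx]),
          span_end = max(genes$end[gidx]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(cluster_id = character(), accession = character(),
                      chrom = character(), n_genes = integer(),
                      members = character(), span_start = integer(),
                      span_end = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$accession, res$leftmost), , drop = FALSE]
  res$cluster_id <- sprintf("%s_%s_%d", res$chrom, res$accession,
                            res$leftmost)
  rownames(res) <- NULL
  res[, c("cluster_id", "accession", "chrom", "n_genes", "members",
          "span_start", "span_end")]
}

# Maximal runs of consecutive integers in a sorted vector.
consecutive_runs <- function(v) {
  if (!length(v)) return(data.frame(first = integer(), last = integer(),
                                    len = integer()))
  brk <- c(TRUE, diff(v) != 1L)
  grp <- cumsum(brk)
  first <- tapply(v, grp, min)
  last <- tapply(v, grp, max)
  data.frame(first = as.integer(first), last = as.integer(last),
             len = as.integer(last - first + 1L))
}

# Ordinals belonging to any seed run of >= seed_run consecutive carriers.
seed_members <- function(mem, seed_run) {
  runs <- consecutive_runs(sort(mem))
  runs <- runs[runs$len >= seed_run, , drop = FALSE]
  unlist(lapply(seq_len(nrow(runs)),
                function(i) runs$first[i]:runs$last[i]))
}

# Merge member ordinal sets whose [min,max] ranges overlap.
merge_member_sets <- function(sets) {
  if (length(sets) <= 1L) return(sets)
  repeat {
    merged_any <- FALSE
    for (i in seq_along(sets)) {
      for (j in seq_along(sets)) {
        if (j <= i) next
        if (min(sets[[i]]) <= max(sets[[j]]) &&
            min(sets[[j]]) <= max(sets[[i]])) {
          sets[[i]] <- sort(unique(c(sets[[i]], sets[[j]])))
          sets <- sets[-j]
          merged_any <- TRUE
          break
        }
      }
      if (merged_any) break
    }
    if (!merged_any) break
  }
  sets
}

#' Classify disease-resistance (R) genes by domain architecture
#'
#' Default rule: a gene is flagged when its domains intersect
#' `rule$any_of` (NB-ARC, TIR, C-JID) or when any `rule$co_occur` pair is
#' jointly present (default: a leucine-rich-repeat accession together with a
#' protein-kinase accession). The rule is fully configuration-driven.
#'
#' @param genes gene records from [gene_records()].
#' @param rule list with `any_of` (character) and `co_occur`
#'   (list of character pairs).
#' @return list with `flags` (logical vector along `genes`) and `count`.
#' @export
classify_r_genes <- function(genes,
                             rule = list(any_of = c("NB-ARC", "TIR", "C-JID"),
                                         co_occur = list(c("LRR", "Pkinase")))) {
  doms <- split_domains(genes$domains)
  flags <- vapply(doms, function(d) {
    if (length(intersect(d, rule$any_of))) return(TRUE)
    for (pair in rule$co_occur) {
      if (all(pair %in% d)) return(TRUE)
    }
    FALSE
  }, TRUE)
  list(flags = flags, count = sum(flags))
}

#' Report clustered genes inside a genomic region
#'
#' Counts genes belonging to any cluster whose interval intersects the region
#' and tallies them by seed accession.
#'
#' @param clusters data.frame from [find_domain_clusters()].
#' @param genes gene records from [gene_records()].
#' @param chrom,start,end region (0-based half-open).
#' @return list with `n_genes` and `by_accession` (named counts).
#' @export
cluster_region_report <- function(clusters, genes, chrom, start, end) {
  n <- 0L
  tally <- integer()
  seen <- character()
  for (i in seq_len(nrow(clusters))) {
    if (clusters$chrom[i] != chrom) next
    gid <- strsplit(clusters$members[i], ",", fixed = TRUE)[[1L]]
    g <- genes[match(gid, genes$gene_id), , drop = FALSE]
    inside <- g$end > start & g$start < end
    gid <- gid[inside]
    gid <- setdiff(gid, seen)
    if (!length(gid)) next
    seen <- c(seen, gid)
    n <- n + length(gid)
    acc <- clusters$accession[i]
    tally[acc] <- (if (acc %in% names(tally)) tally[[acc]] else 0L) +
      length(gid)
  }
  list(n_genes = n, by_accession = tally)
}

#' Toy all-vs-all protein similarity scorer
#'
#' Computes local (Smith-Waterman) alignments between all pairs of short
#' protein sequences with [Biostrings::pairwiseAlignment()] and reports an
#' outfmt-6-like table (percent identity over the aligned region and a
#' Karlin-Altschul-style e-value from the raw score), so synthetic tests need
#' no external aligner. Intended for toy inputs (<= 500 aa, few hundred
#' sequences), not production searches.
#'
#' @param proteins named character vector of amino-acid sequences.
#' @param gap_open,gap_extend gap penalties.
#' @param k,lambda Karlin-Altschul constants for the e-value.
#' @return data.frame query, subject, pident, evalue (both directions).
#' @export
align_proteins <- function(proteins, gap_open = 10, gap_extend = 0.5,
                           k = 0.1, lambda = 0.267) {
  stopifnot(!is.null(names(proteins)))
  ids <- names(proteins)
  subj <- Biostrings::AAStringSet(proteins)
  out <- list()
  total <- sum(nchar(proteins))
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i == j) next
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(proteins[[i]]), subj[[j]],
        type = "local", substitutionMatrix = "BLOSUM62",
        gapOpening = gap_open, gapExtension = gap_extend)
      sc <- Biostrings::score(aln)
      pid <- Biostrings::pid(aln)
      ev <- k * nchar(proteins[[i]]) * total * exp(-lambda * sc)
      out[[length(out) + 1L]] <- data.frame(
        query = ids[i], subject = ids[j], pident = pid, evalue = ev,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
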