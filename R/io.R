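# Readers/writers for the standard formats the pipeline touches.
#
# Coordinate conventions: everything inside the package is 0-based half-open.
# GFF3 (1-based inclusive) and VCF (1-based positions) are converted at this
# boundary and converted back on write.

#' Read a genome FASTA
#'
#' Reads a (multi-)FASTA into a named character vector of uppercase sequences.
#' `U` is mapped to `T`; any letter outside `ACGTNU` is mapped to `N` with a
#' warning. Record IDs are the first whitespace-delimited token of the header.
#'
#' @param path path to a FASTA file.
#' @return named character vector, one element per record; names are unique
#'   chromosome IDs.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgt"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA record ID: ", dup[1L])
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  bad <- gsub("[ACGTN]", "", seqs)
  n_bad <- sum(nchar(bad))
  if (n_bad > 0L) {
    warning(n_bad, " non-ACGTN letters mapped to N")
    seqs <- vapply(seqs, function(s) gsub("[^ACGTN]", "N", s), "",
                   USE.NAMES = FALSE)
  }
  names(seqs) <- ids
  seqs
}

#' Write a genome FASTA
#'
#' @param genome named character vector of sequences.
#' @param path output path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  check_genome(genome)
  set <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# Map a GFF3 type / Classification attribute to the internal feature kind and
# subtype. Documented mapping:
#   type "gene"                          -> kind "gene"
#   type in transposable-element types,  -> kind "TE", subtype = last path
#     or a Classification attribute         component of Classification
#     (e.g. "LTR/Gypsy" -> "Gypsy")
#   type "rRNA"/"rDNA"                   -> kind "rDNA"
#   anything else                        -> kind "custom", subtype = type
gff3_kind <- function(type, classification) {
  te_types <- c("transposable_element", "TE", "repeat_region",
                "dispersed_repeat", "mobile_genetic_element")
  kind <- rep("custom", length(type))
  kind[type == "gene"] <- "gene"
  kind[type %in% te_types | !is.na(classification)] <- "TE"
  kind[type %in% c("rRNA", "rDNA", "rRNA_gene")] <- "rDNA"
  subtype <- ifelse(!is.na(classification),
                    sub("^.*/", "", classification),
                    ifelse(kind == "custom", type, NA_character_))
  list(kind = kind, subtype = subtype)
}

#' Read feature annotations from GFF3
#'
#' Imports a GFF3 (1-based inclusive) and converts to the internal 0-based
#' half-open convention. Feature kind is inferred from column 3 and the
#' `Classification` attribute (see Details).
#'
#' @details Mapping: type `gene` -> `gene`; transposable-element types or any
#'   record with a `Classification` attribute -> `TE` with subtype the final
#'   path component (`LTR/Gypsy` -> `Gypsy`); `rRNA`/`rDNA` -> `rDNA`;
#'   otherwise `custom`.
#'
#' @param path path to a GFF3 file.
#' @return data.frame with columns chrom, start (0-based), end, kind, subtype,
#'   id, strand.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  # light pre-validation so coordinate errors report the offending line
  raw <- readLines(path)
  body <- which(!startsWith(raw, "#") & nzchar(raw))
  for (i in body) {
    f <- strsplit(raw[i], "\t", fixed = TRUE)[[1]]
    if (length(f) >= 5L) {
      s <- suppressWarnings(as.numeric(f[4L])); e <- suppressWarnings(as.numeric(f[5L]))
      if (!is.na(s) && !is.na(e) && s > e)
        stop("GFF3 line ", i, ": start > end")
    }
  }
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  classification <- if ("Classification" %in% names(mc))
    as.character(mc$Classification) else rep(NA_character_, length(gr))
  ks <- gff3_kind(as.character(mc$type), classification)
  id <- if ("ID" %in% names(mc)) as.character(mc$ID) else rep(NA_character_, length(gr))
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    kind = ks$kind,
    subtype = ks$subtype,
    id = id,
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Write features to GFF3
#'
#' Converts internal 0-based half-open features back to 1-based inclusive GFF3.
#'
#' @param features data.frame as returned by [read_gff3()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  type <- ifelse(features$kind == "gene", "gene",
          ifelse(features$kind == "TE", "transposable_element",
          ifelse(features$kind == "rDNA", "rRNA",
                 ifelse(is.na(features$subtype), "region", features$subtype))))
  gr <- GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = ifelse(features$strand %in% c("+", "-"), features$strand, "*")
  )
  S4Vectors::mcols(gr)$type <- type
  S4Vectors::mcols(gr)$ID <- features$id
  if (!all(is.na(features$subtype)) && any(features$kind == "TE")) {
    S4Vectors::mcols(gr)$Classification <-
      ifelse(features$kind == "TE", features$subtype, NA_character_)
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a multi-sample VCF
#'
#' Reads a VCF 4.x with GT and GQ FORMAT fields. Multi-allelic records are
#' preserved (filtering is a later stage); missing genotypes are `NA`.
#'
#' @param path path to a VCF (plain or gzipped).
#' @return an object of class `variant_set`: list with `sites` (data.frame
#'   chrom, pos [0-based], ref, alt [comma-separated], n_alleles), `gt`
#'   (site x sample character matrix, e.g. "0/1"), `gq` (numeric matrix) and
#'   `samples`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fmt <- v@gt[, 1L]
  if (!all(grepl("(^|:)GT(:|$)", fmt))) stop("VCF lacks GT FORMAT field")
  gt <- vcfR::extract.gt(v, element = "GT")
  gq <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = 7L, dimnames = list(NULL, colnames(fix)))
  alt <- as.character(fix[, "ALT"])
  sites <- data.frame(
    chrom = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]) - 1L,
    ref = as.character(fix[, "REF"]),
    alt = alt,
    n_alleles = 1L + ifelse(is.na(alt) | alt == ".", 0L,
                            lengths(strsplit(alt, ",", fixed = TRUE))),
    stringsAsFactors = FALSE
  )
  gt[gt %in% c("./.", ".|.", ".")] <- NA_character_
  structure(
    list(sites = sites, gt = gt, gq = gq, samples = colnames(gt)),
    class = "variant_set"
  )
}

#' @export
print.variant_set <- function(x, ...) {
  cat("variant_set:", nrow(x$sites), "sites x", length(x$samples), "samples\n")
  cat("samples:", paste(x$samples, collapse = ", "), "\n")
  invisible(x)
}

#' Write regions to BED
#'
#' BED is 0-based half-open; records are sorted by (chrom, start). Optional
#' `name` and `score` columns are carried through.
#'
#' @param records data.frame with chrom, start, end and optional name, score.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(records, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score"),
                    colnames(records))
  if (nrow(records) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  if (!all(c("chrom", "start", "end") %in% cols))
    stop("records need chrom, start, end")
  if (any(records$start < 0) || any(records$end < 0))
    stop("negative BED coordinate")
  out <- records[order(records$chrom, records$start), cols, drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file
#'
#' @param path path to a BED3+ file.
#' @return data.frame with chrom, start, end (+ name, score when present).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4L) names(df)[4L] <- "name"
  if (ncol(df) >= 5L) names(df)[5L] <- "score"
  df
}

#' Write a plain TSV with header
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a variant set as plain-text VCF 4.2
#'
#' Emits GT and GQ FORMAT fields for all samples; positions are converted back
#' to 1-based. Used by the simulator and the filtering stage.
#'
#' @param vs a `variant_set`.
#' @param path output path.
#' @param chrom_lengths optional named vector for `##contig` headers.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vs, path, chrom_lengths = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=t2tscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype Quality">'
  )
  if (!is.null(chrom_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(chrom_lengths), as.integer(chrom_lengths)))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", vs$samples), collapse = "\t"))
  n <- nrow(vs$sites)
  lines <- character(n)
  if (n > 0L) {
    gt <- vs$gt
    gt[is.na(gt)] <- "./."
    gq <- vs$gq
    gqs <- ifelse(is.na(gq), ".", format(gq, trim = TRUE, scientific = FALSE))
    sample_fields <- matrix(paste(gt, gqs, sep = ":"), nrow = n)
    lines <- paste(vs$sites$chrom, vs$sites$pos + 1L, ".", vs$sites$ref,
                   vs$sites$alt, ".", "PASS", ".", "GT:GQ",
                   apply(sample_fields, 1L, paste, collapse = "\t"),
                   sep = "\t")
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}
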