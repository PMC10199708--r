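# Low-level sequence and RNG helpers shared across modules.
# Internal coordinate convention: 0-based half-open everywhere; GFF3/VCF are
# converted at the I/O boundary.

DNA_BASES <- c("A", "C", "G", "T")

#' Run code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so seeded
#' simulation helpers do not perturb the session stream.
#' @param seed integer seed, or NULL to use the current stream.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a distinct 31-bit sub-seed from a master seed and a stream label.
derive_seed <- function(seed, stream) {
  s <- sum(utf8ToInt(as.character(stream))) * 7919
  as.integer((as.numeric(seed) * 69069 + s) %% 2147483647)
}

#' Random DNA string
#' @param n length in bp.
#' @return a single uppercase ACGT string.
#' @keywords internal
random_dna <- function(n) {
  if (n <= 0) return("")
  intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4L, n, replace = TRUE)])
}

# Split a string into single characters.
str_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

#' Reverse complement of a DNA string
#' @param s ACGTN string.
#' @return reverse complement string.
#' @keywords internal
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# All rotations of a string.
rotations <- function(s) {
  n <- nchar(s)
  if (n == 0L) return(s)
  d <- paste0(s, s)
  substring(d, seq_len(n), seq_len(n) + n - 1L)
}

# Smallest p dividing nchar(s) such that s is p-periodic.
fundamental_period <- function(s) {
  n <- nchar(s)
  for (p in seq_len(n)) {
    if (n %% p == 0L && s == strrep(substr(s, 1L, p), n %/% p)) return(p)
  }
  n
}

# Encode ACGTN string to integer codes 0..3 (N and anything else -> NA).
encode_dna <- function(s) {
  lut <- rep(NA_integer_, 256L)
  lut[utf8ToInt("A")] <- 0L
  lut[utf8ToInt("C")] <- 1L
  lut[utf8ToInt("G")] <- 2L
  lut[utf8ToInt("T")] <- 3L
  lut[utf8ToInt(s)]
}

# Identity between two equal-length strings; positions with N count mismatched.
string_identity <- function(a, b) {
  x <- utf8ToInt(a)
  y <- utf8ToInt(b)
  stopifnot(length(x) == length(y))
  nn <- utf8ToInt("N")
  mean(x == y & x != nn & y != nn)
}

# Substitute each position independently with probability `rate` (to a
# different base; N untouched). Uses the current RNG stream.
mutate_dna <- function(s, rate) {
  n <- nchar(s)
  if (rate <= 0 || n == 0L) return(s)
  x <- utf8ToInt(s)
  hit <- which(stats::runif(n) < rate)
  if (length(hit)) {
    codes <- c(65L, 67L, 71L, 84L)
    cur <- match(x[hit], codes)
    ok <- !is.na(cur)
    hit <- hit[ok]; cur <- cur[ok]
    if (length(hit)) {
      nb <- (cur - 1L + sample.int(3L, length(hit), replace = TRUE)) %% 4L + 1L
      x[hit] <- codes[nb]
    }
  }
  intToUtf8(x)
}

# Validate a genome object: named character vector of ACGTN sequences.
check_genome <- function(genome) {
  if (is.null(names(genome)) || anyDuplicated(names(genome)))
    stop("genome must be a character vector with unique chromosome names")
  genome
}

# Merge overlapping/adjacent 0-based half-open intervals in a data.frame with
# columns start, end (single chromosome). Returns the merged data.frame.
merge_intervals <- function(df, gap = 0L) {
  if (nrow(df) == 0L) return(df)
  df <- df[order(df$start, df$end), , drop = FALSE]
  out_s <- df$start[1L]
  out_e <- df$end[1L]
  res_s <- c(); res_e <- c()
  for (i in seq_len(nrow(df))[-1L]) {
    if (df$start[i] <= out_e + gap) {
      out_e <- max(out_e, df$end[i])
    } else {
      res_s <- c(res_s, out_s); res_e <- c(res_e, out_e)
      out_s <- df$start[i]; out_e <- df$end[i]
    }
  }
  res_s <- c(res_s, out_s); res_e <- c(res_e, out_e)
  data.frame(start = res_s, end = res_e)
}

# Jaccard index of two 0-based half-open intervals.
interval_jaccard <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2))
  uni <- (e1 - s1) + (e2 - s2) - inter
  if (uni <= 0) return(0)
  inter / uni
}
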