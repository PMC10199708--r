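# Density profiles, centromeric family selection, centromere calls and
# captured-gene extraction.

test_that("density profiles compute per-window covered bp", {
  f <- data.frame(chrom = "c1", start = 0L, end = 50000L)
  p <- density_profile(f, 300000L, window = 100000L)
  expect_equal(nrow(p), 3L)
  expect_equal(p$bp, c(50000, 0, 0))
  # array spanning a window boundary splits, total conserved
  f2 <- data.frame(chrom = "c1", start = 80000L, end = 130000L)
  p2 <- density_profile(f2, 300000L, window = 100000L)
  expect_equal(p2$bp, c(20000, 30000, 0))
  expect_equal(sum(p2$bp), 50000)
  # overlapping features count once per bp
  f3 <- data.frame(chrom = "c1", start = c(0L, 10000L), end = c(30000L, 40000L))
  expect_equal(density_profile(f3, 100000L, 100000L)$bp, 40000)
  # empty input, zero vector
  expect_equal(density_profile(f[0, ], 250000L, 100000L)$bp, c(0, 0, 0))
  expect_equal(nrow(density_profile(f, 250000L, 100000L)), 3L)
  expect_error(density_profile(data.frame(start = 0L, end = 400000L),
                               300000L), "beyond")
})

test_that("window coverage conserves total array bp", {
  set.seed(10)
  arr <- data.frame(chrom = "c1",
                    start = sort(sample.int(900000L, 20)))
  arr$end <- pmin(arr$start + sample.int(40000L, 20), 1000000L)
  arr <- arr[!duplicated(arr$start), ]
  merged <- merge_intervals(arr[, c("start", "end")])
  p <- density_profile(arr, 1000000L, 100000L)
  expect_equal(sum(p$bp), sum(merged$end - merged$start))
})

test_that("centromeric family selection honors local dominance", {
  arrays <- data.frame(
    chrom = c("chr1", "chr2", "chr2", "chr3"),
    start = 0L, end = c(400000L, 100000L, 350000L, 90000L),
    period = c(107L, 107L, 135L, 107L),
    family_id = c("fam1", "fam1", "fam2", "fam1"))
  arrays$end <- as.integer(arrays$end)
  families <- data.frame(family_id = c("fam1", "fam2"),
                         base_period = c(107L, 135L),
                         total_bp = c(590000, 350000))
  grouped <- list(families = families, arrays = arrays)
  sel <- select_centromeric_family(grouped,
                                   chroms = c("chr1", "chr2", "chr3", "chr4"))
  expect_equal(sel$base_period[sel$chrom == "chr1"], 107L)
  # chr2: fam2 has 3.5x fam1 bp locally -> override
  expect_equal(sel$base_period[sel$chrom == "chr2"], 135L)
  expect_equal(sel$base_period[sel$chrom == "chr3"], 107L)
  expect_message(
    sel2 <- select_centromeric_family(grouped, chroms = "chr4"),
    "no repeat family")
  expect_true(is.na(sel2$base_period))
})

test_that("centromere call picks the depleted bp-maximal region", {
  set.seed(11)
  L <- 2000000L
  arrays <- data.frame(chrom = "c1", start = c(900000L, 1060000L, 300000L),
                       end = c(1050000L, 1200000L, 320000L))
  # genes/TEs everywhere except the array region
  pos <- seq(0L, L - 5000L, by = 25000L)
  feats <- data.frame(chrom = "c1", start = pos, end = pos + 4000L)
  feats <- feats[feats$end < 880000L | feats$start > 1220000L, ]
  res <- call_centromere(arrays, feats, feats[0, ], L)
  expect_false(is.null(res$call))
  # gaps <= max_gap are bridged; boundaries snap to outermost arrays
  expect_equal(res$call$start, 900000L)
  expect_equal(res$call$end, 1200000L)
  expect_lt(res$call$gene_te_inside, res$call$gene_te_outside)
  # the distal small array is a separate, losing candidate
  expect_equal(nrow(res$candidates), 2L)
  # no arrays -> no call
  res0 <- call_centromere(arrays[0, ], feats, feats[0, ], L)
  expect_null(res0$call)
})

test_that("sub-threshold candidates and non-depleted regions yield no call", {
  L <- 1000000L
  arrays <- data.frame(chrom = "c1", start = 500000L, end = 530000L)
  feats <- data.frame(chrom = "c1", start = seq(0L, L - 10000L, 50000L))
  feats$end <- feats$start + 5000L
  expect_warning(res <- call_centromere(arrays, feats, feats[0, ], L),
                 "min_array_bp")
  expect_null(res$call)
  # dense features *inside* the candidate only -> depletion test fails
  arrays2 <- data.frame(chrom = "c1", start = 400000L, end = 600000L)
  inside <- data.frame(chrom = "c1",
                       start = seq(400000L, 590000L, 10000L))
  inside$end <- inside$start + 9000L
  expect_warning(res2 <- call_centromere(arrays2, inside, inside[0, ], L),
                 "depletion")
  expect_null(res2$call)
})

test_that("captured genes use the 1-bp overlap rule", {
  calls <- data.frame(chrom = "c1", start = 1000L, end = 2000L)
  genes <- data.frame(chrom = "c1",
                      start = c(1200L, 999L, 2000L, 500L, 1999L),
                      end = c(1300L, 1000L, 2100L, 999L, 2050L),
                      id = paste0("g", 1:5))
  cap <- captured_genes(calls, genes)
  # inside; end-touching (no overlap, half-open); 1-bp boundary overlap
  expect_setequal(cap$id, c("g1", "g5"))
  expect_equal(cap$id, c("g1", "g5"))  # sorted by position
  expect_equal(nrow(captured_genes(calls, genes[0, ])), 0L)
})

test_that("planted centromeres are recovered across seeded genomes", {
  jacs <- c()
  for (seed in 1:10) {
    spec <- simulation_spec(seed = 1000 + seed, n_chroms = 3,
                            chrom_length_range = c(45e4, 6e5),
                            centromere_plan = list(
                              array_length_range = c(4e4, 8e4)),
                            telomere_plan = list(
                              copies_range = c(100L, 400L)))
    sim <- simulate_genome(spec)
    arr <- scan_tandem_arrays(sim$genome)
    gr <- group_harmonics(arr, genome_length = sum(nchar(sim$genome)))
    cens <- suppressWarnings(
      call_centromeres(gr, sim$features, vapply(sim$genome, nchar, 0L),
                       window = 20000L, min_array_bp = 20000L,
                       max_gap = 100000L))
    expect_lte(nrow(cens$calls), 3L)  # at most one call per chromosome
    expect_false(anyDuplicated(cens$calls$chrom) > 0)
    for (i in seq_len(nrow(sim$truth$centromeres))) {
      tr <- sim$truth$centromeres[i, ]
      cl <- cens$calls[cens$calls$chrom == tr$chrom, ]
      jacs <- c(jacs, if (nrow(cl))
        truth_jaccard(cl$start[1], cl$end[1], tr$start, tr$end) else 0)
    }
  }
  expect_equal(length(jacs), 30L)
  expect_gte(mean(jacs >= 0.8), 0.95)
})
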