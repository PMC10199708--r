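# Simulator: planted arrays, determinism, truth consistency, SNP structure.

test_that("planted arrays have the stated length and divergence", {
  set.seed(71)
  mono <- random_dna(107)
  bg <- random_dna(5000)
  r <- plant_tandem_array(bg, mono, 10, 0, 2000)
  expect_equal(r$truth$end - r$truth$start, 1070L)
  expect_identical(substr(r$seq, 2001, 2107), mono)
  # fractional copies round the span
  r2 <- plant_tandem_array(bg, mono, 10.5, 0, 2000)
  expect_equal(r2$truth$end - r2$truth$start, round(10.5 * 107))
  expect_equal(r2$truth$end - r2$truth$start, 1124L)
  # out-of-bounds placement errors
  expect_error(plant_tandem_array(bg, mono, 100, 0, 4000), "bounds")
})

test_that("per-copy mutation rate reproduces the expected identity", {
  set.seed(72)
  mono <- random_dna(107)
  bg <- random_dna(15000)
  r <- plant_tandem_array(bg, mono, 100, 0.05, 2000)
  arr <- substr(r$seq, 2001, 2000 + 100 * 107)
  ident <- vapply(seq_len(100), function(i)
    string_identity(substr(arr, (i - 1) * 107 + 1, i * 107), mono), 0)
  expect_equal(mean(ident), 0.95, tolerance = 0.02)
})

test_that("genomes are deterministic given the seed", {
  spec <- simulation_spec(seed = 5, n_chroms = 2,
                          chrom_length_range = c(4e5, 5e5))
  s1 <- simulate_genome(spec)
  s2 <- simulate_genome(spec)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$features, s2$features)
  expect_identical(s1$domains, s2$domains)
  # and byte-identical on disk
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(s1, d1)
  write_simulation(s2, d2)
  expect_identical(readLines(file.path(d1, "genome.fasta")),
                   readLines(file.path(d2, "genome.fasta")))
  # a different seed changes the genome
  s3 <- simulate_genome(simulation_spec(seed = 6, n_chroms = 2,
                                        chrom_length_range = c(4e5, 5e5)))
  expect_false(identical(s1$genome, s3$genome))
})

test_that("seed is mandatory and plans are validated", {
  expect_error(simulation_spec(), "seed")
  expect_error(simulation_spec(seed = 1, centromere_plan =
                                 list(mutation_rate = 2)))
})

test_that("truth intervals are consistent with the emitted sequence", {
  spec <- simulation_spec(seed = 9, n_chroms = 2,
                          chrom_length_range = c(5e5, 6e5),
                          centromere_plan = list(mutation_rate = 0,
                                                 array_length_range =
                                                   c(5e4, 8e4)))
  sim <- simulate_genome(spec)
  # telomere truth: re-extract and confirm pure unit repeats
  for (i in seq_len(nrow(sim$truth$telomeres))) {
    tr <- sim$truth$telomeres[i, ]
    s <- substr(sim$genome[[tr$chrom]], tr$start + 1, tr$end)
    u <- if (tr$arm == "left") revcomp("TTTAGGG") else "TTTAGGG"
    expect_identical(s, strrep(u, tr$copies))
  }
  # centromere truth at mutation rate 0: re-extract, count exact monomer
  # copies; planted copy number reproduced within +- 1 copy
  for (i in seq_len(nrow(sim$truth$centromeres))) {
    tr <- sim$truth$centromeres[i, ]
    s <- substr(sim$genome[[tr$chrom]], tr$start + 1, tr$end)
    n_exact <- lengths(gregexpr(tr$monomer, s, fixed = TRUE))
    planted <- (tr$end - tr$start) / nchar(tr$monomer)
    expect_lte(abs(n_exact - planted), 1)
  }
  # genes never overlap planted satellite arrays
  genes <- sim$features[sim$features$kind == "gene", ]
  for (i in seq_len(nrow(sim$truth$centromeres))) {
    tr <- sim$truth$centromeres[i, ]
    g <- genes[genes$chrom == tr$chrom, ]
    expect_false(any(g$end > tr$start & g$start < tr$end))
  }
})

test_that("TE features are depleted inside centromeres", {
  spec <- simulation_spec(seed = 14, n_chroms = 4,
                          chrom_length_range = c(9e5, 1.1e6),
                          te_plan = list(density_per_mb = 150))
  sim <- simulate_genome(spec)
  tes <- sim$features[sim$features$kind == "TE", ]
  inside <- 0; in_bp <- 0; outside <- 0; out_bp <- 0
  for (i in seq_len(nrow(sim$truth$centromeres))) {
    tr <- sim$truth$centromeres[i, ]
    t <- tes[tes$chrom == tr$chrom, ]
    L <- nchar(sim$genome[[tr$chrom]])
    n_in <- sum(t$start >= tr$start & t$start < tr$end)
    inside <- inside + n_in
    in_bp <- in_bp + (tr$end - tr$start)
    outside <- outside + (nrow(t) - n_in)
    out_bp <- out_bp + (L - (tr$end - tr$start))
  }
  ratio <- (outside / out_bp) / (inside / in_bp)
  expect_gt(ratio, 2.5)   # 5-fold depletion, binomial noise allowed
})

test_that("SNP sharing fraction and hotspot enrichment follow the plan", {
  lens <- c(c1 = 3e6, c2 = 3e6)
  hs <- data.frame(chrom = "c1", start = 1e6, end = 1.5e6)
  snp <- simulate_snp_samples(lens, seed = 15, background_rate = 1e-3,
                              hotspots = hs, hotspot_multiplier = 10,
                              shared_fraction = 0.853)
  lab <- snp$truth$sharing
  n <- length(lab)
  expect_gt(n, 5000)
  phat <- mean(lab == "all")
  expect_lt(abs(phat - 0.853), 3 * sqrt(0.853 * 0.147 / n) + 0.005)
  # every site in exactly one class
  expect_true(all(lab %in% c("all", "partial")))
  het <- het_matrix(snp$variants)
  nhet <- rowSums(het)
  expect_true(all(nhet[lab == "all"] == 4L))
  expect_true(all(nhet[lab == "partial"] %in% 1:3))
  # hotspot density ~ 10x background
  sites <- snp$variants$sites
  in_hs <- sites$chrom == "c1" & sites$pos >= 1e6 & sites$pos < 1.5e6
  rate_in <- sum(in_hs) / 0.5e6
  rate_out <- sum(!in_hs) / (sum(lens) - 0.5e6)
  expect_equal(rate_in / rate_out, 10, tolerance = 0.15)
})

test_that("zero background with one hotspot confines all sites to it", {
  hs <- data.frame(chrom = "c1", start = 2e5, end = 3e5, rate = 1e-3)
  snp <- simulate_snp_samples(c(c1 = 1e6), seed = 16, background_rate = 0,
                              hotspots = hs)
  sites <- snp$variants$sites
  expect_gt(nrow(sites), 0L)
  expect_true(all(sites$pos >= 2e5 & sites$pos < 3e5))
})

test_that("overlapping hotspot intervals are merged with a warning", {
  hs <- data.frame(chrom = c("c1", "c1"), start = c(1e5, 1.5e5),
                   end = c(2e5, 2.5e5))
  expect_warning(
    snp <- simulate_snp_samples(c(c1 = 1e6), seed = 17,
                                background_rate = 1e-4, hotspots = hs),
    "merged")
  expect_equal(nrow(snp$truth$hotspots), 1L)
  expect_equal(snp$truth$hotspots$end - snp$truth$hotspots$start, 1.5e5)
})

test_that("genotype qualities fail GQ<30 at the configured fraction", {
  snp <- simulate_snp_samples(c(c1 = 5e6), seed = 18,
                              background_rate = 1e-3,
                              gq_fail_fraction = 0.05)
  frac <- mean(snp$variants$gq < 30)
  expect_lt(abs(frac - 0.05), 0.01)
})
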