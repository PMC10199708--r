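test_that("canonical_monomer unifies strands and rotations", {
  expect_identical(canonical_monomer("TTTAGGG"), canonical_monomer("CCCTAAA"))
  expect_identical(canonical_monomer("TTTAGGG"), "AAACCCT")
  expect_identical(canonical_monomer("AAAA"), "AAAA")
  # idempotent
  expect_identical(canonical_monomer(canonical_monomer("GATTACA")),
                   canonical_monomer("GATTACA"))
  expect_error(canonical_monomer("ACGX"), "non-ACGT")
  # agrees with naive enumeration on random units
  set.seed(17)
  for (i in 1:25) {
    u <- paste(sample(c("A", "C", "G", "T"), sample(5:30, 1),
                      replace = TRUE), collapse = "")
    expect_identical(canonical_monomer(u), oracle_canonical(u))
  }
})

test_that("scanner recovers planted exact and fractional arrays", {
  set.seed(42)
  mono <- random_dna(107)
  r1 <- plant_tandem_array(random_dna(10000), mono, 20, 0, 5000)
  a1 <- scan_tandem_arrays(c(chrA = r1$seq))
  expect_equal(nrow(a1), 1L)
  expect_equal(a1$period, 107L)
  expect_equal(a1$copies, 20)
  expect_equal(a1$identity, 1)
  expect_lte(abs(a1$start - 5000), 107)
  expect_lte(abs(a1$end - 7140), 107)
  # fractional trailing copy
  r2 <- plant_tandem_array(random_dna(8000), mono, 10.5, 0, 3000)
  a2 <- scan_tandem_arrays(c(chrB = r2$seq))
  expect_equal(a2$copies, 10.5, tolerance = 0.01)
  # random sequence without arrays is empty (cross-checked by oracle)
  s <- rand_seq(5000, 99)
  expect_equal(nrow(scan_tandem_arrays(c(chrC = s))), 0L)
  expect_equal(nrow(oracle_scan(s)), 0L)
})

test_that("mutated arrays are recovered with matching identity", {
  set.seed(7)
  mono <- random_dna(107)
  r <- plant_tandem_array(random_dna(30000), mono, 100, 0.05, 10000)
  a <- scan_tandem_arrays(c(chr = r$seq))
  expect_equal(nrow(a), 1L)
  expect_equal(a$period, 107L)
  expect_equal(a$copies, 100, tolerance = 0.02)
  expect_equal(a$identity, 0.95, tolerance = 0.02)
  expect_lte(abs(a$start - 10000), 107)
})

test_that("scanner agrees with the exhaustive period-scan oracle", {
  set.seed(5)
  cases <- list(
    list(n = 1800, period = 40, copies = 12, rate = 0),
    list(n = 2000, period = 107, copies = 8, rate = 0.02),
    list(n = 1500, period = 61, copies = 10, rate = 0.03),
    list(n = 1900, period = 250, copies = 5, rate = 0)
  )
  for (cs in cases) {
    mono <- random_dna(cs$period)
    pos <- 300
    r <- plant_tandem_array(random_dna(cs$n), mono, cs$copies, cs$rate, pos)
    got <- scan_tandem_arrays(c(chr = r$seq), min_copies = 3)
    orc <- oracle_scan(r$seq)
    expect_gte(nrow(got), 1L)
    expect_gte(nrow(orc), 1L)
    # scanner period matches an oracle period up to harmonic ambiguity
    hit <- orc[orc$period %% got$period[1] == 0 |
                 got$period[1] %% orc$period == 0, , drop = FALSE]
    expect_gte(nrow(hit), 1L)
    # span agreement within one period against the best oracle interval
    best <- hit[which.max(pmin(hit$end, got$end[1]) -
                            pmax(hit$start, got$start[1])), ]
    expect_lte(abs(got$start[1] - best$start), got$period[1])
    expect_lte(abs(got$end[1] - best$end), got$period[1])
  }
})

test_that("scanning the reverse complement mirrors coordinates and units", {
  set.seed(13)
  mono <- random_dna(80)
  r <- plant_tandem_array(random_dna(6000), mono, 15, 0, 2500)
  fwd <- scan_tandem_arrays(c(chr = r$seq))
  rev <- scan_tandem_arrays(c(
    chr = as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(r$seq)))))
  expect_equal(nrow(fwd), nrow(rev))
  expect_identical(fwd$canonical, rev$canonical)
  n <- nchar(r$seq)
  expect_equal(fwd$start, n - rev$end)
  expect_equal(fwd$end, n - rev$start)
})

test_that("planted arrays at <= 5% divergence are recovered precisely", {
  set.seed(21)
  n_hit <- 0L; n_tot <- 0L
  for (rep in 1:6) {
    mono <- random_dna(sample(40:200, 1))
    copies <- sample(10:40, 1)
    bg <- random_dna(30000)
    pos <- sample(2000:15000, 1)
    r <- plant_tandem_array(bg, mono, copies, 0.05, pos)
    a <- scan_tandem_arrays(c(chr = r$seq))
    n_tot <- n_tot + 1L
    if (nrow(a) == 1L &&
        abs(a$start - r$truth$start) <= a$period &&
        abs(a$end - r$truth$end) <= a$period) n_hit <- n_hit + 1L
  }
  expect_gte(n_hit / n_tot, 0.95)
})

test_that("harmonic grouping unifies integer-multiple units", {
  set.seed(33)
  m <- random_dna(107)
  sA <- plant_tandem_array(random_dna(20000), m, 40, 0.01, 6000)$seq
  dimer <- paste0(m, mutate_dna(m, 0.30))
  sB <- plant_tandem_array(random_dna(20000), dimer, 25, 0.005, 6000)$seq
  arr <- scan_tandem_arrays(c(chrA = sA, chrB = sB))
  expect_setequal(arr$period, c(107L, 214L))
  gr <- group_harmonics(arr, genome_length = 4e4)
  expect_equal(nrow(gr$families), 1L)
  expect_equal(gr$families$base_period, 107L)
  expect_identical(gr$families$member_periods, "107,214")
  # a lone unrelated period founds its own family
  set.seed(34)
  sC <- plant_tandem_array(random_dna(15000), random_dna(187), 12, 0, 4000)$seq
  arr2 <- scan_tandem_arrays(c(chrA = sA, chrC = sC))
  gr2 <- group_harmonics(arr2)
  expect_equal(sort(gr2$families$base_period), c(107L, 187L))
})

test_that("repeat-unit summary ranks by covered bp with correct fractions", {
  expect_equal(nrow(summarize_repeat_units(
    scan_tandem_arrays(c(c1 = rand_seq(2000, 3))), 2000)), 0L)
  arrays <- data.frame(chrom = "c1", start = c(0L, 5000L, 9000L),
                       end = c(1070L, 7500L, 9500L),
                       period = c(107L, 321L, 135L),
                       copies = c(10, 7.8, 3.7),
                       identity = 1,
                       consensus = "X", canonical = "X")
  s <- summarize_repeat_units(arrays, 107000)
  expect_equal(s$period, c(321L, 107L, 135L))  # by total bp descending
  expect_equal(s$genome_fraction[s$period == 107L], 0.01)
  # conservation: family bp never exceeds genome length
  gr <- group_harmonics(arrays, genome_length = 107000)
  expect_lte(sum(gr$families$total_bp), 107000)
})
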