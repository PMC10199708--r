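# Domain-run gene clusters, similarity-hit filtering, R-gene architecture.

toy_genes <- function(domlists, chrom = "chr1") {
  n <- length(domlists)
  g <- data.frame(chrom = chrom, start = seq(0L, by = 1000L, length.out = n),
                  end = seq(500L, by = 1000L, length.out = n),
                  kind = "gene", subtype = NA_character_,
                  id = sprintf("g%02d", seq_len(n) - 1L), strand = "+")
  dm <- data.frame(gene_id = g$id,
                   domains = vapply(domlists, paste, "", collapse = ","))
  gene_records(g, dm)
}

test_that("similarity filtering applies strict thresholds and shared domains", {
  recs <- toy_genes(list("PF00931", "PF00931", "Pkinase", c("PF00931", "LRR")))
  hits <- data.frame(
    query = c("g00", "g00", "g00", "g00"),
    subject = c("g01", "g02", "g03", "g01"),
    pident = c(45, 45, 45, 45),
    evalue = c(1e-6, 1e-6, 1e-6, 1e-4))
  f <- filter_similarity_hits(hits[1:3, ], recs)
  # g00-g02 dropped (no shared domain); symmetric closure adds g01->g00 etc.
  expect_setequal(paste(f$query, f$subject),
                  c("g00 g01", "g01 g00", "g00 g03", "g03 g00"))
  # e-value boundary is strict <
  expect_equal(nrow(filter_similarity_hits(hits[4, ], recs)), 0L)
  # identity boundary is strict >
  h30 <- data.frame(query = "g00", subject = "g01", pident = 30.0,
                    evalue = 1e-6)
  expect_equal(nrow(filter_similarity_hits(h30, recs)), 0L)
  hu <- data.frame(query = "g00", subject = "nope", pident = 50,
                   evalue = 1e-8)
  expect_error(filter_similarity_hits(hu, recs), "unknown gene")
})

test_that("domain runs seed clusters and extension collects carriers", {
  recs <- toy_genes(list("A", "A", "A", "B", "A", "B", "B", "B", "C", "A"))
  cl <- find_domain_clusters(recs)
  expect_equal(nrow(cl), 2L)
  a <- cl[cl$accession == "A", ]
  b <- cl[cl$accession == "B", ]
  expect_identical(a$members, "g00,g01,g02,g04,g09")
  expect_identical(b$members, "g03,g05,g06,g07")
  # run of two does not seed
  expect_equal(nrow(find_domain_clusters(toy_genes(list("A", "A")))), 0L)
})

test_that("distant runs of one accession stay separate clusters", {
  doms <- rep(list("X"), 100)
  doms[4:73] <- list("Z")          # ordinals 3..72 carry only Z
  doms[[1]] <- doms[[2]] <- doms[[3]] <- "A"
  doms[[74]] <- doms[[75]] <- doms[[76]] <- "A"
  recs <- toy_genes(doms)
  cl <- find_domain_clusters(recs)
  a <- cl[cl$accession == "A", ]
  # runs at ordinals 0-2 and 73-75 are 70 apart: windows disjoint
  expect_equal(nrow(a), 2L)
  expect_identical(a$members[1], "g00,g01,g02")
})

test_that("cluster detection matches exhaustive enumeration on small inputs", {
  set.seed(41)
  for (rep in 1:8) {
    n <- sample(20:50, 1)
    domlists <- lapply(seq_len(n), function(i)
      sample(c("A", "B", "C"), sample(1:2, 1)))
    recs <- toy_genes(domlists)
    got <- find_domain_clusters(recs)
    orc <- oracle_clusters(recs$ordinal, lapply(recs$domains, function(d)
      strsplit(d, ",")[[1]]))
    got_sets <- sort(vapply(seq_len(nrow(got)), function(i)
      paste(got$accession[i], got$members[i]), ""))
    orc_sets <- sort(vapply(orc, function(o)
      paste(o$accession,
            paste(recs$gene_id[match(o$members, recs$ordinal)],
                  collapse = ",")), ""))
    expect_identical(got_sets, orc_sets)
  }
})

test_that("hit order and gene file order never change memberships", {
  set.seed(43)
  domlists <- lapply(1:30, function(i) sample(c("A", "B"), 1))
  domlists[10:13] <- list("A")
  recs <- toy_genes(domlists)
  base <- find_domain_clusters(recs)
  perm <- recs[sample.int(nrow(recs)), ]
  again <- find_domain_clusters(perm)
  expect_identical(base$members, again$members)
  expect_identical(base$cluster_id, again$cluster_id)
})

test_that("appending a carrier-free gene leaves memberships unchanged", {
  domlists <- c(rep(list("A"), 4), list("B"), list("A"))
  recs <- toy_genes(domlists)
  before <- find_domain_clusters(recs)
  g2 <- toy_genes(c(domlists, list("ZZZ")))
  after <- find_domain_clusters(g2)
  expect_identical(before$members, after$members)
})

test_that("simulator-planted clusters are recovered exactly", {
  spec <- simulation_spec(seed = 77, n_chroms = 2,
                          chrom_length_range = c(5e5, 6e5),
                          gene_plan = list(count_per_mb = 80))
  sim <- simulate_genome(spec)
  recs <- gene_records(sim$features[sim$features$kind == "gene", ],
                       sim$domains)
  cl <- find_domain_clusters(recs)
  expect_gte(nrow(sim$truth$clusters), 1L)
  for (i in seq_len(nrow(sim$truth$clusters))) {
    tr <- sim$truth$clusters[i, ]
    hit <- cl[cl$accession == tr$accession & cl$chrom == tr$chrom, ]
    expect_equal(nrow(hit), 1L)
    expect_setequal(strsplit(hit$members, ",")[[1]],
                    strsplit(tr$members, ",")[[1]])
  }
})

test_that("R-gene classification follows the configured architecture rule", {
  recs <- toy_genes(list(c("NB-ARC", "LRR"), "LRR", c("LRR", "Pkinase"),
                         "TIR", "C-JID", character(0)))
  rg <- classify_r_genes(recs)
  expect_equal(rg$flags, c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(rg$count, 4L)
  # custom rule
  rg2 <- classify_r_genes(recs, rule = list(any_of = "LRR",
                                            co_occur = list()))
  expect_equal(rg2$count, 3L)
})

test_that("region reports count only clustered genes inside the region", {
  recs <- toy_genes(list("A", "A", "A", "A", "A", "B"))
  cl <- find_domain_clusters(recs)
  # genes at starts 0..5000; region covering first three
  r <- cluster_region_report(cl, recs, "chr1", 0, 2600)
  expect_equal(r$n_genes, 3L)
  expect_equal(unname(r$by_accession["A"]), 3L)
  expect_equal(cluster_region_report(cl, recs, "chr1", 50000, 60000)$n_genes,
               0L)
  full <- cluster_region_report(cl, recs, "chr1", 0, 10000)
  expect_equal(full$n_genes, 5L)
})

test_that("the toy protein scorer ranks duplicates above unrelated pairs", {
  set.seed(51)
  aa <- c("M", "A", "L", "K", "R", "E", "D", "S", "T", "G", "P", "V")
  p1 <- paste(sample(aa, 120, TRUE), collapse = "")
  prot <- c(a = p1, b = p1, c = paste(sample(aa, 120, TRUE), collapse = ""))
  hits <- align_proteins(prot)
  ab <- hits[hits$query == "a" & hits$subject == "b", ]
  ac <- hits[hits$query == "a" & hits$subject == "c", ]
  expect_equal(ab$pident, 100)
  expect_lt(ab$evalue, ac$evalue)
})
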