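test_that("rank_top_genes sorts by abundance with deterministic ties", {
  expr <- data.frame(gene_id = c("g1", "g2", "g3"), medium = "YPD",
                     phase = "logarithmic", abundance = c(5, 9, 1))
  expect_identical(rank_top_genes(expr, "YPD", "logarithmic", 2),
                   c("g2", "g1"))
  expect_identical(rank_top_genes(expr, "YPD", "logarithmic", 3),
                   c("g2", "g1", "g3"))
  expect_identical(rank_top_genes(expr, "YPD", "logarithmic", 99),
                   c("g2", "g1", "g3"))
  ties <- data.frame(gene_id = c("b", "a", "c"), medium = "M", phase = "p",
                     abundance = c(7, 7, 7))
  expect_identical(rank_top_genes(ties, "M", "p", 2), c("a", "b"))
  expect_error(rank_top_genes(expr, "SC", "logarithmic", 2),
               "\\(SC, logarithmic\\)")
})

test_that("ranking a random matrix matches a full-sort oracle", {
  set.seed(42)
  expr <- data.frame(gene_id = sprintf("g%03d", 1:200), medium = "YPD",
                     phase = "stationary",
                     abundance = round(rexp(200, 1 / 100), 3))
  top <- rank_top_genes(expr, "YPD", "stationary", 15)
  ord <- expr$gene_id[order(-expr$abundance, expr$gene_id)]
  expect_identical(top, ord[1:15])
})

test_that("merge_candidates dedups with provenance and stable order", {
  m <- merge_candidates(list(c1 = c("g1", "g2"), c2 = c("g2", "g3")))
  expect_equal(nrow(m), 3L)
  expect_identical(m$gene_id[1], "g2")  # most conditions first
  expect_identical(m$provenance[m$gene_id == "g2"], "c1,c2")
  expect_identical(m$provenance[m$gene_id == "g1"], "c1")
  # 8 identical top-15 lists collapse to 15 with 8 conditions each
  lists <- setNames(rep(list(sprintf("g%02d", 1:15)), 8),
                    paste0("cond", 1:8))
  m8 <- merge_candidates(lists)
  expect_equal(nrow(m8), 15L)
  expect_true(all(m8$n_conditions == 8L))
  # disjoint-support conditions union to K * n candidates
  disj <- list(a = sprintf("x%02d", 1:15), b = sprintf("y%02d", 1:15))
  expect_equal(nrow(merge_candidates(disj)), 30L)
  expect_error(merge_candidates(list(c("g1"))), "named")
})

test_that("extract_upstream handles both strands on a hand-checked contig", {
  genome <- c(c = "AAACCCGGGTTT")
  plus <- extract_upstream(genome,
                           list(contig = "c", strand = "+", cds_start = 10),
                           length = 3)
  expect_identical(plus$sequence, "GGG")
  expect_false(plus$truncated)
  minus <- extract_upstream(genome,
                            list(contig = "c", strand = "-", cds_start = 3),
                            length = 4)
  expect_identical(minus$sequence, "CGGG")  # revcomp of CCCG
  # truncation at the contig edge returns the partial window, flagged
  tr <- extract_upstream(genome,
                         list(contig = "c", strand = "+", cds_start = 4),
                         length = 10)
  expect_identical(tr$sequence, "AAA")
  expect_true(tr$truncated)
  expect_equal(tr$length, 3L)
  expect_error(extract_upstream(genome,
    list(contig = "c", strand = "+", cds_start = 1), length = 5),
    "zero upstream")
  expect_error(extract_upstream(genome,
    list(contig = "c", strand = "-", cds_start = 12), length = 5),
    "zero upstream")
  expect_error(extract_upstream(genome,
    list(contig = "nope", strand = "+", cds_start = 5), length = 2),
    "nope")
})

test_that("extraction equals the naive slice/revcomp oracle on random genes", {
  set.seed(7)
  for (i in 1:100) {
    clen <- sample(200:600, 1)
    contig <- random_seq(clen)
    strand <- sample(c("+", "-"), 1)
    cds <- sample(50:(clen - 50), 1)
    len <- sample(10:120, 1)
    g <- list(contig = "c", strand = strand, cds_start = cds)
    got <- extract_upstream(c(c = contig), g, len)
    expect_identical(got$sequence, oracle_upstream(contig, strand, cds, len))
    expect_lte(got$length, len)
    expect_equal(got$length == len, !got$truncated)
  }
})

test_that("extraction is invariant under reverse-complementing the genome", {
  set.seed(8)
  clen <- 400
  contig <- random_seq(clen)
  rc <- oracle_upstream(paste0("A", contig), "-", 1, clen)  # full revcomp
  for (i in 1:25) {
    strand <- sample(c("+", "-"), 1)
    cds <- sample(100:300, 1)
    g <- list(contig = "c", strand = strand, cds_start = cds)
    # mirrored coordinates on the reverse-complemented contig
    g2 <- list(contig = "c", strand = if (strand == "+") "-" else "+",
               cds_start = clen - cds + 1)
    a <- extract_upstream(c(c = contig), g, 60)
    b <- extract_upstream(c(c = rc), g2, 60)
    expect_identical(a$sequence, b$sequence)
  }
})

test_that("extract_promoters warns when a window overlaps a neighbour", {
  genome <- c(c = random_seq(3000))
  genes <- data.frame(
    gene_id = c("g1", "g2"), contig = "c", strand = "+",
    start = c(1000, 1500), end = c(1200, 1800),
    cds_start = c(1000, 1500), stringsAsFactors = FALSE)
  expect_warning(extract_promoters(genome, genes, length = 400),
                 "overlap")
  expect_silent(res <- extract_promoters(genome, genes, length = 200))
  expect_identical(res$promoter_id, c("P_g1", "P_g2"))
  expect_true(all(res$length == 200))
})

test_that("screening ledger derives the cascade counts and refuses nonsense", {
  led <- screening_ledger(52, 3, 11, 7, 3)
  expect_equal(led$n_assayed, 49L)
  expect_equal(led$n_strong, 31L)
  expect_equal(led$n_strong_incl_controls, 34L)
  led0 <- screening_ledger(10)
  expect_equal(led0$n_strong, 10L)
  expect_error(screening_ledger(5, 6), "clone failures exceed")
  expect_error(screening_ledger(10, 2, 5, 4), "exceed assayed")
  expect_error(screening_ledger(-1), "non-negative")
})
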