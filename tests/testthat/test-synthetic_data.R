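test_that("generation is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 11, n_genes = 60)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    w <- generate_genome(cfg)
    write_genome_fasta(w$genome, file.path(d, "genome.fasta"))
    write_annotation_gff3(w$genes, w$genome, file.path(d, "genes.gff3"))
  }
  expect_identical(readLines(file.path(d1, "genome.fasta")),
                   readLines(file.path(d2, "genome.fasta")))
  expect_identical(readLines(file.path(d1, "genes.gff3")),
                   readLines(file.path(d2, "genes.gff3")))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(n_clone_fail = 30, n_null = 20, n_weak = 10),
               "n_candidates_target")
  expect_error(sim_config(strength_fold_range = c(0, 19)), "lower bound")
  expect_error(sim_config(fluor_cv = 1.2), "fluor_cv")
  expect_error(sim_config(n_candidates_target = 5, top_n = 15,
                          n_clone_fail = 0, n_null = 0, n_weak = 0),
               "top_n")
  expect_error(sim_config(n_genes = 30), "n_genes too small")
})

test_that("an over-tight contig budget raises a sizing error", {
  expect_error(generate_genome(sim_config(seed = 3, contig_length = 5000L)),
               "infeasible packing")
})

test_that("world structure matches its screening-class targets", {
  w <- cached_world()
  cfg <- w$config
  tab <- table(w$promoters$class)
  expect_equal(unname(tab[["clone_fail"]]), cfg$n_clone_fail)
  expect_equal(unname(tab[["null"]]), cfg$n_null)
  expect_equal(unname(tab[["weak"]]), cfg$n_weak)
  expect_equal(unname(tab[["strong"]]),
               cfg$n_candidates_target - cfg$n_clone_fail - cfg$n_null -
                 cfg$n_weak)
  expect_equal(unname(tab[["reference"]]), 1L)
  # reference strength is 1 in every condition; genes fit their contigs
  expect_true(all(w$true_strength["P_GPD1", ] == 1))
  clen <- setNames(nchar(w$genome), names(w$genome))
  expect_true(all(w$genes$start >= 1 &
                    w$genes$end <= clen[w$genes$contig]))
  # same-contig neighbours keep at least the intergenic clearance
  for (ctg in unique(w$genes$contig)) {
    g <- w$genes[w$genes$contig == ctg, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1)
      expect_true(all(g$start[-1] - g$end[-nrow(g)] > cfg$intergenic_min))
  }
  # strong-class strengths span exactly the configured fold range
  st <- w$true_strength[w$promoters$promoter_id[
    w$promoters$class == "strong"], ]
  expect_equal(range(st), cfg$strength_fold_range)
})

test_that("minus-strand upstream windows equal the revcomp genomic slice", {
  w <- cached_world()
  cand <- w$genes[w$genes$gene_id %in% w$candidates & w$genes$strand == "-", ]
  expect_gt(nrow(cand), 0)
  for (i in seq_len(nrow(cand))) {
    g <- cand[i, ]
    got <- extract_upstream(w$genome, g, w$config$promoter_length)
    expect_identical(got$sequence,
                     oracle_upstream(w$genome[[g$contig]], g$strand,
                                     g$cds_start, w$config$promoter_length))
    expect_false(got$truncated)
  }
})

test_that("planted elements are recovered by the scans", {
  w <- cached_world()
  proms <- extract_promoters(
    w$genome, w$genes[w$genes$gene_id %in% w$candidates, ],
    w$config$promoter_length)
  seqs <- setNames(proms$sequence, proms$promoter_id)
  for (id in names(w$planted)) {
    el <- w$planted[[id]]
    if (!id %in% names(seqs)) next  # reference/control promoters not mined
    if ("GC_BOX" %in% el$element) {
      off <- el$offset[el$element == "GC_BOX"]
      expect_true(off %in% find_motif(seqs[[id]], "GGGCGGG"))
    }
    if ("CAAT" %in% el$element) {
      off <- el$offset[el$element == "CAAT"]
      expect_true(off %in% find_motif(seqs[[id]], "CAAT"))
    }
  }
})

test_that("expression boosts plant exactly the candidate set as top-N union", {
  w <- cached_world()
  expr <- generate_expression(w)
  mined <- mine_candidates(expr, w$config$top_n)
  expect_equal(nrow(mined), 52L)
  expect_setequal(mined$gene_id, w$candidates)
  expect_true(all(expr$abundance >= 0))
})

test_that("degenerate top-N returns all genes; zero boost matches raw sort", {
  w <- cached_world()
  cfg0 <- w$config
  cfg0$expr_boost <- 0
  expr <- generate_expression(w, cfg0)
  m <- cfg0$media[1]; ph <- cfg0$phases[1]
  one <- expr[expr$medium == m & expr$phase == ph, ]
  expect_setequal(rank_top_genes(expr, m, ph, n = nrow(one)), one$gene_id)
  # brute-force sort oracle on the raw draws
  ord <- one$gene_id[order(-one$abundance, one$gene_id)]
  expect_identical(rank_top_genes(expr, m, ph, 15), ord[1:15])
})

test_that("noiseless plate follows the forward model exactly", {
  w0 <- cached_world(noiseless = TRUE)
  plate <- cached_plate(noiseless = TRUE)
  cfg <- w0$config
  nulls <- w0$promoters$promoter_id[w0$promoters$class == "null"]
  blank_rows <- plate$promoter_id == "blank"
  expect_true(all(plate$fluorescence[plate$promoter_id %in% nulls] ==
                    cfg$blank_fluor))
  expect_true(all(plate$fluorescence[blank_rows] == cfg$blank_fluor))
  # clone-fail promoters were never assayed
  cf <- w0$promoters$promoter_id[w0$promoters$class == "clone_fail"]
  expect_false(any(plate$promoter_id %in% cf))
  # estimator inverts the model: folds recovered exactly
  prof <- quantify_strengths(plate)
  key <- paste(prof$folds$medium, prof$folds$phase, sep = ".")
  truth <- w0$true_strength[cbind(prof$folds$promoter_id, key)]
  expect_equal(prof$folds$fold, unname(truth), tolerance = 1e-12)
})

test_that("a missing true strength is reported by promoter name", {
  w <- cached_world()
  w$true_strength["P_FAS1", 1] <- NA
  expect_error(generate_plate_reader(w, w$config), "P_FAS1")
})

test_that("noise-free titers are deterministic and won by the strongest pair", {
  w0 <- cached_world(noiseless = TRUE)
  pool <- c(w0$roles$extreme, w0$roles$mid, "P_GPD1")
  designs <- enumerate_designs(pool)
  names(designs) <- c("design_id", "promoter_fad9", "promoter_fad12")
  t1 <- generate_titers(w0, designs)
  t2 <- generate_titers(w0, designs)
  expect_identical(t1, t2)
  # identical promoter pairs get identical titers
  dup <- designs[c(1, 1), ]; dup$design_id <- c("A", "B")
  td <- generate_titers(w0, dup)
  expect_equal(td$c18_2_mg_per_l[td$strain_id == "A"],
               td$c18_2_mg_per_l[td$strain_id == "B"])
  # exhaustive oracle: the measured argmax equals the model-score argmax
  # over all 16 ordered pairs (with min-saturation this is the pair of
  # highest effective strengths, here the strongest promoter used twice)
  sat <- function(f) f / (f + w0$config$titer_K)
  for (m in w0$config$media) {
    sub <- t1[t1$medium == m, ]
    key <- paste(m, w0$config$phases[1], sep = ".")
    score <- pmin(sat(w0$true_strength[sub$promoter_fad9, key]),
                  sat(w0$true_strength[sub$promoter_fad12, key]))
    expect_setequal(sub$strain_id[sub$c18_2_mg_per_l ==
                                    max(sub$c18_2_mg_per_l)],
                    sub$strain_id[score == max(score)])
  }
  expect_error(generate_titers(w0, data.frame(
    design_id = "X", promoter_fad9 = "P_NOPE", promoter_fad12 = "P_GPD1")),
    "P_NOPE")
})

test_that("noiseless titers are monotone in either promoter's strength", {
  w0 <- cached_world(noiseless = TRUE)
  key <- paste(w0$config$media[1], w0$config$phases[1], sep = ".")
  base_f <- w0$true_strength[w0$roles$mid, key]
  mk <- function(f9, f12) {
    w <- w0
    w$true_strength <- rbind(w$true_strength,
                             P_A = rep(f9, ncol(w$true_strength)),
                             P_B = rep(f12, ncol(w$true_strength)))
    w$promoters <- rbind(w$promoters, data.frame(
      promoter_id = c("P_A", "P_B"), gene_id = c("a", "b"),
      class = "strong"))
    d <- data.frame(design_id = "D", promoter_fad9 = "P_A",
                    promoter_fad12 = "P_B")
    t <- generate_titers(w, d)
    t$c18_2_mg_per_l[t$medium == w0$config$media[1]]
  }
  grid <- c(0.1, 0.5, 1, 2, 8)
  for (f12 in c(0.5, 4)) {
    titers <- vapply(grid, mk, numeric(1), f12 = f12)
    expect_true(all(diff(titers) >= 0))
  }
})

test_that("sugar series: xylose starts higher, glucose runs out first", {
  s <- generate_sugar_series()
  expect_gt(s$xylose_g_l[1], s$glucose_g_l[1])
  ex <- function(col) min(s$time_h[s[[col]] < 0.05 * s[[col]][1]])
  expect_lt(ex("glucose_g_l"), ex("xylose_g_l"))
  expect_true(all(diff(s$time_h) > 0))
  expect_true(all(as.matrix(s[, -1]) >= 0))
})
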