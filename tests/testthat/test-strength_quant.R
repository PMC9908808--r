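test_that("normalize_signal does blank subtraction then per-OD ratio", {
  w <- data.frame(od600 = 0.6, fluorescence = 1100)
  b <- data.frame(od600 = 0.1, fluorescence = 100)
  ns <- normalize_signal(w, b)
  expect_equal(ns$mean, 2000)  # 1000 / 0.5
  expect_equal(ns$sd, 0)
  expect_equal(ns$n, 1L)
  # wells at blank fluorescence normalize to zero (after clipping)
  w2 <- data.frame(od600 = c(0.5, 0.6), fluorescence = c(100, 99))
  expect_warning(ns2 <- normalize_signal(w2, b), "clipped")
  expect_equal(ns2$mean, 0)
  expect_error(normalize_signal(data.frame(od600 = 0.05, fluorescence = 500),
                                b), "no growth")
  expect_error(normalize_signal(w, b[0, ]), "blank")
})

test_that("folds are ratios to the reference within each condition", {
  sig <- data.frame(
    promoter_id = rep(c("P_X", "P_GPD1"), each = 2),
    medium = "YPD", phase = rep(c("logarithmic", "stationary"), 2),
    signal_mean = c(4000, 500, 2000, 1000),
    signal_sd = 0, n = 3, raw_f_mean = 1, blank_f_mean = 0, blank_f_sd = 0,
    detected = TRUE, stringsAsFactors = FALSE)
  f <- relative_strength(sig)
  expect_equal(f$fold[f$promoter_id == "P_X"], c(2.0, 0.5))
  expect_true(all(f$fold[f$promoter_id == "P_GPD1"] == 1))
  expect_error(relative_strength(sig, "P_NOPE"), "P_NOPE")
  sig0 <- sig; sig0$signal_mean[3] <- 0
  expect_error(relative_strength(sig0), "YPD.logarithmic")
})

test_that("folds are invariant under scaling all raw fluorescence", {
  plate <- cached_plate()
  prof1 <- suppressWarnings(quantify_strengths(plate))
  plate_k <- plate
  plate_k$fluorescence <- plate_k$fluorescence * 3.7
  prof2 <- suppressWarnings(quantify_strengths(plate_k))
  expect_equal(prof2$folds$fold, prof1$folds$fold, tolerance = 1e-12)
})

test_that("classification maps folds to classes with modal overall call", {
  mk <- function(folds, detected = TRUE) data.frame(
    promoter_id = "P", medium = rep(c("A", "B", "C", "D"), 2),
    phase = rep(c("logarithmic", "stationary"), each = 4),
    fold = folds, detected = detected, stringsAsFactors = FALSE)
  cl <- classify_strength(mk(rep(1, 8)))
  expect_equal(cl$overall$overall_class, "medium")  # the reference's class
  cl2 <- classify_strength(mk(rep(10, 8)))
  expect_equal(cl2$overall$overall_class, "extreme")
  expect_true(cl2$overall$extreme_in_all_media)
  cl3 <- classify_strength(mk(rep(0.001, 8), detected = FALSE))
  expect_equal(cl3$overall$overall_class, "none")
  # ties resolve toward the lower class
  cl4 <- classify_strength(mk(c(0.05, 0.05, 0.05, 0.05, 3, 3, 3, 3)))
  expect_equal(cl4$overall$overall_class, "very_weak")
})

test_that("responsiveness flags phase ratios and medium variability", {
  d <- data.frame(
    promoter_id = "P", medium = rep(c("YPD", "YPX"), each = 2),
    phase = rep(c("logarithmic", "stationary"), 2),
    fold = c(1, 9, 2, 2), detected = TRUE, stringsAsFactors = FALSE)
  r <- responsiveness(d)
  expect_equal(r$phase_ratios$phase_ratio[r$phase_ratios$medium == "YPD"], 9)
  expect_true(r$flags$phase_responsive)
  flat <- d; flat$fold <- 2
  r2 <- responsiveness(flat)
  expect_true(all(r2$medium_cv$cv == 0))
  expect_false(r2$flags$phase_responsive)
  expect_false(r2$flags$medium_variable)
  z <- d; z$fold[1] <- 0
  expect_true(is.infinite(
    responsiveness(z)$phase_ratios$phase_ratio[1]))
  expect_error(responsiveness(d[d$phase == "logarithmic", ]),
               "stationary")
})

test_that("strength_matrix orders rows by median fold and round-trips TSV", {
  d <- expand.grid(promoter_id = c("P_lo", "P_hi", "P_GPD1"),
                   medium = c("YPD", "YPX", "SC", "MM"),
                   phase = c("logarithmic", "stationary"),
                   stringsAsFactors = FALSE)
  d$fold <- ifelse(d$promoter_id == "P_hi", 6,
                   ifelse(d$promoter_id == "P_lo", 0.3, 1))
  d$detected <- TRUE
  mat <- strength_matrix(d)
  expect_equal(dim(mat), c(3L, 8L))
  expect_identical(rownames(mat), c("P_hi", "P_GPD1", "P_lo"))
  expect_true(all(mat["P_GPD1", ] == 1))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  wide <- data.frame(promoter_id = rownames(mat), mat, check.names = FALSE)
  write_stage_tsv(wide, tmp, seed = 1, hash = "x")
  back <- promotermine:::read_strength_matrix_tsv(tmp)
  expect_equal(back, mat)
})

test_that("estimated folds recover the planted strengths within noise", {
  # single default-seed simulation at CV 5%, triplicates: every strong
  # promoter's estimate within +/-15% of its planted fold
  w <- cached_world()
  prof <- suppressWarnings(quantify_strengths(cached_plate()))
  strong <- w$promoters$promoter_id[w$promoters$class == "strong"]
  f <- prof$folds[prof$folds$promoter_id %in% strong, ]
  truth <- w$true_strength[cbind(f$promoter_id,
                                 paste(f$medium, f$phase, sep = "."))]
  rel_err <- abs(f$fold - truth) / truth
  expect_lt(max(rel_err), 0.15)
  expect_lt(mean(rel_err), 0.10)
})
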