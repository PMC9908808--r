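#' Pipeline configuration
#'
#' One object holding the simulation block plus every module parameter the
#' staged pipeline needs. The defaults are the study conditions; all
#' parameters are documented on their module functions.
#'
#' @param sim a [sim_config()] used by the simulate stage.
#' @param top_n,promoter_length mining parameters.
#' @param reporter_head,caat_pattern,gc_pattern,ct_min_fraction,ct_win_len,junction_depth
#'   motif-scan parameters.
#' @param reference,thresholds strength-quantification parameters.
#' @param K,horizon_h,sugar_threshold pathway parameters.
#' @param with_titers generate/analyse titers (set `FALSE` to exercise the
#'   skip path).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            top_n = sim$top_n,
                            promoter_length = sim$promoter_length,
                            reporter_head = egfp_head(),
                            caat_pattern = "CAAT", gc_pattern = "GGGCGGG",
                            ct_min_fraction = 0.6, ct_win_len = 20L,
                            junction_depth = 25L,
                            reference = "P_GPD1",
                            thresholds = c(0.1, 0.5, 2, 5),
                            K = 1, horizon_h = 30, sugar_threshold = 0.8,
                            with_titers = TRUE) {
  validate_sim_config(sim)
  cfg <- list(sim = sim, top_n = as.integer(top_n),
              promoter_length = as.integer(promoter_length),
              reporter_head = reporter_head, caat_pattern = caat_pattern,
              gc_pattern = gc_pattern, ct_min_fraction = ct_min_fraction,
              ct_win_len = as.integer(ct_win_len),
              junction_depth = as.integer(junction_depth),
              reference = reference, thresholds = thresholds, K = K,
              horizon_h = horizon_h, sugar_threshold = sugar_threshold,
              with_titers = isTRUE(with_titers))
  class(cfg) <- "pipeline_config"
  cfg
}

pipe_paths <- function(dir) {
  files <- c(genome = "genome.fasta", gff = "genes.gff3",
             expression = "expression.tsv", plate = "plate.tsv",
             titers = "titers.tsv", sugars = "sugars.tsv",
             truth = "truth.tsv", candidates = "candidates.tsv",
             promoters = "promoters.fasta", motifs = "motifs.tsv",
             strengths = "strengths.tsv", matrix = "strength_matrix.tsv",
             classes = "classes.tsv", designs = "designs.tsv",
             improvement = "improvement.tsv",
             sugar_summary = "sugar_summary.tsv", report = "report.tsv")
  setNames(file.path(dir, files), names(files))
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Simulate stage: write every synthetic input to disk
#'
#' @param config a [pipeline_config()].
#' @param dir output directory (created if needed).
#' @return the `synthetic_world`, invisibly.
#' @export
stage_simulate <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- pipe_paths(dir)
  seed <- config$sim$seed
  h <- config_hash(unclass(config))
  world <- generate_genome(config$sim)
  write_genome_fasta(world$genome, p[["genome"]])
  write_annotation_gff3(world$genes, world$genome, p[["gff"]])
  write_stage_tsv(generate_expression(world), p[["expression"]], seed, h)
  write_stage_tsv(generate_plate_reader(world), p[["plate"]], seed, h)
  if (config$with_titers && length(world$roles))
    write_stage_tsv(generate_titers(world), p[["titers"]], seed, h)
  write_stage_tsv(generate_sugar_series(config$sim), p[["sugars"]], seed, h)

  st <- world$true_strength
  truth <- data.frame(
    promoter_id = rep(rownames(st), times = ncol(st)),
    condition = rep(colnames(st), each = nrow(st)),
    true_fold = as.vector(st), stringsAsFactors = FALSE)
  truth <- merge(world$promoters, truth, by = "promoter_id", sort = TRUE)
  truth$planted_elements <- vapply(truth$promoter_id, function(id) {
    el <- world$planted[[id]]
    if (is.null(el)) "" else paste(el$element, collapse = ",")
  }, character(1))
  truth <- truth[order(truth$promoter_id, truth$condition), ]
  write_stage_tsv(truth, p[["truth"]], seed, h)
  invisible(world)
}

#' Mine stage: rank, merge, and extract candidate promoters
#'
#' Reads `expression.tsv`, `genome.fasta`, and `genes.gff3` from `dir`;
#' writes `candidates.tsv` and `promoters.fasta`.
#'
#' @inheritParams stage_simulate
#' @return the candidates data frame, invisibly.
#' @export
stage_mine <- function(config, dir) {
  p <- pipe_paths(dir)
  with_stage("mine", {
    expr <- read_stage_tsv(p[["expression"]])
    genome <- read_genome_fasta(p[["genome"]])
    genes <- read_annotation_gff3(p[["gff"]])
    cands <- mine_candidates(expr, config$top_n)
    cand_genes <- genes[match(cands$gene_id, genes$gene_id), , drop = FALSE]
    proms <- extract_promoters(genome, cand_genes, config$promoter_length)
    out <- cbind(proms[, c("promoter_id", "gene_id", "length", "truncated")],
                 cands[, c("n_conditions", "provenance")])
    write_stage_tsv(out, p[["candidates"]], config$sim$seed,
                    config_hash(unclass(config)))
    write_promoters_fasta(proms, p[["promoters"]])
    invisible(out)
  })
}

#' Motif stage: element and splice-risk scan of mined promoters
#'
#' Reads `promoters.fasta`; writes `motifs.tsv`.
#'
#' @inheritParams stage_simulate
#' @return the motif report, invisibly.
#' @export
stage_motifs <- function(config, dir) {
  p <- pipe_paths(dir)
  with_stage("motifs", {
    seqs <- read_genome_fasta(p[["promoters"]])
    proms <- data.frame(promoter_id = names(seqs), sequence = unname(seqs),
                        stringsAsFactors = FALSE)
    rep_ <- scan_promoters(proms, config$reporter_head, config$caat_pattern,
                           config$gc_pattern, config$ct_min_fraction,
                           config$ct_win_len, config$junction_depth)
    write_stage_tsv(rep_, p[["motifs"]], config$sim$seed,
                    config_hash(unclass(config)))
    invisible(rep_)
  })
}

#' Strength stage: plate wells to folds, classes, and the fold matrix
#'
#' Reads `plate.tsv`; writes `strengths.tsv` (long), `strength_matrix.tsv`
#' (wide), and `classes.tsv`.
#'
#' @inheritParams stage_simulate
#' @return the `strength_profiles` object, invisibly.
#' @export
stage_strength <- function(config, dir) {
  p <- pipe_paths(dir)
  with_stage("strength", {
    plate <- read_stage_tsv(p[["plate"]])
    prof <- suppressWarnings(
      quantify_strengths(plate, config$reference, config$thresholds,
                         config$sim$phases))
    seed <- config$sim$seed; h <- config_hash(unclass(config))
    write_stage_tsv(prof$folds, p[["strengths"]], seed, h)
    wide <- data.frame(promoter_id = rownames(prof$matrix), prof$matrix,
                       check.names = FALSE, stringsAsFactors = FALSE)
    write_stage_tsv(wide, p[["matrix"]], seed, h)
    classes <- prof$classes
    if (!is.null(prof$responsiveness))
      classes <- merge(classes, prof$responsiveness$flags,
                       by = "promoter_id", sort = TRUE)
    write_stage_tsv(classes, p[["classes"]], seed, h)
    invisible(prof)
  })
}

read_strength_matrix_tsv <- function(path) {
  wide <- read.delim(path, comment.char = "#", check.names = FALSE,
                     stringsAsFactors = FALSE)
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$promoter_id
  mat
}

#' Pathway stage: design scoring, titer ranking, and sugar utilization
#'
#' Reads `strength_matrix.tsv`, `titers.tsv`, and `sugars.tsv`; writes
#' `designs.tsv`, `improvement.tsv`, and `sugar_summary.tsv`. If no titer
#' table is present the stage is skipped with a notice and earlier outputs
#' stay intact.
#'
#' @inheritParams stage_simulate
#' @return list with `designs`, `improvement`, `sugars`, invisibly (or
#'   `NULL` when skipped).
#' @export
stage_pathway <- function(config, dir) {
  p <- pipe_paths(dir)
  if (!file.exists(p[["titers"]])) {
    message("[stage pathway] no titer table found; stage skipped")
    return(invisible(NULL))
  }
  with_stage("pathway", {
    seed <- config$sim$seed; h <- config_hash(unclass(config))
    mat <- read_strength_matrix_tsv(p[["matrix"]])
    titers <- read_stage_tsv(p[["titers"]])
    designs <- unique(titers[, c("strain_id", "promoter_fad9",
                                 "promoter_fad12")])
    rows <- list(); imp <- list()
    for (m in unique(titers$medium)) {
      d <- designs
      names(d) <- c("design_id", "promoter_fad9", "promoter_fad12")
      d <- score_designs(d, mat, m, phase = config$sim$phases[1],
                         K = config$K)
      sub <- titers[titers$medium == m, , drop = FALSE]
      d <- merge(d, sub[, c("strain_id", "c18_2_mg_per_l",
                            "total_fa_mg_per_l")],
                 by.x = "design_id", by.y = "strain_id", sort = TRUE)
      d$medium <- m
      d$titer_rank <- rank(-d$c18_2_mg_per_l, ties.method = "min")
      rows[[m]] <- d
      best <- best_design(sub, m)
      ref_pair <- sub[sub$promoter_fad9 == config$reference &
                        sub$promoter_fad12 == config$reference, ,
                      drop = FALSE]
      imp[[m]] <- data.frame(
        medium = m, best_strain = best$strain_id[1],
        best_c18_2_mg_per_l = best$c18_2_mg_per_l[1],
        reference_pair_strain = if (nrow(ref_pair)) ref_pair$strain_id[1]
          else NA_character_,
        reference_pair_c18_2 = if (nrow(ref_pair))
          ref_pair$c18_2_mg_per_l[1] else NA_real_,
        improvement_vs_reference_pct = if (nrow(ref_pair))
          percent_improvement(best$c18_2_mg_per_l[1],
                              ref_pair$c18_2_mg_per_l[1]) else NA_real_,
        stringsAsFactors = FALSE)
    }
    designs_out <- do.call(rbind, rows)
    rownames(designs_out) <- NULL
    improvement <- do.call(rbind, imp)
    rownames(improvement) <- NULL
    write_stage_tsv(designs_out, p[["designs"]], seed, h)
    write_stage_tsv(improvement, p[["improvement"]], seed, h)
    sugars_out <- NULL
    if (file.exists(p[["sugars"]])) {
      series <- read_stage_tsv(p[["sugars"]])
      ss <- sugar_summary(series, config$horizon_h, config$sugar_threshold)
      sugars_out <- rbind(
        ss$per_sugar,
        data.frame(sugar = "total", initial_g_l = sum(ss$per_sugar$initial_g_l),
                   at_horizon_g_l = sum(ss$per_sugar$at_horizon_g_l),
                   consumed_fraction = ss$total_consumed_fraction,
                   exhaustion_time_h = NA_real_, stringsAsFactors = FALSE))
      write_stage_tsv(sugars_out, p[["sugar_summary"]], seed, h)
    }
    invisible(list(designs = designs_out, improvement = improvement,
                   sugars = sugars_out))
  })
}

#' Report stage: consolidated pipeline summary
#'
#' Rebuilds the screening ledger from the on-disk intermediates (assayed =
#' candidate promoters present on the plate; clone failures are the
#' remainder; class counts from `classes.tsv`), summarises the strength
#' extremes, extreme-in-all-media promoters, best designs, improvement
#' percentages, and sugar utilization, and writes `report.tsv` as
#' key/value rows.
#'
#' @inheritParams stage_simulate
#' @return named list of report values, invisibly.
#' @export
stage_report <- function(config, dir) {
  p <- pipe_paths(dir)
  with_stage("report", {
    cands <- read_stage_tsv(p[["candidates"]])
    plate <- read_stage_tsv(p[["plate"]])
    classes <- read_stage_tsv(p[["classes"]])
    folds <- read_stage_tsv(p[["strengths"]])
    plated <- setdiff(unique(plate$promoter_id), "blank")
    assayed_cand <- intersect(cands$promoter_id, plated)
    controls <- setdiff(plated, cands$promoter_id)
    cand_cls <- classes[classes$promoter_id %in% assayed_cand, , drop = FALSE]
    n_null <- sum(cand_cls$overall_class == "none")
    n_weak <- sum(cand_cls$overall_class == "very_weak")
    ledger <- screening_ledger(
      n_candidates = nrow(cands),
      n_clone_fail = nrow(cands) - length(assayed_cand),
      n_null = n_null, n_weak = n_weak, n_controls = length(controls))

    strong_ids <- cand_cls$promoter_id[
      !cand_cls$overall_class %in% c("none", "very_weak")]
    sf <- folds[folds$promoter_id %in% strong_ids & folds$detected, ,
                drop = FALSE]
    i_min <- which.min(sf$fold); i_max <- which.max(sf$fold)
    extreme <- classes$promoter_id[classes$extreme_in_all_media &
                                     classes$promoter_id %in% strong_ids]

    kv <- list(
      n_candidates = ledger$n_candidates,
      n_clone_fail = ledger$n_clone_fail,
      n_assayed = ledger$n_assayed,
      n_null = ledger$n_null,
      n_weak = ledger$n_weak,
      n_strong = ledger$n_strong,
      n_controls = ledger$n_controls,
      n_strong_incl_controls = ledger$n_strong_incl_controls,
      fold_min = sf$fold[i_min],
      fold_min_at = sprintf("%s@%s", sf$promoter_id[i_min],
                            cond_key(sf$medium[i_min], sf$phase[i_min])),
      fold_max = sf$fold[i_max],
      fold_max_at = sprintf("%s@%s", sf$promoter_id[i_max],
                            cond_key(sf$medium[i_max], sf$phase[i_max])),
      extreme_in_all_media = paste(sort(extreme), collapse = ","))

    if (file.exists(p[["improvement"]])) {
      imp <- read_stage_tsv(p[["improvement"]])
      for (k in seq_len(nrow(imp))) {
        kv[[paste0("best_design_", imp$medium[k])]] <- imp$best_strain[k]
        kv[[paste0("improvement_pct_", imp$medium[k])]] <-
          imp$improvement_vs_reference_pct[k]
      }
    }
    if (file.exists(p[["sugar_summary"]])) {
      ss <- read_stage_tsv(p[["sugar_summary"]])
      kv$sugar_total_consumed_fraction <-
        ss$consumed_fraction[ss$sugar == "total"]
      kv$first_exhausted_sugar <-
        ss$sugar[ss$sugar != "total"][
          which.min(ss$exhaustion_time_h[ss$sugar != "total"])]
    }
    report <- data.frame(key = names(kv),
                         value = vapply(kv, function(v)
                           paste(format(v, trim = TRUE), collapse = ","),
                           character(1)),
                         stringsAsFactors = FALSE)
    write_stage_tsv(report, p[["report"]], config$sim$seed,
                    config_hash(unclass(config)))
    invisible(kv)
  })
}

#' Run the full pipeline
#'
#' Executes simulate -> mine -> motifs -> strength -> pathway -> report in
#' dependency order; every stage writes its outputs before the next starts,
#' so any single stage can be re-run from the on-disk intermediates with
#' identical results.
#'
#' @param config a [pipeline_config()].
#' @param dir working/output directory.
#' @param quiet suppress progress messages.
#' @return the [stage_report()] value list, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), dir, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  say("simulate: seed ", config$sim$seed)
  stage_simulate(config, dir)
  say("mine: top-", config$top_n, " per condition, ",
      config$promoter_length, " bp upstream windows")
  stage_mine(config, dir)
  say("motifs: CAAT/GC/CT-box and splice-risk scan")
  stage_motifs(config, dir)
  say("strength: normalize, folds vs ", config$reference, ", classes")
  stage_strength(config, dir)
  say("pathway: design scoring and sugar utilization")
  stage_pathway(config, dir)
  rep_ <- stage_report(config, dir)
  say(sprintf("report: %d candidates -> %d assayed -> %d strong (+%d controls)",
              rep_$n_candidates, rep_$n_assayed, rep_$n_strong,
              rep_$n_controls))
  invisible(rep_)
}
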