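#' Simulation configuration for the synthetic study world
#'
#' Bundles every constant the synthetic-data generator needs: genome layout,
#' the media x growth-phase condition grid, the screening-cascade targets
#' (how many candidates are planted and how many of them fail cloning, show
#' no fluorescence, or are very weak), the span of promoter strengths
#' relative to the reference promoter, plate-reader noise, and the titer
#' model. Defaults reproduce the study conditions: top-15 ranking in
#' 4 media x 2 phases, a 52 = 3 + 11 + 7 + 31 cascade, strengths spanning
#' 0.1-19.0 times the reference, a stationary/logarithmic ratio of up to 9
#' in YPD, and triplicate wells at 5% fluorescence CV.
#'
#' @param seed integer seed; every generator output is a pure function of it.
#' @param n_contigs number of contigs in the synthetic genome.
#' @param n_genes number of ordinary genes (the reference and two control
#'   genes are added on top).
#' @param gene_length_range min/max gene length in bp.
#' @param intergenic_min minimum clearance between neighbouring genes (bp).
#'   Values below the promoter window length are raised internally so every
#'   candidate keeps a full upstream window.
#' @param contig_length optional fixed contig length (bp). `NULL` sizes each
#'   contig to fit its genes; a fixed budget that cannot hold them raises a
#'   sizing error.
#' @param media,phases condition grid; `length(media) * length(phases)`
#'   conditions are simulated.
#' @param top_n genes taken per condition when ranking expression.
#' @param n_candidates_target size of the planted candidate set (union of the
#'   per-condition top-`top_n` lists).
#' @param n_clone_fail,n_null,n_weak screening-class counts among the
#'   candidates; the remainder is the strong class.
#' @param strength_fold_range min/max planted strength fold vs the reference.
#' @param max_phase_ratio largest planted stationary/logarithmic fold ratio
#'   (placed in the first medium, by default YPD).
#' @param fluor_cv coefficient of variation of the multiplicative
#'   fluorescence noise; 0 gives a noiseless plate.
#' @param replicates wells per promoter x condition.
#' @param gain fluorescence units per OD unit per strength fold.
#' @param blank_fluor,blank_od plate background fluorescence and OD600.
#' @param promoter_length upstream window length in bp.
#' @param expr_background_mean log-normal location of background expression.
#' @param expr_boost mean count scale given to a planted top gene (per rank);
#'   0 disables boosting.
#' @param expr_dispersion negative-binomial dispersion (1/size).
#' @param titer_base_per_medium named baseline C18:2 titer (mg/L) per medium.
#' @param titer_gain titer gained at full pathway saturation (mg/L).
#' @param titer_K half-saturation fold of the titer model.
#' @param titer_cv coefficient of variation of titer noise.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' length(cfg$media) * length(cfg$phases)  # 8 conditions
sim_config <- function(seed = 1,
                       n_contigs = 6,
                       n_genes = 150,
                       gene_length_range = c(300L, 3000L),
                       intergenic_min = 1200L,
                       contig_length = NULL,
                       media = c("YPD", "YPX", "SC", "MM"),
                       phases = c("logarithmic", "stationary"),
                       top_n = 15L,
                       n_candidates_target = 52L,
                       n_clone_fail = 3L,
                       n_null = 11L,
                       n_weak = 7L,
                       strength_fold_range = c(0.1, 19.0),
                       max_phase_ratio = 9,
                       fluor_cv = 0.05,
                       replicates = 3L,
                       gain = 2000,
                       blank_fluor = 50,
                       blank_od = 0.09,
                       promoter_length = 1000L,
                       expr_background_mean = 30,
                       expr_boost = 2e5,
                       expr_dispersion = 0.1,
                       titer_base_per_medium = c(YPD = 164.3, YPX = 150,
                                                 SC = 140, MM = 79.08),
                       titer_gain = 190,
                       titer_K = 1,
                       titer_cv = 0.05) {
  cfg <- list(
    seed = as.integer(seed), n_contigs = as.integer(n_contigs),
    n_genes = as.integer(n_genes),
    gene_length_range = as.integer(gene_length_range),
    intergenic_min = as.integer(intergenic_min),
    contig_length = if (is.null(contig_length)) NULL else as.integer(contig_length),
    media = as.character(media), phases = as.character(phases),
    top_n = as.integer(top_n),
    n_candidates_target = as.integer(n_candidates_target),
    n_clone_fail = as.integer(n_clone_fail), n_null = as.integer(n_null),
    n_weak = as.integer(n_weak),
    strength_fold_range = as.numeric(strength_fold_range),
    max_phase_ratio = as.numeric(max_phase_ratio),
    fluor_cv = as.numeric(fluor_cv), replicates = as.integer(replicates),
    gain = as.numeric(gain), blank_fluor = as.numeric(blank_fluor),
    blank_od = as.numeric(blank_od),
    promoter_length = as.integer(promoter_length),
    expr_background_mean = as.numeric(expr_background_mean),
    expr_boost = as.numeric(expr_boost),
    expr_dispersion = as.numeric(expr_dispersion),
    titer_base_per_medium = titer_base_per_medium,
    titer_gain = as.numeric(titer_gain), titer_K = as.numeric(titer_K),
    titer_cv = as.numeric(titer_cv)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  counts <- c(cfg$n_contigs, cfg$n_genes, cfg$top_n, cfg$n_candidates_target,
              cfg$n_clone_fail, cfg$n_null, cfg$n_weak, cfg$replicates)
  if (any(is.na(counts)) || any(counts < 0))
    stop("all counts must be non-negative", call. = FALSE)
  if (cfg$n_clone_fail + cfg$n_null + cfg$n_weak >= cfg$n_candidates_target)
    stop("n_clone_fail + n_null + n_weak must be < n_candidates_target",
         call. = FALSE)
  if (cfg$strength_fold_range[1] <= 0)
    stop("strength_fold_range lower bound must be > 0", call. = FALSE)
  if (diff(cfg$strength_fold_range) <= 0)
    stop("strength_fold_range must be increasing", call. = FALSE)
  if (cfg$fluor_cv < 0 || cfg$fluor_cv >= 1 ||
      cfg$titer_cv < 0 || cfg$titer_cv >= 1)
    stop("fluor_cv and titer_cv must lie in [0, 1)", call. = FALSE)
  if (length(cfg$media) < 1L || length(cfg$phases) < 1L)
    stop("at least one medium and one phase required", call. = FALSE)
  n_cond <- length(cfg$media) * length(cfg$phases)
  if (cfg$n_candidates_target < cfg$top_n ||
      cfg$n_candidates_target > n_cond * cfg$top_n)
    stop("n_candidates_target must lie in [top_n, n_conditions * top_n] ",
         "so the union of top-N lists can equal it exactly", call. = FALSE)
  if (cfg$n_candidates_target + 3L > cfg$n_genes)
    stop("n_genes too small to host the candidate set plus reference/controls",
         call. = FALSE)
  if (diff(cfg$gene_length_range) < 0 || cfg$gene_length_range[1] < 10L)
    stop("invalid gene_length_range", call. = FALSE)
  if (!all(cfg$media %in% names(cfg$titer_base_per_medium)))
    stop("titer_base_per_medium must name every medium", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: seed", x$seed, "|", x$n_genes, "genes on", x$n_contigs,
      "contigs |", length(x$media), "media x", length(x$phases), "phases\n")
  cat("  cascade:", x$n_candidates_target, "candidates =",
      x$n_clone_fail, "clone-fail +", x$n_null, "null +", x$n_weak,
      "weak +", x$n_candidates_target - x$n_clone_fail - x$n_null - x$n_weak,
      "strong\n")
  cat("  strength span:", paste(x$strength_fold_range, collapse = "-"),
      "fold vs reference; fluor CV", x$fluor_cv, "x", x$replicates, "reps\n")
  invisible(x)
}

# condition label shared across modules
cond_key <- function(medium, phase) paste(medium, phase, sep = ".")

sim_conditions <- function(cfg) {
  grid <- expand.grid(phase = cfg$phases, medium = cfg$media,
                      stringsAsFactors = FALSE)[, c("medium", "phase")]
  grid <- grid[order(match(grid$medium, cfg$media),
                     match(grid$phase, cfg$phases)), , drop = FALSE]
  rownames(grid) <- NULL
  grid
}
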