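#' @importFrom stats rnbinom rlnorm rnorm runif sd median setNames approx
#' @importFrom utils head write.table read.delim
NULL

BASES <- c("A", "C", "G", "T")

random_bases <- function(n) sample(BASES, n, replace = TRUE)

revcomp_chr <- function(x) {
  # character-vector reverse complement used during construction;
  # sequence-level I/O goes through Biostrings
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rev(unname(comp[x]))
}

#' Generate the synthetic genome, annotation, and ground-truth world
#'
#' Places genes on both strands of random contigs with guaranteed intergenic
#' clearance, writes a start codon at each gene's translational start, and for
#' every candidate (and the reference/control genes) constructs the full
#' upstream promoter window explicitly, planting the diagnostic elements the
#' downstream scans look for: a literal `CAAT`, the GC-box heptamer
#' `GGGCGGG`, a pyrimidine-rich CT box inside -90..-10 from the start codon,
#' and -- for the null screening class -- a `G|GT` splice donor within the
#' last 25 bp of the promoter (its `AG|G` acceptor partner sits in the fixed
#' reporter head, see [egfp_head()]). Ground-truth strength folds relative to
#' the reference promoter are drawn to span `strength_fold_range`, with two
#' promoters extreme in every condition, one promoter hitting the range
#' maximum in YPX/stationary, one hitting the minimum in MM, and two
#' phase-responsive promoters whose stationary/logarithmic ratio reaches
#' `max_phase_ratio` in the first medium.
#'
#' Generation is a pure function of `config$seed`: the same config yields
#' byte-identical FASTA/GFF3 output.
#'
#' @param config a [sim_config()].
#' @return an object of class `synthetic_world`: a list with `genome` (named
#'   character vector of contig sequences), `genes` (annotation data frame
#'   with 1-based inclusive coordinates and `cds_start`), `promoters`
#'   (promoter_id, gene_id, class), `true_strength` (promoter x condition
#'   fold matrix; NA for clone-fail promoters), `planted` (per-promoter
#'   element table with promoter-local 1-based offsets), `top_sets` (the
#'   planted per-condition top-N gene sets), and `roles` (ids of the special
#'   promoters).
#' @export
generate_genome <- function(config = sim_config()) {
  validate_sim_config(config)
  cfg <- config
  set.seed(cfg$seed)
  plen <- cfg$promoter_length

  gene_ids <- c(sprintf("RTG%04d", seq_len(cfg$n_genes)),
                "GPD1", "FAS1", "TPI1")
  special <- c("GPD1", "FAS1", "TPI1")
  candidates <- sort(sample(setdiff(gene_ids, special),
                            cfg$n_candidates_target))
  cls_pool <- sample(candidates)  # class assignment order
  n_strong <- cfg$n_candidates_target - cfg$n_clone_fail - cfg$n_null -
    cfg$n_weak
  class_of <- setNames(rep(c("clone_fail", "null", "weak", "strong"),
                           c(cfg$n_clone_fail, cfg$n_null, cfg$n_weak,
                             n_strong)), cls_pool)
  class_of[special] <- c("reference", "control", "control")

  ## ---- gene placement -------------------------------------------------
  n_total <- length(gene_ids)
  lens <- sample(seq(cfg$gene_length_range[1], cfg$gene_length_range[2]),
                 n_total, replace = TRUE)
  strands <- sample(c("+", "-"), n_total, replace = TRUE)
  contig_of <- sample(rep_len(seq_len(cfg$n_contigs), n_total))
  # neighbouring genes may both project promoter windows into the shared
  # intergenic gap (a minus-strand gene upstream-right, the next gene
  # upstream-left), so the gap must hold two full windows
  gap_min <- max(cfg$intergenic_min, 2L * plen + 100L)
  margin <- plen + 100L

  genes <- data.frame(gene_id = gene_ids, contig = NA_character_,
                      strand = strands, start = NA_integer_,
                      end = NA_integer_, cds_start = NA_integer_,
                      length = lens, stringsAsFactors = FALSE)
  contig_len <- integer(cfg$n_contigs)
  for (k in seq_len(cfg$n_contigs)) {
    idx <- which(contig_of == k)
    pos <- margin + 1L
    for (i in idx) {
      genes$contig[i] <- sprintf("contig_%02d", k)
      genes$start[i] <- pos
      genes$end[i] <- pos + lens[i] - 1L
      pos <- genes$end[i] + gap_min + sample(0:200, 1L)
    }
    contig_len[k] <- (if (length(idx)) genes$end[idx[length(idx)]] else 0L) +
      margin
    if (!is.null(cfg$contig_length)) {
      if (contig_len[k] > cfg$contig_length)
        stop(sprintf(paste0("infeasible packing: contig_%02d needs %d bp ",
                            "but the contig budget is %d bp"),
                     k, contig_len[k], cfg$contig_length), call. = FALSE)
      contig_len[k] <- cfg$contig_length
    }
  }
  genes$cds_start <- ifelse(genes$strand == "+", genes$start, genes$end)

  contig_names <- sprintf("contig_%02d", seq_len(cfg$n_contigs))
  seqs <- lapply(contig_len, random_bases)
  names(seqs) <- contig_names

  # write start codons (transcript-oriented ATG)
  for (i in seq_len(n_total)) {
    s <- seqs[[genes$contig[i]]]
    if (genes$strand[i] == "+") {
      s[genes$start[i] + 0:2] <- c("A", "T", "G")
    } else {
      s[genes$end[i] - 2:0] <- c("C", "A", "T")
    }
    seqs[[genes$contig[i]]] <- s
  }

  ## ---- promoter construction with planted elements --------------------
  with_promoter <- c(candidates, special)
  planted <- list()
  for (g in with_promoter) {
    i <- match(g, genes$gene_id)
    cls <- class_of[[g]]
    prom <- random_bases(plen)
    elems <- data.frame(element = character(), offset = integer(),
                        length = integer(), stringsAsFactors = FALSE)
    add <- function(el, off, len) rbind(elems, data.frame(
      element = el, offset = as.integer(off), length = as.integer(len),
      stringsAsFactors = FALSE))

    if (cls %in% c("strong", "reference", "control")) {
      # CT box: 25 bp, ~88% pyrimidine, wholly inside -90..-10
      ct_len <- 25L
      lo <- plen - 90L + 1L
      hi <- plen - 10L + 1L - ct_len
      ct_at <- sample(lo:hi, 1L)
      ct <- sample(c("C", "T"), ct_len, replace = TRUE)
      ct[sample(ct_len, 3L)] <- sample(c("A", "G"), 3L, replace = TRUE)
      prom[ct_at + seq_len(ct_len) - 1L] <- ct
      elems <- add("CT_BOX", ct_at, ct_len)
    }
    if (cls == "strong" && runif(1) < 0.6) {
      at <- sample(100:400, 1L)  # disjoint from the GC-box plant range
      prom[at + 0:3] <- c("C", "A", "A", "T")
      elems <- add("CAAT", at, 4L)
    }
    if (cls == "strong" && runif(1) < 0.4) {
      at <- sample(500:800, 1L)
      prom[at + 0:6] <- c("G", "G", "G", "C", "G", "G", "G")
      elems <- add("GC_BOX", at, 7L)
    }
    if (cls == "null") {
      # splice donor G|GT with its G inside the last 25 bp; the acceptor
      # AG|G partner is carried by the fixed reporter head
      at <- sample((plen - 24L):(plen - 2L), 1L)
      prom[at + 0:2] <- c("G", "G", "T")
      elems <- add("SPLICE_RISK", at, 3L)
    }
    planted[[paste0("P_", g)]] <- elems

    s <- seqs[[genes$contig[i]]]
    if (genes$strand[i] == "+") {
      up <- genes$cds_start[i] - plen
      s[up:(genes$cds_start[i] - 1L)] <- prom
    } else {
      s[(genes$cds_start[i] + 1L):(genes$cds_start[i] + plen)] <-
        revcomp_chr(prom)
    }
    seqs[[genes$contig[i]]] <- s
  }
  genome <- vapply(seqs, paste, character(1), collapse = "")

  promoters <- data.frame(
    promoter_id = paste0("P_", with_promoter),
    gene_id = with_promoter,
    class = unname(class_of[with_promoter]),
    stringsAsFactors = FALSE)

  ## ---- ground-truth strengths -----------------------------------------
  conds <- sim_conditions(cfg)
  ckeys <- cond_key(conds$medium, conds$phase)
  strength <- matrix(NA_real_, nrow = nrow(promoters), ncol = length(ckeys),
                     dimnames = list(promoters$promoter_id, ckeys))
  lohi <- cfg$strength_fold_range
  clamp <- function(x, lo = lohi[1] * 1.05, hi = lohi[2] * 0.95)
    pmin(pmax(x, lo), hi)

  strong_ids <- promoters$promoter_id[promoters$class == "strong"]
  roles <- list()
  if (length(strong_ids) >= 6L && length(cfg$media) >= 2L &&
      length(cfg$phases) == 2L) {
    roles <- list(extreme = strong_ids[1:2],
                  phase_responsive = strong_ids[3:4],
                  strongest = strong_ids[3], weakest = strong_ids[5],
                  mid = strong_ids[6])
  }
  ph_log <- cond_key(conds$medium[conds$phase == cfg$phases[1]], cfg$phases[1])
  ph_sta <- cond_key(conds$medium[conds$phase == cfg$phases[2]], cfg$phases[2])

  for (p in strong_ids) {
    base <- exp(runif(1, log(0.15), log(8)))
    strength[p, ] <- clamp(base * exp(rnorm(length(ckeys), 0, 0.3)))
  }
  if (length(roles)) {
    for (p in roles$extreme) {
      f <- runif(length(cfg$media), 5.5, 15)
      strength[p, ph_log] <- f
      strength[p, ph_sta] <- clamp(f * runif(length(f), 0.7, 0.95), lo = 5.2)
    }
    # strongest promoter: phase-responsive, ratio = max_phase_ratio in the
    # first medium, range maximum planted in the second medium, stationary
    p <- roles$strongest
    fl <- runif(length(cfg$media), 1.2, 1.8)
    strength[p, ph_log] <- fl
    strength[p, ph_sta] <- clamp(fl * runif(length(fl), 2.5, 4))
    strength[p, ph_sta[1]] <- fl[1] * cfg$max_phase_ratio
    strength[p, ph_sta[min(2L, length(ph_sta))]] <- lohi[2]
    p2 <- roles$phase_responsive[2]
    fl <- runif(length(cfg$media), 0.5, 1.5)
    strength[p2, ph_log] <- fl
    strength[p2, ph_sta] <- clamp(fl * runif(length(fl), 3, 6))
    # weakest promoter: range minimum planted in the last medium (MM by
    # default), logarithmic phase
    p <- roles$weakest
    strength[p, ] <- runif(length(ckeys), 0.15, 0.5)
    mm <- length(cfg$media)
    strength[p, ph_log[mm]] <- lohi[1]
    strength[p, ph_sta[mm]] <- runif(1, 0.12, 0.2)
    strength[roles$mid, ] <- runif(length(ckeys), 2.5, 4.5)
  }
  weak_ids <- promoters$promoter_id[promoters$class == "weak"]
  for (p in weak_ids) {
    base <- runif(1, 0.02, 0.08)
    strength[p, ] <- pmin(pmax(base * exp(rnorm(length(ckeys), 0, 0.1)),
                               0.01), 0.095)
  }
  strength[promoters$promoter_id[promoters$class == "null"], ] <- 0
  strength["P_GPD1", ] <- 1
  strength["P_FAS1", ] <- runif(length(ckeys), 0.73, 0.77)
  strength["P_TPI1", ] <- runif(length(ckeys), 1.1, 1.3)
  # clone-fail promoters keep NA: they are never assayed

  ## ---- per-condition top-N sets (expression boosts) --------------------
  n_cond <- length(ckeys)
  top_sets <- rep(list(character()), n_cond)
  names(top_sets) <- ckeys
  cand_shuffled <- sample(candidates)
  for (i in seq_along(cand_shuffled)) {
    k <- ((i - 1L) %% n_cond) + 1L
    top_sets[[k]] <- c(top_sets[[k]], cand_shuffled[i])
  }
  for (k in seq_len(n_cond)) {
    need <- cfg$top_n - length(top_sets[[k]])
    if (need > 0L) {
      pool <- setdiff(candidates, top_sets[[k]])
      top_sets[[k]] <- c(top_sets[[k]], sample(pool, need))
    } else if (need < 0L) {
      stop("top_n too small for the candidate assignment", call. = FALSE)
    }
    top_sets[[k]] <- sample(top_sets[[k]])  # within-condition rank order
  }

  world <- list(config = cfg, genome = genome, genes = genes,
                promoters = promoters, candidates = candidates,
                true_strength = strength, planted = planted,
                top_sets = top_sets, roles = roles,
                conditions = conds)
  class(world) <- "synthetic_world"
  world
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("synthetic_world:", length(x$genome), "contigs (",
      sum(nchar(x$genome)), "bp ),", nrow(x$genes), "genes,",
      length(x$candidates), "planted candidates\n")
  print(table(x$promoters$class))
  invisible(x)
}

#' Generate the condition-wise expression matrix
#'
#' Draws negative-binomial counts with a gene-specific background mean and a
#' shared dispersion, boosts the planted per-condition top-N genes far above
#' background (rank-ordered within each condition), and rescales each
#' condition to a TPM-like per-million abundance. With the default boost the
#' union of per-condition top-N sets recovers exactly the planted candidate
#' set; with `expr_boost = 0` the matrix is pure background noise.
#'
#' @param world a [generate_genome()] result.
#' @param config its [sim_config()] (defaults to the one inside `world`).
#' @return long data frame: `gene_id`, `medium`, `phase`, `abundance`
#'   (TPM-like, non-negative).
#' @export
generate_expression <- function(world, config = world$config) {
  stopifnot(inherits(world, "synthetic_world"))
  cfg <- config
  set.seed(cfg$seed + 1L)
  genes <- world$genes$gene_id
  n <- length(genes)
  size <- 1 / cfg$expr_dispersion
  bg_mean <- pmin(rlnorm(n, log(cfg$expr_background_mean), 1), 500)
  names(bg_mean) <- genes

  conds <- world$conditions
  out <- vector("list", nrow(conds))
  for (k in seq_len(nrow(conds))) {
    key <- cond_key(conds$medium[k], conds$phase[k])
    mu <- bg_mean
    if (cfg$expr_boost > 0) {
      top <- world$top_sets[[key]]
      # rank 1 strongest; means strictly separated across ranks
      mu[top] <- cfg$expr_boost * (length(top):1)
    }
    counts <- rnbinom(n, mu = mu, size = size)
    tpm <- counts / sum(counts) * 1e6
    out[[k]] <- data.frame(gene_id = genes, medium = conds$medium[k],
                           phase = conds$phase[k], abundance = tpm,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate plate-reader wells (fluorescence and OD600)
#'
#' Emits one well per assayed promoter x condition x replicate following the
#' forward model `raw_F = blank_F + (OD - blank_OD) * gain * fold * (1 + e)`
#' with `e ~ Normal(0, fluor_cv)`, plus three blank wells per condition
#' (jittered around the plate constants by the same CV, so `fluor_cv = 0`
#' yields an exactly invertible plate). OD600 is a deterministic function of
#' medium and phase. Clone-fail promoters are absent -- they were never
#' assayed; null-class promoters carry fold 0 and therefore read exactly at
#' blank level in the noiseless plate.
#'
#' @inheritParams generate_expression
#' @return data frame: `promoter_id` (or `"blank"`), `medium`, `phase`,
#'   `replicate`, `od600`, `fluorescence`.
#' @export
generate_plate_reader <- function(world, config = world$config) {
  stopifnot(inherits(world, "synthetic_world"))
  cfg <- config
  set.seed(cfg$seed + 2L)
  assayed <- world$promoters$promoter_id[world$promoters$class != "clone_fail"]
  miss <- assayed[!assayed %in% rownames(world$true_strength) |
                    apply(world$true_strength[assayed, , drop = FALSE], 1,
                          function(r) any(is.na(r)))]
  if (length(miss))
    stop("missing true_strength for promoter(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  conds <- world$conditions
  od_for <- function(medium, phase) {
    base <- if (phase == cfg$phases[1]) 0.8 else 1.7
    base + 0.05 * (match(medium, cfg$media) - 1L)
  }
  rows <- vector("list", nrow(conds))
  for (k in seq_len(nrow(conds))) {
    m <- conds$medium[k]; ph <- conds$phase[k]
    od <- od_for(m, ph)
    key <- cond_key(m, ph)
    fold <- world$true_strength[assayed, key]
    nrep <- cfg$replicates
    eps <- if (cfg$fluor_cv > 0)
      rnorm(length(assayed) * nrep, 0, cfg$fluor_cv) else 0
    fl <- cfg$blank_fluor +
      (od - cfg$blank_od) * cfg$gain * rep(fold, each = nrep) * (1 + eps)
    sample_rows <- data.frame(
      promoter_id = rep(assayed, each = nrep), medium = m, phase = ph,
      replicate = rep(seq_len(nrep), times = length(assayed)),
      od600 = od, fluorescence = fl, stringsAsFactors = FALSE)
    nb <- 3L
    bj <- if (cfg$fluor_cv > 0) rnorm(nb, 0, cfg$fluor_cv) else rep(0, nb)
    oj <- if (cfg$fluor_cv > 0) rnorm(nb, 0, cfg$fluor_cv) else rep(0, nb)
    blank_rows <- data.frame(
      promoter_id = "blank", medium = m, phase = ph, replicate = seq_len(nb),
      od600 = cfg$blank_od * (1 + oj),
      fluorescence = cfg$blank_fluor * (1 + bj), stringsAsFactors = FALSE)
    rows[[k]] <- rbind(sample_rows, blank_rows)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Default combinatorial pathway designs for the synthetic world
#'
#' Five strain designs mirroring the study layout -- the two extreme
#' promoters paired, each extreme paired with the reference, a mid-strength
#' promoter used twice, and the reference used twice -- drawn from the
#' world's special-role promoters.
#'
#' @param world a [generate_genome()] result with populated roles.
#' @return data frame: `design_id`, `promoter_fad9`, `promoter_fad12`.
#' @export
default_designs <- function(world) {
  stopifnot(inherits(world, "synthetic_world"))
  if (!length(world$roles))
    stop("world has no special promoter roles (too few strong promoters)",
         call. = FALSE)
  r <- world$roles
  data.frame(
    design_id = sprintf("S%d", 56:60),
    promoter_fad9 = c(r$extreme[1], r$extreme[1], "P_GPD1", r$mid, "P_GPD1"),
    promoter_fad12 = c(r$extreme[2], "P_GPD1", r$extreme[2], r$mid, "P_GPD1"),
    stringsAsFactors = FALSE)
}

#' Generate fatty-acid titers for pathway designs
#'
#' C18:2 (linoleic acid) titer per design and medium follows a
#' bottleneck-limited two-step model:
#' `titer = base(medium) + gain * min(sat(f9), sat(f12)) * (1 + e)` with
#' `sat(f) = f / (f + K)` and `f` the promoter's logarithmic-phase fold in
#' that medium. Total fatty acid is C18:2 divided by a ~0.35 linoleic
#' fraction. Noise-free titers are strictly monotone in either promoter's
#' strength, so the design pairing the two strongest promoters wins in every
#' medium.
#'
#' @param world a [generate_genome()] result.
#' @param designs data frame with `design_id`, `promoter_fad9`,
#'   `promoter_fad12` (default [default_designs()]).
#' @param config its [sim_config()].
#' @return data frame: `strain_id`, `medium`, `promoter_fad9`,
#'   `promoter_fad12`, `c18_2_mg_per_l`, `total_fa_mg_per_l`.
#' @export
generate_titers <- function(world, designs = default_designs(world),
                            config = world$config) {
  stopifnot(inherits(world, "synthetic_world"))
  cfg <- config
  set.seed(cfg$seed + 3L)
  proms <- unique(c(designs$promoter_fad9, designs$promoter_fad12))
  unknown <- setdiff(proms, rownames(world$true_strength))
  if (length(unknown))
    stop("unknown promoter(s) in designs: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  sat <- function(f) f / (f + cfg$titer_K)
  rows <- vector("list", 0L)
  for (m in cfg$media) {
    key <- cond_key(m, cfg$phases[1])
    f9 <- world$true_strength[designs$promoter_fad9, key]
    f12 <- world$true_strength[designs$promoter_fad12, key]
    score <- pmin(sat(f9), sat(f12))
    e1 <- if (cfg$titer_cv > 0) rnorm(nrow(designs), 0, cfg$titer_cv) else 0
    c18 <- (cfg$titer_base_per_medium[[m]] + cfg$titer_gain * score) * (1 + e1)
    frac <- pmin(pmax(0.35 * (1 + if (cfg$titer_cv > 0)
      rnorm(nrow(designs), 0, cfg$titer_cv / 2) else 0), 0.2), 0.9)
    rows[[length(rows) + 1L]] <- data.frame(
      strain_id = designs$design_id, medium = m,
      promoter_fad9 = designs$promoter_fad9,
      promoter_fad12 = designs$promoter_fad12,
      c18_2_mg_per_l = unname(c18),
      total_fa_mg_per_l = unname(c18 / frac), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Generate the mixed-sugar consumption time series
#'
#' Emulates growth on corncob hydrolysate: xylose starts much higher than
#' glucose, yet glucose is exhausted first, and more than 80% of total sugar
#' is consumed within 30 h. Concentrations decline linearly to zero with
#' sugar-specific depletion times (glucose 20 h, xylose 36 h, arabinose
#' 60 h); the series is deterministic.
#'
#' @param config a [sim_config()] (only used for the time grid convention).
#' @param t_max,dt time grid extent and step in hours.
#' @return data frame: `time_h`, `glucose_g_l`, `xylose_g_l`,
#'   `arabinose_g_l`.
#' @export
generate_sugar_series <- function(config = sim_config(), t_max = 48, dt = 2) {
  t <- seq(0, t_max, by = dt)
  lin <- function(c0, t_end) c0 * pmax(0, 1 - t / t_end)
  data.frame(time_h = t,
             glucose_g_l = lin(15, 20),
             xylose_g_l = lin(25, 36),
             arabinose_g_l = lin(5, 60))
}
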