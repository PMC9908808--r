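STRENGTH_CLASSES <- c("none", "very_weak", "weak", "medium", "strong",
                      "extreme")

#' Blank-subtracted fluorescence per OD for one promoter and condition
#'
#' Per replicate well, `signal = (F - mean blank F) / (OD - mean blank OD)`:
#' additive plate background is removed from both channels before the
#' per-cell ratio is taken. Negative per-replicate signals (wells
#' indistinguishable from blanks) are clipped to zero with a warning.
#'
#' @param wells data frame of sample wells (`od600`, `fluorescence`), one
#'   promoter x condition.
#' @param blanks data frame of blank wells from the same plate/condition.
#' @return list: `mean`, `sd` (sample sd across replicates; 0 when a single
#'   replicate), `n`.
#' @export
#' @examples
#' w <- data.frame(od600 = 0.6, fluorescence = 1100)
#' b <- data.frame(od600 = 0.1, fluorescence = 100)
#' normalize_signal(w, b)$mean  # 2000
normalize_signal <- function(wells, blanks) {
  if (nrow(wells) < 1L) stop("no sample wells", call. = FALSE)
  if (nrow(blanks) < 1L) stop("no blank wells", call. = FALSE)
  if (any(!is.finite(wells$od600)) || any(!is.finite(wells$fluorescence)))
    stop("non-finite well measurements", call. = FALSE)
  mb_f <- mean(blanks$fluorescence)
  mb_od <- mean(blanks$od600)
  if (any(wells$od600 <= mb_od))
    stop("sample OD at or below blank OD: no growth in well", call. = FALSE)
  sig <- (wells$fluorescence - mb_f) / (wells$od600 - mb_od)
  if (any(sig < 0)) {
    warning("negative normalized signal(s) clipped to 0", call. = FALSE)
    sig <- pmax(sig, 0)
  }
  list(mean = mean(sig),
       sd = if (length(sig) > 1L) sd(sig) else 0,
       n = length(sig))
}

#' Summarise a plate table into per-condition normalized signals
#'
#' Groups wells by promoter x (medium, phase), normalizes against the blank
#' wells of the same condition, and attaches a detection call: a promoter is
#' detected in a condition when its mean raw fluorescence exceeds the blank
#' mean plus three blank standard deviations (limit-of-detection
#' convention).
#'
#' @param plate data frame: `promoter_id` (blank wells labelled `"blank"`),
#'   `medium`, `phase`, `replicate`, `od600`, `fluorescence`.
#' @return data frame with one row per promoter x condition: `signal_mean`,
#'   `signal_sd`, `n`, `raw_f_mean`, `blank_f_mean`, `blank_f_sd`,
#'   `detected`.
#' @export
summarize_plate <- function(plate) {
  needed <- c("promoter_id", "medium", "phase", "od600", "fluorescence")
  if (!all(needed %in% names(plate)))
    stop("plate table must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  conds <- unique(plate[, c("medium", "phase")])
  rows <- list()
  for (k in seq_len(nrow(conds))) {
    m <- conds$medium[k]; ph <- conds$phase[k]
    sub <- plate[plate$medium == m & plate$phase == ph, , drop = FALSE]
    blanks <- sub[sub$promoter_id == "blank", , drop = FALSE]
    if (nrow(blanks) == 0L)
      stop(sprintf("no blank wells for condition (%s, %s)", m, ph),
           call. = FALSE)
    for (p in unique(sub$promoter_id[sub$promoter_id != "blank"])) {
      wells <- sub[sub$promoter_id == p, , drop = FALSE]
      ns <- normalize_signal(wells, blanks)
      rows[[length(rows) + 1L]] <- data.frame(
        promoter_id = p, medium = m, phase = ph,
        signal_mean = ns$mean, signal_sd = ns$sd, n = ns$n,
        raw_f_mean = mean(wells$fluorescence),
        blank_f_mean = mean(blanks$fluorescence),
        blank_f_sd = if (nrow(blanks) > 1L) sd(blanks$fluorescence) else 0,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$detected <- res$raw_f_mean > res$blank_f_mean + 3 * res$blank_f_sd
  rownames(res) <- NULL
  res
}

#' Fold strength relative to the reference promoter
#'
#' `fold(p, c) = signal(p, c) / signal(reference, c)`, computed within each
#' condition so any per-plate gain cancels. The reference promoter's folds
#' are exactly 1 in every condition.
#'
#' @param signals a [summarize_plate()] data frame.
#' @param reference reference promoter id (default `"P_GPD1"`).
#' @return `signals` with a `fold` column appended.
#' @export
relative_strength <- function(signals, reference = "P_GPD1") {
  if (!reference %in% signals$promoter_id)
    stop(sprintf("reference promoter '%s' not present", reference),
         call. = FALSE)
  key <- cond_key(signals$medium, signals$phase)
  ref <- signals[signals$promoter_id == reference, , drop = FALSE]
  ref_key <- cond_key(ref$medium, ref$phase)
  missing_cond <- setdiff(unique(key), ref_key)
  if (length(missing_cond))
    stop("reference not measured in condition(s): ",
         paste(missing_cond, collapse = ", "), call. = FALSE)
  ref_sig <- setNames(ref$signal_mean, ref_key)
  zero <- names(ref_sig)[ref_sig <= 0]
  if (length(zero))
    stop("reference signal is zero in condition(s): ",
         paste(zero, collapse = ", "), call. = FALSE)
  signals$fold <- signals$signal_mean / unname(ref_sig[key])
  signals$fold[signals$promoter_id == reference] <- 1
  signals
}

#' Classify promoter strength per condition and overall
#'
#' Per condition: `none` when the promoter is below the detection limit,
#' otherwise `very_weak` (< `thresholds[1]`), `weak` (< `thresholds[2]`),
#' `medium` (< `thresholds[3]`), `strong` (< `thresholds[4]`), or `extreme`.
#' The default thresholds 0.1/0.5/2/5 x reference make the reference itself
#' `medium`. The overall class is the modal per-condition class, ties
#' resolved toward the lower class; a promoter `extreme` in every condition
#' is annotated extreme-in-all-media.
#'
#' @param folds a [relative_strength()] data frame (needs `fold` and
#'   `detected`).
#' @param thresholds increasing fold cut-points, length 4.
#' @return list: `per_condition` (input with `cond_class`), `overall`
#'   (`promoter_id`, `overall_class`, `extreme_in_all_media`).
#' @export
classify_strength <- function(folds, thresholds = c(0.1, 0.5, 2, 5)) {
  stopifnot(length(thresholds) == 4L, all(diff(thresholds) > 0))
  cls <- function(fold, detected) {
    if (!detected) return("none")
    if (fold < thresholds[1]) return("very_weak")
    if (fold < thresholds[2]) return("weak")
    if (fold < thresholds[3]) return("medium")
    if (fold < thresholds[4]) return("strong")
    "extreme"
  }
  folds$cond_class <- mapply(cls, folds$fold, folds$detected)
  overall <- do.call(rbind, lapply(split(folds, folds$promoter_id),
                                   function(d) {
    tab <- table(factor(d$cond_class, levels = STRENGTH_CLASSES))
    winners <- names(tab)[tab == max(tab)]
    data.frame(promoter_id = d$promoter_id[1],
               overall_class = winners[1],  # levels ordered low -> high
               extreme_in_all_media = all(d$cond_class == "extreme"),
               stringsAsFactors = FALSE)
  }))
  rownames(overall) <- NULL
  list(per_condition = folds, overall = overall)
}

#' Phase and medium responsiveness of promoter strengths
#'
#' Per promoter and medium, the phase ratio is the stationary-phase fold
#' divided by the logarithmic-phase fold; a promoter is phase-responsive
#' when any ratio is >= 2 or <= 0.5 (a zero logarithmic fold with nonzero
#' stationary fold gives an infinite ratio, flagged). Per phase, the medium
#' CV is sd/mean of folds across media; a promoter is medium-variable when
#' any CV >= `cv_threshold`.
#'
#' @param folds a [relative_strength()] data frame.
#' @param phases character vector naming the logarithmic and stationary
#'   phase labels, in that order.
#' @param cv_threshold medium-variability cut-off (default 0.5).
#' @return list: `phase_ratios` (`promoter_id`, `medium`, `phase_ratio`),
#'   `medium_cv` (`promoter_id`, `phase`, `cv`), `flags` (`promoter_id`,
#'   `phase_responsive`, `medium_variable`).
#' @export
responsiveness <- function(folds, phases = c("logarithmic", "stationary"),
                           cv_threshold = 0.5) {
  missing_ph <- setdiff(phases, unique(folds$phase))
  if (length(missing_ph))
    stop("phase(s) not measured: ", paste(missing_ph, collapse = ", "),
         call. = FALSE)
  pr <- list(); mc <- list()
  for (p in unique(folds$promoter_id)) {
    d <- folds[folds$promoter_id == p, , drop = FALSE]
    for (m in unique(d$medium)) {
      f_log <- d$fold[d$medium == m & d$phase == phases[1]]
      f_sta <- d$fold[d$medium == m & d$phase == phases[2]]
      if (length(f_log) == 1L && length(f_sta) == 1L) {
        ratio <- if (f_log == 0) {
          if (f_sta == 0) NA_real_ else Inf
        } else f_sta / f_log
        pr[[length(pr) + 1L]] <- data.frame(
          promoter_id = p, medium = m, phase_ratio = ratio,
          stringsAsFactors = FALSE)
      }
    }
    for (ph in phases) {
      f <- d$fold[d$phase == ph]
      if (length(f) >= 2L) {
        cv <- if (mean(f) == 0) NA_real_ else sd(f) / mean(f)
        mc[[length(mc) + 1L]] <- data.frame(
          promoter_id = p, phase = ph, cv = cv, stringsAsFactors = FALSE)
      }
    }
  }
  phase_ratios <- do.call(rbind, pr)
  medium_cv <- do.call(rbind, mc)
  flags <- do.call(rbind, lapply(unique(folds$promoter_id), function(p) {
    r <- phase_ratios$phase_ratio[phase_ratios$promoter_id == p]
    cv <- medium_cv$cv[medium_cv$promoter_id == p]
    data.frame(
      promoter_id = p,
      phase_responsive = any(r >= 2 | r <= 0.5, na.rm = TRUE),
      medium_variable = any(cv >= cv_threshold, na.rm = TRUE),
      stringsAsFactors = FALSE)
  }))
  rownames(phase_ratios) <- rownames(medium_cv) <- rownames(flags) <- NULL
  list(phase_ratios = phase_ratios, medium_cv = medium_cv, flags = flags)
}

#' Promoters x conditions fold matrix
#'
#' Dense matrix of fold strengths with columns ordered medium-major,
#' phase-minor, and rows ordered by descending overall median fold
#' (gene id breaks ties) -- the layout used for heatmap rendering and for
#' pathway scoring.
#'
#' @param folds a [relative_strength()] data frame.
#' @param media,phases column ordering; defaults to order of appearance.
#' @return numeric matrix, `dimnames = list(promoter, condition)` with
#'   condition labels `medium.phase`.
#' @export
strength_matrix <- function(folds, media = unique(folds$medium),
                            phases = unique(folds$phase)) {
  keys <- as.vector(t(outer(media, phases, cond_key)))
  proms <- unique(folds$promoter_id)
  mat <- matrix(NA_real_, length(proms), length(keys),
                dimnames = list(proms, keys))
  mat[cbind(match(folds$promoter_id, proms),
            match(cond_key(folds$medium, folds$phase), keys))] <- folds$fold
  med <- apply(mat, 1, median, na.rm = TRUE)
  mat[order(-med, rownames(mat)), , drop = FALSE]
}

#' Full strength quantification of a plate table
#'
#' Blank subtraction, per-OD normalization, replicate aggregation, folds
#' versus the reference, strength classes, responsiveness, and the fold
#' matrix in one call.
#'
#' @inheritParams summarize_plate
#' @inheritParams relative_strength
#' @inheritParams classify_strength
#' @param phases logarithmic/stationary phase labels, in that order.
#' @return list of class `strength_profiles`: `signals`, `folds`, `classes`
#'   (see [classify_strength()]), `responsiveness`, `matrix`.
#' @export
quantify_strengths <- function(plate, reference = "P_GPD1",
                               thresholds = c(0.1, 0.5, 2, 5),
                               phases = c("logarithmic", "stationary")) {
  signals <- summarize_plate(plate)
  folds <- relative_strength(signals, reference)
  classes <- classify_strength(folds, thresholds)
  resp <- if (all(phases %in% folds$phase))
    responsiveness(folds, phases) else NULL
  out <- list(signals = signals, folds = classes$per_condition,
              classes = classes$overall, responsiveness = resp,
              matrix = strength_matrix(folds))
  class(out) <- "strength_profiles"
  out
}

#' @export
print.strength_profiles <- function(x, ...) {
  cat("strength_profiles:", nrow(x$classes), "promoters x",
      ncol(x$matrix), "conditions\n")
  print(table(factor(x$classes$overall_class, levels = STRENGTH_CLASSES)))
  rng <- range(x$folds$fold[x$folds$detected], na.rm = TRUE)
  cat(sprintf("  detected fold span: %.3g - %.3g\n", rng[1], rng[2]))
  invisible(x)
}
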