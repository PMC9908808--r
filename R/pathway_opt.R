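#' Enumerate all ordered promoter pairs for a two-gene pathway
#'
#' All ordered pairs with repetition (a promoter may drive both genes), in
#' deterministic pool order with the first gene's promoter varying slowest.
#'
#' @param pool character vector of promoter ids.
#' @param genes the two pathway genes (names of the design columns).
#' @return data frame: `design_id`, `promoter_<gene1>`, `promoter_<gene2>`.
#' @export
#' @examples
#' nrow(enumerate_designs(c("A", "B")))  # 4
enumerate_designs <- function(pool, genes = c("FAD9", "FAD12")) {
  if (length(pool) < 1L) stop("promoter pool is empty", call. = FALSE)
  stopifnot(length(genes) == 2L)
  grid <- expand.grid(p2 = pool, p1 = pool, stringsAsFactors = FALSE)
  res <- data.frame(design_id = sprintf("D%02d", seq_len(nrow(grid))),
                    p1 = grid$p1, p2 = grid$p2, stringsAsFactors = FALSE)
  names(res)[2:3] <- paste0("promoter_", tolower(genes))
  res
}

#' Bottleneck-limited pathway score for a promoter pair
#'
#' `score = min(sat(f1), sat(f2))` with `sat(f) = f / (f + K)`: a two-step
#' sequential pathway is limited by its weaker step, and each step
#' saturates in promoter strength. Monotone non-decreasing in each fold and
#' bounded in [0, 1).
#'
#' @param f1,f2 fold strengths of the two promoters (vectors recycle).
#' @param K half-saturation fold (default 1).
#' @return numeric score(s).
#' @export
predict_score <- function(f1, f2, K = 1) {
  if (any(is.na(f1)) || any(is.na(f2)))
    stop("missing fold for a design promoter", call. = FALSE)
  if (any(f1 < 0) || any(f2 < 0)) stop("folds must be >= 0", call. = FALSE)
  sat <- function(f) f / (f + K)
  pmin(sat(f1), sat(f2))
}

#' Score designs from a strength matrix
#'
#' Looks up each design promoter's fold in the given medium and phase
#' (logarithmic phase by default: expression during growth drives desaturase
#' levels) and applies [predict_score()].
#'
#' @param designs an [enumerate_designs()] data frame (first promoter column
#'   drives the first gene).
#' @param strength_mat a [strength_matrix()] result.
#' @param medium,phase condition whose folds feed the score.
#' @param K half-saturation fold.
#' @return `designs` with a `predicted_score` column.
#' @export
score_designs <- function(designs, strength_mat, medium,
                          phase = "logarithmic", K = 1) {
  key <- cond_key(medium, phase)
  if (!key %in% colnames(strength_mat))
    stop(sprintf("condition '%s' not in the strength matrix", key),
         call. = FALSE)
  pcols <- grep("^promoter_", names(designs), value = TRUE)
  stopifnot(length(pcols) == 2L)
  proms <- unique(unlist(designs[pcols]))
  unknown <- setdiff(proms, rownames(strength_mat))
  if (length(unknown))
    stop("promoter(s) missing from the strength matrix: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  f1 <- strength_mat[designs[[pcols[1]]], key]
  f2 <- strength_mat[designs[[pcols[2]]], key]
  designs$predicted_score <- predict_score(f1, f2, K)
  designs
}

#' Percent titer improvement over a parental strain
#'
#' `100 * (engineered - parental) / parental`, reported to one decimal with
#' round-half-away-from-zero.
#'
#' @param engineered,parental titers in the same units; `parental` must be
#'   positive.
#' @return percent improvement, one decimal.
#' @export
#' @examples
#' percent_improvement(248.5, 79.08)  # 214.2
percent_improvement <- function(engineered, parental) {
  if (any(parental <= 0))
    stop("parental titer must be positive", call. = FALSE)
  p <- 100 * (engineered - parental) / parental
  sign(p) * floor(abs(p) * 10 + 0.5) / 10
}

#' Best design by measured C18:2 titer in one medium
#'
#' @param titers titer table (`strain_id`, `medium`, `c18_2_mg_per_l`, ...).
#' @param medium medium to rank within.
#' @return the maximal-titer row(s); ties are all reported, ordered by
#'   strain id.
#' @export
best_design <- function(titers, medium) {
  sub <- titers[titers$medium == medium, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop(sprintf("no measured designs in medium '%s'", medium),
         call. = FALSE)
  best <- sub[sub$c18_2_mg_per_l == max(sub$c18_2_mg_per_l), , drop = FALSE]
  best <- best[order(best$strain_id), , drop = FALSE]
  rownames(best) <- NULL
  best
}

#' Summarise mixed-sugar utilization
#'
#' Per sugar: the consumed fraction `1 - c(horizon)/c(0)` (linear
#' interpolation at the horizon) and the exhaustion time -- the first time
#' the concentration drops below `exhaustion_frac` of its initial value
#' (linearly interpolated between grid points; `Inf` if never). Sugars are
#' ordered by exhaustion time. The total consumed fraction over all sugars
#' is compared against `threshold`.
#'
#' @param series data frame with `time_h` (strictly increasing, starting at
#'   0) and one `<sugar>_g_l` column per sugar.
#' @param horizon_h evaluation horizon in hours (default 30).
#' @param threshold total consumed fraction to flag (default 0.8).
#' @param exhaustion_frac residual fraction defining exhaustion
#'   (default 0.05).
#' @return list: `per_sugar` (`sugar`, `initial_g_l`, `at_horizon_g_l`,
#'   `consumed_fraction`, `exhaustion_time_h`), `total_consumed_fraction`,
#'   `meets_threshold`, `exhaustion_order`.
#' @export
sugar_summary <- function(series, horizon_h = 30, threshold = 0.8,
                          exhaustion_frac = 0.05) {
  t <- series$time_h
  if (is.unsorted(t, strictly = TRUE))
    stop("time grid must be strictly increasing", call. = FALSE)
  if (t[1] > 0 || max(t) < horizon_h)
    stop("series must cover t = 0 through the horizon", call. = FALSE)
  sugar_cols <- setdiff(names(series), "time_h")
  rows <- list(); totals0 <- 0; totals_h <- 0
  for (col in sugar_cols) {
    c0 <- series[[col]][t == 0]
    sugar <- sub("_g_l$", "", col)
    if (c0 == 0) {
      warning(sprintf("sugar '%s' has zero initial concentration; skipped",
                      sugar), call. = FALSE)
      next
    }
    ch <- approx(t, series[[col]], xout = horizon_h)$y
    thr <- exhaustion_frac * c0
    below <- which(series[[col]] < thr)
    ex_t <- if (!length(below)) Inf else {
      i <- below[1]
      if (i == 1L) t[1] else {
        # linear crossing between the bracketing grid points
        t[i - 1L] + (t[i] - t[i - 1L]) *
          (series[[col]][i - 1L] - thr) /
          (series[[col]][i - 1L] - series[[col]][i])
      }
    }
    totals0 <- totals0 + c0
    totals_h <- totals_h + ch
    rows[[length(rows) + 1L]] <- data.frame(
      sugar = sugar, initial_g_l = c0, at_horizon_g_l = ch,
      consumed_fraction = 1 - ch / c0, exhaustion_time_h = ex_t,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no sugars with nonzero initial concentration",
                          call. = FALSE)
  per_sugar <- do.call(rbind, rows)
  rownames(per_sugar) <- NULL
  total_frac <- 1 - totals_h / totals0
  list(per_sugar = per_sugar,
       total_consumed_fraction = total_frac,
       meets_threshold = total_frac >= threshold,
       exhaustion_order =
         per_sugar$sugar[order(per_sugar$exhaustion_time_h)])
}
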