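#' The fixed reporter head sequence
#'
#' The first 22 bp of the EGFP coding sequence, the window analysed for
#' cryptic splice acceptors at the promoter-reporter junction. It contains
#' `AG|G` acceptor trigrams, so any promoter contributing a `G|GT` donor near
#' its 3' end forms a potential cryptic intron across the junction.
#'
#' @return a 22-character nucleotide string.
#' @export
egfp_head <- function() "ATGGTGAGCAAGGGCGAGGAGC"

#' Find all occurrences of a nucleotide motif
#'
#' Forward-strand scan for a (possibly degenerate IUPAC) pattern, reporting
#' every match start position -- overlapping matches included -- as 1-based
#' offsets in ascending order.
#'
#' @param sequence nucleotide string (promoter sequences are already
#'   transcript-oriented, so only the forward strand is scanned).
#' @param pattern non-empty IUPAC nucleotide string (e.g. `"CAAT"`,
#'   `"GGGCGGG"`, `"YYYY"`).
#' @return integer vector of 1-based match start positions.
#' @export
#' @examples
#' find_motif("GGGCGGGCGGG", "GGGCGGG")  # 1 5 (overlapping)
find_motif <- function(sequence, pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || !nzchar(pattern))
    stop("pattern must be a non-empty string", call. = FALSE)
  bad <- setdiff(strsplit(toupper(pattern), "")[[1]],
                 names(Biostrings::IUPAC_CODE_MAP))
  if (length(bad))
    stop("invalid IUPAC character(s) in pattern: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  if (nchar(sequence) < nchar(pattern)) return(integer(0))
  m <- Biostrings::matchPattern(toupper(pattern),
                                Biostrings::DNAString(toupper(sequence)),
                                fixed = FALSE)
  sort(Biostrings::start(m))
}

#' Scan a promoter for CAAT motif and GC box occurrences
#'
#' @param sequence promoter nucleotide string (transcript-oriented).
#' @param caat_pattern motif scanned as the CAAT element (IUPAC accepted);
#'   the literal tetramer by default.
#' @param gc_pattern motif scanned as the GC box; the literal heptamer
#'   `GGGCGGG` by default.
#' @return list with integer vectors `caat_positions` and
#'   `gc_box_positions` (1-based).
#' @export
scan_elements <- function(sequence, caat_pattern = "CAAT",
                          gc_pattern = "GGGCGGG") {
  if (!nzchar(sequence)) stop("empty promoter sequence", call. = FALSE)
  list(caat_positions = find_motif(sequence, caat_pattern),
       gc_box_positions = find_motif(sequence, gc_pattern))
}

#' Scan for a pyrimidine-rich CT box upstream of the start codon
#'
#' The promoter sequence ends immediately before the start codon, so offset
#' `-k` denotes the k-th base from its 3' end. A window of `win_len` bp
#' slides across the region `window_start..window_end` (default -90..-10,
#' both inclusive); the window with the maximal C+T fraction is reported and
#' the CT box is called found when that fraction reaches `min_fraction`.
#' Promoters shorter than the region are scanned over the available range
#' and flagged.
#'
#' @param sequence promoter string ending immediately before the ATG.
#' @param window_start,window_end scan region as negative offsets from the
#'   start codon.
#' @param min_fraction C+T fraction needed to call the box (default 0.6).
#' @param win_len sliding window length in bp (default 20).
#' @return list: `found`, `best_fraction`, `best_window` (named numeric,
#'   `from`/`to` offsets from the start codon), `truncated_scan`.
#' @export
ct_box_scan <- function(sequence, window_start = -90L, window_end = -10L,
                        min_fraction = 0.6, win_len = 20L) {
  if (!nzchar(sequence)) stop("empty promoter sequence", call. = FALSE)
  stopifnot(window_start < window_end, window_end <= -1L, win_len >= 1L)
  L <- nchar(sequence)
  # offset -k maps to string index L - k + 1
  i_from <- L + window_start + 1L
  i_to <- L + window_end + 1L
  truncated <- FALSE
  if (i_from < 1L) { i_from <- 1L; truncated <- TRUE }
  if (i_to < 1L)
    stop("promoter too short for the requested scan region", call. = FALSE)
  region <- strsplit(substr(sequence, i_from, i_to), "")[[1]]
  is_py <- as.integer(region %in% c("C", "T"))
  w <- min(win_len, length(is_py))
  if (w < win_len) truncated <- TRUE
  cs <- cumsum(c(0L, is_py))
  starts <- seq_len(length(is_py) - w + 1L)
  frac <- (cs[starts + w] - cs[starts]) / w
  best <- which.max(frac)  # leftmost on ties
  s_idx <- i_from + starts[best] - 1L
  e_idx <- s_idx + w - 1L
  list(found = frac[best] >= min_fraction,
       best_fraction = unname(frac[best]),
       best_window = c(from = -(L - s_idx + 1L), to = -(L - e_idx + 1L)),
       truncated_scan = truncated)
}

#' Flag cryptic splice-site risk across the promoter-reporter junction
#'
#' Forms the junction string from the last `junction_depth` bp of the
#' promoter followed by the reporter head, then flags risk iff a splice
#' donor `G|GT` (literal trigram `GGT`) starts within the promoter portion
#' and a splice acceptor `AG|G` (literal trigram `AGG`) starts downstream of
#' that donor anywhere in the junction. The 5'-most qualifying donor and its
#' nearest downstream acceptor are reported: the donor as an offset from the
#' promoter 3' end (1 = last promoter base) and the acceptor relative to the
#' reporter head 5' end (1 = first head base; values <= 0 fall inside the
#' promoter tail).
#'
#' @param promoter promoter nucleotide string (non-empty).
#' @param reporter_head downstream reporter sequence (default [egfp_head()];
#'   must be at least 3 bp).
#' @param junction_depth how many promoter 3'-end bases to search
#'   (default 25).
#' @return list: `risk`, `donor_offset_from_3prime`, `acceptor_offset_in_head`.
#' @export
splice_risk <- function(promoter, reporter_head = egfp_head(),
                        junction_depth = 25L) {
  if (!is.character(promoter) || !nzchar(promoter))
    stop("empty promoter sequence", call. = FALSE)
  if (nchar(reporter_head) < 3L)
    stop("reporter head must be at least 3 bp", call. = FALSE)
  P <- min(junction_depth, nchar(promoter))
  tail_seq <- substr(promoter, nchar(promoter) - P + 1L, nchar(promoter))
  junction <- paste0(tail_seq, reporter_head)
  trigram_at <- function(tri) {
    n <- nchar(junction) - 2L
    if (n < 1L) return(integer(0))
    starts <- seq_len(n)
    hits <- vapply(starts, function(i)
      substr(junction, i, i + 2L) == tri, logical(1))
    starts[hits]
  }
  donors <- trigram_at("GGT")
  donors <- donors[donors <= P]  # exonic G must lie within the promoter
  acceptors <- trigram_at("AGG")
  res <- list(risk = FALSE, donor_offset_from_3prime = NA_integer_,
              acceptor_offset_in_head = NA_integer_)
  for (d in donors) {
    after <- acceptors[acceptors > d]
    if (length(after)) {
      res$risk <- TRUE
      res$donor_offset_from_3prime <- P - d + 1L
      res$acceptor_offset_in_head <- after[1] - P
      break
    }
  }
  res
}

#' Build the full motif report for a set of promoters
#'
#' Runs [scan_elements()], [ct_box_scan()], and [splice_risk()] on every
#' promoter and returns one row per promoter.
#'
#' @param promoters data frame with `promoter_id` and `sequence` (as from
#'   [extract_promoters()]).
#' @param reporter_head see [splice_risk()].
#' @param caat_pattern,gc_pattern see [scan_elements()].
#' @param ct_min_fraction,ct_win_len see [ct_box_scan()].
#' @param junction_depth see [splice_risk()].
#' @return data frame: per-promoter motif counts, comma-joined positions,
#'   CT-box fraction/window, and the splice-risk flag with its offsets.
#' @export
scan_promoters <- function(promoters, reporter_head = egfp_head(),
                           caat_pattern = "CAAT", gc_pattern = "GGGCGGG",
                           ct_min_fraction = 0.6, ct_win_len = 20L,
                           junction_depth = 25L) {
  rows <- lapply(seq_len(nrow(promoters)), function(i) {
    s <- promoters$sequence[i]
    el <- scan_elements(s, caat_pattern, gc_pattern)
    ct <- ct_box_scan(s, min_fraction = ct_min_fraction,
                      win_len = ct_win_len)
    sp <- splice_risk(s, reporter_head, junction_depth)
    data.frame(
      promoter_id = promoters$promoter_id[i],
      n_caat = length(el$caat_positions),
      caat_positions = paste(el$caat_positions, collapse = ","),
      n_gc_box = length(el$gc_box_positions),
      gc_box_positions = paste(el$gc_box_positions, collapse = ","),
      ct_box_found = ct$found,
      ct_best_fraction = ct$best_fraction,
      ct_window_from = ct$best_window[["from"]],
      ct_window_to = ct$best_window[["to"]],
      splice_risk = sp$risk,
      donor_offset_from_3prime = sp$donor_offset_from_3prime,
      acceptor_offset_in_head = sp$acceptor_offset_in_head,
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
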