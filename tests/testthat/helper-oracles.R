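# Independent brute-force oracles. These deliberately avoid the package's
# implementation paths (Biostrings, cumulative sums, vectorised scans).

# naive one-line slice / reverse-complement upstream extraction
oracle_upstream <- function(contig, strand, cds_start, len) {
  if (strand == "+") {
    substr(contig, max(1, cds_start - len), cds_start - 1)
  } else {
    s <- substr(contig, cds_start + 1, min(nchar(contig), cds_start + len))
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
}

iupac_regex <- function(pattern) {
  map <- Biostrings::IUPAC_CODE_MAP
  paste(vapply(strsplit(pattern, "")[[1]], function(ch) {
    alt <- map[[ch]]
    if (nchar(alt) == 1) alt else paste0("[", alt, "]")
  }, character(1)), collapse = "")
}

# regex-with-lookahead scan: overlapping forward-strand matches, 1-based
oracle_motif_regex <- function(sequence, pattern) {
  rx <- paste0("(?=", iupac_regex(pattern), ")")
  m <- gregexpr(rx, sequence, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

# exhaustive enumeration of all CT-box windows
oracle_ct_best <- function(sequence, window_start = -90, window_end = -10,
                           win_len = 20) {
  L <- nchar(sequence)
  i_from <- max(1, L + window_start + 1)
  i_to <- L + window_end + 1
  chars <- strsplit(sequence, "")[[1]]
  w <- min(win_len, i_to - i_from + 1)
  best_frac <- -1; best_from <- NA
  for (s in i_from:(i_to - w + 1)) {
    frac <- mean(chars[s:(s + w - 1)] %in% c("C", "T"))
    if (frac > best_frac) { best_frac <- frac; best_from <- s }
  }
  list(fraction = best_frac,
       window = c(from = -(L - best_from + 1),
                  to = -(L - (best_from + w - 1) + 1)))
}

# brute force over all (donor, acceptor) index pairs in the junction
oracle_splice <- function(promoter, head, depth = 25) {
  P <- min(depth, nchar(promoter))
  junction <- paste0(substr(promoter, nchar(promoter) - P + 1,
                            nchar(promoter)), head)
  n <- nchar(junction)
  for (d in seq_len(max(0, n - 2))) {
    if (substr(junction, d, d + 2) != "GGT" || d > P) next
    for (a in seq_len(max(0, n - 2))) {
      if (a > d && substr(junction, a, a + 2) == "AGG") return(TRUE)
    }
  }
  FALSE
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
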