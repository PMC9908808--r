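#' Rank the top-expressed genes in one condition
#'
#' Returns the `n` genes with the highest abundance in the given
#' (medium, phase) condition, in descending order. Ties are broken by
#' `gene_id` ascending, which is deterministic and data-independent. If `n`
#' is at least the number of genes, all genes are returned.
#'
#' @param expr long expression data frame (`gene_id`, `medium`, `phase`,
#'   `abundance`), one abundance per gene per condition.
#' @param medium,phase the condition to rank.
#' @param n how many genes to return.
#' @return character vector of gene ids, strongest first.
#' @export
#' @examples
#' expr <- data.frame(gene_id = c("g1", "g2", "g3"), medium = "YPD",
#'                    phase = "logarithmic", abundance = c(5, 9, 1))
#' rank_top_genes(expr, "YPD", "logarithmic", 2)  # "g2" "g1"
rank_top_genes <- function(expr, medium, phase, n = 15L) {
  stopifnot(n >= 1L)
  sub <- expr[expr$medium == medium & expr$phase == phase, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop(sprintf("condition (%s, %s) not present in the expression matrix",
                 medium, phase), call. = FALSE)
  if (any(sub$abundance < 0))
    stop("negative abundances are not allowed", call. = FALSE)
  ord <- order(-sub$abundance, sub$gene_id)
  head(sub$gene_id[ord], n)
}

#' Merge per-condition top-gene lists into a deduplicated candidate set
#'
#' Each gene appears once; its provenance is the set of conditions in which
#' it ranked. Output is ordered by number of supporting conditions
#' (descending) then gene id (ascending) for reproducibility.
#'
#' @param per_condition_lists named list, condition label -> character vector
#'   of gene ids.
#' @return data frame: `gene_id`, `n_conditions`, `provenance`
#'   (comma-joined condition labels in input order).
#' @export
merge_candidates <- function(per_condition_lists) {
  if (is.null(names(per_condition_lists)) ||
      any(!nzchar(names(per_condition_lists))))
    stop("every list must be named by its condition", call. = FALSE)
  prov <- list()
  for (cond in names(per_condition_lists)) {
    for (g in per_condition_lists[[cond]])
      prov[[g]] <- c(prov[[g]], cond)
  }
  genes <- names(prov)
  res <- data.frame(
    gene_id = genes,
    n_conditions = vapply(prov, length, integer(1)),
    provenance = vapply(prov, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE, row.names = NULL)
  res <- res[order(-res$n_conditions, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Mine promoter candidates from an expression matrix
#'
#' Convenience wrapper: ranks the top `top_n` genes in every condition found
#' in `expr` and merges the lists with [merge_candidates()].
#'
#' @inheritParams rank_top_genes
#' @param top_n genes taken per condition.
#' @return the [merge_candidates()] data frame.
#' @export
mine_candidates <- function(expr, top_n = 15L) {
  conds <- unique(expr[, c("medium", "phase")])
  lists <- list()
  for (k in seq_len(nrow(conds))) {
    key <- cond_key(conds$medium[k], conds$phase[k])
    lists[[key]] <- rank_top_genes(expr, conds$medium[k], conds$phase[k],
                                   top_n)
  }
  merge_candidates(lists)
}

#' Extract the upstream promoter window of one gene
#'
#' Takes the `length` bp immediately upstream of the translational start
#' codon, on the gene's coding strand: for a plus-strand gene the genomic
#' slice `[cds_start - length, cds_start - 1]` (1-based inclusive) as-is; for
#' a minus-strand gene the slice `[cds_start + 1, cds_start + length]`
#' reverse-complemented. The returned sequence therefore reads 5'->3' on the
#' coding strand and ends immediately before the ATG, so concatenating it
#' with the coding sequence reconstructs a contiguous transcript-oriented
#' string. A window that runs off the contig edge is truncated to the
#' available portion and flagged; a gene whose start codon sits at the very
#' contig edge (zero upstream bases) is an error.
#'
#' @param genome named character vector (or `DNAStringSet`) of contig
#'   sequences.
#' @param gene a list or one-row data frame with `contig`, `strand`,
#'   `cds_start` (1-based genomic coordinate of the first base of the start
#'   codon).
#' @param length requested window length in bp (default 1000).
#' @return list with `sequence`, `length`, `truncated`.
#' @export
#' @examples
#' g <- list(contig = "c", strand = "+", cds_start = 10)
#' extract_upstream(c(c = "AAACCCGGGTTT"), g, length = 3)$sequence  # "GGG"
extract_upstream <- function(genome, gene, length = 1000L) {
  if (methods::is(genome, "DNAStringSet"))
    genome <- setNames(as.character(genome), names(genome))
  if (!gene$contig %in% names(genome))
    stop(sprintf("contig '%s' not present in genome", gene$contig),
         call. = FALSE)
  stopifnot(gene$strand %in% c("+", "-"), length >= 1L)
  contig <- genome[[gene$contig]]
  clen <- nchar(contig)
  cds <- as.integer(gene$cds_start)
  if (cds < 1L || cds > clen)
    stop("cds_start outside contig bounds", call. = FALSE)
  if (gene$strand == "+") {
    to <- cds - 1L
    if (to < 1L)
      stop("gene has zero upstream bases (start codon at contig edge)",
           call. = FALSE)
    from <- max(1L, cds - length)
    seq <- substr(contig, from, to)
    truncated <- (cds - length) < 1L
  } else {
    from <- cds + 1L
    if (from > clen)
      stop("gene has zero upstream bases (start codon at contig edge)",
           call. = FALSE)
    to <- min(clen, cds + length)
    seq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(contig, from, to))))
    truncated <- (cds + length) > clen
  }
  list(sequence = seq, length = nchar(seq), truncated = truncated)
}

#' Extract promoter windows for a set of genes
#'
#' Vectorised [extract_upstream()] over an annotation table. Windows are
#' fixed-length regardless of overlap with a neighbouring gene (a warning
#' reports how many windows overlap another gene body).
#'
#' @param genome named character vector or `DNAStringSet`.
#' @param genes annotation data frame with `gene_id`, `contig`, `strand`,
#'   `start`, `end`, `cds_start`.
#' @param length window length in bp.
#' @return data frame: `promoter_id` (`P_<gene_id>`), `gene_id`, `length`,
#'   `truncated`, `sequence`.
#' @export
extract_promoters <- function(genome, genes, length = 1000L) {
  if (methods::is(genome, "DNAStringSet"))
    genome <- setNames(as.character(genome), names(genome))
  n_overlap <- 0L
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    up <- extract_upstream(genome, g, length)
    win <- if (g$strand == "+")
      c(max(1L, g$cds_start - length), g$cds_start - 1L)
    else
      c(g$cds_start + 1L, min(nchar(genome[[g$contig]]), g$cds_start + length))
    other <- genes[-i, , drop = FALSE]
    other <- other[other$contig == g$contig, , drop = FALSE]
    if (nrow(other) && any(other$start <= win[2] & other$end >= win[1]))
      n_overlap <- n_overlap + 1L
    out[[i]] <- data.frame(promoter_id = paste0("P_", g$gene_id),
                           gene_id = g$gene_id, length = up$length,
                           truncated = up$truncated, sequence = up$sequence,
                           stringsAsFactors = FALSE)
  }
  if (n_overlap > 0L)
    warning(sprintf("%d upstream window(s) overlap a neighbouring gene body",
                    n_overlap), call. = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Screening-cascade ledger
#'
#' Bookkeeping of the candidate filter cascade: selected -> amplified ->
#' fluorescent. Derived counts follow
#' `assayed = candidates - clone_fail`,
#' `strong = assayed - null - weak`,
#' `strong_incl_controls = strong + controls`; inconsistent inputs (any
#' negative derived count) are refused.
#'
#' @param n_candidates,n_clone_fail,n_null,n_weak,n_controls non-negative
#'   counts. Cloning failure is an experimental input label, not a computed
#'   property.
#' @return object of class `screening_ledger` with fields `n_candidates`,
#'   `n_clone_fail`, `n_assayed`, `n_null`, `n_weak`, `n_strong`,
#'   `n_controls`, `n_strong_incl_controls`.
#' @export
#' @examples
#' screening_ledger(52, 3, 11, 7, 3)  # 49 assayed, 31 strong, 34 incl controls
screening_ledger <- function(n_candidates, n_clone_fail = 0L, n_null = 0L,
                             n_weak = 0L, n_controls = 0L) {
  counts <- c(n_candidates, n_clone_fail, n_null, n_weak, n_controls)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("all counts must be non-negative integers", call. = FALSE)
  n_assayed <- n_candidates - n_clone_fail
  if (n_assayed < 0)
    stop("inconsistent counts: clone failures exceed candidates",
         call. = FALSE)
  n_strong <- n_assayed - n_null - n_weak
  if (n_strong < 0)
    stop("inconsistent counts: null + weak exceed assayed promoters",
         call. = FALSE)
  out <- list(n_candidates = as.integer(n_candidates),
              n_clone_fail = as.integer(n_clone_fail),
              n_assayed = as.integer(n_assayed),
              n_null = as.integer(n_null), n_weak = as.integer(n_weak),
              n_strong = as.integer(n_strong),
              n_controls = as.integer(n_controls),
              n_strong_incl_controls = as.integer(n_strong + n_controls))
  class(out) <- "screening_ledger"
  out
}

#' @export
print.screening_ledger <- function(x, ...) {
  cat(sprintf(paste0("screening ledger: %d candidates | %d clone-fail -> ",
                     "%d assayed | %d null + %d very weak -> %d strong ",
                     "(+%d controls = %d)\n"),
              x$n_candidates, x$n_clone_fail, x$n_assayed, x$n_null,
              x$n_weak, x$n_strong, x$n_controls, x$n_strong_incl_controls))
  invisible(x)
}
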