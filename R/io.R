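#' Write contig sequences as FASTA
#'
#' @param genome named character vector of contig sequences.
#' @param path output file; 60-column wrapped.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path,
                              width = 60L)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file.
#' @return named character vector (first whitespace token of each header
#'   used as the name).
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write gene models as GFF3
#'
#' One `gene` feature per row, 1-based inclusive coordinates, with `ID` and
#' `cds_start` attributes; contig lengths are recorded so coordinate bounds
#' survive the round trip.
#'
#' @param genes annotation data frame (`gene_id`, `contig`, `strand`,
#'   `start`, `end`, `cds_start`).
#' @param genome named character vector supplying contig lengths.
#' @param path output file.
#' @export
write_annotation_gff3 <- function(genes, genome, path) {
  si <- GenomeInfoDb::Seqinfo(seqnames = names(genome),
                               seqlengths = nchar(genome))
  gr <- GenomicRanges::GRanges(
    seqnames = factor(genes$contig, levels = names(genome)),
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand, seqinfo = si)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "promotermine", type = "gene", ID = genes$gene_id,
    cds_start = genes$cds_start)
  rtracklayer::export(gr, path, format = "gff3")
  # drop the run-date header line so identical configs give identical bytes
  lines <- readLines(path)
  writeLines(lines[!startsWith(lines, "##date")], path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' @param path GFF3 file with `gene` features carrying `ID` and `cds_start`
#'   attributes.
#' @return annotation data frame (`gene_id`, `contig`, `strand`, `start`,
#'   `end`, `cds_start`).
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  data.frame(gene_id = S4Vectors::mcols(gr)$ID,
             contig = as.character(GenomicRanges::seqnames(gr)),
             strand = as.character(GenomicRanges::strand(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             cds_start = as.integer(S4Vectors::mcols(gr)$cds_start),
             stringsAsFactors = FALSE)
}

#' Write promoter sequences as FASTA
#'
#' @param promoters data frame with `promoter_id` and `sequence`.
#' @param path output file.
#' @export
write_promoters_fasta <- function(promoters, path) {
  write_genome_fasta(setNames(promoters$sequence, promoters$promoter_id),
                     path)
}

# deterministic short hash of an R object (config fingerprinting)
config_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(x), tmp)
  unname(substr(tools::md5sum(tmp), 1, 8))
}

#' Write a stage TSV with a provenance header
#'
#' Plain tab-separated values preceded by `#` comment lines recording the
#' package version, seed, and config fingerprint, so every intermediate is
#' greppable and reproducibility-stamped. No timestamps: identical runs
#' produce byte-identical files.
#'
#' @param df data frame to write.
#' @param path output file.
#' @param seed integer seed recorded in the header.
#' @param hash config fingerprint recorded in the header.
#' @export
write_stage_tsv <- function(df, path, seed = NA, hash = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# promotermine %s | seed=%s | config=%s",
                     as.character(utils::packageVersion("promotermine")),
                     seed, hash), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a stage TSV (skipping `#` header comments)
#'
#' @param path file written by [write_stage_tsv()].
#' @return data frame.
#' @export
read_stage_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
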