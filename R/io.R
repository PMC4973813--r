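#' Read / write FASTA sequence sets
#'
#' Thin wrappers over Biostrings keeping sequences as named character
#' vectors, the representation used throughout the package.
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write a synthetic reference as FASTA + GFF3
#'
#' @param ref a `synthetic_reference` from [make_reference()].
#' @param fasta_path,gff_path output paths.
#' @export
write_reference <- function(ref, fasta_path, gff_path) {
  write_fasta(ref$sequences, fasta_path)
  genes <- GenomicRanges::GRanges(
    ref$genes$chrom,
    IRanges::IRanges(ref$genes$start, ref$genes$end),
    strand = ref$genes$strand,
    type = "gene", ID = ref$genes$gene_id, Note = ref$genes$annotation)
  gex <- ref$genes[match(ref$exons$gene_id, ref$genes$gene_id), ]
  exons <- GenomicRanges::GRanges(
    gex$chrom, IRanges::IRanges(ref$exons$start, ref$exons$end),
    strand = gex$strand, type = "exon",
    ID = paste0(ref$exons$gene_id, ".exon",
                stats::ave(seq_len(nrow(ref$exons)), ref$exons$gene_id,
                           FUN = seq_along)),
    Parent = ref$exons$gene_id)
  rtracklayer::export(c(genes, exons), gff_path, format = "gff3")
  invisible(gff_path)
}

#' Read gene models from a GFF3 annotation
#'
#' Collects `gene` features (id, span, strand, free-text annotation
#' from the Note attribute) and their `exon` children.
#'
#' @param path GFF3 file path.
#' @return list with `genes` (gene_id, chrom, start, end, strand,
#'   annotation) and `exons` (gene_id, start, end), coordinates 1-based
#'   inclusive.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gt <- gr[gr$type == "gene"]
  genes <- data.frame(
    gene_id = gt$ID,
    chrom = as.character(GenomicRanges::seqnames(gt)),
    start = GenomicRanges::start(gt), end = GenomicRanges::end(gt),
    strand = as.character(GenomicRanges::strand(gt)),
    annotation = if (!is.null(gt$Note))
      vapply(gt$Note, function(x) paste(x, collapse = " "), "")
    else NA_character_,
    stringsAsFactors = FALSE)
  et <- gr[gr$type == "exon"]
  exons <- data.frame(
    gene_id = vapply(et$Parent, `[`, "", 1L),
    start = GenomicRanges::start(et), end = GenomicRanges::end(et),
    stringsAsFactors = FALSE)
  exons <- exons[order(exons$gene_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  list(genes = genes, exons = exons)
}

#' Write a hit table in 12-column tabular format
#'
#' @param hits hit data.frame in the [parse_hits()] layout.
#' @param path output path.
#' @export
write_hits <- function(hits, path) {
  cols <- c("query_id", "subject_id", "percent_identity",
            "alignment_length", "mismatches", "gap_opens", "query_start",
            "query_end", "subject_start", "subject_end", "e_value",
            "bit_score")
  write.table(hits[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
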