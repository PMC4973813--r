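#' Parse tabular homology-search hits
#'
#' Reads the standard 12-column tabular output of nucleotide homology
#' search tools (query, subject, percent identity, alignment length,
#' mismatches, gap opens, query start/end, subject start/end, E-value,
#' bit score). Lines starting with `#` are skipped. A subject interval
#' with start greater than end encodes a minus-strand match; coordinates
#' are kept 1-based inclusive as in the file.
#'
#' @param x a file path, or a character vector of hit lines.
#' @return A data.frame with columns `query_id`, `subject_id`,
#'   `percent_identity`, `alignment_length`, `mismatches`, `gap_opens`,
#'   `query_start`, `query_end`, `subject_start`, `subject_end`,
#'   `e_value`, `bit_score`, `strand` (`"+"`/`"-"`).
#' @export
parse_hits <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 12L)
  if (length(bad) > 0L)
    abort("line %d: expected >=12 fields, got %d", bad[1L],
          length(fields[[bad[1L]]]))
  m <- do.call(rbind, lapply(fields, function(f) f[1:12]))
  num <- function(j) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v))
      abort("line %d: field %d is not numeric ('%s')",
            which(is.na(v))[1L], j, m[which(is.na(v))[1L], j])
    v
  }
  hits <- data.frame(
    query_id = m[, 1L], subject_id = m[, 2L],
    percent_identity = num(3L), alignment_length = as.integer(num(4L)),
    mismatches = as.integer(num(5L)), gap_opens = as.integer(num(6L)),
    query_start = as.integer(num(7L)), query_end = as.integer(num(8L)),
    subject_start = as.integer(num(9L)), subject_end = as.integer(num(10L)),
    e_value = num(11L), bit_score = num(12L),
    stringsAsFactors = FALSE
  )
  hits$strand <- ifelse(hits$subject_start > hits$subject_end, "-", "+")
  if (any(hits$alignment_length < 1L))
    abort("line %d: alignment length < 1", which(hits$alignment_length < 1L)[1L])
  if (any(hits$e_value < 0))
    abort("line %d: negative E-value", which(hits$e_value < 0)[1L])
  hits
}

empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             percent_identity = numeric(), alignment_length = integer(),
             mismatches = integer(), gap_opens = integer(),
             query_start = integer(), query_end = integer(),
             subject_start = integer(), subject_end = integer(),
             e_value = numeric(), bit_score = numeric(),
             strand = character(), stringsAsFactors = FALSE)
}

# Filter hits on HSP length / E-value and collapse multiple HSPs between
# the same query/subject to the single best HSP (lowest E, then highest
# bit score). The length threshold applies to that HSP, not a sum.
qualify_hits <- function(hits, min_len, max_e) {
  hits <- hits[hits$alignment_length >= min_len & hits$e_value <= max_e, ,
               drop = FALSE]
  if (nrow(hits) == 0L) return(hits)
  o <- order(hits$query_id, hits$subject_id, hits$e_value, -hits$bit_score)
  hits <- hits[o, , drop = FALSE]
  keep <- !duplicated(hits[, c("query_id", "subject_id")])
  hits[keep, , drop = FALSE]
}

# Per query: the unique best subject, or NA when the top (E, bit score)
# is shared by more than one subject ("unique" fails on residual ties).
unique_best_subject <- function(hits) {
  if (nrow(hits) == 0L)
    return(data.frame(query_id = character(), subject_id = character(),
                      stringsAsFactors = FALSE))
  o <- order(hits$query_id, hits$e_value, -hits$bit_score)
  hits <- hits[o, , drop = FALSE]
  res <- lapply(split(hits, hits$query_id), function(h) {
    top <- h[1L, ]
    tied <- h$e_value == top$e_value & h$bit_score == top$bit_score
    if (sum(tied) > 1L) return(NULL)
    data.frame(query_id = top$query_id, subject_id = top$subject_id,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(query_id = character(), subject_id = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Unique reciprocal best hits between two transcriptome assemblies
#'
#' A contig pair (a, b) is reported iff, after discarding HSPs shorter
#' than `min_len` or weaker than `max_e`, b is the unique best hit of a
#' in the A-vs-B search and a is the unique best hit of b in the B-vs-A
#' search. "Best" means lowest E-value, ties broken by highest bit
#' score; any residual tie disqualifies the contig.
#'
#' @param hits_ab,hits_ba hit tables from [parse_hits()] for the A-vs-B
#'   and B-vs-A searches.
#' @param min_len minimum HSP length in bases (default 100).
#' @param max_e maximum E-value (default 1e-30).
#' @return data.frame with columns `contig_a`, `contig_b`, sorted by
#'   `contig_a`.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba, min_len = 100,
                                 max_e = 1e-30) {
  ab <- unique_best_subject(qualify_hits(hits_ab, min_len, max_e))
  ba <- unique_best_subject(qualify_hits(hits_ba, min_len, max_e))
  if (nrow(ab) == 0L || nrow(ba) == 0L)
    return(data.frame(contig_a = character(), contig_b = character(),
                      stringsAsFactors = FALSE))
  back <- setNames(ba$subject_id, ba$query_id)
  keep <- !is.na(back[ab$subject_id]) & back[ab$subject_id] == ab$query_id
  out <- data.frame(contig_a = ab$query_id[keep],
                    contig_b = ab$subject_id[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$contig_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Chromosome number encoded in a reference gene identifier
#'
#' Gene identifiers of the form `MtXgYYYYYY` (Mt3.5 convention, e.g.
#' `Mt3g092840`) carry the chromosome number as the digit after "Mt".
#'
#' @param gene_id character vector of gene identifiers.
#' @return integer vector of chromosome numbers (1-8).
#' @export
gene_chromosome <- function(gene_id) {
  m <- regmatches(gene_id, regexec("^Mt([1-8])g[0-9]+$", gene_id))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad))
    abort("gene id '%s' does not match the MtXgYYYYYY pattern",
          gene_id[bad][1L])
  as.integer(vapply(m, `[`, "", 2L))
}

#' Anchor a reciprocal-best-hit contig pair to a single reference gene
#'
#' The pair is accepted iff, among hits qualifying on `min_len`/`max_e`,
#' each contig hits exactly one reference gene and both hit the same
#' gene. A contig with qualifying hits to more than one gene yields
#' `rejected` with reason `multi_gene`; a contig with no qualifying hit
#' yields reason `no_hit`.
#'
#' @param contig_a,contig_b the two contig identifiers.
#' @param hits_to_genes hit table of contigs vs the reference gene set.
#' @param min_len,max_e thresholds as in [reciprocal_best_hits()].
#' @return One-row data.frame: `contig_a`, `contig_b`,
#'   `reference_gene_id`, `reference_chromosome`, `status`
#'   (`"accepted"`/`"rejected"`), `reason` (NA when accepted),
#'   `orientation` (strand of contig_a's best hit on the gene).
#' @export
anchor_to_ortholog <- function(contig_a, contig_b, hits_to_genes,
                               min_len = 100, max_e = 1e-30) {
  q <- qualify_hits(hits_to_genes, min_len, max_e)
  reject <- function(reason) {
    data.frame(contig_a = contig_a, contig_b = contig_b,
               reference_gene_id = NA_character_,
               reference_chromosome = NA_integer_,
               status = "rejected", reason = reason,
               orientation = NA_character_, stringsAsFactors = FALSE)
  }
  ga <- q[q$query_id == contig_a, , drop = FALSE]
  gb <- q[q$query_id == contig_b, , drop = FALSE]
  if (nrow(ga) == 0L || nrow(gb) == 0L) return(reject("no_hit"))
  genes_a <- unique(ga$subject_id)
  genes_b <- unique(gb$subject_id)
  if (length(genes_a) > 1L || length(genes_b) > 1L)
    return(reject("multi_gene"))
  if (genes_a != genes_b) return(reject("multi_gene"))
  data.frame(contig_a = contig_a, contig_b = contig_b,
             reference_gene_id = genes_a,
             reference_chromosome = gene_chromosome(genes_a),
             status = "accepted", reason = NA_character_,
             orientation = ga$strand[1L], stringsAsFactors = FALSE)
}

#' Anchor all reciprocal-best-hit pairs
#'
#' Vectorised convenience wrapper around [anchor_to_ortholog()].
#'
#' @param pairs data.frame from [reciprocal_best_hits()].
#' @param hits_to_genes hit table of contigs vs the reference gene set.
#' @inheritParams anchor_to_ortholog
#' @return data.frame, one row per pair.
#' @export
anchor_pairs <- function(pairs, hits_to_genes, min_len = 100,
                         max_e = 1e-30) {
  out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    anchor_to_ortholog(pairs$contig_a[i], pairs$contig_b[i],
                       hits_to_genes, min_len, max_e)
  }))
  if (is.null(out)) out <- anchor_to_ortholog("x", "y", empty_hits())[0, ]
  out
}
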