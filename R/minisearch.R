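# Minimal exact-k-mer seeded, ungapped nucleotide search.
#
# This exists only so that synthetic fixtures are self-contained: it
# produces hit tables in the same 12-column shape as parse_hits() without
# shelling out to an external search engine. It assumes substitution-only
# divergence (which is what the synthetic transcriptome generator plants)
# and is NOT a general aligner. Real data should come from a standard
# search tool's tabular output.
#
# Scoring: ungapped +2 match / -3 mismatch; bit score = raw score;
# E-value = qlen * slen * 2^(-bit), a crude Karlin-Altschul stand-in that
# is monotone in score, which is all the downstream thresholds need.

seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character())
  substring(s, 1:(n - k + 1L), k:n)
}

best_diagonal_hit <- function(q, s, k) {
  qk <- seq_kmers(q, k)
  sk <- seq_kmers(s, k)
  m <- match(qk, sk)          # first occurrence is enough for seeding
  seeds <- which(!is.na(m))
  if (length(seeds) == 0L) return(NULL)
  diag <- m[seeds] - seeds     # spos - qpos
  d <- as.integer(names(sort(table(diag), decreasing = TRUE))[1L])
  # ungapped extension over the full overlap of that diagonal
  qlo <- max(1L, 1L - d); qhi <- min(nchar(q), nchar(s) - d)
  if (qhi - qlo + 1L < k) return(NULL)
  qc <- strsplit(substr(q, qlo, qhi), "")[[1L]]
  sc <- strsplit(substr(s, qlo + d, qhi + d), "")[[1L]]
  eq <- qc == sc
  # trim the ends to the outermost matching positions
  first <- which(eq)[1L]; last <- which(eq)[length(which(eq))]
  if (is.na(first)) return(NULL)
  eq <- eq[first:last]
  len <- length(eq)
  matches <- sum(eq)
  score <- 2 * matches - 3 * (len - matches)
  if (score <= 0) return(NULL)
  list(qstart = qlo + first - 1L, qend = qlo + last - 1L,
       sstart = qlo + d + first - 1L, send = qlo + d + last - 1L,
       len = len, matches = matches, score = score)
}

#' Exact k-mer seeded ungapped search over sequence sets
#'
#' Desk-scale stand-in for an external homology search, used to make
#' synthetic pipelines self-contained (see source for caveats). Reports
#' one best ungapped hit per query/subject pair that shares at least one
#' exact k-mer on the dominant diagonal and passes `min_len`.
#'
#' @param queries,subjects named character vectors of sequences.
#' @param k seed length (default 16).
#' @param min_len minimum reported hit length (default 40).
#' @return hit data.frame in the [parse_hits()] column layout.
#' @export
kmer_hits <- function(queries, subjects, k = 16, min_len = 40) {
  rows <- list()
  for (qi in names(queries)) {
    for (si in names(subjects)) {
      h <- best_diagonal_hit(queries[[qi]], subjects[[si]], k)
      if (is.null(h) || h$len < min_len) next
      e <- nchar(queries[[qi]]) * nchar(subjects[[si]]) * 2^(-h$score)
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = qi, subject_id = si,
        percent_identity = 100 * h$matches / h$len,
        alignment_length = h$len,
        mismatches = h$len - h$matches, gap_opens = 0L,
        query_start = h$qstart, query_end = h$qend,
        subject_start = h$sstart, subject_end = h$send,
        e_value = e, bit_score = h$score, strand = "+",
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty_hits())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
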