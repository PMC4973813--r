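IUPAC_OK <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N")

#' Optimal global alignment with affine gap penalties
#'
#' Needleman-Wunsch/Gotoh global alignment of two nucleotide sequences.
#' A gap of length k costs `gap_open + (k - 1) * gap_extend`. The
#' traceback is deterministic: ties prefer diagonal over a gap in
#' `seq_b` over a gap in `seq_a`.
#'
#' @param seq_a,seq_b non-empty nucleotide sequences (IUPAC characters).
#' @param match,mismatch,gap_open,gap_extend scoring parameters
#'   (defaults +2/-3/-8/-1).
#' @return An object of class `pairwise_alignment`: list with
#'   `aligned_a`, `aligned_b` (gapped strings of equal length), `score`,
#'   and `column_map`, a data.frame with one row per alignment column
#'   giving 0-based offsets `pos_a`/`pos_b` (NA at gaps).
#' @export
global_align <- function(seq_a, seq_b, match = 2, mismatch = -3,
                         gap_open = -8, gap_extend = -1) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (nchar(seq_a) == 0L || nchar(seq_b) == 0L)
    abort("sequences must be non-empty")
  chk <- function(s, lab) {
    bad <- setdiff(unique(strsplit(s, "")[[1L]]), IUPAC_OK)
    if (length(bad) > 0L)
      abort("non-IUPAC character '%s' in %s", bad[1L], lab)
  }
  chk(seq_a, "seq_a"); chk(seq_b, "seq_b")
  res <- .gotoh_align(seq_a, seq_b, match, mismatch, gap_open, gap_extend)
  ca <- strsplit(res$aligned_a, "")[[1L]]
  cb <- strsplit(res$aligned_b, "")[[1L]]
  pos_a <- ifelse(ca == "-", NA_integer_, cumsum(ca != "-") - 1L)
  pos_b <- ifelse(cb == "-", NA_integer_, cumsum(cb != "-") - 1L)
  structure(list(aligned_a = res$aligned_a, aligned_b = res$aligned_b,
                 score = res$score,
                 column_map = data.frame(column = seq_along(ca),
                                         pos_a = pos_a, pos_b = pos_b)),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("Global alignment, score", x$score, "\n")
  cat(" a:", substr(x$aligned_a, 1, 60),
      if (nchar(x$aligned_a) > 60) "..." else "", "\n")
  cat(" b:", substr(x$aligned_b, 1, 60),
      if (nchar(x$aligned_b) > 60) "..." else "", "\n")
  invisible(x)
}

# degapping must reproduce the input sequences exactly
degap <- function(s) gsub("-", "", s, fixed = TRUE)
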